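#' Three-shell spherical head geometry
#'
#' Concentric brain / skull / scalp conductor with classical radii and
#' conductivities (skull-to-brain conductivity ratio 1/80).
#'
#' @param radii Shell outer radii in metres (brain, skull, scalp).
#' @param sigma Conductivities in S/m for the same compartments.
#' @return List with `radii` and `sigma`.
#' @export
head_geometry <- function(radii = c(0.087, 0.092, 0.100),
                          sigma = c(0.33, 0.0042, 0.33)) {
  stopifnot(length(radii) == 3, length(sigma) == 3, all(diff(radii) > 0),
            all(sigma > 0))
  list(radii = radii, sigma = sigma)
}

#' Standard 64-channel 10/10 montage on a spherical scalp
#'
#' Electrode positions are generated from the 10/10 construction rules on an
#' ideal sphere: rows Fp/AF/F/FC/C/CP/P/PO/O at midline inclinations of 23
#' degree steps from Cz, lateral electrodes at even fractions along the
#' great-circle arc from the midline electrode to the row's outer-ring (10%)
#' electrode, and mastoids M1/M2 below the equatorial ring. Axes: +x right,
#' +y anterior, +z up.
#'
#' @param radius Scalp radius in metres (must equal the outer shell radius of
#'   the head geometry used for the lead field).
#' @return Data frame with `name`, `x`, `y`, `z` (64 rows).
#' @export
standard_montage <- function(radius = 0.100) {
  rows <- c(Fp = 90, AF = 69, F = 46, FC = 23, C = 0,
            CP = -23, P = -46, PO = -69, O = -90)
  outer_az <- c(Fp = 18, AF = 36, F = 54, FC = 72, C = 90,
                CP = 108, P = 126, PO = 144, O = 162)
  names64 <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
               "FC5", "FC1", "FC2", "FC6", "M1", "T7", "C3", "Cz", "C4", "T8",
               "M2", "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
               "POz", "O1", "Oz", "O2", "AF7", "AF3", "AF4", "AF8",
               "F5", "F1", "F2", "F6", "FC3", "FCz", "FC4",
               "C5", "C1", "C2", "C6", "CP3", "CPz", "CP4",
               "P5", "P1", "P2", "P6", "PO5", "PO3", "PO4", "PO6",
               "FT7", "FT8", "TP7", "TP8", "PO7", "PO8")

  slerp <- function(p, q, f) {
    om <- acos(max(-1, min(1, sum(p * q))))
    if (om < 1e-12) return(p)
    (sin((1 - f) * om) * p + sin(f * om) * q) / sin(om)
  }
  deg <- pi / 180
  pos_of <- function(nm) {
    if (nm == "M1") return(c(-sin(100 * deg), 0, cos(100 * deg)))
    if (nm == "M2") return(c(sin(100 * deg), 0, cos(100 * deg)))
    # split row letters and column token
    m <- regmatches(nm, regexec("^([A-Za-z]+?)(z|[0-9]+)$", nm))[[1]]
    row <- m[2]; col <- m[3]
    # T/FT/TP are the 7/8 columns of the C/FC/CP rows
    if (row == "T") { row <- "C"; }
    if (row == "FT") { row <- "FC"; }
    if (row == "TP") { row <- "CP"; }
    a <- rows[[row]] * deg
    mid <- c(0, sin(a), cos(a))
    if (col == "z") return(mid)
    k <- as.integer(col)
    left <- k %% 2 == 1
    frac_map <- c(`1` = 0.25, `3` = 0.5, `5` = 0.75, `7` = 1)
    fr <- frac_map[[as.character(if (left) k else k - 1)]]
    if (row %in% c("Fp", "O")) fr <- 1   # Fp1/2, O1/2 sit on the outer ring
    th <- outer_az[[row]] * deg
    outer <- c(-sin(th), cos(th), 0)
    p <- slerp(mid, outer, fr)
    if (!left) p <- p * c(-1, 1, 1)
    p
  }
  xyz <- t(vapply(names64, pos_of, numeric(3))) * radius
  data.frame(name = names64, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Build a lead field for fixed-orientation dipoles
#'
#' In `"spherical"` mode, scalp potentials are the analytic series solution
#' for a current dipole inside a three-shell concentric spherical conductor:
#' per spherical-harmonic degree the radial potential profile is solved from
#' the interface conditions (continuity of potential and radial current,
#' insulating scalp surface), and the dipole source enters through its radial
#' and tangential multipole coefficients. In `"random"` mode a seeded random
#' matrix with singular values on \[1, 3\] (bounded condition number) is
#' returned, useful for protocol tests that need no physics.
#'
#' @param space A [build_source_space()] result.
#' @param montage Electrode table from [standard_montage()] (or any data frame
#'   with `name`, `x`, `y`, `z` on the scalp sphere). At least 2 electrodes.
#' @param model `"spherical"` or `"random"`.
#' @param seed Seed for `"random"` mode.
#' @param head Head geometry from [head_geometry()].
#' @param n_terms Series truncation degree for the spherical solution.
#' @return Object of class `forward_model`: list with `lead_field`
#'   (channels x sources), `channel_positions`, `channel_names`, `head`,
#'   `model`, and the `space` it was built for.
#' @export
build_lead_field <- function(space, montage = standard_montage(),
                             model = c("spherical", "random"),
                             seed = NULL, head = head_geometry(),
                             n_terms = 80L) {
  stopifnot(inherits(space, "source_space"))
  model <- match.arg(model)
  if (nrow(montage) < 2)
    stop_invalid("at least 2 channels are required")
  pos <- as.matrix(montage[, c("x", "y", "z")])
  ns <- n_sources(space)

  if (model == "random") {
    lf <- with_seed(seed %||% 1L, {
      m <- matrix(rnorm(nrow(pos) * ns), nrow(pos), ns)
      s <- svd(m)
      d <- seq(1, 3, length.out = length(s$d))
      s$u %*% (d * t(s$v))
    })
  } else {
    lf <- spherical_lead_field(pos, space$vertices, space$orientations,
                               head, n_terms)
  }
  dimnames(lf) <- list(montage$name, NULL)
  structure(list(
    lead_field = lf,
    channel_positions = pos,
    channel_names = montage$name,
    head = head,
    model = model,
    space = space
  ), class = "forward_model")
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf("<forward_model> %s: %d channels x %d sources\n",
              x$model, nrow(x$lead_field), ncol(x$lead_field)))
  invisible(x)
}

# Scalp potentials of unit-moment fixed-orientation dipoles in a 3-shell
# sphere. electrodes: m x 3 at scalp radius; dipoles: n x 3 inside the brain
# shell; orientations: n x 3 unit vectors. Returns m x n.
spherical_lead_field <- function(electrodes, dipoles, orientations, head,
                                 n_terms = 80L) {
  c_out <- head$radii[3]
  b0 <- sqrt(rowSums(dipoles^2))
  if (any(b0 >= head$radii[1]))
    stop_invalid("invalid geometry: dipole outside the brain compartment")
  edir <- electrodes / sqrt(rowSums(electrodes^2))
  if (any(abs(sqrt(rowSums(electrodes^2)) - c_out) > 1e-9 * c_out))
    stop_invalid("electrodes must lie on the scalp shell")

  Tn <- radial_transfer(n_terms, head)   # potential at scalp per unit source coef

  # dipole decomposition; a dipole at the exact centre has no radial axis --
  # only the n = 1 term survives and any axis convention gives the same field.
  rhat <- dipoles / ifelse(b0 > 0, b0, 1)
  rhat[b0 == 0, ] <- rep(c(0, 0, 1), each = sum(b0 == 0))
  qr <- rowSums(orientations * rhat)
  qt <- orientations - qr * rhat

  U <- edir %*% t(rhat)                 # cos(gamma), m x n
  Qt <- edir %*% t(qt)                  # tangential projection, m x n
  brel <- b0 / c_out

  Pprev <- matrix(1, nrow(U), ncol(U))  # P_0
  Pcur <- U                             # P_1
  dPprev <- matrix(0, nrow(U), ncol(U)) # P_0'
  dPcur <- matrix(1, nrow(U), ncol(U))  # P_1'
  V <- matrix(0, nrow(U), ncol(U))
  bpow <- rep(1, length(b0))            # brel^(n-1), n = 1 term: b^0 = 1
  for (n in seq_len(n_terms)) {
    term <- sweep(Pcur, 2, n * qr * bpow, "*") + sweep(Qt, 2, bpow, "*") * dPcur
    V <- V + Tn[n] * term
    # advance recurrences to degree n + 1
    Pnext <- ((2 * n + 1) * U * Pcur - n * Pprev) / (n + 1)
    dPnext <- dPprev + (2 * n + 1) * Pcur
    Pprev <- Pcur; Pcur <- Pnext
    dPprev <- dPcur; dPcur <- dPnext
    bpow <- bpow * brel
  }
  V / (4 * pi * head$sigma[1] * c_out^2)
}

# Per-degree radial transfer factors T_n: scalp-surface potential of the
# harmonic-n source term with unit coefficient, radii normalised to the scalp
# radius. Solved from the 5 interface/boundary conditions (unknowns: regular
# part in brain, both parts in skull and scalp).
radial_transfer <- function(n_terms, head) {
  a <- head$radii[1] / head$radii[3]
  b <- head$radii[2] / head$radii[3]
  s1 <- head$sigma[1]; s2 <- head$sigma[2]; s3 <- head$sigma[3]
  vapply(seq_len(n_terms), function(n) {
    np1 <- n + 1
    # unknowns: A1, A2, B2, A3, B3
    M <- rbind(
      c(a^n, -a^n, -a^(-np1), 0, 0),
      c(s1 * n * a^(n - 1), -s2 * n * a^(n - 1), s2 * np1 * a^(-n - 2), 0, 0),
      c(0, b^n, b^(-np1), -b^n, -b^(-np1)),
      c(0, s2 * n * b^(n - 1), -s2 * np1 * b^(-n - 2),
        -s3 * n * b^(n - 1), s3 * np1 * b^(-n - 2)),
      c(0, 0, 0, n, -np1)
    )
    rhs <- c(-a^(-np1), s1 * np1 * a^(-n - 2), 0, 0, 0)
    x <- solve(M, rhs)
    x[4] + x[5]   # A3 * 1^n + B3 * 1^-(n+1)
  }, numeric(1))
}
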