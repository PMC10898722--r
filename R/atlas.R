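#' The 34 cortical region names of the Desikan-Killiany parcellation
#'
#' Returned per hemisphere; the full atlas therefore has 68 regions.
#' @return Character vector of length 34.
#' @export
dk_region_names <- function() {
  c("bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
    "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
    "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
    "precentral", "precuneus", "rostralanteriorcingulate",
    "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
    "superiortemporal", "supramarginal", "temporalpole", "transversetemporal")
}

#' The six pleasantness regions of interest
#'
#' Rostral anterior cingulate, medial orbitofrontal and lateral orbitofrontal
#' cortex in both hemispheres: the regions whose activity tracks the
#' instantaneous pleasantness of thermal stimuli and whose band powers form
#' the classification features.
#'
#' @return Character vector of six region labels (`<name>_lh` / `<name>_rh`).
#' @export
pleasantness_rois <- function() {
  base <- c("rostralanteriorcingulate", "medialorbitofrontal",
            "lateralorbitofrontal")
  as.vector(t(outer(base, c("lh", "rh"), paste, sep = "_")))
}

# Canonical seed directions (unit vectors in hemisphere-local coordinates,
# +x = medial for the left hemisphere, +y = anterior, +z = superior) for the
# regions whose placement matters downstream: the three frontal ROIs and the
# superiorparietal region used as the default velocity-confound site. The
# remaining 30 seeds per hemisphere are drawn uniformly on the sphere from
# the atlas seed.
canonical_seed_dirs <- function() {
  d <- rbind(
    rostralanteriorcingulate = c(0.80, 0.55, 0.25),
    medialorbitofrontal      = c(0.50, 0.72, -0.48),
    lateralorbitofrontal     = c(-0.55, 0.70, -0.45),
    superiorparietal         = c(-0.30, -0.70, 0.65)
  )
  d / sqrt(rowSums(d^2))
}

#' Partition a source space into a surrogate 68-region parcellation
#'
#' A nearest-seed (Voronoi) partition on each hemispheric shell stands in for
#' the Desikan-Killiany atlas: 34 seed directions per hemisphere (the three
#' pleasantness ROIs and the superiorparietal confound site at fixed canonical
#' frontal-inferior/parietal coordinates, the other 30 drawn uniformly from
#' `seed`) claim the vertices nearest to them in great-circle distance.
#' Region labels are `<dk name>_lh` / `<dk name>_rh`. On coarse spaces a
#' canonical region whose Voronoi cell is empty is guaranteed non-empty by
#' reassigning its single closest vertex.
#'
#' @param space A [build_source_space()] result.
#' @param seed Integer seed fixing the 30 non-canonical seed directions.
#' @return Object of class `atlas`: list with `label_of_vertex` (factor,
#'   length = total vertices, 68 levels), `region_names` (68), `seed`.
#' @export
build_atlas <- function(space, seed = 1L) {
  stopifnot(inherits(space, "source_space"))
  names34 <- dk_region_names()
  nv_hemi <- sum(space$hemisphere == "left")
  if (nv_hemi < length(names34))
    stop_invalid("source space has fewer vertices per hemisphere (", nv_hemi,
                 ") than atlas regions (34); use a finer subdivision level")

  canon <- canonical_seed_dirs()
  free_names <- setdiff(names34, rownames(canon))
  region_names <- as.vector(vapply(c("lh", "rh"), function(h)
    paste(names34, h, sep = "_"), character(34)))

  labels <- character(nrow(space$vertices))
  for (h in c("left", "right")) {
    suffix <- if (h == "left") "lh" else "rh"
    idx <- which(space$hemisphere == h)
    center <- space$centers[if (h == "left") 1 else 2, ]
    # unit directions of this hemisphere's vertices about its own centre
    dirs <- sweep(space$vertices[idx, , drop = FALSE], 2, center, "-")
    dirs <- dirs / sqrt(rowSums(dirs^2))

    seeds <- matrix(NA_real_, 34, 3,
                    dimnames = list(names34, NULL))
    cn <- canon
    if (h == "right") cn[, 1] <- -cn[, 1]   # mirror medial axis
    seeds[rownames(cn), ] <- cn
    rnd <- with_seed(child_seed(seed, if (h == "left") 1 else 2), {
      m <- matrix(rnorm(length(free_names) * 3), ncol = 3)
      m / sqrt(rowSums(m^2))
    })
    seeds[free_names, ] <- rnd

    # nearest seed by great-circle distance = max cosine
    cosang <- dirs %*% t(seeds)
    assign_idx <- max.col(cosang, ties.method = "first")
    lab <- names34[assign_idx]

    # guarantee the canonical regions are non-empty
    for (rn in rownames(canon)) {
      if (!any(lab == rn)) {
        best <- which.max(cosang[, match(rn, names34)])
        lab[best] <- rn
      }
    }
    labels[idx] <- paste(lab, suffix, sep = "_")
  }
  structure(list(
    label_of_vertex = factor(labels, levels = region_names),
    region_names = region_names,
    seed = seed
  ), class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  nz <- sum(table(x$label_of_vertex) > 0)
  cat(sprintf("<atlas> 68 regions (%d non-empty) over %d vertices\n",
              nz, length(x$label_of_vertex)))
  invisible(x)
}

# Integer vertex indices of a named region; error if unknown.
region_vertices <- function(atlas, region) {
  if (!region %in% atlas$region_names)
    stop_invalid("unknown region: ", region)
  which(atlas$label_of_vertex == region)
}
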