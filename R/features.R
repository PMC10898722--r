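# Welch band-power features: PSD estimation, ROI aggregation, band averages,
# and the 24-column log band-power feature table.

#' Frequency bands (Hz, inclusive integer bins)
#' @return Named list of c(lo, hi) band edges: theta 4-7, alpha 8-13,
#'   beta 14-30, gamma 31-45.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 13), beta = c(14, 30), gamma = c(31, 45))
}

#' Welch power spectral density
#'
#' Mean of modified periodograms over 50%-overlapping Hann-windowed segments
#' (window 512 samples = 1 s at 512 Hz, hop 256), one-sided density scaling:
#' `sum(psd) * df` equals the signal variance (up to window edge effects).
#' With the defaults the frequency bin spacing is exactly 1 Hz.
#'
#' @param x Numeric vector, or samples x signals matrix (each column a
#'   signal; all columns share the segmentation and one FFT call per
#'   segment).
#' @param fs Sampling frequency (Hz).
#' @param win Segment length in samples.
#' @param overlap Segment overlap in samples.
#' @return List with `freq` (Hz, length `win/2 + 1`) and `psd` (density,
#'   matrix bins x signals, or a vector if `x` was a vector).
#' @export
welch_psd <- function(x, fs = 512, win = 512, overlap = 256) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < win)
    stop_invalid("signal length (", n, ") is below the window length (", win, ")")
  step <- win - overlap
  nseg <- (n - win) %/% step + 1L
  w <- 0.5 * (1 - cos(2 * pi * seq_len(win) / win))  # periodic Hann
  scale <- 2 / (fs * sum(w^2))
  nb <- win %/% 2 + 1L
  acc <- matrix(0, nb, ncol(x))
  for (s in seq_len(nseg)) {
    idx <- (s - 1L) * step + seq_len(win)
    seg <- x[idx, , drop = FALSE] * w
    sp <- mvfft(seg)[seq_len(nb), , drop = FALSE]
    acc <- acc + Re(sp)^2 + Im(sp)^2
  }
  psd <- acc * (scale / nseg)
  psd[1, ] <- psd[1, ] / 2                 # DC not doubled
  psd[nb, ] <- psd[nb, ] / 2               # Nyquist not doubled
  freq <- (seq_len(nb) - 1L) * fs / win
  if (vec) psd <- psd[, 1]
  list(freq = freq, psd = psd)
}

#' Average vertex powers into atlas regions
#'
#' Unweighted mean over the member vertices of each requested region,
#' independently per frequency bin.
#'
#' @param vertex_powers Vertices x bins matrix (or vertices vector).
#' @param atlas An `atlas` labelling every vertex.
#' @param regions Regions to aggregate (default: all 68).
#' @return Regions x bins matrix with region row names.
#' @export
aggregate_rois <- function(vertex_powers, atlas,
                           regions = atlas$region_names) {
  vp <- if (is.null(dim(vertex_powers))) cbind(vertex_powers) else vertex_powers
  if (nrow(vp) != length(atlas$label_of_vertex))
    stop_invalid("vertex count does not match the atlas")
  out <- matrix(NA_real_, length(regions), ncol(vp),
                dimnames = list(regions, NULL))
  for (r in regions) {
    idx <- region_vertices(atlas, r)
    if (length(idx) == 0)
      stop_invalid("undefined region: '", r, "' has no member vertices")
    out[r, ] <- colMeans(vp[idx, , drop = FALSE])
  }
  out
}

#' Average 1-Hz PSD bins into canonical bands
#'
#' Inclusive integer-bin averages: theta over 4..7 Hz, alpha 8..13, beta
#' 14..30, gamma 31..45 (4, 6, 17 and 15 bins).
#'
#' @param region_powers Regions x bins matrix from [aggregate_rois()] (or any
#'   rows x bins matrix).
#' @param freq Bin frequencies (Hz) matching the columns.
#' @return Regions x 4 matrix with band column names.
#' @export
band_powers <- function(region_powers, freq) {
  rp <- if (is.null(dim(region_powers))) rbind(region_powers) else region_powers
  bands <- eeg_bands()
  if (max(freq) < 45 || min(freq) > 4)
    stop_invalid("frequency bins must cover 4-45 Hz")
  out <- vapply(bands, function(b) {
    idx <- which(freq >= b[1] & freq <= b[2])
    if (length(idx) == 0) stop_invalid("no bins inside band")
    rowMeans(rp[, idx, drop = FALSE])
  }, numeric(nrow(rp)))
  out <- matrix(out, nrow = nrow(rp),
                dimnames = list(rownames(rp), names(bands)))
  out
}

#' Feature column names in their fixed order
#'
#' Order: for each ROI (rostral ACC, medial OFC, lateral OFC; left before
#' right), the four bands theta, alpha, beta, gamma.
#' @return Character vector of 24 names `<roi>_<band>`.
#' @export
feature_columns <- function() {
  as.vector(vapply(pleasantness_rois(), function(r)
    paste(r, names(eeg_bands()), sep = "_"), character(4)))
}

#' Assemble the trials x 24 log band-power feature table
#'
#' Natural-log-transformed band powers of the six pleasantness ROIs, one row
#' per retained trial, with velocity and score metadata joined.
#'
#' @param roi_band_powers Trials-long list of ROI x band matrices, or an
#'   array trials x ROIs x bands (ROI order as [pleasantness_rois()]).
#' @param meta Data frame with one row per trial (`velocity`, `score`).
#' @return Object of class `feature_table` (a data frame): 24 feature columns
#'   in [feature_columns()] order plus `velocity` and `score`.
#' @export
build_feature_table <- function(roi_band_powers, meta) {
  if (is.list(roi_band_powers))
    roi_band_powers <- simplify2array(roi_band_powers)  # roi x band x trials
  if (length(dim(roi_band_powers)) != 3)
    stop_invalid("expected one ROI x band matrix per trial")
  nt <- dim(roi_band_powers)[3]
  if (nrow(meta) != nt)
    stop_invalid("metadata row count does not match trial count")
  if (any(!is.finite(roi_band_powers)) || any(roi_band_powers <= 0))
    stop_invalid("numerical error: non-positive band power (upstream bug)")
  X <- t(apply(log(roi_band_powers), 3, function(m) as.vector(t(m))))
  colnames(X) <- feature_columns()
  out <- cbind(as.data.frame(X), velocity = meta$velocity, score = meta$score)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Extract the feature table from preprocessed epochs
#'
#' Convenience pipeline stage: applies the inverse operator trial by trial
#' (with channel-EEG baseline correction), estimates each vertex's Welch PSD
#' over the analysis window, averages power over the vertices of the six
#' pleasantness ROIs and over the four canonical bands, and log-transforms.
#'
#' @param analysis,baseline `epoch_segments` from [crop_analysis_window()].
#' @param operator An `inverse_operator`.
#' @param atlas The `atlas` of the operator's source space.
#' @param rois Region labels to use (default the six pleasantness ROIs).
#' @return A `feature_table`.
#' @export
extract_features <- function(analysis, operator, atlas, baseline = NULL,
                             rois = pleasantness_rois()) {
  d <- dim(analysis$data)
  nt <- d[3]
  roi_idx <- lapply(rois, function(r) region_vertices(atlas, r))
  vlist <- sort(unique(unlist(roi_idx)))
  K <- operator$kernel[vlist, , drop = FALSE]
  roi_local <- lapply(roi_idx, function(i) match(i, vlist))
  bands <- eeg_bands()
  out <- vector("list", nt)
  for (i in seq_len(nt)) {
    x <- analysis$data[, , i]
    if (!is.null(baseline))
      x <- x - rowMeans(baseline$data[, , i])
    src <- K %*% x
    ps <- welch_psd(t(src), fs = analysis$fs)
    region <- t(vapply(roi_local, function(j)
      rowMeans(ps$psd[, j, drop = FALSE]), numeric(nrow(ps$psd))))
    rownames(region) <- rois
    out[[i]] <- band_powers(region, ps$freq)
  }
  build_feature_table(out, analysis$meta)
}
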