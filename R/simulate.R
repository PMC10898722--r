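#' Simulate a continuous synthetic EEG recording of the wind experiment
#'
#' Generates one participant's full three-session recording at 512 Hz. Each
#' 18 s trial is 2 s rest, 10 s wind and 6 s report. Source activity has
#' three components: (i) a band-limited oscillatory carrier (default alpha,
#' 8-13 Hz) coherent across the vertices of each of the six pleasantness
#' ROIs, active during the wind period with amplitude
#' `roi_amplitude * (1 + effect_beta * (score - 5))`; (ii) a velocity-keyed
#' band-limited oscillation (default beta band) of amplitude
#' `confound_gamma * velocity` in a designated non-ROI region of both
#' hemispheres; and (iii) 1/f background noise at every vertex. Source
#' activity is synthesised over a 13 s task window per trial (rest + wind +
#' 1 s, cosine-ramped); the reporting period carries no simulated EEG.
#' Sensor data are `lead field x sources` plus white sensor noise; the lead
#' field is rescaled so that the background alone produces an average
#' channel RMS of 7 microvolts (resting-EEG scale, which also keeps clean
#' epochs below the default artifact-rejection threshold), and source
#' amplitudes are expressed in units of the per-vertex background RMS.
#'
#' @param schedule A [make_trial_schedule()] result.
#' @param profile A [participant_profile()].
#' @param forward A [build_lead_field()] result consistent with `space`.
#' @param atlas A [build_atlas()] result for `space`.
#' @param space The [build_source_space()] used for `forward` and `atlas`.
#' @param seed Integer seed; defaults to `profile$seed`.
#' @param eog If `TRUE`, add a synthetic slow ocular signal with a frontal
#'   topography and store its reference trace in the result.
#' @return Object of class `eeg_recording`: list with `data` (channels x
#'   samples, microvolts), `fs` (512), `events` (data frame: `sample`,
#'   `kind` in wind_on/wind_off/report, `velocity`, `score`), `channel_names`,
#'   `schedule`, `profile`, and optionally `eog`.
#' @export
simulate_recording <- function(schedule, profile, forward, atlas, space,
                               seed = NULL, eog = FALSE) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(profile, "participant_profile"),
            inherits(forward, "forward_model"),
            inherits(atlas, "atlas"),
            inherits(space, "source_space"))
  if (ncol(forward$lead_field) != n_sources(space) ||
      length(atlas$label_of_vertex) != n_sources(space))
    stop_invalid("forward model / atlas / source space dimensions disagree")
  if (profile$roi_amplitude < 0 || profile$confound_gamma < 0)
    stop_invalid("amplitudes must be non-negative")
  seed <- seed %||% profile$seed

  fs <- 512L
  rest_s <- 2L; wind_s <- 10L; report_s <- 6L
  trial_len <- (rest_s + wind_s + report_s) * fs        # 9216
  pad <- 8L * fs %/% 2L                                  # 4 s lead-in/out
  n_trials <- nrow(schedule)
  n_total <- 2L * pad + n_trials * trial_len
  n_chan <- nrow(forward$lead_field)

  # Rescale the lead field so the unit-RMS 1/f background at every vertex
  # produces an average channel RMS of 7 microvolts (resting-EEG scale,
  # chosen so that clean epochs stay below the 150 uV peak-to-peak artifact
  # threshold by construction); all source amplitudes are expressed in units
  # of the per-vertex background RMS.
  G0 <- forward$lead_field
  Gn <- G0 * (7 / sqrt(mean(rowSums(G0^2))))

  rois <- pleasantness_rois()
  roi_verts <- lapply(rois, function(r) region_vertices(atlas, r))
  conf_regions <- paste(profile$confound_region, c("lh", "rh"), sep = "_")
  conf_verts <- lapply(conf_regions, function(r) region_vertices(atlas, r))
  # summed lead-field column per coherent patch
  g_roi <- vapply(roi_verts, function(v)
    rowSums(Gn[, v, drop = FALSE]), numeric(n_chan))
  g_conf <- vapply(conf_verts, function(v)
    rowSums(Gn[, v, drop = FALSE]), numeric(n_chan))

  trial_start <- pad + (seq_len(n_trials) - 1L) * trial_len + 1L
  wind_on <- trial_start + rest_s * fs
  wind_off <- wind_on + wind_s * fs
  wind_len <- wind_s * fs

  with_seed(seed, {
    scores <- sample_pleasantness(schedule$velocity, profile)

    data <- matrix(0, n_chan, n_total)

    # Source activity is synthesised for the task window of each trial
    # (rest + wind + 1 s, i.e. 13 s of the 18 s trial clock) with half-second
    # cosine ramps; report periods carry no simulated EEG (a stated
    # non-goal), so the background needs no cross-trial stitching.
    task_len <- 13L * fs
    edge <- fs %/% 2L
    taskwin <- ramp_window(task_len, edge)
    nsrc <- n_sources(space)

    # The projected background `Gn %*% s` with s iid unit-RMS 1/f noise at
    # every vertex is a Gaussian field with spatial covariance Gn Gn'; it is
    # generated directly at the sensors through the exact linear-transform
    # identity x = chol(Gn Gn')' e with e iid 1/f channels -- the same
    # distribution at half the cost.
    A_bg <- t(chol(tcrossprod(Gn) +
                     diag(1e-10 * mean(diag(tcrossprod(Gn))), n_chan)))
    block <- 12L                               # trials per generation block
    n_block <- ceiling(n_trials / block)
    for (bi in seq_len(n_block)) {
      tr <- ((bi - 1L) * block + 1L):min(bi * block, n_trials)
      Lgen <- stats::nextn(task_len * length(tr), c(2, 3))
      bg <- spectral_noise(Lgen, n_chan, fs, shape = "pink")
      for (k in seq_along(tr)) {
        t <- tr[k]
        rows <- (k - 1L) * task_len + seq_len(task_len)
        y <- A_bg %*% t(bg[rows, , drop = FALSE])
        y <- y * rep(taskwin, each = n_chan)
        if (profile$sensor_noise_sd > 0)
          y <- y + profile$sensor_noise_sd * matrix(rnorm(n_chan * task_len), n_chan)
        cols <- trial_start[t]:(trial_start[t] + task_len - 1L)
        data[, cols] <- y
      }
    }

    # --- wind-locked oscillatory sources ----------------------------------
    wind_cols_of <- function(t) wind_on[t]:(wind_off[t] - 1L)
    ramp <- ramp_window(wind_len, fs %/% 4L)   # 0.25 s cosine ramps
    drv_all <- spectral_noise(wind_len, length(rois) * n_trials, fs,
                              shape = "band", band = profile$signal_band)
    drvc_all <- spectral_noise(wind_len, length(conf_regions) * n_trials, fs,
                               shape = "band", band = profile$confound_band)
    for (t in seq_len(n_trials)) {
      amp_sig <- profile$roi_amplitude *
        (1 + profile$effect_beta * (scores[t] - 5))
      if (amp_sig < 0) amp_sig <- 0
      cols <- wind_cols_of(t)
      if (amp_sig > 0) {
        drv <- drv_all[, (t - 1L) * length(rois) + seq_along(rois),
                       drop = FALSE]
        data[, cols] <- data[, cols] + (g_roi %*% t(drv * ramp)) * amp_sig
      }
      amp_conf <- profile$confound_gamma * schedule$velocity[t]
      if (amp_conf > 0) {
        drvc <- drvc_all[, (t - 1L) * length(conf_regions) +
                           seq_along(conf_regions), drop = FALSE]
        data[, cols] <- data[, cols] + (g_conf %*% t(drvc * ramp)) * amp_conf
      }
    }

    eog_trace <- NULL
    if (isTRUE(eog)) {
      eog_trace <- 50 * spectral_noise(n_total, 1L, fs, shape = "lowpass",
                                       band = c(0, 4))[, 1]
      topo <- pmax(forward$channel_positions[, 2], 0)  # frontal weighting
      topo <- topo / max(topo)
      data <- data + outer(topo, eog_trace)
    }

    events <- data.frame(
      sample = as.integer(rbind(wind_on, wind_off, wind_off + fs %/% 2L)),
      kind = rep(c("wind_on", "wind_off", "report"), n_trials),
      velocity = rep(schedule$velocity, each = 3L),
      score = rep(scores, each = 3L)
    )

    rec <- list(data = data, fs = fs, events = events,
                channel_names = forward$channel_names,
                channel_positions = forward$channel_positions,
                schedule = schedule, profile = profile,
                active_windows = cbind(start = trial_start,
                                       end = trial_start + task_len - 1L))
    if (!is.null(eog_trace)) rec$eog <- eog_trace
    class(rec) <- "eeg_recording"
    rec
  })
}

#' Simulate band-pass-filtered analysis epochs directly
#'
#' Fused fast path for cohort simulation: generates the same trial windows
#' as [simulate_recording()] (identical random-number stream), applies the
#' zero-phase band-pass to each 13 s task window, and slices the -1..10 s
#' epochs -- without materialising the full continuous recording. The
#' result is byte-identical to
#' `extract_epochs(bandpass_filter(simulate_recording(...)))`.
#'
#' @inheritParams simulate_recording
#' @param hp,lp Band-pass cutoffs passed to the filter stage.
#' @return An `epoch_set` (already filtered; still needs bad-channel
#'   handling, rejection, re-referencing and cropping).
#' @export
simulate_epochs <- function(schedule, profile, forward, atlas, space,
                            seed = NULL, hp = 0.5, lp = 45) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(profile, "participant_profile"),
            inherits(forward, "forward_model"))
  seed <- seed %||% profile$seed
  fs <- 512L
  rest_s <- 2L; wind_s <- 10L; report_s <- 6L
  trial_len <- (rest_s + wind_s + report_s) * fs
  pad <- 8L * fs %/% 2L
  n_trials <- nrow(schedule)
  n_chan <- nrow(forward$lead_field)

  G0 <- forward$lead_field
  Gn <- G0 * (7 / sqrt(mean(rowSums(G0^2))))
  rois <- pleasantness_rois()
  conf_regions <- paste(profile$confound_region, c("lh", "rh"), sep = "_")
  g_roi <- vapply(lapply(rois, function(r) region_vertices(atlas, r)),
                  function(v) rowSums(Gn[, v, drop = FALSE]), numeric(n_chan))
  g_conf <- vapply(lapply(conf_regions, function(r) region_vertices(atlas, r)),
                   function(v) rowSums(Gn[, v, drop = FALSE]), numeric(n_chan))

  trial_start <- pad + (seq_len(n_trials) - 1L) * trial_len + 1L
  wind_on <- trial_start + rest_s * fs
  wind_len <- wind_s * fs
  task_len <- 13L * fs
  edge <- fs %/% 2L
  taskwin <- ramp_window(task_len, edge)
  # sample positions inside the task window
  wind_rel <- rest_s * fs + seq_len(wind_len)           # wind period
  epoch_rel <- (rest_s * fs - fs) + seq_len(11L * fs)   # -1 .. 10 s

  with_seed(seed, {
    scores <- sample_pleasantness(schedule$velocity, profile)
    task <- array(0, c(n_chan, task_len, n_trials))

    A_bg <- t(chol(tcrossprod(Gn) +
                     diag(1e-10 * mean(diag(tcrossprod(Gn))), n_chan)))
    block <- 12L
    n_block <- ceiling(n_trials / block)
    for (bi in seq_len(n_block)) {
      tr <- ((bi - 1L) * block + 1L):min(bi * block, n_trials)
      Lgen <- stats::nextn(task_len * length(tr), c(2, 3))
      bg <- spectral_noise(Lgen, n_chan, fs, shape = "pink")
      for (k in seq_along(tr)) {
        rows <- (k - 1L) * task_len + seq_len(task_len)
        y <- A_bg %*% t(bg[rows, , drop = FALSE])
        y <- y * rep(taskwin, each = n_chan)
        if (profile$sensor_noise_sd > 0)
          y <- y + profile$sensor_noise_sd * matrix(rnorm(n_chan * task_len), n_chan)
        task[, , tr[k]] <- y
      }
    }

    ramp <- ramp_window(wind_len, fs %/% 4L)
    drv_all <- spectral_noise(wind_len, length(rois) * n_trials, fs,
                              shape = "band", band = profile$signal_band)
    drvc_all <- spectral_noise(wind_len, length(conf_regions) * n_trials, fs,
                               shape = "band", band = profile$confound_band)
    for (t in seq_len(n_trials)) {
      amp_sig <- profile$roi_amplitude *
        (1 + profile$effect_beta * (scores[t] - 5))
      if (amp_sig < 0) amp_sig <- 0
      if (amp_sig > 0) {
        drv <- drv_all[, (t - 1L) * length(rois) + seq_along(rois),
                       drop = FALSE]
        task[, wind_rel, t] <- task[, wind_rel, t] +
          (g_roi %*% t(drv * ramp)) * amp_sig
      }
      amp_conf <- profile$confound_gamma * schedule$velocity[t]
      if (amp_conf > 0) {
        drvc <- drvc_all[, (t - 1L) * length(conf_regions) +
                           seq_along(conf_regions), drop = FALSE]
        task[, wind_rel, t] <- task[, wind_rel, t] +
          (g_conf %*% t(drvc * ramp)) * amp_conf
      }
    }

    data <- fft_bandpass_epochs(task, fs, hp, lp, 4, 10, epoch_rel)

    structure(list(
      data = data,
      meta = data.frame(trial = seq_len(n_trials),
                        velocity = schedule$velocity, score = scores,
                        onset_sample = wind_on, rejected = FALSE),
      fs = fs, tmin = -1,
      channel_names = forward$channel_names,
      channel_positions = forward$channel_positions,
      bad_channels = character(0),
      eog = NULL
    ), class = "epoch_set")
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples (%.1f min at %d Hz), %d events\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs / 60, x$fs,
              nrow(x$events)))
  invisible(x)
}

# Unit-RMS Gaussian noise with a prescribed amplitude spectrum, generated in
# the frequency domain. shape: "pink" (power ~ 1/f above f_floor, flat
# below), "band" (flat inside `band`, zero outside), "lowpass" (flat up to
# band[2]). Returns an L x nsig matrix.
#
# Each column pair shares one complex inverse FFT: with a symmetric
# amplitude profile and iid circular complex Gaussian spectra, the real and
# imaginary parts of the synthesis are two independent real signals with the
# prescribed spectrum.
spectral_noise <- function(L, nsig, fs, shape = c("pink", "band", "lowpass"),
                           band = NULL, f_floor = 0.5) {
  shape <- match.arg(shape)
  half <- pmin(0:(L - 1), L - (0:(L - 1)))   # mirrored bin index
  f <- half * fs / L
  amp <- switch(shape,
    pink = 1 / sqrt(pmax(f, f_floor)),
    band = as.numeric(f >= band[1] & f <= band[2]),
    lowpass = as.numeric(f <= band[2]))
  amp[1] <- 0                                 # no DC
  nc <- (nsig + 1L) %/% 2L
  X <- complex(real = rnorm(L * nc), imaginary = rnorm(L * nc))
  X <- X * amp                      # amp (length L) recycles down columns
  dim(X) <- c(L, nc)
  z <- mvfft(X, inverse = TRUE)
  s <- 1 / sqrt(sum(amp^2))
  out <- matrix(0, L, nsig)
  re_cols <- seq_len((nsig + 1L) %/% 2L)
  out[, 2L * re_cols - 1L] <- Re(z[, re_cols, drop = FALSE]) * s
  im_cols <- seq_len(nsig %/% 2L)
  if (length(im_cols))
    out[, 2L * im_cols] <- Im(z[, im_cols, drop = FALSE]) * s
  out
}

# Unit-amplitude window with raised-cosine on/off ramps.
ramp_window <- function(n, ramp) {
  w <- rep(1, n)
  up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
  w[seq_len(ramp)] <- up
  w[n + 1 - seq_len(ramp)] <- up
  w
}
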