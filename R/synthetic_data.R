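#' Block-design task timing
#'
#' Builds the sampled task design: `n_trials` repetitions of `task_s`
#' seconds of task followed by `rest_s` seconds of rest, preceded by a
#' lead-in rest of `lead_in_s` seconds.  The boxcar (task function) is 1
#' exactly during `[onset, onset + task_s)` and 0 otherwise.  The
#' fundamental response frequency of the design is
#' `1 / (task_s + rest_s)` (0.04 Hz for the default 10 s + 15 s blocks).
#' Record length is floored to whole samples.
#'
#' @param n_trials number of trials (>= 1).
#' @param task_s,rest_s task and rest durations in seconds.
#' @param fs sampling rate in Hz.
#' @param lead_in_s rest before the first trial (default one rest period).
#' @return an object of class `task_design`: list with `n_trials`,
#'   `task_s`, `rest_s`, `fs`, `onsets` (seconds), `time` (seconds),
#'   `boxcar` (0/1 vector) and `block_freq_hz`.
#' @export
make_design <- function(n_trials = 20, task_s = 10, rest_s = 15, fs = 7.14,
                        lead_in_s = rest_s) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (task_s <= 0 || rest_s <= 0 || fs <= 0 || lead_in_s < 0)
    stop("durations and sampling rate must be positive")
  period <- task_s + rest_s
  onsets <- lead_in_s + (seq_len(n_trials) - 1) * period
  duration <- lead_in_s + n_trials * period
  n <- floor(duration * fs)
  time <- (seq_len(n) - 1) / fs
  boxcar <- numeric(n)
  for (on in onsets) boxcar[time >= on & time < on + task_s] <- 1
  structure(
    list(n_trials = n_trials, task_s = task_s, rest_s = rest_s, fs = fs,
         lead_in_s = lead_in_s, onsets = onsets, time = time,
         boxcar = boxcar, block_freq_hz = 1 / period),
    class = "task_design"
  )
}

#' Parameters of the shared systemic interference model
#'
#' The systemic signal shared across channels is a sum of four sinusoidal
#' components with frequencies drawn inside the physiological bands:
#' cardiac pulsation 1-2 Hz, respiration 0.2-0.4 Hz, Mayer waves near
#' 0.1 Hz and very-low-frequency (VLF) fluctuations 0.01-0.05 Hz.  Phases
#' are random per realisation.
#'
#' An optional fifth component (`task_locked_amp > 0`) is a slow sinusoid
#' *entrained to the task*: its frequency is the block frequency of the
#' design (0.04 Hz for 10 s + 15 s blocks, squarely inside the VLF band)
#' and its peak trails each task onset by `task_locked_lag_s` seconds plus
#' a per-realisation jitter.  It emulates task-evoked systemic activity
#' (blood-pressure / autonomic responses entrained by the block rhythm) -
#' the stress case in which a slow systemic oscillation masquerades as
#' activation across a whole group.  A free-running oscillation with
#' random phase averages out over subjects and cannot bias a group
#' t-test, which is why the stress component must be task-locked.
#'
#' Amplitudes are in the same (arbitrary, pathlength-scaled) units as the
#' hemodynamic response; the defaults make the slow systemic components
#' comparable in amplitude to a unit response.
#'
#' @param cardiac_band,respiration_band,mayer_band,vlf_band frequency bands
#'   in Hz.
#' @param cardiac_amp,respiration_amp,mayer_amp,vlf_amp amplitudes.
#' @param task_locked_amp amplitude of the task-entrained slow component
#'   (default 0: absent).
#' @param task_locked_lag_s lag of the entrained component's peak after
#'   each task onset.
#' @param task_locked_jitter_s SD (seconds) of the per-realisation jitter
#'   of that lag.
#' @param coupling_gain_range range of the per-channel multipliers applied
#'   to the shared signal.
#' @return list of class `systemic_params`.
#' @export
systemic_params <- function(cardiac_band = c(1, 2), cardiac_amp = 0.4,
                            respiration_band = c(0.2, 0.4),
                            respiration_amp = 0.4,
                            mayer_band = c(0.08, 0.12), mayer_amp = 1,
                            vlf_band = c(0.01, 0.05), vlf_amp = 1,
                            task_locked_amp = 0,
                            task_locked_lag_s = 8,
                            task_locked_jitter_s = 2,
                            coupling_gain_range = c(0.4, 1.2)) {
  structure(
    list(
      bands = list(cardiac = cardiac_band, respiration = respiration_band,
                   mayer = mayer_band, vlf = vlf_band),
      amps = c(cardiac = cardiac_amp, respiration = respiration_amp,
               mayer = mayer_amp, vlf = vlf_amp),
      task_locked_amp = task_locked_amp,
      task_locked_lag_s = task_locked_lag_s,
      task_locked_jitter_s = task_locked_jitter_s,
      coupling_gain_range = coupling_gain_range
    ),
    class = "systemic_params"
  )
}

#' Simulate the shared systemic interference series
#'
#' @param params a [systemic_params()] object.
#' @param n_samples length of the series.
#' @param fs sampling rate in Hz.
#' @param seed optional integer seed; if `NULL` the current RNG state is
#'   used (identical seed gives an identical series).
#' @param design optional [make_design()] object, required when
#'   `params$task_locked_amp > 0` so the entrained component can take the
#'   block frequency and reference its phase to the first task onset.
#' @return numeric vector with attribute `components` (data.frame of drawn
#'   component frequency, amplitude and phase).
#' @export
simulate_systemic <- function(params, n_samples, fs, seed = NULL,
                              design = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- (seq_len(n_samples) - 1) / fs
  comp <- data.frame(component = names(params$bands), freq = NA_real_,
                     amp = unname(params$amps), phase = NA_real_)
  s <- numeric(n_samples)
  for (i in seq_len(nrow(comp))) {
    b <- params$bands[[comp$component[i]]]
    f <- stats::runif(1, b[1], b[2])
    ph <- stats::runif(1, 0, 2 * pi)
    comp$freq[i] <- f
    comp$phase[i] <- ph
    s <- s + comp$amp[i] * sin(2 * pi * f * t + ph)
  }
  if (params$task_locked_amp > 0) {
    if (is.null(design))
      stop("a task design is required for a task-locked systemic component")
    f <- design$block_freq_hz
    lag <- params$task_locked_lag_s +
      stats::rnorm(1, 0, params$task_locked_jitter_s)
    # peak of the sinusoid placed `lag` seconds after each onset
    ph <- pi / 2 - 2 * pi * f * (design$onsets[1] + lag)
    comp <- rbind(comp, data.frame(component = "task_locked", freq = f,
                                   amp = params$task_locked_amp,
                                   phase = ph))
    s <- s + params$task_locked_amp * sin(2 * pi * f * t + ph)
  }
  attr(s, "components") <- comp
  s
}

#' Ground-truth specification for a simulated recording
#'
#' @param layout a `probe_layout`.
#' @param active_channels channel ids carrying a hemodynamic response.
#' @param response_amplitude peak response amplitude (signal units) in the
#'   active channels; may be a single value or one per active channel.
#' @param noise_sd white measurement noise SD per channel (recycled).
#' @param pathlength_range range of the unknown per-channel pathlength
#'   factor L (drawn uniformly; L > 0).
#' @param local_vlf_amp amplitude scale of the per-channel (uncoupled) slow
#'   physiological oscillation; channel amplitudes are drawn uniformly in
#'   `[0.5, 1.5] * local_vlf_amp`.
#' @param drift_sd SD of the random per-channel quadratic drift
#'   coefficients.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(layout, active_channels = integer(0),
                         response_amplitude = 1, noise_sd = 0.3,
                         pathlength_range = c(0.5, 2), local_vlf_amp = 1,
                         drift_sd = 0.5) {
  nc <- nrow(layout$channels)
  amp <- numeric(nc)
  amp[active_channels] <- response_amplitude
  structure(
    list(active_channels = as.integer(active_channels),
         amplitudes = amp,
         noise_sd = rep_len(noise_sd, nc),
         pathlength_range = pathlength_range,
         local_vlf_amp = local_vlf_amp,
         drift_sd = drift_sd,
         hrf = "double-gamma"),
    class = "ground_truth"
  )
}

#' Recording container
#'
#' @param data channels x samples numeric matrix.
#' @param fs sampling rate in Hz.
#' @param subject_id,condition,species metadata; condition is one of
#'   `ME_left`, `ME_right`, `MI_left`, `MI_right` (motor execution/imagery,
#'   left/right hand) and species one of `HbO2`, `HbR`, `HbT`.
#' @return object of class `nirs_recording`.
#' @export
new_recording <- function(data, fs, subject_id = "S1", condition = "ME_left",
                          species = "HbO2") {
  stopifnot(is.matrix(data), fs > 0)
  structure(
    list(data = data, fs = fs, subject_id = subject_id,
         condition = condition, species = species,
         flags = logical(nrow(data))),
    class = "nirs_recording"
  )
}

#' Simulate one multichannel recording
#'
#' Each channel c is generated as
#' `L_c * (amplitude_c * response + gain_c * shared + local_c + drift_c + noise)`
#' where `response` is the boxcar convolved with the canonical HRF (unit
#' peak for one trial), `shared` is the systemic series common to all
#' channels, `local_c` is a per-channel slow sinusoid (uncoupled superficial
#' physiology; this is what makes channels differ in their task
#' correlation), `drift_c` a random quadratic, and `L_c` the unknown
#' pathlength factor.
#'
#' @param layout a `probe_layout`.
#' @param design a [make_design()] object.
#' @param truth a [ground_truth()] object.
#' @param params a [systemic_params()] object.
#' @param seed integer seed (identical seed gives an identical recording).
#' @param subject_id,condition metadata for the recording.
#' @return list with elements `recording` (class `nirs_recording`) and
#'   `truth` (the input truth completed with the drawn `pathlength_factors`,
#'   `coupling_gains` and systemic component table).
#' @export
simulate_recording <- function(layout, design, truth, params, seed,
                               subject_id = "S1", condition = "ME_left") {
  set.seed(seed)
  nc <- nrow(layout$channels)
  n <- length(design$boxcar)
  fs <- design$fs
  hrf <- canonical_hrf(fs)
  resp <- .hrf_convolve(design$boxcar, hrf) / .response_scale(design, hrf)
  shared <- simulate_systemic(params, n, fs, seed = NULL, design = design)
  gains <- stats::runif(nc, params$coupling_gain_range[1],
                        params$coupling_gain_range[2])
  L <- stats::runif(nc, truth$pathlength_range[1], truth$pathlength_range[2])
  u <- design$time / max(design$time)
  data <- matrix(0, nc, n)
  for (c in seq_len(nc)) {
    la <- stats::runif(1, 0.5, 1.5) * truth$local_vlf_amp
    lf <- stats::runif(1, 0.01, 0.06)
    lp <- stats::runif(1, 0, 2 * pi)
    local <- la * sin(2 * pi * lf * design$time + lp)
    dc <- stats::rnorm(3, 0, truth$drift_sd)
    drift <- dc[1] + dc[2] * u + dc[3] * u^2
    noise <- stats::rnorm(n, 0, truth$noise_sd[c])
    data[c, ] <- L[c] * (truth$amplitudes[c] * resp + gains[c] * shared +
                           local + drift + noise)
  }
  rownames(data) <- paste0("ch", seq_len(nc))
  truth$pathlength_factors <- L
  truth$coupling_gains <- gains
  truth$systemic_components <- attr(shared, "components")
  list(recording = new_recording(data, fs, subject_id, condition),
       truth = truth)
}

#' Named simulation scenarios
#'
#' * `"null"` - no active channels, free-running systemic components.
#' * `"stress-null"` - no active channels, plus a shared slow component at
#'   the 0.04 Hz block frequency entrained to the task (the
#'   over-activation stress case).
#' * `"contralateral-M1"` - response in the M1 channels contralateral to
#'   the performing hand, default systemic interference.
#' * `"bilateral-SMC"` - response in the SMC channels of both hemispheres.
#'
#' @param name scenario name.
#' @param layout a `probe_layout` with ROIs.
#' @param condition condition the recording will represent (determines the
#'   performing hand for lateralised scenarios).
#' @return list with `truth_args` (arguments to [ground_truth()] minus the
#'   layout) and `params` (a [systemic_params()] object).
#' @export
scenario_params <- function(name, layout, condition = "ME_left") {
  hand <- if (grepl("_left$", condition)) "left" else "right"
  contra <- if (hand == "left") "right" else "left"
  switch(
    name,
    "null" = list(truth_args = list(), params = systemic_params()),
    "stress-null" = list(truth_args = list(),
                         params = systemic_params(task_locked_amp = 0.4)),
    "contralateral-M1" = list(
      truth_args = list(active_channels = roi_channels(layout, "M1", contra),
                        response_amplitude = 1),
      params = systemic_params()
    ),
    "bilateral-SMC" = list(
      truth_args = list(active_channels = roi_channels(layout, "SMC"),
                        response_amplitude = 1),
      params = systemic_params()
    ),
    stop("unknown scenario: ", name)
  )
}

#' Simulate a group dataset
#'
#' Independent subjects with per-subject seeds derived from the master seed
#' (a fixed-seed draw, so reruns with the same master seed are
#' bit-identical).  Between-subject variability multiplies each subject's
#' response amplitude by `max(0, rnorm(1, 1, amplitude_sd))`.
#'
#' @param n_subjects number of subjects (default 16).
#' @param layout a `probe_layout` with ROIs.
#' @param scenario scenario name, see [scenario_params()].
#' @param seed master integer seed.
#' @param conditions character vector of conditions to simulate per
#'   subject.
#' @param design a [make_design()] object (default: 20 trials of 10 s task
#'   + 15 s rest at 7.14 Hz).
#' @param amplitude_sd between-subject SD of the response amplitude
#'   multiplier.
#' @return list of class `nirs_group` with `recordings` (flat list),
#'   `truths` (parallel list), `layout`, `design`, `scenario`, `seed`.
#' @export
simulate_group <- function(n_subjects = 16, layout = build_default_layout(),
                           scenario = "null", seed = 1,
                           conditions = "ME_left",
                           design = make_design(), amplitude_sd = 0.3) {
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2, n_subjects * length(conditions))
  amp_mult <- pmax(0, stats::rnorm(n_subjects, 1, amplitude_sd))
  recs <- list()
  truths <- list()
  k <- 0
  for (s in seq_len(n_subjects)) {
    for (cond in conditions) {
      k <- k + 1
      sc <- scenario_params(scenario, layout, cond)
      ta <- sc$truth_args
      if (!is.null(ta$response_amplitude))
        ta$response_amplitude <- ta$response_amplitude * amp_mult[s]
      truth <- do.call(ground_truth, c(list(layout = layout), ta))
      sim <- simulate_recording(layout, design, truth, sc$params,
                                seed = sub_seeds[k],
                                subject_id = sprintf("S%02d", s),
                                condition = cond)
      recs[[k]] <- sim$recording
      truths[[k]] <- sim$truth
    }
  }
  structure(list(recordings = recs, truths = truths, layout = layout,
                 design = design, scenario = scenario, seed = seed),
            class = "nirs_group")
}
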