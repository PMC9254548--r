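#' Trajectory helpers for programmed learning dynamics
#'
#' Run-indexed trajectories used by the simulator: constant, linear ramp
#' over the first `over` runs (then held), and a rise-then-plateau ramp
#' (alias of linear with a shorter rise). All return a function of the run
#' index valid for every r >= 1.
#'
#' @param v constant value.
#' @return A function `r -> value`.
#' @export
trajectory_constant <- function(v) {
  force(v)
  function(r) rep(v, length(r))
}

#' @rdname trajectory_constant
#' @param from,to start and end values.
#' @param over number of runs over which the ramp rises (held at `to`
#'   afterwards).
#' @export
trajectory_linear <- function(from, to, over) {
  force(from); force(to); force(over)
  function(r) from + (to - from) * pmin(1, pmax(0, (r - 1) / (over - 1)))
}

#' Default class topography
#'
#' Which (channel, band) pairs each motor-imagery class modulates and how
#' deeply. Hands imagery desynchronizes lateral sensorimotor electrodes,
#' feet imagery medial ones; the beta band carries the deeper modulation,
#' matching the band that longitudinal SMR training typically reinforces.
#'
#' @param depth_mu,depth_beta modulation depths in [0, 1): the fraction of
#'   band power suppressed (ERD) at full separability gain.
#' @return data.frame `class`, `channel`, `band`, `depth`.
#' @export
default_topography <- function(depth_mu = 0.5, depth_beta = 0.8) {
  lateral <- c("FC3", "C3", "FC4", "C4")
  medial <- c("FCz", "Cz", "CPz")
  rbind(
    expand.grid(class = "both_hands", channel = lateral, band = "mu",
                depth = depth_mu, stringsAsFactors = FALSE),
    expand.grid(class = "both_hands", channel = lateral, band = "beta",
                depth = depth_beta, stringsAsFactors = FALSE),
    expand.grid(class = "both_feet", channel = medial, band = "mu",
                depth = depth_mu, stringsAsFactors = FALSE),
    expand.grid(class = "both_feet", channel = medial, band = "beta",
                depth = depth_beta, stringsAsFactors = FALSE)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic-EEG generator: session structure (trials
#' per class, trial duration), class topography with a run-indexed
#' separability gain, per-band within-class drift split into a slow
#' band-power shift along a fixed channel direction (visible to the
#' channels' domain) and a slow rotation of the band's inter-channel
#' correlation structure (visible to the Riemann domain but, by
#' construction, invisible to per-channel band power), an optional long
#' break with per-band retention of the rotated covariance structure,
#' ocular artifact rates, and a spatially correlated pink-noise
#' background.
#'
#' @param rate sampling rate, Hz.
#' @param trials_per_class cue-guided trials per class per run.
#' @param trial_duration length-2 range of trial durations, s (uniform).
#' @param iti inter-trial interval, s.
#' @param latency cue-to-task latency, s (task modulation and window
#'   labeling both start this long after the cue).
#' @param topography data.frame from [default_topography()].
#' @param separability trajectory `r -> g` scaling all modulation depths.
#' @param power_drift per-band trajectories `r -> d` of the band-power
#'   drift magnitude (log-scale shift along a fixed random channel
#'   direction).
#' @param rotation_drift per-band trajectories `r -> theta` (radians) of
#'   the correlation-structure rotation.
#' @param drift_jitter list with `power` and `rotation`: standard
#'   deviations of zero-mean run-to-run jitter added to the programmed
#'   drift magnitudes, emulating day-to-day neural state variability
#'   (defaults: power 0.08 log-units, rotation 0.25 rad).
#' @param break_spec NULL or `list(after_run =, retained =)` where
#'   `retained` names the bands whose rotated covariance structure
#'   survives the break; power-shift drift restarts for every band after
#'   the break, the rotation only for non-retained bands.
#' @param blink_rate eye-blink rate, events/min.
#' @param saccade_rate horizontal saccade rate, events/min.
#' @param blink_amplitude blink peak amplitude on the EOG electrodes, uV.
#' @param band_rms baseline RMS amplitude of the mu and beta carriers, uV.
#' @param noise list: `pink_exponent` (1/f exponent), `spatial_scale`
#'   (correlation length on the 10-20 grid, grid units), `eeg_rms`
#'   (background RMS on EEG channels, uV), `eog_rms` (background RMS on
#'   the frontal EOG electrodes, uV).
#' @param seed master seed; identical configs and seeds give
#'   byte-identical sessions.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(rate = 512,
                              trials_per_class = 15,
                              trial_duration = c(4.5, 5.5),
                              iti = 2.5,
                              latency = 0.5,
                              topography = default_topography(),
                              separability = trajectory_constant(1),
                              power_drift = list(
                                mu = trajectory_constant(0),
                                beta = trajectory_constant(0)),
                              rotation_drift = list(
                                mu = trajectory_constant(0),
                                beta = trajectory_constant(0)),
                              drift_jitter = list(power = 0.08,
                                                  rotation = 0.25),
                              break_spec = NULL,
                              blink_rate = 6,
                              saccade_rate = 3,
                              blink_amplitude = 150,
                              band_rms = c(mu = 7, beta = 6),
                              noise = list(pink_exponent = 1.3,
                                           spatial_scale = 1.5,
                                           eeg_rms = 10, eog_rms = 4),
                              seed = 1L) {
  stopifnot(rate > 0, trials_per_class >= 1,
            length(trial_duration) == 2,
            trial_duration[1] <= trial_duration[2],
            all(topography$depth >= 0))
  if (!is.null(break_spec)) {
    if (is.null(break_spec$after_run) || break_spec$after_run < 1) {
      stop("break_spec$after_run must be a run index >= 1")
    }
    if (is.null(break_spec$retained)) break_spec$retained <- character(0)
  }
  structure(
    list(rate = rate, trials_per_class = trials_per_class,
         trial_duration = trial_duration, iti = iti, latency = latency,
         topography = topography, separability = separability,
         power_drift = power_drift, rotation_drift = rotation_drift,
         drift_jitter = drift_jitter,
         break_spec = break_spec, blink_rate = blink_rate,
         saccade_rate = saccade_rate, blink_amplitude = blink_amplitude,
         band_rms = band_rms, noise = noise, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Internal: structural randomness shared by all runs of a history (drift
# directions, rotation generators, base correlation structure). Derived
# from the config seed only.
session_structure <- function(config, montage = sensorimotor_montage()) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(config$seed)
  nch <- length(montage$channels)
  D <- as.matrix(stats::dist(montage$coords))
  K_spat <- exp(-D / config$noise$spatial_scale)
  # band carriers are strongly spatially coherent (long correlation
  # length), as rhythmic sensorimotor sources project broadly; this is
  # what the correlation-structure drift rotates
  base_corr <- exp(-D / (2 * config$noise$spatial_scale))
  out <- list(K_spat = K_spat)
  for (b in c("mu", "beta")) {
    A <- matrix(stats::rnorm(nch * nch), nch)
    A <- (A - t(A)) / 2
    # normalize to unit spectral norm so theta is the largest principal
    # rotation angle of expm(theta * A)
    A <- A / max(Mod(eigen(A, only.values = TRUE)$values))
    u <- stats::rnorm(nch)
    u <- u / sqrt(sum(u^2))                      # power-drift direction
    out[[b]] <- list(skew = A, power_dir = u, base_corr = base_corr)
  }
  out
}

# Internal: effective trajectory arguments for run r given the break spec.
# Power drift restarts for every band after the break; the rotation is
# kept (continues with r) only for retained bands.
drift_indices <- function(config, r) {
  br <- config$break_spec
  out <- list()
  for (b in c("mu", "beta")) {
    r_pow <- r
    r_rot <- r
    if (!is.null(br) && r > br$after_run) {
      r_pow <- r - br$after_run
      if (!(b %in% br$retained)) r_rot <- r - br$after_run
    }
    out[[b]] <- list(power = r_pow, rotation = r_rot)
  }
  out
}

# Internal: 1/f^alpha noise, one column per channel, unit RMS. Shaped in
# the frequency domain on an FFT-friendly padded length, then truncated.
pink_noise <- function(n, nch, alpha) {
  m <- stats::nextn(n, c(2, 3, 5))
  w <- matrix(stats::rnorm(m * nch), m, nch)
  f <- c(1, seq_len(m - 1))                      # avoid f = 0
  f <- pmin(f, m - f + 1)                        # two-sided frequency index
  shape <- f^(-alpha / 2)
  x <- Re(stats::mvfft(stats::mvfft(w) * shape, inverse = TRUE)) / m
  x <- x[seq_len(n), , drop = FALSE]
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

# Internal: band-limited unit-variance carriers, n x nch.
band_carriers <- function(n, nch, band, rate) {
  bf <- signal::butter(4, band / (rate / 2), type = "pass")
  w <- matrix(stats::rnorm(n * nch), n, nch)
  x <- apply(w, 2, function(col) signal::filtfilt(bf, col))
  sweep(x, 2, apply(x, 2, stats::sd), "/")
}

#' Simulate one training run
#'
#' Generates a cue-guided calibration/online run: spatially correlated
#' pink-noise background plus amplitude-modulated band-limited mu and beta
#' carriers on the 14 montage channels, with class-dependent
#' event-related desynchronization at the configured channels (contrast
#' scaled by the separability gain `g(run_index)`), run-indexed
#' within-class drift of band power and of the band correlation structure,
#' and frontal EOG channels carrying background noise plus injected
#' blinks and saccades. Deterministic given the config seed and run index.
#'
#' @param config a `simulation_config`.
#' @param run_index run index (>= 1).
#' @param montage a `montage`.
#' @return list with `recording` (16-channel `eeg_recording`), `trials`
#'   (data.frame `onset`, `duration`, `label`), and `truth` (programmed
#'   gain, drifts, blink/saccade event log, trial table).
#' @export
simulate_session <- function(config, run_index,
                             montage = sensorimotor_montage()) {
  stopifnot(inherits(config, "simulation_config"), run_index >= 1)
  g <- config$separability(run_index)
  di <- drift_indices(config, run_index)
  drift <- lapply(c(mu = "mu", beta = "beta"), function(b) {
    list(power = config$power_drift[[b]](di[[b]]$power),
         rotation = config$rotation_drift[[b]](di[[b]]$rotation))
  })
  vals <- c(g, unlist(drift))
  if (any(!is.finite(vals))) stop("non-finite trajectory value")

  struct <- session_structure(config, montage)
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed((config$seed * 10007L + as.integer(run_index)) %% 2147483647L)

  # day-to-day neural state variability around the programmed trajectories
  jit <- config$drift_jitter
  if (!is.null(jit)) {
    drift <- lapply(drift, function(z) {
      list(power = z$power + stats::rnorm(1, 0, jit$power),
           rotation = z$rotation + stats::rnorm(1, 0, jit$rotation))
    })
  }

  rate <- config$rate
  nch <- length(montage$channels)
  ntr <- 2L * config$trials_per_class
  labels <- sample(rep(mi_classes(), config$trials_per_class))
  durations <- stats::runif(ntr, config$trial_duration[1],
                            config$trial_duration[2])
  onsets <- 2 + cumsum(c(0, durations[-ntr] + config$iti))
  total <- onsets[ntr] + durations[ntr] + 2
  n <- ceiling(total * rate)
  trials <- data.frame(onset = onsets, duration = durations,
                       label = labels)

  # background: spatially correlated pink noise
  Ls <- t(chol(struct$K_spat))
  bg <- pink_noise(n, nch, config$noise$pink_exponent) %*% t(Ls)
  bg <- sweep(bg, 2, apply(bg, 2, stats::sd), "/") * config$noise$eeg_rms
  x <- bg

  bands <- list(mu = c(8, 12), beta = c(16, 26))
  tgrid <- (seq_len(n) - 1) / rate
  ramp <- 0.2                                    # ERD on/off ramp, s
  for (b in names(bands)) {
    st <- struct[[b]]
    theta <- drift[[b]]$rotation
    K <- st$base_corr
    if (theta != 0) {
      Q <- pracma::expm(theta * st$skew)
      K <- stats::cov2cor(Q %*% K %*% t(Q))
    }
    carriers <- band_carriers(n, nch, bands[[b]], rate) %*% chol(K)
    # baseline amplitude with drifted per-channel power
    a0 <- config$band_rms[[b]] *
      exp(0.5 * drift[[b]]$power * st$power_dir)
    # class-dependent modulation envelope per channel
    env <- matrix(1, n, nch)
    topo <- config$topography
    for (ti in seq_len(ntr)) {
      t0 <- onsets[ti] + config$latency
      t1 <- onsets[ti] + durations[ti]
      rows <- topo$class == labels[ti] & topo$band == b
      if (!any(rows)) next
      span <- which(tgrid > t0 & tgrid < t1)
      w <- pmin(1, (tgrid[span] - t0) / ramp, (t1 - tgrid[span]) / ramp)
      for (j in which(rows)) {
        ch <- match(topo$channel[j], montage$channels)
        depth <- min(g * topo$depth[j], 0.95)
        amp <- sqrt(1 - depth)                   # ERD: power suppression
        env[span, ch] <- pmin(env[span, ch], 1 - w * (1 - amp))
      }
    }
    x <- x + sweep(carriers, 2, a0, "*") * env
  }

  # frontal EOG electrodes: correlated low-amplitude background
  eog_bg <- pink_noise(n, 2, config$noise$pink_exponent)
  mix <- matrix(c(1, 0.6, 0.6, 1), 2)
  eog <- eog_bg %*% chol(mix)
  eog <- sweep(eog, 2, apply(eog, 2, stats::sd), "/") *
    config$noise$eog_rms

  data <- cbind(x, eog)
  rec <- eeg_recording(
    data, rate, c(montage$channels, eog_channels()),
    meta = list(run_index = run_index, run_type = "calibration")
  )
  truth <- list(g = g, drift = drift, trials = trials,
                blinks = data.frame(onset = numeric(0), duration = numeric(0),
                                    amplitude = numeric(0),
                                    type = character(0)))
  if (config$blink_rate > 0 || config$saccade_rate > 0) {
    inj <- inject_eog(rec, truth, blink_rate = config$blink_rate,
                      amplitude = config$blink_amplitude,
                      saccade_rate = config$saccade_rate)
    rec <- inj$recording
    truth <- inj$truth
  }
  list(recording = rec, trials = trials, truth = truth)
}

#' Inject ocular artifacts into a recording
#'
#' Adds eye-blink templates (raised-cosine bumps of 150-400 ms, the
#' configured peak amplitude, same sign on both frontal electrodes) and
#' horizontal saccades (opposite sign on the two electrodes) at Poisson
#' event times; every event is logged in the returned ground truth. A
#' small fraction of each event also couples into the frontal-adjacent
#' EEG channels. With both rates zero the recording is returned
#' unchanged.
#'
#' @param recording an `eeg_recording` with the two EOG channels.
#' @param truth ground-truth list to append the event log to (may be an
#'   empty list).
#' @param blink_rate blinks per minute.
#' @param amplitude blink peak amplitude, uV.
#' @param saccade_rate saccades per minute.
#' @param eeg_leak fraction of the event amplitude leaking into frontal
#'   EEG channels (default 0.15).
#' @return list with `recording` and `truth` (with `blinks` event log).
#' @export
inject_eog <- function(recording, truth = list(), blink_rate = 6,
                       amplitude = 150, saccade_rate = 3,
                       eeg_leak = 0.15) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!all(eog_channels() %in% recording$channels)) {
    stop("recording lacks the frontal EOG channels")
  }
  if (blink_rate == 0 && saccade_rate == 0) {
    truth$blinks <- data.frame(onset = numeric(0), duration = numeric(0),
                               amplitude = numeric(0), type = character(0))
    return(list(recording = recording, truth = truth))
  }
  rate <- recording$rate
  n <- nrow(recording$data)
  dur <- n / rate
  data <- recording$data
  e1 <- match(eog_channels()[1], recording$channels)
  e2 <- match(eog_channels()[2], recording$channels)
  frontal <- intersect(c("Fz", "FC1", "FC2"), recording$channels)
  events <- data.frame(onset = numeric(0), duration = numeric(0),
                       amplitude = numeric(0), type = character(0))
  place <- function(type, n_ev) {
    if (n_ev == 0) return(invisible())
    onset <- sort(stats::runif(n_ev, 0.5, max(0.6, dur - 1)))
    width <- stats::runif(n_ev, 0.15, 0.4)
    for (i in seq_len(n_ev)) {
      i0 <- floor(onset[i] * rate) + 1
      len <- round(width[i] * rate)
      idx <- i0:min(i0 + len - 1, n)
      bump <- amplitude * sin(pi * seq_along(idx) / length(idx))^2
      if (type == "blink") {
        data[idx, e1] <<- data[idx, e1] + bump
        data[idx, e2] <<- data[idx, e2] + bump
      } else {
        data[idx, e1] <<- data[idx, e1] + bump / 2
        data[idx, e2] <<- data[idx, e2] - bump / 2
      }
      for (ch in frontal) {
        ci <- match(ch, recording$channels)
        data[idx, ci] <<- data[idx, ci] + eeg_leak * bump
      }
      events <<- rbind(events, data.frame(
        onset = onset[i], duration = width[i], amplitude = amplitude,
        type = type))
    }
  }
  place("blink", stats::rpois(1, blink_rate * dur / 60))
  place("saccade", stats::rpois(1, saccade_rate * dur / 60))
  out <- eeg_recording(data, rate, recording$channels, recording$meta)
  truth$blinks <- events[order(events$onset), , drop = FALSE]
  list(recording = out, truth = truth)
}

#' Canonical study histories
#'
#' Pre-parameterized simulation configurations emulating the three
#' longitudinal scenarios the analysis is designed to detect:
#' \describe{
#'   \item{`growth`}{an initial training period: class separability grows
#'     linearly from 0.2 to 1 over 25 runs while within-class drift
#'     (band-power shift and correlation rotation) accumulates — the
#'     positive bcDist/accuracy/wcDist trend scenario.}
#'   \item{`break`}{a stable-skill history (separability 0.8 throughout)
#'     with a long break after run 20: band-power drift resets for both
#'     bands, the mu-band correlation rotation resets, but the beta-band
#'     rotation — the structure reinforced by training — is retained, so
#'     the within-class distance drops after the break in the channels'
#'     domain and in the Riemann mu band, while the Riemann beta band
#'     stays continuous.}
#'   \item{`null`}{flat separability and no drift: no metric should show
#'     a significant trend.}
#' }
#' Drift magnitudes (power-shift log-scale 1.6/1.2 for mu/beta, rotation
#' angle 2 rad with a pre-break plateau) are fixed study conditions chosen
#' to emulate the qualitative longitudinal phenomenology; see the methods
#' vignette.
#'
#' @param kind `"growth"`, `"break"` or `"null"`.
#' @param seed master seed.
#' @return A `simulation_config`.
#' @export
study_history <- function(kind = c("growth", "break", "null"), seed = 1L) {
  kind <- match.arg(kind)
  switch(
    kind,
    growth = simulation_config(
      seed = seed,
      separability = trajectory_linear(0.2, 1, 25),
      power_drift = list(mu = trajectory_linear(0, 1.6, 25),
                         beta = trajectory_linear(0, 1.2, 25)),
      rotation_drift = list(mu = trajectory_linear(0, 2, 25),
                            beta = trajectory_linear(0, 2, 25))),
    `break` = simulation_config(
      seed = seed,
      separability = trajectory_constant(0.8),
      power_drift = list(mu = trajectory_linear(0, 1.6, 15),
                         beta = trajectory_linear(0, 0.4, 15)),
      rotation_drift = list(mu = trajectory_linear(0, 2, 12),
                            beta = trajectory_linear(0, 2, 12)),
      break_spec = list(after_run = 20, retained = "beta")),
    null = simulation_config(
      seed = seed,
      separability = trajectory_constant(0.8))
  )
}

#' Simulate a multi-run training history
#'
#' An ordered, lazily generated set of sessions sharing one configuration:
#' run r is produced on demand by [simulate_session()] so that month-long
#' histories never need to be held in memory at once. Runs after a
#' configured break restart the power-shift drift for every band while
#' retained bands keep their rotated covariance structure; period tags
#' split the history at the break.
#'
#' @param config a `simulation_config`.
#' @param n_runs number of runs (>= 2).
#' @param n_calibration how many initial runs are tagged `calibration`
#'   (default 3, the decoder's calibration data).
#' @return list of class `session_set`: `config`, `runs` (data.frame
#'   `run`, `type`, `period`), and accessor via [get_session()].
#' @export
simulate_training_history <- function(config, n_runs, n_calibration = 3) {
  stopifnot(inherits(config, "simulation_config"), n_runs >= 2)
  br <- config$break_spec
  if (!is.null(br) && (br$after_run < 1 || br$after_run >= n_runs)) {
    stop("break index outside [1, n_runs)")
  }
  period <- if (is.null(br)) rep("period1", n_runs) else
    ifelse(seq_len(n_runs) <= br$after_run, "period1", "period2")
  runs <- data.frame(
    run = seq_len(n_runs),
    type = c(rep("calibration", min(n_calibration, n_runs)),
             rep("online", max(0, n_runs - n_calibration))),
    period = period
  )
  structure(list(config = config, runs = runs), class = "session_set")
}

#' @rdname simulate_training_history
#' @param set a `session_set`.
#' @param r run index.
#' @export
get_session <- function(set, r) {
  stopifnot(inherits(set, "session_set"))
  if (r < 1 || r > nrow(set$runs)) stop("run index out of range")
  s <- simulate_session(set$config, r)
  s$recording$meta$run_type <- set$runs$type[r]
  s$recording$meta$period <- set$runs$period[r]
  s
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf("<session_set> %d runs (%s)\n", nrow(x$runs),
              paste(unique(x$runs$period), collapse = ", ")))
  invisible(x)
}
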