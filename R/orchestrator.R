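#' Experiment configuration
#'
#' Bundles everything needed for an end-to-end longitudinal experiment:
#' the synthetic-history configuration, decoder settings, the
#' re-calibration policy (re-fit when a run's sample accuracy drops below
#' the floor, carrying over the previous feature mask), and the batch
#' analysis resolution (window strides traded against runtime).
#'
#' @param history a `simulation_config`.
#' @param n_runs number of runs in the history.
#' @param n_calibration initial calibration runs pooled to fit the first
#'   decoder (default 3).
#' @param n_features features selected for the decoder (default 6).
#' @param n_prototypes Gaussian prototypes per class (default 2).
#' @param th_rej rejection threshold (default 0.6).
#' @param transform decoder feature transform, `"raw"` or `"log"`.
#' @param recalibrate apply the accuracy-floor re-calibration policy
#'   (default TRUE).
#' @param accuracy_floor re-calibration floor in percent (default 75).
#' @param psd_stride keep every k-th PSD window in batch analysis
#'   (default 4).
#' @param scm_stride keep every k-th SCM window (default 8).
#' @param convention dispersion convention for the learning metrics.
#' @param races simulate one race per post-calibration run (default TRUE).
#' @param group_size runs per first/last comparison group (default 15,
#'   shrunk to fit short periods).
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(history = simulation_config(),
                              n_runs = 30, n_calibration = 3,
                              n_features = 6, n_prototypes = 2,
                              th_rej = 0.6,
                              transform = c("raw", "log"),
                              recalibrate = TRUE, accuracy_floor = 75,
                              psd_stride = 3, scm_stride = 8,
                              convention = c("meandist", "sd"),
                              races = TRUE, group_size = 15) {
  stopifnot(accuracy_floor > 0, accuracy_floor < 100,
            n_runs > n_calibration)
  structure(
    list(history = history, n_runs = n_runs,
         n_calibration = n_calibration, n_features = n_features,
         n_prototypes = n_prototypes, th_rej = th_rej,
         transform = match.arg(transform), recalibrate = recalibrate,
         accuracy_floor = accuracy_floor, psd_stride = psd_stride,
         scm_stride = scm_stride, convention = match.arg(convention),
         races = races, group_size = group_size),
    class = "experiment_config"
  )
}

# Internal: per-run domain summaries (class means and dispersions) for
# both bands and both domains. `frame` must be the sensor-space
# (non-Laplacian) PSD frame: the learning metrics live in the raw channel
# space, while the Laplacian-filtered PSD is the decoder's feature space.
run_summaries <- function(rec, trials, frame, det, opts) {
  bands <- list(mu = band_definition("mu"), beta = band_definition("beta"))
  keep <- clean_labeled(frame)
  y <- frame$labels[keep]
  out <- list()
  for (b in names(bands)) {
    bp <- band_power(frame, bands[[b]])[keep, , drop = FALSE]
    ss <- scm_set(rec, trials, bands[[b]], stride = opts$scm_stride,
                  artifact_intervals = det$intervals)
    for (dom in c("channels", "riemann")) {
      for (cl in mi_classes()) {
        dat <- if (dom == "channels") bp[y == cl, , drop = FALSE] else
          ss$scms[ss$labels == cl]
        nd <- if (dom == "channels") nrow(dat) else length(dat)
        if (nd < 2) stop("fewer than 2 clean windows for class ", cl)
        d <- run_distribution(dat, dom, class = cl)
        m <- rd_mean(d)
        s <- rd_dispersion(d, m, opts$convention)
        out[[b]][[dom]][[cl]] <- list(mean = m, sigma = s)
      }
    }
  }
  out
}

# Internal: learning metrics of run r against the run-1 reference.
metrics_from_summaries <- function(sm, ref, convention) {
  rows <- list()
  for (b in names(sm)) {
    for (dom in names(sm[[b]])) {
      s2 <- sm[[b]][[dom]]
      bh <- s2$both_hands
      bf <- s2$both_feet
      bc <- mean_distance(bh$mean, bf$mean, dom) /
        combine_sigma(bh$sigma, bf$sigma, convention)
      wc <- mean(vapply(mi_classes(), function(cl) {
        a <- ref[[b]][[dom]][[cl]]
        z <- s2[[cl]]
        mean_distance(a$mean, z$mean, dom) /
          combine_sigma(a$sigma, z$sigma, convention)
      }, numeric(1)))
      rows[[length(rows) + 1]] <- data.frame(
        metric = c("bcDist", "wcDist"), band = b, domain = dom,
        value = c(bc, wc))
    }
  }
  do.call(rbind, rows)
}

# Internal: core longitudinal engine over a run provider.
# get_run(r) must return list(recording, trials).
analyze_history <- function(get_run, runs_meta, opts, model = NULL) {
  n_runs <- nrow(runs_meta)
  calib <- list()
  ref <- NULL
  curve_rows <- list()
  recal <- data.frame(run = integer(0), reason = character(0))
  race_rows <- list()
  section_times <- list()
  prev_mask <- NULL
  counts <- data.frame(run = integer(0), total = integer(0),
                       artifact = integer(0), labeled_clean = integer(0))
  for (r in seq_len(n_runs)) {
    s <- get_run(r)
    det <- detect_eog_artifacts(s$recording)
    frame <- psd_frames(s$recording, stride = opts$psd_stride)
    frame <- label_windows(frame, s$trials)
    frame <- mask_artifacts(frame, det$intervals)
    keep <- clean_labeled(frame)
    counts <- rbind(counts, data.frame(
      run = r, total = length(frame$times), artifact = sum(frame$artifact),
      labeled_clean = length(keep)))
    grid <- feature_grid(frame)
    X <- psd_features(frame, grid)[keep, , drop = FALSE]
    y <- droplevels(factor(frame$labels[keep]))
    if (is.null(model) && r <= opts$n_calibration) {
      calib[[r]] <- list(X = X, y = y)
    }
    if (is.null(model) && r == opts$n_calibration) {
      Xc <- do.call(rbind, lapply(calib, `[[`, "X"))
      yc <- factor(unlist(lapply(calib, function(z) as.character(z$y))),
                   levels = mi_classes())
      ranked <- cva_rank_features(Xc, yc, mask = grid)
      mask <- select_features(ranked, opts$n_features,
                              carryover = prev_mask)
      cols <- match(paste(mask$channel, mask$freq),
                    paste(grid$channel, grid$freq))
      model <- fit_gaussian_classifier(
        Xc[, cols, drop = FALSE], yc, mask = mask[, c("channel", "freq")],
        n_prototypes = opts$n_prototypes, th_rej = opts$th_rej,
        transform = opts$transform)
      prev_mask <- model$mask
      calib <- list()
    }
    perf <- if (!is.null(model)) decoding_performance(frame, model) else
      list(accuracy = NA_real_, rejection = NA_real_)
    # re-calibration policy: accuracy floor, carryover feature mask
    if (!is.null(model) && isTRUE(opts$recalibrate) &&
        r > opts$n_calibration && is.finite(perf$accuracy) &&
        perf$accuracy < opts$accuracy_floor) {
      ranked <- cva_rank_features(X, y, mask = grid)
      mask <- select_features(ranked, opts$n_features,
                              carryover = prev_mask)
      cols <- match(paste(mask$channel, mask$freq),
                    paste(grid$channel, grid$freq))
      model <- fit_gaussian_classifier(
        X[, cols, drop = FALSE], y, mask = mask[, c("channel", "freq")],
        n_prototypes = opts$n_prototypes, th_rej = opts$th_rej,
        transform = opts$transform)
      prev_mask <- model$mask
      recal <- rbind(recal, data.frame(
        run = r, reason = sprintf("accuracy %.1f%% below floor %.0f%%",
                                  perf$accuracy, opts$accuracy_floor)))
      perf <- decoding_performance(frame, model)
    }
    frame_raw <- psd_frames(s$recording, stride = opts$psd_stride,
                            laplacian = FALSE)
    frame_raw <- mask_artifacts(label_windows(frame_raw, s$trials),
                                det$intervals)
    sm <- run_summaries(s$recording, s$trials, frame_raw, det, opts)
    if (r == 1) ref <- sm
    mrows <- metrics_from_summaries(sm, ref, opts$convention)
    mrows$run <- r
    mrows$period <- runs_meta$period[r]
    curve_rows[[r]] <- rbind(
      mrows,
      data.frame(metric = c("accuracy", "rejection"), band = NA,
                 domain = NA, value = c(perf$accuracy, perf$rejection),
                 run = r, period = runs_meta$period[r]))
    if (isTRUE(opts$races) && !is.null(model) &&
        r > opts$n_calibration && is.finite(perf$accuracy)) {
      res <- simulate_race(
        list(accuracy = min(perf$accuracy, 100) / 100, seed = r),
        generate_track(seed = r))
      race_rows[[length(race_rows) + 1]] <- data.frame(
        run = r, period = runs_meta$period[r], time = res$time,
        complete = res$complete)
      st <- tapply(res$section_times, names(res$section_times), sum)
      section_times[[length(section_times) + 1]] <-
        data.frame(run = r, period = runs_meta$period[r],
                   section = names(st), time = as.numeric(st))
    }
  }
  list(curves = do.call(rbind, curve_rows), model = model,
       recalibrations = recal,
       races = if (length(race_rows)) do.call(rbind, race_rows) else NULL,
       section_times = if (length(section_times))
         do.call(rbind, section_times) else NULL,
       window_counts = counts)
}

# Internal: metric identifier string used in the report tables.
metric_id <- function(metric, band, domain) {
  ifelse(is.na(band), metric, paste(metric, domain, band, sep = "_"))
}

# Internal: trend + group statistics over a curve table.
curve_statistics <- function(curves, group_size) {
  curves$id <- metric_id(curves$metric, curves$band, curves$domain)
  trends <- list()
  groups <- list()
  for (id in unique(curves$id)) {
    sub <- curves[curves$id == id & is.finite(curves$value), ]
    glist <- list()
    for (per in unique(sub$period)) {
      ss <- sub[sub$period == per, ]
      if (nrow(ss) >= 3) {
        tr <- pearson_trend(ss$value, ss$run)
        trends[[length(trends) + 1]] <- data.frame(
          id = id, period = per, r = tr$r, p = tr$p, n = tr$n,
          slope = tr$slope)
      }
      ng <- min(group_size, floor(nrow(ss) / 2))
      if (ng >= 2) {
        ord <- ss[order(ss$run), ]
        glist[[paste0("first_", per)]] <- utils::head(ord$value, ng)
        glist[[paste0("last_", per)]] <- utils::tail(ord$value, ng)
      }
    }
    if (length(glist) >= 2) {
      cmp <- first_last_comparison(glist)
      groups[[length(groups) + 1]] <- list(id = id, comparison = cmp)
    }
  }
  list(trends = do.call(rbind, trends), groups = groups)
}

# Internal: break dissociation tests: rank-sum of the last k runs before
# vs the first k runs after the break, per within-class metric.
break_tests <- function(curves, break_run, k = 8) {
  curves$id <- metric_id(curves$metric, curves$band, curves$domain)
  out <- list()
  for (id in unique(curves$id[curves$metric == "wcDist"])) {
    sub <- curves[curves$id == id & is.finite(curves$value), ]
    sub <- sub[order(sub$run), ]
    before <- sub$value[sub$run <= break_run]
    after <- sub$value[sub$run > break_run]
    kk <- min(k, length(before), length(after))
    if (kk < 2) next
    a <- utils::tail(before, kk)
    b <- utils::head(after, kk)
    p <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided")$p.value)
    out[[length(out) + 1]] <- data.frame(
      id = id, p = p, median_before = stats::median(a),
      median_after = stats::median(b), n_per_group = kk)
  }
  do.call(rbind, out)
}

#' Run a full longitudinal experiment
#'
#' Simulates the configured training history, fits the decoder on the
#' pooled initial calibration runs, evaluates every subsequent run
#' (sample accuracy and rejection, with the accuracy-floor re-calibration
#' policy), computes the between-/within-class learning curves in both
#' neural domains and bands, optionally simulates one race per run, and
#' runs the statistical battery: per-period Pearson trends, first-vs-last
#' group comparisons, per-section race-time comparisons, and (for
#' break-configured histories) before/after-break rank-sum tests on the
#' within-class distances. Fully reproducible from the history seed.
#'
#' @param config an `experiment_config`.
#' @return list of class `experiment_report`: `curves` (tidy run x metric
#'   table), `trends`, `groups`, `break_tests`, `races`,
#'   `section_comparison`, `recalibrations`, `window_counts`, `model`,
#'   `config`.
#' @export
run_longitudinal_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set <- simulate_training_history(config$history, config$n_runs,
                                   config$n_calibration)
  res <- analyze_history(function(r) get_session(set, r), set$runs, config)
  stats <- curve_statistics(res$curves, config$group_size)
  br <- config$history$break_spec
  btests <- if (!is.null(br)) break_tests(res$curves, br$after_run) else
    NULL
  sec_cmp <- NULL
  if (!is.null(res$races) && nrow(res$races) >= 8) {
    rt <- data.frame(metric = "race_time", band = NA, domain = NA,
                     value = res$races$time, run = res$races$run,
                     period = res$races$period)
    stats$trends <- rbind(stats$trends,
                          curve_statistics(rt, config$group_size)$trends)
    ng <- min(config$group_size, floor(nrow(res$races) / 2))
    st <- res$section_times
    first_runs <- utils::head(sort(unique(st$run)), ng)
    last_runs <- utils::tail(sort(unique(st$run)), ng)
    pick <- function(runs) {
      lapply(split(st$time[st$run %in% runs], st$section[st$run %in% runs]),
             as.numeric)
    }
    sec_cmp <- section_time_comparison(pick(first_runs), pick(last_runs))
  }
  structure(
    list(curves = res$curves, trends = stats$trends, groups = stats$groups,
         break_tests = btests, races = res$races,
         section_comparison = sec_cmp, recalibrations = res$recalibrations,
         window_counts = res$window_counts, model = res$model,
         config = config),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d runs, %d metrics\n",
              max(x$curves$run), length(unique(
                metric_id(x$curves$metric, x$curves$band, x$curves$domain)))))
  if (!is.null(x$trends)) {
    cat("trends:\n")
    print(x$trends, row.names = FALSE)
  }
  if (!is.null(x$break_tests)) {
    cat("break tests (rank-sum before vs after):\n")
    print(x$break_tests, row.names = FALSE)
  }
  if (nrow(x$recalibrations)) {
    cat("re-calibrations at runs:",
        paste(x$recalibrations$run, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Re-analyze recorded sessions with a fitted decoder
#'
#' The offline replay path: identical metric outputs to the simulated
#' pipeline, computed from provided recordings and trial tables (or file
#' paths written by [write_recording()] plus trial CSVs). Runs that fail
#' to load are skipped with a warning and itemized in the report.
#'
#' @param sessions list of runs; each entry either
#'   `list(recording = , trials = )` or `list(path = , trials_path = )`.
#' @param model a fitted `decoder_model` (or NULL: metrics only, no
#'   accuracy/rejection).
#' @param config an `experiment_config` supplying the analysis options
#'   (its history/n_runs fields are ignored).
#' @param periods optional character vector of period tags per run.
#' @return An `experiment_report` (without races), plus `errors`
#'   (itemized load failures).
#' @export
replay <- function(sessions, model = NULL,
                   config = experiment_config(races = FALSE),
                   periods = NULL) {
  loaded <- list()
  errors <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    out <- tryCatch({
      if (!is.null(s$recording)) {
        list(recording = s$recording, trials = s$trials)
      } else {
        trials <- utils::read.csv(s$trials_path)
        list(recording = read_recording(s$path), trials = trials)
      }
    }, error = function(e) e)
    if (inherits(out, "error")) {
      warning("run ", i, " skipped: ", conditionMessage(out))
      errors[[length(errors) + 1]] <- data.frame(
        run = i, error = conditionMessage(out))
    } else {
      loaded[[length(loaded) + 1]] <- out
    }
  }
  if (!length(loaded)) stop("no readable sessions")
  if (is.null(periods)) periods <- rep("period1", length(loaded))
  runs_meta <- data.frame(run = seq_along(loaded),
                          type = "replay", period = periods)
  opts <- config
  opts$races <- FALSE
  opts$recalibrate <- FALSE
  res <- analyze_history(function(r) loaded[[r]], runs_meta, opts,
                         model = model)
  stats <- curve_statistics(res$curves, config$group_size)
  structure(
    list(curves = res$curves, trends = stats$trends, groups = stats$groups,
         break_tests = NULL, races = NULL, section_comparison = NULL,
         recalibrations = res$recalibrations,
         window_counts = res$window_counts, model = res$model,
         config = config,
         errors = if (length(errors)) do.call(rbind, errors) else NULL),
    class = "experiment_report"
  )
}
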