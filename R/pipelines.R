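#' Run the fast-tracking analysis pipeline
#'
#' Chains the fast-tracking (10 ms/frame) stages on one trajectory set:
#' per-trajectory MSD diffusion coefficients with the R^2 filter, the
#' two-component log10 D mixture, the two-state jump-length-distribution
#' fit, HMM displacement classification with trajectory sub-classification,
#' and radius-of-confinement fits for bound-only trajectories. Stages are
#' independent, so one stage failing is recorded in the manifest and the
#' rest still run.
#'
#' @param trajectories tidy trajectory table (`track_id`, `frame`, `x_um`,
#'   `y_um`).
#' @param frame_interval frame duration (s).
#' @param seed master seed; per-stage seeds are derived from it by stable
#'   hashing, so one value reproduces the whole run.
#' @param min_displacements_D minimum displacements for the D histogram.
#' @param dZ axial detection depth (um) for the two-state fit.
#' @param output_dir optional directory; when given, per-stage CSV/JSON
#'   reports are written there.
#' @return List of class `fast_pipeline` with `D_fits`, `mixture`,
#'   `two_state`, `hmm`, `classes`, `class_summary`, `confinement`, and a
#'   `manifest` tibble (stage, status, n, seed).
#' @export
run_fast_pipeline <- function(trajectories, frame_interval = 0.01,
                              seed = 1L, min_displacements_D = 5L,
                              dZ = 0.6, output_dir = NULL) {
  check_trajectory_cols(trajectories)
  results <- list()
  manifest <- list()
  note <- function(stage, status, n, sd = NA_integer_) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, status = status, n = n,
      seed = if (is.null(sd)) NA_integer_ else as.integer(sd))
  }
  run_stage <- function(stage, n_fun, sd, expr) {
    res <- tryCatch(expr, error = function(e) {
      rlang::warn(sprintf("stage %s failed: %s", stage, conditionMessage(e)))
      NULL
    })
    note(stage, if (is.null(res)) "failed" else "ok",
         if (is.null(res)) 0L else n_fun(res), sd)
    res
  }

  # MSD-based D histogram: tracks with >= min_displacements_D displacements
  results$D_fits <- run_stage("msd_D", nrow, NA, {
    long <- trajectories |>
      group_by(.data$track_id) |>
      filter(n() > min_displacements_D) |>
      ungroup()
    compute_msd(long, max_lag = 5L, frame_interval = frame_interval) |>
      fit_diffusion_coefficient()
  })

  results$mixture <- run_stage("log10D_mixture", function(x) x$n, NA, {
    fit_log10D_mixture(filter(results$D_fits, .data$accepted))
  })

  s_two <- derive_seed(seed, "two_state")
  results$two_state <- run_stage("two_state_fit", function(x) x$n_jumps, s_two, {
    build_jump_length_data(trajectories, frame_interval = frame_interval) |>
      fit_two_state(dZ = dZ, seed = s_two)
  })

  s_hmm <- derive_seed(seed, "hmm")
  results$hmm <- run_stage("hmm_fit", function(x) x$n_sequences, s_hmm, {
    fit_hmm_two_state(trajectories, frame_interval = frame_interval,
                      seed = s_hmm)
  })
  results$classes <- run_stage("hmm_classes", nrow, NA, {
    classify_displacements(results$hmm, trajectories) |>
      subclassify_trajectories()
  })
  if (!is.null(results$classes)) {
    results$class_summary <- class_summary(results$classes)
  }

  results$confinement <- run_stage("confinement", nrow, NA, {
    bound_ids <- results$classes |>
      filter(.data$class == "bound_only") |>
      pull(.data$track_id)
    bound <- trajectories |>
      filter(.data$track_id %in% bound_ids) |>
      group_by(.data$track_id) |>
      filter(n() >= 12L) |>   # >= 10 usable MSD lags
      ungroup()
    if (nrow(bound) == 0) rlang::abort("no bound-only trajectories long enough")
    compute_msd(bound, max_lag = 10L, frame_interval = frame_interval) |>
      fit_confinement()
  })

  results$manifest <- dplyr::bind_rows(manifest)
  results$seed <- seed
  results$frame_interval <- frame_interval

  if (!is.null(output_dir)) write_fast_reports(results, output_dir)
  structure(results, class = "fast_pipeline")
}

write_fast_reports <- function(results, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(results$D_fits)) {
    readr::write_csv(results$D_fits, file.path(output_dir, "D_fits.csv"))
  }
  if (!is.null(results$mixture)) {
    jsonlite::write_json(list(components = tidy(results$mixture),
                              glance = glance(results$mixture)),
                         file.path(output_dir, "log10D_mixture.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(results$two_state)) {
    jsonlite::write_json(c(as.list(results$two_state$estimate),
                           list(sse = results$two_state$sse,
                                seed = results$two_state$seed)),
                         file.path(output_dir, "two_state_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    readr::write_csv(results$two_state$cdf,
                     file.path(output_dir, "two_state_cdf.csv"))
  }
  if (!is.null(results$hmm)) {
    jsonlite::write_json(list(D = as.list(results$hmm$D),
                              transition = results$hmm$transition,
                              loglik = results$hmm$loglik,
                              seed = results$hmm$seed),
                         file.path(output_dir, "hmm_model.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(results$classes)) {
    readr::write_csv(results$classes, file.path(output_dir, "trajectory_classes.csv"))
  }
  if (!is.null(results$confinement)) {
    readr::write_csv(results$confinement, file.path(output_dir, "confinement.csv"))
  }
  readr::write_csv(results$manifest, file.path(output_dir, "manifest.csv"))
  invisible(output_dir)
}

#' Run the slow-tracking residence-time pipeline
#'
#' From slow-tracking (250 ms/frame) dwell times - either given directly or
#' derived by gap-tolerant linking of a localization table - builds the
#' survival curve, fits the double-exponential model, corrects residence
#' times against a reference standard, and bootstraps errors. When a
#' kinetic parameter bundle is supplied, the search-kinetics chain and a
#' target-occupancy trace simulation are run as well.
#'
#' @param dwells dwell times (vector or data frame with `dwell_s`), or
#'   `NULL` if `localizations` is given.
#' @param localizations optional localization table (`frame`, `x_um`,
#'   `y_um`) linked with [link_with_gaps()].
#' @param reference_dwells optional reference-standard dwell times; when
#'   absent the report is marked uncorrected and `tau` values are apparent.
#' @param kinetics optional one-row bundle for [derive_search_kinetics()] /
#'   [propagate_errors()]; needs `F_bound`, `N_targets`, `N_molecules` (and
#'   optional `*_se`), with `f_sb`/`tau_sb`/`tau_tb` taken from the fit.
#' @param frame_interval frame duration (s).
#' @param min_frames minimum event length in frames.
#' @param n_boot bootstrap replicates.
#' @param seed master seed.
#' @param trace_duration duration (s) of the occupancy trace simulation.
#' @return List of class `slow_pipeline` with `survival`, `fit`,
#'   `corrected` (or apparent values flagged), `bootstrap`,
#'   `search_kinetics`, `occupancy_trace`, `manifest`.
#' @export
run_slow_pipeline <- function(dwells = NULL, localizations = NULL,
                              reference_dwells = NULL, kinetics = NULL,
                              frame_interval = 0.25, min_frames = 3L,
                              n_boot = 100L, seed = 1L,
                              trace_duration = 500) {
  if (is.null(dwells) && is.null(localizations)) {
    rlang::abort("supply `dwells` or `localizations`")
  }
  manifest <- list()
  note <- function(stage, status, n) {
    manifest[[length(manifest) + 1L]] <<- tibble(stage = stage,
                                                 status = status, n = n)
  }
  if (is.null(dwells)) {
    linked <- link_with_gaps(localizations)
    dwells <- trajectory_dwell_times(linked, frame_interval)
    note("link", "ok", dplyr::n_distinct(linked$track_id))
  }
  if (is.data.frame(dwells)) dwells <- dwells$dwell_s

  surv <- survival_curve(dwells, min_frames, frame_interval)
  note("survival", "ok", attr(surv, "n_events"))
  fit <- fit_double_exponential(surv)
  note("double_exp_fit", if (fit$ill_separated) "ill_separated" else "ok",
       attr(surv, "n_events"))

  corrected <- NULL
  k_ref <- 0
  if (is.null(reference_dwells)) {
    rlang::warn("no reference standard supplied; residence times are uncorrected (apparent)")
    corrected <- structure(
      list(tau_sb = 1 / fit$k_sb, tau_tb = 1 / fit$k_tb,
           f_sb = fit$f_sb, k_ref = 0, uncorrected = TRUE),
      class = "corrected_residence")
    note("correction", "skipped_no_reference", 0L)
  } else {
    k_ref <- reference_rate(reference_dwells, min_frames, frame_interval)
    corrected <- correct_residence(fit, k_ref)
    corrected$uncorrected <- FALSE
    note("correction", "ok", 1L)
  }

  boot <- bootstrap_errors(dwells, k_ref = k_ref, n_boot = n_boot,
                           seed = derive_seed(seed, "bootstrap"),
                           min_frames = min_frames,
                           frame_interval = frame_interval)
  note("bootstrap", "ok", n_boot - boot$n_failed)

  search <- NULL; trace <- NULL
  if (!is.null(kinetics)) {
    kin <- as.list(kinetics)
    kin$f_sb <- kin$f_sb %||% corrected$f_sb
    kin$tau_sb <- kin$tau_sb %||% corrected$tau_sb
    kin$tau_tb <- kin$tau_tb %||% corrected$tau_tb
    search <- propagate_errors(kin, seed = derive_seed(seed, "propagate"))
    note("search_kinetics", "ok", nrow(search))
    si <- search$value[search$quantity == "sampling_interval"]
    if (si > kin$tau_sb) {
      trace <- simulate_trace(kin$tau_sb, si, duration = trace_duration,
                              factor = kin$factor %||% "factor",
                              seed = derive_seed(seed, "trace"))
      note("occupancy_trace", "ok", nrow(trace))
    } else {
      note("occupancy_trace", "skipped_si_not_above_tau_sb", 0L)
    }
  }

  structure(
    list(survival = surv, fit = fit, corrected = corrected, bootstrap = boot,
         search_kinetics = search, occupancy_trace = trace,
         manifest = dplyr::bind_rows(manifest), seed = seed,
         frame_interval = frame_interval),
    class = "slow_pipeline")
}
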