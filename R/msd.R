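#' Time-averaged mean squared displacement per trajectory
#'
#' For each trajectory, computes the time-averaged MSD at lags `1..max_lag`
#' frames, averaging the squared displacement over all ordered localization
#' pairs whose frame difference equals the lag. Pairs are matched on exact
#' frame difference, so frames missing from a gapped track simply contribute
#' no pairs.
#'
#' @param trajectories tidy trajectory table (`track_id`, `frame`, `x_um`,
#'   `y_um`).
#' @param max_lag maximum lag in frames.
#' @param frame_interval frame duration (s).
#' @return Tibble `track_id`, `lag`, `time_s`, `msd` (um^2), `n_pairs`.
#'   Lags with no pairs are omitted.
#' @export
compute_msd <- function(trajectories, max_lag = 5L, frame_interval = 0.01) {
  check_trajectory_cols(trajectories)
  stop_if_not_scalar_pos(max_lag, "max_lag")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  max_lag <- as.integer(max_lag)
  trajectories |>
    group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$frame)
      if (max_lag >= nrow(df)) {
        rlang::abort(sprintf(
          "max_lag (%d) must be smaller than trajectory length (%d) for track %s",
          max_lag, nrow(df), format(key$track_id)))
      }
      purrr::map_dfr(seq_len(max_lag), function(L) {
        i <- match(df$frame + L, df$frame)
        ok <- !is.na(i)
        if (!any(ok)) return(NULL)
        sq <- (df$x_um[i[ok]] - df$x_um[ok])^2 + (df$y_um[i[ok]] - df$y_um[ok])^2
        tibble(lag = L, time_s = L * frame_interval,
               msd = mean(sq), n_pairs = sum(ok))
      })
    }) |>
    ungroup()
}

#' Diffusion coefficient from a linear MSD fit
#'
#' Fits MSD versus lag time by ordinary least squares over the stated lags
#' (default 2-5 frames, excluding lag 1 to suppress localization-error bias)
#' and converts the slope to a diffusion coefficient `D = slope / (2 d)`
#' with `d = 2` dimensions. Fits with `R^2 < min_r2` (or non-positive slope)
#' are flagged as rejected, mirroring the conventional R^2 >= 0.8 filter for
#' MSD-based D histograms.
#'
#' @param msd output of [compute_msd()] (one or many trajectories).
#' @param lags frame lags used in the regression.
#' @param min_r2 acceptance threshold on the regression R^2.
#' @return Tibble `track_id`, `D` (um^2/s), `r_squared`, `accepted`.
#' @export
fit_diffusion_coefficient <- function(msd, lags = 2:5, min_r2 = 0.8) {
  d_dim <- 2
  msd |>
    group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      df <- filter(df, .data$lag %in% lags)
      if (nrow(df) < 2L || sd(df$msd) == 0) {
        return(tibble(D = NA_real_, r_squared = NA_real_, accepted = FALSE))
      }
      fit <- lm(msd ~ time_s, data = df)
      slope <- coef(fit)[["time_s"]]
      r2 <- summary(fit)$r.squared
      D <- slope / (2 * d_dim)
      tibble(D = D, r_squared = r2,
             accepted = is.finite(r2) && r2 >= min_r2 && D > 0)
    }) |>
    ungroup()
}

#' Two-component Gaussian mixture of log10 diffusion coefficients
#'
#' Decomposes a population of per-trajectory diffusion coefficients into
#' slow (chromatin-bound) and fast (chromatin-free) components by fitting a
#' two-component Gaussian mixture to `log10(D)`. Fitting uses model-based
#' clustering (EM with deterministic hierarchical initialization), so
#' results are reproducible without a seed.
#'
#' @param D_values numeric vector of diffusion coefficients (um^2/s),
#'   positive; or a data frame with a `D` column (e.g. the accepted rows of
#'   [fit_diffusion_coefficient()]).
#' @return Object of class `gmm_fit`: list with `components` (tibble
#'   `component`, `mean`, `sd`, `weight`, slow first), `loglik`, `n`, and a
#'   `degenerate` flag (one component carries >= 95% of the weight or the
#'   means overlap: closer than twice the larger component s.d.).
#' @export
fit_log10D_mixture <- function(D_values) {
  if (is.data.frame(D_values)) D_values <- D_values$D
  D_values <- D_values[is.finite(D_values) & D_values > 0]
  if (length(unique(D_values)) < 2L) {
    rlang::abort("need at least two distinct positive D values")
  }
  x <- log10(D_values)
  fit <- Mclust(x, G = 2, modelNames = c("E", "V"), verbose = FALSE)
  if (is.null(fit)) rlang::abort("mixture fit failed to converge")
  mu <- as.numeric(fit$parameters$mean)
  sig <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sig) == 1L) sig <- rep(sig, 2L)
  w <- as.numeric(fit$parameters$pro)
  ord <- order(mu)
  comps <- tibble(component = c("slow", "fast"),
                  mean = mu[ord], sd = sig[ord], weight = w[ord])
  structure(
    list(components = comps,
         loglik = fit$loglik,
         n = length(x),
         degenerate = max(comps$weight) >= 0.95 ||
           diff(comps$mean) < 2 * max(comps$sd)),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit> two-component Gaussian mixture of log10(D), n =", x$n, "\n")
  print(x$components)
  if (x$degenerate) cat("note: degenerate fit (single effective component)\n")
  invisible(x)
}

#' @export
tidy.gmm_fit <- function(x, ...) x$components

#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(loglik = x$loglik, n = x$n, degenerate = x$degenerate)
}

#' Radius of confinement from the circular confined-diffusion model
#'
#' Fits the first `n_points` MSD values of a chromatin-bound trajectory to
#' the circular confinement model
#' `MSD(t) = Rc^2 * (1 - exp(-4 D t / Rc^2))`,
#' whose plateau is `Rc^2` and whose short-time slope is `4 D`. A trajectory
#' is rejected when the preliminary linear fit has `R^2 < min_r2`, the
#' residual sum of squares exceeds `max_rss`, the fitted radius exceeds
#' `max_rc`, or the optimizer fails.
#'
#' @param msd output of [compute_msd()] with at least `n_points` lags per
#'   trajectory.
#' @param n_points number of initial MSD points used.
#' @param max_rss rejection threshold on the RSS (um^4).
#' @param max_rc rejection threshold on the confinement radius (um).
#' @param min_r2 lenient preliminary linear-fit threshold (confined tracks
#'   have strongly curved MSDs, so this is far below the free-diffusion 0.8).
#' @return Tibble `track_id`, `Rc` (um), `D_short` (um^2/s), `rss`,
#'   `accepted`, `reason`.
#' @export
fit_confinement <- function(msd, n_points = 10L, max_rss = 1e-5,
                            max_rc = 0.3, min_r2 = 0.1) {
  msd |>
    group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      df <- arrange(df, .data$lag) |> head(n_points)
      rejected <- function(reason) {
        tibble(Rc = NA_real_, D_short = NA_real_, rss = NA_real_,
               accepted = FALSE, reason = reason)
      }
      if (nrow(df) < 3L) return(rejected("too_few_points"))
      lin <- lm(msd ~ time_s, data = df)
      r2 <- summary(lin)$r.squared
      if (!is.finite(r2) || r2 < min_r2) return(rejected("low_linear_r2"))
      start <- list(Rc2 = max(df$msd), D = max(coef(lin)[["time_s"]] / 4, 1e-4))
      fit <- tryCatch(
        minpack.lm::nlsLM(
          msd ~ Rc2 * (1 - exp(-4 * D * time_s / Rc2)),
          data = df, start = start,
          lower = c(Rc2 = 1e-8, D = 1e-8),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) return(rejected("no_convergence"))
      p <- coef(fit)
      rss <- sum(residuals(fit)^2)
      rc <- sqrt(p[["Rc2"]])
      if (rss > max_rss) return(
        tibble(Rc = rc, D_short = p[["D"]], rss = rss,
               accepted = FALSE, reason = "rss_above_threshold"))
      if (rc > max_rc) return(
        tibble(Rc = rc, D_short = p[["D"]], rss = rss,
               accepted = FALSE, reason = "rc_above_threshold"))
      tibble(Rc = rc, D_short = p[["D"]], rss = rss,
             accepted = TRUE, reason = NA_character_)
    }) |>
    ungroup()
}
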