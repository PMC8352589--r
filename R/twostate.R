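#' Pooled jump-length data for two-state kinetic fitting
#'
#' Collects jump lengths `|r(t + n dt) - r(t)|` from a fast-tracking
#' trajectory set for lags `n = 1..n_timepoints`, using at most
#' `jumps_to_consider` jumps per trajectory per lag (the first ones in
#' time), discarding jumps longer than `max_jump`, and tabulating empirical
#' CDFs on a regular grid of `bin_width`. Trajectories contribute only pairs
#' separated by exactly the lag, so gapped frames contribute nothing.
#'
#' @param trajectories tidy trajectory table; trajectories with fewer than
#'   two displacements are dropped.
#' @param frame_interval frame duration (s), 0.01 for fast tracking.
#' @param n_timepoints number of lag times.
#' @param jumps_to_consider per-trajectory, per-lag cap on contributed jumps.
#' @param bin_width CDF evaluation grid spacing (um).
#' @param max_jump maximum admissible jump (um).
#' @return Object of class `jump_length_data`: list with `jumps` (tibble
#'   `lag`, `time_s`, `r_um`), `cdf` (tibble `lag`, `time_s`, `r_um`,
#'   `cdf`), and the settings.
#' @export
build_jump_length_data <- function(trajectories, frame_interval = 0.01,
                                   n_timepoints = 6L, jumps_to_consider = 4L,
                                   bin_width = 0.01, max_jump = 2) {
  check_trajectory_cols(trajectories)
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  if (nrow(trajectories) == 0) rlang::abort("empty trajectory set")
  traj <- trajectories |>
    group_by(.data$track_id) |>
    filter(n() >= 3L) |>   # >= 2 displacements
    ungroup()
  if (nrow(traj) == 0) rlang::abort("no trajectory has >= 2 displacements")

  jumps <- purrr::map_dfr(seq_len(n_timepoints), function(L) {
    traj |>
      group_by(.data$track_id) |>
      dplyr::group_modify(function(df, key) {
        df <- arrange(df, .data$frame)
        i <- match(df$frame + L, df$frame)
        ok <- which(!is.na(i))
        if (length(ok) == 0) return(tibble(r_um = double()))
        ok <- head(ok, jumps_to_consider)
        tibble(r_um = sqrt((df$x_um[i[ok]] - df$x_um[ok])^2 +
                           (df$y_um[i[ok]] - df$y_um[ok])^2))
      }) |>
      ungroup() |>
      mutate(lag = L, time_s = L * frame_interval)
  }) |>
    filter(.data$r_um <= max_jump) |>
    dplyr::select("lag", "time_s", "r_um")

  grid <- seq(bin_width, max_jump, by = bin_width)
  cdf <- jumps |>
    group_by(.data$lag, .data$time_s) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) == 0) return(tibble(r_um = double(), cdf = double()))
      tibble(r_um = grid, cdf = ecdf(df$r_um)(grid))
    }) |>
    ungroup()

  structure(
    list(jumps = jumps, cdf = cdf,
         frame_interval = frame_interval, n_timepoints = as.integer(n_timepoints),
         jumps_to_consider = as.integer(jumps_to_consider),
         bin_width = bin_width, max_jump = max_jump),
    class = "jump_length_data"
  )
}

#' @export
print.jump_length_data <- function(x, ...) {
  cat("<jump_length_data> ", nrow(x$jumps), " jumps over ",
      length(unique(x$jumps$lag)), " lag times (dt = ",
      x$frame_interval, " s)\n", sep = "")
  invisible(x)
}

#' Fraction of molecules remaining in the axial detection slab
#'
#' Survival probability of a molecule with 1D Brownian z-motion (diffusion
#' coefficient `D`) started uniformly inside a slab of depth `dZ` with
#' absorbing boundaries, at time `t`. Computed from the eigenfunction
#' expansion of the absorbing-slab heat kernel,
#' `P(t) = sum over odd n of (8 / (n pi)^2) exp(-(n pi / dZ)^2 D t)`,
#' truncated when terms fall below 1e-10. This is the defocalization
#' correction applied to the free component of the two-state jump model:
#' fast molecules leave the focal plane and are undercounted at long lags.
#'
#' @param D diffusion coefficient (um^2/s); vectorized.
#' @param t elapsed time (s); vectorized.
#' @param dZ slab depth (um).
#' @return Fraction(s) in `[0, 1]`.
#' @export
defocalization_fraction <- function(D, t, dZ = 0.6) {
  if (any(D < 0) || any(t < 0) || dZ <= 0) {
    rlang::abort("need D >= 0, t >= 0, dZ > 0")
  }
  n <- max(length(D), length(t))
  D <- rep_len(D, n); t <- rep_len(t, n)
  alpha <- pi^2 * D * t / dZ^2
  out <- numeric(n)
  out[alpha == 0 | !is.finite(dZ)] <- 1
  todo <- which(alpha > 0 & is.finite(alpha))
  if (length(todo) > 0) {
    a <- alpha[todo]
    small <- a < 3e-7
    # short-time limit: absorbed mass grows as 2 sqrt(4 D t / pi) / dZ
    if (any(small)) {
      Dt <- D[todo][small] * t[todo][small]
      out[todo[small]] <- 1 - 2 * sqrt(4 * Dt / pi) / dZ
    }
    if (any(!small)) {
      a2 <- a[!small]
      acc <- numeric(length(a2))
      k <- 1
      repeat {
        term <- (8 / (k^2 * pi^2)) * exp(-k^2 * a2)
        acc <- acc + term
        if (all(term < 1e-10) || k > 2e5) break
        k <- k + 2
      }
      out[todo[!small]] <- acc
    }
  }
  pmin(pmax(out, 0), 1)
}

#' Slab survival under per-frame monitoring
#'
#' Probability that a molecule with 1D Brownian z-motion, started uniformly
#' in a slab of depth `dZ`, is found inside the slab at every one of
#' `n_frames` consecutive sampling times spaced `dt` apart. Unlike the
#' continuously absorbing slab of [defocalization_fraction()], the molecule
#' is only checked at frame times - which is how a camera actually loses a
#' defocalized molecule - so survival is higher, substantially so when the
#' per-frame z-step is comparable to the slab. Computed exactly (to
#' quadrature accuracy) by propagating the in-slab density with the
#' Gaussian step kernel restricted to the slab (trapezoid rule on `n_grid`
#' points).
#'
#' @param D diffusion coefficient (um^2/s).
#' @param n_frames integer vector of frame counts.
#' @param dZ slab depth (um); `Inf` gives 1.
#' @param dt frame interval (s).
#' @param n_grid quadrature grid size.
#' @return Survival fractions, one per entry of `n_frames`.
#' @export
sampled_slab_survival <- function(D, n_frames, dZ, dt, n_grid = 151L) {
  if (!is.finite(dZ)) return(rep(1, length(n_frames)))
  if (any(n_frames < 0)) rlang::abort("`n_frames` must be non-negative")
  s <- sqrt(2 * D * dt)
  if (s == 0) return(rep(1, length(n_frames)))
  z <- seq(-dZ / 2, dZ / 2, length.out = n_grid)
  h <- z[2] - z[1]
  w <- rep(h, n_grid); w[c(1, n_grid)] <- h / 2
  K <- outer(z, z, function(a, b) stats::dnorm(a, b, s))
  v <- rep(1 / dZ, n_grid)
  mx <- max(n_frames)
  surv <- numeric(mx)
  for (m in seq_len(mx)) {
    v <- as.numeric(K %*% (w * v))
    surv[m] <- sum(w * v)
  }
  ifelse(n_frames == 0, 1, surv[pmax(n_frames, 1L)])
}

#' Model CDF of the two-state jump-length distribution
#'
#' Mixture CDF of jump lengths at one lag time for the two-state kinetic
#' model: a bound Rayleigh component with scale^2 = `2 (D_bound t + sigma^2)`
#' and a free Rayleigh component with scale^2 = `2 (D_free t + sigma^2)`,
#' the free weight attenuated by the defocalization survival fraction
#' (`Use Z correction`), and the mixture renormalized to a proper CDF.
#' `sigma` is the localization error s.d. per coordinate; each displacement
#' coordinate carries `2 sigma^2` of noise variance (two localizations).
#'
#' With `dt_frame` supplied, the free weight instead uses the per-frame
#' monitored survival of [sampled_slab_survival()], averaged over the jump
#' start frames in `start_frames`: a jump at lag `n` starting at frame `j`
#' is only observed if the molecule stayed detectable for `j + n` frames
#' since track start. This is the self-consistent weighting for
#' frame-sampled detection and is what [fit_two_state()] uses by default.
#'
#' @param r jump lengths at which to evaluate (um).
#' @param lag_time lag time `n * dt` (s).
#' @param F_bound fraction bound.
#' @param D_bound,D_free state diffusion coefficients (um^2/s).
#' @param sigma localization error s.d. (um).
#' @param dZ axial detection depth (um); `Inf` disables the correction.
#' @param dt_frame frame interval (s) for the frame-sampled correction;
#'   `NULL` (default) uses the continuously absorbing slab at the lag time.
#' @param start_frames integer vector of jump start frames averaged over
#'   (used only with `dt_frame`).
#' @return CDF values, monotone non-decreasing in `r`.
#' @export
model_jump_cdf <- function(r, lag_time, F_bound, D_bound, D_free,
                           sigma, dZ = 0.6, dt_frame = NULL,
                           start_frames = 0L) {
  stop_if_not_fraction(F_bound, "F_bound")
  stop_if_not_scalar_pos(lag_time, "lag_time")
  w_b <- F_bound
  z_surv <- if (!is.finite(dZ)) {
    1
  } else if (is.null(dt_frame)) {
    defocalization_fraction(D_free, lag_time, dZ)
  } else {
    n_lag <- max(1L, round(lag_time / dt_frame))
    mean(sampled_slab_survival(D_free, start_frames + n_lag, dZ, dt_frame))
  }
  w_f <- (1 - F_bound) * z_surv
  tot <- w_b + w_f
  if (tot <= 0) rlang::abort("degenerate mixture: zero total weight")
  s2_b <- 2 * (D_bound * lag_time + sigma^2)
  s2_f <- 2 * (D_free * lag_time + sigma^2)
  (w_b * (1 - exp(-r^2 / (2 * s2_b))) +
     w_f * (1 - exp(-r^2 / (2 * s2_f)))) / tot
}

#' Fit the two-state kinetic model to pooled jump-length CDFs
#'
#' Least-squares fit of [model_jump_cdf()] to the empirical jump-length
#' CDFs jointly across all lag times (all lags weighted equally), with the
#' fraction bound, both diffusion coefficients and the localization error
#' free within box constraints. Optimization uses `L-BFGS-B` on
#' `(F_bound, log10 D_bound, log10 D_free, sigma)` with `n_init` restarts
#' (one from mid-bounds, the rest drawn within bounds from `seed`); the
#' lowest-SSE solution is returned.
#'
#' The default `"frame-sampled"` Z correction weights the free component by
#' the per-frame monitored slab survival averaged over jump start frames
#' (see [model_jump_cdf()]); `"continuous"` uses the continuously absorbing
#' slab at the bare lag time, which over-corrects for camera-sampled
#' detection and biases the fitted fraction bound downward.
#'
#' @param data a `jump_length_data` object with at least two populated lags.
#' @param D_bound_range,D_free_range,sigma_range box constraints; defaults
#'   match the standard two-state configuration for yeast nuclear factors.
#' @param dZ axial detection depth for the Z correction (um).
#' @param z_correction `"frame-sampled"` (default) or `"continuous"`.
#' @param n_init number of optimizer starts.
#' @param seed integer seed for the random restarts.
#' @return Object of class `twostate_fit`: list with `estimate` (tibble
#'   `F_bound`, `D_bound`, `D_free`, `sigma`), `sse`, `n_jumps`, `n_lags`,
#'   `converged`, `n_init`, `seed`, `dZ`, plus the per-lag model and
#'   empirical CDFs in `cdf` for plotting.
#' @export
fit_two_state <- function(data,
                          D_bound_range = c(0.0005, 0.1),
                          D_free_range = c(0.15, 25),
                          sigma_range = c(0.01, 0.1),
                          dZ = 0.6,
                          z_correction = c("frame-sampled", "continuous"),
                          n_init = 3L, seed = 1L) {
  if (!inherits(data, "jump_length_data")) {
    rlang::abort("`data` must come from build_jump_length_data()")
  }
  z_correction <- match.arg(z_correction)
  lags <- unique(data$cdf$lag)
  if (length(lags) < 2L) rlang::abort("need jump data at >= 2 lag times")
  local_seed_if_given(seed)

  dt_frame <- if (z_correction == "frame-sampled") data$frame_interval else NULL
  start_frames <- 0:(data$jumps_to_consider - 1L)
  cdf_by_lag <- split(data$cdf, data$cdf$lag)
  objective <- function(par) {
    F_b <- par[1]; D_b <- 10^par[2]; D_f <- 10^par[3]; sig <- par[4]
    sum(vapply(cdf_by_lag, function(df) {
      m <- model_jump_cdf(df$r_um, df$time_s[1], F_b, D_b, D_f, sig, dZ,
                          dt_frame = dt_frame, start_frames = start_frames)
      sum((m - df$cdf)^2)
    }, numeric(1)))
  }

  lower <- c(0, log10(D_bound_range[1]), log10(D_free_range[1]), sigma_range[1])
  upper <- c(1, log10(D_bound_range[2]), log10(D_free_range[2]), sigma_range[2])
  starts <- vector("list", n_init)
  starts[[1]] <- (lower + upper) / 2
  if (n_init > 1L) {
    for (i in 2:n_init) starts[[i]] <- runif(4, lower, upper)
  }

  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      optim(st, objective, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) rlang::abort("all optimizer starts failed")

  # round-trip through log10 can overshoot the box by an ulp; clamp exactly
  est <- tibble(
    F_bound = min(max(best$par[1], 0), 1),
    D_bound = min(max(10^best$par[2], D_bound_range[1]), D_bound_range[2]),
    D_free = min(max(10^best$par[3], D_free_range[1]), D_free_range[2]),
    sigma = min(max(best$par[4], sigma_range[1]), sigma_range[2]))
  model_cdf <- data$cdf |>
    group_by(.data$lag) |>
    mutate(model = model_jump_cdf(.data$r_um, .data$time_s[1], est$F_bound,
                                  est$D_bound, est$D_free, est$sigma, dZ,
                                  dt_frame = dt_frame,
                                  start_frames = start_frames)) |>
    ungroup()

  structure(
    list(estimate = est, sse = best$value,
         n_jumps = nrow(data$jumps), n_lags = length(lags),
         converged = best$convergence == 0, n_init = as.integer(n_init),
         seed = seed, dZ = dZ, z_correction = z_correction, cdf = model_cdf,
         bounds = list(D_bound = D_bound_range, D_free = D_free_range,
                       sigma = sigma_range)),
    class = "twostate_fit"
  )
}

#' @export
print.twostate_fit <- function(x, ...) {
  e <- x$estimate
  cat(sprintf(
    "<twostate_fit> F_bound = %.3f, D_bound = %.4f, D_free = %.3f um^2/s, sigma = %.3f um (SSE %.4g, %d jumps, %d lags)\n",
    e$F_bound, e$D_bound, e$D_free, e$sigma, x$sse, x$n_jumps, x$n_lags))
  invisible(x)
}

#' @export
tidy.twostate_fit <- function(x, ...) {
  tidyr::pivot_longer(x$estimate, dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' @export
glance.twostate_fit <- function(x, ...) {
  tibble(sse = x$sse, n_jumps = x$n_jumps, n_lags = x$n_lags,
         converged = x$converged, n_init = x$n_init)
}
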