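#' Ratio of non-specific to specific sites from slow-tracking fractions
#'
#' Estimates `r_s = N_ns / N_s` from the stable-binding fraction and the two
#' corrected residence times under two limiting interpretations of `f_sb`,
#' and averages them:
#' * scenario 1 - `f_sb` is the fraction of *time* spent bound specifically:
#'   `rs1 = (tau_sb / tau_tb) (1 / f_sb - 1)`;
#' * scenario 2 - `f_sb` is the *probability* of binding a specific site:
#'   `rs2 = 1 / f_sb - 1`;
#' * `rs = (rs1 + rs2) / 2 = (1/2) (1 / f_sb - 1) (tau_sb / tau_tb + 1)`.
#'
#' @param f_sb stable-binding fraction in `(0, 1]`.
#' @param tau_sb,tau_tb corrected stable and transient residence times (s).
#' @return Tibble `rs1`, `rs2`, `rs`.
#' @export
specificity_ratio <- function(f_sb, tau_sb, tau_tb) {
  stop_if_not_fraction(f_sb, "f_sb", open_left = TRUE)
  stop_if_not_scalar_pos(tau_sb, "tau_sb")
  stop_if_not_scalar_pos(tau_tb, "tau_tb")
  rs1 <- (tau_sb / tau_tb) * (1 / f_sb - 1)
  rs2 <- 1 / f_sb - 1
  tibble(rs1 = rs1, rs2 = rs2, rs = (rs1 + rs2) / 2)
}

#' Mean free time between chromatin-binding events
#'
#' Solves the overall bound-fraction balance
#' `F_bound = (N_trials tau_tb + tau_sb) /
#'            (N_trials tau_tb + tau_sb + (N_trials + 1) tau_free)`
#' (with `N_trials = 1 + rs`) for the free time:
#' `tau_free = ((1 + rs) tau_tb + tau_sb) (1 / F_bound - 1) / (2 + rs)`.
#'
#' @param F_bound overall chromatin-bound fraction from fast tracking, in
#'   `(0, 1)`; 1 gives a degenerate zero free time (warned).
#' @param rs non-specific to specific site ratio.
#' @param tau_sb,tau_tb residence times (s).
#' @return Free time (s).
#' @export
free_time <- function(F_bound, rs, tau_sb, tau_tb) {
  stop_if_not_fraction(F_bound, "F_bound", open_left = TRUE)
  if (F_bound == 1) {
    rlang::warn("F_bound = 1: free time is degenerate zero")
    return(0)
  }
  ((1 + rs) * tau_tb + tau_sb) * (1 / F_bound - 1) / (2 + rs)
}

#' Target search time
#'
#' Mean time from leaving one specific site to binding the next:
#' `N_trials` non-specific binding trials of mean `tau_tb` interleaved with
#' `N_trials + 1` free-diffusion excursions of mean `tau_free`:
#' `tau_search = N_trials tau_tb + (N_trials + 1) tau_free`.
#'
#' @param rs non-specific to specific site ratio (`N_trials = 1 + rs`).
#' @param tau_tb transient residence time (s).
#' @param tau_free mean free time (s).
#' @return Tibble `n_trials`, `tau_search`.
#' @export
search_time <- function(rs, tau_tb, tau_free) {
  n_trials <- 1 + rs
  tibble(n_trials = n_trials,
         tau_search = n_trials * tau_tb + (n_trials + 1) * tau_free)
}

#' Sampling interval at a specific target site
#'
#' Mean time between successive specific-binding events at one target site
#' across the nuclear population:
#' `SI = (tau_search + tau_sb) * N_targets / N_molecules`.
#'
#' @param tau_search search time (s).
#' @param tau_sb stable residence time (s).
#' @param N_targets number of specific target sites per nucleus.
#' @param N_molecules number of molecules per nucleus.
#' @return Sampling interval (s).
#' @export
sampling_interval <- function(tau_search, tau_sb, N_targets, N_molecules) {
  stop_if_not_scalar_pos(N_targets, "N_targets")
  stop_if_not_scalar_pos(N_molecules, "N_molecules")
  (tau_search + tau_sb) * N_targets / N_molecules
}

#' Temporal occupancy of a specific site
#'
#' Fraction of time a given specific site is occupied: `tau_sb / SI`. The
#' ratio is not capped at 1 (a value above 1 signals near-saturating
#' sampling and is reported with a warning rather than truncated).
#'
#' @param tau_sb stable residence time (s).
#' @param SI sampling interval (s).
#' @return Occupancy fraction.
#' @export
occupancy <- function(tau_sb, SI) {
  if (SI <= 0) rlang::abort("`SI` must be positive")
  occ <- tau_sb / SI
  if (occ > 1) rlang::warn(sprintf("occupancy %.2f exceeds 1 (saturating sampling)", occ))
  occ
}

#' Full search-kinetics chain for one factor
#'
#' Chains [specificity_ratio()], [free_time()], [search_time()],
#' [sampling_interval()] and [occupancy()] from the measured kinetic bundle
#' of a factor.
#'
#' @inheritParams specificity_ratio
#' @inheritParams free_time
#' @inheritParams sampling_interval
#' @return One-row tibble `rs1`, `rs2`, `rs`, `n_trials`, `tau_free`,
#'   `tau_search`, `sampling_interval`, `occupancy`.
#' @examples
#' derive_search_kinetics(F_bound = 0.66, f_sb = 0.27, tau_sb = 5.0,
#'                        tau_tb = 0.5, N_targets = 3702, N_molecules = 4355)
#' @export
derive_search_kinetics <- function(F_bound, f_sb, tau_sb, tau_tb,
                                   N_targets, N_molecules) {
  rs <- specificity_ratio(f_sb, tau_sb, tau_tb)
  tf <- free_time(F_bound, rs$rs, tau_sb, tau_tb)
  st <- search_time(rs$rs, tau_tb, tf)
  si <- sampling_interval(st$tau_search, tau_sb, N_targets, N_molecules)
  occ <- occupancy(tau_sb, si)
  tibble(rs1 = rs$rs1, rs2 = rs$rs2, rs = rs$rs,
         n_trials = st$n_trials, tau_free = tf, tau_search = st$tau_search,
         sampling_interval = si, occupancy = occ)
}

#' Monte-Carlo error propagation through the occupancy calculus
#'
#' Draws the measured inputs from independent Gaussians (truncated to their
#' valid ranges; invalid draws are redrawn), pushes each draw through
#' [derive_search_kinetics()], and reports the mean and standard deviation
#' of every derived quantity.
#'
#' @param kinetics a one-row data frame (or named list) with `F_bound`,
#'   `f_sb`, `tau_sb`, `tau_tb`, `N_targets`, `N_molecules` and optional
#'   standard errors named `<input>_se` (absent or `NA` means exact).
#' @param n_draws number of Monte-Carlo draws.
#' @param seed integer seed.
#' @return Tibble `quantity`, `value` (computed at the input point
#'   estimates), `mc_mean`, `se`.
#' @export
propagate_errors <- function(kinetics, n_draws = 10000L, seed = 1L) {
  kin <- as.list(kinetics)
  need <- c("F_bound", "f_sb", "tau_sb", "tau_tb", "N_targets", "N_molecules")
  missing <- setdiff(need, names(kin))
  if (length(missing) > 0) {
    rlang::abort(paste0("kinetics bundle missing: ", paste(missing, collapse = ", ")))
  }
  local_seed_if_given(seed)

  ranges <- list(F_bound = c(1e-6, 1 - 1e-6), f_sb = c(1e-6, 1),
                 tau_sb = c(1e-9, Inf), tau_tb = c(1e-9, Inf),
                 N_targets = c(1, Inf), N_molecules = c(1, Inf))
  draw_input <- function(name) {
    mu <- as.numeric(kin[[name]])
    se <- kin[[paste0(name, "_se")]]
    if (is.null(se) || is.na(se) || se == 0) return(rep(mu, n_draws))
    lo <- ranges[[name]][1]; hi <- ranges[[name]][2]
    x <- rnorm(n_draws, mu, se)
    bad <- which(x < lo | x > hi)
    tries <- 0L
    while (length(bad) > 0 && tries < 100L) {
      x[bad] <- rnorm(length(bad), mu, se)
      bad <- bad[x[bad] < lo | x[bad] > hi]
      tries <- tries + 1L
    }
    if (length(bad) > 0) {
      rlang::warn(sprintf("%d persistently invalid draws for %s clamped to range",
                          length(bad), name))
      x[bad] <- pmin(pmax(x[bad], lo), hi)
    }
    x
  }

  draws <- purrr::map(setNames(need, need), draw_input)
  # vectorized chain over draws (same algebra as derive_search_kinetics)
  rs1 <- (draws$tau_sb / draws$tau_tb) * (1 / draws$f_sb - 1)
  rs2 <- 1 / draws$f_sb - 1
  rs <- (rs1 + rs2) / 2
  tf <- ((1 + rs) * draws$tau_tb + draws$tau_sb) *
    (1 / draws$F_bound - 1) / (2 + rs)
  n_trials <- 1 + rs
  ts <- n_trials * draws$tau_tb + (n_trials + 1) * tf
  si <- (ts + draws$tau_sb) * draws$N_targets / draws$N_molecules
  occ <- draws$tau_sb / si

  point <- suppressWarnings(derive_search_kinetics(
    as.numeric(kin$F_bound), as.numeric(kin$f_sb), as.numeric(kin$tau_sb),
    as.numeric(kin$tau_tb), as.numeric(kin$N_targets),
    as.numeric(kin$N_molecules)))
  out <- list(rs1 = rs1, rs2 = rs2, rs = rs, n_trials = n_trials,
              tau_free = tf, tau_search = ts, sampling_interval = si,
              occupancy = occ)
  tibble(quantity = names(out),
         value = as.numeric(point[1, names(out)]),
         mc_mean = vapply(out, mean, numeric(1)),
         se = vapply(out, sd, numeric(1)))
}

#' Bundled kinetic parameters for promoter-acting yeast remodelers
#'
#' Literature-derived parameter bundles for the four NDR-acting
#' S. cerevisiae chromatin remodelers (RSC, SWI/SNF, INO80, ISW2):
#' live-cell SMT kinetic measurements (fraction bound, stable-binding
#' fraction and residence time, search time, sampling interval, occupancy)
#' together with genomic target counts and, where derivable, nuclear copy
#' numbers. The transient residence time `tau_tb` is a representative
#' assumed value (flagged in `tau_tb_source`), not a measured constant.
#'
#' @return Tibble, one row per remodeler; `*_se` columns are standard
#'   errors, fractions are on `[0, 1]`, times in seconds.
#' @export
remodeler_kinetics <- function() {
  path <- system.file("extdata", "remodeler_kinetics.csv",
                      package = "smtkinetics", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
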