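#' Configuration for the two-state trajectory simulator
#'
#' Bundles and validates the parameters of the synthetic single-molecule
#' tracking data generator. The generator emulates a molecule switching
#' between a chromatin-bound state (slow diffusion) and a free state (fast
#' diffusion) inside a yeast-sized nucleus, observed through a microscope
#' with finite localization precision, a finite axial detection window, and
#' photobleaching-limited track lengths.
#'
#' @param D_bound,D_free diffusion coefficients of the bound and free state
#'   (um^2/s); `D_bound < D_free` is required.
#' @param k_off_state bound-to-free switching rate (1/s).
#' @param k_on_state free-to-bound switching rate (1/s).
#' @param sigma_loc localization error s.d. per coordinate (um).
#' @param frame_interval time between frames (s); 0.01 s corresponds to the
#'   fast-tracking regime.
#' @param n_frames_mean expected number of frames before photobleaching;
#'   track lengths are geometric with this mean.
#' @param nucleus_radius radius of the reflecting circular nuclear boundary
#'   (um).
#' @param dZ depth of the axial detection window (um). Freely diffusing
#'   molecules whose 1D Brownian z-coordinate leaves the slab are lost
#'   (defocalization); pass `Inf` to disable.
#' @param n_trajectories number of trajectories to simulate.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_two_state_trajectories()]
#' @export
sim_config <- function(D_bound = 0.03,
                       D_free = 1.0,
                       k_off_state = 5,
                       k_on_state = 5,
                       sigma_loc = 0.025,
                       frame_interval = 0.01,
                       n_frames_mean = 20,
                       nucleus_radius = 1.0,
                       dZ = 0.6,
                       n_trajectories = 1000,
                       seed = 1L) {
  stop_if_not_scalar_pos(D_bound, "D_bound")
  stop_if_not_scalar_pos(D_free, "D_free")
  stop_if_not_scalar_pos(k_off_state, "k_off_state", allow_zero = TRUE)
  stop_if_not_scalar_pos(k_on_state, "k_on_state", allow_zero = TRUE)
  stop_if_not_scalar_pos(sigma_loc, "sigma_loc")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  stop_if_not_scalar_pos(n_frames_mean, "n_frames_mean")
  stop_if_not_scalar_pos(nucleus_radius, "nucleus_radius")
  if (!(is.numeric(dZ) && length(dZ) == 1L && dZ > 0)) {
    rlang::abort("`dZ` must be positive (possibly Inf)")
  }
  stop_if_not_scalar_pos(n_trajectories, "n_trajectories")
  if (D_bound >= D_free) {
    rlang::abort("`D_bound` must be smaller than `D_free`")
  }
  # a typical free-state step must fit inside the nucleus
  if (sqrt(2 * D_free * frame_interval) > nucleus_radius) {
    rlang::abort("free-state step s.d. exceeds `nucleus_radius`; non-physical config")
  }
  structure(
    list(D_bound = D_bound, D_free = D_free,
         k_off_state = k_off_state, k_on_state = k_on_state,
         sigma_loc = sigma_loc, frame_interval = frame_interval,
         n_frames_mean = n_frames_mean, nucleus_radius = nucleus_radius,
         dZ = dZ, n_trajectories = as.integer(n_trajectories),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate two-state single-molecule trajectories with ground truth
#'
#' Generates 2D random-walk trajectories of molecules switching between a
#' bound (slow) and a free (fast) diffusive state as a discrete-time Markov
#' chain, with per-frame transition probabilities `1 - exp(-k * dt)`.
#' Per-frame displacements are Gaussian with variance `2 * D_state * dt` per
#' coordinate; positions are reflected at the circular nuclear boundary;
#' independent Gaussian localization noise of s.d. `sigma_loc` is added per
#' coordinate; track length is geometric (photobleaching) with mean
#' `n_frames_mean`; and molecules in the free state are lost when their 1D
#' Brownian z-coordinate (uniform initial position) exits the detection slab
#' of depth `dZ`.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `smt_sim` with elements
#'   * `trajectories`: tibble with columns `track_id`, `frame`, `x_um`,
#'     `y_um` (localization-noise-corrupted observed positions),
#'   * `ground_truth`: tibble with columns `track_id`, `step` (frame index
#'     of the displacement's later endpoint), `state` (`"bound"`/`"free"`),
#'     one row per observed displacement,
#'   * `config`: the input configuration.
#' @examples
#' sim <- simulate_two_state_trajectories(sim_config(n_trajectories = 50))
#' head(sim$trajectories)
#' @export
simulate_two_state_trajectories <- function(config) {
  if (!inherits(config, "sim_config")) {
    rlang::abort("`config` must be created with sim_config()")
  }
  local_seed_if_given(config$seed)
  dt <- config$frame_interval
  n_traj <- config$n_trajectories

  # per-trajectory photobleaching-limited length (number of localizations)
  n_loc <- pmax(2L, rgeom(n_traj, prob = 1 / config$n_frames_mean) + 1L)
  max_disp <- max(n_loc) - 1L

  p_bf <- 1 - exp(-config$k_off_state * dt)  # bound -> free per frame
  p_fb <- 1 - exp(-config$k_on_state * dt)   # free  -> bound per frame
  k_tot <- config$k_on_state + config$k_off_state
  p_bound_stat <- if (k_tot > 0) config$k_on_state / k_tot else 0.5

  # state per displacement, simulated as a vectorized Markov chain across
  # trajectories (1 = bound, 2 = free)
  states <- matrix(NA_integer_, nrow = max_disp, ncol = n_traj)
  cur <- ifelse(runif(n_traj) < p_bound_stat, 1L, 2L)
  states[1L, ] <- cur
  if (max_disp > 1L) {
    for (t in 2:max_disp) {
      u <- runif(n_traj)
      cur <- ifelse(cur == 1L,
                    ifelse(u < p_bf, 2L, 1L),
                    ifelse(u < p_fb, 1L, 2L))
      states[t, ] <- cur
    }
  }

  sd_step <- sqrt(2 * c(config$D_bound, config$D_free) * dt)
  step_sd <- matrix(sd_step[states], nrow = max_disp)

  # xy positions with radial reflection at the nuclear envelope
  R <- config$nucleus_radius
  x <- matrix(NA_real_, nrow = max_disp + 1L, ncol = n_traj)
  y <- matrix(NA_real_, nrow = max_disp + 1L, ncol = n_traj)
  r0 <- R * sqrt(runif(n_traj))
  th0 <- runif(n_traj, 0, 2 * pi)
  x[1L, ] <- r0 * cos(th0)
  y[1L, ] <- r0 * sin(th0)
  for (t in seq_len(max_disp)) {
    xn <- x[t, ] + rnorm(n_traj, sd = step_sd[t, ])
    yn <- y[t, ] + rnorm(n_traj, sd = step_sd[t, ])
    rr <- sqrt(xn^2 + yn^2)
    out <- rr > R & is.finite(rr)
    if (any(out)) {
      fac <- (2 * R - rr[out]) / rr[out]
      fac <- pmax(fac, 0)  # guard pathological double-radius excursions
      xn[out] <- xn[out] * fac
      yn[out] <- yn[out] * fac
    }
    x[t + 1L, ] <- xn
    y[t + 1L, ] <- yn
  }

  # axial coordinate: uniform start in the slab; a molecule is lost at the
  # first frame where it sits outside the slab while in the free state
  keep_loc <- n_loc
  if (is.finite(config$dZ)) {
    half <- config$dZ / 2
    z <- matrix(NA_real_, nrow = max_disp + 1L, ncol = n_traj)
    z[1L, ] <- runif(n_traj, -half, half)
    for (t in seq_len(max_disp)) {
      z[t + 1L, ] <- z[t, ] + rnorm(n_traj, sd = step_sd[t, ])
    }
    for (j in seq_len(n_traj)) {
      nd <- n_loc[j] - 1L
      esc <- which(abs(z[2:(nd + 1L), j]) > half & states[1:nd, j] == 2L)
      if (length(esc) > 0) keep_loc[j] <- esc[1L]  # position esc+1 unobserved
    }
  }

  keep <- which(keep_loc >= 2L)
  traj_list <- vector("list", length(keep))
  gt_list <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    j <- keep[i]
    nl <- keep_loc[j]
    traj_list[[i]] <- tibble(
      track_id = i,
      frame = 0:(nl - 1L),
      x_um = x[1:nl, j] + rnorm(nl, sd = config$sigma_loc),
      y_um = y[1:nl, j] + rnorm(nl, sd = config$sigma_loc)
    )
    gt_list[[i]] <- tibble(
      track_id = i,
      step = seq_len(nl - 1L),
      state = c("bound", "free")[states[1:(nl - 1L), j]]
    )
  }

  structure(
    list(trajectories = dplyr::bind_rows(traj_list),
         ground_truth = dplyr::bind_rows(gt_list),
         config = config),
    class = "smt_sim"
  )
}

#' @export
print.smt_sim <- function(x, ...) {
  n_tr <- length(unique(x$trajectories$track_id))
  cat("<smt_sim> ", n_tr, " trajectories, ",
      nrow(x$trajectories), " localizations, frame interval ",
      x$config$frame_interval, " s\n", sep = "")
  invisible(x)
}

#' Simulate apparent chromatin dwell times (slow-tracking forward model)
#'
#' Draws binding-event durations from a two-component exponential mixture
#' (stable events with probability `f_sb` and rate `k_sb`, transient events
#' otherwise with rate `k_tb`), truncates each by an independent exponential
#' photobleaching time of rate `k_bleach`, and quantizes the observed
#' duration up to whole frames (a molecule present during any part of a
#' frame is detected).
#'
#' @param f_sb fraction of stable-binding events in `[0, 1]`.
#' @param k_sb,k_tb dissociation rates (1/s) of the stable and transient
#'   class; `k_sb < k_tb` is required.
#' @param k_bleach apparent loss rate (1/s) from photobleaching and focal
#'   drift; 0 disables truncation.
#' @param n number of events.
#' @param frame_interval frame duration used for quantization (s); defaults
#'   to the 250 ms slow-tracking convention.
#' @param seed integer seed.
#' @return Tibble with columns `event`, `class` (`"stable"`/`"transient"`),
#'   `true_s` (untruncated duration) and `dwell_s` (observed, quantized).
#' @export
simulate_dwell_events <- function(f_sb, k_sb, k_tb, k_bleach = 0, n = 1000,
                                  frame_interval = 0.25, seed = NULL) {
  stop_if_not_fraction(f_sb, "f_sb")
  stop_if_not_scalar_pos(k_sb, "k_sb")
  stop_if_not_scalar_pos(k_tb, "k_tb")
  stop_if_not_scalar_pos(k_bleach, "k_bleach", allow_zero = TRUE)
  stop_if_not_scalar_pos(n, "n")
  stop_if_not_scalar_pos(frame_interval, "frame_interval")
  if (k_sb >= k_tb) {
    rlang::abort("`k_sb` must be smaller than `k_tb` (stable events live longer)")
  }
  local_seed_if_given(seed)
  n <- as.integer(n)
  stable <- runif(n) < f_sb
  true_s <- ifelse(stable, rexp(n, rate = k_sb), rexp(n, rate = k_tb))
  obs <- if (k_bleach > 0) pmin(true_s, rexp(n, rate = k_bleach)) else true_s
  dwell <- ceiling(obs / frame_interval) * frame_interval
  tibble(event = seq_len(n),
         class = ifelse(stable, "stable", "transient"),
         true_s = true_s,
         dwell_s = dwell)
}

#' Simulate an apparent-dwell reference standard
#'
#' Generates single-exponential apparent dwell times mimicking a stably
#' incorporated reference protein (histone H2B) whose apparent loss under
#' slow tracking is dominated by photobleaching and chromatin movement out
#' of focus rather than true dissociation.
#'
#' @param k_apparent apparent single-exponential loss rate (1/s).
#' @param n number of events.
#' @inheritParams simulate_dwell_events
#' @return Tibble with columns `event` and `dwell_s`.
#' @export
simulate_reference_standard <- function(k_apparent, n = 1000,
                                        frame_interval = 0.25, seed = NULL) {
  stop_if_not_scalar_pos(k_apparent, "k_apparent")
  stop_if_not_scalar_pos(n, "n")
  local_seed_if_given(seed)
  n <- as.integer(n)
  dwell <- ceiling(rexp(n, rate = k_apparent) / frame_interval) * frame_interval
  tibble(event = seq_len(n), dwell_s = dwell)
}
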