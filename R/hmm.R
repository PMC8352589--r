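# Internal: squared displacements between consecutive frames, split into
# gapless segments so every emission spans exactly one frame interval.
displacement_sequences <- function(trajectories, min_displacements = 2L) {
  check_trajectory_cols(trajectories)
  trajectories |>
    arrange(.data$track_id, .data$frame) |>
    group_by(.data$track_id) |>
    mutate(seg = cumsum(c(0L, diff(.data$frame) != 1L))) |>
    group_by(.data$track_id, .data$seg) |>
    filter(n() >= min_displacements + 1L) |>
    mutate(step = .data$frame + 1L,  # displacement attributed to its later frame
           r2 = (lead(.data$x_um) - .data$x_um)^2 +
                (lead(.data$y_um) - .data$y_um)^2) |>
    filter(!is.na(.data$r2)) |>
    ungroup() |>
    dplyr::select("track_id", "seg", "step", "r2")
}

# Emission density of a squared 2D displacement under isotropic diffusion:
# r^2 ~ Exponential(mean 4 D dt). Localization error is deliberately not
# modeled (it inflates the slow-state D by sigma^2/dt).
emission_matrix <- function(R2, D, dt) {
  m <- 4 * D * dt
  exp(-R2 / m) / m
}

#' Fit a two-state displacement hidden Markov model
#'
#' Maximum-likelihood two-state HMM over all trajectory displacement
#' sequences via Baum-Welch (EM). Hidden states are "bound" (slow) and
#' "free" (fast); emissions are squared consecutive-frame displacements,
#' exponential with mean `4 D_state dt`. Multiple restarts draw initial
#' diffusion coefficients log-uniformly in `init_D_range` and initial state
#' dwell times uniformly in `init_dwell_frames` frames; the best-likelihood
#' solution is kept and states are relabeled so `D1 < D2`.
#'
#' @param trajectories tidy trajectory table; tracks are split at frame gaps
#'   and segments with fewer than `min_displacements` displacements are
#'   dropped.
#' @param frame_interval frame duration (s).
#' @param min_displacements minimum displacements per segment.
#' @param n_restarts number of EM restarts.
#' @param max_iter,tol EM stopping rule (relative log-likelihood change).
#' @param init_D_range,init_dwell_frames restart initialization ranges.
#' @param seed integer seed for the restarts.
#' @return Object of class `hmm_model`: `D` (named vector, um^2/s),
#'   `transition` (2x2 per-frame matrix, rows sum to 1), `initial`,
#'   `loglik`, `n_sequences`, `n_displacements`, `iterations`, `degenerate`
#'   (states collapsed: `|log10(D2/D1)| < 0.1`), `frame_interval`, `seed`.
#' @export
fit_hmm_two_state <- function(trajectories, frame_interval = 0.01,
                              min_displacements = 2L, n_restarts = 3L,
                              max_iter = 200L, tol = 1e-8,
                              init_D_range = c(0.001, 16),
                              init_dwell_frames = c(2, 20),
                              seed = 1L) {
  seqs <- displacement_sequences(trajectories, min_displacements)
  if (nrow(seqs) == 0) rlang::abort("no usable displacement sequences")
  local_seed_if_given(seed)
  dt <- frame_interval

  sp <- split(seqs$r2, interaction(seqs$track_id, seqs$seg, drop = TRUE))
  len <- lengths(sp)
  N <- length(sp); Tm <- max(len)
  R2 <- matrix(NA_real_, nrow = Tm, ncol = N)
  for (i in seq_len(N)) R2[seq_len(len[i]), i] <- sp[[i]]

  run_em <- function(D, A, pi0) {
    ll_old <- -Inf
    ll_trace <- numeric(0)
    for (iter in seq_len(max_iter)) {
      B1 <- emission_matrix(R2, D[1], dt)
      B2 <- emission_matrix(R2, D[2], dt)
      # scaled forward
      a1 <- matrix(0, Tm, N); a2 <- matrix(0, Tm, N); cs <- matrix(1, Tm, N)
      a1[1, ] <- pi0[1] * B1[1, ]; a2[1, ] <- pi0[2] * B2[1, ]
      c1 <- a1[1, ] + a2[1, ]
      a1[1, ] <- a1[1, ] / c1; a2[1, ] <- a2[1, ] / c1; cs[1, ] <- c1
      if (Tm > 1) for (t in 2:Tm) {
        act <- !is.na(R2[t, ])
        p1 <- (a1[t - 1, act] * A[1, 1] + a2[t - 1, act] * A[2, 1]) * B1[t, act]
        p2 <- (a1[t - 1, act] * A[1, 2] + a2[t - 1, act] * A[2, 2]) * B2[t, act]
        ct <- p1 + p2
        a1[t, act] <- p1 / ct; a2[t, act] <- p2 / ct; cs[t, act] <- ct
      }
      ll <- sum(log(cs[!is.na(R2)]))
      ll_trace <- c(ll_trace, ll)
      # scaled backward
      b1 <- matrix(0, Tm, N); b2 <- matrix(0, Tm, N)
      b1[cbind(len, seq_len(N))] <- 1; b2[cbind(len, seq_len(N))] <- 1
      xi11 <- xi12 <- xi21 <- xi22 <- 0
      g1s <- g1e <- g2s <- g2e <- 0  # gamma sums over t < T (s) and all t (e)
      gr1 <- gr2 <- 0                # gamma-weighted r^2 sums
      gi1 <- gi2 <- 0                # initial-state gamma sums
      if (Tm > 1) for (t in (Tm - 1):1) {
        act <- which(!is.na(R2[t + 1, ]))
        v1 <- B1[t + 1, act] * b1[t + 1, act]
        v2 <- B2[t + 1, act] * b2[t + 1, act]
        ct <- cs[t + 1, act]
        b1[t, act] <- (A[1, 1] * v1 + A[1, 2] * v2) / ct
        b2[t, act] <- (A[2, 1] * v1 + A[2, 2] * v2) / ct
        xi11 <- xi11 + sum(a1[t, act] * A[1, 1] * v1 / ct)
        xi12 <- xi12 + sum(a1[t, act] * A[1, 2] * v2 / ct)
        xi21 <- xi21 + sum(a2[t, act] * A[2, 1] * v1 / ct)
        xi22 <- xi22 + sum(a2[t, act] * A[2, 2] * v2 / ct)
        # sequences of length exactly t also end here; their beta stays 1
        ended <- which(len == t)
        if (length(ended) > 0) { b1[t, ended] <- 1; b2[t, ended] <- 1 }
      }
      g1 <- a1 * b1; g2 <- a2 * b2
      valid <- !is.na(R2)
      g1e <- sum(g1[valid]); g2e <- sum(g2[valid])
      gr1 <- sum(g1[valid] * R2[valid]); gr2 <- sum(g2[valid] * R2[valid])
      lastmask <- matrix(FALSE, Tm, N); lastmask[cbind(len, seq_len(N))] <- TRUE
      notlast <- valid & !lastmask
      g1s <- sum(g1[notlast]); g2s <- sum(g2[notlast])
      gi1 <- sum(g1[1, ]); gi2 <- sum(g2[1, ])

      D_new <- c(gr1 / (4 * dt * g1e), gr2 / (4 * dt * g2e))
      A_new <- A
      if (g1s > 0) A_new[1, ] <- c(xi11, xi12) / g1s
      if (g2s > 0) A_new[2, ] <- c(xi21, xi22) / g2s
      A_new <- A_new / rowSums(A_new)
      pi_new <- c(gi1, gi2) / N

      D <- pmax(D_new, 1e-8); A <- pmin(pmax(A_new, 1e-8), 1 - 1e-8)
      A <- A / rowSums(A); pi0 <- pmin(pmax(pi_new, 1e-8), 1 - 1e-8)
      pi0 <- pi0 / sum(pi0)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) break
      ll_old <- ll
    }
    list(D = D, A = A, pi = pi0, loglik = ll, iterations = iter,
         loglik_trace = ll_trace)
  }

  best <- NULL
  for (r in seq_len(n_restarts)) {
    D0 <- sort(10^runif(2, log10(init_D_range[1]), log10(init_D_range[2])))
    dwell <- runif(2, init_dwell_frames[1], init_dwell_frames[2])
    A0 <- rbind(c(1 - 1 / dwell[1], 1 / dwell[1]),
                c(1 / dwell[2], 1 - 1 / dwell[2]))
    fit <- run_em(D0, A0, c(0.5, 0.5))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(best$D)
  D <- best$D[ord]
  A <- best$A[ord, ord, drop = FALSE]
  pi0 <- best$pi[ord]
  degenerate <- abs(log10(D[2] / D[1])) < 0.1
  if (degenerate) {
    rlang::warn("HMM states collapsed (|log10(D2/D1)| < 0.1); model flagged degenerate")
  }
  dimnames(A) <- list(c("bound", "free"), c("bound", "free"))
  structure(
    list(D = setNames(D, c("bound", "free")), transition = A,
         initial = setNames(pi0, c("bound", "free")),
         loglik = best$loglik, loglik_trace = best$loglik_trace,
         n_sequences = N,
         n_displacements = sum(len), iterations = best$iterations,
         degenerate = degenerate, frame_interval = dt, seed = seed),
    class = "hmm_model"
  )
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf(
    "<hmm_model> D_bound = %.4f, D_free = %.3f um^2/s; p(b->f) = %.3f, p(f->b) = %.3f per frame; loglik %.1f (%d sequences)\n",
    x$D[1], x$D[2], x$transition[1, 2], x$transition[2, 1],
    x$loglik, x$n_sequences))
  if (x$degenerate) cat("note: degenerate (collapsed states)\n")
  invisible(x)
}

#' @export
tidy.hmm_model <- function(x, ...) {
  tibble(state = c("bound", "free"),
         D = as.numeric(x$D),
         p_stay = diag(x$transition),
         p_switch = 1 - diag(x$transition),
         initial = as.numeric(x$initial))
}

#' @export
glance.hmm_model <- function(x, ...) {
  tibble(loglik = x$loglik, n_sequences = x$n_sequences,
         n_displacements = x$n_displacements, iterations = x$iterations,
         degenerate = x$degenerate)
}

#' Classify each displacement as bound or free (Viterbi decoding)
#'
#' Most-probable hidden-state path per trajectory segment under a fitted
#' two-state displacement HMM. Viterbi decoding (rather than per-step
#' posterior thresholding) yields contiguous state runs, which the
#' trajectory sub-classification rule relies on.
#'
#' @param model a fitted `hmm_model`.
#' @param trajectories tidy trajectory table (same frame interval as used
#'   for fitting).
#' @param min_displacements minimum displacements per segment, as in
#'   [fit_hmm_two_state()].
#' @return Tibble `track_id`, `step` (frame index of the displacement
#'   start), `state` (`"bound"`/`"free"`).
#' @export
classify_displacements <- function(model, trajectories,
                                   min_displacements = 2L) {
  if (!inherits(model, "hmm_model")) rlang::abort("`model` must be an hmm_model")
  if (model$degenerate) {
    rlang::abort("refusing to decode with a degenerate (collapsed-state) model")
  }
  seqs <- displacement_sequences(trajectories, min_displacements)
  dt <- model$frame_interval
  lA <- log(model$transition); lpi <- log(model$initial)
  seqs |>
    group_by(.data$track_id, .data$seg) |>
    dplyr::group_modify(function(df, key) {
      r2 <- df$r2
      Tn <- length(r2)
      if (Tn == 0L) return(tibble(step = integer(0), state = character(0)))
      lb <- cbind(log(emission_matrix(r2, model$D[1], dt)),
                  log(emission_matrix(r2, model$D[2], dt)))
      delta <- matrix(-Inf, Tn, 2); psi <- matrix(1L, Tn, 2)
      delta[1, ] <- lpi + lb[1, ]
      if (Tn > 1) for (t in 2:Tn) {
        for (s in 1:2) {
          cand <- delta[t - 1, ] + lA[, s]
          psi[t, s] <- which.max(cand)
          delta[t, s] <- cand[psi[t, s]] + lb[t, s]
        }
      }
      path <- integer(Tn)
      path[Tn] <- which.max(delta[Tn, ])
      if (Tn > 1) for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
      tibble(step = df$step, state = c("bound", "free")[path])
    }) |>
    ungroup() |>
    dplyr::select("track_id", "step", "state")
}

#' Sub-classify trajectories from displacement state labels
#'
#' Applies the three-way rule: a trajectory is `bound_only` if every
#' displacement is bound, `free_only` if every displacement is free, and
#' `transitioning` if both states occur with at least two consecutive
#' displacements in each state. Trajectories containing both states but
#' lacking a two-displacement run in each (e.g. B,F,B,F) fall into
#' `mixed_unclassified` and are excluded from the three-class percentages.
#'
#' @param labels output of [classify_displacements()].
#' @return Tibble `track_id`, `class`, `n_bound`, `n_free`, `n_bf`, `n_fb`
#'   (`n_bf` counts bound-to-free state changes).
#' @export
subclassify_trajectories <- function(labels) {
  labels |>
    group_by(.data$track_id) |>
    dplyr::group_modify(function(df, key) {
      s <- df$state[order(df$step)]
      runs <- rle(s)
      n_b <- sum(s == "bound"); n_f <- sum(s == "free")
      cls <- if (n_f == 0) "bound_only"
      else if (n_b == 0) "free_only"
      else if (max(c(0, runs$lengths[runs$values == "bound"])) >= 2 &&
               max(c(0, runs$lengths[runs$values == "free"])) >= 2) "transitioning"
      else "mixed_unclassified"
      ch <- paste0(head(runs$values, -1), "->", tail(runs$values, -1))
      tibble(class = cls, n_bound = n_b, n_free = n_f,
             n_bf = sum(ch == "bound->free"), n_fb = sum(ch == "free->bound"))
    }) |>
    ungroup()
}

#' Summarize trajectory classes and transition directions
#'
#' @param classes output of [subclassify_trajectories()].
#' @return List with `classes` (tibble `class`, `n`, `pct`; percentages over
#'   the three assigned classes, with `mixed_unclassified` shown but
#'   excluded from the denominator) and `transitions` (tibble `direction`,
#'   `n`, `frac`).
#' @export
class_summary <- function(classes) {
  counts <- classes |>
    dplyr::count(.data$class, name = "n")
  denom <- sum(counts$n[counts$class != "mixed_unclassified"])
  counts <- counts |>
    mutate(pct = ifelse(.data$class == "mixed_unclassified", NA_real_,
                        100 * .data$n / denom))
  n_bf <- sum(classes$n_bf); n_fb <- sum(classes$n_fb)
  trans <- tibble(direction = c("bound->free", "free->bound"),
                  n = c(n_bf, n_fb),
                  frac = if (n_bf + n_fb > 0) c(n_bf, n_fb) / (n_bf + n_fb)
                         else c(NA_real_, NA_real_))
  list(classes = counts, transitions = trans)
}
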