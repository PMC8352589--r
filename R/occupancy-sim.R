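#' Simulate a stochastic occupied/vacant trace of a promoter target
#'
#' Event-driven simulation of a single specific target site alternating
#' between occupied and vacant states. Occupied durations are exponential
#' with mean `tau_sb`; vacant durations exponential with mean
#' `SI - tau_sb`, so one occupied-vacant cycle averages one sampling
#' interval and the long-run occupied fraction is `tau_sb / SI`. The
#' initial state is drawn from the stationary distribution (occupied with
#' probability `tau_sb / SI`), which together with the memoryless durations
#' makes the trace exactly stationary - no burn-in is needed.
#'
#' @param tau_sb mean occupied duration (s).
#' @param SI sampling interval (s); must exceed `tau_sb`.
#' @param duration trace length (s).
#' @param factor label carried in the output.
#' @param seed integer seed.
#' @return Tibble of class `occupancy_trace` with columns `factor`,
#'   `start_s`, `end_s`, `state` (`"occupied"`/`"vacant"`); intervals are
#'   contiguous and cover `[0, duration]`.
#' @export
simulate_trace <- function(tau_sb, SI, duration = 500, factor = "factor",
                           seed = 1L) {
  stop_if_not_scalar_pos(tau_sb, "tau_sb")
  stop_if_not_scalar_pos(duration, "duration")
  if (!(is.numeric(SI) && length(SI) == 1L && SI > tau_sb)) {
    rlang::abort("`SI` must exceed `tau_sb` (vacant mean SI - tau_sb must be positive)")
  }
  local_seed_if_given(seed)
  mean_off <- SI - tau_sb
  occupied_first <- runif(1) < tau_sb / SI

  # draw interval durations in chunks until the trace is covered
  durs <- numeric(0)
  total <- 0
  chunk <- max(64L, ceiling(2.5 * duration / SI))
  first_occ <- occupied_first
  while (total < duration) {
    k <- length(durs)
    # alternate means depending on the parity of the next interval
    next_occ <- xor(first_occ, k %% 2L == 1L)
    n_pairs <- ceiling(chunk / 2)
    on <- rexp(n_pairs, rate = 1 / tau_sb)
    off <- rexp(n_pairs, rate = 1 / mean_off)
    new <- if (next_occ) as.numeric(rbind(on, off)) else as.numeric(rbind(off, on))
    durs <- c(durs, new)
    total <- sum(durs)
  }
  ends <- cumsum(durs)
  n_keep <- which(ends >= duration)[1]
  durs <- durs[seq_len(n_keep)]
  ends <- cumsum(durs)
  ends[n_keep] <- duration
  starts <- c(0, ends[-n_keep])
  state <- rep(c("occupied", "vacant"), length.out = n_keep)
  if (!occupied_first) state <- rep(c("vacant", "occupied"), length.out = n_keep)

  out <- tibble(factor = factor, start_s = starts, end_s = ends, state = state)
  class(out) <- c("occupancy_trace", class(out))
  out
}

#' Time-weighted occupied fraction of a trace
#'
#' @param trace an `occupancy_trace`.
#' @return Fraction of the trace duration spent occupied.
#' @export
occupied_fraction <- function(trace) {
  dur <- trace$end_s - trace$start_s
  sum(dur[trace$state == "occupied"]) / sum(dur)
}

#' Co-occupancy statistics for several factors at one target
#'
#' Overlays independent occupancy traces of equal duration and computes the
#' time-weighted fraction of the trace in every Boolean combination: each
#' factor alone, at least one factor bound, all factors bound, and the
#' distribution of the number of simultaneously bound factors.
#'
#' @param traces list of `occupancy_trace` objects of identical duration.
#' @return List with `summary` (tibble `metric`, `fraction`: per-factor
#'   occupancies plus `any_occupied` and `all_occupied`) and `by_count`
#'   (tibble `n_occupied`, `fraction`).
#' @export
co_occupancy <- function(traces) {
  if (!is.list(traces) || length(traces) == 0) {
    rlang::abort("`traces` must be a non-empty list of occupancy traces")
  }
  durs <- vapply(traces, function(tr) max(tr$end_s), numeric(1))
  if (max(durs) - min(durs) > 1e-9) {
    rlang::abort("all traces must have the same duration")
  }
  duration <- durs[1]
  edges <- sort(unique(c(0, duration,
                         unlist(lapply(traces, function(tr) c(tr$start_s, tr$end_s))))))
  edges <- edges[edges >= 0 & edges <= duration]
  seg_start <- head(edges, -1)
  seg_len <- diff(edges)
  mid <- seg_start + seg_len / 2

  occ_mat <- vapply(traces, function(tr) {
    idx <- findInterval(mid, tr$start_s)
    tr$state[idx] == "occupied"
  }, logical(length(mid)))
  if (is.null(dim(occ_mat))) occ_mat <- matrix(occ_mat, ncol = length(traces))

  labels <- vapply(seq_along(traces), function(i) {
    f <- unique(traces[[i]]$factor)[1]
    if (is.na(f) || f == "factor") paste0("factor_", i) else f
  }, character(1))

  per_factor <- colSums(occ_mat * seg_len) / duration
  n_occ <- rowSums(occ_mat)
  by_count <- tibble(n_occupied = 0:length(traces)) |>
    mutate(fraction = vapply(.data$n_occupied, function(k) {
      sum(seg_len[n_occ == k]) / duration
    }, numeric(1)))

  summary <- dplyr::bind_rows(
    tibble(metric = labels, fraction = per_factor),
    tibble(metric = "any_occupied",
           fraction = sum(seg_len[n_occ >= 1]) / duration),
    tibble(metric = "all_occupied",
           fraction = sum(seg_len[n_occ == length(traces)]) / duration)
  )
  list(summary = summary, by_count = by_count)
}
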