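#' Read a trajectory table from CSV
#'
#' Reads a trajectory CSV (columns `track_id`, `frame`, and positions either
#' in micrometres as `x_um`/`y_um` or in pixels as `x_px`/`y_px`), converts
#' positions to micrometres, validates frame ordering and returns a tidy
#' trajectory table sorted by track then frame.
#'
#' @param path CSV file path.
#' @param pixel_size camera pixel size in um (default 0.107, a 150x EM-CCD
#'   configuration) used when positions are given in pixels.
#' @return Tibble with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @export
read_trajectories <- function(path, pixel_size = 0.107) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("track_id", "frame") %in% names(df))) {
    rlang::abort("trajectory CSV must contain `track_id` and `frame` columns")
  }
  if (all(c("x_um", "y_um") %in% names(df))) {
    df <- dplyr::select(df, "track_id", "frame", "x_um", "y_um")
  } else if (all(c("x_px", "y_px") %in% names(df))) {
    stop_if_not_scalar_pos(pixel_size, "pixel_size")
    df <- df |>
      mutate(x_um = .data$x_px * pixel_size, y_um = .data$y_px * pixel_size) |>
      dplyr::select("track_id", "frame", "x_um", "y_um")
  } else {
    rlang::abort("positions must be given as `x_um`/`y_um` or `x_px`/`y_px`")
  }
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um))) {
    rlang::abort("non-finite coordinates in trajectory file")
  }
  if (any(df$frame < 0)) rlang::abort("negative frame indices")
  dup <- df |> dplyr::count(.data$track_id, .data$frame) |> filter(n > 1L)
  if (nrow(dup) > 0) {
    rlang::abort(sprintf("duplicated (track_id, frame) pairs, e.g. track %s frame %s",
                         dup$track_id[1], dup$frame[1]))
  }
  df <- arrange(df, .data$track_id, .data$frame)
  n_single <- df |> dplyr::count(.data$track_id) |> filter(n < 2L) |> nrow()
  if (n_single > 0) {
    rlang::inform(sprintf("dropping %d single-localization track(s)", n_single))
    df <- df |> group_by(.data$track_id) |> filter(n() >= 2L) |> ungroup()
  }
  rlang::inform(sprintf("read %d localizations in %d trajectories",
                        nrow(df), dplyr::n_distinct(df$track_id)))
  df
}

#' Write a trajectory table (with optional simulation sidecar)
#'
#' @param trajectories tibble with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @param path output CSV path.
#' @param config optional [sim_config()] (or named list) written as a YAML
#'   sidecar `<path>.yaml` recording the frame interval and, for synthetic
#'   data, the true generating parameters.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path, config = NULL) {
  check_trajectory_cols(trajectories)
  readr::write_csv(trajectories[, c("track_id", "frame", "x_um", "y_um")], path)
  if (!is.null(config)) {
    yaml::write_yaml(unclass(config), paste0(path, ".yaml"))
  }
  invisible(path)
}

#' Link localizations into trajectories with gap tolerance
#'
#' Reconstructs slow-tracking trajectories from per-frame localizations by
#' greedy nearest-neighbour linking: a localization is appended to an active
#' track when it lies strictly closer than `max_dist` pixels to the track's
#' last position and at most `max_gap` full frames are missing in between
#' (blinking / transient mislocalization tolerance). Candidate links are
#' resolved by smallest distance, then earliest last frame, then lowest
#' track index, which makes the greedy assignment deterministic. Linking
#' only partitions the input: every localization appears in exactly one
#' output track.
#'
#' @param locs tibble with columns `frame`, `x_um`, `y_um` (no track ids).
#' @param max_gap maximum number of missing frames bridged within one track.
#' @param max_dist maximum linking distance in pixels (strict inequality).
#' @param pixel_size pixel size in um used to convert `max_dist`.
#' @return Tibble `track_id`, `frame`, `x_um`, `y_um`; single-localization
#'   tracks are retained (they carry no displacement but count as events).
#' @export
link_with_gaps <- function(locs, max_gap = 2L, max_dist = 3,
                           pixel_size = 0.107) {
  if (nrow(locs) == 0) {
    return(tibble(track_id = integer(), frame = integer(),
                  x_um = double(), y_um = double()))
  }
  check_trajectory_cols(locs, c("frame", "x_um", "y_um"))
  max_dist_um <- max_dist * pixel_size
  locs <- arrange(as_tibble(locs), .data$frame)
  frames <- sort(unique(locs$frame))

  track_of <- integer(nrow(locs))
  last_x <- last_y <- numeric(0)
  last_frame <- integer(0)
  n_tracks <- 0L

  idx_by_frame <- split(seq_len(nrow(locs)), locs$frame)
  for (f in frames) {
    idx <- idx_by_frame[[as.character(f)]]
    active <- which(last_frame >= f - 1L - max_gap & last_frame < f)
    assigned_loc <- rep(FALSE, length(idx))
    if (length(active) > 0) {
      cand <- expand.grid(ti = seq_along(active), li = seq_along(idx))
      tr <- active[cand$ti]
      d <- sqrt((last_x[tr] - locs$x_um[idx[cand$li]])^2 +
                (last_y[tr] - locs$y_um[idx[cand$li]])^2)
      ok <- d < max_dist_um
      cand <- cand[ok, , drop = FALSE]
      d <- d[ok]
      ord <- order(d, last_frame[active[cand$ti]], active[cand$ti])
      used_track <- rep(FALSE, length(active))
      for (k in ord) {
        ti <- cand$ti[k]; li <- cand$li[k]
        if (used_track[ti] || assigned_loc[li]) next
        used_track[ti] <- TRUE
        assigned_loc[li] <- TRUE
        tr_id <- active[ti]
        track_of[idx[li]] <- tr_id
        last_x[tr_id] <- locs$x_um[idx[li]]
        last_y[tr_id] <- locs$y_um[idx[li]]
        last_frame[tr_id] <- f
      }
    }
    for (li in which(!assigned_loc)) {
      n_tracks <- n_tracks + 1L
      track_of[idx[li]] <- n_tracks
      last_x[n_tracks] <- locs$x_um[idx[li]]
      last_y[n_tracks] <- locs$y_um[idx[li]]
      last_frame[n_tracks] <- f
    }
  }
  out <- locs |>
    mutate(track_id = track_of) |>
    dplyr::select("track_id", "frame", "x_um", "y_um") |>
    arrange(.data$track_id, .data$frame)
  rlang::inform(sprintf("linked %d localizations into %d trajectories",
                        nrow(out), n_tracks))
  out
}

#' Filter trajectories by a binary nuclear mask
#'
#' Keeps trajectories whose centroid falls inside the mask (whole-track
#' rather than point-wise exclusion, so tracks straddling the mask edge are
#' not fragmented). The mask is a logical matrix indexed `[row = y, col = x]`
#' on the camera pixel grid.
#'
#' @param trajectories tidy trajectory table.
#' @param mask logical matrix; `TRUE` marks nuclear pixels.
#' @param pixel_size pixel size in um.
#' @return The retained subset of `trajectories`.
#' @export
filter_by_mask <- function(trajectories, mask, pixel_size = 0.107) {
  check_trajectory_cols(trajectories)
  if (!is.matrix(mask) || !is.logical(mask)) {
    rlang::abort("`mask` must be a logical matrix")
  }
  cent <- trajectories |>
    group_by(.data$track_id) |>
    summarise(cx = mean(.data$x_um), cy = mean(.data$y_um), .groups = "drop") |>
    mutate(col = floor(.data$cx / pixel_size) + 1L,
           row = floor(.data$cy / pixel_size) + 1L)
  inside <- cent$row >= 1L & cent$row <= nrow(mask) &
    cent$col >= 1L & cent$col <= ncol(mask)
  inside[inside] <- mask[cbind(cent$row[inside], cent$col[inside])]
  keep <- cent$track_id[inside]
  out <- filter(trajectories, .data$track_id %in% keep)
  rlang::inform(sprintf("mask filter kept %d of %d trajectories",
                        length(keep), nrow(cent)))
  out
}

#' Apparent trajectory durations (dwell times) from a linked set
#'
#' Under slow tracking only chromatin-bound molecules register, so the
#' temporal length of a trajectory is the apparent chromatin dwell time.
#' Duration spans first to last frame inclusive, in frames times
#' `frame_interval`.
#'
#' @param trajectories tidy trajectory table (gaps allowed).
#' @param frame_interval frame duration (s).
#' @return Tibble `track_id`, `n_frames`, `dwell_s`.
#' @export
trajectory_dwell_times <- function(trajectories, frame_interval = 0.25) {
  check_trajectory_cols(trajectories, c("track_id", "frame"))
  trajectories |>
    group_by(.data$track_id) |>
    summarise(n_frames = max(.data$frame) - min(.data$frame) + 1L,
              .groups = "drop") |>
    mutate(dwell_s = .data$n_frames * frame_interval)
}
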