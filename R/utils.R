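# internal validators and small shared helpers

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (x > 0 || (allow_zero && x >= 0))
  if (!ok) {
    rlang::abort(sprintf(
      "`%s` must be a single finite %s number, got %s",
      name, if (allow_zero) "non-negative" else "positive",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

stop_if_not_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && lo_ok && hi_ok)) {
    rlang::abort(sprintf("`%s` must be a fraction in %s0, 1%s",
                         name, if (open_left) "(" else "[",
                         if (open_right) ")" else "]"))
  }
  invisible(x)
}

# Set the RNG locally for the calling function; the caller's RNG state is
# restored on exit so simulation helpers do not perturb the session stream.
local_seed_if_given <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      rlang::abort("`seed` must be a single integer")
    }
    withr::local_seed(as.integer(seed), .local_envir = env)
  }
  invisible(NULL)
}

# Stable per-stage sub-seed derived from a master seed, kept below 2^31.
derive_seed <- function(master, stage) {
  if (is.null(master)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 1000003 + h) %% 2147483647)
}

check_trajectory_cols <- function(df, cols = c("track_id", "frame", "x_um", "y_um")) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(paste0("trajectory table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  invisible(df)
}
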