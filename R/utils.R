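`%||%` <- function(a, b) if (is.null(a)) b else a

#' Indices of the trailing analysis window
#'
#' Descriptors that the workflow reports as "last-window" averages (RMSD,
#' RMSF, Rg, SASA, hydrogen bonds, salt bridges, native contacts) are
#' evaluated over the final fraction of frames of a trajectory. With the
#' default fraction of 0.5 a 1001-frame run recorded every 0.1 ns yields the
#' last 500 frames, i.e. the last 50 ns.
#'
#' @param n_frames total number of frames.
#' @param fraction fraction of frames in the window, in (0, 1).
#' @return integer vector of frame indices (at least one).
#' @export
last_window_idx <- function(n_frames, fraction = 0.5) {
  stopifnot(n_frames >= 1, fraction > 0, fraction < 1)
  n_win <- max(1L, floor(fraction * n_frames))
  seq.int(n_frames - n_win + 1L, n_frames)
}

#' Mean of a series over its trailing window
#'
#' @param x numeric per-frame series.
#' @param fraction window fraction, see [last_window_idx()].
#' @return scalar mean over the window.
#' @export
last_window_mean <- function(x, fraction = 0.5) {
  mean(x[last_window_idx(length(x), fraction)])
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic code in the package funnels through this so
# that generators and CV splits are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_aggkin <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn_aggkin <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# squared Euclidean row norms
row_norms2 <- function(m) rowSums(m * m)
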