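#' Exact Shapley feature attribution
#'
#' Model-agnostic Shapley values under the interventional value function:
#' v(S) is the model output averaged over background rows whose features
#' in S are replaced by the explained row's values. Every subset of
#' features is enumerated (hence the p <= 15 limit), and each feature's
#' attribution sums its marginal contributions with the Shapley kernel
#' weights |S|! (p-|S|-1)! / p!. Satisfies the efficiency, null-player
#' and symmetry axioms to numerical precision.
#'
#' @param model_fn function taking a numeric matrix (rows = inputs,
#'   columns = the features of `x_row`) and returning one prediction per
#'   row.
#' @param x_row the explained input (named numeric vector or 1-row
#'   data.frame).
#' @param background matrix/data.frame of reference rows.
#' @return object of class `shapley_result` with `phi`, `base_value`.
#' @export
shapley_exact <- function(model_fn, x_row, background) {
  x <- unlist(as.data.frame(as.list(x_row)))
  B <- as.matrix(as.data.frame(background))
  p <- length(x)
  if (p > 15)
    stop_aggkin("p = %d exceeds the exact-enumeration limit (15); use shapley_permutation()", p)
  if (!nrow(B)) stop_aggkin("background must be nonempty")
  nb <- nrow(B)
  masks <- 0:(2^p - 1)
  # v(S) for every subset, one model call over nb rows each
  v <- vapply(masks, function(m) {
    Z <- B
    for (i in seq_len(p)) if (bitwAnd(m, bitwShiftL(1L, i - 1L)))
      Z[, i] <- x[i]
    mean(model_fn(Z))
  }, numeric(1))
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0),
                  numeric(1))
  wts <- numeric(length(masks))
  proper <- sizes < p
  wts[proper] <- factorial(sizes[proper]) *
    factorial(p - sizes[proper] - 1) / factorial(p)
  phi <- numeric(p)
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- masks[bitwAnd(masks, bit) == 0]
    idx <- match(without, masks)
    phi[i] <- sum(wts[idx] * (v[match(bitwOr(without, bit), masks)] - v[idx]))
  }
  structure(list(phi = stats::setNames(phi, names(x)),
                 base_value = v[1], method = "exact",
                 n_permutations = NULL, seed = NULL, se = NULL),
            class = "shapley_result")
}

#' Permutation-sampling Shapley estimates
#'
#' Monte Carlo estimator for feature counts beyond the exact-enumeration
#' limit: features are inserted in seeded random orders and each
#' feature's marginal contribution is averaged across orders; standard
#' errors come from the between-permutation variance (shrinking as
#' 1/sqrt(n_permutations)).
#'
#' @inheritParams shapley_exact
#' @param n_permutations number of random orderings (>= 10).
#' @param seed RNG seed (caller's RNG state untouched).
#' @return `shapley_result` with `phi` and per-feature `se`.
#' @export
shapley_permutation <- function(model_fn, x_row, background,
                                n_permutations = 200, seed = 1) {
  x <- unlist(as.data.frame(as.list(x_row)))
  B <- as.matrix(as.data.frame(background))
  p <- length(x)
  if (n_permutations < 10) stop_aggkin("n_permutations must be >= 10")
  if (!nrow(B)) stop_aggkin("background must be nonempty")
  contrib <- with_seed(seed, {
    out <- matrix(0, n_permutations, p)
    for (s in seq_len(n_permutations)) {
      ord <- sample.int(p)
      Z <- B
      v_prev <- mean(model_fn(Z))
      for (i in ord) {
        Z[, i] <- x[i]
        v_cur <- mean(model_fn(Z))
        out[s, i] <- v_cur - v_prev
        v_prev <- v_cur
      }
    }
    out
  })
  phi <- colMeans(contrib)
  se <- apply(contrib, 2, stats::sd) / sqrt(n_permutations)
  base_value <- mean(model_fn(B))
  structure(list(phi = stats::setNames(phi, names(x)),
                 base_value = base_value, method = "permutation",
                 n_permutations = n_permutations, seed = seed,
                 se = stats::setNames(se, names(x))),
            class = "shapley_result")
}

#' @export
print.shapley_result <- function(x, ...) {
  cat(sprintf("<shapley_result> %s, base value %.4g\n", x$method,
              x$base_value))
  print(round(x$phi, 4))
  invisible(x)
}

#' Explain many rows
#'
#' @param model_fn,background as in [shapley_exact()].
#' @param X rows to explain (matrix/data.frame).
#' @param method `"exact"` or `"permutation"`.
#' @param ... passed to the per-row explainer.
#' @return matrix of phi values, one row per explained row.
#' @export
explain_model <- function(model_fn, X, background,
                          method = c("exact", "permutation"), ...) {
  method <- match.arg(method)
  X <- as.matrix(as.data.frame(X))
  fun <- if (method == "exact") shapley_exact else shapley_permutation
  phi <- t(apply(X, 1, function(row)
    fun(model_fn, stats::setNames(row, colnames(X)), background, ...)$phi))
  colnames(phi) <- colnames(X)
  phi
}

#' Global feature importance from Shapley attributions
#'
#' Ranks features by the mean absolute attribution across explained rows
#' (the usual global-importance bar chart). An all-zero attribution
#' matrix keeps the input order and is flagged degenerate.
#'
#' @param phi matrix of per-row attributions (from [explain_model()]).
#' @return data.frame with `feature`, `mean_abs_phi`, ordered descending;
#'   attribute `degenerate` when all attributions vanish.
#' @export
global_importance <- function(phi) {
  phi <- as.matrix(phi)
  imp <- colMeans(abs(phi))
  degenerate <- all(imp == 0)
  ord <- if (degenerate) seq_along(imp) else order(-imp)
  out <- data.frame(feature = colnames(phi)[ord] %||%
                      paste0("x", seq_along(imp))[ord],
                    mean_abs_phi = imp[ord], row.names = NULL)
  attr(out, "degenerate") <- degenerate
  out
}
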