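as_design <- function(X) {
  X <- as.matrix(as.data.frame(X))
  if (!is.numeric(X)) stop_aggkin("design matrix must be numeric")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

standardize_fit <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  if (any(scale == 0))
    stop_aggkin("zero-variance column(s): %s",
                paste(colnames(X)[scale == 0], collapse = ", "))
  list(center = center, scale = scale,
       Z = sweep(sweep(X, 2, center), 2, scale, `/`))
}

new_model <- function(kind, beta, intercept, std, names, n, r2,
                      n_components = NULL, extra = list()) {
  structure(c(list(kind = kind, coefficients = stats::setNames(beta, names),
                   intercept = intercept, standardization = std,
                   feature_names = names, n = n, r2_train = r2,
                   n_components = n_components), extra),
            class = "aggkin_model")
}

#' Multiple linear regression (ordinary least squares)
#'
#' Fits y on the columns of X by a QR decomposition of the standardized
#' design; coefficients are reported on the original scale. Requires more
#' observations than features and a full-rank design (the error names the
#' collinear columns).
#'
#' @param X n x p numeric matrix or data.frame.
#' @param y numeric response of length n.
#' @return fitted model of class `aggkin_model`.
#' @export
fit_ols <- function(X, y) {
  X <- as_design(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_aggkin("X and y sizes differ")
  if (n <= p) stop_aggkin("need n > p (n=%d, p=%d)", n, p)
  if (stats::sd(y) == 0) {
    return(new_model("ols", rep(0, p), mean(y),
                     list(center = colMeans(X), scale = rep(1, p)),
                     colnames(X), n, r2 = NA_real_))
  }
  st <- standardize_fit(X)
  qrz <- qr(cbind(`(Intercept)` = 1, st$Z))
  if (qrz$rank < p + 1) {
    piv <- qrz$pivot[seq_len(qrz$rank)]
    bad <- setdiff(colnames(X), colnames(st$Z)[setdiff(piv, 1) - 1])
    stop_aggkin("rank-deficient design; collinear column(s): %s",
                paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qrz, y)
  bz <- coefs[-1]
  beta <- bz / st$scale
  intercept <- unname(coefs[1]) - sum(beta * st$center)
  fitted <- as.numeric(X %*% beta + intercept)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  new_model("ols", beta, intercept,
            list(center = st$center, scale = st$scale),
            colnames(X), n, r2)
}

#' Partial least squares regression by NIPALS
#'
#' Features are z-scored and the response centered internally. Each
#' component takes the weight vector proportional to X'y (unit norm),
#' scores t = Xw, X-loading p = X't/(t't) and y-loading q = y't/(t't),
#' then deflates X and y. Regression coefficients are back-transformed to
#' the original feature scale.
#'
#' @param X n x p numeric matrix or data.frame.
#' @param y numeric response.
#' @param n_components number of latent components, between 1 and
#'   min(n - 1, p).
#' @return fitted model of class `aggkin_model` with `n_components`,
#'   `weights`, `loadings`, `scores` retained.
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as_design(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop_aggkin("X and y sizes differ")
  a_max <- min(n - 1, p)
  if (n_components < 1 || n_components > a_max)
    stop_aggkin("n_components must be in [1, %d]", a_max)
  st <- standardize_fit(X)
  Z <- st$Z
  y_center <- mean(y)
  u <- y - y_center
  A <- n_components
  W <- P <- matrix(0, p, A); qv <- numeric(A); Tm <- matrix(0, n, A)
  for (a in seq_len(A)) {
    w <- drop(crossprod(Z, u))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12)
      stop_aggkin("degenerate component %d: X'y vanished", a)
    w <- w / nw
    t <- drop(Z %*% w)
    tt <- sum(t^2)
    pl <- drop(crossprod(Z, t)) / tt
    q <- sum(u * t) / tt
    Z <- Z - tcrossprod(t, pl)
    u <- u - q * t
    W[, a] <- w; P[, a] <- pl; qv[a] <- q; Tm[, a] <- t
  }
  # coefficients in standardized space: B = W (P'W)^-1 q
  bz <- drop(W %*% solve(crossprod(P, W), qv))
  beta <- bz / st$scale
  intercept <- y_center - sum(beta * st$center)
  fitted <- as.numeric(X %*% beta + intercept)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  new_model("pls", beta, intercept,
            list(center = st$center, scale = st$scale),
            colnames(X), n, r2, n_components = A,
            extra = list(weights = W, loadings = P, y_loadings = qv,
                         scores = Tm))
}

#' @export
print.aggkin_model <- function(x, ...) {
  cat(sprintf("<aggkin_model> %s%s | n=%d, p=%d, training R2 = %.4f\n",
              toupper(x$kind),
              if (!is.null(x$n_components))
                sprintf(" (%d components)", x$n_components) else "",
              x$n, length(x$coefficients), x$r2_train))
  invisible(x)
}

#' Predict from a fitted regression model
#'
#' @param object an `aggkin_model`.
#' @param newdata matrix/data.frame whose columns cover the training
#'   feature names (order-insensitive; mismatch is an error).
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.aggkin_model <- function(object, newdata, ...) {
  X <- as.matrix(as.data.frame(newdata))
  miss <- setdiff(object$feature_names, colnames(X))
  if (length(miss))
    stop_aggkin("newdata lacks feature(s): %s", paste(miss, collapse = ", "))
  X <- X[, object$feature_names, drop = FALSE]
  as.numeric(X %*% object$coefficients + object$intercept)
}

#' Regression error metrics
#'
#' @param y observed values.
#' @param y_hat predictions.
#' @return list with `mse` (mean squared error) and `r2`
#'   (1 - SS_res/SS_tot; can be negative out of sample).
#' @export
regression_metrics <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  list(mse = mean((y - y_hat)^2),
       r2 = 1 - sum((y - y_hat)^2) / sum((y - mean(y))^2))
}

#' Seeded k-fold partition
#'
#' Shuffles indices 1..n under the seed and cuts them into k folds whose
#' sizes differ by at most one (k = n gives leave-one-out). The caller's
#' RNG state is untouched.
#'
#' @param n number of observations.
#' @param k number of folds, 2..n.
#' @param seed integer seed.
#' @return list of k disjoint, exhaustive index vectors.
#' @export
kfold_split <- function(n, k, seed = 1) {
  if (k < 2 || k > n) stop_aggkin("k must be in [2, %d]", n)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  unname(split(perm, rep(seq_len(k), times = sizes)))
}

#' Model specification for cross-validation
#'
#' @param kind `"ols"`, `"pls"`, or `"custom"`.
#' @param n_components for PLS: an integer, or `"auto"` to choose by inner
#'   5-fold CV minimising MSE on each training split.
#' @param fit_fn,predict_fn for `kind = "custom"`: `fit_fn(X, y)` returns
#'   an object consumed by `predict_fn(object, X)`. Adapters for external
#'   learners (random forest, SVR) plug in here; they carry no
#'   from-scratch guarantee and are for comparison reports only.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(kind = c("ols", "pls", "custom"),
                       n_components = "auto", fit_fn = NULL,
                       predict_fn = NULL) {
  kind <- match.arg(kind)
  if (kind == "custom" && (is.null(fit_fn) || is.null(predict_fn)))
    stop_aggkin("custom spec needs fit_fn and predict_fn")
  structure(list(kind = kind, n_components = n_components,
                 fit_fn = fit_fn, predict_fn = predict_fn),
            class = "model_spec")
}

choose_pls_components <- function(X, y, seed, k_inner = 5) {
  n <- nrow(X); p <- ncol(X)
  a_max <- max(1, min(p, n - ceiling(n / k_inner) - 1))
  if (a_max == 1) return(1L)
  k_inner <- min(k_inner, n)
  folds <- kfold_split(n, k_inner, seed)
  mse <- vapply(seq_len(a_max), function(a) {
    errs <- unlist(lapply(folds, function(te) {
      tr <- setdiff(seq_len(n), te)
      m <- fit_pls(X[tr, , drop = FALSE], y[tr], a)
      (y[te] - predict(m, X[te, , drop = FALSE]))^2
    }))
    mean(errs)
  }, numeric(1))
  which.min(mse)
}

fit_spec <- function(spec, X, y, seed = 1) {
  switch(spec$kind,
    ols = fit_ols(X, y),
    pls = {
      a <- spec$n_components
      if (identical(a, "auto")) a <- choose_pls_components(X, y, seed)
      fit_pls(X, y, a)
    },
    custom = spec$fit_fn(X, y))
}

predict_spec <- function(spec, model, X) {
  if (spec$kind == "custom") spec$predict_fn(model, X)
  else predict(model, X)
}

#' k-fold cross-validation of a model specification
#'
#' Refits the model from scratch on each training split (standardization
#' parameters, and the PLS component count when `"auto"`, are learned on
#' the training fold only — no leakage) and scores the held-out fold.
#' The evaluation R-squared pools the out-of-fold predictions of all
#' folds against y.
#'
#' @param spec a [model_spec()].
#' @param X,y data.
#' @param k number of folds (k = n is leave-one-out).
#' @param seed fold-assignment seed.
#' @return object of class `cv_report` with per-fold MSE, mean/max/std
#'   MSE, evaluation R-squared and pooled predictions.
#' @export
cross_validate <- function(spec, X, y, k = 10, seed = 1) {
  X <- as_design(X); y <- as.numeric(y)
  n <- nrow(X)
  folds <- kfold_split(n, k, seed)
  pred <- rep(NA_real_, n)
  fold_mse <- vapply(seq_along(folds), function(i) {
    te <- folds[[i]]; tr <- setdiff(seq_len(n), te)
    if (spec$kind == "ols" && length(tr) <= ncol(X))
      stop_aggkin("fold %d leaves n_train <= p for OLS", i)
    m <- fit_spec(spec, X[tr, , drop = FALSE], y[tr], seed = seed + i)
    yh <- predict_spec(spec, m, X[te, , drop = FALSE])
    pred[te] <<- yh
    mean((y[te] - yh)^2)
  }, numeric(1))
  structure(list(k = k, seed = seed, fold_mse = fold_mse,
                 mean_mse = mean(fold_mse), max_mse = max(fold_mse),
                 std_mse = stats::sd(fold_mse),
                 evaluation_r2 = regression_metrics(y, pred)$r2,
                 predictions = pred, kind = spec$kind),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %s, k=%d | mean MSE %.4g, max %.4g, sd %.4g | eval R2 %.3f\n",
    toupper(x$kind), x$k, x$mean_mse, x$max_mse, x$std_mse,
    x$evaluation_r2))
  invisible(x)
}

#' Fold-number sensitivity analysis
#'
#' Cross-validates the model at every k in `k_range` and at k = n
#' (leave-one-out, the reference baseline), and recommends the k whose
#' mean MSE is closest to the LOOCV baseline (ties towards smaller k).
#' The conventional k = 10 remains available by simply using it.
#'
#' @param spec a [model_spec()].
#' @param X,y data.
#' @param k_range candidate fold counts (values above n are dropped;
#'   k = n is reported as the LOOCV baseline, not a candidate).
#' @param seed seed shared by all splits.
#' @return list with `table` (k, mean/max/std MSE, eval R2), `loocv`
#'   (its [cross_validate()] report) and `recommended_k`.
#' @export
k_sensitivity <- function(spec, X, y, k_range = 2:31, seed = 1) {
  n <- nrow(as_design(X))
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (!length(k_range)) stop_aggkin("no admissible k in range")
  reports <- lapply(k_range, function(k)
    cross_validate(spec, X, y, k = k, seed = seed))
  loocv <- cross_validate(spec, X, y, k = n, seed = seed)
  tab <- data.frame(
    k = k_range,
    mean_mse = vapply(reports, `[[`, numeric(1), "mean_mse"),
    max_mse = vapply(reports, `[[`, numeric(1), "max_mse"),
    std_mse = vapply(reports, `[[`, numeric(1), "std_mse"),
    evaluation_r2 = vapply(reports, `[[`, numeric(1), "evaluation_r2"))
  gap <- abs(tab$mean_mse - loocv$mean_mse)
  rec <- tab$k[order(gap, tab$k)][1]
  list(table = tab, loocv = loocv, recommended_k = rec)
}

#' Stability-aware model selection
#'
#' Default rule: candidates whose MSE standard deviation exceeds the
#' median across candidates are excluded as unstable; among the rest the
#' lowest mean MSE wins (ties by input order, logged). The full ranking
#' and the exclusion list are reported; pass a different `rule` to
#' replace the default.
#'
#' @param cv_reports named list of [cross_validate()] reports at a common k.
#' @param rule optional function(reports) returning the selected name.
#' @return list with `selected`, `ranking` data.frame, `excluded`.
#' @export
select_model <- function(cv_reports, rule = NULL) {
  if (!length(cv_reports)) stop_aggkin("empty candidate set")
  nm <- names(cv_reports) %||% paste0("model", seq_along(cv_reports))
  names(cv_reports) <- nm
  if (!is.null(rule)) {
    sel <- rule(cv_reports)
    return(list(selected = sel, ranking = NULL, excluded = character(0)))
  }
  mean_mse <- vapply(cv_reports, `[[`, numeric(1), "mean_mse")
  std_mse <- vapply(cv_reports, `[[`, numeric(1), "std_mse")
  rank_df <- data.frame(model = nm, mean_mse = mean_mse, std_mse = std_mse,
                        evaluation_r2 = vapply(cv_reports, `[[`, numeric(1),
                                               "evaluation_r2"),
                        row.names = NULL)
  rank_df <- rank_df[order(rank_df$mean_mse), ]
  if (length(cv_reports) == 1)
    return(list(selected = nm, ranking = rank_df, excluded = character(0)))
  med <- stats::median(std_mse)
  stable <- nm[std_mse <= med]
  excluded <- setdiff(nm, stable)
  pool <- mean_mse[stable]
  selected <- stable[which.min(pool)]  # which.min: first on ties (input order)
  list(selected = selected, ranking = rank_df, excluded = excluded)
}
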