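test_that("OLS recovers exact linear structure and satisfies the
           normal equations", {
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 3 * X[, 1] - 2 * X[, 2] + 1
  m <- fit_ols(X, y)
  expect_equal(unname(m$coefficients), c(3, -2), tolerance = 1e-10)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(m$r2_train, 1, tolerance = 1e-12)

  mc <- fit_ols(X, rep(5, 10))
  expect_equal(unname(mc$coefficients), c(0, 0))
  expect_equal(mc$intercept, 5)

  Xw <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("x", 1:3)))
  yw <- rnorm(20)
  mw <- fit_ols(Xw, yw)
  res <- yw - predict(mw, Xw)
  expect_lt(max(abs(crossprod(Xw, res))), 1e-8)

  Xr <- cbind(Xw, x4 = Xw[, 1] * 2)
  expect_error(fit_ols(Xr, yw), "collinear")
  expect_error(fit_ols(Xw[1:3, ], yw[1:3]), "n > p")
})

test_that("NIPALS PLS: rank-1 exact fit, OLS equivalence at full
           components, monotone training R2 and planted-coefficient
           recovery", {
  # rank-1 X, response proportional to the latent score
  st1 <- synth_feature_table(feature_table_spec(
    n_rows = 15, features = paste0("f", 1:5), latent_rank = 1, seed = 2))
  m1 <- fit_pls(st1$X, st1$y, 1)
  expect_equal(m1$r2_train, 1, tolerance = 1e-9)

  # full components reproduce OLS predictions
  set.seed(3)
  X <- matrix(rnorm(25 * 4), 25, 4, dimnames = list(NULL, paste0("x", 1:4)))
  y <- rnorm(25)
  p_pls <- predict(fit_pls(X, y, 4), X)
  p_ols <- predict(fit_ols(X, y), X)
  expect_lt(max(abs(p_pls - p_ols)), 1e-8)

  # training R2 non-decreasing in component count; equals OLS R2 at rank
  r2s <- vapply(1:4, function(a) fit_pls(X, y, a)$r2_train, numeric(1))
  expect_true(all(diff(r2s) >= -1e-12))
  expect_equal(r2s[4], fit_ols(X, y)$r2_train, tolerance = 1e-10)

  # near-noiseless low-rank table: planted coefficients recovered
  st <- synth_feature_table(feature_table_spec(
    n_rows = 40, features = paste0("f", 1:6), latent_rank = 2,
    noise_sd = 1e-5, seed = 4))
  mrec <- fit_pls(st$X, st$y, 6)
  expect_equal(unname(mrec$coefficients), unname(st$beta_true),
               tolerance = 1e-3)

  expect_error(fit_pls(X, y, 0), "n_components")
  expect_error(fit_pls(cbind(X, k = rep(1, 25)), y, 2), "zero-variance")
})

test_that("PLS agrees with an independent implementation", {
  set.seed(8)
  X <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- X %*% c(1, -2, 0.5, 0, 1) + rnorm(30, sd = 0.3)
  ours <- predict(fit_pls(X, y, 2), X)
  ref <- mixOmics::pls(X, y, ncomp = 2, mode = "regression",
                       scale = TRUE)
  theirs <- predict(ref, X)$predict[, 1, 2]
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("prediction metrics follow the definitions", {
  y <- c(1, 2, 4)
  expect_equal(regression_metrics(y, y), list(mse = 0, r2 = 1))
  expect_equal(regression_metrics(y, rep(mean(y), 3))$r2, 0)
  yh <- c(1.5, 2, 3)
  expect_equal(regression_metrics(y, yh)$mse, (0.25 + 0 + 1) / 3)
  expect_equal(regression_metrics(y, yh)$r2,
               1 - 1.25 / sum((y - mean(y))^2))

  m <- fit_ols(matrix(rnorm(20), 10, 2,
                      dimnames = list(NULL, c("a", "b"))), rnorm(10))
  expect_error(predict(m, matrix(0, 2, 2,
                                 dimnames = list(NULL, c("a", "zz")))),
               "lacks feature")
})

test_that("k-fold splits partition near-equally, deterministically", {
  folds <- kfold_split(49, 10, seed = 7)
  sizes <- sort(lengths(folds))
  expect_equal(sizes, c(4, rep(5, 9)))
  expect_equal(sort(unlist(folds)), 1:49)

  loo <- kfold_split(49, 49, seed = 7)
  expect_true(all(lengths(loo) == 1))

  expect_identical(kfold_split(30, 7, seed = 3), kfold_split(30, 7, seed = 3))
  expect_false(identical(kfold_split(30, 7, seed = 3),
                         kfold_split(30, 7, seed = 4)))
  expect_error(kfold_split(10, 1), "k must be")
  expect_error(kfold_split(10, 11), "k must be")
})

test_that("cross-validation: exact-linear data scores zero error, pure
           noise scores non-positive out-of-sample R2, and LOOCV matches
           the hat-matrix identity", {
  set.seed(11)
  X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y_lin <- drop(X %*% c(1, 2, -1)) + 0.5
  for (k in c(4, 10)) {
    cv <- cross_validate(model_spec("ols"), X, y_lin, k = k, seed = 1)
    expect_lt(cv$mean_mse, 1e-20)
  }

  # intercept-only model on pure noise: pooled out-of-fold R2 <= 0
  noise_spec <- model_spec("custom",
                           fit_fn = function(X, y) mean(y),
                           predict_fn = function(m, X) rep(m, nrow(X)))
  y_noise <- rnorm(40)
  cvn <- cross_validate(noise_spec, X, y_noise, k = 8, seed = 2)
  expect_lte(cvn$evaluation_r2, 0)

  # LOOCV of OLS equals the closed-form hat-matrix shortcut
  y2 <- drop(X %*% c(1, 0, 2)) + rnorm(40)
  cv_loo <- cross_validate(model_spec("ols"), X, y2, k = 40, seed = 5)
  expect_equal(cv_loo$mean_mse, oracle_loocv_ols(X, y2), tolerance = 1e-8)

  # report internals recompute
  expect_equal(cv_loo$mean_mse, mean(cv_loo$fold_mse), tolerance = 1e-12)
  expect_equal(cv_loo$std_mse, sd(cv_loo$fold_mse), tolerance = 1e-12)
  expect_equal(length(cv_loo$fold_mse), 40)
})

test_that("fold-number sensitivity reports every k, the LOOCV baseline,
           and is reproducible under a seed", {
  set.seed(13)
  X <- matrix(rnorm(32 * 3), 32, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- drop(X %*% c(2, -1, 1))
  ks <- k_sensitivity(model_spec("ols"), X, y, k_range = 2:31, seed = 9)
  expect_equal(ks$table$k, 2:31)     # k = 32 is the LOOCV baseline, not a k
  expect_true(all(ks$table$mean_mse < 1e-18))
  expect_lt(ks$loocv$mean_mse, 1e-18)
  expect_true(ks$recommended_k %in% 2:31)

  ks2 <- k_sensitivity(model_spec("ols"), X, y, k_range = 2:31, seed = 9)
  expect_identical(ks$table, ks2$table)
})

test_that("model selection excludes unstable candidates and breaks ties
           by input order", {
  mk <- function(mean, std, r2 = 0.5)
    structure(list(mean_mse = mean, std_mse = std, max_mse = mean + std,
                   evaluation_r2 = r2, k = 10), class = "cv_report")
  # low-mean but unstable A is excluded; B wins despite higher mean
  sel <- select_model(list(A = mk(3.7, 4.8), B = mk(5.6, 3.3)))
  expect_equal(sel$selected, "B")
  expect_equal(sel$excluded, "A")

  expect_equal(select_model(list(only = mk(1, 1)))$selected, "only")

  tie <- select_model(list(first = mk(2, 1), second = mk(2, 1)))
  expect_equal(tie$selected, "first")

  expect_error(select_model(list()), "empty")
})
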