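# Independent oracles used to freeze expected values. Each deliberately
# avoids the code path it checks.

# Minimum RMSD over proper rotations by coarse Euler-angle grid search
# followed by Nelder-Mead refinement (optimal translation = centroid
# alignment). Independent of the SVD-based superposition.
oracle_min_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  euler_rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((A %*% t(euler_rot(ang)) - B)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0); bestv <- obj(best)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < bestv) { bestv <- v; best <- c(a1, a2, a3) }
  }
  fit <- stats::optim(best, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  fit$value
}

# Closed-form leave-one-out MSE for OLS with intercept via the hat matrix.
oracle_loocv_ols <- function(X, y) {
  Xd <- cbind(1, as.matrix(X))
  H <- Xd %*% solve(crossprod(Xd), t(Xd))
  e <- y - H %*% y
  mean((e / (1 - diag(H)))^2)
}

# Exact Shapley values of a linear model with an independent background:
# phi_i = w_i * (x_i - mean(background_i)).
oracle_linear_shapley <- function(w, x, background) {
  w * (x - colMeans(background))
}
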