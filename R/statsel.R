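#' Pairwise correlation matrix
#'
#' Pearson or Spearman correlation across the numeric columns of a table,
#' using pairwise-complete observations. Zero-variance columns yield
#' missing coefficients (never zero) and a warning.
#'
#' @param table data.frame or matrix of numeric columns.
#' @param method `"pearson"` or `"spearman"` (Pearson on average ranks).
#' @return object of class `correlation_matrix`: list with `labels`, `r`
#'   (symmetric, unit diagonal), `method`.
#' @export
correlation_matrix <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.matrix(as.data.frame(table))
  if (!is.numeric(x)) stop_aggkin("all columns must be numeric")
  if (nrow(x) < 3) stop_aggkin("at least 3 rows required")
  zv <- apply(x, 2, function(col) stats::sd(col, na.rm = TRUE) == 0 ||
                all(is.na(col)))
  if (any(zv))
    warn_aggkin("zero-variance column(s): %s (coefficients reported missing)",
                paste(colnames(x)[zv], collapse = ", "))
  r <- suppressWarnings(
    stats::cor(x, use = "pairwise.complete.obs", method = method))
  r[zv, ] <- NA_real_; r[, zv] <- NA_real_
  diag(r) <- ifelse(zv, NA_real_, 1)
  structure(list(labels = colnames(x), r = r, method = method),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %s, %d variables\n", x$method,
              length(x$labels)))
  print(round(x$r, 3))
  invisible(x)
}

#' Redundancy-based feature selection
#'
#' Greedy removal of redundant features: every feature pair whose absolute
#' correlation exceeds the threshold is processed in descending absolute
#' correlation, and at each the member with the weaker absolute
#' correlation to the response is dropped (ties drop the later column;
#' logged). Pairs involving an already-dropped feature are skipped, making
#' the procedure deterministic for a given column order.
#'
#' @param corr [correlation_matrix()] over the candidate features (or a
#'   plain symmetric matrix with dimnames).
#' @param target_corr named numeric vector: each feature's correlation
#'   with the response.
#' @param threshold redundancy threshold on |r|, in (0, 1].
#' @param keep optional character vector of features never removed
#'   (domain-knowledge keep-list).
#' @return list with `retained`, `removed`, and a `log` data.frame of the
#'   decisions taken.
#' @export
select_nonredundant <- function(corr, target_corr, threshold = 0.8,
                                keep = NULL) {
  r <- if (inherits(corr, "correlation_matrix")) corr$r else as.matrix(corr)
  feats <- colnames(r)
  if (threshold <= 0 || threshold > 1)
    stop_aggkin("threshold must be in (0, 1]")
  if (!all(feats %in% names(target_corr)))
    stop_aggkin("target_corr must cover every feature")
  tc <- abs(target_corr[feats])
  ut <- which(upper.tri(r) & abs(r) > threshold, arr.ind = TRUE)
  ord <- order(-abs(r[ut]))
  ut <- ut[ord, , drop = FALSE]
  dropped <- character(0)
  log <- list()
  for (row in seq_len(nrow(ut))) {
    a <- feats[ut[row, 1]]; b <- feats[ut[row, 2]]
    if (a %in% dropped || b %in% dropped) next
    cand <- setdiff(c(a, b), keep)
    if (!length(cand)) next
    tie <- FALSE
    if (length(cand) == 2) {
      if (tc[a] > tc[b]) drop <- b
      else if (tc[a] < tc[b]) drop <- a
      else { drop <- b; tie <- TRUE }   # tie: drop the later column
    } else drop <- cand
    dropped <- c(dropped, drop)
    log[[length(log) + 1]] <- data.frame(
      feature_a = a, feature_b = b, r = r[ut[row, 1], ut[row, 2]],
      dropped = drop, tie_break = tie)
  }
  list(retained = setdiff(feats, dropped), removed = dropped,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(feature_a = character(0), feature_b = character(0),
                    r = numeric(0), dropped = character(0),
                    tie_break = logical(0)))
}

#' Three-band single-feature aggregation classifier
#'
#' Conditions are banded by their measured aggregation kinetics:
#' high when ln(v) is strictly above the upper edge, low when strictly
#' below the lower edge, medium otherwise (values exactly at an edge fall
#' in the middle band). A single descriptor then flags conditions as
#' high-risk by thresholding, and the confusion counts of that flag
#' against the high band are reported, with precision = 100 TP/(TP+FP).
#'
#' @param feature_values numeric descriptor per condition.
#' @param ln_v measured log aggregation rates, same length.
#' @param feature_threshold threshold on the descriptor.
#' @param direction `"below_flags_high"` (e.g. native contacts: low values
#'   flag risk) or `"above_flags_high"`.
#' @param band_edges lower and upper ln(v) band edges, default `c(0, 4)`.
#' @return object of class `banded_classification`.
#' @export
banded_classifier <- function(feature_values, ln_v, feature_threshold,
                              direction = c("below_flags_high",
                                            "above_flags_high"),
                              band_edges = c(0, 4)) {
  direction <- match.arg(direction)
  if (length(feature_values) != length(ln_v))
    stop_aggkin("feature and ln_v lengths differ")
  if (!is.finite(feature_threshold))
    stop_aggkin("feature threshold must be finite")
  n <- length(ln_v)
  if (n < 1) stop_aggkin("need at least one condition")
  band <- ifelse(ln_v > band_edges[2], "high",
                 ifelse(ln_v < band_edges[1], "low", "medium"))
  flagged <- if (direction == "below_flags_high")
    feature_values < feature_threshold else feature_values > feature_threshold
  high <- band == "high"
  tp <- sum(flagged & high); fp <- sum(flagged & !high)
  fn <- sum(!flagged & high); tn <- sum(!flagged & !high)
  precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  structure(list(
    counts = c(low = sum(band == "low"), medium = sum(band == "medium"),
               high = sum(band == "high")),
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
    precision = precision, feature_threshold = feature_threshold,
    direction = direction, band_edges = band_edges, band = band,
    flagged = flagged, n = n), class = "banded_classification")
}

#' @export
print.banded_classification <- function(x, ...) {
  cat(sprintf("<banded_classification> n=%d | low %d / medium %d / high %d\n",
              x$n, x$counts["low"], x$counts["medium"], x$counts["high"]))
  cat(sprintf("  flag: feature %s %.4g -> TP %d FP %d FN %d TN %d",
              if (x$direction == "below_flags_high") "<" else ">",
              x$feature_threshold, x$confusion["TP"], x$confusion["FP"],
              x$confusion["FN"], x$confusion["TN"]))
  cat(if (is.na(x$precision)) "  (precision undefined)\n"
      else sprintf("  precision %.1f%%\n", x$precision))
  invisible(x)
}

#' Residue-level regression R-squared map
#'
#' For each residue, a simple linear regression of the response on that
#' residue's RMSF across conditions; the reported value is the squared
#' Pearson correlation (identical to the OLS R-squared with one
#' predictor). Residues with constant RMSF yield missing values.
#'
#' @param rmsf_matrix conditions x residues numeric matrix (column names
#'   are residue indices).
#' @param ln_v response per condition.
#' @return named numeric vector of per-residue R-squared values.
#' @export
residue_level_r2 <- function(rmsf_matrix, ln_v) {
  m <- as.matrix(rmsf_matrix)
  if (nrow(m) < 3) stop_aggkin("at least 3 conditions required")
  if (nrow(m) != length(ln_v)) stop_aggkin("row/response length mismatch")
  apply(m, 2, function(col) {
    if (stats::sd(col) == 0) return(NA_real_)
    stats::cor(col, ln_v)^2
  })
}

#' Principal component overview of a data set
#'
#' Columns are z-scored (optionally) and decomposed by SVD. Loading signs
#' are fixed so the largest-magnitude element of each component is
#' positive; variance-explained fractions sum to one.
#'
#' @param table numeric data.frame/matrix (>= 3 rows, >= 2 columns).
#' @param standardize z-score columns first (default TRUE).
#' @return list with `loadings`, `scores`, `variance_explained`.
#' @export
pca_overview <- function(table, standardize = TRUE) {
  x <- as.matrix(as.data.frame(table))
  if (nrow(x) < 3 || ncol(x) < 2) stop_aggkin("need >= 3 rows and >= 2 columns")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop_aggkin("zero-variance column(s): %s",
                paste(colnames(x)[sds == 0], collapse = ", "))
  p <- stats::prcomp(x, center = TRUE, scale. = standardize)
  load <- p$rotation
  scores <- p$x
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]; scores[, j] <- -scores[, j]
    }
  }
  list(loadings = load, scores = scores,
       variance_explained = p$sdev^2 / sum(p$sdev^2))
}
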