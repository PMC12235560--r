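#' Normalize a raw average Euler number
#'
#' The Euler number of a reconstructed cortical surface (`2 - 2 * holes`,
#' averaged over hemispheres) is strongly left-skewed across scans: most
#' surfaces are near-perfect while poor-quality scans have very negative
#' values. The log transform `-ln(-raw + 1)` maps `(-Inf, 1)` bijectively
#' onto the real line, compressing the heavy tail so the quality proxy is
#' usable as a linear covariate.
#'
#' @param raw Numeric vector of raw average Euler numbers, each `< 1`.
#' @return Numeric vector of normalized Euler numbers; `0` maps to `0` and
#'   the transform is strictly increasing.
#' @seealso [synthesize_euler()] for the exact inverse used by the cohort
#'   generator.
#' @export
#' @examples
#' normalize_euler(c(0, -100))
normalize_euler <- function(raw) {
  if (!is.numeric(raw) || anyNA(raw)) {
    stop("raw Euler values must be numeric and non-missing", call. = FALSE)
  }
  if (any(raw >= 1)) {
    stop("normalize_euler is defined only for raw < 1 (got values >= 1)",
         call. = FALSE)
  }
  -log(-raw + 1)
}

#' Fit a training-anchored feature scaler
#'
#' Records the per-feature mean and sample standard deviation (`n - 1`
#' denominator) of the training matrix. Features with zero variance are
#' dropped with a warning and excluded consistently when the scaler is
#' applied. Out-of-sample matrices are standardized with these training
#' statistics only — never re-centred on themselves — so projections of test
#' scans stay anchored to the training cohort.
#'
#' @param train Numeric matrix, scans x features, with column names.
#' @return An object of class `scaler_model` with fields `mean`, `sd`,
#'   `features` (retained names) and `dropped`.
#' @export
fit_feature_scaler <- function(train) {
  train <- as_feature_matrix(train)
  if (nrow(train) < 2) stop("need at least 2 rows to fit a scaler", call. = FALSE)
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) {
    stop("all features have zero variance: ",
         paste(colnames(train), collapse = ", "), call. = FALSE)
  }
  if (any(!keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(train)[!keep], collapse = ", "), call. = FALSE)
  }
  out <- list(mean = mu[keep], sd = sdv[keep],
              features = colnames(train)[keep],
              dropped = colnames(train)[!keep])
  class(out) <- "scaler_model"
  out
}

#' Apply a fitted scaler to a feature matrix
#'
#' @param X Numeric matrix containing (at least) all retained features.
#' @param scaler A [fit_feature_scaler()] result.
#' @return Standardized matrix restricted to the retained features, in the
#'   scaler's feature order.
#' @export
apply_scaler <- function(X, scaler) {
  stopifnot(inherits(scaler, "scaler_model"))
  X <- as_feature_matrix(X)
  missing <- setdiff(scaler$features, colnames(X))
  if (length(missing) > 0) {
    stop("feature(s) missing from input matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- X[, scaler$features, drop = FALSE]
  sweep(sweep(X, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("feature matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- feature_names(ncol(X))
  X
}

#' Fit PCA on a standardized training matrix
#'
#' Singular-value-decomposition PCA of the (already standardized) training
#' matrix. Loadings are column-orthonormal; each loading's sign is flipped so
#' its largest-magnitude entry is positive, making stored models reproducible
#' across SVD implementations.
#'
#' @param scaled Standardized feature matrix (output of [apply_scaler()]).
#' @param max_components Number of components to retain; at most
#'   `min(nrow - 1, ncol)`.
#' @return An object of class `pca_model` with fields `loadings` (features x
#'   components), `singular_values`, `explained_variance` (fractions of total
#'   sum of squares) and `n_fitted`.
#' @export
fit_pca <- function(scaled, max_components = NULL) {
  scaled <- as_feature_matrix(scaled)
  n <- nrow(scaled); p <- ncol(scaled)
  if (n < 2) stop("need at least 2 rows to fit PCA", call. = FALSE)
  kmax <- min(n - 1, p)
  if (is.null(max_components)) max_components <- kmax
  if (max_components > kmax) {
    stop("max_components (", max_components, ") exceeds min(rows - 1, features) = ",
         kmax, call. = FALSE)
  }
  # input is standardized, so no further centering: training scores from the
  # fit and scores from project_scores() coincide exactly
  sv <- svd(scaled, nu = 0, nv = max_components)
  L <- sv$v
  # sign convention: largest-magnitude entry of each loading is positive
  flip <- apply(L, 2, function(v) sign(v[which.max(abs(v))]))
  L <- sweep(L, 2, flip, "*")
  rownames(L) <- colnames(scaled)
  colnames(L) <- sprintf("PC%d", seq_len(ncol(L)))
  d <- sv$d[seq_len(max_components)]
  ev <- sv$d^2 / sum(sv$d^2)
  out <- list(loadings = L, singular_values = d,
              explained_variance = ev[seq_len(max_components)],
              n_fitted = n)
  class(out) <- "pca_model"
  out
}

#' Project scans onto training principal components
#'
#' Standardizes `X` with the training scaler and multiplies by the first `k`
#' training loadings. Out-of-sample scans therefore use training
#' normalization and training axes only, which is what makes per-component
#' motion effects in a test cohort interpretable in the training feature
#' space.
#'
#' @param X Feature matrix (raw, unscaled).
#' @param scaler A `scaler_model`.
#' @param pca A `pca_model` fitted on the scaled training matrix.
#' @param k Number of components to keep (`0` gives an empty score matrix).
#' @return Numeric score matrix, scans x `k`, columns `PC1..PCk`.
#' @export
project_scores <- function(X, scaler, pca, k = ncol(pca$loadings)) {
  stopifnot(inherits(pca, "pca_model"))
  if (k > ncol(pca$loadings)) {
    stop("k (", k, ") exceeds the ", ncol(pca$loadings),
         " available components", call. = FALSE)
  }
  S <- apply_scaler(X, scaler)
  scores <- S %*% pca$loadings[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(S)
  scores
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d components fitted on %d scans x %d features\n",
              ncol(x$loadings), x$n_fitted, nrow(x$loadings)))
  cat(sprintf("  explained variance (first %d): %s\n",
              min(5, length(x$explained_variance)),
              paste(sprintf("%.3f", utils::head(x$explained_variance, 5)),
                    collapse = " ")))
  invisible(x)
}
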