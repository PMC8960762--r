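#' Phylogenetic (GLS) mean of trait columns
#'
#' The generalized least squares estimate of the root state for each trait:
#' `a = (1' C^-1 1)^-1 1' C^-1 X`.
#'
#' @param X species x trait numeric matrix, rows ordered as `C`'s labels.
#' @param C a `"phylo_vcv"` object or covariance matrix.
#' @return Named numeric vector, one entry per trait.
#' @export
phylo_mean <- function(X, C) {
  X <- as.matrix(X)
  Cm <- .vcv_mat(C)
  stopifnot(nrow(X) == nrow(Cm))
  U <- tryCatch(chol(Cm), error = function(e)
    stop("singular phylogenetic covariance", call. = FALSE))
  one <- matrix(1, nrow(X), 1)
  w1 <- backsolve(U, one, transpose = TRUE)
  wX <- backsolve(U, X, transpose = TRUE)
  drop(crossprod(w1, wX) / sum(w1^2))
}

#' Evolutionary covariance matrix
#'
#' The phylogenetically corrected trait covariance
#' `E = (X - 1a)' C^-1 (X - 1a) / (n - 1)` with `a` the GLS root state.
#' With `C = I` this is the ordinary sample covariance.
#'
#' @inheritParams phylo_mean
#' @return trait x trait covariance matrix.
#' @export
evolutionary_covariance <- function(X, C) {
  X <- as.matrix(X)
  Cm <- .vcv_mat(C)
  a <- phylo_mean(X, Cm)
  Xc <- sweep(X, 2L, a)
  U <- chol(Cm)
  w <- backsolve(U, Xc, transpose = TRUE)
  crossprod(w) / (nrow(X) - 1)
}

#' Phylogenetic principal components analysis
#'
#' Eigendecomposition of the evolutionary covariance (or correlation) matrix
#' of the trait columns; scores are the centred data projected onto the
#' eigenvectors. Inputs are typically the size-corrected PGLS residuals of
#' each log trait on log head mass. By default the Brownian covariance is
#' used as-is (lambda fixed at 1); a lambda value may be supplied. The sign
#' of each component is fixed so that its largest-magnitude loading is
#' positive, making results reproducible across runs.
#'
#' @inheritParams phylo_mean
#' @param lambda Pagel's lambda applied to `C` before the analysis.
#' @param mode `"cov"` (default) or `"cor"`.
#' @return Object of class `"ppca_fit"`: `eigenvalues` (descending),
#'   `loadings` (trait x component), `scores` (species x component),
#'   `variance_proportion`, `center` (GLS means), `mode`.
#' @export
ppca <- function(X, C, lambda = 1, mode = c("cov", "cor")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (!all(is.finite(X)))
    stop("trait matrix contains non-finite values", call. = FALSE)
  Cm <- lambda_transform(.vcv_mat(C), lambda)
  E <- evolutionary_covariance(X, Cm)
  if (mode == "cor") {
    s <- sqrt(diag(E))
    E <- E / tcrossprod(s)
  }
  eg <- eigen(E, symmetric = TRUE)
  V <- eg$vectors
  # deterministic sign: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  a <- phylo_mean(X, Cm)
  Xc <- sweep(X, 2L, a)
  if (mode == "cor") Xc <- sweep(Xc, 2L, sqrt(diag(evolutionary_covariance(X, Cm))), "/")
  scores <- Xc %*% V
  cn <- paste0("pPC", seq_len(ncol(V)))
  dimnames(V) <- list(colnames(X), cn)
  dimnames(scores) <- list(rownames(X), cn)
  structure(list(eigenvalues = eg$values,
                 loadings = V, scores = scores,
                 variance_proportion = eg$values / sum(eg$values),
                 center = a, mode = mode),
            class = "ppca_fit")
}

#' @export
print.ppca_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic PCA (%s mode): %d traits, %d species\n",
              x$mode, nrow(x$loadings), nrow(x$scores)))
  vp <- round(100 * x$variance_proportion[1:min(6, length(x$variance_proportion))], 1)
  cat("  % variance:", paste(vp, collapse = ", "), "\n")
  invisible(x)
}
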