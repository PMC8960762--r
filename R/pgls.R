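#' Candidate model specification
#'
#' Describes one candidate PGLS model for a trait: the allometric covariate
#' (log head mass) alone, with additive or interacting ecological group, or
#' with additive or interacting dive score (aquatic-only analyses).
#'
#' @param trait name of the response column (modelled on the natural-log
#'   scale).
#' @param predictors one of `"HM"`, `"HM+GROUP"`, `"HMxGROUP"`, `"HM+DIVE"`,
#'   `"HMxDIVE"`.
#' @param reference_group the factor reference level: `"terrestrial"` for
#'   all-species analyses, `"surface-foraging"` for aquatic-only analyses.
#' @return Object of class `"model_spec"`.
#' @export
model_spec <- function(trait, predictors = c("HM", "HM+GROUP", "HMxGROUP",
                                             "HM+DIVE", "HMxDIVE"),
                       reference_group = "terrestrial") {
  predictors <- match.arg(predictors)
  if (!reference_group %in% c("terrestrial", "surface-foraging"))
    stop("reference_group must be 'terrestrial' or 'surface-foraging'",
         call. = FALSE)
  if (predictors %in% c("HM+DIVE", "HMxDIVE") &&
      reference_group == "terrestrial")
    stop("dive-score models belong to aquatic-only analyses ",
         "(reference 'surface-foraging')", call. = FALSE)
  structure(list(trait = trait, predictors = predictors,
                 reference_group = reference_group),
            class = "model_spec")
}

#' Design matrix for a candidate model
#'
#' Builds the fixed-effect design with treatment (dummy) coding and the
#' stated reference level. Head mass enters as its natural logarithm;
#' interaction columns are products of log head mass with group dummies or
#' with the numeric 0-4 dive score.
#'
#' @param table trait table with columns `head_mass` (g), `group`, and (for
#'   dive models) `dive_score`.
#' @param spec a [model_spec()].
#' @return Numeric matrix with column names; one row per table row.
#' @export
design_matrix <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!"head_mass" %in% names(table))
    stop("table must contain a 'head_mass' column", call. = FALSE)
  lhm <- log(table$head_mass)
  dat <- data.frame(log_head_mass = lhm)
  form <- switch(spec$predictors,
                 "HM" = ~ log_head_mass,
                 "HM+GROUP" = ~ log_head_mass + group,
                 "HMxGROUP" = ~ log_head_mass * group,
                 "HM+DIVE" = ~ log_head_mass + dive_score,
                 "HMxDIVE" = ~ log_head_mass * dive_score)
  if (spec$predictors %in% c("HM+GROUP", "HMxGROUP")) {
    if (!"group" %in% names(table))
      stop("table must contain a 'group' column", call. = FALSE)
    levs <- if (spec$reference_group == "terrestrial") .ear_groups
            else .ear_aquatic_groups
    bad <- setdiff(unique(as.character(table$group)), levs)
    if (length(bad))
      stop("unknown group label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    dat$group <- factor(as.character(table$group), levels = levs)
    dat$group <- droplevels(dat$group)
    dat$group <- stats::relevel(dat$group, ref = spec$reference_group)
  }
  if (spec$predictors %in% c("HM+DIVE", "HMxDIVE")) {
    if (!"dive_score" %in% names(table))
      stop("table must contain a 'dive_score' column", call. = FALSE)
    dat$dive_score <- as.numeric(table$dive_score)
  }
  X <- stats::model.matrix(form, dat)
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  X
}

#' Generalized least squares fit with known covariance
#'
#' Fits `y = X beta + e`, `e ~ N(0, sigma2 * V)`, by whitening with the
#' Cholesky factor of `V`. Returns the GLS coefficients, their standard
#' errors (using the unbiased residual variance), the maximum-likelihood
#' `sigma2`, and the multivariate-normal ML log-likelihood.
#'
#' @param y numeric response vector.
#' @param X design matrix (full column rank).
#' @param V symmetric positive-definite covariance structure.
#' @return List with `beta`, `se`, `sigma2` (ML), `sigma2_unbiased`,
#'   `loglik`, `residuals` (response scale), `XtVinvX_inv`.
#' @export
gls_fit <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  V <- .vcv_mat(V)
  n <- length(y)
  stopifnot(nrow(X) == n, nrow(V) == n)
  if (max(abs(V - t(V))) > 1e-8 * max(abs(V)))
    stop("V must be symmetric", call. = FALSE)
  U <- tryCatch(chol(V), error = function(e)
    stop("V is not positive definite", call. = FALSE))
  wy <- backsolve(U, y, transpose = TRUE)
  wX <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(wX)
  if (qrX$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  beta <- qr.coef(qrX, wy)
  wr <- wy - wX %*% beta
  rss <- sum(wr^2)
  p <- ncol(X)
  sigma2 <- rss / n
  sigma2_u <- if (n > p) rss / (n - p) else NA_real_
  XtX_inv <- chol2inv(qr.R(qrX))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  se <- sqrt(pmax(diag(XtX_inv), 0) * sigma2_u)
  logdetV <- 2 * sum(log(diag(U)))
  loglik <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  list(beta = setNames(as.numeric(beta), colnames(X)),
       se = setNames(as.numeric(se), colnames(X)),
       sigma2 = sigma2, sigma2_unbiased = sigma2_u, loglik = loglik,
       residuals = as.numeric(y - X %*% beta), XtVinvX_inv = XtX_inv)
}

#' Small-sample corrected Akaike information criterion
#'
#' `-2 loglik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; must exceed `k + 1`.
#' @return AICc value.
#' @export
aicc <- function(loglik, k, n) {
  stopifnot(is.finite(loglik), k >= 0, n > 0)
  if (n <= k + 1)
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' PGLS with maximum-likelihood Pagel's lambda
#'
#' Fits a phylogenetic generalized least squares regression in which the
#' residual covariance is `sigma2 * C(lambda)`, with `C(lambda)` the
#' Brownian covariance whose off-diagonals are scaled by Pagel's lambda.
#' Lambda is profiled over \[0, 1\] by bounded scalar maximization of the ML
#' log-likelihood (tolerance 1e-6), searched on each half of the interval
#' and compared against the boundary values to avoid local optima; boundary
#' optima are valid results. The parameter count for AICc is the number of
#' regression coefficients plus two (sigma2 and lambda, both ML-estimated).
#'
#' @param y numeric response (natural-log trait values).
#' @param X design matrix.
#' @param C a `"phylo_vcv"` object or Brownian covariance matrix, rows
#'   ordered as `y`.
#' @param spec optional [model_spec()] stored with the fit.
#' @return Object of class `"pgls_fit"`: coefficients `beta`, `se`,
#'   `lambda_hat`, `sigma2`, `loglik`, `n`, `k`, `aicc`, `residuals`,
#'   `r2_adj`, `fitted`, `df_residual`.
#' @export
fit_pgls <- function(y, X, C, spec = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  Cm <- .vcv_mat(C)
  n <- length(y)
  p <- ncol(X)
  k <- p + 2L               # coefficients + sigma2 + lambda
  if (n <= k + 1L)
    stop("too few species: need n > k + 1 for AICc", call. = FALSE)
  prof <- function(lam) gls_fit(y, X, lambda_transform(Cm, lam))$loglik
  cand <- c(0, 0.5, 1)
  ll_cand <- vapply(cand, prof, numeric(1))
  opts <- list(optimize(prof, c(0, 0.5), maximum = TRUE, tol = 1e-6),
               optimize(prof, c(0.5, 1), maximum = TRUE, tol = 1e-6))
  lam_all <- c(cand, vapply(opts, `[[`, numeric(1), "maximum"))
  ll_all <- c(ll_cand, vapply(opts, `[[`, numeric(1), "objective"))
  best <- which.max(ll_all)
  lambda_hat <- lam_all[best]
  g <- gls_fit(y, X, lambda_transform(Cm, lambda_hat))
  # R^2 on the lambda-whitened GLS scale, against the GLS intercept-only fit
  g0 <- gls_fit(y, matrix(1, n, 1), lambda_transform(Cm, lambda_hat))
  r2 <- 1 - (g$sigma2 * n) / (g0$sigma2 * n)
  k_coef <- p - 1L
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - k_coef - 1)
  structure(list(spec = spec, beta = g$beta, se = g$se,
                 lambda_hat = lambda_hat, sigma2 = g$sigma2,
                 loglik = g$loglik, n = n, k = k,
                 aicc = aicc(g$loglik, k, n),
                 residuals = g$residuals,
                 fitted = y - g$residuals,
                 r2_adj = r2_adj, df_residual = n - p,
                 XtVinvX_inv = g$XtVinvX_inv),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  hdr <- if (!is.null(x$spec))
    sprintf("PGLS fit: log(%s) ~ %s", x$spec$trait, x$spec$predictors)
  else "PGLS fit"
  cat(hdr, "\n")
  cat(sprintf("  n = %d, lambda = %.4g, logLik = %.4f, AICc = %.4f (k = %d)\n",
              x$n, x$lambda_hat, x$loglik, x$aicc, x$k))
  cat(sprintf("  adjusted R^2 = %.4f\n", x$r2_adj))
  print(round(cbind(estimate = x$beta, se = x$se), 4))
  invisible(x)
}

#' Per-coefficient t tests
#'
#' Two-sided t tests of each coefficient against zero, with `n - p` degrees
#' of freedom (p = number of coefficients), flagged at alpha = 0.05.
#'
#' @param fit a [fit_pgls()] object.
#' @param alpha significance level for flagging.
#' @return Data frame: `term`, `estimate`, `se`, `t`, `p`, `significant`.
#' @export
coef_tests <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (any(fit$se == 0 & fit$beta != 0))
    stop("degenerate fit: zero standard error with nonzero estimate",
         call. = FALSE)
  tval <- ifelse(fit$se == 0, 0, fit$beta / fit$se)
  pval <- 2 * pt(-abs(tval), df = fit$df_residual)
  data.frame(term = names(fit$beta), estimate = as.numeric(fit$beta),
             se = as.numeric(fit$se), t = as.numeric(tval),
             p = as.numeric(pval), significant = pval < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Response-scale PGLS residuals
#'
#' `y - X beta`, in natural-log trait units, ordered as the input table.
#' These are the size-corrected values fed to the phylogenetic PCA.
#'
#' @param fit a [fit_pgls()] object.
#' @return Numeric vector.
#' @export
pgls_residuals <- function(fit) {
  stopifnot(inherits(fit, "pgls_fit"))
  fit$residuals
}

#' Model selection by the AICc parsimony rule
#'
#' Among candidate fits within `delta` AICc of the minimum, choose the one
#' with the fewest estimated parameters; ties on the parameter count are
#' broken by the lower AICc.
#'
#' @param fits list of [fit_pgls()] objects on identical data.
#' @param delta AICc window (default 2).
#' @return Object of class `"pgls_selection"`: `fits`, `chosen` (index),
#'   `delta_aicc`, `table` (summary data frame).
#' @export
select_model <- function(fits, delta = 2) {
  stopifnot(is.list(fits), length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "pgls_fit")))
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L)
    stop("candidate fits were made on differing sample sizes", call. = FALSE)
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  k <- vapply(fits, `[[`, numeric(1), "k")
  d <- a - min(a)
  in_window <- which(d < delta)
  cand <- in_window[k[in_window] == min(k[in_window])]
  chosen <- cand[which.min(a[cand])]
  tab <- data.frame(
    model = vapply(fits, function(f)
      if (is.null(f$spec)) NA_character_ else f$spec$predictors,
      character(1)),
    k = k, aicc = a, delta_aicc = d,
    lambda = vapply(fits, `[[`, numeric(1), "lambda_hat"),
    r2_adj = vapply(fits, `[[`, numeric(1), "r2_adj"),
    chosen = seq_along(fits) == chosen,
    stringsAsFactors = FALSE)
  structure(list(fits = fits, chosen = chosen, delta_aicc = d, table = tab),
            class = "pgls_selection")
}

#' @export
print.pgls_selection <- function(x, ...) {
  cat("PGLS model selection (parsimony within dAICc < 2):\n")
  print(transform(x$table, aicc = round(aicc, 3),
                  delta_aicc = round(delta_aicc, 3),
                  lambda = round(lambda, 4), r2_adj = round(r2_adj, 4)))
  invisible(x)
}

#' Convert a log-scale coefficient to a percentage of the reference level
#'
#' A group coefficient `beta` on a natural-log response means the group's
#' trait value is `100 * exp(beta)` percent of the reference group's value
#' at equal head mass.
#'
#' @param beta log-scale coefficient(s).
#' @param digits rounding for reporting; `NA` for no rounding. Default 0
#'   (nearest integer percent).
#' @return Percentage(s).
#' @export
effect_to_percentage <- function(beta, digits = 0) {
  stopifnot(all(is.finite(beta)))
  out <- 100 * exp(beta)
  if (!is.na(digits)) out <- round(out, digits)
  out
}
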