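#' Equal-tailed credible interval and decision rule
#'
#' Computes the equal-tailed quantile interval of posterior draws and
#' applies the decision rule: the null (parameter = 0) is rejected when the
#' interval excludes zero.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param level credible level (default 0.95).
#' @return List with `lower`, `upper`, `reject`.
#' @export
ci_decision <- function(draws, level = 0.95) {
  draws <- as.numeric(draws)
  if (length(draws) < 100L)
    stop("need at least 100 draws for a credible interval", call. = FALSE)
  a <- (1 - level) / 2
  q <- unname(quantile(draws, c(a, 1 - a)))
  list(lower = q[1], upper = q[2], reject = q[1] > 0 || q[2] < 0)
}

# split-chain potential scale reduction factor (Rhat)
.rhat <- function(mat) {
  # mat: iterations x chains; split each chain in half
  half <- floor(nrow(mat) / 2)
  if (half < 2L) return(NA_real_)
  sub <- cbind(mat[seq_len(half), , drop = FALSE],
               mat[half + seq_len(half), , drop = FALSE])
  m <- ncol(sub); n <- nrow(sub)
  mu <- colMeans(sub)
  B <- n * var(mu)
  W <- mean(apply(sub, 2L, var))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayesian phylogenetic cumulative-logit regression
#'
#' Fits an ordinal (cumulative-logit) model for a 3-level connectivity state
#' with a phylogenetic random effect:
#' `P(y_i <= k) = logistic(tau_k - x_i' beta - u_i)`,
#' `u ~ MVN(0, sigma_u^2 * C_scaled)`, where `C_scaled` is the Brownian
#' covariance scaled to unit maximum diagonal (for identifiability of
#' `sigma_u`). Priors are weakly informative: slopes `N(0, 5)`, thresholds
#' Student-t(3, 0, 2.5) subject to ordering, `sigma_u`
#' half-Student-t(3, 0, 2.5). The threshold prior anchors the latent scale:
#' with one observation per species the per-species effect can otherwise
#' absorb the data entirely (quasi-separation), letting thresholds, slopes
#' and `sigma_u` inflate without bound.
#' Sampling is Metropolis-within-Gibbs with step sizes adapted during the
#' first half of each chain, which is discarded as burn-in; runs are
#' bit-reproducible given identical seed, chains and iterations.
#'
#' @param y ordered factor or integer vector with levels 1..3 (low, medium,
#'   high closure). At least two levels must be observed.
#' @param X predictor matrix (no intercept column; the thresholds play that
#'   role).
#' @param C a `"phylo_vcv"` object or covariance matrix, rows ordered as
#'   `y`; rescaled internally to unit maximum diagonal.
#' @param chains number of chains (>= 2).
#' @param iterations iterations per chain (first half discarded).
#' @param seed integer RNG seed.
#' @param priors list overriding `slope_sd`, `sigma_nu`, `sigma_scale`.
#' @param sigma_u_fixed if 0, the phylogenetic effect is switched off
#'   (independent observations); `NULL` (default) samples `sigma_u`.
#' @return Object of class `"phylo_ordinal"`: `draws` (named list of draw
#'   vectors pooled over chains), `summary` (data frame with mean, sd,
#'   ci2.5, ci97.5, rhat, decision), `n_chains`, `n_iter`, `convergence_ok`.
#' @export
fit_phylo_ordinal <- function(y, X, C, chains = 2L, iterations = 6000L,
                              seed = 1L, priors = list(),
                              sigma_u_fixed = NULL) {
  if (is.ordered(y) || is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (any(is.na(y)) || any(y < 1L) || any(y > 3L))
    stop("response must be an ordered factor with levels in 1..3",
         call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("fewer than 2 response levels observed", call. = FALSE)
  if (chains < 2L) stop("need at least 2 chains", call. = FALSE)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("b", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n)
  pr <- modifyList(list(slope_sd = 5, tau_nu = 3, tau_scale = 2.5,
                        sigma_nu = 3, sigma_scale = 2.5), priors)
  fix0 <- !is.null(sigma_u_fixed) && sigma_u_fixed == 0
  Cs <- scale_vcv(.vcv_mat(C))
  stopifnot(nrow(Cs) == n)
  Cinv <- if (fix0) diag(n) else chol2inv(chol(Cs))
  res <- .ordinal_mcmc_cpp(y, X, Cinv, 3L, as.integer(iterations),
                           as.integer(chains), as.integer(seed),
                           pr$slope_sd, pr$tau_nu, pr$tau_scale,
                           pr$sigma_nu, pr$sigma_scale, fix0)
  par_names <- c(colnames(X), "tau1", "tau2", "sigma_u")
  keep <- res$n_kept
  draws <- setNames(vector("list", length(par_names)), par_names)
  rhat <- numeric(length(par_names))
  for (j in seq_along(par_names)) {
    mat <- vapply(res$chains, function(m) m[, j], numeric(keep))
    draws[[j]] <- as.numeric(mat)
    rhat[j] <- .rhat(mat)
  }
  slope_idx <- seq_len(ncol(X))
  summ <- do.call(rbind, lapply(seq_along(par_names), function(j) {
    ci <- ci_decision(draws[[j]])
    data.frame(parameter = par_names[j], mean = mean(draws[[j]]),
               sd = sd(draws[[j]]), ci2.5 = ci$lower, ci97.5 = ci$upper,
               rhat = rhat[j],
               decision = if (j %in% slope_idx)
                 if (ci$reject) "reject" else "retain"
               else NA_character_,
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  conv_ok <- all(is.na(rhat) | rhat < 1.1)
  if (!conv_ok)
    warning("convergence warning: Rhat > 1.1 for ",
            paste(par_names[!is.na(rhat) & rhat >= 1.1], collapse = ", "),
            call. = FALSE)
  structure(list(draws = draws, summary = summ, n_chains = chains,
                 n_iter = iterations, rhat = setNames(rhat, par_names),
                 convergence_ok = conv_ok, seed = seed),
            class = "phylo_ordinal")
}

#' @export
print.phylo_ordinal <- function(x, ...) {
  cat(sprintf(
    "Phylogenetic ordinal regression: %d chains x %d iterations%s\n",
    x$n_chains, x$n_iter,
    if (x$convergence_ok) "" else "  [convergence warning]"))
  s <- x$summary
  s[, c("mean", "sd", "ci2.5", "ci97.5", "rhat")] <-
    round(s[, c("mean", "sd", "ci2.5", "ci97.5", "rhat")], 3)
  print(s)
  invisible(x)
}
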