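test_that("design matrices implement treatment coding with stated reference", {
  tab <- data.frame(
    species = paste0("s", 1:8), head_mass = exp(1:8),
    group = rep(c("terrestrial", "surface-foraging", "plunge-diving",
                  "underwater-pursuit"), 2),
    dive_score = c(0, 1, 2, 4, 0, 1, 3, 4))
  X1 <- design_matrix(tab, model_spec("y", "HM"))
  expect_equal(dim(X1), c(8L, 2L))
  expect_equal(X1[, "log_head_mass"], as.numeric(1:8), ignore_attr = TRUE)
  X2 <- design_matrix(tab, model_spec("y", "HM+GROUP"))
  expect_equal(ncol(X2), 5L)
  # terrestrial rows carry zero dummies (reference level)
  expect_true(all(X2[tab$group == "terrestrial",
                     grep("^group", colnames(X2))] == 0))
  X3 <- design_matrix(tab, model_spec("y", "HMxGROUP"))
  expect_equal(ncol(X3), 8L)
  aq <- tab[tab$group != "terrestrial", ]
  X4 <- design_matrix(aq, model_spec("y", "HM+DIVE", "surface-foraging"))
  expect_equal(ncol(X4), 3L)
  expect_equal(X4[, "dive_score"], aq$dive_score, ignore_attr = TRUE)
  expect_error(design_matrix(transform(tab, group = "aerial"),
                             model_spec("y", "HM+GROUP")), "aerial")
  expect_error(model_spec("y", "HM+DIVE", "terrestrial"), "aquatic")
})

test_that("GLS with identity covariance equals ordinary least squares", {
  set.seed(10)
  n <- 40
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(X %*% c(1, 2, -0.5)) + rnorm(n)
  g <- gls_fit(y, X, diag(n))
  ols <- lm.fit(X, y)
  expect_equal(unname(g$beta), unname(ols$coefficients), tolerance = 1e-10)
  expect_equal(g$residuals, unname(ols$residuals), tolerance = 1e-10)
  sm <- summary(lm(y ~ X - 1))
  expect_equal(unname(g$se), unname(sm$coefficients[, 2]),
               tolerance = 1e-10)
  # intercept-only: beta is the sample mean
  g0 <- gls_fit(y, matrix(1, n), diag(n))
  expect_equal(unname(g0$beta), mean(y), tolerance = 1e-12)
  # exact linear data: zero residuals under any valid V
  yy <- drop(X %*% c(1, 2, -0.5))
  V <- crossprod(matrix(rnorm(n * n), n)) + diag(n)
  ge <- gls_fit(yy, X, V)
  expect_equal(max(abs(ge$residuals)), 0, tolerance = 1e-8)
  expect_equal(ge$sigma2, 0, tolerance = 1e-10)
  expect_error(gls_fit(y, cbind(X, X[, 2]), diag(n)), "rank")
})

test_that("GLS matches the closed-form normal equations and nlme", {
  set.seed(11)
  tr <- sim_tree(30, seed = 11)
  V <- phylo_covariance(tr)$C
  n <- 30
  X <- cbind(1, rnorm(n))
  y <- drop(X %*% c(0.5, 1.5)) + drop(crossprod(chol(V), rnorm(n)))
  g <- gls_fit(y, X, V)
  Vi <- solve(V)
  beta_oracle <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(unname(g$beta), drop(beta_oracle), tolerance = 1e-9)
  skip_if_not_installed("nlme")
  df <- data.frame(y = y, x = X[, 2], sp = rownames(V))
  gn <- nlme::gls(y ~ x, data = df, method = "ML",
                  correlation = ape::corBrownian(form = ~sp, phy = tr))
  expect_equal(unname(g$beta), unname(coef(gn)), tolerance = 1e-6)
  expect_equal(g$loglik, as.numeric(gn$logLik), tolerance = 1e-4)
})

test_that("AICc follows the small-sample formula and its AIC limit", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  expect_equal(aicc(-5, 0, 10), 10)
  expect_equal(aicc(-10, 3, 1e9), -2 * -10 + 2 * 3, tolerance = 1e-6)
  expect_error(aicc(0, 4, 5), "n must exceed")
})

test_that("profiled lambda dominates a grid and equals OLS at identity C", {
  tr <- sim_tree(60, seed = 21)
  sim <- sim_traits(tr, sim_truth(lambda_true = 0.6), seed = 21,
                    traits = "t1")
  y <- log(sim$table$t1)
  X <- design_matrix(sim$table, model_spec("t1", "HM"))
  C <- phylo_covariance(tr)
  fit <- fit_pgls(y, X, C)
  for (lam in c(0, 0.25, 0.5, 0.75, 1)) {
    ll <- gls_fit(y, X, lambda_transform(C, lam)$C)$loglik
    expect_gte(fit$loglik + 1e-8, ll)
  }
  # with an identity covariance the fit must reduce to OLS exactly
  fit_id <- fit_pgls(y, X, diag(length(y)))
  ols <- lm.fit(X, y)
  expect_equal(unname(fit_id$beta), unname(ols$coefficients),
               tolerance = 1e-10)
  expect_equal(fit_id$residuals, unname(ols$residuals), tolerance = 1e-10)
  expect_error(fit_pgls(y[1:5], X[1:5, ], diag(5)), "too few")
})

test_that("lambda is recovered at both ends of its range", {
  no_offset <- c("terrestrial" = 0, "surface-foraging" = 0,
                 "plunge-diving" = 0, "underwater-pursuit" = 0)
  lam_hat <- function(lambda_true, reps = 50, n = 200) {
    vapply(seq_len(reps), function(r) {
      tr <- sim_tree(n, seed = 3000 + r)
      sim <- sim_traits(tr, sim_truth(lambda_true = lambda_true,
                                      group_offsets = no_offset),
                        seed = 3000 + r, traits = "t1")
      X <- design_matrix(sim$table, model_spec("t1", "HM"))
      fit_pgls(log(sim$table$t1), X, phylo_covariance(tr))$lambda_hat
    }, numeric(1))
  }
  expect_gte(median(lam_hat(1)), 0.9)
  expect_lte(median(lam_hat(0)), 0.1)
})

test_that("coefficient recovery is unbiased within Monte-Carlo error", {
  reps <- 100
  est <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    tr <- sim_tree(130, seed = 4000 + r)
    sim <- sim_traits(tr, seed = 4000 + r, traits = "t1")
    X <- design_matrix(sim$table, model_spec("t1", "HM+GROUP"))
    fit <- fit_pgls(log(sim$table$t1), X, phylo_covariance(tr))
    est[r, ] <- c(fit$beta["log_head_mass"],
                  fit$beta["groupunderwater-pursuit"])
  }
  truth <- c(0.6, -1.20)
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(est) - truth) < 2 * mc_se + 1e-3))
})

test_that("model selection applies the dAICc < 2 parsimony rule", {
  mk <- function(aicc, k) structure(list(aicc = aicc, k = k, n = 50,
                                         lambda_hat = 1, r2_adj = 0.5,
                                         spec = NULL),
                                    class = "pgls_fit")
  s1 <- select_model(list(mk(100, 4), mk(101.5, 3)))
  expect_equal(s1$chosen, 2L)
  s2 <- select_model(list(mk(100, 3), mk(103, 2), mk(105, 2)))
  expect_equal(s2$chosen, 1L)
  s3 <- select_model(list(mk(100, 3), mk(101.9, 3)))
  expect_equal(s3$chosen, 1L)
  bad <- list(mk(100, 3), structure(list(aicc = 99, k = 3, n = 40,
                                         lambda_hat = 1, r2_adj = 0.5,
                                         spec = NULL),
                                    class = "pgls_fit"))
  expect_error(select_model(bad), "differing")
})

test_that("selection recovers the generating model at strong group effects", {
  strong <- c("terrestrial" = 0, "surface-foraging" = -1.0,
              "plunge-diving" = -1.5, "underwater-pursuit" = -2.0)
  hits <- 0L
  reps <- 100
  for (r in seq_len(reps)) {
    tr <- sim_tree(130, seed = 5000 + r)
    sim <- sim_traits(tr, sim_truth(group_offsets = strong), seed = 5000 + r,
                      traits = "t1", clade_wise = FALSE)
    C <- phylo_covariance(tr)
    y <- log(sim$table$t1)
    fits <- lapply(c("HM", "HM+GROUP", "HMxGROUP"), function(p) {
      sp <- model_spec("t1", p)
      fit_pgls(y, design_matrix(sim$table, sp), C, sp)
    })
    sel <- select_model(fits)
    if (sel$chosen == 2L) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.8)
})

test_that("coefficient tests have power at strong effects and honest nulls", {
  # strong effect: flagged significant in nearly all replicates
  flags <- vapply(seq_len(100), function(r) {
    tr <- sim_tree(100, seed = 6000 + r)
    off <- c("terrestrial" = 0, "surface-foraging" = 0,
             "plunge-diving" = 0,
             "underwater-pursuit" = 5 * sqrt(0.1))
    sim <- sim_traits(tr, sim_truth(group_offsets = off), seed = 6000 + r,
                      traits = "t1", clade_wise = FALSE)
    fit <- fit_pgls(log(sim$table$t1),
                    design_matrix(sim$table, model_spec("t1", "HM+GROUP")),
                    phylo_covariance(tr))
    ct <- coef_tests(fit)
    ct$significant[ct$term == "groupunderwater-pursuit"]
  }, logical(1))
  expect_gte(mean(flags), 0.95)
  # a zero coefficient yields p = 1
  f0 <- structure(list(beta = c(a = 0), se = c(a = 0.5), df_residual = 10),
                  class = "pgls_fit")
  expect_equal(coef_tests(f0)$p, 1)
  fbad <- structure(list(beta = c(a = 1), se = c(a = 0), df_residual = 10),
                    class = "pgls_fit")
  expect_error(coef_tests(fbad), "degenerate")
})

test_that("residuals are GLS-orthogonal to the design", {
  tr <- sim_tree(50, seed = 31)
  sim <- sim_traits(tr, seed = 31, traits = "t1")
  X <- design_matrix(sim$table, model_spec("t1", "HM+GROUP"))
  C <- phylo_covariance(tr)
  fit <- fit_pgls(log(sim$table$t1), X, C)
  r <- pgls_residuals(fit)
  Vi <- solve(lambda_transform(C, fit$lambda_hat)$C)
  expect_lt(max(abs(t(X) %*% Vi %*% r)), 1e-8)
  # perfect linear data gives all-zero residuals
  y_lin <- drop(X %*% c(1, 0.6, -0.3, -0.5, -1.2))
  expect_lt(max(abs(pgls_residuals(fit_pgls(y_lin, X, C)))), 1e-8)
})

test_that("log-scale effects convert to percentages of the reference", {
  expect_equal(effect_to_percentage(0), 100)
  expect_equal(effect_to_percentage(-2.7), 7)
  expect_equal(effect_to_percentage(-1.20), 30)
  expect_equal(effect_to_percentage(-0.72, digits = NA), 48.67523,
               tolerance = 1e-6)
})
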