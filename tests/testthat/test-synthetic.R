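test_that("tree simulation is seeded, unit-height and sized correctly", {
  t2 <- sim_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2L)
  expect_equal(max(ape::node.depth.edgelength(t2)), 1, tolerance = 1e-12)
  a <- write_newick(sim_tree(130, seed = 77))
  b <- write_newick(sim_tree(130, seed = 77))
  expect_identical(a, b)
  expect_false(identical(a, write_newick(sim_tree(130, seed = 78))))
  big <- sim_tree(130, seed = 77)
  expect_true(ape::is.ultrametric(big, tol = 1e-8))
  expect_error(sim_tree(1), "2 tips")
})

test_that("noise-free traits are exactly allometric", {
  tr <- sim_tree(40, seed = 6)
  sim <- sim_traits(tr, sim_truth(sigma2_true = 0), seed = 6,
                    traits = "t1")
  X <- design_matrix(sim$table, model_spec("t1", "HM+GROUP"))
  fit <- fit_pgls(log(sim$table$t1), X, phylo_covariance(tr))
  expect_equal(unname(fit$beta["log_head_mass"]), 0.6, tolerance = 1e-8)
  expect_equal(unname(fit$beta["(Intercept)"]), -1, tolerance = 1e-8)
  expect_equal(unname(fit$beta["groupunderwater-pursuit"]), -1.2,
               tolerance = 1e-8)
})

test_that("residual covariance matches sigma2 * C(lambda) empirically", {
  tr <- sim_tree(5, seed = 16)
  truth <- sim_truth(lambda_true = 0.7, sigma2_true = 0.4,
                     group_offsets = c("terrestrial" = 0,
                                       "surface-foraging" = 0,
                                       "plunge-diving" = 0,
                                       "underwater-pursuit" = 0))
  sim <- sim_traits(tr, truth, seed = 16,
                    traits = paste0("t", 1:2000))
  lhm <- log(sim$table$head_mass)
  eps <- sapply(paste0("t", 1:2000), function(nm)
    log(sim$table[[nm]]) - (-1 + 0.6 * lhm))
  emp <- cov(t(eps)) * (2000 - 1) / 2000   # known zero mean
  V <- 0.4 * lambda_transform(phylo_covariance(tr)$C, 0.7)
  expect_lt(max(abs(emp - V)), 0.1 * max(diag(V)))
  expect_true(all(abs(diag(emp) / diag(V) - 1) < 0.1))
})

test_that("ordinal generator matches analytic level probabilities", {
  trbig <- sim_tree(5000, seed = 17)
  X <- matrix(0, 5000, 1)
  sim <- sim_ordinal(trbig, X, beta = 0, thresholds = c(-1, 1),
                     sigma_u = 0, seed = 17)
  freq <- tabulate(sim$y, 3) / 5000
  expected <- c(plogis(-1), plogis(1) - plogis(-1), 1 - plogis(1))
  expect_true(all(abs(freq - expected) < 0.03))
  # saturation: a huge positive effect pushes its group to the top level
  tr <- sim_tree(60, seed = 18)
  grp <- rep(c(0, 1), each = 30)
  sat <- sim_ordinal(tr, matrix(grp), beta = 50, sigma_u = 0, seed = 18)
  expect_true(all(sat$y[grp == 1] == 3L))
  # determinism
  s1 <- sim_ordinal(tr, matrix(grp), beta = 1, sigma_u = 1, seed = 19)
  s2 <- sim_ordinal(tr, matrix(grp), beta = 1, sigma_u = 1, seed = 19)
  expect_identical(s1$y, s2$y)
  expect_error(sim_ordinal(tr, matrix(grp), 1, thresholds = c(1, -1)),
               "increasing")
})

test_that("ear geometry generator is exact at zero noise, close under noise", {
  g <- sim_ear_geometry(seed = 20)
  m <- measure_specimen(g$landmarks)
  expect_equal(m$tympanic_membrane_area, g$truth$tympanic_membrane_area,
               tolerance = 5e-3)
  expect_equal(m$umbo_height, g$truth$umbo_height, tolerance = 1e-9)
  expect_equal(m$tympanic_membrane_angle, g$truth$tympanic_membrane_angle,
               tolerance = 1e-7)
  flat <- sim_ear_geometry(list(umbo_height = 0), seed = 21)
  mf <- measure_specimen(flat$landmarks)
  expect_equal(mf$tympanic_membrane_angle, 0, tolerance = 1e-9)
  expect_equal(mf$umbo_height, 0, tolerance = 1e-9)
  # 1 % coordinate noise keeps areas within 5 % of truth across seeds
  errs <- vapply(1:100, function(s) {
    gg <- sim_ear_geometry(list(noise_sd = 0.03), seed = s)
    mm <- measure_specimen(gg$landmarks)
    abs(mm$tympanic_membrane_area / gg$truth$tympanic_membrane_area - 1)
  }, numeric(1))
  expect_lt(max(errs), 0.05)
  # determinism and parameter validation
  d1 <- sim_ear_geometry(seed = 22)$landmarks
  d2 <- sim_ear_geometry(seed = 22)$landmarks
  expect_identical(d1, d2)
  expect_error(sim_ear_geometry(list(tm_radius = -1)), "positive")
  expect_error(sim_ear_geometry(list(ring_points = 4)), "ring_points")
})

test_that("generator output round-trips through the file formats", {
  tr <- sim_tree(12, seed = 23)
  sim <- sim_traits(tr, seed = 23, traits = c("t1", "t2"))
  td <- withr::local_tempdir()
  write_newick(tr, file.path(td, "tree.nwk"))
  write_trait_table(sim$table, file.path(td, "traits.csv"))
  tr2 <- parse_newick(file = file.path(td, "tree.nwk"))
  tab2 <- read_trait_table(file.path(td, "traits.csv"))
  expect_setequal(tr2$tip.label, sim$table$species)
  expect_equal(tab2$t1, sim$table$t1, tolerance = 1e-9)
  expect_equal(tab2$group, sim$table$group)
})
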