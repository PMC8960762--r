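test_that("base plane fitting recovers exact and noisy planes", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  pl <- fit_base_plane(sq)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_equal(pl$rms_residual, 0, tolerance = 1e-12)

  tri <- rbind(c(0, 0, 0), c(2, 0, 1), c(0, 3, -1))
  pl3 <- fit_base_plane(tri)
  expect_true(all(abs((sweep(tri, 2, pl3$origin) %*% pl3$normal)) < 1e-12))

  set.seed(42)
  pts <- cbind(runif(200, -1, 1), runif(200, -1, 1), rnorm(200, sd = 0.01))
  plf <- fit_base_plane(pts)
  # oracle: plane from a direct SVD of the centred cloud
  sv <- svd(scale(pts, scale = FALSE))
  oracle_normal <- sv$v[, 3]
  ang <- acos(min(1, abs(sum(plf$normal * oracle_normal)))) * 180 / pi
  expect_lt(ang, 1e-8)
  ang_z <- acos(min(1, abs(plf$normal[3]))) * 180 / pi
  expect_lt(ang_z, 1)

  expect_error(fit_base_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "3 points")
  coll <- cbind(seq(0, 1, length.out = 5), 0, 0)
  expect_error(fit_base_plane(coll), "collinear")
})

test_that("ring areas match shoelace and analytic values", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(ring_area(sq), 1, tolerance = 1e-12)

  circ <- flat_circle(1, 512L)
  expect_equal(ring_area(circ), pi, tolerance = pi * 1e-4)

  # tilted ellipse: projection to its own plane recovers the exact area
  th <- 2 * pi * (seq_len(1024L) - 1L) / 1024L
  ell <- cbind(2 * cos(th), sin(th), 0)
  rot <- rbind(c(1, 0, 0),
               c(0, cos(pi / 6), -sin(pi / 6)),
               c(0, sin(pi / 6), cos(pi / 6)))
  expect_equal(ring_area(ell %*% t(rot)), 2 * pi, tolerance = 2 * pi * 5e-4)

  bow <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(ring_area(bow, "tympanic_rim"), "tympanic_rim")
})

test_that("umbo height, membrane angle and offset follow cone geometry", {
  rim <- flat_circle(1, 64L)
  expect_equal(umbo_height(rim, c(0.2, 0.1, 0)), 0, tolerance = 1e-12)
  expect_equal(umbo_height(rim, c(0, 0, 2)), 2, tolerance = 1e-12)

  expect_equal(membrane_angle(rim, c(0, 0, 0)), 0, tolerance = 1e-9)
  expect_equal(membrane_angle(rim, c(0, 0, 1)), 45, tolerance = 1e-9)
  h22 <- tan(22 * pi / 180)
  expect_equal(membrane_angle(rim, c(0, 0, h22)), 22, tolerance = 1e-9)
  expect_error(membrane_angle(rim, rim[1, ]), "coincides")

  expect_equal(columella_offset(rim, c(0, 0, 0.7)), 0, tolerance = 1e-12)
  expect_equal(columella_offset(rim, c(0.5, 0, 3)), 0.5, tolerance = 1e-12)
})

test_that("all measures are invariant to rigid motion", {
  ear <- cone_ear()
  moved <- cone_ear(move = rigid_motion(7))
  m1 <- measure_specimen(ear)
  m2 <- measure_specimen(moved)
  for (v in setdiff(names(m1), c("species", "n_specimens")))
    expect_equal(m2[[v]], m1[[v]], tolerance = 1e-9, label = v)
})

test_that("lever arms behave as a second-order lever", {
  rim <- flat_circle(2, 64L)
  # tip and umbo both projecting to the centroid: no lever
  lv0 <- lever_arms(rim, c(0, 0, 0.5), c(0, 0, 1))
  expect_equal(lv0$ratio, 1, tolerance = 1e-12)
  # collinear: fulcrum at (2,0), tip at distance 1, umbo at the centre
  lv <- lever_arms(rim, c(1, 0, 0.5), c(0, 0, 1))
  expect_equal(lv$l2, 1, tolerance = 1e-9)
  expect_equal(lv$l1, 2, tolerance = 1e-9)
  expect_equal(lv$ratio, 2, tolerance = 1e-9)
  # sweeping the offset toward zero drives the ratio monotonically to 1
  offs <- seq(1.5, 0, length.out = 12)
  ratios <- vapply(offs, function(o)
    lever_arms(rim, c(o, 0, 0.5), c(0, 0, 1))$ratio, numeric(1))
  expect_true(all(diff(ratios) <= 1e-12))
  expect_equal(ratios[length(ratios)], 1, tolerance = 1e-9)
  expect_error(lever_arms(rim, c(2, 0, 0), c(0, 0, 1)), "l2")
})

test_that("segment_length is the Euclidean metric", {
  expect_equal(segment_length(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(segment_length(c(0, 0, 0), c(3, 4, 0)), 5)
  mv <- rigid_motion(3)
  p <- c(0.3, -1, 2); q <- c(5, 0.1, -2)
  expect_equal(segment_length(drop(mv(p)), drop(mv(q))),
               segment_length(p, q), tolerance = 1e-12)
})

test_that("measure_specimen recovers generator truth and flags missing input", {
  g <- sim_ear_geometry(seed = 11)
  m <- measure_specimen(g$landmarks)
  for (v in setdiff(names(m), c("species", "n_specimens")))
    expect_equal(m[[v]], g$truth[[v]], tolerance = 0.01, label = v)

  flat <- sim_ear_geometry(list(umbo_height = 0), seed = 2)
  mf <- measure_specimen(flat$landmarks)
  expect_equal(mf$umbo_height, 0, tolerance = 1e-9)
  expect_equal(mf$tympanic_membrane_angle, 0, tolerance = 1e-9)

  ear <- cone_ear()
  ear$rings$tympanic_rim <- NULL
  expect_error(measure_specimen(ear), "tympanic_rim")
})

test_that("species means average components and recompute ratios", {
  r1 <- measure_specimen(cone_ear(r = 3, h = 1.2))
  expect_equal(species_mean(r1), r1)
  r2 <- measure_specimen(cone_ear(r = 2, h = 0.8))
  r2$species <- "spA"
  avg <- species_mean(rbind(r1, r2))
  expect_equal(avg$n_specimens, 2L)
  expect_equal(avg$tympanic_membrane_area,
               mean(c(r1$tympanic_membrane_area, r2$tympanic_membrane_area)))
  expect_equal(avg$area_ratio,
               avg$tympanic_membrane_area / avg$footplate_area,
               tolerance = 1e-12)
  expect_equal(avg$lever_ratio, avg$lever_arm_l1 / avg$lever_arm_l2,
               tolerance = 1e-12)
  r3 <- r2; r3$species <- "spB"
  expect_error(species_mean(rbind(r1, r3)), "mix")
  expect_error(species_mean(r1[0, ]), "no records")
})

test_that("averaging noisy replicates reduces error (RMS over simulations)", {
  truth <- sim_ear_geometry(seed = 1)$truth
  err_single <- err_mean <- numeric(60)
  for (s in seq_len(60)) {
    reps <- lapply(1:4, function(k)
      measure_specimen(sim_ear_geometry(list(noise_sd = 0.03),
                                        seed = 1000 * s + k)$landmarks))
    recs <- do.call(rbind, reps)
    avg <- species_mean(recs)
    err_single[s] <- abs(recs$tympanic_membrane_area[1] -
                           truth$tympanic_membrane_area)
    err_mean[s] <- abs(avg$tympanic_membrane_area -
                         truth$tympanic_membrane_area)
  }
  expect_lt(sqrt(mean(err_mean^2)), sqrt(mean(err_single^2)))
})

test_that("fiducial CSV round-trips points and ring order", {
  ear <- cone_ear(m = 16L)
  f <- withr::local_tempfile(fileext = ".fcsv")
  write_fcsv(ear, f)
  back <- read_fcsv(f, specimen_id = "s1", species = "spA")
  expect_equal(back$points[order(names(back$points))],
               ear$points[order(names(ear$points))], tolerance = 1e-9)
  expect_equal(back$rings[order(names(back$rings))],
               ear$rings[order(names(ear$rings))], tolerance = 1e-9)
  m1 <- measure_specimen(ear); m2 <- measure_specimen(back)
  expect_equal(m2, m1, tolerance = 1e-9)
})
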