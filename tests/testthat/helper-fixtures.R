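# shared fixture builders; everything is generated in code at test time

# points of a regular m-gon of radius r in the plane z = 0, centred at origin
flat_circle <- function(r = 1, m = 32L) {
  th <- 2 * pi * (seq_len(m) - 1L) / m
  cbind(r * cos(th), r * sin(th), 0)
}

# a deterministic rigid motion: rotation (from a seeded QR) plus translation
rigid_motion <- function(seed = 1L, shift = c(3, -2, 5)) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 3] <- -q[, 3]
  function(x) {
    x <- rbind(x)
    sweep(x %*% t(q), 2L, shift, "+")
  }
}

# full synthetic landmark set: cone eardrum (apex over centre), offset tip
cone_ear <- function(r = 3, h = 1.2, offset = 1, m = 32L,
                     move = identity) {
  rim <- flat_circle(r, m)
  umbo <- c(0, 0, h)
  tip <- c(offset, 0, 0.5 * h)
  fp_ctr <- tip - c(0, 0, 2.5)
  fp <- sweep(flat_circle(0.8, m), 2L, fp_ctr, "+")
  rw <- sweep(flat_circle(0.5, m), 2L, c(7, 0, 0), "+")
  ca <- sweep(flat_circle(0.3, m), 2L, c(10, 0, 0), "+")
  landmark_set("s1", "spA",
    points = list(umbo = drop(move(umbo)),
                  columella_tip = drop(move(tip)),
                  extrastapedius_tip = drop(move(umbo)),
                  extrastapedius_base = drop(move(tip)),
                  columella_footplate_center = drop(move(fp_ctr))),
    rings = list(tympanic_rim = move(rim), footplate_rim = move(fp),
                 round_window_rim = move(rw),
                 cochlear_aqueduct_rim = move(ca)))
}

# independent covariance oracle: shared path length via MRCA depths
brute_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n))
    for (j in seq_len(n))
      C[i, j] <- if (i == j) depth[i] else depth[mr[i, j]]
  C
}

# aquatic-only table whose traits depend on dive score, with known slope
sim_dive_trait <- function(tree, dive_slope, sigma2 = 0.1, seed = 1L) {
  sim <- sim_traits(tree, sim_truth(sigma2_true = 0), seed = seed,
                    traits = character(0),
                    group_probs = c("terrestrial" = 0,
                                    "surface-foraging" = 0.4,
                                    "plunge-diving" = 0.3,
                                    "underwater-pursuit" = 0.3))
  tab <- sim$table
  n <- nrow(tab)
  C <- phylo_covariance(tree)$C
  set.seed(seed + 500L)
  eps <- drop(crossprod(chol(sigma2 * C + diag(1e-12, n)), rnorm(n)))
  tab$trait1 <- exp(-1 + 0.6 * log(tab$head_mass) +
                      dive_slope * tab$dive_score + eps)
  tab
}
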