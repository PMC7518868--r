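test_that("row thresholding keeps the top entries per row", {
  set.seed(1)
  p <- 30
  m <- matrix(rnorm(p * p), p)
  m <- (m + t(m)) / 2
  diag(m) <- 1

  tm <- threshold_rows(m, 0.2)
  k <- floor(0.2 * (p - 1))
  for (i in seq_len(p)) {
    off <- tm[i, -i]
    expect_equal(sum(off != 0), k)
    # retained set equals the brute-force sort oracle
    oracle <- order(m[i, -i], decreasing = TRUE)[seq_len(k)]
    expect_setequal(which(off != 0), oracle)
  }
  expect_equal(diag(tm), diag(m))

  # keep_fraction = 1 leaves the matrix unchanged
  expect_equal(threshold_rows(m, 1), m)

  # the 90% cutoff on 400 parcels: 39 off-diagonal + diagonal = 40 nonzero
  m4 <- matrix(runif(400 * 400), 400)
  m4 <- (m4 + t(m4)) / 2
  diag(m4) <- 1
  t4 <- threshold_rows(m4, 0.10)
  expect_equal(unique(rowSums(t4 != 0)), 40)
})

test_that("normalized-angle affinity hits its geometric identities", {
  rows <- rbind(
    a = c(1, 0, 0), b = c(0, 1, 0), c = c(2, 0, 0), d = c(-1, 0, 0)
  )
  aff <- normalized_angle_affinity(rows)
  expect_equal(aff$values["a", "c"], 1) # identical direction
  expect_equal(aff$values["a", "b"], 0.5) # orthogonal
  expect_equal(aff$values["a", "d"], 0) # anti-parallel
  expect_equal(diag(aff$values), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(aff$values >= 0 & aff$values <= 1))

  expect_error(normalized_angle_affinity(rbind(c(1, 1), c(0, 0))), "zero")
})

test_that("diffusion embedding matches a dense Markov-operator oracle", {
  set.seed(2)
  p <- 80
  w <- exp(-as.matrix(dist(matrix(rnorm(p * 2), p)))^2)
  diag(w) <- 1
  for (alpha in c(0, 0.5)) {
    gs <- diffusion_embedding(parcel_matrix(w, "affinity"),
      n_components = 3, alpha = alpha
    )
    # oracle: eigendecompose the (nonsymmetric) Markov operator directly
    d <- rowSums(w)
    wa <- w / outer(d^alpha, d^alpha)
    pmat <- wa / rowSums(wa)
    ep <- eigen(pmat)
    lam <- Re(ep$values)
    ord <- order(lam, decreasing = TRUE)
    expect_equal(gs$eigenvalues, lam[ord][2:4], tolerance = 1e-8)
    for (k in 1:3) {
      v_oracle <- Re(ep$vectors[, ord[k + 1]])
      v_oracle <- v_oracle / sqrt(sum(v_oracle^2))
      v_got <- gs$coords[, k] / sqrt(sum(gs$coords[, k]^2))
      expect_lt(min(
        max(abs(v_got - v_oracle)),
        max(abs(v_got + v_oracle))
      ), 1e-8)
    }
    # Markov rows sum to 1
    expect_lt(max(abs(rowSums(pmat) - 1)), 1e-12)
  }
})

test_that("ring-graph embedding recovers the circular ordering exactly", {
  p <- 64
  w <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (d in 1:3) {
      j <- ((i - 1 + d) %% p) + 1
      w[i, j] <- w[j, i] <- 1 / d
    }
  }
  diag(w) <- 1
  gs <- diffusion_embedding(parcel_matrix(w, "affinity"), n_components = 2)
  ang <- atan2(gs$coords[, 2], gs$coords[, 1])
  ord <- order(ang)
  steps <- diff(ord)
  expect_true(
    all(steps == 1 | steps == -(p - 1)) || all(steps == -1 | steps == (p - 1))
  )
})

test_that("two-block affinity separates blocks on G1; disconnection errors", {
  w <- matrix(0.02, 40, 40)
  w[1:20, 1:20] <- 0.9
  w[21:40, 21:40] <- 0.9
  diag(w) <- 1
  gs <- diffusion_embedding(parcel_matrix(w, "affinity"), n_components = 2)
  expect_true(all(sign(gs$coords[1:20, 1]) != sign(gs$coords[21:40, 1])))

  w0 <- w
  w0[1:20, 21:40] <- 0
  w0[21:40, 1:20] <- 0
  expect_error(
    diffusion_embedding(parcel_matrix(w0, "affinity")),
    "disconnected"
  )
})

test_that("embedding is invariant (up to sign) to parcel reordering", {
  set.seed(3)
  p <- 50
  w <- exp(-as.matrix(dist(matrix(rnorm(p * 2), p))))
  diag(w) <- 1
  gs <- diffusion_embedding(parcel_matrix(w, "affinity"), n_components = 2)
  perm <- sample(p)
  gs_p <- diffusion_embedding(parcel_matrix(w[perm, perm], "affinity"),
    n_components = 2
  )
  for (k in 1:2) {
    expect_gt(abs(cor(gs_p$coords[, k], gs$coords[perm, k])), 1 - 1e-8)
  }
  expect_true(all(diff(gs$eigenvalues) <= 1e-12))
  expect_lte(sum(gs$variance_explained), 1 + 1e-12)
})

test_that("gradient bins are balanced and average the source correctly", {
  set.seed(4)
  p <- 400
  grad <- rnorm(p)
  src <- matrix(rnorm(p * p), p)
  src <- (src + t(src)) / 2
  bins <- bin_gradient(grad, src, n_bins = 10)
  expect_equal(unname(tabulate(bins$assignment, 10)), rep(40, 10))
  # bins contiguous in gradient rank
  expect_true(all(diff(bins$assignment[order(grad)]) >= 0))

  # identity-like source: off-diagonal bin means 0
  bins_id <- bin_gradient(grad, diag(p), n_bins = 10)
  expect_equal(max(abs(bins_id$bin_matrix[upper.tri(bins_id$bin_matrix)])), 0)

  # planted two-block structure aligned with the gradient: hand-binned oracle
  p2 <- 40
  g2 <- seq(-1, 1, length.out = p2)
  blk <- outer(g2 > 0, g2 > 0, "==") * 1.0
  blk[blk == 0] <- -0.5
  diag(blk) <- 1
  b2 <- bin_gradient(g2, blk, n_bins = 4)
  expect_equal(b2$bin_matrix[1, 1], 1) # within lower block
  expect_equal(b2$bin_matrix[1, 4], -0.5) # across blocks
  # oracle for one cell: mean over the exact index sets
  i1 <- which(b2$assignment == 2)
  i4 <- which(b2$assignment == 3)
  expect_equal(b2$bin_matrix[2, 3], mean(blk[i1, i4]))
})

test_that("gradient alignment recovers sign flips, permutations, and nulls", {
  set.seed(5)
  a <- matrix(rnorm(200 * 3), 200)
  colnames(a) <- paste0("G", 1:3)

  flip <- a %*% diag(c(-1, 1, -1))
  colnames(flip) <- colnames(a)
  al <- align_gradients(a, flip)
  expect_equal(al$r, rep(1, 3))
  expect_equal(al$sign_flipped, c(TRUE, FALSE, TRUE))

  perm <- a[, c(2, 3, 1)]
  colnames(perm) <- paste0("G", 1:3)
  al2 <- align_gradients(a, perm)
  expect_equal(
    al2$gradient_b[match(paste0("G", 1:3), al2$gradient_a)],
    paste0("G", c(3, 1, 2))
  )

  # independent gradient sets on 400 parcels: matched |r| stays small
  hits <- vapply(1:20, function(s) {
    set.seed(400 + s)
    x <- matrix(rnorm(400 * 2), 400)
    y <- matrix(rnorm(400 * 2), 400)
    max(align_gradients(x, y)$r)
  }, numeric(1))
  expect_gt(mean(hits < 0.2), 0.9)

  expect_error(align_gradients(a, matrix(0, 10, 2)), "different parcel sets")
})

test_that("planted gradient axes are recovered from simulated cohorts", {
  geom <- make_sphere_parcellation(100, mesh_resolution = 4)
  truth <- make_ground_truth(geom, h2_mean = 0.5, weights = c(1, 0.1))
  co <- simulate_cohort(truth, 0, 0, 400, seed = 8)
  sc <- structural_covariance(residualize(co))
  gs <- covariance_gradients(sc, anchor = truth$g1_axis)
  expect_gt(abs(cor(gs$coords[, 1], truth$g1_axis)), 0.85)
  # sign convention: anchored gradient correlates positively
  expect_gt(cor(gs$coords[, 1], truth$g1_axis), 0)
})
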