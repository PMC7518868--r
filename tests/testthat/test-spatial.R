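test_that("mesh geodesics match edge lengths and great-circle distances", {
  # single triangle: distance equals edge length
  tri <- structure(
    list(
      vertices = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
      faces = rbind(c(1, 2, 3))
    ),
    class = "cortex_mesh"
  )
  d <- geodesic_distance(tri, sources = 1)
  expect_equal(d, c(0, 3, 4))

  # unit icosphere, antipodal source: max distance close to pi
  m <- icosphere(4, radius = 1)
  src <- which.max(m$vertices[, 3])
  d2 <- geodesic_distance(m, src)
  expect_lt(abs(max(d2) - pi) / pi, 0.05)
  expect_true(all(d2 >= 0))
  expect_equal(d2[src], 0)

  # source set covering everything: all distances zero
  d3 <- geodesic_distance(tri, sources = 1:3)
  expect_equal(d3, c(0, 0, 0))

  # Dijkstra reduces to breadth-first steps on a unit-weight graph
  sq <- structure(
    list(
      vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
      edges = rbind(c(1, 2), c(2, 3), c(3, 4))
    ),
    class = "cortex_mesh"
  )
  expect_equal(geodesic_distance(sq, 1), c(0, 1, 2, 3))
})

test_that("origin distance fields vanish at seeds and satisfy the triangle inequality", {
  fl <- origin_distance_fields(fix_geom)
  expect_true(all(fl$archicortex_distance > 0))
  seed_parcels <- unique(stats::na.omit(
    fix_geom$vertex_to_parcel[fix_geom$seed_points$archicortex]
  ))
  expect_lt(min(fl$archicortex_distance[seed_parcels]), min(fl$archicortex_distance) + 1e-9)

  dm <- geodesic_parcel_matrix(fix_geom)
  v <- dm$values
  expect_equal(v, t(v))
  left <- which(fix_geom$hemisphere == "L")
  expect_true(all(is.finite(v[left, left])))
  right <- which(fix_geom$hemisphere == "R")
  expect_true(all(is.na(v[left, right])))
  # triangle inequality on within-hemisphere triples
  trip <- utils::combn(left[1:5], 3)
  for (k in seq_len(ncol(trip))) {
    i <- trip[1, k]; j <- trip[2, k]; l <- trip[3, k]
    expect_lte(v[i, j], v[i, l] + v[l, j] + 1e-9)
  }
})

test_that("spin permutations are proper rotations preserving the value multiset", {
  sp <- spin_permutations(fix_geom, 25, seed = 3)
  # bijective option: every assignment is an exact permutation, so any
  # map's value multiset is preserved exactly
  spb <- spin_permutations(fix_geom, 25, seed = 3, assignment = "bijective")
  for (b in 1:25) {
    expect_setequal(spb$assignments[b, ], 1:20)
  }
  for (r in sp$rotations[1:5]) {
    expect_lt(max(abs(crossprod(r) - diag(3))), 1e-10)
    expect_equal(det(r), 1, tolerance = 1e-10)
  }
  map <- rnorm(20)
  for (b in 1:25) {
    null_map <- map[sp$assignments[b, ]]
    # resampled maps draw only from the original values
    expect_true(all(null_map %in% map))
    # left parcels stay left, right stay right
    expect_true(all(
      fix_geom$hemisphere[sp$assignments[b, ]] == fix_geom$hemisphere
    ))
  }
})

test_that("spin test is minimal on self-comparison and deterministic", {
  fl <- origin_distance_fields(fix_geom)
  a <- fl$archicortex_distance
  st <- spin_test(a, a, fix_geom, n_rotations = 99, seed = 1)
  expect_equal(st$r_observed, 1)
  expect_equal(st$p_spin, 1 / 100)

  st2 <- spin_test(a, fl$paleocortex_distance, fix_geom, n_rotations = 99, seed = 7)
  st3 <- spin_test(a, fl$paleocortex_distance, fix_geom, n_rotations = 99, seed = 7)
  expect_identical(st2$p_spin, st3$p_spin)

  expect_error(spin_test(rep(1, 20), a, fix_geom), "degenerate")
})

test_that("spin test holds its nominal size on smooth null maps", {
  geom <- make_sphere_parcellation(100, mesh_resolution = 4)
  draw <- gp_map_sampler(geom)
  spins <- spin_permutations(geom, 500, seed = 11)
  set.seed(12)
  ps <- replicate(300, spin_test(draw(), draw(), spins = spins)$p_spin)
  expect_gte(mean(ps < 0.05), 0.02)
  expect_lte(mean(ps < 0.05), 0.09)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("energy test separates shifted samples and is zero on identical ones", {
  expect_equal(energy_test(c(1, 2, 3), c(1, 2, 3), n_perm = 100)$statistic, 0)

  set.seed(13)
  et <- energy_test(rnorm(100), rnorm(100, 5), n_perm = 1000, seed = 2)
  expect_equal(et$p_value, 1 / 1001)
  expect_gt(et$statistic, 0)

  # statistic is non-negative on arbitrary inputs
  for (i in 1:10) {
    a <- rnorm(sample(3:30, 1))
    b <- rnorm(sample(3:30, 1))
    expect_gte(energy_test(a, b, n_perm = 100)$statistic, 0)
  }

  expect_warning(energy_test(1, c(1, 2), n_perm = 100), "size 1")
  expect_error(energy_test(numeric(0), 1), "nonempty")

  et_log <- energy_test(rnorm(30), rnorm(30, 3), n_perm = 200, potential = "log")
  expect_lt(et_log$p_value, 0.05)
})

test_that("energy-test p-values are uniform under the null", {
  set.seed(14)
  ps <- vapply(1:200, function(s) {
    energy_test(rnorm(40), rnorm(40), n_perm = 200, seed = s)$p_value
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.02)
  expect_lte(mean(ps < 0.05), 0.09)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("distance regression removes quadratic distance structure", {
  dm <- geodesic_parcel_matrix(fix_geom)
  d <- dm$values
  # covariance exactly quadratic in distance: residuals vanish
  v <- 2 - 0.01 * d + 1e-5 * d^2
  v[is.na(v)] <- 0.5
  diag(v) <- 0
  v <- (v + t(v)) / 2
  res <- regress_distance(parcel_matrix(v, "covariance"), dm)
  ok <- upper.tri(d) & !is.na(d)
  expect_lt(max(abs(res$values[ok])), 1e-10)
  # cross-hemisphere entries pass through unchanged
  cross <- upper.tri(d) & is.na(d)
  expect_equal(res$values[cross], v[cross])

  # random input: residuals orthogonal to the [1, d, d^2] design
  set.seed(15)
  v2 <- matrix(rnorm(400), 20)
  v2 <- (v2 + t(v2)) / 2
  diag(v2) <- 0
  res2 <- regress_distance(parcel_matrix(v2, "covariance"), dm)
  x <- cbind(1, d[ok], d[ok]^2)
  expect_lt(max(abs(crossprod(x, res2$values[ok]))), 1e-8)
})

test_that("correlation confidence intervals match the Fisher-z formula", {
  # n = 403, r = 0.5: textbook Fisher-z interval ~ (0.42, 0.57)
  set.seed(16)
  n <- 403
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n) * sqrt(0.75)
  # construct data with sample r exactly 0.5
  y <- resid(lm(y ~ x))
  y <- y / sd(y)
  x_s <- (x - mean(x)) / sd(x)
  y <- 0.5 * x_s + sqrt(0.75) * y
  ci <- correlate_with_ci(x_s, y)
  expect_equal(ci$r, 0.5, tolerance = 1e-10)
  expect_equal(ci$ci_low, tanh(atanh(0.5) - 1.959964 / sqrt(400)), tolerance = 1e-6)
  expect_equal(ci$ci_high, tanh(atanh(0.5) + 1.959964 / sqrt(400)), tolerance = 1e-6)
  expect_equal(round(c(ci$ci_low, ci$ci_high), 2), c(0.42, 0.57))

  ci_id <- correlate_with_ci(x, x)
  expect_equal(ci_id$r, 1)
  expect_true(ci_id$degenerate)
  expect_equal(correlate_with_ci(x, -x)$r, -1)

  ci_sp <- correlate_with_ci(x, y, method = "spearman")
  expect_true(ci_sp$ci_low < ci_sp$r && ci_sp$r < ci_sp$ci_high)
  expect_error(correlate_with_ci(x, rep(1, n)), "zero-variance")
})

test_that("dual-origin analysis recovers a gradient aligned with paleocortex distance", {
  geom <- make_sphere_parcellation(60, mesh_resolution = 4)
  fl <- origin_distance_fields(geom)

  # gradient equal to the paleocortex distance: perfect linear relation
  rep1 <- dual_origin_association(fl$paleocortex_distance, fl, geom,
    n_rotations = 199, seed = 4
  )
  paleo <- rep1[rep1$origin == "paleocortex", ]
  expect_equal(paleo$r, 1)
  expect_equal(paleo$p_spin, 1 / 200)
  expect_lt(paleo$p_energy, 0.05)

  # the planted inferior-superior axis tracks paleocortex distance
  r_axis <- cor(geom$centroid[, 3], fl$paleocortex_distance)
  expect_gt(abs(r_axis), 0.6)

  # gradient independent of the fields: spin p not extreme
  draw <- gp_map_sampler(geom)
  set.seed(17)
  ps <- replicate(30, {
    dual_origin_association(draw(), fl, geom,
      n_rotations = 99, seed = 5
    )$p_spin[1]
  })
  expect_gt(mean(ps > 0.05), 0.6)
})
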