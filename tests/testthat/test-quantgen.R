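test_that("inverse normal transform maps ranks to Blom quantiles", {
  # n = 3 distinct values: closed-form Blom plotting positions
  got <- inverse_normal_transform(c(10, -5, 2))
  expected <- qnorm((c(3, 1, 2) - 3 / 8) / (3 + 1 / 4))
  expect_equal(got, expected)

  set.seed(1)
  x <- rnorm(1000)
  y <- inverse_normal_transform(x)
  expect_gt(cor(x, y), 0.99) # monotone, near-identity on normal data
  expect_lt(abs(mean(y)), 0.01)
  expect_lt(abs(sd(y) - 1), 0.02)
  expect_identical(order(x), order(y))

  expect_error(inverse_normal_transform(c(1, 1, 1)), "equal")
  expect_error(inverse_normal_transform(c(1, NA, NA)), "non-missing")
})

test_that("univariate AE fit recovers null, intermediate, and perfect h2", {
  # pure noise: h2 estimated near zero
  set.seed(2)
  ped <- simulate_cohort(toy_truth(), 500, 500, 0, seed = 2)$pheno
  y0 <- rnorm(2000)
  f0 <- fit_univariate_ae(y0, ped)
  expect_lt(f0$h2, 0.05)

  # planted h2 = 0.5: ML within 2 SE of the Falconer estimate
  co <- simulate_cohort(toy_truth(), 250, 250, 0, seed = 3)
  y <- inverse_normal_transform(thickness_matrix(co)[, 1])
  f <- fit_univariate_ae(y, co$pheno)
  expect_lt(abs(f$h2 - 0.5), 0.1)
  mz1 <- which(co$pheno$zygosity == "MZ")[c(TRUE, FALSE)]
  dz1 <- which(co$pheno$zygosity == "DZ")[c(TRUE, FALSE)]
  falconer <- 2 * (cor(y[mz1], y[mz1 + 1]) - cor(y[dz1], y[dz1 + 1]))
  se_falconer <- 2 * sqrt(1 / 250 + 1 / 250)
  expect_lt(abs(f$h2 - falconer), 2 * se_falconer)

  # MZ-duplicate trait: boundary h2 = 1
  y1 <- rnorm(2000)
  mz2 <- which(ped$zygosity == "MZ")[c(FALSE, TRUE)]
  y1[mz2] <- y1[mz2 - 1]
  dz <- which(ped$zygosity == "DZ")
  dz1 <- dz[c(TRUE, FALSE)]
  y1[dz1 + 1] <- 0.5 * y1[dz1] + sqrt(0.75) * y1[dz1 + 1]
  f1 <- fit_univariate_ae(y1, ped)
  expect_gt(f1$h2, 0.95)

  expect_error(
    fit_univariate_ae(rnorm(4), tibble::tibble(
      family_id = paste0("F", 1:4), zygosity = rep("singleton", 4)
    )),
    "no twin pairs"
  )
})

test_that("h2 estimates are unbiased across planted levels", {
  for (h2_true in c(0.2, 0.8)) {
    errs <- vapply(1:6, function(s) {
      co <- simulate_cohort(toy_truth(h2 = c(h2_true, h2_true)), 250, 250, 0,
        seed = 100 + s
      )
      y <- inverse_normal_transform(thickness_matrix(co)[, 1])
      fit_univariate_ae(y, co$pheno)$h2 - h2_true
    }, numeric(1))
    expect_lt(abs(mean(errs)), 0.08)
  }
})

test_that("estimates are invariant to family order and affine rescaling", {
  co <- simulate_cohort(toy_truth(), 150, 150, 30, seed = 9)
  y <- thickness_matrix(co)[, 1]
  f <- fit_univariate_ae(y, co$pheno)
  # shuffle whole families
  ord <- unlist(split(seq_len(630), co$pheno$family_id)[sample(330)])
  f_perm <- fit_univariate_ae(y[ord], co$pheno[ord, ])
  expect_equal(f_perm$h2, f$h2, tolerance = 1e-6)
  f_scaled <- fit_univariate_ae(100 * y - 42, co$pheno)
  expect_equal(f_scaled$h2, f$h2, tolerance = 1e-6)

  fb <- fit_bivariate_ae(y, thickness_matrix(co)[, 2], co$pheno, compute_lrt = FALSE)
  fb_s <- fit_bivariate_ae(-3 * y + 1, 0.1 * thickness_matrix(co)[, 2],
    co$pheno,
    compute_lrt = FALSE
  )
  expect_equal(abs(fb_s$rho_g), abs(fb$rho_g), tolerance = 1e-4)
  expect_equal(fb_s$h2_i, fb$h2_i, tolerance = 1e-4)
})

test_that("bivariate fit handles the identity pair and recovers planted rho_g", {
  co <- simulate_cohort(toy_truth(), 200, 200, 0, seed = 4)
  y <- thickness_matrix(co)
  f_id <- fit_bivariate_ae(y[, 1], y[, 1], co$pheno, compute_lrt = FALSE)
  expect_gte(f_id$rho_g, 0.99)
  expect_gte(f_id$rho_e, 0.99)
  expect_gte(f_id$rho_p, 0.99)

  # planted rho_g = 0.6, rho_e = 0.2, h2 = 0.5/0.5 at 300+300 families
  hits <- 0L
  for (s in 1:3) {
    co2 <- simulate_cohort(toy_truth(), 300, 300, 0, seed = 200 + s)
    yi <- inverse_normal_transform(thickness_matrix(co2)[, 1])
    yj <- inverse_normal_transform(thickness_matrix(co2)[, 2])
    fb <- fit_bivariate_ae(yi, yj, co2$pheno)
    hits <- hits + (abs(fb$rho_g - 0.6) < 0.15)
    # reconstruction identity at the optimum
    rec <- fb$rho_g * sqrt(fb$h2_i * fb$h2_j) +
      fb$rho_e * sqrt((1 - fb$h2_i) * (1 - fb$h2_j))
    expect_lt(abs(rec - fb$rho_p), 1e-6)
    # LRT statistics are non-negative by construction
    expect_true(fb$p_rho_g >= 0 && fb$p_rho_g <= 1)
    expect_true(fb$p_rho_e >= 0 && fb$p_rho_e <= 1)
  }
  expect_gte(hits, 2)
})

test_that("LRT p-values for rho_g are roughly uniform for independent traits", {
  # independent traits with h2 = 0.5 each: null genetic correlation
  ps <- vapply(1:40, function(s) {
    co <- simulate_cohort(toy_truth(rho_g = 0, rho_e = 0), 120, 120, 0,
      seed = 300 + s
    )
    y <- thickness_matrix(co)
    fit_bivariate_ae(y[, 1], y[, 2], co$pheno, multi_start = FALSE)$p_rho_g
  }, numeric(1))
  # boundary-free null: coarse uniformity (KS at alpha = 0.01)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("phenotypic decomposition follows the path formulas exactly", {
  d <- decompose_phenotypic(1, 1, 0.5, 0.9)
  expect_equal(d$rho_p, 0.5)
  expect_equal(d$prop_genetic, 1)

  d2 <- decompose_phenotypic(0.5, 0.5, 0.6, 0.2)
  expect_equal(d2$rho_ph_g, 0.3)
  expect_equal(d2$rho_ph_e, 0.1)
  expect_equal(d2$rho_p, 0.4)
  expect_equal(d2$prop_genetic, 0.75)

  # random valid inputs: decomposition matches the bivariate fit's rho_p
  set.seed(5)
  for (i in 1:20) {
    h2i <- runif(1)
    h2j <- runif(1)
    rg <- runif(1, -1, 1)
    re <- runif(1, -1, 1)
    d3 <- decompose_phenotypic(h2i, h2j, rg, re)
    expect_lt(
      abs(d3$rho_p - (rg * sqrt(h2i * h2j) + re * sqrt((1 - h2i) * (1 - h2j)))),
      1e-12
    )
  }
  expect_true(is.na(decompose_phenotypic(0.5, 0.5, 0, 0)$prop_genetic))
})

test_that("pairwise matrix assembly is symmetric, unit-diagonal, order-invariant", {
  co <- simulate_cohort(fix_truth, 80, 80, 0, seed = 6)
  y <- apply(thickness_matrix(co)[, 1:3], 2, inverse_normal_transform)
  ae <- genetic_correlation_matrix(y, co$pheno)
  expect_equal(diag(ae$rho_g$values), rep(1, 3), ignore_attr = TRUE)
  expect_equal(ae$rho_g$values, t(ae$rho_g$values))

  # permuting parcel order permutes the result consistently
  perm <- c(3, 1, 2)
  ae2 <- genetic_correlation_matrix(y[, perm], co$pheno)
  expect_equal(ae2$rho_g$values[c(2, 3, 1), c(2, 3, 1)], ae$rho_g$values,
    ignore_attr = TRUE, tolerance = 1e-4
  )

  tt <- tidy(ae)
  expect_equal(nrow(tt), 3)
  expect_true(all(c("rho_g", "rho_ph_g", "prop_genetic") %in% names(tt)))
  expect_equal(nrow(glance(ae)), 1)
})

test_that("malformed pedigrees are rejected", {
  ped <- tibble::tibble(
    subject_id = paste0("S", 1:5),
    family_id = c("F1", "F1", "F1", "F2", "F2"),
    zygosity = c("MZ", "MZ", "MZ", "DZ", "DZ")
  )
  expect_error(fit_univariate_ae(rnorm(5), ped), "exactly 2 members")
})
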