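# Shared small fixtures, built once per test run.

fix_geom <- make_sphere_parcellation(20, mesh_resolution = 3)
fix_truth <- make_ground_truth(fix_geom, h2_mean = 0.5)

# two-trait ground truth with planted genetic/environmental correlations
toy_truth <- function(rho_g = 0.6, rho_e = 0.2, h2 = c(0.5, 0.5)) {
  dg <- sqrt(h2)
  de <- sqrt(1 - h2)
  structure(
    list(
      sigma_g = matrix(c(1, rho_g, rho_g, 1), 2) * tcrossprod(dg),
      sigma_e = matrix(c(1, rho_e, rho_e, 1), 2) * tcrossprod(de),
      h2_true = h2,
      rho_g_true = matrix(c(1, rho_g, rho_g, 1), 2),
      rho_e_true = matrix(c(1, rho_e, rho_e, 1), 2),
      g1_axis = c(-1, 1), g2_axis = c(0, 0),
      betas = c(age = 0, sex = 0)
    ),
    class = "ground_truth"
  )
}

# smooth spatially autocorrelated null maps on a parcellation
gp_map_sampler <- function(geom, ell = 0.5) {
  k <- exp(-as.matrix(stats::dist(geom$centroid))^2 / (2 * ell^2))
  ch <- chol(k + 1e-8 * diag(nrow(k)))
  function() as.numeric(crossprod(ch, stats::rnorm(nrow(k))))
}
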