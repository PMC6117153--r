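# Estimation chain: per-direction D*, tensor fit, eigensystem, FA/MD,
# masking, smoothing, ellipsoids, and whole-volume properties.

test_that("estimate_dstar inverts the forward model", {
  expect_identical(estimate_dstar(5, 5, 107), 0)
  expect_equal(estimate_dstar(0.4988, 1, 107), 0.0065, tolerance = 1e-3)
  expect_error(estimate_dstar(1, 1, 0), "positive")
  expect_true(is.na(estimate_dstar(-1, 1, 107)))
  # monotone: smaller S -> larger D*
  s <- seq(0.9, 0.1, by = -0.1)
  expect_true(all(diff(estimate_dstar(s, 1, 107)) > 0))
  # S > S0 gives a (permitted) negative value rather than NA
  expect_lt(estimate_dstar(1.1, 1, 107), 0)
})

test_that("forward/inverse round trip is exact to 1e-12", {
  withr::with_seed(31, {
    for (k in 1:50) {
      D <- random_psd_tensor()
      g <- random_unit_vec()
      b <- runif(1, 10, 300)
      S0 <- runif(1, 0.5, 200)
      truth <- as.numeric(t(g) %*% D %*% g)
      est <- estimate_dstar(dwi_signal(S0, b, g, D), S0, b)
      expect_equal(est, truth, tolerance = 1e-12)
    }
  })
})

test_that("fit_tensor recovers noiseless tensors exactly", {
  g6 <- default_directions()
  withr::with_seed(41, {
    for (k in 1:20) {
      D <- random_psd_tensor()
      s <- apply(g6, 1, function(gi) dwi_signal(1, 107, gi, D))
      Dhat <- fit_tensor(s, 1, g6, b = 107)
      expect_lt(max(abs(Dhat - D)) / max(abs(D)), 1e-10)
    }
  })
  # isotropic signals with an isotropic-capable design give d * I
  d <- 4e-3
  s <- rep(exp(-107 * d), 6)
  expect_equal(fit_tensor(s, 1, g6, b = 107), diag(d, 3),
               tolerance = 1e-10)
})

test_that("fit_tensor rejects deficient designs and bad signals", {
  # coplanar directions: rank < 6
  gbad <- rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0) / sqrt(2),
                c(-1, 1, 0) / sqrt(2), c(0.6, 0.8, 0), c(0.8, 0.6, 0))
  expect_error(fit_tensor(rep(0.5, 6), 1, gbad, b = 107),
               "rank-deficient")
  expect_error(fit_tensor(rep(0.5, 5), 1, default_directions()[1:5, ],
                          b = 107), "at least 6")
  expect_error(fit_tensor(c(rep(0.5, 5), -1), 1, default_directions(),
                          b = 107), "> 0")
  # externally supplied full b-matrices are honoured
  D <- tensor_from_fa_md(0.5, 3e-3, c(0, 1, 0))
  g6 <- default_directions()
  bm <- build_bmatrix(rep(107, 6), g6)
  s <- apply(g6, 1, function(gi) dwi_signal(1, 107, gi, D))
  expect_equal(fit_tensor(s, 1, bm), D, tolerance = 1e-10)
})

test_that("eig_sorted orders, orients and signs the eigensystem", {
  es <- eig_sorted(diag(c(3, 2, 1)))
  expect_equal(es$values, c(3, 2, 1))
  expect_equal(abs(es$vectors), diag(3), tolerance = 1e-12)
  # identity tensor: any orthonormal triad
  ei <- eig_sorted(diag(3))
  expect_equal(ei$values, rep(1, 3))
  expect_equal(crossprod(ei$vectors), diag(3), tolerance = 1e-12)

  withr::with_seed(51, {
    for (k in 1:10) {
      R <- random_rotation()
      es <- eig_sorted(R %*% diag(c(3, 2, 1)) %*% t(R))
      expect_equal(es$values, c(3, 2, 1), tolerance = 1e-10)
      for (j in 1:3) {
        expect_lt(axis_angle_deg(es$vectors[, j], R[, j]), 1e-5)
        nz <- which(abs(es$vectors[, j]) > 1e-12)[1]
        if (j < 3) expect_gte(es$vectors[nz, j], 0)
      }
      expect_equal(det(es$vectors), 1, tolerance = 1e-10)
    }
  })
  expect_error(eig_sorted(matrix(1:9, 3, 3)), "symmetric")
})

test_that("fractional anisotropy and mean diffusivity match closed forms", {
  expect_equal(fractional_anisotropy(2e-3, 1e-3, 1e-3), 0.408,
               tolerance = 1e-3)
  expect_equal(fractional_anisotropy(5e-3, 5e-3, 5e-3), 0)
  expect_equal(fractional_anisotropy(5e-3, 0, 0), 1)
  expect_true(is.na(fractional_anisotropy(0, 0, 0)))
  expect_equal(mean_diffusivity(2e-3, 1e-3, 1e-3), 4e-3 / 3)
  expect_equal(mean_diffusivity(c(7e-4, 7e-4, 7e-4)), 7e-4)
  withr::with_seed(61, {
    D <- random_psd_tensor()
    R <- random_rotation()
    expect_equal(mean_diffusivity(eig_sorted(R %*% D %*% t(R))$values),
                 mean_diffusivity(eig_sorted(D)$values),
                 tolerance = 1e-12)
  })
})

test_that("threshold_mask isolates the fluid compartments", {
  sim <- noiseless_sim()
  gt <- default_truth()
  b0 <- sim$dwi$data[, , 1, 1]
  mask <- threshold_mask(b0)
  fluid <- gt$label_map %in% gt$labels[c("subarachnoid", "pvs",
                                         "ventricle")]
  expect_identical(as.vector(mask), as.vector(fluid))
  # otsu lands in the same gap for this bimodal image
  expect_identical(threshold_mask(b0, method = "otsu"), mask)
  expect_warning(m0 <- threshold_mask(matrix(0, 4, 4)), "constant")
  expect_false(any(m0))
  expect_true(all(threshold_mask(matrix(1:4, 2, 2), cutoff = 0)))
})

test_that("smooth_edge_preserving is a masked median filter", {
  m <- matrix(5, 7, 7)
  expect_identical(smooth_edge_preserving(m, 0), m)
  expect_identical(smooth_edge_preserving(m, 1), m)
  out <- m; out[4, 4] <- 50
  expect_identical(smooth_edge_preserving(out, 1), m)
  # an edge between two in-mask regions is preserved when the mask
  # separates them
  m2 <- matrix(rep(c(1, 10), each = 21), 6, 7)
  mask <- matrix(rep(c(TRUE, FALSE), each = 21), 6, 7)
  sm <- smooth_edge_preserving(m2, 1, mask)
  expect_identical(sm, m2)
  expect_error(smooth_edge_preserving(m, -1), "radius")
})

test_that("fit_dti recovers the noiseless phantom maps exactly", {
  sim <- noiseless_sim()
  gt <- default_truth()
  fit <- fit_dti(sim$dwi)
  pvs <- label_mask(gt, "pvs"); sa <- label_mask(gt, "subarachnoid")
  expect_equal(roi_mean(fit$fa_map, pvs), 0.44, tolerance = 1e-8)
  expect_equal(roi_mean(fit$md_map, pvs), 0.0042, tolerance = 1e-10)
  expect_equal(roi_mean(fit$fa_map, sa), 0.60, tolerance = 1e-8)
  expect_equal(roi_mean(fit$md_map, sa), 0.0065, tolerance = 1e-10)
  expect_true(all(fit$valid_mask[pvs]))
  expect_lt(max(fit$residual[pvs]), 1e-10)
  # ellipsoid long axis parallel to the tract tangent
  ell <- tensor_ellipsoids(fit)
  idx <- which(pvs, arr.ind = TRUE)
  k <- which(ell$i == idx[1, 1] - 1 & ell$j == idx[1, 2] - 1)
  v1 <- fit$eigenvectors[idx[1, 1], idx[1, 2], , 1]
  expect_lt(axis_angle_deg(v1, gt$tangent_map[idx[1, 1], idx[1, 2], ]),
            1e-4)
  # semi-axis ratios preserve eigenvalue ratios; quaternion is unit
  expect_equal(ell$a1[k] / ell$a2[k],
               fit$eigenvalues[idx[1, 1], idx[1, 2], 1] /
                 fit$eigenvalues[idx[1, 1], idx[1, 2], 2],
               tolerance = 1e-8)
  expect_equal(ell$qw^2 + ell$qx^2 + ell$qy^2 + ell$qz^2,
               rep(1, nrow(ell)), tolerance = 1e-8)
})

test_that("isotropic voxels yield spherical ellipsoid glyphs", {
  sim <- noiseless_sim()
  gt <- default_truth()
  fit <- fit_dti(sim$dwi)
  vent <- which(label_mask(gt, "ventricle"), arr.ind = TRUE)
  l <- fit$eigenvalues[vent[1, 1], vent[1, 2], ]
  expect_equal(l, rep(0.003, 3), tolerance = 1e-8)
})

test_that("the fitting chain is equivariant under 90-degree rotation", {
  sim <- noiseless_sim()
  dwi <- sim$dwi
  # rotate the image and the gradient table by +90 degrees in plane
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE]
  unrot90 <- function(m) t(m[, ncol(m):1, drop = FALSE])
  nvol <- dim(dwi$data)[4]
  nx <- dim(dwi$data)[1]; ny <- dim(dwi$data)[2]
  rdata <- array(0, c(ny, nx, 1, nvol))
  for (v in seq_len(nvol)) rdata[, , 1, v] <- rot90(dwi$data[, , 1, v])
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  rvecs <- t(R %*% t(dwi$bvecs))
  rdwi <- dwi_volume(rdata, dwi$bvals, rvecs, dwi$voxel_size_mm)
  f0 <- fit_dti(dwi)
  f1 <- fit_dti(rdwi)
  fa_back <- unrot90(f1$fa_map)
  md_back <- unrot90(f1$md_map)
  ok <- !is.na(f0$fa_map) & !is.na(fa_back)
  expect_gt(sum(ok), 500)
  expect_lt(max(abs(f0$fa_map[ok] - fa_back[ok])), 1e-6)
  expect_lt(max(abs(f0$md_map[ok] - md_back[ok])), 1e-6)
})

test_that("fit_dti flags non-positive-definite fits instead of failing", {
  # heavy noise at tiny b produces some non-PSD voxels
  spec <- phantom_spec(noise_sigma = 3, seed = 9, matrix = c(48L, 48L))
  sim <- simulate_phantom(spec, acq_params())
  fit <- fit_dti(sim$dwi, mask = sim$dwi$data[, , 1, 1] > 0)
  expect_true(any(!fit$valid_mask[fit$mask]))
  inmask <- fit$mask & !is.na(fit$fa_map)
  expect_true(all(fit$fa_map[inmask] >= 0 & fit$fa_map[inmask] <= 1))
})

test_that("dstar_maps produces one map per direction", {
  sim <- noiseless_sim()
  gt <- default_truth()
  dm <- dstar_maps(sim$dwi)
  expect_equal(dim(dm$dstar)[3], 6)
  # isotropic ventricle: every direction sees the same D*
  vent <- label_mask(gt, "ventricle")
  for (k in 1:6) {
    expect_equal(roi_mean(dm$dstar[, , k], vent), 0.003,
                 tolerance = 1e-8)
  }
})
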