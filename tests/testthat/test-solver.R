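# Finite-volume assembly and conjugate-gradient solve, validated against
# closed-form solutions.

test_that("homogeneous cube reproduces the series-resistance solution exactly", {
  toy <- toy_phantom("uniform_cube", sigma = 1, I = 1e-4, size_mm = 10,
                     voxel_um = 1000)
  sys <- assemble_system(toy$phantom, toy$montage, toy$placement)
  # operator is symmetric with zero row sums (pure divergence form)
  expect_lt(max(abs(sys$A - Matrix::t(sys$A))), 1e-15)
  expect_lt(max(abs(Matrix::rowSums(sys$A))), 1e-15)
  expect_equal(sum(sys$b), 0)
  sol <- solve_montage(toy$phantom, toy$montage, toy$placement, tol = 1e-12)
  # linear potential: |E| = I/(sigma A), |J| = I/A in every voxel
  expect_equal(max(abs(sol$fields$magJ - toy$expected$magJ_A_per_m2)), 0,
               tolerance = 1e-8)
  expect_equal(max(abs(sol$fields$magE - toy$expected$magE_V_per_m)), 0,
               tolerance = 1e-8)
  # end-to-end drop, extrapolated half a voxel to the physical faces
  prof <- apply(sol$potential$phi, 1, mean)
  h_m <- toy$phantom$voxel_size_um * 1e-6
  A_m2 <- (10e-3)^2
  drop <- (prof[1] - prof[length(prof)]) + h_m * 1e-4 / (1 * A_m2)
  expect_equal(drop, toy$expected$face_drop_V, tolerance = 1e-10)
})

test_that("two-layer slab matches the series-resistance closed form to 1e-8", {
  toy <- toy_phantom("layered_slab", sigma = c(1, 0.5), I = 1e-4,
                     t_mm = c(1, 1), area_mm2 = 1, voxel_um = 250)
  sys <- assemble_system(toy$phantom, toy$montage, toy$placement)
  # face conductance across the interface is the harmonic mean 2*s1*s2/(s1+s2)
  uid <- array(0L, sys$dims)
  uid[sys$domain_index] <- seq_along(sys$domain_index)
  n1 <- toy$expected$n_layer1
  i1 <- uid[n1, 1, 1]; i2 <- uid[n1 + 1, 1, 1]
  h_m <- 250e-6
  expect_equal(-sys$A[i1, i2], 2 * 1 * 0.5 / (1 + 0.5) * h_m,
               tolerance = 1e-12)
  sol <- solve_montage(toy$phantom, toy$montage, toy$placement, tol = 1e-12)
  prof <- apply(sol$potential$phi, 1, mean)
  A_m2 <- 1e-6; I <- 1e-4
  n2 <- toy$expected$n_layer2
  d1 <- prof[1] - prof[n1] + h_m * I / (1 * A_m2)
  d2 <- prof[n1 + 1] - prof[n1 + n2] + h_m * I / (0.5 * A_m2)
  expect_equal(d1, toy$expected$layer_drops_V[1], tolerance = 1e-8)
  expect_equal(d2, toy$expected$layer_drops_V[2], tolerance = 1e-8)
  # |J| = I/A away from the interface voxels (central differences straddle
  # the conductivity kink there)
  interior <- sol$fields$magJ[c(2:(n1 - 1), (n1 + 2):(n1 + n2 - 1)), , ]
  expect_equal(max(abs(interior - toy$expected$magJ_A_per_m2)), 0,
               tolerance = 1e-6)
})

test_that("zero injection gives zero potential and the solve is linear in I", {
  toy <- toy_phantom("uniform_cube", voxel_um = 1000)
  sys <- assemble_system(toy$phantom, toy$montage, toy$placement)
  sys$b[] <- 0
  pot0 <- solve_potential(sys, tol = 1e-10)
  expect_true(all(pot0$phi[!is.na(pot0$phi)] == 0))
  sol1 <- solve_montage(toy$phantom, toy$montage, toy$placement, tol = 1e-12)
  toy2 <- toy_phantom("uniform_cube", I = 2e-4, voxel_um = 1000)
  sol2 <- solve_montage(toy2$phantom, toy2$montage, toy2$placement,
                        tol = 1e-12)
  scale <- max(abs(sol1$potential$phi), na.rm = TRUE)
  expect_lt(max(abs(sol2$potential$phi - 2 * sol1$potential$phi),
                na.rm = TRUE), 1e-8 * scale)
})

test_that("point source in a grounded box follows the monopole law within 5%", {
  toy <- toy_phantom("point_source_box", sigma = 0.3, I = 1e-4,
                     voxel_um = 100, box_dims = c(61, 61, 61))
  sol <- solve_montage(toy$phantom, toy$montage, toy$placement, tol = 1e-10)
  phi <- sol$potential$phi
  src <- toy$expected$source_voxel
  h <- 1e-4
  r <- 5:15 # five voxels out to a quarter of the domain
  comp <- vapply(r, function(rr) phi[src[1] - rr, src[2], src[3]], 0)
  ana <- analytic_point_source(0.3, 1e-4, r * h)
  # radial potential drops relative to the outermost sampled radius
  cd <- comp - comp[length(comp)]
  ad <- ana - ana[length(ana)]
  expect_lt(max(abs(cd[-length(r)] - ad[-length(r)]) / ad[-length(r)]), 0.05)
})

test_that("discrete current is conserved and divergence-free", {
  toy <- toy_phantom("layered_slab", voxel_um = 250)
  sys <- assemble_system(toy$phantom, toy$montage, toy$placement)
  pot <- solve_potential(sys, tol = 1e-12)
  d <- sys$dims
  # surfaces separating source from sink at several cut planes
  for (cut in c(2, 4, 6)) {
    enc <- which(slice.index(array(0L, d), 1) <= cut)
    expect_equal(enclosed_current(sys, pot, enc), 1e-4, tolerance = 1e-6)
  }
  res <- divergence_residual(sys, pot)
  electrode_u <- unlist(lapply(sys$placement$electrodes, function(e) {
    uid <- array(0L, d); uid[sys$domain_index] <- seq_along(sys$domain_index)
    uid[e$voxels]
  }))
  interior <- setdiff(seq_along(res), c(electrode_u, sys$gauge))
  expect_lt(max(abs(res[interior])), 1e-10 * 1e-4)
})

test_that("symmetric phantom and montage give a mirror-symmetric field", {
  sol <- coarse_solution()
  magE <- sol$fields$magE
  expect_lt(max(abs(magE - mirror_ml(magE))) / max(magE), 1e-6)
})

test_that("hippocampal field is stable under grid refinement", {
  ph200 <- build_phantom(phantom_spec(voxel_size_um = 200))
  s200 <- solve_montage(ph200, bilateral_montage())
  ph100 <- build_phantom(phantom_spec(voxel_size_um = 100))
  s100 <- solve_montage(ph100, bilateral_montage())
  m200 <- mean(s200$fields$magE[ph200$labels == 6])
  m100 <- mean(s100$fields$magE[ph100$labels == 6])
  expect_lt(abs(m100 - m200) / m100, 0.10)
})

test_that("quasi-static ratio follows its closed form and is linear in f", {
  tab <- data.frame(label_id = 1L, name = "x", sigma_S_per_m = 1,
                    eps_r = 80, frequency_Hz = 40)
  r40 <- check_quasistatic(tab, 40)
  expect_equal(r40$ratio, 2 * pi * 40 * 8.854e-12 * 80, tolerance = 1e-12)
  expect_equal(r40$ratio, 1.78e-7, tolerance = 1e-2)
  expect_false(r40$flagged)
  expect_equal(check_quasistatic(tab, 0)$ratio, 0)
  expect_equal(check_quasistatic(tab, 80)$ratio, 2 * r40$ratio)
})

test_that("analytic point-source potential obeys its scaling laws", {
  expect_equal(analytic_point_source(0.3, 1e-4, 1e-3), 2.653e-2,
               tolerance = 1e-3)
  expect_equal(analytic_point_source(1, 1, 2), analytic_point_source(1, 1, 1) / 2)
  expect_equal(analytic_point_source(2, 2e-4, 0.01),
               analytic_point_source(1, 1e-4, 0.01))
  expect_error(analytic_point_source(1, 1, 0), "> 0")
})

test_that("non-convergence raises a diagnostic error with residual history", {
  toy <- toy_phantom("uniform_cube", voxel_um = 1000)
  sys <- assemble_system(toy$phantom, toy$montage, toy$placement)
  err <- tryCatch(solve_potential(sys, tol = 1e-14, maxiter = 3),
                  error = function(e) e)
  expect_s3_class(err, "iacsim_nonconvergence")
})
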