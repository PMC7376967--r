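# Phantom construction: geometry, shells, coordinates, electrode placement.

test_that("default spec reproduces the reference grid with all tissue classes", {
  ph <- build_phantom(phantom_spec(voxel_size_um = 100))
  expect_identical(dim(ph$labels), c(189L, 236L, 152L))
  expect_setequal(sort(unique(ph$labels[ph$labels > 0])), 1:7)
  # electrode disc voxel count matches the brute-force half-open
  # rasterization rule at the reference resolution (r = 7.5 voxels)
  pl <- place_montage(ph, bilateral_montage())
  expected <- brute_disc_count(7.5)
  for (e in pl$electrodes) expect_equal(length(e$voxels), expected)
  # arithmetic of the stereotaxic map at 100 um
  expect_identical(stereotaxic_to_voxel(ph, 0, 0, 0), ph$bregma_voxel)
  expect_identical(stereotaxic_to_voxel(ph, -2, 4, 0),
                   as.integer(ph$bregma_voxel + c(-20, 40, 0)))
  left <- stereotaxic_to_voxel(ph, -2, -4, 0)
  right <- stereotaxic_to_voxel(ph, -2, 4, 0)
  expect_equal(right[1], left[1])
  expect_equal(right[2] - ph$bregma_voxel[2], ph$bregma_voxel[2] - left[2])
  expect_error(stereotaxic_to_voxel(ph, 1000, 0, 0), "outside the grid")
})

test_that("zero-size ventricles produce a phantom without ventricle or SVZ labels", {
  ph <- build_phantom(coarse_spec(ventricle_semiaxes_mm = c(0, 0, 0)))
  lab <- phantom_labels()
  present <- unique(ph$labels[ph$labels > 0])
  expect_false(lab[["ventricle"]] %in% present)
  expect_false(lab[["svz"]] %in% present)
  expect_true(all(lab[c("dura", "csf", "gray", "white", "hippocampus")]
                  %in% present))
})

test_that("SVZ shell matches a brute-force 6-adjacency scan", {
  ph <- coarse_phantom()
  expect_identical(sum(ph$labels == phantom_labels()[["svz"]]),
                   brute_svz_count(ph))
})

test_that("structure collisions and undersized grids are rejected", {
  expect_error(build_phantom(coarse_spec(
    hippocampus_center_mm = c(1.5, 1.2, 1.1))),
    "ventricle intersects hippocampus")
  expect_error(build_phantom(phantom_spec(voxel_size_um = 400,
                                          grid_shape = c(20, 20, 12))),
               "grid too small")
})

test_that("effective shell conductivity preserves sheet conductance", {
  expect_equal(effective_shell_conductivity(1.79, 43, 100), 0.7697)
  expect_equal(effective_shell_conductivity(2, 100, 100), 2)
  expect_equal(effective_shell_conductivity(2, 50, 100), 1)
  expect_error(effective_shell_conductivity(1, 150, 100), "exceeds")
})

test_that("add_shell grows the right number of covering layers and nothing else", {
  # small synthetic blob at 100 um voxels
  labels <- array(0L, c(21, 21, 21))
  labels[8:14, 8:14, 8:14] <- 3L
  props <- rbind(default_tissue_table(),
                 data.frame(label_id = 9L, name = "test_shell",
                            sigma_S_per_m = 1, eps_r = 10, frequency_Hz = 40))
  ph <- structure(list(labels = labels, voxel_size_um = 100,
                       bregma_voxel = c(11L, 11L, 11L), properties = props,
                       spec = NULL, provenance = "test"),
                  class = "voxel_phantom")
  before <- ph$labels
  sh <- add_shell(ph, 300, 9L) # 3 layers
  # interior labels untouched
  expect_identical(sh$labels[before > 0], before[before > 0])
  # a 7-cube dilated 3x along each axis spans 13 voxels
  expect_identical(range(which(apply(sh$labels > 0, 1, any))), c(5L, 17L))
  # every former surface voxel has a shell-label 6-neighbor
  lab9 <- sh$labels == 9L
  surf <- which(before == 3L, arr.ind = TRUE)
  surf <- surf[surf[, 1] %in% c(8, 14) | surf[, 2] %in% c(8, 14) |
                 surf[, 3] %in% c(8, 14), , drop = FALSE]
  for (r in seq_len(nrow(surf))) {
    v <- surf[r, ]
    nb <- c(lab9[v[1] + 1, v[2], v[3]], lab9[v[1] - 1, v[2], v[3]],
            lab9[v[1], v[2] + 1, v[3]], lab9[v[1], v[2] - 1, v[3]],
            lab9[v[1], v[2], v[3] + 1], lab9[v[1], v[2], v[3] - 1])
    expect_true(any(nb))
  }
  # unregistered label rejected; overflow past the grid edge rejected
  expect_error(add_shell(ph, 300, 12L), "not registered")
  expect_error(add_shell(ph, 1200, 9L), "exceeds grid bounds")
})

test_that("a symmetric spec yields a mirror-symmetric phantom and placement", {
  ph <- coarse_phantom()
  expect_identical(ph$labels, mirror_ml(ph$labels))
  pl <- place_montage(ph, bilateral_montage())
  d <- dim(ph$labels)
  mirror_lin <- function(v) {
    idx <- arrayInd(v, d)
    idx[, 2] <- d[2] + 1L - idx[, 2]
    sort(idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2])
  }
  expect_identical(mirror_lin(pl$electrodes[[1]]$voxels),
                   sort(pl$electrodes[[2]]$voxels))
})

test_that("phantom construction is deterministic", {
  expect_identical(build_phantom(coarse_spec())$labels,
                   coarse_phantom()$labels)
})

test_that("electrode placement constraints are enforced", {
  ph <- coarse_phantom()
  # all contact voxels are dura and none touches parenchyma
  pl <- place_montage(ph, bilateral_montage())
  lab <- phantom_labels()
  for (e in pl$electrodes)
    expect_true(all(ph$labels[e$voxels] == lab[["dura"]]))
  # a contact of one voxel size rasterizes to a single voxel
  m1 <- montage(list(electrode(-2, -4, 0.4, "source"),
                     electrode(-2, 4, 0.4, "sink")), 1e-4, 40, "tiny")
  pl1 <- place_montage(ph, m1)
  expect_identical(lengths(lapply(pl1$electrodes, `[[`, "voxels")),
                   c(1L, 1L))
  # overlapping discs rejected
  m2 <- montage(list(electrode(-2, 4, 1.5, "source"),
                     electrode(-2, 4.4, 1.5, "sink")), 1e-4, 40, "overlap")
  expect_error(place_montage(ph, m2), "overlap")
  # a contact hanging past the dural dome finds no dura column
  m3 <- montage(list(electrode(-2, -5.5, 1.5, "source"),
                     electrode(-2, 5.5, 1.5, "sink")), 1e-4, 40, "off_dome")
  expect_error(place_montage(ph, m3), "no dura surface")
})

test_that("tissue tables are validated", {
  tab <- default_tissue_table()
  expect_silent(validate_tissue_table(tab))
  bad <- tab; bad$sigma_S_per_m[bad$name == "gray_matter"] <- 2.5
  expect_error(validate_tissue_table(bad), "ordering")
  bad2 <- tab; bad2$label_id[2] <- bad2$label_id[1]
  expect_error(validate_tissue_table(bad2), "duplicated")
  shipped <- read_tissue_table(system.file("extdata", "tissue_properties.csv",
                                           package = "iacsim"))
  expect_equal(shipped$sigma_S_per_m, tab$sigma_S_per_m)
})
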