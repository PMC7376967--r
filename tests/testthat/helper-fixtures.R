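# Shared fixtures, computed lazily and cached for the whole run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) assign(name, expr, .fixture_env)
  get(name, envir = .fixture_env)
}

# odd ML dimension so the midline falls on a voxel column (exact mirror
# symmetry); 400 um keeps these solves to a few seconds
coarse_spec <- function(...) {
  phantom_spec(voxel_size_um = 400, grid_shape = c(47, 59, 38), ...)
}

coarse_phantom <- function() memo("coarse_phantom", build_phantom(coarse_spec()))

coarse_solution <- function() memo("coarse_solution", {
  ph <- coarse_phantom()
  c(list(phantom = ph),
    solve_montage(ph, bilateral_montage(), tol = 1e-10))
})

# brute-force oracles, deliberately written as plain loops, independent of
# the vectorized implementation paths they check

brute_svz_count <- function(phantom) {
  lab <- phantom_labels()
  L <- phantom$labels
  d <- dim(L)
  par_lab <- c(lab[["gray"]], lab[["white"]], lab[["hippocampus"]])
  vent <- which(L == lab[["ventricle"]], arr.ind = TRUE)
  if (nrow(vent) == 0) return(0L)
  lo <- pmax(apply(vent, 2, min) - 1L, 1L)
  hi <- pmin(apply(vent, 2, max) + 1L, d)
  cnt <- 0L
  for (i in lo[1]:hi[1]) for (j in lo[2]:hi[2]) for (k in lo[3]:hi[3]) {
    v <- L[i, j, k]
    if (!(v %in% par_lab || v == lab[["svz"]])) next
    touch <- FALSE
    for (s in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      p <- c(i, j, k) + s
      if (all(p >= 1) && all(p <= d) &&
          L[p[1], p[2], p[3]] == lab[["ventricle"]]) { touch <- TRUE; break }
    }
    if (touch) cnt <- cnt + 1L
  }
  cnt
}

brute_disc_count <- function(radius_vox) {
  cnt <- 0L
  m <- ceiling(radius_vox)
  for (dx in -m:m) for (dy in -m:m)
    if (dx^2 + dy^2 < radius_vox^2) cnt <- cnt + 1L
  cnt
}

mirror_ml <- function(a) a[, dim(a)[2]:1, , drop = FALSE]
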