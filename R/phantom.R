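# Axis convention (documented, nothing in the source data fixes it):
#   axis 1 = AP (index increases anterior), axis 2 = ML (index increases to
#   the right), axis 3 = DV (index increases dorsally, i.e. depth decreases).
# Voxel indices are 1-based; stereotaxic DV is measured downward from the
# dura surface at bregma, so voxel = bregma + (AP, ML, -DV)/voxel_size.

shift_array <- function(a, axis, by) {
  # shift array contents by `by` voxels along `axis`, padding with FALSE/0
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, dim = d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  dst <- src
  if (by > 0) {
    dst[[axis]] <- (by + 1):n; src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    dst[[axis]] <- 1:(n + by); src[[axis]] <- (1 - by):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

adjacent_to <- function(mask) {
  # voxels 6-adjacent to TRUE voxels of `mask` (excluding mask itself is the
  # caller's job)
  adj <- array(FALSE, dim(mask))
  for (ax in 1:3) for (by in c(-1L, 1L)) adj <- adj | shift_array(mask, ax, by)
  adj
}

ellipsoid_mask <- function(dims, center_vox, semi_vox) {
  # voxel centers inside the ellipsoid; computed on the bounding box only
  if (any(semi_vox <= 0)) return(array(FALSE, dims))
  lo <- pmax(1L, floor(center_vox - semi_vox))
  hi <- pmin(dims, ceiling(center_vox + semi_vox))
  if (any(lo > hi)) return(array(FALSE, dims))
  qx <- ((lo[1]:hi[1] - center_vox[1]) / semi_vox[1])^2
  qy <- ((lo[2]:hi[2] - center_vox[2]) / semi_vox[2])^2
  qz <- ((lo[3]:hi[3] - center_vox[3]) / semi_vox[3])^2
  box <- outer(outer(qx, qy, "+"), qz, "+") <= 1
  m <- array(FALSE, dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- box
  m
}

#' Specification of the parametric mouse-head phantom
#'
#' Describes a layered voxel phantom: an ellipsoidal brain (cortical gray
#' shell over white matter) containing paired lateral ventricles (CSF) and
#' paired hippocampal bodies, wrapped in a thin CSF film and a dura layer.
#' Structure centers are given relative to the brain center as
#' `(AP, |ML|, z)` offsets in mm, with `z` positive dorsally; the paired
#' structures are mirrored across the midline. Defaults follow mouse
#' stereotaxic anatomy: dorsal hippocampus about 1.8 mm and lateral
#' ventricles about 2.4 mm below the dural surface.
#'
#' @param voxel_size_um Isotropic voxel edge (um), default 100.
#' @param grid_shape Integer triple of voxel counts; default derives the
#'   standard 18.9 x 23.6 x 15.2 mm bounding grid at the requested
#'   resolution (189 x 236 x 152 voxels at 100 um).
#' @param brain_semiaxes_mm Brain ellipsoid semi-axes (AP, ML, DV), mm.
#' @param cortex_thickness_mm Gray-matter shell thickness, mm.
#' @param ventricle_center_mm,ventricle_semiaxes_mm Paired-ventricle center
#'   offset and semi-axes, mm. Zero semi-axes suppress ventricles (and the
#'   SVZ shell).
#' @param hippocampus_center_mm,hippocampus_semiaxes_mm Paired-hippocampus
#'   center offset and semi-axes, mm. Zero semi-axes suppress hippocampi.
#' @param dura_thickness_um Dura layer thickness (um), default 300.
#' @param csf_thickness_um Sub-dural CSF film thickness (um), default 43.
#'   Films thinner than one voxel are rasterized one voxel thick with a
#'   sheet-conductance-preserving effective conductivity.
#' @param bregma_ap_offset_mm AP offset of bregma anterior to the brain
#'   center, mm.
#' @param tissue_table Tissue-property table, see [default_tissue_table()].
#' @return Object of class `phantom_spec`.
#' @seealso [build_phantom()]
#' @export
phantom_spec <- function(voxel_size_um = 100,
                         grid_shape = NULL,
                         brain_semiaxes_mm = c(7.0, 5.0, 3.5),
                         cortex_thickness_mm = 0.8,
                         ventricle_center_mm = c(1.5, 1.2, 1.1),
                         ventricle_semiaxes_mm = c(1.5, 0.3, 0.9),
                         hippocampus_center_mm = c(0.0, 2.6, 1.7),
                         hippocampus_semiaxes_mm = c(1.5, 0.9, 0.7),
                         dura_thickness_um = 300,
                         csf_thickness_um = 43,
                         bregma_ap_offset_mm = 2.0,
                         tissue_table = default_tissue_table()) {
  if (is.null(grid_shape))
    grid_shape <- as.integer(round(c(18.9, 23.6, 15.2) * 1000 / voxel_size_um))
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 3),
            voxel_size_um > 0, dura_thickness_um > 0, csf_thickness_um > 0,
            all(brain_semiaxes_mm > 0), cortex_thickness_mm > 0,
            length(ventricle_semiaxes_mm) == 3,
            length(hippocampus_semiaxes_mm) == 3,
            all(ventricle_semiaxes_mm >= 0), all(hippocampus_semiaxes_mm >= 0))
  validate_tissue_table(tissue_table)
  structure(list(
    voxel_size_um = voxel_size_um, grid_shape = grid_shape,
    brain_semiaxes_mm = brain_semiaxes_mm,
    cortex_thickness_mm = cortex_thickness_mm,
    ventricle_center_mm = ventricle_center_mm,
    ventricle_semiaxes_mm = ventricle_semiaxes_mm,
    hippocampus_center_mm = hippocampus_center_mm,
    hippocampus_semiaxes_mm = hippocampus_semiaxes_mm,
    dura_thickness_um = dura_thickness_um,
    csf_thickness_um = csf_thickness_um,
    bregma_ap_offset_mm = bregma_ap_offset_mm,
    tissue_table = tissue_table), class = "phantom_spec")
}

#' Build the layered voxel phantom
#'
#' Rasterizes a [phantom_spec()] into a labeled voxel volume: white-matter
#' core, cortical gray shell, CSF-filled lateral ventricles, an SVZ shell
#' (the 1-voxel parenchymal layer 6-adjacent to each ventricle), paired
#' hippocampi, then a CSF film and dura layer grown outward over the brain
#' surface. Thin films get conductance-preserving effective conductivities
#' (see [effective_shell_conductivity()]). Deterministic for a fixed spec.
#'
#' @param spec A `phantom_spec`.
#' @return Object of class `voxel_phantom` with fields `labels` (3-D integer
#'   array), `voxel_size_um`, `bregma_voxel`, `properties` (tissue table with
#'   effective shell conductivities applied), and `spec`.
#' @export
#' @examples
#' ph <- build_phantom(phantom_spec(voxel_size_um = 400))
#' table(ph$labels[ph$labels > 0])
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- phantom_labels()
  dims <- spec$grid_shape
  h <- spec$voxel_size_um / 1000 # mm per voxel
  center <- floor((dims + 1L) / 2L)

  shell_vox <- ceiling(spec$csf_thickness_um / spec$voxel_size_um) +
    ceiling(spec$dura_thickness_um / spec$voxel_size_um)
  if (any(spec$brain_semiaxes_mm / h + shell_vox + 1 > (dims - 1) / 2))
    stop("invalid spec: grid too small for brain plus dura/CSF shells")

  semi_vox <- spec$brain_semiaxes_mm / h
  brain <- ellipsoid_mask(dims, center, semi_vox)
  inner <- ellipsoid_mask(dims, center,
                          pmax(semi_vox - spec$cortex_thickness_mm / h, 1e-9))
  labels <- array(lab[["background"]], dims)
  labels[brain] <- lab[["gray"]]
  labels[inner] <- lab[["white"]]

  mirror_pair <- function(center_mm, semi_mm) {
    if (any(semi_mm <= 0)) return(array(FALSE, dims))
    m <- array(FALSE, dims)
    for (side in c(-1, 1)) {
      c_vox <- center + c(center_mm[1], side * center_mm[2], center_mm[3]) / h
      m <- m | ellipsoid_mask(dims, c_vox, semi_mm / h)
    }
    m
  }
  vent <- mirror_pair(spec$ventricle_center_mm, spec$ventricle_semiaxes_mm)
  hipp <- mirror_pair(spec$hippocampus_center_mm, spec$hippocampus_semiaxes_mm)
  if (any(vent & hipp))
    stop("invalid spec: ventricle intersects hippocampus")
  vent <- vent & brain
  hipp <- hipp & brain
  labels[vent] <- lab[["ventricle"]]
  labels[hipp & labels == lab[["white"]]] <- lab[["hippocampus"]]
  if (any(vent)) {
    svz <- adjacent_to(vent) & !vent &
      array(labels %in% c(lab[["gray"]], lab[["white"]], lab[["hippocampus"]]),
            dims)
    labels[svz] <- lab[["svz"]]
  }

  props <- spec$tissue_table
  phantom <- structure(list(
    labels = labels, voxel_size_um = spec$voxel_size_um,
    bregma_voxel = NULL, properties = props, spec = spec,
    provenance = "parametric layered mouse-head phantom"),
    class = "voxel_phantom")

  # CSF film then dura, grown outward; sub-voxel films get effective sigma
  phantom <- add_thin_layer(phantom, spec$csf_thickness_um, lab[["csf"]],
                            "csf_shell")
  phantom <- add_thin_layer(phantom, spec$dura_thickness_um, lab[["dura"]],
                            "dura")

  bcol <- c(center[1] + as.integer(round(spec$bregma_ap_offset_mm / h)),
            center[2])
  zs <- which(phantom$labels[bcol[1], bcol[2], ] > 0)
  if (length(zs) == 0) stop("invalid spec: no head surface at bregma column")
  phantom$bregma_voxel <- as.integer(c(bcol, max(zs)))
  phantom
}

add_thin_layer <- function(phantom, thickness_um, new_label, prop_name) {
  # wraps add_shell, replacing conductivity for sub-voxel layers
  if (thickness_um < phantom$voxel_size_um) {
    i <- match(prop_name, phantom$properties$name)
    phantom$properties$sigma_S_per_m[i] <- effective_shell_conductivity(
      phantom$properties$sigma_S_per_m[i], thickness_um, phantom$voxel_size_um)
  }
  add_shell(phantom, thickness_um, new_label)
}

#' Grow an outward shell over the current head surface
#'
#' Adds `ceiling(thickness / voxel_size)` morphological layers of
#' `new_label` over all background voxels 6-adjacent to the current
#' non-background surface. Interior labels are never touched. For layers
#' thinner than one voxel the caller must replace the label's conductivity
#' via [effective_shell_conductivity()] (done automatically by
#' [build_phantom()] for its CSF film and dura).
#'
#' @param phantom A `voxel_phantom`.
#' @param thickness Shell thickness in um.
#' @param new_label Integer label id, registered in `phantom$properties`.
#' @return The phantom with the shell added.
#' @export
add_shell <- function(phantom, thickness, new_label) {
  stopifnot(inherits(phantom, "voxel_phantom"), thickness > 0)
  if (!new_label %in% phantom$properties$label_id)
    stop("new_label ", new_label, " not registered in the tissue-property table")
  n_layers <- ceiling(thickness / phantom$voxel_size_um)
  labels <- phantom$labels
  d <- dim(labels)
  for (i in seq_len(n_layers)) {
    occ <- labels > 0
    boundary_occ <- any(occ[c(1, d[1]), , ]) || any(occ[, c(1, d[2]), ]) ||
      any(occ[, , c(1, d[3])])
    if (boundary_occ)
      stop("invalid spec: shell exceeds grid bounds")
    grow <- adjacent_to(occ) & !occ
    labels[grow] <- as.integer(new_label)
  }
  phantom$labels <- labels
  phantom
}

#' Map stereotaxic coordinates to a voxel index
#'
#' `voxel = bregma_voxel + (AP, ML, -DV) / voxel_size`, rounded to the
#' nearest voxel. AP is positive anterior, ML positive right, DV positive
#' downward from the dura surface at bregma (all mm).
#'
#' @param phantom A `voxel_phantom`.
#' @param AP,ML,DV Stereotaxic offsets from bregma, mm.
#' @return Integer voxel index triple (1-based).
#' @export
#' @examples
#' ph <- build_phantom(phantom_spec(voxel_size_um = 400))
#' stereotaxic_to_voxel(ph, 0, 0, 0) # bregma itself
stereotaxic_to_voxel <- function(phantom, AP, ML, DV) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  h <- phantom$voxel_size_um / 1000
  v <- as.integer(round(phantom$bregma_voxel + c(AP, ML, -DV) / h))
  if (any(v < 1L) || any(v > dim(phantom$labels)))
    stop("stereotaxic coordinate (", AP, ", ", ML, ", ", DV,
         ") maps outside the grid")
  v
}

#' Conductivity volume of a phantom
#'
#' @param phantom A `voxel_phantom`.
#' @return 3-D numeric array of conductivities (S/m), 0 in background.
#' @export
conductivity_volume <- function(phantom) {
  sig <- numeric(max(phantom$properties$label_id) + 1L)
  sig[phantom$properties$label_id + 1L] <- phantom$properties$sigma_S_per_m
  array(sig[phantom$labels + 1L], dim(phantom$labels))
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("voxel_phantom: %d x %d x %d voxels at %g um\n",
              d[1], d[2], d[3], x$voxel_size_um))
  cat("bregma voxel:", paste(x$bregma_voxel, collapse = ", "), "\n")
  tab <- table(factor(x$labels[x$labels > 0],
                      levels = x$properties$label_id,
                      labels = x$properties$name))
  cat("voxel counts:\n")
  print(tab)
  invisible(x)
}
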