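#' Define an epidural screw electrode
#'
#' @param center_AP,center_ML Contact center in stereotaxic mm relative to
#'   bregma (AP positive anterior, ML positive right).
#' @param contact_diameter Contact diameter, mm (default 1.5, the burr-hole
#'   diameter; the screw itself is nominally 1.6 mm, so this is
#'   configurable).
#' @param role `"source"` or `"sink"`.
#' @return Object of class `electrode`.
#' @export
electrode <- function(center_AP, center_ML, contact_diameter = 1.5,
                      role = c("source", "sink")) {
  role <- match.arg(role)
  stopifnot(contact_diameter > 0)
  structure(list(center_AP = center_AP, center_ML = center_ML,
                 contact_diameter = contact_diameter, role = role),
            class = "electrode")
}

#' Define an electrode montage
#'
#' A set of source/sink electrodes with the injected current amplitude and
#' frequency. Total source current equals total sink current (net zero
#' injection); `current_amplitude` is the total current through the source
#' side.
#'
#' @param electrodes List of [electrode()] objects (at least one source and
#'   one sink).
#' @param current_amplitude Injected current, A (default 1e-4, i.e. 100 uA).
#' @param frequency Stimulation frequency, Hz (default 40).
#' @param name Label used in rankings and reports.
#' @return Object of class `montage`.
#' @export
montage <- function(electrodes, current_amplitude = 1e-4, frequency = 40,
                    name = "montage") {
  stopifnot(is.list(electrodes), length(electrodes) >= 2,
            all(vapply(electrodes, inherits, TRUE, "electrode")),
            current_amplitude > 0, frequency > 0)
  roles <- vapply(electrodes, `[[`, "", "role")
  if (!any(roles == "source") || !any(roles == "sink"))
    stop("montage needs at least one source and one sink electrode")
  structure(list(electrodes = electrodes,
                 current_amplitude = current_amplitude,
                 frequency = frequency, name = name), class = "montage")
}

#' The bilateral epidural montage used for SVZ/hippocampus targeting
#'
#' Two 1.5 mm contacts on the dura at AP = -2 mm, ML = -4 mm (source) and
#' +4 mm (sink) relative to bregma, 100 uA at 40 Hz.
#'
#' @param current_amplitude Injected current, A.
#' @param frequency Frequency, Hz.
#' @param contact_diameter Contact diameter, mm.
#' @return A `montage`.
#' @export
bilateral_montage <- function(current_amplitude = 1e-4, frequency = 40,
                          contact_diameter = 1.5) {
  montage(list(
    electrode(-2, -4, contact_diameter, "source"),
    electrode(-2, 4, contact_diameter, "sink")),
    current_amplitude, frequency, name = "bilateral_ML4")
}

#' A narrower bilateral montage variant
#'
#' Same AP plane as [bilateral_montage()] but with the two contacts at
#' `ML = +/- ml` mm, for reproducing the montage-position comparison
#' (closer electrode pairs concentrate current superficially and cover
#' less of the deep brain).
#'
#' @param ml Half-separation in mm.
#' @param ap AP coordinate in mm.
#' @param current_amplitude Injected current, A.
#' @param contact_diameter Contact diameter, mm.
#' @return A `montage`.
#' @export
narrow_montage <- function(ml = 1, ap = -2, current_amplitude = 1e-4,
                           contact_diameter = 1.5) {
  montage(list(
    electrode(ap, -ml, contact_diameter, "source"),
    electrode(ap, ml, contact_diameter, "sink")),
    current_amplitude, frequency = 40,
    name = sprintf("bilateral_ML%g_AP%g", ml, ap))
}

#' Place a montage on the dura surface of a phantom
#'
#' Each electrode occupies the dura-surface voxels (topmost dura voxel of
#' each grid column) whose column center lies strictly within
#' `contact_diameter/2` of the contact center (half-open, center-based
#' rasterization). Contacts must be disjoint, must consist of dura voxels
#' only, and must not be 6-adjacent to brain parenchyma: the screws touch
#' the dura but never the brain.
#'
#' @param phantom A `voxel_phantom`.
#' @param mont A `montage`.
#' @return Object of class `montage_placement`: a list with one entry per
#'   electrode carrying `voxels` (linear indices into the label volume),
#'   `role` and the electrode definition, plus the montage.
#' @export
place_montage <- function(phantom, mont) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(mont, "montage"))
  lab <- phantom_labels()
  h <- phantom$voxel_size_um / 1000
  d <- dim(phantom$labels)
  placed <- vector("list", length(mont$electrodes))
  for (k in seq_along(mont$electrodes)) {
    el <- mont$electrodes[[k]]
    cv <- stereotaxic_to_voxel(phantom, el$center_AP, el$center_ML, 0)
    r_vox <- (el$contact_diameter / 2) / h
    di <- seq.int(floor(-r_vox), ceiling(r_vox))
    grid <- expand.grid(i = cv[1] + di, j = cv[2] + di)
    keep <- (grid$i - cv[1])^2 + (grid$j - cv[2])^2 < r_vox^2
    grid <- grid[keep & grid$i >= 1 & grid$i <= d[1] &
                   grid$j >= 1 & grid$j <= d[2], , drop = FALSE]
    if (nrow(grid) == 0)
      stop("electrode ", k, " rasterizes to zero voxels")
    vox <- integer(nrow(grid))
    for (m in seq_len(nrow(grid))) {
      zs <- which(phantom$labels[grid$i[m], grid$j[m], ] == lab[["dura"]])
      if (length(zs) == 0)
        stop("electrode ", k, " (", mont$name,
             "): no dura surface under contact column (",
             grid$i[m], ", ", grid$j[m], ")")
      vox[m] <- grid$i[m] + (grid$j[m] - 1L) * d[1] +
        (max(zs) - 1L) * d[1] * d[2]
    }
    placed[[k]] <- list(electrode = el, role = el$role, voxels = vox)
  }
  allv <- unlist(lapply(placed, `[[`, "voxels"))
  if (anyDuplicated(allv))
    stop("electrode contact discs overlap (montage ", mont$name, ")")
  # contacts must not touch parenchyma
  contact <- array(FALSE, d)
  contact[allv] <- TRUE
  par_mask <- array(phantom$labels %in% parenchyma_labels(), d)
  if (any(adjacent_to(contact) & par_mask))
    stop("electrode contact touches brain parenchyma (montage ",
         mont$name, ")")
  structure(list(electrodes = placed, montage = mont, dims = d),
            class = "montage_placement")
}

#' @export
print.montage_placement <- function(x, ...) {
  cat("montage_placement:", x$montage$name, "\n")
  for (k in seq_along(x$electrodes)) {
    e <- x$electrodes[[k]]
    cat(sprintf("  electrode %d (%s): %d contact voxels\n",
                k, e$role, length(e$voxels)))
  }
  invisible(x)
}
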