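dilate26 <- function(mask) {
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    m <- mask
    if (dx != 0) m <- shift_array(m, 1L, dx)
    if (dy != 0) m <- shift_array(m, 2L, dy)
    if (dz != 0) m <- shift_array(m, 3L, dz)
    out <- out | m
  }
  out
}

contact_exclusion_mask <- function(dims, placement) {
  # contact voxels plus a 1-voxel (26-neighborhood) shell: the uniform-flux
  # electrode model makes fields there discretization-dominated
  m <- array(FALSE, dims)
  if (is.null(placement)) return(m)
  m[unlist(lapply(placement$electrodes, `[[`, "voxels"))] <- TRUE
  dilate26(m)
}

#' Region-of-interest field statistics
#'
#' Unweighted voxelwise mean and maximum of |E| and |J| over each requested
#' label.
#'
#' @param fields A `field_maps` object.
#' @param phantom The matching `voxel_phantom`.
#' @param regions Character names (from [phantom_labels()]) or integer label
#'   ids. Default: every non-background tissue class present.
#' @return data.frame of class `roi_stats` with one row per region:
#'   `region`, `label_id`, `mean_magJ_A_per_m2`, `max_magJ_A_per_m2`,
#'   `mean_magE_V_per_m`, `max_magE_V_per_m`, `voxel_count`.
#' @export
roi_statistics <- function(fields, phantom, regions = NULL) {
  stopifnot(inherits(fields, "field_maps"), inherits(phantom, "voxel_phantom"))
  if (!all(dim(fields$magE) == dim(phantom$labels)))
    stop("fields and phantom grids differ")
  lab <- phantom_labels()
  if (is.null(regions)) {
    ids <- sort(unique(phantom$labels[phantom$labels > 0]))
    nms <- names(lab)[match(ids, lab)]
  } else if (is.character(regions)) {
    if (!all(regions %in% names(lab)))
      stop("unknown region name(s): ",
           paste(setdiff(regions, names(lab)), collapse = ", "))
    ids <- unname(lab[regions]); nms <- regions
  } else {
    ids <- as.integer(regions)
    nms <- names(lab)[match(ids, lab)]
    nms[is.na(nms)] <- as.character(ids[is.na(nms)])
  }
  out <- data.frame(region = nms, label_id = ids,
                    mean_magJ_A_per_m2 = NA_real_, max_magJ_A_per_m2 = NA_real_,
                    mean_magE_V_per_m = NA_real_, max_magE_V_per_m = NA_real_,
                    voxel_count = NA_integer_, stringsAsFactors = FALSE)
  for (r in seq_along(ids)) {
    sel <- phantom$labels == ids[r]
    if (!any(sel)) stop("region '", nms[r], "' (label ", ids[r],
                        ") has no voxels in this phantom")
    out$mean_magJ_A_per_m2[r] <- mean(fields$magJ[sel])
    out$max_magJ_A_per_m2[r] <- max(fields$magJ[sel])
    out$mean_magE_V_per_m[r] <- mean(fields$magE[sel])
    out$max_magE_V_per_m[r] <- max(fields$magE[sel])
    out$voxel_count[r] <- sum(sel)
  }
  class(out) <- c("roi_stats", "data.frame")
  out
}

#' Lesion-safety check on the current-density map
#'
#' Maximum |J| over brain parenchyma (gray, white, hippocampus, SVZ shell;
#' dura and CSF excluded), additionally excluding the electrode contact
#' voxels and their 1-voxel neighborhood where the uniform-flux contact
#' model dominates the discretization. Compared against the tissue lesion
#' bound, reported above 20 A/m^2.
#'
#' @param fields A `field_maps` object (with placement metadata, if
#'   available, for the contact exclusion).
#' @param phantom The matching `voxel_phantom`.
#' @param threshold Lesion bound, A/m^2 (default 20).
#' @return Object of class `safety_report`: `max_parenchymal_magJ`,
#'   `argmax_voxel` (grid index triple), `threshold`, `passed`,
#'   `n_voxels_considered`.
#' @export
safety_check <- function(fields, phantom, threshold = 20) {
  stopifnot(threshold > 0)
  d <- dim(phantom$labels)
  mask <- array(phantom$labels %in% parenchyma_labels(), d) &
    !contact_exclusion_mask(d, fields$placement)
  vals <- fields$magJ[mask]
  mx <- if (length(vals)) max(vals) else 0
  arg <- if (length(vals) && mx > 0) {
    idx <- which(mask)[which.max(vals)]
    as.integer(arrayInd(idx, d))
  } else NA_integer_
  structure(list(max_parenchymal_magJ = mx, argmax_voxel = arg,
                 threshold = threshold, passed = mx < threshold,
                 n_voxels_considered = sum(mask)),
            class = "safety_report")
}

#' @export
print.safety_report <- function(x, ...) {
  cat(sprintf(
    "safety_report: max parenchymal |J| = %.3g A/m^2 (threshold %g) -> %s\n",
    x$max_parenchymal_magJ, x$threshold, if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

#' Current amplitude at which the lesion bound would be reached
#'
#' The ohmic problem is linear in the injected current, so the maximum
#' parenchymal |J| scales proportionally: the bound is reached at
#' `I0 * threshold / max_parenchymal_magJ(I0)`.
#'
#' @param fields `field_maps` solved at current `I0`.
#' @param phantom The matching `voxel_phantom`.
#' @param I0 Current the fields were solved at, A (defaults to the value
#'   recorded in `fields`).
#' @param threshold Lesion bound, A/m^2.
#' @return Current, A.
#' @export
lesion_threshold_current <- function(fields, phantom, I0 = fields$current_A,
                                     threshold = 20) {
  stopifnot(is.finite(I0), I0 > 0, threshold > 0)
  mx <- safety_check(fields, phantom, threshold)$max_parenchymal_magJ
  if (mx <= 0) stop("zero parenchymal field: threshold current undefined")
  I0 * threshold / mx
}

#' Solve and rank a set of montages by deep-target coverage
#'
#' Each montage is placed, solved and summarized over the target regions;
#' the coverage score is the maximin rule min over targets of mean |E|
#' (a montage must reach *both* neurogenic targets). Ranked by score
#' descending; ties broken by larger summed target mean |E|, then input
#' order.
#'
#' @param phantom A `voxel_phantom`.
#' @param montages List of `montage` objects.
#' @param targets Target region names (default hippocampus and SVZ shell).
#' @param tol,maxiter Solver settings.
#' @param keep_fields Keep the full `field_maps` per montage (memory!).
#' @return Object of class `montage_evaluation`: `table` (data.frame with
#'   montage, coverage_score_V_per_m, rank), `roi` (list of `roi_stats`),
#'   optionally `fields`.
#' @export
compare_montages <- function(phantom, montages, targets = c("hippocampus", "svz"),
                             tol = 1e-8, maxiter = 50000,
                             keep_fields = FALSE) {
  stopifnot(length(montages) >= 1)
  nms <- vapply(montages, `[[`, "", "name")
  roi <- vector("list", length(montages)); names(roi) <- nms
  flds <- if (keep_fields) vector("list", length(montages)) else NULL
  score <- tot <- numeric(length(montages))
  for (k in seq_along(montages)) {
    sol <- tryCatch(
      solve_montage(phantom, montages[[k]], tol = tol, maxiter = maxiter),
      error = function(e) stop("montage '", nms[k], "': ",
                               conditionMessage(e), call. = FALSE))
    roi[[k]] <- roi_statistics(sol$fields, phantom, targets)
    score[k] <- min(roi[[k]]$mean_magE_V_per_m)
    tot[k] <- sum(roi[[k]]$mean_magE_V_per_m)
    if (keep_fields) flds[[k]] <- sol$fields
  }
  ord <- order(-score, -tot, seq_along(montages))
  rank <- integer(length(montages)); rank[ord] <- seq_along(montages)
  tab <- data.frame(montage = nms, coverage_score_V_per_m = score,
                    rank = rank, stringsAsFactors = FALSE)
  if (keep_fields) names(flds) <- nms
  structure(list(table = tab, roi = roi, fields = flds, targets = targets),
            class = "montage_evaluation")
}

#' @export
print.montage_evaluation <- function(x, ...) {
  cat("montage_evaluation (maximin mean |E| over:",
      paste(x$targets, collapse = ", "), ")\n")
  print(x$table[order(x$table$rank), ], row.names = FALSE)
  invisible(x)
}
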