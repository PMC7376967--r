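# Synthetic inputs with the statistical structure the analysis assumes:
# normal between-animal variation (the ANOVA model) with optional Poisson
# view-level sampling underneath, plus toy phantoms with analytic field
# solutions for solver validation.

#' The published neurogenesis group summaries
#'
#' The 18 printed (mean, SEM, n = 5) triples: 3 groups (WT, 5xFAD,
#' 5xFAD+iACS) x 2 regions (SVZ, hippocampus) x 3 markers (Ki67, Nestin,
#' DCX). Also shipped as `inst/extdata/neurogenesis_group_summaries.csv`.
#'
#' @return data.frame with columns `group`, `region`, `marker`, `mean`,
#'   `sem`, `n`.
#' @export
#' @examples
#' subset(neurogenesis_summaries(), region == "SVZ" & marker == "Ki67")
neurogenesis_summaries <- function() {
  g <- c("WT", "5xFAD", "5xFAD+iACS")
  out <- rbind(
    data.frame(group = g, region = "SVZ", marker = "Ki67",
               mean = c(1036, 224, 812), sem = c(57, 37, 67)),
    data.frame(group = g, region = "SVZ", marker = "Nestin",
               mean = c(273, 96, 154), sem = c(28, 10, 22)),
    data.frame(group = g, region = "SVZ", marker = "DCX",
               mean = c(873, 172, 454), sem = c(71, 51, 39)),
    data.frame(group = g, region = "hippocampus", marker = "Ki67",
               mean = c(403, 170, 293), sem = c(43, 23, 27)),
    data.frame(group = g, region = "hippocampus", marker = "Nestin",
               mean = c(1554, 241, 942), sem = c(78, 24, 85)),
    data.frame(group = g, region = "hippocampus", marker = "DCX",
               mean = c(1941, 777, 1510), sem = c(113, 45, 157)))
  out$n <- 5L
  out
}

rnorm_trunc0 <- function(n, mu, sd) {
  # normal draws truncated at zero by redrawing; negligible bias at the
  # count scales modelled here (mu >> sd typically)
  if (sd == 0) return(rep(mu, n))
  x <- stats::rnorm(n, mu, sd)
  while (any(neg <- x < 0)) x[neg] <- stats::rnorm(sum(neg), mu, sd)
  x
}

#' Generate per-animal cell counts for one group
#'
#' Draws from Normal(mu, sd^2) truncated at zero and rounded to integers -
#' the between-animal model the one-way ANOVA assumes.
#'
#' @param mu Target group mean (cells).
#' @param sd Between-animal SD (cells); from a printed summary use
#'   [sd_from_sem()].
#' @param n_animals Number of animals (>= 2).
#' @param seed Optional integer seed for reproducibility.
#' @param group,region,marker Metadata carried into the output.
#' @return data.frame with columns `animal_id`, `group`, `region`,
#'   `marker`, `value`.
#' @export
#' @examples
#' generate_animal_counts(224, sd_from_sem(37, 5), 5, seed = 1)
generate_animal_counts <- function(mu, sd, n_animals, seed = NULL,
                                   group = "group", region = "region",
                                   marker = "marker") {
  stopifnot(mu >= 0, sd >= 0, n_animals >= 2)
  if (!is.null(seed)) set.seed(seed)
  data.frame(animal_id = paste0(group, "_", seq_len(n_animals)),
             group = group, region = region, marker = marker,
             value = round(rnorm_trunc0(n_animals, mu, sd)),
             stringsAsFactors = FALSE)
}

#' Generate hierarchical view-level counts for one group
#'
#' Per animal a latent total theta ~ Normal(mu, sd^2) truncated at zero is
#' drawn; each of the `sections * views_per_section` sampled views then
#' receives a Poisson count with rate theta / (sections * views), so
#' [aggregate_views()] with the sum convention recovers totals with
#' expectation mu.
#'
#' @param mu,sd,n_animals As in [generate_animal_counts()].
#' @param sections Number of sampled sections (default 6, 240 um apart).
#' @param views_per_section Views of 200 x 200 um^2 per section (default 3).
#' @param seed Optional integer seed.
#' @param group,region,marker Metadata.
#' @return data.frame with columns `animal_id`, `group`, `region`,
#'   `marker`, `section_index`, `view_index`, `count`.
#' @export
generate_view_counts <- function(mu, sd, n_animals, sections = 6,
                                 views_per_section = 3, seed = NULL,
                                 group = "group", region = "region",
                                 marker = "marker") {
  stopifnot(mu >= 0, sd >= 0, n_animals >= 2,
            sections >= 1, views_per_section >= 1)
  if (!is.null(seed)) set.seed(seed)
  nv <- sections * views_per_section
  theta <- rnorm_trunc0(n_animals, mu, sd)
  out <- expand.grid(view_index = seq_len(views_per_section),
                     section_index = seq_len(sections),
                     animal_id = seq_len(n_animals))
  out$count <- stats::rpois(nrow(out), rep(theta / nv, each = nv))
  data.frame(animal_id = paste0(group, "_", out$animal_id),
             group = group, region = region, marker = marker,
             section_index = out$section_index, view_index = out$view_index,
             count = out$count, stringsAsFactors = FALSE)
}

#' Empirical power of the ANOVA pipeline at given effect sizes
#'
#' Simulates `reps` experiments of k groups with the supplied means and SDs
#' at `n_per_group` animals each, runs [anova_from_counts()] on every
#' replicate, and returns the fraction rejecting at level `alpha`.
#'
#' @param means,sds Numeric vectors, one entry per group.
#' @param n_per_group Animals per group.
#' @param reps Number of replicates.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return Rejection rate in `[0, 1]`.
#' @export
power_rejection_rate <- function(means, sds, n_per_group = 5, reps = 2000,
                                 alpha = 0.05, seed = 1) {
  stopifnot(length(means) == length(sds), length(means) >= 2)
  set.seed(seed)
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    g <- lapply(seq_along(means), function(i)
      round(rnorm_trunc0(n_per_group, means[i], sds[i])))
    rej[r] <- anova_from_counts(g)$p < alpha
  }
  mean(rej)
}

toy_properties <- function(label_id, name, sigma) {
  data.frame(label_id = label_id, name = name, sigma_S_per_m = sigma,
             eps_r = 1e5, frequency_Hz = 40, stringsAsFactors = FALSE)
}

toy_voxel_phantom <- function(labels, voxel_size_um, properties, kind) {
  d <- dim(labels)
  structure(list(labels = labels, voxel_size_um = voxel_size_um,
                 bregma_voxel = as.integer(floor((d + 1) / 2)),
                 properties = properties, spec = NULL,
                 provenance = paste0("toy phantom: ", kind)),
            class = "voxel_phantom")
}

toy_placement <- function(dims, source_vox, sink_vox, mont) {
  structure(list(
    electrodes = list(
      list(electrode = mont$electrodes[[1]], role = "source",
           voxels = source_vox),
      list(electrode = mont$electrodes[[2]], role = "sink",
           voxels = sink_vox)),
    montage = mont, dims = dims), class = "montage_placement")
}

#' Toy phantoms with analytic field solutions
#'
#' Solver-validation geometries:
#' \describe{
#'   \item{`uniform_cube`}{Homogeneous cube with two full opposite faces as
#'     electrodes; the exact solution is a linear potential with
#'     `|J| = I / A` and `|E| = I / (sigma A)` everywhere.}
#'   \item{`layered_slab`}{Two-material bar with end-face electrodes; the
#'     per-layer potential drops follow the series-resistance closed form
#'     `V_k = I t_k / (sigma_k A)` exactly.}
#'   \item{`point_source_box`}{Homogeneous box with a single-voxel source at
#'     the center and the sink spread over the outer boundary (a distant
#'     ground); radial potential drops follow the free-space monopole
#'     [analytic_point_source()].}
#' }
#'
#' @param kind One of `"uniform_cube"`, `"layered_slab"`,
#'   `"point_source_box"`.
#' @param sigma Conductivity (S/m); for `layered_slab`, a length-2 vector.
#' @param I Injected current, A.
#' @param size_mm Cube edge (uniform_cube) in mm.
#' @param voxel_um Voxel size, um.
#' @param t_mm Layer thicknesses (layered_slab), mm.
#' @param area_mm2 Bar cross-section (layered_slab), mm^2.
#' @param box_dims Grid shape (point_source_box), voxels.
#' @return List with `phantom`, `montage`, `placement` and an `expected`
#'   list of closed-form values.
#' @export
#' @examples
#' toy <- toy_phantom("uniform_cube", voxel_um = 1000)
#' toy$expected$magJ_A_per_m2
toy_phantom <- function(kind = c("uniform_cube", "layered_slab",
                                 "point_source_box"),
                        sigma = NULL, I = 1e-4, size_mm = 10,
                        voxel_um = 500, t_mm = c(1, 1), area_mm2 = 1,
                        box_dims = c(61, 61, 61)) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown toy phantom kind: ",
                                            kind[1], call. = FALSE))
  h_mm <- voxel_um / 1000
  if (kind == "uniform_cube") {
    if (is.null(sigma)) sigma <- 1
    n <- round(size_mm / h_mm)
    labels <- array(3L, c(n, n, n))
    ph <- toy_voxel_phantom(labels, voxel_um,
                            toy_properties(3L, "uniform", sigma), kind)
    mont <- montage(list(electrode(0, 0, h_mm, "source"),
                         electrode(0, 0, h_mm, "sink")), I, 40,
                    name = "cube_faces")
    d <- dim(labels)
    face <- function(i) which(slice.index(labels, 1) == i)
    pl <- toy_placement(d, face(1L), face(n), mont)
    A_m2 <- (size_mm * 1e-3)^2
    expected <- list(magJ_A_per_m2 = I / A_m2,
                     magE_V_per_m = I / (sigma * A_m2),
                     face_drop_V = I * size_mm * 1e-3 / (sigma * A_m2))
  } else if (kind == "layered_slab") {
    if (is.null(sigma)) sigma <- c(1, 0.5)
    stopifnot(length(sigma) == 2, length(t_mm) == 2)
    side <- sqrt(area_mm2)
    nside <- round(side / h_mm)
    n1 <- round(t_mm[1] / h_mm); n2 <- round(t_mm[2] / h_mm)
    labels <- array(0L, c(n1 + n2, nside, nside))
    labels[1:n1, , ] <- 3L
    labels[(n1 + 1):(n1 + n2), , ] <- 4L
    ph <- toy_voxel_phantom(labels, voxel_um,
                            toy_properties(c(3L, 4L), c("layer1", "layer2"),
                                           sigma), kind)
    mont <- montage(list(electrode(0, 0, h_mm, "source"),
                         electrode(0, 0, h_mm, "sink")), I, 40,
                    name = "slab_faces")
    d <- dim(labels)
    face <- function(i) which(slice.index(labels, 1) == i)
    pl <- toy_placement(d, face(1L), face(n1 + n2), mont)
    A_m2 <- area_mm2 * 1e-6
    expected <- list(layer_drops_V = I * t_mm * 1e-3 / (sigma * A_m2),
                     magJ_A_per_m2 = I / A_m2, n_layer1 = n1, n_layer2 = n2)
  } else { # point_source_box
    # single-voxel source at the center; the sink is spread uniformly over
    # the whole outer boundary, which acts like a distant ground shell and
    # adds a nearly constant potential inside, so radial potential drops
    # follow the free-space monopole I/(4 pi sigma r)
    if (is.null(sigma)) sigma <- 0.3
    labels <- array(3L, box_dims)
    ph <- toy_voxel_phantom(labels, voxel_um,
                            toy_properties(3L, "uniform", sigma), kind)
    mont <- montage(list(electrode(0, 0, h_mm, "source"),
                         electrode(0, 0, h_mm, "sink")), I, 40,
                    name = "point_source_grounded_box")
    d <- box_dims
    src <- as.integer(floor((d + 1) / 2))
    lin <- function(v) v[1] + (v[2] - 1L) * d[1] + (v[3] - 1L) * d[1] * d[2]
    bnd <- which(slice.index(labels, 1) %in% c(1L, d[1]) |
                   slice.index(labels, 2) %in% c(1L, d[2]) |
                   slice.index(labels, 3) %in% c(1L, d[3]))
    pl <- toy_placement(d, lin(src), bnd, mont)
    expected <- list(source_voxel = src, sigma = sigma,
                     phi_1mm_V = analytic_point_source(sigma, I, 1e-3))
  }
  list(phantom = ph, montage = mont, placement = pl, expected = expected,
       kind = kind)
}
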