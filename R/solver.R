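# Finite-volume discretization of div(sigma grad phi) = 0 on the voxel grid.
# One unknown per conductive voxel (background excluded); the conductance of
# the face between two voxels is the harmonic mean of their conductivities
# times face area over spacing (= sigma_harm * h for cubic voxels), which is
# exact for 1-D piecewise-constant media. Outer boundaries are zero-flux
# (Neumann). Current is injected as equal shares over each electrode's
# contact voxels; one sink contact voxel is pinned to 0 V as the gauge.

#' Assemble the quasi-electrostatic linear system
#'
#' @param phantom A `voxel_phantom`.
#' @param mont A `montage` (used for the current amplitude and roles).
#' @param placement A `montage_placement`; computed via [place_montage()]
#'   when omitted. Toy phantoms from [toy_phantom()] supply their own.
#' @return Object of class `qs_system`: sparse SPD operator `A` (Siemens),
#'   right-hand side `b` (A), `domain_index` (grid linear index per
#'   unknown), `gauge` (unknown index pinned to 0 V), grid metadata and the
#'   placement.
#' @export
assemble_system <- function(phantom, mont, placement = NULL) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(mont, "montage"))
  if (is.null(placement)) placement <- place_montage(phantom, mont)
  sigma <- conductivity_volume(phantom)
  d <- dim(sigma)
  domain <- sigma > 0
  domain_index <- which(domain)
  n <- length(domain_index)
  uid <- array(0L, d)
  uid[domain_index] <- seq_len(n)
  h_m <- phantom$voxel_size_um * 1e-6
  stride <- c(1L, d[1], d[1] * d[2])

  ii <- jj <- integer(0); gg <- numeric(0)
  for (ax in 1:3) {
    nb <- shift_array(domain, ax, -1L) # nb[v] = domain[v + e_ax]
    pair <- which(domain & nb)
    if (length(pair) == 0) next
    s1 <- sigma[pair]; s2 <- sigma[pair + stride[ax]]
    g <- 2 * s1 * s2 / (s1 + s2) * h_m
    ii <- c(ii, uid[pair]); jj <- c(jj, uid[pair + stride[ax]])
    gg <- c(gg, g)
  }
  A <- Matrix::sparseMatrix(
    i = c(ii, jj, ii, jj), j = c(jj, ii, ii, jj),
    x = c(-gg, -gg, gg, gg), dims = c(n, n))

  roles <- vapply(placement$electrodes, `[[`, "", "role")
  b <- numeric(n)
  I <- mont$current_amplitude
  for (k in seq_along(placement$electrodes)) {
    e <- placement$electrodes[[k]]
    share <- I / sum(roles == e$role) / length(e$voxels)
    sgn <- if (e$role == "source") 1 else -1
    u <- uid[e$voxels]
    if (any(u == 0L)) stop("electrode voxel outside conductive domain")
    b[u] <- b[u] + sgn * share
  }
  gauge <- uid[placement$electrodes[[which(roles == "sink")[1]]]$voxels[1]]

  # source and sink must be connected through the conductive domain;
  # cheap necessary check: every unknown has at least one face conductance
  if (any(Matrix::diag(A) == 0))
    stop("singular system: isolated voxels in the conductive domain")

  structure(list(A = A, b = b, domain_index = domain_index, gauge = gauge,
                 dims = d, h_m = h_m, placement = placement, montage = mont),
            class = "qs_system")
}

cg_jacobi <- function(A, b, tol, maxiter) {
  nb <- sqrt(sum(b^2))
  if (nb == 0)
    return(list(x = numeric(length(b)), relres = 0, iterations = 0L,
                converged = TRUE, history = numeric(0)))
  Minv <- 1 / Matrix::diag(A)
  x <- numeric(length(b))
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  history <- numeric(0)
  relres <- 1
  for (it in seq_len(maxiter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    relres <- sqrt(sum(r * r)) / nb
    if (it %% 25 == 0 || relres <= tol) history <- c(history, relres)
    if (relres <= tol)
      return(list(x = x, relres = relres, iterations = it, converged = TRUE,
                  history = history))
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, relres = relres, iterations = maxiter, converged = FALSE,
       history = history)
}

#' Solve for the electric potential
#'
#' Conjugate-gradient solve (Jacobi preconditioner) of the reduced system
#' with the gauge voxel eliminated. Deterministic for fixed inputs.
#'
#' @param system A `qs_system` from [assemble_system()].
#' @param tol Relative residual tolerance (default 1e-8).
#' @param maxiter Iteration cap.
#' @return Object of class `qs_potential`: `phi` (3-D array, V; `NA`
#'   outside the conductive domain, 0 at the gauge), `residual`,
#'   `iterations`, `converged`, plus solve metadata.
#' @export
solve_potential <- function(system, tol = 1e-8, maxiter = 50000) {
  stopifnot(inherits(system, "qs_system"))
  n <- length(system$b)
  keep <- setdiff(seq_len(n), system$gauge)
  res <- cg_jacobi(system$A[keep, keep, drop = FALSE], system$b[keep],
                   tol, maxiter)
  if (!res$converged)
    stop(errorCondition(
      sprintf("CG failed to converge in %d iterations (relative residual %.3e)",
              res$iterations, res$relres),
      class = "iacsim_nonconvergence", history = res$history))
  x <- numeric(n)
  x[keep] <- res$x
  phi <- array(NA_real_, system$dims)
  phi[system$domain_index] <- x
  structure(list(phi = phi, residual = res$relres,
                 iterations = res$iterations, converged = res$converged,
                 tol = tol, unknowns = x,
                 gauge_grid_index = system$domain_index[system$gauge]),
            class = "qs_potential")
}

#' Derive electric field and current density from a potential
#'
#' E is the negative gradient of phi by central differences, falling back to
#' one-sided differences at domain surfaces; J = sigma E voxelwise.
#' Background voxels carry zero field.
#'
#' @param potential A converged `qs_potential`.
#' @param phantom The `voxel_phantom` the potential was solved on.
#' @param placement Optional `montage_placement` (propagated for the
#'   electrode-neighborhood exclusion in [safety_check()]).
#' @param current_A Injected current the solve used (propagated for
#'   linear-scaling utilities).
#' @return Object of class `field_maps` with 3-D arrays `Ex`, `Ey`, `Ez`
#'   (V/m), `Jx`, `Jy`, `Jz` (A/m^2), `magE`, `magJ`.
#' @export
fields_from_potential <- function(potential, phantom, placement = NULL,
                                  current_A = NA_real_) {
  stopifnot(inherits(potential, "qs_potential"))
  if (!potential$converged) stop("potential did not converge")
  phi <- potential$phi
  h_m <- phantom$voxel_size_um * 1e-6
  d <- dim(phi)
  E <- vector("list", 3)
  for (ax in 1:3) {
    up <- shift_array(phi, ax, -1L)   # phi[v + e_ax]
    dn <- shift_array(phi, ax, 1L)    # phi[v - e_ax]
    # shift_array pads numerically with 0; rebuild NA masks from a shifted
    # availability mask instead
    avail <- !is.na(phi)
    up_ok <- shift_array(avail, ax, -1L) & avail
    dn_ok <- shift_array(avail, ax, 1L) & avail
    fwd <- array(0, d); bwd <- array(0, d)
    fwd[up_ok] <- (up[up_ok] - phi[up_ok]) / h_m
    bwd[dn_ok] <- (phi[dn_ok] - dn[dn_ok]) / h_m
    g <- array(0, d)
    both <- up_ok & dn_ok
    g[both] <- (fwd[both] + bwd[both]) / 2
    only_f <- up_ok & !dn_ok; g[only_f] <- fwd[only_f]
    only_b <- dn_ok & !up_ok; g[only_b] <- bwd[only_b]
    E[[ax]] <- -g
  }
  sigma <- conductivity_volume(phantom)
  J <- lapply(E, function(e) e * sigma)
  magE <- sqrt(E[[1]]^2 + E[[2]]^2 + E[[3]]^2)
  magJ <- sqrt(J[[1]]^2 + J[[2]]^2 + J[[3]]^2)
  structure(list(Ex = E[[1]], Ey = E[[2]], Ez = E[[3]],
                 Jx = J[[1]], Jy = J[[2]], Jz = J[[3]],
                 magE = magE, magJ = magJ,
                 voxel_size_um = phantom$voxel_size_um,
                 placement = placement, current_A = current_A),
            class = "field_maps")
}

#' Build, place, solve and differentiate in one call
#'
#' @param phantom A `voxel_phantom`.
#' @param mont A `montage`.
#' @param placement Optional pre-computed placement.
#' @param tol,maxiter Passed to [solve_potential()].
#' @return List with `system`, `potential`, `fields`, `placement`.
#' @export
solve_montage <- function(phantom, mont, placement = NULL,
                          tol = 1e-8, maxiter = 50000) {
  if (is.null(placement)) placement <- place_montage(phantom, mont)
  system <- assemble_system(phantom, mont, placement)
  potential <- solve_potential(system, tol = tol, maxiter = maxiter)
  fields <- fields_from_potential(potential, phantom, placement,
                                  current_A = mont$current_amplitude)
  list(system = system, potential = potential, fields = fields,
       placement = placement)
}

#' Net current out of a voxel set (discrete flux)
#'
#' Sums the discrete face fluxes leaving the given voxels, computed exactly
#' from the assembled operator as `sum((A phi)[S])`. For any set containing
#' all source contacts and no sink contacts this equals the injected
#' current, up to the solver residual.
#'
#' @param system A `qs_system`.
#' @param potential The corresponding `qs_potential`.
#' @param grid_voxels Linear indices into the label volume.
#' @return Net outward current, A.
#' @export
enclosed_current <- function(system, potential, grid_voxels) {
  uid <- array(0L, system$dims)
  uid[system$domain_index] <- seq_along(system$domain_index)
  u <- uid[grid_voxels]
  u <- u[u > 0L]
  Ax <- as.numeric(system$A %*% potential$unknowns)
  sum(Ax[u])
}

#' Discrete divergence residual of the solved field
#'
#' `A phi - b` per unknown: zero (up to solver tolerance) at every
#' non-electrode voxel expresses conservation of current.
#'
#' @param system A `qs_system`.
#' @param potential The corresponding `qs_potential`.
#' @return Numeric vector, one entry per unknown (gauge entry included).
#' @export
divergence_residual <- function(system, potential) {
  as.numeric(system$A %*% potential$unknowns) - system$b
}

#' Free-space monopole potential
#'
#' Potential at distance `r` from a point current source `I` in an infinite
#' homogeneous medium of conductivity `sigma`: `I / (4 pi sigma r)`. Used as
#' an analytic oracle for the voxel solver.
#'
#' @param sigma Conductivity, S/m.
#' @param I Injected current, A.
#' @param r Distance, m (> 0).
#' @return Potential, V.
#' @export
#' @examples
#' analytic_point_source(0.3, 1e-4, 1e-3) # 0.02653 V
analytic_point_source <- function(sigma, I, r) {
  stopifnot(sigma > 0)
  if (any(r <= 0)) stop("r must be > 0")
  I / (4 * pi * sigma * r)
}

#' @export
print.qs_potential <- function(x, ...) {
  cat(sprintf("qs_potential: %d iterations, relative residual %.3e (%s)\n",
              x$iterations, x$residual,
              if (x$converged) "converged" else "NOT converged"))
  rng <- range(x$phi, na.rm = TRUE)
  cat(sprintf("phi range: [%.4g, %.4g] V\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
print.field_maps <- function(x, ...) {
  cat(sprintf("field_maps: max |E| = %.3g V/m, max |J| = %.3g A/m^2\n",
              max(x$magE), max(x$magJ)))
  invisible(x)
}

#' Plot a coronal slice of a field map
#'
#' @param x A `field_maps` object.
#' @param what `"magE"` or `"magJ"`.
#' @param ap_slice Index along the AP axis (default: middle).
#' @param ... Passed to [graphics::image()].
#' @export
plot.field_maps <- function(x, what = c("magE", "magJ"), ap_slice = NULL,
                            ...) {
  what <- match.arg(what)
  vol <- x[[what]]
  if (is.null(ap_slice)) ap_slice <- round(dim(vol)[1] / 2)
  graphics::image(vol[ap_slice, , ],
                  main = sprintf("%s, AP slice %d", what, ap_slice),
                  xlab = "ML", ylab = "DV", useRaster = TRUE, ...)
  invisible(x)
}
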