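# Minimum-pore-radius profiling along the barrel axis. At each axial slice
# the pore radius is the largest sphere clearance achievable at any candidate
# centre in a lateral search disc around the axis: a deterministic coarse
# grid followed by local grid refinement (no stochastic annealing, so runs
# are exactly reproducible).

#' Pore radius profile along the barrel axis
#'
#' For each axial slice `z` across the membrane slab, the radius is
#' `max_c min_atoms (|c - x_atom| - vdw_atom)` over candidate centres `c` in
#' the plane at `z` within `disc_radius` of the axis. The maximisation uses
#' a deterministic coarse grid refined locally down to `refine_tol`.
#' Negative clearances (slice fully blocked) are floored at zero and
#' flagged.
#'
#' @param model A `structure_model` (whole structure, [extract_core()]
#'   output, or [polyalanine()] output).
#' @param axis Unit 3-vector: the barrel axis.
#' @param origin Point on the axis; default the atom centroid.
#' @param slab Axial range `c(z_lo, z_hi)` to profile; default the axial
#'   span of the atoms.
#' @param mode Label recorded in the profile: `"whole"`, `"core"` or
#'   `"polyA"`.
#' @param step Axial slice spacing in Angstrom (default 0.25).
#' @param disc_radius Lateral search disc radius in Angstrom (default 5).
#' @param coarse Coarse in-plane grid spacing (default 0.5).
#' @param refine_tol Final in-plane grid spacing (default 0.01).
#' @return A `pore_profile`: data frame `samples` (`z`, `cx`, `cy`, `cz`,
#'   `radius`, `blocked`), with `min_radius`, `z_at_min` and `mode`.
#' @export
pore_profile <- function(model, axis, origin = NULL, slab = NULL,
                         mode = c("whole", "core", "polyA"), step = 0.25,
                         disc_radius = 5, coarse = 0.5, refine_tol = 0.01) {
  mode <- match.arg(mode)
  if (!inherits(model, "structure_model") || nrow(model$atoms) == 0)
    pe_stop("empty structure model", "pe_empty_structure")
  axis <- unitv(axis)
  xyz <- coords(model)
  vdw <- model$atoms$vdw
  if (is.null(origin)) origin <- colMeans(xyz)
  fr <- axis_frame(axis)
  ax <- axial_coord(xyz, axis, origin)
  if (is.null(slab)) slab <- range(ax)
  zs <- seq(slab[1], slab[2], by = step)
  # in-plane atom coordinates
  d <- sweep(xyz, 2, origin)
  px <- as.numeric(d %*% fr$e1)
  py <- as.numeric(d %*% fr$e2)

  disc <- expand.grid(dx = seq(-disc_radius, disc_radius, by = coarse),
                      dy = seq(-disc_radius, disc_radius, by = coarse))
  disc <- disc[disc$dx^2 + disc$dy^2 <= disc_radius^2, ]
  disc <- rbind(data.frame(dx = 0, dy = 0), disc)  # axis always a candidate

  clearance <- function(cx, cy, z, sel) {
    dz2 <- (ax[sel] - z)^2
    min(sqrt((px[sel] - cx)^2 + (py[sel] - cy)^2 + dz2) - vdw[sel])
  }
  n_z <- length(zs)
  rad <- numeric(n_z); cxs <- numeric(n_z); cys <- numeric(n_z)
  max_vdw <- max(vdw)
  for (iz in seq_along(zs)) {
    z <- zs[iz]
    sel <- which(abs(ax - z) < disc_radius + max_vdw + 12)
    if (length(sel) == 0) { rad[iz] <- disc_radius; next }
    # coarse grid (vectorised over candidate centres)
    dz2 <- (ax[sel] - z)^2
    coarse_cl <- vapply(seq_len(nrow(disc)), function(g)
      min(sqrt((px[sel] - disc$dx[g])^2 + (py[sel] - disc$dy[g])^2 + dz2) -
            vdw[sel]), numeric(1))
    # local refinement (successively finer 5x5 grids, within the disc)
    # from the three best coarse candidates, so the global basin is found
    # even when several near-optimal pockets compete
    refine <- function(bx, by, best) {
      h <- coarse / 2
      while (h >= refine_tol) {
        off <- h * (-2:2)
        for (ox in off) for (oy in off) {
          nx <- bx + ox; ny <- by + oy
          if (nx^2 + ny^2 > disc_radius^2 + 1e-12) next
          cl <- clearance(nx, ny, z, sel)
          if (cl > best) { best <- cl; bx <- nx; by <- ny }
        }
        h <- h / 2
      }
      c(best, bx, by)
    }
    starts <- utils::head(order(coarse_cl, decreasing = TRUE), 3)
    cand <- vapply(starts, function(g)
      refine(disc$dx[g], disc$dy[g], coarse_cl[g]), numeric(3))
    w <- which.max(cand[1, ])
    rad[iz] <- cand[1, w]; cxs[iz] <- cand[2, w]; cys[iz] <- cand[3, w]
  }
  blocked <- rad < 0
  rad[blocked] <- 0
  centers <- matrix(origin, n_z, 3, byrow = TRUE) +
    outer(zs, fr$axis) + outer(cxs, fr$e1) + outer(cys, fr$e2)
  imin <- which.min(rad)
  structure(list(
    samples = data.frame(z = zs, cx = centers[, 1], cy = centers[, 2],
                         cz = centers[, 3], radius = rad,
                         blocked = blocked),
    min_radius = rad[imin], z_at_min = zs[imin], mode = mode
  ), class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat(sprintf("<pore_profile> mode %s: min radius %.2f A at z = %.2f A (%d slices%s)\n",
              x$mode, x$min_radius, x$z_at_min, nrow(x$samples),
              if (any(x$samples$blocked)) ", some blocked" else ""))
  invisible(x)
}

#' @export
plot.pore_profile <- function(x, ...) {
  graphics::plot(x$samples$z, x$samples$radius, type = "l",
                 xlab = "axial position (A)", ylab = "pore radius (A)", ...)
  graphics::abline(h = x$min_radius, lty = 2, col = "grey40")
  invisible(x)
}

#' Reduce a structure to its poly-alanine backbone
#'
#' Every residue keeps only N, CA, C, O and CB (glycine gains no atoms).
#' Original residue identities are recorded in the `orig_residue` column of
#' the atom table; residue names become ALA (GLY stays GLY).
#'
#' @param model A `structure_model`.
#' @return A `structure_model`.
#' @export
polyalanine <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  keep <- a$atom_name %in% c("N", "CA", "C", "O", "CB")
  a <- a[keep, , drop = FALSE]
  a$orig_residue <- a$residue_name
  a$residue_name <- ifelse(a$residue_name == "GLY", "GLY", "ALA")
  new_structure_model(a, paste0(model$source_id, "_polyA"),
                      model$model_number, model$chain_id,
                      n_gaps = model$n_gaps)
}

#' Whole / core / poly-alanine pore analysis of an annotated structure
#'
#' Convenience wrapper computing the three standard profiles using the axis
#' and slab of the annotation.
#'
#' @param model A `structure_model`.
#' @param annotation Its `topology_annotation`.
#' @param ... Passed to [pore_profile()].
#' @return Named list of `pore_profile`s (`whole`, `core`, `polyA`).
#' @export
pore_analysis <- function(model, annotation, ...) {
  axis <- attr(annotation, "axis")
  origin <- attr(annotation, "origin")
  slab <- attr(annotation, "slab")
  core <- extract_core(model, annotation)
  list(
    whole = pore_profile(model, axis, origin, slab, mode = "whole", ...),
    core = pore_profile(core, axis, origin, slab, mode = "core", ...),
    polyA = pore_profile(polyalanine(core), axis, origin, slab,
                         mode = "polyA", ...))
}
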