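# Interface geometry and cavity metrics: centroid distance, Shrake-Rupley
# SASA, buried-surface contact area, grid-based pocket volume.

#' Default van der Waals radii (Bondi-type, by element)
#'
#' @param default radius in Angstrom for elements not in the table.
#' @return named numeric vector of radii (Angstrom).
#' @export
default_radii <- function(default = 1.70) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  attr(r, "default") <- default
  r
}

#' Read a van der Waals radii table
#'
#' Two-column delimited file `element,radius` (Angstrom) overriding the
#' built-in set.
#'
#' @param path file path.
#' @return named numeric vector of radii.
#' @export
read_radii <- function(path) {
  df <- read_delim_checked(path, c("element", "radius"), "radii table")
  if (any(df$radius <= 0)) stop("radii must be positive")
  r <- stats::setNames(as.numeric(df$radius), toupper(df$element))
  attr(r, "default") <- attr(default_radii(), "default")
  r
}

atom_radii <- function(topology, radii) {
  el <- toupper(topology$element)
  r <- radii[el]
  miss <- is.na(r)
  if (any(miss)) {
    dflt <- attr(radii, "default")
    if (is.null(dflt))
      stop("element(s) missing from radii table: ",
           paste(unique(el[miss]), collapse = ", "))
    r[miss] <- dflt
  }
  unname(r)
}

# Deterministic quasi-uniform unit-sphere quadrature (golden-spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  s <- sqrt(pmax(1 - z^2, 0))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Distance between the geometric centres of two atom sets
#'
#' @param coords `n x 3` coordinate matrix (Angstrom), e.g. from
#'   [get_frame()].
#' @param sel_a,sel_b nonempty integer atom index vectors.
#' @return distance in Angstrom.
#' @export
centroid_distance <- function(coords, sel_a, sel_b) {
  if (length(sel_a) == 0L || length(sel_b) == 0L)
    stop("centroid_distance: empty atom selection")
  sqrt(sum((colMeans(coords[sel_a, , drop = FALSE]) -
              colMeans(coords[sel_b, , drop = FALSE]))^2))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Quasi-uniform test points are placed on every atom's solvent-expanded
#' sphere (radius + probe); a point is exposed iff it lies outside every
#' other expanded sphere, and the atom's area is the exposed fraction of
#' `4*pi*(r+probe)^2`.
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param topology matching ensemble topology (supplies elements), or a
#'   numeric vector of per-atom radii.
#' @param radii radii table from [default_radii()] / [read_radii()].
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points quadrature points per atom (default 960).
#' @param subset optional atom indices to restrict the system to.
#' @return numeric vector of per-atom areas (Angstrom^2) with attribute
#'   `total`.
#' @export
sasa <- function(coords, topology, radii = default_radii(), probe = 1.4,
                 n_points = 960L, subset = NULL) {
  r <- if (is.numeric(topology)) topology else atom_radii(topology, radii)
  if (!is.null(subset)) {
    coords <- coords[subset, , drop = FALSE]
    r <- r[subset]
  }
  n <- nrow(coords)
  if (n == 0L) stop("sasa: no atoms")
  re <- r + probe
  pts <- sphere_points(n_points)
  areas <- numeric(n)
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (re[i] + re)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * re[i]^2
      next
    }
    p <- sweep(pts * re[i], 2L, coords[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    # nearest occluders first: most points get rejected early
    nb <- nb[order(d2[i, nb])]
    for (j in nb) {
      if (!any(exposed)) break
      idx <- which(exposed)
      dx <- p[idx, 1L] - coords[j, 1L]
      dy <- p[idx, 2L] - coords[j, 2L]
      dz <- p[idx, 3L] - coords[j, 3L]
      exposed[idx[dx * dx + dy * dy + dz * dz < re[j]^2]] <- FALSE
    }
    areas[i] <- 4 * pi * re[i]^2 * sum(exposed) / n_points
  }
  attr(areas, "total") <- sum(areas)
  areas
}

#' Buried-surface contact area between two chains
#'
#' Half the solvent-accessible area buried on complex formation:
#' `(SASA(A) + SASA(B) - SASA(A+B)) / 2`. Negative values (possible only as
#' quadrature noise) are floored at zero with a warning.
#'
#' @param coords `n x 3` coordinate matrix for the full system.
#' @param topology matching topology.
#' @param chain_a,chain_b disjoint nonempty atom index vectors.
#' @inheritParams sasa
#' @return contact area in Angstrom^2.
#' @export
contact_area <- function(coords, topology, chain_a, chain_b,
                         radii = default_radii(), probe = 1.4,
                         n_points = 960L) {
  if (length(chain_a) == 0L || length(chain_b) == 0L)
    stop("contact_area: empty chain selection")
  if (length(intersect(chain_a, chain_b)) > 0L)
    stop("contact_area: chain selections overlap")
  r <- if (is.numeric(topology)) topology else atom_radii(topology, radii)
  a <- attr(sasa(coords, r, probe = probe, n_points = n_points,
                 subset = chain_a), "total")
  b <- attr(sasa(coords, r, probe = probe, n_points = n_points,
                 subset = chain_b), "total")
  ab <- attr(sasa(coords, r, probe = probe, n_points = n_points,
                  subset = c(chain_a, chain_b)), "total")
  ca <- (a + b - ab) / 2
  if (ca < 0) {
    warning("contact area slightly negative (quadrature noise); floored at 0")
    ca <- 0
  }
  ca
}

#' Grid-based pocket volume
#'
#' POVME-style inclusion-sphere grid count: a regular grid is laid over the
#' inclusion sphere and a grid point contributes `spacing^3` iff it lies
#' outside every solvent-expanded protein atom sphere.
#'
#' @param coords `n x 3` protein coordinates (Angstrom).
#' @param topology matching topology (or per-atom radii vector).
#' @param center sphere centre: numeric length-3, or `NULL` to use the
#'   centroid of `lining` atoms.
#' @param radius inclusion-sphere radius (Angstrom), must exceed `spacing`.
#' @param lining optional atom indices of the pocket-lining residues (used
#'   for the default centre).
#' @param spacing grid spacing in Angstrom (default 0.5).
#' @param radii radii table.
#' @param probe probe radius added to each atom sphere (default 1.4).
#' @return pocket volume in Angstrom^3.
#' @export
pocket_volume <- function(coords, topology, center = NULL, radius = 8,
                          lining = NULL, spacing = 0.5,
                          radii = default_radii(), probe = 1.4) {
  if (radius <= spacing) stop("inclusion radius must exceed grid spacing")
  if (is.null(center)) {
    if (is.null(lining))
      stop("either an explicit center or lining atoms are required")
    center <- colMeans(coords[lining, , drop = FALSE])
  }
  g1 <- seq(-radius, radius, by = spacing)
  grid <- as.matrix(expand.grid(x = g1 + center[1L], y = g1 + center[2L],
                                z = g1 + center[3L]))
  inside <- rowSums(sweep(grid, 2L, center)^2) <= radius^2
  grid <- grid[inside, , drop = FALSE]
  if (nrow(grid) == 0L) stop("inclusion sphere contains no grid points")
  r <- if (is.numeric(topology)) topology else atom_radii(topology, radii)
  re2 <- (r + probe)^2
  # only atoms whose expanded sphere can reach the inclusion sphere matter
  reach <- rowSums(sweep(coords, 2L, center)^2) <= (radius + sqrt(max(re2)))^2
  occ <- rep(FALSE, nrow(grid))
  for (a in which(reach)) {
    dx <- grid[, 1L] - coords[a, 1L]
    dy <- grid[, 2L] - coords[a, 2L]
    dz <- grid[, 3L] - coords[a, 3L]
    occ <- occ | (dx * dx + dy * dy + dz * dz < re2[a])
  }
  sum(!occ) * spacing^3
}
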