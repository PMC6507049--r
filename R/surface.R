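# Golden-spiral (Fibonacci) point set on the unit sphere: deterministic,
# near-uniform, so surfaces are bit-reproducible without a random seed.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta), y = sin(phi) * sin(theta), z = cos(phi))
}

#' Build a solvent-accessible dot surface
#'
#' Shrake-Rupley-style construction: each atom's sphere is expanded by the
#' probe radius and sampled with a deterministic golden-spiral point set;
#' dots falling strictly inside any other atom's expanded sphere are
#' removed. Each surviving dot carries an area of
#' \eqn{4\pi(r+probe)^2/dots\_per\_atom}, so total dot area approximates the
#' solvent-accessible surface area.
#'
#' @param s a \code{protein_structure} with radii assigned
#'   (\code{\link{assign_charges}}).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param dots_per_atom sample points per atom sphere (default 256).
#' @return an object of class \code{dot_surface}: \code{dots} (data.frame
#'   x, y, z, atom, area, nx, ny, nz), \code{probe}, \code{dots_per_atom};
#'   the neighbour graph is added by \code{\link{link_neighbours}}.
#' @export
build_dot_surface <- function(s, probe = 1.4, dots_per_atom = 256) {
  at <- s$atoms
  if (nrow(at) == 0) stop("structure has no atoms")
  if (probe < 0) stop("probe radius must be >= 0")
  if (any(is.na(at$radius))) {
    stop("atom radii missing; run assign_charges() first")
  }
  unit <- fibonacci_sphere(dots_per_atom)
  rex <- at$radius + probe
  n <- nrow(at)
  m <- dots_per_atom
  pts <- matrix(0, n * m, 3)
  parent <- rep(seq_len(n), each = m)
  for (i in seq_len(n)) {
    rows <- ((i - 1) * m + 1):(i * m)
    pts[rows, 1] <- at$x[i] + rex[i] * unit[, 1]
    pts[rows, 2] <- at$y[i] + rex[i] * unit[, 2]
    pts[rows, 3] <- at$z[i] + rex[i] * unit[, 3]
  }
  keep <- .cp_exposed_dots(as.matrix(at[, c("x", "y", "z")]), rex, pts, parent)
  pts <- pts[keep, , drop = FALSE]
  parent <- parent[keep]
  area <- 4 * pi * rex[parent]^2 / m
  normal <- (pts - as.matrix(at[parent, c("x", "y", "z")])) / rex[parent]
  dots <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                     atom = parent, area = area,
                     nx = normal[, 1], ny = normal[, 2], nz = normal[, 3])
  out <- list(dots = dots, probe = probe, dots_per_atom = dots_per_atom,
              neighbours = NULL, link_distance = NULL)
  class(out) <- "dot_surface"
  out
}

#' Total dot-surface area
#' @param surface a \code{dot_surface}.
#' @return total area, Angstrom^2.
#' @export
surface_area <- function(surface) sum(surface$dots$area)

#' Link neighbouring surface dots
#'
#' Two dots are adjacent iff their Euclidean distance is at most
#' \code{link_distance}. The default link distance is 2 x the mean
#' nearest-neighbour dot spacing, clamped to [0.5, 5] Angstrom, which keeps
#' patch connectivity stable across dot densities.
#'
#' @param surface a \code{dot_surface}.
#' @param link_distance adjacency cutoff in Angstrom; NULL for the auto
#'   rule.
#' @return the surface with \code{neighbours} (2-column index matrix) and
#'   \code{link_distance} filled in.
#' @export
link_neighbours <- function(surface, link_distance = NULL) {
  X <- as.matrix(surface$dots[, c("x", "y", "z")])
  if (is.null(link_distance)) {
    # mean nearest-neighbour spacing from the per-atom dot density:
    # area per dot a = 4 pi rex^2 / m  =>  spacing ~ sqrt(a)
    spacing <- sqrt(mean(surface$dots$area))
    link_distance <- min(5, max(0.5, 2 * spacing))
  }
  if (link_distance <= 0) stop("link_distance must be > 0")
  surface$neighbours <- .cp_pairs_within(X, link_distance)
  surface$link_distance <- link_distance
  surface
}

#' @export
print.dot_surface <- function(x, ...) {
  cat(sprintf("dot_surface: %d dots (probe %.2f A, %d dots/atom), area %.1f A^2\n",
              nrow(x$dots), x$probe, x$dots_per_atom, surface_area(x)))
  if (!is.null(x$neighbours)) {
    cat(sprintf("  neighbour graph: %d edges at link distance %.2f A\n",
                nrow(x$neighbours), x$link_distance))
  }
  invisible(x)
}
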