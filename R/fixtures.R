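# Deterministic toy-structure generators with analytic expectations, plus
# peptide backbone construction from CA guide paths.

# CA positions of an ideal alpha-helix: radius 2.3 A, rise 1.5 A/residue,
# 100 degrees/residue, right-handed about the axis direction.
helix_ca <- function(n, origin = c(0, 0, 0), axis = c(0, 0, 1), phase = 0,
                     radius = 2.3, rise = 1.5, twist = 100) {
  d <- axis / sqrt(sum(axis^2))
  e1 <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2], d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  k <- seq_len(n) - 1
  th <- (phase + twist * k) * pi / 180
  t(vapply(seq_len(n), function(i)
    origin + rise * k[i] * d + radius * (cos(th[i]) * e1 + sin(th[i]) * e2),
    numeric(3)))
}

# Natural-cubic-spline curve through 3D control points, resampled at m
# equal arc-length fractions strictly between the two endpoints.
spline_interior <- function(ctrl, m, nsamp = 600) {
  u <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  u <- u / max(u)
  tt <- seq(0, 1, length.out = nsamp)
  P <- cbind(stats::spline(u, ctrl[, 1], xout = tt)$y,
             stats::spline(u, ctrl[, 2], xout = tt)$y,
             stats::spline(u, ctrl[, 3], xout = tt)$y)
  s <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
  s <- s / max(s)
  want <- seq_len(m) / (m + 1)
  P[vapply(want, function(w) which.min(abs(s - w)), 1L), , drop = FALSE]
}

# Approximate backbone frames along a CA guide path: N and C placed in the
# local tangent/curvature plane (N-CA 1.46, CA-C 1.52, N-CA-C ~108 deg),
# O (and terminal OXT) from internal coordinates.
backbone_from_ca <- function(ca) {
  n <- nrow(ca)
  N <- C <- O <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    prev <- ca[max(1, i - 1), ]
    nxt <- ca[min(n, i + 1), ]
    t <- nxt - prev
    if (sqrt(sum(t^2)) < 1e-6) t <- c(1, 0, 0)  # single-residue chain
    t <- t / sqrt(sum(t^2))
    curv <- (prev - ca[i, ]) + (nxt - ca[i, ])
    cn <- sqrt(sum(curv^2))
    if (cn < 1e-6) {
      curv <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
      curv <- curv - sum(curv * t) * t
      cn <- sqrt(sum(curv^2))
    }
    curv <- curv / cn
    uN <- -t + 0.72 * curv
    uN <- uN / sqrt(sum(uN^2))
    uC <- t + 0.72 * curv
    uC <- uC / sqrt(sum(uC^2))
    N[i, ] <- ca[i, ] + 1.46 * uN
    C[i, ] <- ca[i, ] + 1.52 * uC
    O[i, ] <- place_atom(N[i, ], ca[i, ], C[i, ], 1.23, 120.5, 135)
  }
  list(N = N, CA = ca, C = C, O = O)
}

#' Build a peptide structure along a CA guide path
#'
#' Threads a sequence onto backbone frames derived from CA positions;
#' sidechains are built from ideal internal geometry in the extended
#' (all-anti) rotamer.
#'
#' @param sequence one-letter sequence string.
#' @param ca numeric matrix of CA positions (n x 3, Angstrom), n matching
#'   the sequence length.
#' @param chain chain id.
#' @param resno_start first residue number.
#' @return an uncharged \code{protein_structure} (run
#'   \code{\link{assign_charges}} before surface work).
#' @export
build_peptide <- function(sequence, ca, chain = "A", resno_start = 1) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) != nrow(ca)) stop("sequence length does not match CA count")
  bb <- backbone_from_ca(ca)
  rows <- vector("list", length(aa))
  for (i in seq_along(aa)) {
    r3 <- aa_three(aa[i])
    resno <- resno_start + i - 1
    bbdf <- data.frame(
      name = c("N", "CA", "C", "O"),
      x = c(bb$N[i, 1], bb$CA[i, 1], bb$C[i, 1], bb$O[i, 1]),
      y = c(bb$N[i, 2], bb$CA[i, 2], bb$C[i, 2], bb$O[i, 2]),
      z = c(bb$N[i, 3], bb$CA[i, 3], bb$C[i, 3], bb$O[i, 3]),
      elem = c("N", "C", "C", "O"), stringsAsFactors = FALSE)
    sc <- build_sidechain(r3, bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    if (i == length(aa)) {
      oxt <- place_atom(bb$N[i, ], bb$CA[i, ], bb$C[i, ], 1.25, 120.5, -45)
      bbdf <- rbind(bbdf, data.frame(name = "OXT", x = oxt[1], y = oxt[2],
                                     z = oxt[3], elem = "O",
                                     stringsAsFactors = FALSE))
    }
    df <- rbind(bbdf, sc)
    rows[[i]] <- data.frame(serial = 0L, name = df$name, elem = df$elem,
                            resid = r3, chain = chain, resno = resno,
                            x = df$x, y = df$y, z = df$z,
                            radius = NA_real_, charge = 0,
                            stringsAsFactors = FALSE)
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  new_structure(at)
}

# Closed-form SASA of two intersecting spheres with radii r1, r2 (already
# probe-expanded) at centre distance d.
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  if (d <= abs(r1 - r2)) return(4 * pi * max(r1, r2)^2)
  h1 <- r1 - (d^2 + r1^2 - r2^2) / (2 * d)
  h2 <- r2 - (d^2 + r2^2 - r1^2) / (2 * d)
  (4 * pi * r1^2 - 2 * pi * r1 * h1) + (4 * pi * r2^2 - 2 * pi * r2 * h2)
}

#' Deterministic toy structures with analytic expectations
#'
#' Generators for the test corpus: every toy is emitted as plausible PDB
#' residues (so no parser special-casing exists) together with a record of
#' expected values computed by closed form at generation time.
#'
#' \describe{
#'   \item{single_sphere}{one atom of radius \code{radius}, optional
#'     central charge; expected SASA \eqn{4\pi(r+probe)^2} and potential at
#'     listed probe distances.}
#'   \item{dumbbell}{two atoms at \code{separation}; expected SASA from the
#'     two-sphere closed form; optional charges per atom.}
#'   \item{helix}{ideal poly-Ala alpha-helix of \code{n} residues with
#'     programmable substitutions (e.g. one Lys).}
#'   \item{charge_lattice}{a cubic grid of neutral atoms with charges
#'     placed on listed node indices; used for patch-topology tests.}
#' }
#'
#' @param kind toy kind (see Details).
#' @param radius,charge single_sphere parameters.
#' @param separation,radii,charges dumbbell parameters.
#' @param n,substitutions helix parameters; substitutions as
#'   \code{c("10" = "K")} (residue number to one-letter code).
#' @param nside,spacing,lattice_charges charge_lattice parameters;
#'   \code{lattice_charges} as data.frame(index, q).
#' @param probe probe radius used for the expected-SASA record.
#' @return object of class \code{toy_structure}: \code{kind}, \code{pdb}
#'   (PDB text), \code{structure} (parsed, radii/charges assigned),
#'   \code{expected} (named list of analytic values).
#' @export
make_toy <- function(kind = c("single_sphere", "dumbbell", "helix",
                              "charge_lattice"),
                     radius = 1.9, charge = 0,
                     separation = 4, radii = c(1.9, 1.9), charges = c(0, 0),
                     n = 20, substitutions = NULL,
                     nside = 3, spacing = 6, lattice_charges = NULL,
                     probe = 1.4) {
  kind <- match.arg(kind)
  if (kind == "single_sphere") {
    at <- data.frame(serial = 1L, name = "CA", elem = "C", resid = "GLY",
                     chain = "A", resno = 1L, x = 0, y = 0, z = 0,
                     radius = radius, charge = charge,
                     stringsAsFactors = FALSE)
    s <- new_structure(at)
    expected <- list(
      sasa = 4 * pi * (radius + probe)^2,
      potential_mV_at_10A_vacuum_eps78.4 =
        .K_COUL_MV * charge / (78.4 * 10),
      n_atoms = 1L)
  } else if (kind == "dumbbell") {
    if (separation <= 0) stop("separation must be > 0")
    at <- data.frame(serial = 1:2, name = "CA", elem = "C", resid = "GLY",
                     chain = "A", resno = 1:2,
                     x = c(0, separation), y = 0, z = 0,
                     radius = radii, charge = charges,
                     stringsAsFactors = FALSE)
    s <- new_structure(at)
    expected <- list(
      sasa = two_sphere_area(radii[1] + probe, radii[2] + probe, separation),
      n_atoms = 2L)
  } else if (kind == "helix") {
    seqv <- rep("A", n)
    if (!is.null(substitutions)) {
      idx <- as.integer(names(substitutions))
      if (any(idx < 1 | idx > n)) stop("substitution index out of range")
      seqv[idx] <- toupper(unname(substitutions))
    }
    s <- build_peptide(paste(seqv, collapse = ""), helix_ca(n))
    # capped helix: no terminal charges, so the charge layout is exactly
    # the programmed sidechain placements
    s <- assign_charges(s, termini = FALSE)
    expected <- list(n_residues = n, n_chains = 1L,
                     net_charge = sum(formal_charge_aa(seqv)),
                     n_pos_patches_25mV = sum(formal_charge_aa(seqv) > 0))
  } else {
    g <- seq_len(nside) - 1
    grid <- as.matrix(expand.grid(x = g, y = g, z = g)) * spacing
    nat <- nrow(grid)
    q <- rep(0, nat)
    if (!is.null(lattice_charges)) {
      if (any(lattice_charges$index < 1 | lattice_charges$index > nat)) {
        stop("lattice charge index out of range")
      }
      q[lattice_charges$index] <- lattice_charges$q
    }
    at <- data.frame(serial = seq_len(nat), name = "CA", elem = "C",
                     resid = "GLY", chain = "A", resno = seq_len(nat),
                     x = grid[, 1], y = grid[, 2], z = grid[, 3],
                     radius = 1.9, charge = q, stringsAsFactors = FALSE)
    s <- new_structure(at)
    expected <- list(n_atoms = nat)
  }
  out <- list(kind = kind, pdb = write_structure(s), structure = s,
              expected = expected, probe = probe)
  class(out) <- "toy_structure"
  out
}

#' @export
print.toy_structure <- function(x, ...) {
  cat(sprintf("toy_structure '%s': %d atoms\n", x$kind,
              nrow(x$structure$atoms)))
  str(x$expected, give.attr = FALSE)
  invisible(x)
}
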