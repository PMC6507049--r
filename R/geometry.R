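# Internal-coordinate construction (NeRF): place atom D given positions of
# A, B, C, the C-D bond length, the B-C-D angle and the A-B-C-D dihedral.

place_atom <- function(A, B, C, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) {  # colinear A,B,C: pick any perpendicular
    n <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- n - sum(n * bc) * bc
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

dihedral_angle <- function(A, B, C, D) {
  b1 <- B - A; b2 <- C - B; b3 <- D - C
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Sidechain internal-coordinate templates. Each atom: name, three reference
# atoms (by name, already placed), bond (A), angle (deg), and a dihedral:
# either a number or list(chi = k, offset = deg). Chirality of CB follows
# the L-amino-acid convention (dihedral N-C-CA-CB = +122.6 deg).

.CB <- list(name = "CB", ref = c("N", "C", "CA"), bond = 1.52,
            angle = 110.4, dih = 122.6)

sc_atom <- function(name, ref, bond, angle, dih) {
  list(name = name, ref = ref, bond = bond, angle = angle, dih = dih)
}
chi <- function(k, offset = 0) list(chi = k, offset = offset)

.SIDECHAIN_TEMPLATES <- list(
  GLY = list(),
  ALA = list(.CB),
  SER = list(.CB, sc_atom("OG", c("N", "CA", "CB"), 1.42, 110.5, chi(1))),
  CYS = list(.CB, sc_atom("SG", c("N", "CA", "CB"), 1.81, 113.8, chi(1))),
  THR = list(.CB,
             sc_atom("OG1", c("N", "CA", "CB"), 1.43, 109.5, chi(1)),
             sc_atom("CG2", c("N", "CA", "CB"), 1.52, 110.5, chi(1, -120))),
  VAL = list(.CB,
             sc_atom("CG1", c("N", "CA", "CB"), 1.52, 110.5, chi(1)),
             sc_atom("CG2", c("N", "CA", "CB"), 1.52, 110.5, chi(1, 122))),
  LEU = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.53, 116.3, chi(1)),
             sc_atom("CD1", c("CA", "CB", "CG"), 1.52, 110.5, chi(2)),
             sc_atom("CD2", c("CA", "CB", "CG"), 1.52, 110.5, chi(2, 122))),
  ILE = list(.CB,
             sc_atom("CG1", c("N", "CA", "CB"), 1.53, 110.4, chi(1)),
             sc_atom("CG2", c("N", "CA", "CB"), 1.53, 110.5, chi(1, -122)),
             sc_atom("CD1", c("CA", "CB", "CG1"), 1.52, 113.8, chi(2))),
  MET = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.52, 114.1, chi(1)),
             sc_atom("SD", c("CA", "CB", "CG"), 1.80, 112.7, chi(2)),
             sc_atom("CE", c("CB", "CG", "SD"), 1.79, 100.9, chi(3))),
  PRO = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.49, 104.5, 30),
             sc_atom("CD", c("CA", "CB", "CG"), 1.50, 105.5, -35)),
  PHE = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.50, 113.8, chi(1)),
             sc_atom("CD1", c("CA", "CB", "CG"), 1.39, 120.8, chi(2)),
             sc_atom("CD2", c("CA", "CB", "CG"), 1.39, 120.8, chi(2, 180)),
             sc_atom("CE1", c("CB", "CG", "CD1"), 1.39, 120.0, 180),
             sc_atom("CE2", c("CB", "CG", "CD2"), 1.39, 120.0, 180),
             sc_atom("CZ", c("CG", "CD1", "CE1"), 1.39, 120.0, 0)),
  TYR = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.51, 113.8, chi(1)),
             sc_atom("CD1", c("CA", "CB", "CG"), 1.39, 120.8, chi(2)),
             sc_atom("CD2", c("CA", "CB", "CG"), 1.39, 120.8, chi(2, 180)),
             sc_atom("CE1", c("CB", "CG", "CD1"), 1.39, 120.0, 180),
             sc_atom("CE2", c("CB", "CG", "CD2"), 1.39, 120.0, 180),
             sc_atom("CZ", c("CG", "CD1", "CE1"), 1.39, 120.0, 0),
             sc_atom("OH", c("CD1", "CE1", "CZ"), 1.38, 119.9, 180)),
  TRP = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.50, 113.6, chi(1)),
             sc_atom("CD1", c("CA", "CB", "CG"), 1.37, 126.9, chi(2)),
             sc_atom("CD2", c("CA", "CB", "CG"), 1.43, 126.7, chi(2, 180)),
             sc_atom("NE1", c("CB", "CG", "CD1"), 1.38, 110.2, 180),
             sc_atom("CE2", c("CB", "CG", "CD2"), 1.41, 107.2, 180),
             sc_atom("CE3", c("CB", "CG", "CD2"), 1.40, 133.9, 0),
             sc_atom("CZ2", c("CG", "CD2", "CE2"), 1.40, 122.4, 180),
             sc_atom("CZ3", c("CG", "CD2", "CE3"), 1.39, 118.7, 180),
             sc_atom("CH2", c("CD2", "CE2", "CZ2"), 1.37, 117.5, 0)),
  ASP = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.52, 113.1, chi(1)),
             sc_atom("OD1", c("CA", "CB", "CG"), 1.25, 118.5, chi(2)),
             sc_atom("OD2", c("CA", "CB", "CG"), 1.25, 118.5, chi(2, 180))),
  ASN = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.52, 112.7, chi(1)),
             sc_atom("OD1", c("CA", "CB", "CG"), 1.23, 120.9, chi(2)),
             sc_atom("ND2", c("CA", "CB", "CG"), 1.33, 116.5, chi(2, 180))),
  GLU = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.52, 114.1, chi(1)),
             sc_atom("CD", c("CA", "CB", "CG"), 1.52, 112.6, chi(2)),
             sc_atom("OE1", c("CB", "CG", "CD"), 1.25, 118.5, chi(3)),
             sc_atom("OE2", c("CB", "CG", "CD"), 1.25, 118.5, chi(3, 180))),
  GLN = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.52, 114.1, chi(1)),
             sc_atom("CD", c("CA", "CB", "CG"), 1.52, 112.6, chi(2)),
             sc_atom("OE1", c("CB", "CG", "CD"), 1.23, 120.9, chi(3)),
             sc_atom("NE2", c("CB", "CG", "CD"), 1.33, 116.5, chi(3, 180))),
  LYS = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.52, 114.1, chi(1)),
             sc_atom("CD", c("CA", "CB", "CG"), 1.52, 111.3, chi(2)),
             sc_atom("CE", c("CB", "CG", "CD"), 1.52, 111.3, chi(3)),
             sc_atom("NZ", c("CG", "CD", "CE"), 1.49, 111.9, chi(4))),
  ARG = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.52, 114.1, chi(1)),
             sc_atom("CD", c("CA", "CB", "CG"), 1.52, 111.3, chi(2)),
             sc_atom("NE", c("CB", "CG", "CD"), 1.46, 112.0, chi(3)),
             sc_atom("CZ", c("CG", "CD", "NE"), 1.33, 124.2, chi(4)),
             sc_atom("NH1", c("CD", "NE", "CZ"), 1.33, 120.0, 0),
             sc_atom("NH2", c("CD", "NE", "CZ"), 1.33, 120.0, 180)),
  HIS = list(.CB,
             sc_atom("CG", c("N", "CA", "CB"), 1.50, 113.8, chi(1)),
             sc_atom("ND1", c("CA", "CB", "CG"), 1.38, 122.7, chi(2)),
             sc_atom("CD2", c("CA", "CB", "CG"), 1.36, 131.1, chi(2, 180)),
             sc_atom("CE1", c("CB", "CG", "ND1"), 1.32, 109.2, 180),
             sc_atom("NE2", c("CB", "CG", "CD2"), 1.37, 107.1, 180))
)

# Number of variable chi angles per residue type
n_chi <- function(resid) {
  tpl <- .SIDECHAIN_TEMPLATES[[resid]]
  if (is.null(tpl) || length(tpl) == 0) return(0L)
  mx <- 0L
  for (a in tpl) if (is.list(a$dih)) mx <- max(mx, a$dih$chi)
  mx
}

# Small deterministic rotamer set: staggered chi1/chi2 combinations, later
# chis extended. Order fixed so clash-count ties resolve reproducibly.
rotamer_set <- function(resid) {
  nc <- n_chi(resid)
  if (nc == 0) return(list(numeric(0)))
  base <- c(-60, 180, 60)
  if (nc == 1) return(lapply(base, function(a) a))
  rts <- list()
  for (a in base) for (b in base) {
    rts[[length(rts) + 1]] <- c(a, b, rep(180, nc - 2))[seq_len(nc)]
  }
  rts
}

# Build sidechain coordinates for one residue given backbone N/CA/C
# positions (3-vectors) and chi angles. Returns data.frame name/x/y/z/elem.
build_sidechain <- function(resid, N, CA, C, chis = NULL) {
  tpl <- .SIDECHAIN_TEMPLATES[[resid]]
  if (is.null(tpl)) stop("no sidechain template for ", resid)
  if (length(tpl) == 0) {
    return(data.frame(name = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), elem = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(chis)) chis <- rep(180, n_chi(resid))
  pos <- list(N = N, CA = CA, C = C)
  out <- vector("list", length(tpl))
  for (k in seq_along(tpl)) {
    a <- tpl[[k]]
    dih <- if (is.list(a$dih)) chis[a$dih$chi] + a$dih$offset else a$dih
    p <- place_atom(pos[[a$ref[1]]], pos[[a$ref[2]]], pos[[a$ref[3]]],
                    a$bond, a$angle, dih)
    pos[[a$name]] <- p
    out[[k]] <- data.frame(name = a$name, x = p[1], y = p[2], z = p[3],
                           elem = guess_element(a$name),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
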