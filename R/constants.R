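# Unit discipline: lengths in Angstrom, potentials in mV, energies in kJ/mol.
# All conversion constants are pinned here and nowhere else.

# e/(4*pi*eps0) expressed as mV * Angstrom per elementary charge
.K_COUL_MV <- 14399.6451

# N_A * e^2/(4*pi*eps0) expressed as kJ * Angstrom / mol per unit-charge pair
.K_COUL_KJ <- 1389.35458

# kappa[1/Angstrom] = .K_KAPPA * sqrt(I[mol/L] / (eps_r/78.4 * T/298.15)) at
# fixed eps_r*T product; computed exactly in debye_kappa() from SI constants.
.NA_CONST <- 6.02214076e23
.E_CHARGE <- 1.602176634e-19
.EPS0 <- 8.8541878128e-12
.KB <- 1.380649e-23
.R_GAS_KJ <- 8.314462618e-3  # kJ/mol/K

# United-atom van der Waals radii (Angstrom), by element
.RADII <- c(C = 1.9, N = 1.7, O = 1.5, S = 1.85, H = 1.0, P = 1.9)
.RADIUS_DEFAULT <- 1.8

# Model (intrinsic) pKa values for titratable groups
.MODEL_PKA <- c(ASP = 4.0, GLU = 4.4, HIS = 6.3, LYS = 10.4, ARG = 12.0,
                TYR = 9.6, CYS = 8.3, NTERM = 7.5, CTERM = 3.8)

# Acid/base classification: acids are neutral protonated (q0 = -1),
# bases positive protonated (q0 = 0)
.SITE_Q0 <- c(ASP = -1, GLU = -1, HIS = 0, LYS = 0, ARG = 0,
              TYR = -1, CYS = -1, NTERM = 0, CTERM = -1)

.AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.AA1 <- structure(names(.AA3), names = .AA3)

aa_three <- function(one) {
  out <- .AA3[toupper(one)]
  if (any(is.na(out))) stop("unknown one-letter amino acid code: ",
                            paste(one[is.na(out)], collapse = ", "))
  unname(out)
}

aa_one <- function(three) {
  out <- .AA1[toupper(three)]
  out[is.na(out)] <- "X"
  unname(out)
}

# Formal sidechain charge at pH 7 (His neutral for the patch map)
.FORMAL_Q <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1, HIS = 0)

formal_charge_aa <- function(aa1) {
  q <- .FORMAL_Q[aa_three(aa1)]
  q[is.na(q)] <- 0
  unname(q)
}
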