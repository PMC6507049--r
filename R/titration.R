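# Protonation-state thermodynamics. Energy convention (one signed formula
# for acids and bases): protonation of site i costs
#   f_i(pH) = ln(10) RT (pH - pKa_int,i)   [kJ/mol]
# and site charges are q_i = q0_i + x_i with q0 = -1 for acids, 0 for
# bases, interacting through the screened-Coulomb matrix W. This recovers
# Henderson-Hasselbalch exactly for non-interacting sites.

#' Build the titratable-site model of a structure
#'
#' Sites: Asp, Glu, His, Lys, Arg, Tyr and free (non-disulphide) Cys
#' sidechains, plus each chain's N- and C-terminus. Each site carries a
#' model (intrinsic) pKa and a charge centre (centroid of its charge-model
#' atoms); the folded-state intrinsic pKa equals the model pKa, i.e. only
#' charge-charge interactions perturb titration. The pairwise interaction
#' matrix comes from \code{\link{interaction_matrix}}.
#'
#' @param s a charged \code{protein_structure}.
#' @param params \code{\link{es_params}}.
#' @return list with \code{sites} (data.frame chain, resno, type, pKa, q0,
#'   x, y, z) and \code{W} (kJ/mol).
#' @export
build_site_model <- function(s, params = es_params()) {
  at <- s$atoms
  ss <- s$disulfides
  if (is.null(ss)) ss <- find_disulfides(s)
  bonded_cys <- unique(c(paste(ss$chain1, ss$resno1),
                         paste(ss$chain2, ss$resno2)))
  model <- default_charge_model()
  centre_atoms <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                       HIS = c("ND1", "NE2"), LYS = "NZ",
                       ARG = c("NH1", "NH2"), TYR = "OH", CYS = "SG")
  rows <- list()
  add_site <- function(type, chain, resno, idx) {
    if (length(idx) == 0) return()
    rows[[length(rows) + 1]] <<- data.frame(
      chain = chain, resno = resno, type = type,
      pKa = unname(.MODEL_PKA[type]), q0 = unname(.SITE_Q0[type]),
      x = mean(at$x[idx]), y = mean(at$y[idx]), z = mean(at$z[idx]),
      stringsAsFactors = FALSE)
  }
  rkey <- paste(at$chain, at$resno)
  for (res in split(seq_len(nrow(at)), rkey)) {
    rn <- at$resid[res[1]]
    if (!rn %in% names(centre_atoms)) next
    ch <- at$chain[res[1]]; rno <- at$resno[res[1]]
    if (rn == "CYS" && paste(ch, rno) %in% bonded_cys) next
    idx <- res[at$name[res] %in% centre_atoms[[rn]]]
    if (length(idx) == 0) idx <- res[length(res)]
    add_site(rn, ch, rno, idx)
  }
  for (ch in unique(at$chain)) {
    ci <- which(at$chain == ch)
    r1 <- min(at$resno[ci]); rN <- max(at$resno[ci])
    add_site("NTERM", ch, r1, ci[at$resno[ci] == r1 & at$name[ci] == "N"])
    add_site("CTERM", ch, rN,
             ci[at$resno[ci] == rN & at$name[ci] %in% c("O", "OXT")])
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(0), resno = integer(0), type = character(0),
               pKa = numeric(0), q0 = numeric(0), x = numeric(0),
               y = numeric(0), z = numeric(0))
  sites <- sites[order(sites$chain, sites$resno, sites$type), ]
  rownames(sites) <- NULL
  W <- if (nrow(sites) > 0) interaction_matrix(sites, params) else
    matrix(0, 0, 0)
  list(sites = sites, W = W)
}

#' The non-interacting ("unfolded") counterpart of a site model
#'
#' Same sites and model pKas, interaction matrix set to zero: the estimated
#' unfolded-state set of interactions that is subtracted to obtain the
#' pH-dependent stability term.
#'
#' @param model a \code{\link{build_site_model}} result.
#' @return the model with \code{W} zeroed.
#' @export
unfolded_site_model <- function(model) {
  model$W <- matrix(0, nrow(model$sites), nrow(model$sites))
  model
}

.field_matrix <- function(sites, pH_grid, RT) {
  outer(sites$pKa, pH_grid, function(pk, ph) log(10) * RT * (ph - pk))
}

new_titration <- function(sites, pH_grid, fraction, G, method, RT,
                          seed = NA) {
  mean_q <- colSums(fraction + sites$q0)
  structure(list(sites = sites, pH = pH_grid, fraction = fraction,
                 mean_charge = mean_q, G = G, method = method, RT = RT,
                 seed = seed),
            class = "titration")
}

#' Exact titration by state enumeration
#'
#' Computes the exact partition function over all 2^N protonation states
#' at every pH grid point: per-site mean protonation fractions, mean net
#' charge and the free energy G(pH) = -RT ln Z(pH) (reference: the zero of
#' the site energy scale, shared between folded and unfolded models so
#' their difference is well defined).
#'
#' @param sites site data.frame from \code{\link{build_site_model}}.
#' @param W interaction matrix, kJ/mol.
#' @param pH_grid numeric vector of pH values (default 0 to 14 by 0.25).
#' @param temperature K.
#' @return a \code{titration} object.
#' @export
titrate_exact <- function(sites, W, pH_grid = seq(0, 14, 0.25),
                          temperature = 298.15) {
  n <- nrow(sites)
  if (n > 20) stop("exact enumeration refused for > 20 sites; use titrate_mc")
  RT <- .R_GAS_KJ * temperature
  if (n == 0) {
    return(new_titration(sites, pH_grid,
                         matrix(0, 0, length(pH_grid)),
                         rep(0, length(pH_grid)), "exact", RT))
  }
  M <- 2L^n
  states <- vapply(seq_len(n), function(i)
    bitwAnd(seq_len(M) - 1L, bitwShiftL(1L, i - 1L)) != 0L,
    logical(M))                      # M x n
  X <- t(states) * 1                 # n x M
  Q <- X + sites$q0
  inter <- colSums(Q * (W %*% Q)) / 2
  fmat <- .field_matrix(sites, pH_grid, RT)
  frac <- matrix(0, n, length(pH_grid))
  G <- numeric(length(pH_grid))
  for (p in seq_along(pH_grid)) {
    E <- as.numeric(crossprod(X, fmat[, p])) + inter
    Emin <- min(E)
    w <- exp(-(E - Emin) / RT)
    Z <- sum(w)
    frac[, p] <- as.numeric(X %*% (w / Z))
    G[p] <- Emin - RT * log(Z)
  }
  new_titration(sites, pH_grid, frac, G, "exact", RT)
}

#' Metropolis Monte Carlo titration
#'
#' Single-site-flip Metropolis sampling of protonation states at each pH
#' grid point. Free energy is recovered by thermodynamic integration of the
#' mean protonated count over pH,
#' \eqn{G(pH) = G(pH_0) + \ln(10) RT \int \langle N_{prot}\rangle\,dpH}
#' (trapezoidal on the grid), anchored at the acidic end of the grid by the
#' fully-protonated state energy, whose dominance there makes the anchor
#' error negligible and common to folded and unfolded models.
#'
#' @param sites,W,pH_grid,temperature as in \code{\link{titrate_exact}}.
#' @param sweeps post-burn-in Monte Carlo sweeps per pH (default 10000).
#' @param burn_in discarded initial sweeps (default 1000).
#' @param seed integer RNG seed (mandatory, for reproducibility).
#' @return a \code{titration} object.
#' @export
titrate_mc <- function(sites, W, pH_grid = seq(0, 14, 0.25), sweeps = 10000,
                       burn_in = 1000, seed, temperature = 298.15) {
  if (missing(seed)) stop("titrate_mc requires an explicit seed")
  if (sweeps < 1) stop("sweeps must be >= 1")
  n <- nrow(sites)
  RT <- .R_GAS_KJ * temperature
  if (n == 0) {
    return(new_titration(sites, pH_grid,
                         matrix(0, 0, length(pH_grid)),
                         rep(0, length(pH_grid)), "mc", RT, seed))
  }
  fmat <- .field_matrix(sites, pH_grid, RT)
  set.seed(seed)
  mc <- .cp_titrate_mc(W, sites$q0, fmat, RT, as.integer(sweeps),
                       as.integer(burn_in))
  # anchor: fully-protonated state at the acidic end of the grid
  qprot <- sites$q0 + 1
  E_anchor <- sum(fmat[, 1]) + sum(qprot * (W %*% qprot)) / 2
  nprot <- mc$mean_nprot
  G <- numeric(length(pH_grid))
  G[1] <- E_anchor
  if (length(pH_grid) > 1) {
    dph <- diff(pH_grid)
    incr <- log(10) * RT * dph * (nprot[-1] + nprot[-length(nprot)]) / 2
    G[-1] <- E_anchor + cumsum(incr)
  }
  new_titration(sites, pH_grid, mc$fraction, G, "mc", RT, seed)
}

#' @export
print.titration <- function(x, ...) {
  cat(sprintf("titration (%s): %d sites, pH %.2g..%.2g (%d points)\n",
              x$method, nrow(x$sites), min(x$pH), max(x$pH), length(x$pH)))
  i7 <- which.min(abs(x$pH - 7))
  cat(sprintf("  at pH %.2f: <Q> = %+.2f e, G = %.2f kJ/mol\n",
              x$pH[i7], x$mean_charge[i7], x$G[i7]))
  invisible(x)
}

#' @export
plot.titration <- function(x, what = c("charge", "fraction", "G"), ...) {
  what <- match.arg(what)
  if (what == "charge") {
    graphics::plot(x$pH, x$mean_charge, type = "l", xlab = "pH",
                   ylab = "mean net charge (e)", ...)
  } else if (what == "G") {
    graphics::plot(x$pH, x$G, type = "l", xlab = "pH",
                   ylab = "G (kJ/mol)", ...)
  } else {
    graphics::matplot(x$pH, t(x$fraction), type = "l", lty = 1,
                      xlab = "pH", ylab = "protonation fraction", ...)
  }
  invisible(x)
}

#' pH-dependent ionisable-group contribution to folded-state stability
#'
#' The folded-minus-unfolded free energy of the ionisable-group system at
#' a given pH: negative values are favourable (stabilising). Zero when the
#' folded and unfolded site models are identical.
#'
#' @param folded,unfolded \code{titration} results sharing the pH grid and
#'   site list.
#' @param pH evaluation pH (default 7.0).
#' @return object of class \code{ph_stability} with fields \code{pH} and
#'   \code{pHstab} (kJ/mol).
#' @export
ph_stability <- function(folded, unfolded, pH = 7.0) {
  if (length(folded$pH) != length(unfolded$pH) ||
      any(abs(folded$pH - unfolded$pH) > 1e-9)) {
    stop("folded and unfolded titrations use different pH grids")
  }
  if (nrow(folded$sites) != nrow(unfolded$sites)) {
    stop("folded and unfolded titrations use different site lists")
  }
  i <- which.min(abs(folded$pH - pH))
  if (abs(folded$pH[i] - pH) > 1e-6) {
    stop(sprintf("pH %.3g is not on the titration grid", pH))
  }
  out <- list(pH = folded$pH[i], pHstab = folded$G[i] - unfolded$G[i])
  class(out) <- "ph_stability"
  out
}

#' @export
print.ph_stability <- function(x, ...) {
  cat(sprintf("pHstab at pH %.2f: %+.3f kJ/mol (%s)\n", x$pH, x$pHstab,
              if (x$pHstab < 0) "favourable" else "unfavourable"))
  invisible(x)
}

#' Full pH-stability calculation for a structure
#'
#' Builds the site model, titrates the folded (interacting) and unfolded
#' (non-interacting) systems, and returns the folded-minus-unfolded term.
#'
#' @param s a charged \code{protein_structure}.
#' @param params \code{\link{es_params}}.
#' @param pH evaluation pH (default 7.0).
#' @param method "exact" (site count permitting) or "mc".
#' @param pH_grid grid for the titration (default 0..14 by 0.25).
#' @param seed RNG seed (required for \code{method = "mc"}).
#' @param ... further arguments to \code{\link{titrate_mc}}.
#' @return a \code{ph_stability} object with the two titrations attached
#'   as attributes "folded" and "unfolded".
#' @export
ph_stability_of <- function(s, params = es_params(), pH = 7.0,
                            method = c("mc", "exact"),
                            pH_grid = seq(0, 14, 0.25), seed = NULL, ...) {
  method <- match.arg(method)
  m <- build_site_model(s, params)
  mu <- unfolded_site_model(m)
  if (method == "exact") {
    tf <- titrate_exact(m$sites, m$W, pH_grid)
    tu <- titrate_exact(mu$sites, mu$W, pH_grid)
  } else {
    if (is.null(seed)) stop("mc method requires a seed")
    tf <- titrate_mc(m$sites, m$W, pH_grid, seed = seed, ...)
    tu <- titrate_mc(mu$sites, mu$W, pH_grid, seed = seed, ...)
  }
  out <- ph_stability(tf, tu, pH)
  attr(out, "folded") <- tf
  attr(out, "unfolded") <- tu
  out
}
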