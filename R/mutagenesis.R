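#' Replace one sidechain in a structure
#'
#' Backbone atoms (N, CA, C, O, OXT) are preserved exactly; the new
#' sidechain is rebuilt from ideal internal geometry. The rotamer is chosen
#' from a small built-in staggered set by minimising the heavy-atom clash
#' count against the rest of the structure (pair distance below 0.7 x the
#' sum of van der Waals radii counts as a clash); ties go to the first
#' rotamer in library order, so replacement is deterministic. Mutating a
#' residue to itself is a no-op. If the structure carried charges they are
#' re-assigned afterwards.
#'
#' @param s a \code{protein_structure}.
#' @param chain,resno residue address (PDB numbering).
#' @param wt expected one-letter wild-type code (checked; mismatch is an
#'   error naming the residue found).
#' @param new one-letter replacement code.
#' @return the mutated structure.
#' @export
mutate_sidechain <- function(s, chain, resno, wt, new) {
  at <- s$atoms
  idx <- which(at$chain == chain & at$resno == resno)
  if (length(idx) == 0) stop(sprintf("no residue %s%d", chain, resno))
  found <- aa_one(at$resid[idx[1]])
  if (found != toupper(wt)) {
    stop(sprintf("wild-type mismatch at %s%d: expected %s, found %s",
                 chain, resno, toupper(wt), found))
  }
  if (toupper(new) == found) return(s)
  new3 <- aa_three(new)
  bb_names <- c("N", "CA", "C", "O", "OXT")
  bb <- idx[at$name[idx] %in% bb_names]
  need <- c("N", "CA", "C")
  if (!all(need %in% at$name[bb])) {
    stop(sprintf("residue %s%d lacks backbone atoms (%s)", chain, resno,
                 paste(setdiff(need, at$name[bb]), collapse = ",")))
  }
  getp <- function(nm) unlist(at[bb[match(nm, at$name[bb])], c("x", "y", "z")],
                              use.names = FALSE)
  N <- getp("N"); CA <- getp("CA"); C <- getp("C")
  had_charges <- any(!is.na(at$radius))
  # environment for clash counting: all atoms outside this residue
  env <- at[-idx, , drop = FALSE]
  envX <- as.matrix(env[, c("x", "y", "z")])
  env_r <- unname(.RADII[env$elem]); env_r[is.na(env_r)] <- .RADIUS_DEFAULT
  best <- NULL; best_clash <- Inf
  for (rot in rotamer_set(new3)) {
    sc <- build_sidechain(new3, N, CA, C, rot)
    cl <- 0L
    if (nrow(sc) > 0 && nrow(env) > 0) {
      sc_r <- unname(.RADII[sc$elem]); sc_r[is.na(sc_r)] <- .RADIUS_DEFAULT
      for (i in seq_len(nrow(sc))) {
        d2 <- (envX[, 1] - sc$x[i])^2 + (envX[, 2] - sc$y[i])^2 +
          (envX[, 3] - sc$z[i])^2
        cl <- cl + sum(d2 < (0.7 * (sc_r[i] + env_r))^2)
      }
    }
    if (cl < best_clash) { best <- sc; best_clash <- cl }
    if (best_clash == 0L) break
  }
  keep <- at[bb, , drop = FALSE]
  keep$resid <- new3
  if (nrow(best) > 0) {
    scrows <- data.frame(serial = 0L, name = best$name, elem = best$elem,
                         resid = new3, chain = chain, resno = resno,
                         x = best$x, y = best$y, z = best$z,
                         radius = NA_real_, charge = 0,
                         stringsAsFactors = FALSE)
  } else scrows <- NULL
  at <- rbind(at[seq_len(min(idx) - 1), , drop = FALSE], keep, scrows,
              at[setdiff(seq(max(idx) + 1, length.out = nrow(at) - max(idx)),
                         integer(0)), , drop = FALSE])
  at$serial <- seq_len(nrow(at))
  s$atoms <- at
  if (had_charges) s <- assign_charges(s) else s
}

#' Apply a set of point mutations
#'
#' Convenience wrapper around \code{\link{mutate_sidechain}} accepting
#' tokens like \code{"R150D"} or \code{"F48D,R150D"}.
#'
#' @param s a \code{protein_structure}.
#' @param mutations mutation token string or \code{\link{parse_edits}}
#'   data.frame.
#' @param chain chain the tokens address (default: first chain).
#' @return the mutated structure.
#' @export
mutate_structure <- function(s, mutations, chain = NULL) {
  if (is.null(chain)) chain <- sort(unique(s$atoms$chain))[1]
  apply_sequence_edits(s, if (is.character(mutations))
    parse_edits(mutations, chain) else mutations)
}

#' Systematic patch-mutation screen
#'
#' Enumerates candidate single mutations among the residues attributed to a
#' surface patch (typically the largest positively-charged one) and re-runs
#' the full profile pipeline for each mutant. Modes follow the screening
#' procedure used for charge engineering: \code{basic_to_D} mutates every
#' Arg/Lys in the patch to Asp (the default negative-charge carrier, chosen
#' over Glu for its shorter sidechain); \code{any_to_D} mutates every
#' residue; \code{acidic_to_basic} mutates every Asp/Glu to Arg and to Lys.
#'
#' @param s a charged \code{protein_structure} (the baseline).
#' @param patch a row index into \code{patches$patches} or a patch id; by
#'   default the largest POS patch of \code{patches}.
#' @param patches a \code{\link{segment_patches}} result for \code{s}.
#' @param mode one of \code{"basic_to_D"}, \code{"any_to_D"},
#'   \code{"acidic_to_basic"}.
#' @param threshold patch-size threshold (Angstrom^2) for the ratio.
#' @param params \code{\link{es_params}}.
#' @param probe,dots_per_atom surface settings passed to
#'   \code{\link{build_dot_surface}}.
#' @return data.frame of class \code{mutation_screen}: mutation, posQmax,
#'   ratio, prediction, sorted by ratio (baseline row first).
#' @export
screen_patch_mutations <- function(s, patches, patch = NULL,
                                   mode = c("basic_to_D", "any_to_D",
                                            "acidic_to_basic"),
                                   threshold, params = es_params(),
                                   probe = 1.4, dots_per_atom = 256) {
  mode <- match.arg(mode)
  ptab <- patches$patches
  if (is.null(patch)) {
    pos <- ptab[ptab$sign == "POS", , drop = FALSE]
    if (nrow(pos) == 0) stop("no positive patch to screen")
    patch <- pos$id[which.max(pos$area)]
  }
  memb <- patches$members[[as.character(patch)]]
  if (is.null(memb) || nrow(memb) == 0) stop("patch has no member residues")
  memb$aa <- NA_character_
  for (i in seq_len(nrow(memb))) {
    r <- s$atoms[s$atoms$chain == memb$chain[i] &
                 s$atoms$resno == memb$resno[i], "resid"]
    memb$aa[i] <- aa_one(r[1])
  }
  cand <- switch(mode,
    basic_to_D = {
      m <- memb[memb$aa %in% c("R", "K"), , drop = FALSE]
      if (nrow(m)) data.frame(chain = m$chain, resno = m$resno, wt = m$aa,
                              new = "D", stringsAsFactors = FALSE)
      else m[0, ]
    },
    any_to_D = {
      m <- memb[memb$aa != "D" & memb$aa != "X", , drop = FALSE]
      if (nrow(m)) data.frame(chain = m$chain, resno = m$resno, wt = m$aa,
                              new = "D", stringsAsFactors = FALSE)
      else m[0, ]
    },
    acidic_to_basic = {
      m <- memb[memb$aa %in% c("D", "E"), , drop = FALSE]
      if (nrow(m)) {
        rbind(data.frame(chain = m$chain, resno = m$resno, wt = m$aa,
                         new = "R", stringsAsFactors = FALSE),
              data.frame(chain = m$chain, resno = m$resno, wt = m$aa,
                         new = "K", stringsAsFactors = FALSE))
      } else m[0, ]
    })
  profile_of <- function(st) {
    surf <- link_neighbours(build_dot_surface(st, probe = probe,
                                              dots_per_atom = dots_per_atom))
    phi <- surface_potential(surf, st, params)
    solubility_profile(segment_patches(surf, phi), threshold)
  }
  base <- profile_of(s)
  rows <- data.frame(mutation = "WT", posQmax = base$posQmax,
                     ratio = base$ratio, prediction = base$prediction,
                     stringsAsFactors = FALSE)
  if (nrow(cand) == 0) {
    warning("empty candidate set for mode ", mode)
  } else {
    res <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
      mstr <- mutate_sidechain(s, cand$chain[i], cand$resno[i],
                               cand$wt[i], cand$new[i])
      pr <- profile_of(mstr)
      res[[i]] <- data.frame(
        mutation = sprintf("%s%d%s", cand$wt[i], cand$resno[i], cand$new[i]),
        posQmax = pr$posQmax, ratio = pr$ratio, prediction = pr$prediction,
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, res)
    rows <- rbind(rows, res[order(res$ratio), ])
  }
  rownames(rows) <- NULL
  class(rows) <- c("mutation_screen", "data.frame")
  rows
}

#' @export
print.mutation_screen <- function(x, ...) {
  cat("Patch mutation screen (baseline first, then by ascending ratio)\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
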