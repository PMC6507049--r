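# Structure container: a list with an atoms data.frame. Columns:
# serial, name (atom name), elem, resid (3-letter), chain, resno, x, y, z,
# radius, charge. Reading goes through bio3d; writing is a fixed-width
# formatter used by the generators and write_structure().

new_structure <- function(atoms) {
  rownames(atoms) <- NULL
  s <- list(atoms = atoms)
  class(s) <- "protein_structure"
  s
}

#' Read a protein structure from PDB text or file
#'
#' Parses ATOM records (waters/HETATM ligands are excluded), resolves
#' alternate locations to the highest-occupancy conformer (ties broken
#' towards altloc "A"), and optionally restricts to selected chains. Radii
#' and formal charges are not assigned here; see
#' \code{\link{assign_charges}}.
#'
#' @param pdb PDB-format text (single string or character vector of lines)
#'   or a path to a PDB file.
#' @param chain optional character vector of chain identifiers to keep.
#' @return a \code{protein_structure}.
#' @export
load_structure <- function(pdb, chain = NULL) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) {
    path <- pdb
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(if (length(pdb) == 1) strsplit(pdb, "\n")[[1]] else pdb, path)
  }
  txt <- readLines(path)
  if (!any(startsWith(txt, "ATOM"))) stop("no ATOM records in PDB input")
  p <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                        rm.alt = FALSE, verbose = FALSE))
  a <- p$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms left after chain selection")
  # altloc resolution: keep highest occupancy, ties -> lexicographically
  # first altloc (""/"A" before "B")
  alt <- a$alt
  alt[is.na(alt)] <- ""
  if (any(alt != "")) {
    key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
    occ <- a$o
    occ[is.na(occ)] <- 1
    ord <- order(key, -occ, alt)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(key[ord]), , drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  known <- a$resid %in% names(.AA1)
  if (!all(known)) {
    warning("unknown residue types retained without charges: ",
            paste(unique(a$resid[!known]), collapse = ", "))
  }
  atoms <- data.frame(
    serial = a$eleno, name = a$elety,
    elem = guess_element(a$elety, a$elesy),
    resid = a$resid, chain = a$chain, resno = a$resno,
    x = a$x, y = a$y, z = a$z,
    radius = NA_real_, charge = 0,
    stringsAsFactors = FALSE)
  atoms <- atoms[atoms$elem != "H", , drop = FALSE]  # united-atom model
  new_structure(atoms)
}

guess_element <- function(name, elesy = NULL) {
  el <- toupper(sub("^([A-Za-z]).*", "\\1", gsub("[^A-Za-z].*$", "",
                                                 sub("^[0-9']+", "", name))))
  if (!is.null(elesy)) {
    ok <- !is.na(elesy) & nzchar(trimws(elesy))
    el[ok] <- toupper(trimws(elesy))[ok]
  }
  el[el == ""] <- "C"
  el
}

#' @export
print.protein_structure <- function(x, ...) {
  at <- x$atoms
  cat(sprintf("protein_structure: %d atoms, %d residues, chains %s\n",
              nrow(at), nrow(unique(at[, c("chain", "resno")])),
              paste(sort(unique(at$chain)), collapse = ",")))
  if (any(!is.na(at$radius))) {
    cat(sprintf("  net formal charge: %+.1f e\n", sum(at$charge)))
  } else cat("  charges/radii not assigned (see assign_charges)\n")
  invisible(x)
}

#' One-letter sequence of a chain
#'
#' @param s a \code{protein_structure}.
#' @param chain chain id; defaults to the first chain present.
#' @return single string of one-letter codes (X for non-standard residues).
#' @export
structure_sequence <- function(s, chain = NULL) {
  at <- s$atoms
  if (is.null(chain)) chain <- sort(unique(at$chain))[1]
  at <- at[at$chain == chain, , drop = FALSE]
  res <- at[!duplicated(at$resno), c("resno", "resid")]
  res <- res[order(res$resno), ]
  paste(aa_one(res$resid), collapse = "")
}

#' Net formal charge of a structure
#' @param s a charged \code{protein_structure}.
#' @return sum of atomic formal charges (elementary units).
#' @export
net_charge <- function(s) sum(s$atoms$charge)

#' Default formal-charge model at pH 7
#'
#' Single formal charges per ionisable group, split over the symmetric
#' charge-centre atoms: Asp OD1/OD2 -0.5 each, Glu OE1/OE2 -0.5, Lys NZ +1,
#' Arg NH1/NH2 +0.5, His neutral (model pKa 6.3 < 7), N-terminus +1 on N,
#' C-terminus -0.5 on each carboxylate oxygen (O/OXT; -1 on O when OXT is
#' absent).
#'
#' @return a list describing the charge placement, class
#'   \code{charge_model}.
#' @export
default_charge_model <- function() {
  m <- list(
    sidechain = list(
      ASP = list(atoms = c("OD1", "OD2"), q = -1),
      GLU = list(atoms = c("OE1", "OE2"), q = -1),
      LYS = list(atoms = "NZ", q = 1),
      ARG = list(atoms = c("NH1", "NH2"), q = 1),
      HIS = list(atoms = character(0), q = 0)),
    nterm = list(atoms = "N", q = 1),
    cterm = list(atoms = c("O", "OXT"), q = -1))
  class(m) <- "charge_model"
  m
}

#' Assign radii and formal charges
#'
#' Radii come from a fixed built-in united-atom table (C 1.9, N 1.7, O 1.5,
#' S 1.85, H 1.0 Angstrom). Formal charges are placed on the model's
#' designated charge-centre atoms; disulphide-bonded cysteines stay neutral.
#' When a charged residue is missing its charge-centre atoms the charge is
#' placed on the sidechain centroid-nearest atom with a warning.
#'
#' @param s a \code{protein_structure}.
#' @param model a \code{\link{default_charge_model}}.
#' @param termini logical; place N-/C-terminal charges on each chain's first
#'   and last residue (default TRUE).
#' @return the structure with \code{radius} and \code{charge} filled in.
#' @export
assign_charges <- function(s, model = default_charge_model(), termini = TRUE) {
  at <- s$atoms
  at$radius <- unname(.RADII[at$elem])
  at$radius[is.na(at$radius)] <- .RADIUS_DEFAULT
  at$charge <- 0
  rkey <- paste(at$chain, at$resno)
  for (res in split(seq_len(nrow(at)), rkey)) {
    rn <- at$resid[res[1]]
    mm <- model$sidechain[[rn]]
    if (is.null(mm) || mm$q == 0) next
    idx <- res[at$name[res] %in% mm$atoms]
    if (length(idx) == 0) {
      sc <- res[!(at$name[res] %in% c("N", "CA", "C", "O", "OXT"))]
      if (length(sc) == 0) sc <- res
      warning(sprintf("missing charge-centre atom(s) in %s %s%d; using sidechain atom",
                      rn, at$chain[res[1]], at$resno[res[1]]))
      idx <- sc[length(sc)]
    }
    at$charge[idx] <- mm$q / length(idx)
  }
  if (termini) {
    for (ch in unique(at$chain)) {
      ci <- which(at$chain == ch)
      r1 <- min(at$resno[ci]); rN <- max(at$resno[ci])
      nt <- ci[at$resno[ci] == r1 & at$name[ci] %in% model$nterm$atoms]
      if (length(nt)) at$charge[nt] <- at$charge[nt] + model$nterm$q / length(nt)
      ct <- ci[at$resno[ci] == rN & at$name[ci] %in% model$cterm$atoms]
      if (length(ct)) at$charge[ct] <- at$charge[ct] + model$cterm$q / length(ct)
    }
  }
  s$atoms <- at
  # disulphide-bonded cysteines carry no thiolate charge (they are neutral
  # already at pH 7 under this model; detection matters for titration)
  s$disulfides <- find_disulfides(s)
  s
}

#' Detect disulphide bridges
#'
#' Cysteine pairs whose SG atoms lie within 2.5 Angstrom.
#'
#' @param s a \code{protein_structure}.
#' @return data.frame with columns chain1, resno1, chain2, resno2.
#' @export
find_disulfides <- function(s) {
  at <- s$atoms
  sg <- which(at$resid == "CYS" & at$name == "SG")
  out <- data.frame(chain1 = character(0), resno1 = integer(0),
                    chain2 = character(0), resno2 = integer(0),
                    stringsAsFactors = FALSE)
  if (length(sg) < 2) return(out)
  X <- as.matrix(at[sg, c("x", "y", "z")])
  pr <- .cp_pairs_within(X, 2.5)
  if (nrow(pr) == 0) return(out)
  data.frame(chain1 = at$chain[sg[pr[, 1]]], resno1 = at$resno[sg[pr[, 1]]],
             chain2 = at$chain[sg[pr[, 2]]], resno2 = at$resno[sg[pr[, 2]]],
             stringsAsFactors = FALSE)
}

#' Parse sequence-edit tokens
#'
#' Tokens like \code{"K24N"} (one-letter wild type, PDB residue number,
#' one-letter replacement), comma-separated or as a vector.
#'
#' @param text e.g. \code{"K24N,K38N,K83N"}.
#' @param chain chain the edits apply to.
#' @return data.frame with columns chain, resno, wt, new.
#' @export
parse_edits <- function(text, chain = "A") {
  tok <- trimws(unlist(strsplit(text, ",")))
  tok <- tok[nzchar(tok)]
  m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tok))
  bad <- vapply(m, length, 1L) != 4
  if (any(bad)) stop("malformed edit token(s): ", paste(tok[bad], collapse = ", "))
  data.frame(chain = chain,
             resno = as.integer(vapply(m, `[`, "", 3)),
             wt = toupper(vapply(m, `[`, "", 2)),
             new = toupper(vapply(m, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

#' Apply sequence edits by sidechain replacement
#'
#' Each edit must name the residue actually present (wild-type mismatch is
#' an error, so re-applying an already-applied edit list fails loudly rather
#' than silently). Backbone atoms are untouched.
#'
#' @param s a \code{protein_structure}.
#' @param edits a \code{\link{parse_edits}} data.frame (or edit string).
#' @return the edited structure.
#' @export
apply_sequence_edits <- function(s, edits) {
  if (is.character(edits)) edits <- parse_edits(edits, sort(unique(s$atoms$chain))[1])
  if (nrow(edits) == 0) return(s)
  for (i in seq_len(nrow(edits))) {
    s <- mutate_sidechain(s, chain = edits$chain[i], resno = edits$resno[i],
                          wt = edits$wt[i], new = edits$new[i])
  }
  s
}

# Fixed-width PDB ATOM formatter (writing only; parsing is bio3d's job)
pdb_format_atoms <- function(at) {
  name <- ifelse(nchar(at$name) < 4, sprintf(" %-3s", at$name),
                 sprintf("%-4s", at$name))
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          at$serial %% 100000, name, at$resid, at$chain, at$resno,
          at$x, at$y, at$z, 1.00, 0.00, at$elem)
}

#' Write a structure as PDB text
#'
#' @param s a \code{protein_structure}.
#' @param file optional path; when NULL the text is returned invisibly.
#' @return the PDB text, invisibly.
#' @export
write_structure <- function(s, file = NULL) {
  at <- s$atoms
  at <- at[order(at$chain, at$resno, at$serial), , drop = FALSE]
  at$serial <- seq_len(nrow(at))
  lines <- c(pdb_format_atoms(at), "TER", "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(paste(lines, collapse = "\n"))
}
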