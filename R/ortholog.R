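# Orthologue survey: thread homologue sequences onto a template backbone by
# sidechain replacement (no loop building) and tabulate per-model patch
# ratios and pH-stability terms.

#' Read an aligned FASTA file
#'
#' @param file path to an aligned FASTA ('-' gaps) or the text itself.
#' @return named character vector of aligned sequences (equal lengths).
#' @export
read_alignment <- function(file) {
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    path <- file
  } else {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path))
    writeLines(if (length(file) == 1) strsplit(file, "\n")[[1]] else file,
               path)
  }
  aln <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aln))
  if (length(unique(nchar(seqs))) != 1) {
    stop("alignment rows have unequal lengths")
  }
  seqs
}

#' Comparative model by sidechain replacement
#'
#' Threads a target sequence onto the template structure using one aligned
#' row pair. Matched columns with differing residues are substituted via
#' \code{\link{mutate_sidechain}}; columns where the target has a gap
#' delete the template residue; columns where the template has a gap
#' (insertions in the target) are skipped and flagged unmodelled. The
#' template backbone is untouched at all modelled positions.
#'
#' @param template a charged \code{protein_structure} (single chain).
#' @param target aligned target sequence (with '-').
#' @param template_aln aligned template sequence; its ungapped residues
#'   must match the template structure's sequence.
#' @param name model name.
#' @return object of class \code{ortholog_model}: \code{structure},
#'   \code{name}, \code{coverage}, \code{unmodelled} (alignment columns of
#'   target insertions), \code{n_subst}.
#' @export
model_from_alignment <- function(template, target, template_aln,
                                 name = "model") {
  if (nchar(target) != nchar(template_aln)) {
    stop("aligned sequences have different lengths")
  }
  chain <- sort(unique(template$atoms$chain))[1]
  at <- template$atoms[template$atoms$chain == chain, , drop = FALSE]
  resnos <- sort(unique(at$resno))
  tseq <- strsplit(structure_sequence(template, chain), "")[[1]]
  tcols <- strsplit(toupper(template_aln), "")[[1]]
  qcols <- strsplit(toupper(target), "")[[1]]
  tpos <- which(tcols != "-")
  if (length(tpos) != length(tseq) ||
      any(tcols[tpos] != tseq)) {
    bad <- if (length(tpos) != length(tseq)) NA else
      tpos[which(tcols[tpos] != tseq)[1]]
    stop("template alignment row does not match the template structure",
         if (!is.na(bad)) sprintf(" (first mismatch at column %d)", bad))
  }
  s <- template
  n_subst <- 0L
  deleted <- integer(0)
  for (k in seq_along(tpos)) {
    col <- tpos[k]
    wt <- tcols[col]; qq <- qcols[col]
    if (qq == "-") {
      deleted <- c(deleted, resnos[k])
    } else if (qq != wt) {
      s <- mutate_sidechain(s, chain, resnos[k], wt, qq)
      n_subst <- n_subst + 1L
    }
  }
  if (length(deleted)) {
    s$atoms <- s$atoms[!(s$atoms$chain == chain &
                         s$atoms$resno %in% deleted), , drop = FALSE]
    s <- assign_charges(s)
  }
  unmodelled <- which(tcols == "-" & qcols != "-")
  coverage <- (length(tpos) - length(deleted)) / length(tpos)
  out <- list(structure = s, name = name, coverage = coverage,
              unmodelled = unmodelled, n_subst = n_subst,
              deleted = deleted)
  class(out) <- "ortholog_model"
  out
}

#' @export
print.ortholog_model <- function(x, ...) {
  cat(sprintf("ortholog_model '%s': %d substitutions, coverage %.2f%s\n",
              x$name, x$n_subst, x$coverage,
              if (length(x$unmodelled))
                sprintf(", %d unmodelled insertion column(s)",
                        length(x$unmodelled)) else ""))
  invisible(x)
}

#' Build models for every row of an alignment
#'
#' @param template a charged \code{protein_structure}.
#' @param alignment named aligned sequences (\code{\link{read_alignment}}).
#' @param template_name name of the template's own row in the alignment.
#' @return list of \code{ortholog_model} (template row excluded).
#' @export
models_from_alignment <- function(template, alignment, template_name) {
  if (!template_name %in% names(alignment)) {
    stop("template row '", template_name, "' not found in alignment")
  }
  taln <- alignment[[template_name]]
  targets <- alignment[setdiff(names(alignment), template_name)]
  lapply(names(targets), function(nm) {
    model_from_alignment(template, targets[[nm]], taln, name = nm)
  })
}

#' Per-orthologue patch and stability survey
#'
#' Runs the full pipeline (surface, potential, patch segmentation, ratio to
#' threshold; site model, Monte Carlo titration, pH-stability term) for each
#' comparative model. Models failing any stage are skipped with the error
#' recorded. Models with coverage below 0.8 are flagged low-confidence.
#'
#' @param models list of \code{ortholog_model} (or of
#'   \code{protein_structure}).
#' @param threshold patch-size threshold, Angstrom^2.
#' @param params \code{\link{es_params}}.
#' @param seed RNG seed for the titrations.
#' @param probe,dots_per_atom surface settings.
#' @param sweeps,burn_in Monte Carlo settings.
#' @param bin_width histogram bin width for the ratio distribution
#'   (default 0.25).
#' @param phstab logical; compute the titration term (default TRUE).
#' @return data.frame of class \code{survey_table}: name, posQmax, ratio,
#'   prediction, pHstab, coverage, low_confidence, with a ratio histogram
#'   in \code{attr(, "histogram")} and skipped models in
#'   \code{attr(, "skipped")}.
#' @export
survey <- function(models, threshold, params = es_params(), seed = 1,
                   probe = 1.4, dots_per_atom = 256, sweeps = 10000,
                   burn_in = 1000, bin_width = 0.25, phstab = TRUE) {
  rows <- list(); skipped <- list()
  for (m in models) {
    if (inherits(m, "protein_structure")) {
      m <- list(structure = m, name = "structure", coverage = 1)
    }
    r <- tryCatch({
      st <- m$structure
      surf <- link_neighbours(build_dot_surface(st, probe = probe,
                                                dots_per_atom = dots_per_atom))
      phi <- surface_potential(surf, st, params)
      prof <- solubility_profile(segment_patches(surf, phi), threshold)
      ph <- NA_real_
      if (phstab) {
        ph <- ph_stability_of(st, params, method = "mc", seed = seed,
                              sweeps = sweeps, burn_in = burn_in)$pHstab
      }
      data.frame(name = m$name, posQmax = prof$posQmax, ratio = prof$ratio,
                 prediction = prof$prediction, pHstab = ph,
                 coverage = m$coverage,
                 low_confidence = m$coverage < 0.8,
                 stringsAsFactors = FALSE)
    }, error = function(e) e)
    if (inherits(r, "error")) {
      skipped[[length(skipped) + 1]] <- data.frame(
        name = m$name, error = conditionMessage(r), stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1]] <- r
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), posQmax = numeric(0), ratio = numeric(0),
               prediction = character(0), pHstab = numeric(0),
               coverage = numeric(0), low_confidence = logical(0))
  rownames(out) <- NULL
  if (nrow(out)) {
    br <- seq(floor(min(out$ratio) / bin_width) * bin_width,
              ceiling(max(out$ratio) / bin_width) * bin_width + bin_width,
              by = bin_width)
    h <- graphics::hist(out$ratio, breaks = br, plot = FALSE)
    attr(out, "histogram") <- data.frame(mid = h$mids, count = h$counts)
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  class(out) <- c("survey_table", "data.frame")
  out
}

#' @export
print.survey_table <- function(x, ...) {
  cat(sprintf("Orthologue survey: %d model(s)\n", nrow(x)))
  print.data.frame(x, digits = 3, row.names = FALSE)
  sk <- attr(x, "skipped")
  if (!is.null(sk)) cat(sprintf("  skipped: %d (see attr(, 'skipped'))\n",
                                nrow(sk)))
  invisible(x)
}

#' UPGMA row ordering by percent identity
#'
#' Reporting convenience: orders alignment rows by average-linkage
#' clustering on pairwise percent identity, so related sequences sit
#' together in survey tables.
#'
#' @param alignment named aligned sequences.
#' @return character vector of names in clustered order.
#' @export
order_by_identity <- function(alignment) {
  n <- length(alignment)
  if (n <= 2) return(names(alignment))
  mats <- lapply(alignment, function(s) strsplit(s, "")[[1]])
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- mats[[i]]; b <- mats[[j]]
    ok <- a != "-" | b != "-"
    D[i, j] <- D[j, i] <- 1 - mean(a[ok] == b[ok])
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  names(alignment)[hc$order]
}
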