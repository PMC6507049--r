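#' Segment the surface into charged and non-charged patches
#'
#' Dots are classified by the electrostatic potential: POS above the
#' positive contour (default +25 mV, strict), NEG below the negative
#' contour (default -25 mV, strict), HYD ("effectively non-charged") in the
#' closed interval between them. Connected components are taken over the
#' dot neighbour graph restricted to each class; patch size is the sum of
#' member dot areas, so the POS/NEG/HYD patches partition the total
#' surface area. A residue is attributed to a patch when it parents at
#' least one member dot.
#'
#' @param surface a linked \code{dot_surface}
#'   (\code{\link{link_neighbours}}).
#' @param field numeric vector of potentials (mV) aligned with the dots.
#' @param pos_mV,neg_mV contour levels (defaults +25 / -25).
#' @param structure optional \code{protein_structure}; when given, member
#'   residues are recorded per patch.
#' @return object of class \code{patch_set}: \code{patches} (data.frame id,
#'   sign, area, n_dots), \code{assignment} (patch id per dot),
#'   \code{members} (per-patch residue tables when a structure was given),
#'   and \code{posQmax}, \code{negQmax}, \code{hydmax} (Angstrom^2).
#' @export
segment_patches <- function(surface, field, pos_mV = 25, neg_mV = -25,
                            structure = NULL) {
  if (is.null(surface$neighbours)) {
    stop("surface has no neighbour graph; run link_neighbours() first")
  }
  nd <- nrow(surface$dots)
  if (length(field) != nd) stop("field length does not match dot count")
  cls <- ifelse(field > pos_mV, "POS", ifelse(field < neg_mV, "NEG", "HYD"))
  ed <- surface$neighbours
  same <- cls[ed[, 1]] == cls[ed[, 2]]
  g <- igraph::graph_from_edgelist(ed[same, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nd - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  area <- as.numeric(tapply(surface$dots$area, comp, sum))
  ids <- sort(unique(comp))
  sign_of <- cls[match(ids, comp)]
  patches <- data.frame(id = ids, sign = sign_of, area = area,
                        n_dots = as.integer(table(comp)[as.character(ids)]),
                        stringsAsFactors = FALSE)
  patches <- patches[order(-patches$area), ]
  rownames(patches) <- NULL
  members <- NULL
  if (!is.null(structure)) {
    at <- structure$atoms
    members <- lapply(ids, function(pid) {
      aidx <- unique(surface$dots$atom[comp == pid])
      unique(data.frame(chain = at$chain[aidx], resno = at$resno[aidx],
                        stringsAsFactors = FALSE))
    })
    names(members) <- as.character(ids)
  }
  maxby <- function(sg) {
    a <- patches$area[patches$sign == sg]
    if (length(a)) max(a) else 0
  }
  out <- list(patches = patches, assignment = comp, members = members,
              class_of_dot = cls, pos_mV = pos_mV, neg_mV = neg_mV,
              posQmax = maxby("POS"), negQmax = maxby("NEG"),
              hydmax = maxby("HYD"))
  class(out) <- "patch_set"
  out
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set: %d patches (contours %+g / %+g mV)\n",
              nrow(x$patches), x$pos_mV, x$neg_mV))
  cat(sprintf("  posQmax %.1f  negQmax %.1f  hydmax %.1f A^2\n",
              x$posQmax, x$negQmax, x$hydmax))
  print(utils::head(x$patches, 8), row.names = FALSE)
  if (nrow(x$patches) > 8) cat("  ...\n")
  invisible(x)
}

#' Solubility profile from a patch set
#'
#' The principal predictor: the ratio of the largest positively-charged
#' patch (posQmax) to a calibrated threshold. A ratio strictly above 1.0
#' predicts insolubility. The largest non-charged patch (hydmax) is
#' reported alongside as the supplemental (positive + non-charged) score,
#' without its own threshold.
#'
#' @param patches a \code{\link{segment_patches}} result (or a list with
#'   \code{posQmax}/\code{hydmax}).
#' @param threshold patch-size threshold in Angstrom^2 (> 0); see
#'   \code{\link{calibrate_threshold}}.
#' @return object of class \code{solubility_profile}: posQmax, threshold,
#'   ratio, prediction ("soluble"/"insoluble"), hydmax.
#' @export
solubility_profile <- function(patches, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a single value > 0")
  }
  ratio <- patches$posQmax / threshold
  out <- list(posQmax = patches$posQmax, threshold = threshold,
              ratio = ratio,
              prediction = if (ratio > 1.0) "insoluble" else "soluble",
              hydmax = if (!is.null(patches$hydmax)) patches$hydmax else NA_real_)
  class(out) <- "solubility_profile"
  out
}

#' @export
print.solubility_profile <- function(x, ...) {
  cat("Solubility profile (largest positive patch vs threshold)\n")
  cat(sprintf("  posQmax: %.1f A^2   threshold: %.1f A^2\n",
              x$posQmax, x$threshold))
  cat(sprintf("  ratio: %.2f  ->  predicted %s\n", x$ratio, x$prediction))
  if (!is.na(x$hydmax)) {
    cat(sprintf("  supplemental: largest non-charged patch %.1f A^2\n",
                x$hydmax))
  }
  invisible(x)
}

#' Calibrate the patch-size threshold on labelled data
#'
#' Scans candidate thresholds (the midpoints of consecutive sorted unique
#' patch sizes, plus one candidate below the minimum and one above the
#' maximum) and picks the value whose rule "insoluble iff size > t"
#' maximises balanced accuracy; ties go to the smallest threshold. A
#' warning is raised when the best achievable balanced accuracy does not
#' beat chance, i.e. the labels are inverted or unseparable.
#'
#' @param sizes numeric vector of largest-positive-patch sizes.
#' @param labels character/factor/logical labels; TRUE / "insoluble" marks
#'   the insoluble class.
#' @return object of class \code{threshold_calibration}: threshold,
#'   balanced_accuracy, accuracy, data.
#' @export
calibrate_threshold <- function(sizes, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- tolower(as.character(labels)) %in% c("insoluble", "insol", "1",
                                                   "true")
  }
  labels <- as.logical(labels)
  if (length(sizes) != length(labels)) stop("sizes/labels length mismatch")
  if (!any(labels) || all(labels)) {
    stop("need both soluble and insoluble examples to calibrate")
  }
  u <- sort(unique(sizes))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  bal <- vapply(cand, function(t) {
    pred <- sizes > t
    (mean(pred[labels]) + mean(!pred[!labels])) / 2
  }, 0)
  best <- which(bal == max(bal))[1]  # ties -> smallest candidate
  if (max(bal) <= 0.5) {
    warning("labels are not separated better than chance by patch size")
  }
  out <- list(threshold = cand[best], balanced_accuracy = bal[best],
              accuracy = mean((sizes > cand[best]) == labels),
              data = data.frame(size = sizes, insoluble = labels))
  class(out) <- "threshold_calibration"
  out
}

#' @export
print.threshold_calibration <- function(x, ...) {
  cat(sprintf("threshold_calibration: t = %.3g A^2 (balanced accuracy %.1f%%, n = %d)\n",
              x$threshold, 100 * x$balanced_accuracy, nrow(x$data)))
  invisible(x)
}
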