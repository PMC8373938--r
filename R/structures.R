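#' Coarse-grained structure container
#'
#' A `coarse_structure` holds a single-chain C-alpha trace with 1-based
#' residue numbering, the amino-acid sequence and (optionally) per-residue
#' 3-state secondary structure. Virtual C-beta positions are derived from the
#' trace with [virtual_cbeta()] when contact geometry is needed.
#'
#' @param xyz numeric L x 3 matrix of C-alpha coordinates (Angstrom).
#' @param seq character vector of one-letter residue codes (length L), or a
#'   single string.
#' @param ss optional character vector of per-residue states in `c("H","E","C")`.
#' @return An object of class `coarse_structure` with elements `L`, `xyz`,
#'   `seq` and `ss`.
#' @export
coarse_structure <- function(xyz, seq = NULL, ss = NULL) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must be an L x 3 matrix")
  L <- nrow(xyz)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (is.null(seq)) seq <- rep("A", L)
  if (length(seq) == 1L && nchar(seq[1L]) > 1L) seq <- strsplit(seq, "")[[1L]]
  if (length(seq) != L) stop("sequence length does not match coordinates")
  if (!is.null(ss)) {
    if (length(ss) == 1L && nchar(ss[1L]) > 1L) ss <- strsplit(ss, "")[[1L]]
    if (length(ss) != L) stop("ss length does not match coordinates")
    if (!all(ss %in% c("H", "E", "C"))) stop("ss states must be H/E/C")
  }
  structure(list(L = L, xyz = xyz, seq = as.character(seq), ss = ss),
            class = "coarse_structure")
}

#' @export
print.coarse_structure <- function(x, ...) {
  cat(sprintf("coarse_structure: %d residues\n", x$L))
  if (!is.null(x$ss))
    cat(sprintf("  SS: %dH %dE %dC\n", sum(x$ss == "H"), sum(x$ss == "E"),
                sum(x$ss == "C")))
  invisible(x)
}

#' Virtual C-beta coordinates
#'
#' Places a virtual C-beta 1.53 Angstrom from each C-alpha along the outward
#' bisector of the local (i-1, i, i+1) frame, tilted out of plane by 37.6
#' degrees. Chain termini and glycine residues use the C-alpha position as
#' their C-beta proxy.
#'
#' @param s a [coarse_structure()].
#' @return numeric L x 3 matrix of C-beta coordinates.
#' @export
virtual_cbeta <- function(s) {
  stopifnot(inherits(s, "coarse_structure"))
  cpp_cbeta(s$xyz, as.integer(s$seq == "G"))
}

#' Contact-map container
#'
#' Predicted residue-residue contacts from one predictor. Pairs are stored
#' with `i < j`, no duplicates, and confidences in `[0, 1]`.
#'
#' @param L sequence length.
#' @param predictions data.frame with columns `i`, `j`, `confidence`.
#' @param predictor_id label of the source predictor.
#' @return An object of class `contact_map`.
#' @export
contact_map <- function(L, predictions, predictor_id = "unknown") {
  L <- as.integer(L)
  p <- as.data.frame(predictions)
  if (nrow(p) == 0L) {
    p <- data.frame(i = integer(), j = integer(), confidence = numeric())
  } else {
    stopifnot(all(c("i", "j", "confidence") %in% names(p)))
    sw <- p$i > p$j
    tmp <- p$i[sw]; p$i[sw] <- p$j[sw]; p$j[sw] <- tmp
    if (any(p$i == p$j)) stop("self-contact (i == j) is not allowed")
    if (any(p$i < 1L | p$j > L))
      stop("contact index outside [1, L]")
    if (any(!is.finite(p$confidence) | p$confidence < 0 | p$confidence > 1))
      stop("confidence must be finite in [0, 1]")
    # collapse duplicates keeping the maximal confidence
    ord <- order(p$i, p$j, -p$confidence)
    p <- p[ord, , drop = FALSE]
    p <- p[!duplicated(p[c("i", "j")]), , drop = FALSE]
    rownames(p) <- NULL
    p$i <- as.integer(p$i); p$j <- as.integer(p$j)
  }
  structure(list(L = L, predictions = p, predictor_id = predictor_id),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map [%s]: L = %d, %d predictions\n",
              x$predictor_id, x$L, nrow(x$predictions)))
  invisible(x)
}
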