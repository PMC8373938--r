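#' Read a CASP RR contact file
#'
#' Accepts the community RR dialect: an optional `PFRMAT RR` header, optional
#' `TARGET`/`MODEL`/`END` lines, optional sequence lines, and records of the
#' form `i j d1 d2 conf` or the three-column short form `i j conf` (d1 = 0 and
#' d2 = 8 assumed). Pairs are canonicalised to `i < j` and duplicates are
#' collapsed keeping the maximal confidence.
#'
#' @param path file path.
#' @param L query length; indices above `L` are a validation error.
#' @param predictor_id label attached to the returned map.
#' @return A [contact_map()].
#' @export
read_rr <- function(path, L, predictor_id = "unknown") {
  if (!file.exists(path)) stop("RR file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (ln == "" || grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK|END)", ln))
      next
    if (grepl("^[A-Za-z]", ln)) next  # sequence line
    f <- strsplit(ln, "[[:space:]]+")[[1L]]
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v) || !(length(f) %in% c(3L, 5L)))
      stop(sprintf("malformed RR record at line %d: '%s'", k, lines[k]))
    conf <- if (length(f) == 3L) v[3L] else v[5L]
    recs[[length(recs) + 1L]] <- c(v[1L], v[2L], conf)
  }
  if (length(recs) == 0L)
    return(contact_map(L, data.frame(i = integer(), j = integer(),
                                     confidence = numeric()), predictor_id))
  m <- do.call(rbind, recs)
  if (any(m[, 1:2] != round(m[, 1:2])))
    stop("non-integer residue index in RR file")
  if (any(m[, 1:2] < 1) || any(m[, 1:2] > L))
    stop("RR contact index outside [1, ", L, "]")
  contact_map(L, data.frame(i = as.integer(m[, 1L]), j = as.integer(m[, 2L]),
                            confidence = m[, 3L]), predictor_id)
}

#' Write a contact map in CASP RR format
#'
#' Records are written as `i j 0 8 conf`, sorted by `(i, j)`.
#'
#' @param map a [contact_map()].
#' @param path output file.
#' @param seq optional query sequence to include as a sequence line.
#' @export
write_rr <- function(map, path, seq = NULL) {
  stopifnot(inherits(map, "contact_map"))
  p <- map$predictions
  p <- p[order(p$i, p$j), , drop = FALSE]
  out <- c("PFRMAT RR",
           if (!is.null(seq)) paste(seq, collapse = ""),
           sprintf("%d %d 0 8 %.6f", p$i, p$j, p$confidence),
           "END")
  writeLines(out, path)
  invisible(path)
}

#' Effective MSA depth (Nf)
#'
#' Computes the effective number of sequences of an alignment as
#' `nf = (1 / sqrt(L)) * sum_n 1 / (1 + m_n)`, where `m_n` is the number of
#' other rows with at least 80 percent identity to row `n` over columns where
#' both rows are non-gap. Row pairs sharing fewer than `0.5 * L` mutually
#' aligned columns are counted as non-neighbours.
#'
#' @param msa character vector of aligned rows (equal length; first row is the
#'   query) or a character matrix of single characters.
#' @return A list of class `msa_summary` with `L`, `N` and `nf`.
#' @export
compute_nf <- function(msa) {
  if (is.matrix(msa)) msa <- apply(msa, 1L, paste, collapse = "")
  msa <- toupper(as.character(msa))
  if (length(msa) == 0L) stop("empty MSA")
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) stop("MSA rows have unequal lengths")
  L <- lens[1L]
  if (L == 0L) stop("empty MSA rows")
  N <- length(msa)
  chm <- matrix(unlist(strsplit(msa, ""), use.names = FALSE), nrow = N, byrow = TRUE)
  gap <- chm == "-" | chm == "."
  m <- integer(N)
  if (N > 1L) {
    for (a in seq_len(N - 1L)) {
      for (b in (a + 1L):N) {
        both <- !(gap[a, ] | gap[b, ])
        nb <- sum(both)
        if (nb < 0.5 * L) next
        if (sum(chm[a, both] == chm[b, both]) / nb >= 0.8) {
          m[a] <- m[a] + 1L
          m[b] <- m[b] + 1L
        }
      }
    }
  }
  nf <- sum(1 / (1 + m)) / sqrt(L)
  structure(list(L = L, N = N, nf = nf), class = "msa_summary")
}

#' Read an aligned FASTA or A3M alignment
#'
#' Lowercase columns (A3M insert states) are removed, which restores equal row
#' lengths for A3M input.
#'
#' @param path file path.
#' @return character vector of aligned rows, named by record headers.
#' @export
read_msa <- function(path) {
  if (!file.exists(path)) stop("MSA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no FASTA records in ", path)
  seqs <- character(length(hdr))
  names(seqs) <- sub("^>\\s*", "", lines[hdr])
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    body <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    seqs[k] <- gsub("[a-z]", "", paste(body, collapse = ""))
  }
  seqs
}

#' Read a PSIPRED SS2 secondary-structure prediction
#'
#' Vertical PSIPRED format: index, residue, state (H/E/C), and the three
#' per-state probabilities (coil, helix, strand). Per-residue probabilities
#' must sum to 1 within 0.05.
#'
#' @param path file path.
#' @return A data.frame of class `sse_prediction` with columns `res`, `aa`,
#'   `state`, `p_c`, `p_h`, `p_e`.
#' @export
read_ss2 <- function(path) {
  if (!file.exists(path)) stop("SS2 file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !grepl("^#", lines)]
  f <- strsplit(lines, "[[:space:]]+")
  bad <- which(vapply(f, length, 1L) != 6L)
  if (length(bad) > 0L) stop("malformed SS2 record at data line ", bad[1L])
  m <- do.call(rbind, f)
  out <- data.frame(res = as.integer(m[, 1L]), aa = m[, 2L], state = m[, 3L],
                    p_c = as.numeric(m[, 4L]), p_h = as.numeric(m[, 5L]),
                    p_e = as.numeric(m[, 6L]), stringsAsFactors = FALSE)
  if (!all(out$state %in% c("H", "E", "C"))) stop("SS2 state must be H/E/C")
  tot <- out$p_c + out$p_h + out$p_e
  if (any(abs(tot - 1) > 0.05))
    stop("SS2 probabilities do not sum to 1 (residue ",
         out$res[which.max(abs(tot - 1))], ")")
  if (!identical(out$res, seq_len(nrow(out))))
    stop("SS2 residue numbering must be 1..L")
  class(out) <- c("sse_prediction", "data.frame")
  out
}

#' Write an SS2-format prediction for a known secondary-structure string
#'
#' Convenience writer used by the fixtures: the planned state receives
#' probability `conf`, the other two split the remainder.
#'
#' @param seq,ss character vectors (or strings) of residues and H/E/C states.
#' @param path output file.
#' @param conf probability assigned to the planned state.
#' @export
write_ss2 <- function(seq, ss, path, conf = 0.9) {
  if (length(seq) == 1L) seq <- strsplit(seq, "")[[1L]]
  if (length(ss) == 1L) ss <- strsplit(ss, "")[[1L]]
  stopifnot(length(seq) == length(ss))
  rest <- (1 - conf) / 2
  p <- matrix(rest, nrow = length(ss), ncol = 3L)  # columns C, H, E
  p[cbind(seq_along(ss), match(ss, c("C", "H", "E")))] <- conf
  writeLines(c("# PSIPRED VFORMAT-like", "",
               sprintf("%4d %s %s  %6.3f %6.3f %6.3f",
                       seq_along(ss), seq, ss, p[, 1L], p[, 2L], p[, 3L])),
             path)
  invisible(path)
}

#' Read a coarse-grained structure from a PDB file
#'
#' Reads single-chain ATOM records via bio3d, keeps C-alpha (and, implicitly
#' for the sequence, residue identity). Every residue must have a C-alpha;
#' insertion codes are unsupported.
#'
#' @param path PDB file path.
#' @return A [coarse_structure()].
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  if (length(unique(at$chain)) > 1L) stop("multi-chain structures unsupported")
  ins <- at$insert
  if (any(!is.na(ins) & ins != "")) stop("insertion codes unsupported")
  resnos <- sort(unique(at$resno))
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing <- setdiff(resnos, ca$resno)
  if (length(missing) > 0L)
    stop("missing C-alpha for residue ", missing[1L])
  ca <- ca[order(ca$resno), , drop = FALSE]
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  aa <- bio3d::aa321(ca$resid)
  aa[is.na(aa) | aa == "X"] <- "A"
  s <- coarse_structure(xyz, seq = aa)
  s$resno <- ca$resno
  s
}

#' Write a coarse-grained structure as a PDB file
#'
#' Writes C-alpha ATOM records (chain A, 1-based numbering); when
#' `with_cbeta = TRUE`, derived virtual C-beta records are written as CB atoms
#' for non-glycine residues.
#'
#' @param s a [coarse_structure()].
#' @param path output file.
#' @param with_cbeta also write virtual C-beta atoms.
#' @export
write_structure <- function(s, path, with_cbeta = FALSE) {
  stopifnot(inherits(s, "coarse_structure"))
  aa3 <- bio3d::aa123(s$seq)
  aa3[is.na(aa3)] <- "ALA"
  fmt <- function(serial, name, resn, resno, x)
    sprintf("ATOM  %5d  %-3s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, name, resn, resno, x[1L], x[2L], x[3L])
  lines <- character(0)
  serial <- 0L
  cb <- if (with_cbeta) virtual_cbeta(s) else NULL
  for (i in seq_len(s$L)) {
    serial <- serial + 1L
    lines <- c(lines, fmt(serial, "CA", aa3[i], i, s$xyz[i, ]))
    if (with_cbeta && s$seq[i] != "G") {
      serial <- serial + 1L
      lines <- c(lines, fmt(serial, "CB", aa3[i], i, cb[i, ]))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
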