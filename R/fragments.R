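#' Remove near-homologous structures from a fragment source library
#'
#' Drops every library structure whose global-alignment sequence identity to
#' the query exceeds `max_identity` (strictly greater), so fragment statistics
#' cannot be contaminated by the target's own homologues. Identity is the
#' fraction of identical aligned positions over the global (Needleman-Wunsch)
#' alignment length, computed with Biostrings.
#'
#' @param library list of [coarse_structure()] objects with sequences.
#' @param query_seq query sequence (string or character vector).
#' @param max_identity identity threshold (default 0.30).
#' @return the filtered library (same list structure), with attribute
#'   `removed` giving the indices dropped.
#' @export
homolog_filter <- function(library, query_seq, max_identity = 0.30) {
  if (length(query_seq) > 1L) query_seq <- paste(query_seq, collapse = "")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  subjects <- Biostrings::AAStringSet(
    vapply(library, function(s) paste(s$seq, collapse = ""), ""))
  al <- Biostrings::pairwiseAlignment(
    subjects, Biostrings::AAString(query_seq),
    substitutionMatrix = get("BLOSUM62"),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")
  ident <- vapply(seq_along(library), function(k) {
    a <- pat[[k]]; b <- sub[[k]]
    sum(a == b & a != "-") / length(a)
  }, 1.0)
  removed <- which(ident > max_identity)
  out <- if (length(removed) > 0L) library[-removed] else library
  attr(out, "removed") <- removed
  attr(out, "identity") <- ident
  out
}

# 3-state secondary structure from C-alpha geometry: helix and strand are
# recognised by their pseudo bond-angle/torsion ranges; everything else is
# coil. Used for library structures in place of DSSP.
geometric_ss <- function(s) {
  ang <- cpp_pseudo_angles(s$xyz)
  th <- ang$theta * 180 / pi
  ta <- ang$tau * 180 / pi
  L <- s$L
  ss <- rep("C", L)
  for (i in seq_len(L)) {
    if (is.na(th[i])) next
    tau_i <- if (!is.na(ta[i])) ta[i] else if (i > 1 && !is.na(ta[i - 1])) ta[i - 1] else NA
    if (is.na(tau_i)) next
    if (th[i] > 75 && th[i] < 108 && tau_i > 20 && tau_i < 80) ss[i] <- "H"
    else if (th[i] > 105 && th[i] < 160 && abs(tau_i) > 120) ss[i] <- "E"
  }
  ss
}

.aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Build a position-specific fragment library by gapless threading
#'
#' Every window of every library structure is scored against every query
#' (position, length) slot by the mean BLOSUM62 substitution score plus
#' `w_ssm` times the secondary-structure match fraction; the top `topk`
#' windows per slot are kept. Library secondary structure is assigned
#' geometrically from the C-alpha trace.
#'
#' @param query_seq query sequence (string or character vector).
#' @param query_ss query 3-state secondary structure (string, vector, or an
#'   `sse_prediction`).
#' @param library list of [coarse_structure()] objects (already
#'   homolog-filtered if desired).
#' @param lengths fragment lengths to thread (default 1:20).
#' @param topk fragments kept per slot (default 200).
#' @param w_ssm weight of the SS-match component.
#' @return list of class `fragment_library` with the slot table (`pos`,
#'   `len`, `source`, `sstart`, `rank`, `score`), the library structures and
#'   their geometric SS.
#' @export
gapless_thread <- function(query_seq, query_ss, library, lengths = 1:20,
                           topk = 200L, w_ssm = 1.0) {
  if (length(library) == 0L) stop("empty fragment source library")
  if (length(query_seq) == 1L && nchar(query_seq[1L]) > 1L)
    query_seq <- strsplit(query_seq, "")[[1L]]
  if (inherits(query_ss, "sse_prediction")) query_ss <- query_ss$state
  if (length(query_ss) == 1L && nchar(query_ss[1L]) > 1L)
    query_ss <- strsplit(query_ss, "")[[1L]]
  stopifnot(length(query_seq) == length(query_ss))
  lengths <- lengths[lengths >= 1L & lengths <= 20L & lengths <= length(query_seq)]
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- get("BLOSUM62")[.aa_alphabet, .aa_alphabet]
  enc <- function(x) {
    v <- match(x, .aa_alphabet) - 1L
    v[is.na(v)] <- 0L
    v
  }
  ss_code <- function(x) match(x, c("C", "H", "E")) - 1L
  lib_ss <- lapply(library, geometric_ss)
  res <- cpp_gapless_thread(enc(query_seq), ss_code(query_ss),
                            lapply(library, function(s) enc(s$seq)),
                            lapply(lib_ss, ss_code),
                            unname(as.matrix(sub)), as.integer(lengths),
                            as.integer(topk), w_ssm)
  slots <- as.data.frame(res)
  structure(list(slots = slots, library = library, lib_ss = lib_ss,
                 L = length(query_seq), topk = topk, query_ss = query_ss),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf("fragment_library: L = %d, %d slot entries from %d structures\n",
              x$L, nrow(x$slots), length(x$library)))
  invisible(x)
}

#' Derive pairwise distance profiles from co-sourced fragments
#'
#' For each residue pair `(i, j)`, distances are accumulated from every pair
#' of top-ranked fragments anchored at positions `i` and `j` that come from
#' the same source structure with a consistent register (equal source offset,
#' so both residues map into that structure under one gapless placement).
#' Histograms use 0.5 Angstrom bins on `[0, 40)`. A profile is usable iff
#' its modal bin centre lies below 9 Angstrom, it holds at least `min_obs`
#' observations, at least 60 percent of its mass lies within 1 Angstrom of
#' the mode (diffuse profiles carry no consistent signal), and both residues
#' carry a helix or strand call in the query (with a miniature source
#' library, loop-residue placements are confidently wrong more often than
#' they are informative).
#'
#' @param flib a [gapless_thread()] library.
#' @param profile_len fragment length whose slots anchor the profiles
#'   (default 9).
#' @param max_rank use fragments up to this rank (default 200).
#' @param min_obs minimal observation count for a usable profile.
#' @param max_sep maximal sequence separation of profiled pairs (default 23):
#'   with a miniature source library, co-sourced placements at larger
#'   separations reflect the library folds' global topology rather than
#'   query-specific signal, so long-range geometry is left to the contact
#'   restraints.
#' @return list of class `distance_profiles` with `pairs` (data.frame `i`,
#'   `j`, `n`, `peak`, `usable`) and `counts` (matrix, one row per pair).
#' @export
build_distance_profiles <- function(flib, profile_len = 9L, max_rank = 200L,
                                    max_sep = 23L, min_obs = 8L) {
  stopifnot(inherits(flib, "fragment_library"))
  sl <- flib$slots
  sl <- sl[sl$len == profile_len & sl$rank <= max_rank, , drop = FALSE]
  empty <- list(pairs = data.frame(i = integer(), j = integer(), n = integer(),
                                   peak = numeric(), usable = logical()),
                counts = matrix(numeric(), 0L, 80L))
  class(empty) <- "distance_profiles"
  if (nrow(sl) == 0L) return(empty)
  # group anchored fragments by (source, register offset); every position pair
  # within a group shares one gapless placement in that source structure
  off <- sl$sstart - sl$pos
  keys <- split(seq_len(nrow(sl)), paste(sl$source, off))
  acc <- new.env(parent = emptyenv())
  brks <- seq(0, 40, by = 0.5)
  for (rows in keys) {
    ps <- sort(unique(sl$pos[rows]))
    if (length(ps) < 2L) next
    src <- sl$source[rows[1L]]
    o <- off[rows[1L]]
    xyz <- flib$library[[src]]$xyz
    for (a in seq_len(length(ps) - 1L)) {
      for (b in (a + 1L):length(ps)) {
        i <- ps[a]; j <- ps[b]
        if (j - i > max_sep) next
        d <- sqrt(sum((xyz[i + o, ] - xyz[j + o, ])^2))
        if (d >= 40) next
        key <- paste(i, j)
        bin <- findInterval(d, brks)
        cur <- acc[[key]]
        if (is.null(cur)) cur <- numeric(80L)
        cur[bin] <- cur[bin] + 1
        acc[[key]] <- cur
      }
    }
  }
  keys2 <- ls(acc)
  if (length(keys2) == 0L) return(empty)
  ij <- do.call(rbind, strsplit(keys2, " "))
  counts <- do.call(rbind, lapply(keys2, function(k) acc[[k]]))
  i <- as.integer(ij[, 1L]); j <- as.integer(ij[, 2L])
  ord <- order(i, j)
  counts <- counts[ord, , drop = FALSE]
  i <- i[ord]; j <- j[ord]
  mode_bin <- apply(counts, 1L, which.max)
  peak <- (mode_bin - 0.5) * 0.5
  nobs <- rowSums(counts)
  conc <- vapply(seq_along(mode_bin), function(k) {
    w <- max(1L, mode_bin[k] - 2L):min(80L, mode_bin[k] + 2L)
    sum(counts[k, w]) / max(nobs[k], 1)
  }, 1.0)
  sse_res <- flib$query_ss %in% c("H", "E")
  pairs <- data.frame(i = i, j = j, n = nobs, peak = peak,
                      usable = peak < 9 & nobs >= min_obs & conc >= 0.6 &
                        sse_res[i] & sse_res[j])
  structure(list(pairs = pairs, counts = counts), class = "distance_profiles")
}

#' Look up one distance profile
#'
#' Profiles are symmetric: `(i, j)` and `(j, i)` return the same profile.
#'
#' @param profiles a `distance_profiles` object.
#' @param i,j residue indices.
#' @return list with `i`, `j`, `counts`, `peak`, `usable`, or `NULL` if the
#'   pair has no profile.
#' @export
get_profile <- function(profiles, i, j) {
  a <- min(i, j); b <- max(i, j)
  k <- which(profiles$pairs$i == a & profiles$pairs$j == b)
  if (length(k) == 0L) return(NULL)
  list(i = a, j = b, counts = profiles$counts[k, ],
       peak = profiles$pairs$peak[k], usable = profiles$pairs$usable[k])
}

#' Serialise distance profiles as TSV
#'
#' One row per (pair, occupied bin): `i`, `j`, `bin_center`, `count`,
#' `usable`.
#'
#' @param profiles a `distance_profiles` object.
#' @param path output file.
#' @export
write_profiles <- function(profiles, path) {
  rows <- do.call(rbind, lapply(seq_len(nrow(profiles$pairs)), function(k) {
    occ <- which(profiles$counts[k, ] > 0)
    if (length(occ) == 0L) return(NULL)
    data.frame(i = profiles$pairs$i[k], j = profiles$pairs$j[k],
               bin_center = (occ - 0.5) * 0.5,
               count = profiles$counts[k, occ],
               usable = profiles$pairs$usable[k])
  }))
  if (is.null(rows))
    rows <- data.frame(i = integer(), j = integer(), bin_center = numeric(),
                       count = numeric(), usable = logical())
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Pack top fragments into the flat layout consumed by the C++ sampler (move
# M5). Slots below `min_len` cannot be superposed and are skipped.
fraglib_for_sampler <- function(flib, max_rank = 25L, min_len = 3L) {
  empty <- list(slot_pos = integer(), slot_len = integer(),
                slot_off = integer(), slot_n = integer(),
                coords = matrix(numeric(), 0L, 3L))
  if (is.null(flib)) return(empty)
  sl <- flib$slots
  sl <- sl[sl$len >= min_len & sl$rank <= max_rank, , drop = FALSE]
  if (nrow(sl) == 0L) return(empty)
  key <- paste(sl$pos, sl$len)
  groups <- split(seq_len(nrow(sl)), key)
  slot_pos <- integer(0); slot_len <- integer(0)
  slot_off <- integer(0); slot_n <- integer(0)
  blocks <- list()
  offset <- 0L
  for (g in groups) {
    p <- sl$pos[g[1L]]; len <- sl$len[g[1L]]
    mats <- lapply(g, function(r) {
      s0 <- sl$sstart[r]
      flib$library[[sl$source[r]]]$xyz[s0:(s0 + len - 1L), , drop = FALSE]
    })
    slot_pos <- c(slot_pos, p - 1L)          # 0-based for C++
    slot_len <- c(slot_len, len)
    slot_off <- c(slot_off, offset)
    slot_n <- c(slot_n, length(mats))
    blocks[[length(blocks) + 1L]] <- do.call(rbind, mats)
    offset <- offset + length(mats) * len
  }
  list(slot_pos = slot_pos, slot_len = slot_len, slot_off = slot_off,
       slot_n = slot_n, coords = do.call(rbind, blocks))
}
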