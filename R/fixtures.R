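# run code under a private RNG state, leaving the caller's stream untouched
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Topology specification for a synthetic fold
#'
#' Describes a toy protein as a sequence of secondary-structure blocks
#' (helix/strand with lengths) connected by loops, plus a packing plan.
#'
#' @param types character vector of block types (`"H"` or `"E"`).
#' @param lengths integer block lengths (helices >= 6, strands >= 4).
#' @param loops integer loop lengths between consecutive blocks
#'   (length `length(types) - 1`).
#' @param packing `"bundle"` (default), `"hairpin"` or `"sandwich"`; controls
#'   inter-block spacing.
#' @return list of class `topology_spec`.
#' @export
topology_spec <- function(types, lengths, loops = NULL,
                          packing = c("bundle", "hairpin", "sandwich")) {
  packing <- match.arg(packing)
  stopifnot(all(types %in% c("H", "E")), length(lengths) == length(types))
  if (is.null(loops)) loops <- rep(4L, max(0L, length(types) - 1L))
  stopifnot(length(loops) == length(types) - 1L)
  total <- sum(lengths) + sum(loops)
  if (total < 20 || total > 300) stop("total length must be in [20, 300]")
  structure(list(types = types, lengths = as.integer(lengths),
                 loops = as.integer(loops), packing = packing, L = total),
            class = "topology_spec")
}

# residue alphabets biased by secondary structure, so threading scores carry
# signal on toy sequences
.ss_alphabet <- list(
  H = c("A", "L", "E", "K", "Q", "M", "R"),
  E = c("V", "I", "Y", "F", "T", "W"),
  C = c("G", "S", "P", "N", "D"))

sample_sequence <- function(ss) {
  vapply(ss, function(st) sample(.ss_alphabet[[st]], 1L), "")
}

# equal-bond arc between two anchors: n_bonds segments of length `bond` whose
# endpoints are a and b, bowed into the plane spanned by (b - a) and `perp`
arc_bridge <- function(a, b, n_pts, bond = 3.8, perp = c(0, 0, 1)) {
  n_b <- n_pts + 1L
  chord <- sqrt(sum((b - a)^2))
  if (chord > 0.999 * n_b * bond) stop("infeasible packing: loop span too long")
  if (n_pts == 0L) return(matrix(numeric(), 0L, 3L))
  u <- (b - a) / max(chord, 1e-9)
  p <- perp - sum(perp * u) * u
  if (sqrt(sum(p^2)) < 1e-6) p <- c(u[2L], -u[1L], 0)
  p <- p / sqrt(sum(p^2))
  if (chord < 1e-6) {  # degenerate: closed circle through a
    alpha <- 2 * pi / n_b
  } else {
    g <- function(al) sin(n_b * al / 2) / sin(al / 2) - chord / bond
    alpha <- stats::uniroot(g, c(1e-9, 2 * pi / n_b - 1e-9), tol = 1e-12)$root
  }
  R <- bond / (2 * sin(alpha / 2))
  h <- sqrt(max(R^2 - (chord / 2)^2, 0))
  mid <- (a + b) / 2
  # enumerate circle centres and walk directions; keep the candidate that ends
  # at b and bulges the farthest toward the outward perpendicular
  best <- NULL
  best_bulge <- -Inf
  for (sgn_c in c(-1, 1)) {
    centre <- mid + sgn_c * h * p
    va <- a - centre
    phi0 <- atan2(sum(va * p), sum(va * u))
    for (dir in c(1, -1)) {
      phis <- phi0 + dir * alpha * seq_len(n_b)
      pts <- t(vapply(phis, function(phi)
        centre + R * (cos(phi) * u + sin(phi) * p), numeric(3L)))
      if (sqrt(sum((pts[n_b, ] - b)^2)) > 1e-6) next
      bulge <- max((pts[, 1L] - mid[1L]) * p[1L] + (pts[, 2L] - mid[2L]) * p[2L] +
                     (pts[, 3L] - mid[3L]) * p[3L])
      if (bulge > best_bulge) {
        best_bulge <- bulge
        best <- pts[seq_len(n_pts), , drop = FALSE]
      }
    }
  }
  if (is.null(best)) stop("infeasible packing: loop arc has no solution")
  best
}

# ideal rigid SSE block built from the state's pseudo angles, starting at the
# origin and oriented along +z
ideal_block <- function(type, len) {
  ang <- ideal_pseudo_angles()
  st <- if (type == "H") 2L else 3L
  theta <- rep(ang$theta[st], len)
  tau <- rep(ang$tau[st], len)
  x <- cpp_build_chain(len, theta, tau, 3.8)
  if (len < 3L) return(x)
  # align the block axis (first -> last) with +z
  axis <- x[len, ] - x[1L, ]
  axis <- axis / sqrt(sum(axis^2))
  v <- cross3(axis, c(0, 0, 1))
  s <- sqrt(sum(v^2))
  if (s > 1e-9) {
    ang2 <- atan2(s, sum(axis * c(0, 0, 1)))
    x <- rotate_about(x, c(0, 0, 0), v / s, ang2)
  }
  sweep(x, 2L, x[1L, ])
}

cross3 <- function(a, b) c(a[2L] * b[3L] - a[3L] * b[2L],
                           a[3L] * b[1L] - a[1L] * b[3L],
                           a[1L] * b[2L] - a[2L] * b[1L])

rotate_about <- function(x, origin, axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  t(apply(x, 1L, function(v) {
    v <- v - origin
    vr <- v * cos(angle) + cross3(k, v) * sin(angle) +
      k * sum(k * v) * (1 - cos(angle))
    vr + origin
  }))
}

#' Generate a synthetic fold with its native contact map
#'
#' Builds an ideal-geometry C-alpha trace for a [topology_spec()]: each SSE
#' block uses the state's ideal pseudo angles (helix rise 1.5, strand rise
#' 3.3 Angstrom per residue under a 3.8 Angstrom virtual bond); blocks are
#' packed side by side with alternating direction at a type-dependent spacing
#' (helix pairs 9.5, strand pairs 4.9, mixed 10 Angstrom) with a small
#' seed-dependent tilt and jitter; loops are equal-bond arcs between block
#' anchors, so all adjacent C-alpha distances are 3.8 +/- 0.01 Angstrom. The
#' sequence is sampled from SSE-biased alphabets. The native map holds all
#' pairs with virtual C-beta distance below 8 Angstrom at separation >= 6.
#'
#' @param spec a [topology_spec()].
#' @param seed integer seed (fixtures are bit-reproducible per (spec, seed)).
#' @return list with `structure` (a [coarse_structure()] carrying `seq` and
#'   `ss`), `native` (a [contact_map()]) and `spec`.
#' @export
make_toy_structure <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "topology_spec"))
  local_seed(seed, {
    nb <- length(spec$types)
    spacing <- function(t1, t2) {
      if (t1 == "E" && t2 == "E") 4.9 else if (t1 == "H" && t2 == "H") 9.5 else 10
    }
    # block axis positions: bundles close into a regular polygon so that the
    # first and last SSE also pack (a 3-helix bundle has three interfaces);
    # hairpins and sandwiches stay sequential in a plane
    centres <- matrix(0, nb, 2L)
    if (spec$packing == "bundle" && nb >= 3L) {
      side <- max(vapply(2L:nb, function(k)
        spacing(spec$types[k - 1L], spec$types[k]), 1.0))
      r <- side / (2 * sin(pi / nb))
      angs <- 2 * pi * (seq_len(nb) - 1L) / nb
      centres <- cbind(r * cos(angs), r * sin(angs))
    } else if (nb > 1L) {
      for (k in 2L:nb)
        centres[k, 1L] <- centres[k - 1L, 1L] +
          spacing(spec$types[k - 1L], spec$types[k])
    }
    blocks <- vector("list", nb)
    for (k in seq_len(nb)) {
      blk <- ideal_block(spec$types[k], spec$lengths[k])
      up <- k %% 2L == 1L
      if (!up) blk <- rotate_about(blk, c(0, 0, 0), c(1, 0, 0), pi)
      tilt_axis <- stats::rnorm(3L)
      blk <- rotate_about(blk, c(0, 0, 0), tilt_axis / sqrt(sum(tilt_axis^2)),
                          stats::runif(1L, -0.06, 0.06))
      org <- centres[k, ] + stats::runif(2L, -0.3, 0.3)
      # place block start near z = 0 for up blocks, near its top for down
      blk <- sweep(blk, 2L, blk[1L, ]) + rep(1, nrow(blk)) %o% c(org[1L], org[2L], 0)
      if (!up) blk[, 3L] <- blk[, 3L] - min(blk[, 3L] - 0)
      blocks[[k]] <- blk
    }
    # assemble chain: blocks joined by equal-bond arc loops
    xyz <- blocks[[1L]]
    ss <- rep(spec$types[1L], spec$lengths[1L])
    if (nb > 1L) {
      core <- colMeans(do.call(rbind, blocks))
      for (k in 2L:nb) {
        a <- xyz[nrow(xyz), ]
        b <- blocks[[k]][1L, ]
        nl <- spec$loops[k - 1L]
        # bow the loop away from the packed core so it cannot cut through SSEs
        perp <- (a + b) / 2 - core
        if (sqrt(sum(perp^2)) < 1e-6) perp <- c(0, 0, 1)
        lp <- arc_bridge(a, b, nl, 3.8, perp)
        xyz <- rbind(xyz, lp, blocks[[k]])
        ss <- c(ss, rep("C", nl), rep(spec$types[k], spec$lengths[k]))
      }
    }
    seq <- sample_sequence(ss)
    s <- coarse_structure(xyz, seq = seq, ss = ss)
    list(structure = s, native = native_contacts(s), spec = spec)
  })
}

#' Corrupt a native contact map to a target precision
#'
#' Emits `round(coverage * L)` predictions with an exact-count composition:
#' `round(precision * n)` native pairs and the remainder non-native pairs at
#' separation >= 6 whose separations are sampled from the native separation
#' distribution (so separation alone cannot identify decoys). Confidences are
#' logistically calibrated: `conf = floor + (1 - floor) * plogis(slope * (y -
#' 0.5) + noise)` with correctness `y`, so higher-confidence predictions are
#' more likely correct.
#'
#' @param native a [contact_map()] of true contacts.
#' @param precision target fraction of true contacts in `[0, 1]`.
#' @param coverage emitted contacts per residue.
#' @param slope calibration slope (>= 0).
#' @param conf_floor lower bound of the confidence range.
#' @param seed integer seed.
#' @param predictor_id label for the emitted map.
#' @return A [contact_map()].
#' @export
corrupt_contacts <- function(native, precision, coverage = 2.4, slope = 2,
                             conf_floor = 0, seed = 1L,
                             predictor_id = "synthetic") {
  stopifnot(inherits(native, "contact_map"),
            precision >= 0, precision <= 1, coverage > 0)
  L <- native$L
  nat <- native$predictions
  n <- round(coverage * L)
  n_true <- round(precision * n)
  if (precision > 0 && nrow(nat) == 0L) stop("native map is empty")
  if (n_true > nrow(nat))
    stop(sprintf("infeasible counts: need %d true contacts, native has %d",
                 n_true, nrow(nat)))
  local_seed(seed, {
    nat_key <- paste(nat$i, nat$j)
    idx <- sample.int(nrow(nat), n_true)
    true_p <- nat[idx, c("i", "j"), drop = FALSE]
    n_false <- n - n_true
    false_p <- NULL
    if (n_false > 0L) {
      seps <- if (nrow(nat) > 0L) nat$j - nat$i else
        sample(6:max(6L, L - 1L), 10L, replace = TRUE)
      got <- 0L
      acc_i <- integer(n_false); acc_j <- integer(n_false)
      guard <- 0L
      while (got < n_false) {
        guard <- guard + 1L
        if (guard > 200000L) stop("infeasible counts: cannot place decoy pairs")
        s <- sample(seps, 1L)
        i <- sample.int(L - s, 1L)
        j <- i + s
        key <- paste(i, j)
        if (key %in% nat_key) next
        if (got > 0L && key %in% paste(acc_i[seq_len(got)], acc_j[seq_len(got)]))
          next
        got <- got + 1L
        acc_i[got] <- i; acc_j[got] <- j
      }
      false_p <- data.frame(i = acc_i, j = acc_j)
    }
    true_p$y <- rep(1, nrow(true_p))
    if (!is.null(false_p)) false_p$y <- rep(0, nrow(false_p))
    pairs <- rbind(true_p, false_p)
    z <- slope * (pairs$y - 0.5) + stats::rnorm(nrow(pairs))
    conf <- conf_floor + (1 - conf_floor) * stats::plogis(z)
    contact_map(L, data.frame(i = pairs$i, j = pairs$j, confidence = conf),
                predictor_id)
  })
}

#' Synthetic multi-predictor contact ensemble
#'
#' One corrupted map per synthetic predictor, with per-tier precision and
#' coverage; predictor ids are chosen so [assign_tiers()] routes them to the
#' intended tiers (respre = very_high, deepcov = high, metapsicov2 = medium,
#' ccmpred = low).
#'
#' @param native a [contact_map()].
#' @param tier_profile data.frame with columns `tier`, `precision`,
#'   `coverage` (defaults to precisions 0.7/0.55/0.45/0.30 at coverage 0.8;
#'   toy natives support roughly 0.5-0.8 true contacts per residue, which
#'   bounds the feasible precision x coverage product).
#' @param slope,conf_floor calibration passed to [corrupt_contacts()].
#' @param seed integer seed.
#' @return list of [contact_map()]s.
#' @export
make_predictor_ensemble <- function(native,
                                    tier_profile = data.frame(
                                      tier = c("very_high", "high", "medium", "low"),
                                      precision = c(0.7, 0.55, 0.45, 0.30),
                                      coverage = 0.8),
                                    slope = 2, conf_floor = 0, seed = 1L) {
  ids <- c(very_high = "respre", high = "deepcov", medium = "metapsicov2",
           low = "ccmpred")
  lapply(seq_len(nrow(tier_profile)), function(k) {
    corrupt_contacts(native, tier_profile$precision[k],
                     tier_profile$coverage[k], slope = slope,
                     conf_floor = conf_floor, seed = seed + 1000L * k,
                     predictor_id = ids[[tier_profile$tier[k]]])
  })
}

#' Synthetic alignment with a target effective depth
#'
#' Builds an MSA whose [compute_nf()] is within 10 percent of `target_nf` by
#' stacking mutually dissimilar (< 80 percent identity) full-length rows:
#' each such row contributes `1 / sqrt(L)` to Nf.
#'
#' @param L row length.
#' @param target_nf desired effective depth (> 0).
#' @param seed integer seed.
#' @param query optional query sequence for the first row.
#' @param max_rows cap on alignment size; an unreachable target is an error
#'   reporting the achievable depth.
#' @return character vector of aligned rows (first row = query).
#' @export
make_synthetic_msa <- function(L, target_nf, seed = 1L, query = NULL,
                               max_rows = 5000L) {
  stopifnot(target_nf > 0)
  k <- max(1L, round(target_nf * sqrt(L)))
  if (k > max_rows)
    stop(sprintf("target nf unreachable with %d rows (achieved nf would be %.3f)",
                 max_rows, max_rows / sqrt(L)))
  local_seed(seed, {
    rows <- character(k)
    rows[1L] <- if (!is.null(query)) paste(query, collapse = "") else
      paste(sample(.aa_alphabet, L, replace = TRUE), collapse = "")
    if (k > 1L)
      for (r in 2L:k)
        rows[r] <- paste(sample(.aa_alphabet, L, replace = TRUE), collapse = "")
    rows
  })
}

#' Miniature fragment source library
#'
#' Generates `n_structures` toy folds of varied topology (helix bundles,
#' hairpins and mixed folds of 2-4 blocks) with SSE-biased sequences, for use
#' as a gapless-threading source library.
#'
#' @param n_structures number of structures.
#' @param seed integer seed.
#' @param write_dir optional directory; when given, each structure is written
#'   as `libNNN.pdb` and a FASTA index `library.fasta` is created.
#' @return list of [coarse_structure()] objects (invisibly also written).
#' @export
make_mini_library <- function(n_structures = 50L, seed = 1L, write_dir = NULL) {
  stopifnot(n_structures >= 1L)
  specs <- local_seed(seed, {
    lapply(seq_len(n_structures), function(k) {
      cls <- sample(c("a", "b", "ab"), 1L)
      nb <- if (cls == "a") sample(2:4, 1L) else sample(3:4, 1L)
      types <- switch(cls,
                      a = rep("H", nb),
                      b = rep("E", nb),
                      ab = sample(c("H", "E"), nb, replace = TRUE))
      # keep block heights comparable so connecting loops stay feasible
      lens <- ifelse(types == "H", sample(10:16, nb, replace = TRUE),
                     sample(5:8, nb, replace = TRUE))
      loops <- sample(4:6, nb - 1L, replace = TRUE)
      packing <- if (all(types == "E")) "hairpin" else "bundle"
      topology_spec(types, lens, loops, packing)
    })
  })
  lib <- lapply(seq_len(n_structures), function(k)
    make_toy_structure(specs[[k]], seed = seed + 7919L * k)$structure)
  if (!is.null(write_dir)) {
    dir.create(write_dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- character(0)
    for (k in seq_len(n_structures)) {
      write_structure(lib[[k]], file.path(write_dir, sprintf("lib%03d.pdb", k)))
      fasta <- c(fasta, sprintf(">lib%03d", k), paste(lib[[k]]$seq, collapse = ""))
    }
    writeLines(fasta, file.path(write_dir, "library.fasta"))
  }
  lib
}
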