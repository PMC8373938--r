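#' Cluster decoys and rank cluster centroids
#'
#' Iterative densest-ball clustering on the pairwise C-alpha RMSD matrix:
#' repeatedly find the decoy with the most neighbours within the cutoff, form
#' a cluster from it and its neighbours, remove them, and continue. The
#' cutoff starts at `rmsd_cutoff_init` and is auto-scaled within
#' `[2.5, 8]` Angstrom until the largest cluster holds 10-70 percent of the
#' decoys. Clusters are ranked by size (largest cluster = lowest free-energy
#' basin), ties broken by lower mean energy. Each cluster's medoid is the
#' member minimising the summed RMSD to its co-members; the reported centroid
#' model averages the members' coordinates after superposition onto the
#' medoid, which cancels thermal noise around the basin.
#'
#' @param decoys a `decoy_set` from [run_remc()], or a list of L x 3
#'   coordinate matrices.
#' @param energies optional per-decoy energies (taken from the decoy set if
#'   present).
#' @param rmsd_cutoff_init initial neighbour cutoff (Angstrom).
#' @param max_clusters maximal number of reported clusters.
#' @return list of class `cluster_result`: `members` (list of index vectors),
#'   `sizes`, `centroids` (decoy indices), `centroid_coords`, `cutoff`.
#' @export
cluster_decoys <- function(decoys, energies = NULL, rmsd_cutoff_init = 3.5,
                           max_clusters = 5L) {
  coords <- if (inherits(decoys, "decoy_set")) decoys$coords else decoys
  if (is.null(energies) && inherits(decoys, "decoy_set"))
    energies <- decoys$energy
  n <- length(coords)
  if (n < 1L) stop("need at least one decoy")
  if (is.null(energies)) energies <- rep(0, n)
  L <- nrow(coords[[1L]])
  stack <- do.call(rbind, lapply(coords, function(x) as.numeric(t(x))))
  D <- cpp_rmsd_matrix(stack, L)

  largest_frac <- function(cutoff) {
    max(rowSums(D < cutoff)) / n
  }
  cutoff <- rmsd_cutoff_init
  for (it in 1:40) {
    f <- largest_frac(cutoff)
    if (f > 0.70 && cutoff > 2.5) cutoff <- max(2.5, cutoff * 0.9)
    else if (f < 0.10 && cutoff < 8) cutoff <- min(8, cutoff * 1.1)
    else break
  }

  avail <- rep(TRUE, n)
  members <- list()
  while (any(avail) && length(members) < max_clusters) {
    counts <- rowSums(D[, avail, drop = FALSE] < cutoff) * avail
    seed <- which.max(counts)
    mem <- which(avail & D[seed, ] < cutoff)
    if (length(mem) == 0L) mem <- seed
    members[[length(members) + 1L]] <- mem
    avail[mem] <- FALSE
  }
  sizes <- lengths(members)
  mean_e <- vapply(members, function(m) mean(energies[m]), 1.0)
  ord <- order(-sizes, mean_e)
  members <- members[ord]
  sizes <- sizes[ord]
  centroids <- vapply(members, function(mem) {
    if (length(mem) == 1L) return(mem)
    ss <- rowSums(D[mem, mem, drop = FALSE])
    mem[which.min(ss)]
  }, 1L)
  centroid_coords <- lapply(seq_along(members), function(k) {
    med <- coords[[centroids[k]]]
    mem <- members[[k]]
    if (length(mem) == 1L) return(med)
    acc <- matrix(0, nrow(med), 3L)
    for (id in mem) acc <- acc + cpp_kabsch_fit(coords[[id]], med)
    acc / length(mem)
  })
  structure(list(members = members, sizes = sizes, centroids = centroids,
                 centroid_coords = centroid_coords, cutoff = cutoff,
                 n_decoys = n),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters from %d decoys (cutoff %.2f A)\n",
              length(x$members), x$n_decoys, x$cutoff))
  cat("  sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Native contact map of a structure
#'
#' All residue pairs whose virtual C-beta distance is below 8 Angstrom at
#' sequence separation >= `min_sep`.
#'
#' @param s a [coarse_structure()].
#' @param min_sep minimal sequence separation (default 6).
#' @return A [contact_map()] with confidence 1 for every native pair.
#' @export
native_contacts <- function(s, min_sep = 6L) {
  cb <- virtual_cbeta(s)
  pr <- which(upper.tri(matrix(0, s$L, s$L)), arr.ind = TRUE)
  pr <- pr[pr[, 2L] - pr[, 1L] >= min_sep, , drop = FALSE]
  d <- sqrt(rowSums((cb[pr[, 1L], , drop = FALSE] - cb[pr[, 2L], , drop = FALSE])^2))
  keep <- d < 8
  contact_map(s$L, data.frame(i = pr[keep, 1L], j = pr[keep, 2L],
                              confidence = rep(1, sum(keep))), "native")
}

.range_bounds <- list(short = c(6L, 11L), medium = c(12L, 23L),
                      long = c(24L, .Machine$integer.max),
                      all = c(6L, .Machine$integer.max))

#' Precision of predicted contacts against a native structure
#'
#' A prediction is correct iff the native virtual C-beta distance is below 8
#' Angstrom. Separation classes follow the community convention: short 6-11,
#' medium 12-23, long >= 24. Precision is computed over the `top_k`
#' highest-confidence predictions in the class (all of them if `top_k`
#' exceeds the pool).
#'
#' @param predicted a [contact_map()] or `restraint_set`.
#' @param native a [coarse_structure()].
#' @param top_k number of top predictions to assess (default `Inf`).
#' @param range_class one of `"short"`, `"medium"`, `"long"`, `"all"`.
#' @return list: `precision`, `k` (effective count), `n_correct`.
#' @export
contact_precision <- function(predicted, native, top_k = Inf,
                              range_class = "all") {
  stopifnot(range_class %in% names(.range_bounds))
  if (inherits(predicted, "restraint_set"))
    predicted <- restraints_as_map(predicted)
  stopifnot(inherits(predicted, "contact_map"),
            inherits(native, "coarse_structure"))
  if (predicted$L != native$L) stop("length mismatch")
  p <- predicted$predictions
  b <- .range_bounds[[range_class]]
  sep <- p$j - p$i
  p <- p[sep >= b[1L] & sep <= b[2L], , drop = FALSE]
  if (nrow(p) == 0L) return(list(precision = NA_real_, k = 0L, n_correct = 0L))
  p <- p[order(-p$confidence, p$i, p$j), , drop = FALSE]
  k <- min(nrow(p), top_k)
  p <- p[seq_len(k), , drop = FALSE]
  cb <- virtual_cbeta(native)
  d <- sqrt(rowSums((cb[p$i, , drop = FALSE] - cb[p$j, , drop = FALSE])^2))
  nc <- sum(d < 8)
  list(precision = nc / k, k = as.integer(k), n_correct = as.integer(nc))
}

#' Restraint satisfaction rate in a model
#'
#' Fraction of restraints whose virtual C-beta distance in the model is below
#' 8 Angstrom.
#'
#' @param restraints a `restraint_set` or [contact_map()] (non-empty).
#' @param s a [coarse_structure()].
#' @return numeric rate in `[0, 1]`.
#' @export
satisfaction_rate <- function(restraints, s) {
  if (inherits(restraints, "contact_map")) restraints <- restraints$predictions
  if (nrow(restraints) == 0L) stop("satisfaction rate undefined for empty restraints")
  cb <- virtual_cbeta(s)
  d <- sqrt(rowSums((cb[restraints$i, , drop = FALSE] -
                     cb[restraints$j, , drop = FALSE])^2))
  mean(d < 8)
}

#' Least-squares C-alpha RMSD
#'
#' RMSD after optimal (Kabsch) superposition of equal-length structures.
#'
#' @param a,b structures or L x 3 matrices.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  xa <- if (inherits(a, "coarse_structure")) a$xyz else as.matrix(a)
  xb <- if (inherits(b, "coarse_structure")) b$xyz else as.matrix(b)
  if (nrow(xa) != nrow(xb)) stop("length mismatch")
  cpp_kabsch_rmsd(xa, xb)
}

#' TM-score normalisation distance
#'
#' `d0 = 1.24 (L - 15)^(1/3) - 1.8`, floored at 0.5 Angstrom.
#'
#' @param L target length.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(L) {
  pmax(0.5, 1.24 * sign(L - 15) * abs(L - 15)^(1 / 3) - 1.8)
}

#' TM-score of a model against a native structure
#'
#' `max (1/L) sum 1 / (1 + (d_i / d0)^2)` over iteratively refined
#' superpositions seeded from contiguous windows; values lie in (0, 1] and a
#' score above 0.5 indicates the same fold. Both structures must have equal
#' length with a 1:1 residue correspondence (normalisation uses the common
#' length).
#'
#' @param model,native structures or L x 3 matrices of equal length.
#' @return TM-score.
#' @export
tm_score <- function(model, native) {
  xm <- if (inherits(model, "coarse_structure")) model$xyz else as.matrix(model)
  xn <- if (inherits(native, "coarse_structure")) native$xyz else as.matrix(native)
  if (nrow(xm) != nrow(xn)) stop("length mismatch")
  cpp_tm_score(xm, xn, tm_d0(nrow(xm)))
}

#' Evaluate a model against a native structure
#'
#' Bundles TM-score, C-alpha RMSD, restraint satisfaction and contact
#' precision by separation class into one report.
#'
#' @param model a [coarse_structure()].
#' @param native a [coarse_structure()] of equal length.
#' @param restraints optional `restraint_set` for the satisfaction rate.
#' @return list of class `eval_report`.
#' @export
evaluate_model <- function(model, native, restraints = NULL) {
  out <- list(tm = tm_score(model, native),
              rmsd = kabsch_rmsd(model, native))
  if (!is.null(restraints) && nrow(restraints) > 0L) {
    out$satisfaction <- satisfaction_rate(restraints, model)
    out$restraint_precision <- contact_precision(restraints, native)$precision
  }
  mc <- native_contacts(model)
  out$model_contacts <- nrow(mc$predictions)
  out$model_contact_accuracy <-
    if (out$model_contacts > 0L) contact_precision(mc, native)$precision else NA_real_
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: TM-score %.3f, RMSD %.2f A\n", x$tm, x$rmsd))
  if (!is.null(x$satisfaction))
    cat(sprintf("  satisfaction %.3f, restraint precision %.3f\n",
                x$satisfaction, x$restraint_precision))
  if (!is.na(x$model_contact_accuracy))
    cat(sprintf("  model contacts %d (accuracy %.3f)\n",
                x$model_contacts, x$model_contact_accuracy))
  invisible(x)
}
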