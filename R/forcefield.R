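#' Gradient width of the contact well
#'
#' The only free parameter of the three-gradient contact potential. Short
#' targets use a narrow well (6 Angstrom below 100 residues); targets above
#' 200 residues use 12 Angstrom so that distant pairs are drawn in smoothly;
#' in between the width bridges linearly.
#'
#' @param L target length (residues).
#' @return gradient width `d_b` in Angstrom.
#' @export
gradient_width <- function(L) {
  stopifnot(all(L >= 1))
  ifelse(L < 100, 6, ifelse(L > 200, 12, 6 + 6 * (L - 100) / 100))
}

#' Three-gradient contact restraint energy
#'
#' Four branches on the C-beta distance `d`: a flat well `-U` below 8
#' Angstrom; a strong sinusoidal rise from 8 to `D = 8 + d_b`; a weak
#' sinusoidal rise from `D` to 80; and a flat plateau `+U` beyond 80. The
#' curve is continuous with zero slope at all three transition points, so the
#' restraint pulls pairs toward the well without singularities, strongly near
#' the well and weakly at long range (where false positives would otherwise
#' overpack the structure).
#'
#' @param d distance(s) in Angstrom.
#' @param U well depth (>= 0).
#' @param d_b gradient width in Angstrom.
#' @return energy value(s).
#' @export
econ <- function(d, U = 1, d_b = 6) {
  stopifnot(all(is.finite(d)), all(d >= 0), U >= 0, d_b > 0)
  as.numeric(cpp_econ(as.numeric(d), U, d_b))
}

#' Adjacent C-alpha bond penalty
#'
#' Quadratic ramp penalising adjacent residue pairs whose C-alpha distance
#' exceeds 4 Angstrom; guards against backbone breaks after fragment moves.
#'
#' @param d adjacent C-alpha distance(s) in Angstrom.
#' @param w_ca weight.
#' @return energy value(s).
#' @export
e_ca <- function(d, w_ca = 1) {
  stopifnot(all(d >= 0))
  w_ca * pmax(d - 4, 0)^2
}

#' Distance-profile statistical energy
#'
#' Negative log of the normalised, smoothed fragment-distance histogram:
#' `-log((h(d) + eps) / (h_max + eps))` on 0.5 Angstrom bins, zero below the
#' first occupied bin and above 20 Angstrom. Only profiles whose modal bin
#' lies below 9 Angstrom are usable.
#'
#' @param d distance(s) in Angstrom.
#' @param profile a `distance_profile` row from [build_distance_profiles()]
#'   (list with `counts`, `usable`).
#' @param eps regulariser.
#' @return energy value(s).
#' @export
e_dp <- function(d, profile, eps = 1e-3) {
  if (!isTRUE(profile$usable)) stop("distance profile is not usable (no peak < 9 A)")
  tab <- profile_energy_table(profile$counts, eps)
  b <- findInterval(d, seq(0, 40, by = 0.5), rightmost.closed = FALSE)
  out <- numeric(length(d))
  inside <- b >= 1 & b <= length(tab)
  out[inside] <- tab[b[inside]]
  out
}

# Energy lookup table for one profile: 80 bins of 0.5 A on [0, 40).
# Peak-preserving smoothing (fractional spill into the four neighbouring
# bins): the modal bin keeps its raw height and scores exactly zero energy,
# while near-peak bins are softened so sparse histograms do not punish small
# deviations. Support: [first occupied bin, 20 A]; zero outside.
profile_energy_table <- function(counts, eps = 1e-3) {
  stopifnot(length(counts) == 80L)
  k <- c(0.1, 0.35, 1, 0.35, 0.1)
  h <- stats::filter(c(0, 0, counts, 0, 0), k, sides = 2)[3:82]
  h[is.na(h)] <- 0
  occupied <- which(counts > 0)
  tab <- numeric(80L)
  if (length(occupied) == 0L) return(tab)
  hmax <- max(h)
  lo <- min(occupied)
  hi <- min(40L, 80L)  # 20 A cap = bin 40
  idx <- lo:hi
  tab[idx] <- -log((h[idx] + eps) / (hmax + eps))
  tab
}

#' Assemble the coarse-grained energy model
#'
#' Bundles the selected contact restraints, fragment distance profiles,
#' secondary-structure prediction and term weights into the model evaluated
#' by [total_energy()] and sampled by [run_remc()]. Weights default to
#' `(w_con, w_dp, w_ca, w_ev, w_ss, w_rg) = (1, 3, 1, 1, 0.5, 0.2)`; the
#' distance-profile weight 3.00 lets fragment statistics veto false-positive
#' contacts. Generic chain terms (excluded volume below 3.6 Angstrom,
#' SS-bias toward ideal pseudo-angles for confidently predicted H/E, and a
#' radius-of-gyration band around `2.2 * L^0.38`) supply the minimal physics
#' the restraints alone do not.
#'
#' @param seq residue sequence (string or character vector).
#' @param restraints a `restraint_set` (may have zero rows for unguided runs).
#' @param profiles output of [build_distance_profiles()] or `NULL`.
#' @param ss secondary-structure states (H/E/C) or an `sse_prediction`;
#'   `NULL` disables the SS bias.
#' @param weights named or positional numeric vector of the six term weights.
#' @param d_b gradient width; defaults to [gradient_width()] of the length.
#' @param ss_conf_min minimal state confidence for the SS bias.
#' @return list of class `energy_model`.
#' @export
energy_model <- function(seq, restraints = NULL, profiles = NULL, ss = NULL,
                         weights = c(w_con = 1, w_dp = 3, w_ca = 1,
                                     w_ev = 1, w_ss = 0.5, w_rg = 0.2),
                         d_b = NULL, ss_conf_min = 0.7) {
  if (length(seq) == 1L && nchar(seq[1L]) > 1L) seq <- strsplit(seq, "")[[1L]]
  L <- length(seq)
  stopifnot(length(weights) == 6L, all(weights >= 0))
  if (is.null(d_b)) d_b <- gradient_width(L)
  ss_state <- rep(0L, L)
  ss_w <- rep(0, L)
  if (!is.null(ss)) {
    if (inherits(ss, "sse_prediction")) {
      stopifnot(nrow(ss) == L)
      st <- ss$state
      conf <- pmax(ss$p_h, ss$p_e, ss$p_c)
    } else {
      if (length(ss) == 1L) ss <- strsplit(ss, "")[[1L]]
      stopifnot(length(ss) == L)
      st <- ss
      conf <- rep(1, L)
    }
    ss_state <- match(st, c("C", "H", "E")) - 1L
    # bias only residues whose local pseudo-angle stencil lies in one SSE:
    # angles at block edges involve loop atoms and have no ideal value
    uniform <- vapply(seq_len(L), function(i) {
      w <- max(1L, i - 1L):min(L, i + 2L)
      all(st[w] == st[i])
    }, TRUE)
    ss_w <- ifelse(ss_state > 0L & conf >= ss_conf_min & uniform, 1, 0)
  }
  if (is.null(restraints) || nrow(restraints) == 0L) {
    rest <- matrix(integer(), 0L, 2L)
    restU <- numeric(0)
  } else {
    if (max(restraints$j) > L) stop("restraint index exceeds sequence length")
    rest <- cbind(restraints$i, restraints$j) - 1L
    restU <- restraints$U
    if (any(restU <= 0)) stop("well depths must be positive")
  }
  if (is.null(profiles) || length(profiles$pairs) == 0L || nrow(profiles$pairs) == 0L) {
    ppairs <- matrix(integer(), 0L, 2L)
    ptab <- matrix(numeric(), 0L, 80L)
  } else {
    use <- profiles$pairs$usable
    ppairs <- cbind(profiles$pairs$i[use], profiles$pairs$j[use]) - 1L
    ptab <- do.call(rbind, lapply(which(use), function(k)
      profile_energy_table(profiles$counts[k, ])))
    if (is.null(ptab)) ptab <- matrix(numeric(), 0L, 80L)
  }
  m <- list(L = L, seq = as.character(seq),
            rest = rest, restU = restU,
            ppairs = ppairs, ptab = ptab,
            weights = unname(as.numeric(weights)),
            db = d_b,
            is_gly = as.integer(seq == "G"),
            ss = ss_state, ss_w = ss_w,
            theta0 = ideal_pseudo_angles()$theta,
            tau0 = ideal_pseudo_angles()$tau,
            rg0 = 2.2 * L^0.38)
  class(m) <- "energy_model"
  m
}

# Ideal C-alpha pseudo bond angles / torsions (radians) by state C/H/E.
# The helix values give a 1.5 A rise per residue, the strand values an
# extended 3.3 A rise, under a fixed 3.8 A virtual bond.
ideal_pseudo_angles <- function() {
  list(theta = c(120, 91, 123) * pi / 180,
       tau = c(180, 50, -165) * pi / 180)
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(paste0("energy_model: L = %d, %d restraints, %d profiles, ",
                     "d_b = %.1f A\n"),
              x$L, nrow(x$rest), nrow(x$ppairs), x$db))
  invisible(x)
}

#' Total energy with per-term breakdown
#'
#' Evaluates the weighted sum of the contact restraint term (on virtual
#' C-beta distances), distance-profile term, adjacent-C-alpha penalty,
#' excluded volume, SS bias and radius-of-gyration band.
#'
#' @param s a [coarse_structure()] (or bare L x 3 coordinate matrix).
#' @param m an [energy_model()].
#' @return list of class `energy_breakdown` with `total` and the six terms.
#' @export
total_energy <- function(s, m) {
  xyz <- if (inherits(s, "coarse_structure")) s$xyz else as.matrix(s)
  if (nrow(xyz) != m$L) stop("structure length does not match energy model")
  tt <- as.numeric(cpp_energy_terms(xyz, unclass(m)))
  out <- list(total = sum(tt), con = tt[1L], dp = tt[2L], ca = tt[3L],
              ev = tt[4L], ss = tt[5L], rg = tt[6L])
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf(paste0("energy: total %.3f (con %.3f, dp %.3f, ca %.3f, ",
                     "ev %.3f, ss %.3f, rg %.3f)\n"),
              x$total, x$con, x$dp, x$ca, x$ev, x$ss, x$rg))
  invisible(x)
}

#' Incremental energy change for a local move
#'
#' Computes `E(after) - E(before)` by re-evaluating only interactions that
#' touch the moved residue window (expanded for the C-beta and pseudo-angle
#' stencils); the global radius-of-gyration term is recomputed in full. This
#' is the evaluation used inside the Monte Carlo sampler.
#'
#' @param before,after structures (or coordinate matrices) of equal length.
#' @param window integer `c(first, last)` 1-based range of moved residues.
#' @param m an [energy_model()].
#' @return numeric energy difference.
#' @export
delta_energy <- function(before, after, window, m) {
  x0 <- if (inherits(before, "coarse_structure")) before$xyz else as.matrix(before)
  x1 <- if (inherits(after, "coarse_structure")) after$xyz else as.matrix(after)
  stopifnot(nrow(x0) == m$L, nrow(x1) == m$L, length(window) == 2L)
  if (window[1L] > window[2L]) return(0)
  cpp_energy_delta(x0, x1, as.integer(window[1L]) - 1L,
                   as.integer(window[2L]) - 1L, unclass(m))
}

#' Dump the contact-potential curve for plotting
#'
#' Writes (d, E) pairs for the three-gradient restraint as TSV.
#'
#' @param path output file.
#' @param U well depth.
#' @param d_b gradient width.
#' @param step grid step in Angstrom.
#' @return the file path, invisibly.
#' @export
dump_econ_curve <- function(path, U = 1, d_b = 6, step = 0.1) {
  d <- seq(0, 90, by = step)
  utils::write.table(data.frame(d = d, E = econ(d, U, d_b)), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
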