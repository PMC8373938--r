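#' Geometric replica temperature ladder
#'
#' `T_k = T_min * (T_max / T_min)^((k - 1) / (n - 1))`: strictly increasing
#' with exact endpoints.
#'
#' @param n number of replicas (>= 2).
#' @param T_min,T_max temperature bounds (energy units, `0 < T_min < T_max`).
#' @return numeric vector of length `n`, class `replica_ladder`.
#' @export
temperature_ladder <- function(n, T_min = 0.02, T_max = 2.5) {
  if (n < 2L) stop("need at least 2 replicas")
  if (!(T_min > 0 && T_max > T_min)) stop("require 0 < T_min < T_max")
  structure(T_min * (T_max / T_min)^((seq_len(n) - 1) / (n - 1)),
            class = "replica_ladder")
}

#' Metropolis acceptance
#'
#' Accepts an energy change `dE` at temperature `T` with probability
#' `min(1, exp(-dE / T))`.
#'
#' @param dE energy change(s).
#' @param T temperature (> 0).
#' @param seed integer seed for the draw stream.
#' @return logical vector of acceptances.
#' @export
metropolis_accept <- function(dE, T, seed = 1L) {
  stopifnot(T > 0)
  as.logical(cpp_metropolis(as.numeric(dE), T, as.integer(seed)))
}

#' Replica-swap step
#'
#' Attempts configuration swaps between adjacent replicas (odd or even
#' pairing), accepting with probability
#' `min(1, exp((1/T_k - 1/T_{k+1}) (E_k - E_{k+1})))`.
#'
#' @param energies per-replica energies.
#' @param ladder temperatures (same length).
#' @param seed integer seed.
#' @param parity 0 for pairs (1,2),(3,4),...; 1 for (2,3),(4,5),...
#' @return list with `perm` (new state index per replica) and `swapped`
#'   (logical per attempted pair).
#' @export
replica_swap <- function(energies, ladder, seed = 1L, parity = 0L) {
  n <- length(energies)
  stopifnot(length(ladder) == n)
  perm <- seq_len(n)
  ks <- seq.int(1L + parity, n - 1L, by = 2L)
  u <- u01_stream(seed, length(ks))
  swapped <- logical(length(ks))
  for (q in seq_along(ks)) {
    k <- ks[q]
    arg <- (1 / ladder[k] - 1 / ladder[k + 1L]) *
      (energies[perm[k]] - energies[perm[k + 1L]])
    if (arg >= 0 || u[q] < exp(arg)) {
      tmp <- perm[k]; perm[k] <- perm[k + 1L]; perm[k + 1L] <- tmp
      swapped[q] <- TRUE
    }
  }
  list(perm = perm, swapped = swapped)
}

# deterministic uniform draws decoupled from R's global RNG
u01_stream <- function(seed, n) as.numeric(cpp_u01(n, as.numeric(seed)))

#' Propose a single Monte Carlo move
#'
#' Applies one of the eleven moves to a structure and reports the perturbed
#' coordinates, the touched residue window, and whether the proposal
#' succeeded (moves whose bond-length check fails are flagged rejections and
#' leave the structure unchanged). Move ids: 1 torsion perturbation, 2 local
#' displacement, 3 bond-angle perturbation, 4 SS-ideal reset, 5 fragment
#' substitution, 6 crankshaft, 7 segment shift, 8 loop re-draw, 9
#' terminal-tail hinge, 10 SSE translation, 11 SSE rotation.
#'
#' @param s a [coarse_structure()].
#' @param move_id integer in 1..11.
#' @param m an [energy_model()] (supplies SS states for moves 4/8/10/11).
#' @param flib optional [gapless_thread()] library (required by move 5).
#' @param seed integer seed.
#' @return list with `ok`, `coords`, `window` (1-based, inclusive).
#' @export
propose_move <- function(s, move_id, m, flib = NULL, seed = 1L) {
  stopifnot(inherits(s, "coarse_structure"), move_id %in% 1:11)
  fl <- fraglib_for_sampler(flib)
  sse <- sse_segments(m$ss)
  cpp_propose_move(s$xyz, as.integer(move_id), unclass(m), fl, sse,
                   as.integer(seed))
}

# contiguous H/E runs of length >= 3 as an n x 2 matrix (1-based)
sse_segments <- function(ss_state) {
  r <- rle(ss_state > 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 3L
  out <- cbind(starts[keep], ends[keep])
  storage.mode(out) <- "integer"
  if (nrow(out) == 0L) out <- matrix(integer(), 0L, 2L)
  out
}

#' Default sampler settings
#'
#' The `desk` preset (8 replicas, 100 cycles, 1 run) keeps full simulations
#' in the minutes range on one CPU; the `paper`-scale preset uses 40
#' replicas, 500 cycles and 5 independent runs. Both use `round(30 *
#' sqrt(L))` moves per replica per cycle.
#'
#' @param preset `"desk"` or `"paper"`.
#' @return list of sampler settings.
#' @export
remc_config <- function(preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  if (preset == "desk")
    list(n_replicas = 8L, n_cycles = 100L, n_runs = 1L,
         T_min = 0.02, T_max = 2.5, stride = 1L, snap_burnin = 0.3,
         level_probs_low = c(0.65, 0.30, 0.05),
         level_probs_high = c(0.40, 0.35, 0.25),
         max_seconds = 600, preset = preset)
  else
    list(n_replicas = 40L, n_cycles = 500L, n_runs = 5L,
         T_min = 0.02, T_max = 2.5, stride = 5L, snap_burnin = 0.3,
         level_probs_low = c(0.65, 0.30, 0.05),
         level_probs_high = c(0.40, 0.35, 0.25),
         max_seconds = 50 * 3600, preset = preset)
}

# extended-chain initial conformation: SS-ideal pseudo angles where the model
# has a confident H/E call, near-extended elsewhere
initial_chain <- function(m) {
  ideal <- ideal_pseudo_angles()
  st <- ifelse(m$ss_w > 0, m$ss + 1L, 1L)  # 1-based state, coil if unconfident
  theta <- ideal$theta[st]
  tau <- ideal$tau[st]
  cpp_build_chain(m$L, theta, tau, 3.8)
}

#' Run a replica-exchange Monte Carlo folding simulation
#'
#' Fragment-assembly REMC under an [energy_model()]: every cycle each replica
#' attempts `round(30 * sqrt(L))` Metropolis moves at its own temperature,
#' after which adjacent replicas swap configurations under the Metropolis
#' criterion (odd/even alternating pairing). Snapshots are collected from the
#' low-temperature half of the ladder at a fixed cycle stride; move-level
#' probabilities anneal toward residue-level moves at low temperature. The
#' run is deterministic for a fixed seed and honours a wall-clock cap.
#'
#' @param m an [energy_model()].
#' @param flib optional [gapless_thread()] fragment library (enables move 5).
#' @param config settings from [remc_config()] (fields may be overridden).
#' @param seed integer master seed; replica streams are derived from it.
#' @param init optional initial L x 3 coordinates (defaults to an extended
#'   chain with SS-ideal angles).
#' @param monitor_restraints optional restraint set whose satisfaction rate
#'   is logged each cycle (defaults to the model's own restraints).
#' @return list of class `decoy_set`: `coords` (list of L x 3 matrices),
#'   `energy`, `replica`, `cycle`, `log` (per-cycle data.frame), `final`,
#'   `cycles_done`, `timed_out`, `seed`.
#' @export
run_remc <- function(m, flib = NULL, config = remc_config("desk"), seed = 1L,
                     init = NULL, monitor_restraints = NULL) {
  stopifnot(inherits(m, "energy_model"))
  L <- m$L
  if (is.null(init)) init <- initial_chain(m)
  init <- as.matrix(init)
  stopifnot(nrow(init) == L)
  mon <- if (!is.null(monitor_restraints)) {
    cbind(monitor_restraints$i, monitor_restraints$j)
  } else if (nrow(m$rest) > 0L) m$rest + 1L else matrix(integer(), 0L, 2L)
  storage.mode(mon) <- "integer"
  temps <- as.numeric(temperature_ladder(config$n_replicas, config$T_min,
                                         config$T_max))
  cfg <- list(temps = temps,
              n_cycles = as.integer(config$n_cycles),
              moves_per_cycle = as.integer(round(30 * sqrt(L))),
              stride = as.integer(config$stride),
              snap_from = as.integer(floor(config$snap_burnin * config$n_cycles)),
              level_probs_low = config$level_probs_low,
              level_probs_high = config$level_probs_high,
              monitor = mon,
              max_seconds = as.numeric(config$max_seconds))
  fl <- fraglib_for_sampler(flib)
  res <- cpp_run_remc(init, unclass(m), fl, sse_segments(m$ss), cfg,
                      as.numeric(seed))
  ns <- nrow(res$snapshots)
  coords <- lapply(seq_len(ns), function(k)
    matrix(res$snapshots[k, ], ncol = 3L, byrow = TRUE))
  lg <- as.data.frame(res$log)
  names(lg) <- c("energy", "satisfaction", "acceptance")
  lg$cycle <- seq_len(nrow(lg))
  structure(list(coords = coords, energy = as.numeric(res$energy),
                 replica = as.integer(res$replica),
                 cycle = as.integer(res$cycle),
                 log = lg[, c("cycle", "energy", "satisfaction", "acceptance")],
                 final = res$final, cycles_done = res$cycles_done,
                 timed_out = res$timed_out, seed = seed, L = L),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat(sprintf("decoy_set: %d snapshots (L = %d, %d cycles, seed %s)\n",
              length(x$coords), x$L, x$cycles_done, format(x$seed)))
  invisible(x)
}

#' Spearman trend of a trajectory statistic
#'
#' Rank correlation between cycle index and a per-cycle statistic (by default
#' the restraint satisfaction rate), computed after discarding the first
#' `burnin` fraction of cycles as equilibration.
#'
#' @param decoys a `decoy_set` from [run_remc()].
#' @param what column of the cycle log.
#' @param burnin fraction of initial cycles discarded (default 0.1).
#' @return `htest` object from [stats::cor.test()] (Spearman).
#' @export
trajectory_trend <- function(decoys, what = "satisfaction", burnin = 0.1) {
  lg <- decoys$log
  keep <- lg$cycle > burnin * max(lg$cycle)
  lg <- lg[keep, , drop = FALSE]
  stats::cor.test(lg$cycle, lg[[what]], method = "spearman", exact = FALSE)
}
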