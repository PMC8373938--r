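#' Build a full run configuration
#'
#' Collects every stage's settings into one object. The `desk` preset (8
#' replicas, 100 cycles, 1 run per seed) keeps complete folds in the minutes
#' range; `paper` scale (40 replicas, 500 cycles, 5 runs) is available for
#' long production runs. A YAML file with the same field names may override
#' any value.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param seed master seed.
#' @param yaml_path optional YAML override file.
#' @param ... direct field overrides (take precedence over YAML).
#' @return list of class `run_config`.
#' @export
fold_config <- function(preset = c("desk", "paper"), seed = 1L,
                        yaml_path = NULL, ...) {
  preset <- match.arg(preset)
  cfg <- remc_config(preset)
  cfg$seed <- as.integer(seed)
  cfg$weights <- c(w_con = 1, w_dp = 3, w_ca = 1, w_ev = 1, w_ss = 0.5,
                   w_rg = 0.2)
  cfg$w_con <- 1.0
  cfg$tier_params <- tier_params()
  cfg$fragment_lengths <- 1:20
  cfg$fragment_topk <- 200L
  cfg$profile_len <- 9L
  cfg$sampler_frag_rank <- 25L
  cfg$cluster_replica_max <- 1L
  if (!is.null(yaml_path)) {
    ov <- yaml::read_yaml(yaml_path)
    cfg[names(ov)] <- ov
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Run the complete folding pipeline
#'
#' Orchestrates restraint selection, fragment library construction,
#' replica-exchange folding, decoy clustering and (optionally) evaluation as
#' one reproducible run: contact maps are combined and filtered into
#' restraints, fragments are threaded from the source library and converted
#' into distance profiles, `n_runs` independent REMC simulations are pooled,
#' and the five largest decoy clusters yield `model1..model5`. When no
#' restraint survives selection the run proceeds unguided (inherent force
#' field only) and is flagged as such in the manifest.
#'
#' @param seq query sequence (string or character vector).
#' @param ss secondary-structure states (string/vector or `sse_prediction`).
#' @param maps list of [contact_map()]s (may be empty for unguided runs).
#' @param nf effective MSA depth (from [compute_nf()]); defaults to 1.
#' @param library fragment source list (from [make_mini_library()] or read
#'   from PDB files); `NULL` disables fragments and profiles.
#' @param native optional native [coarse_structure()] for evaluation.
#' @param config a [fold_config()].
#' @param out_dir optional run directory; when given, models, logs, selected
#'   restraints and a JSON manifest are written there.
#' @return list of class `fold_run`: `models` (list of [coarse_structure()]),
#'   `clusters`, `restraints`, `decoys` (pooled), `logs` (per run),
#'   `eval` (per model, if native given), `unguided`, `config`.
#' @export
run_fold <- function(seq, ss, maps = list(), nf = 1, library = NULL,
                     native = NULL, config = fold_config("desk"),
                     out_dir = NULL) {
  if (length(seq) == 1L && nchar(seq[1L]) > 1L) seq <- strsplit(seq, "")[[1L]]
  L <- length(seq)

  restraints <- if (length(maps) > 0L) {
    select_restraints(maps, nf = nf, params = config$tier_params,
                      w_con = config$w_con)
  } else {
    empty <- data.frame(i = integer(), j = integer(), U = numeric(),
                        confidence = numeric(), predictor = character(),
                        tier = character())
    attr(empty, "L") <- L
    attr(empty, "nf") <- nf
    class(empty) <- c("restraint_set", "data.frame")
    empty
  }
  unguided <- nrow(restraints) == 0L

  flib <- NULL
  profiles <- NULL
  if (!is.null(library) && length(library) > 0L) {
    library <- homolog_filter(library, seq)
    if (length(library) > 0L) {
      flib <- gapless_thread(seq, ss, library,
                             lengths = config$fragment_lengths,
                             topk = config$fragment_topk)
      profiles <- build_distance_profiles(flib, config$profile_len)
    }
  }

  m <- energy_model(seq, restraints = if (unguided) NULL else restraints,
                    profiles = profiles, ss = ss, weights = config$weights)

  monitor <- if (nrow(restraints) > 0L) restraints else NULL
  runs <- lapply(seq_len(config$n_runs), function(r)
    run_remc(m, flib = flib, config = config,
             seed = config$seed + 1000003L * (r - 1L),
             monitor_restraints = monitor))

  decoys <- list(coords = do.call(c, lapply(runs, `[[`, "coords")),
                 energy = do.call(c, lapply(runs, `[[`, "energy")),
                 replica = do.call(c, lapply(runs, `[[`, "replica")),
                 cycle = do.call(c, lapply(runs, `[[`, "cycle")))
  if (length(decoys$coords) == 0L)
    decoys <- list(coords = list(initial_chain(m)), energy = NA_real_,
                   replica = 1L, cycle = 0L)
  # final models come from the coldest replica's basin; warmer low-half
  # replicas stay in the decoy set for trajectory statistics
  rmax <- if (!is.null(config$cluster_replica_max)) config$cluster_replica_max else 1L
  sel <- which(decoys$replica <= rmax)
  if (length(sel) < 10L) sel <- seq_along(decoys$coords)
  cl <- cluster_decoys(decoys$coords[sel], decoys$energy[sel])
  models <- lapply(cl$centroid_coords, coarse_structure, seq = seq)

  ev <- NULL
  if (!is.null(native)) {
    ev <- lapply(models, evaluate_model, native = native,
                 restraints = if (unguided) NULL else restraints)
  }

  out <- structure(list(models = models, clusters = cl,
                        restraints = restraints, decoys = decoys,
                        logs = lapply(runs, `[[`, "log"),
                        eval = ev, unguided = unguided, config = config,
                        L = L),
                   class = "fold_run")
  if (!is.null(out_dir)) write_fold_run(out, out_dir)
  out
}

#' @export
print.fold_run <- function(x, ...) {
  cat(sprintf("fold_run: L = %d, %d restraints%s, %d decoys, %d models\n",
              x$L, nrow(x$restraints), if (x$unguided) " (unguided)" else "",
              length(x$decoys$coords), length(x$models)))
  if (!is.null(x$eval))
    cat(sprintf("  model1: TM-score %.3f, RMSD %.2f A\n",
                x$eval[[1L]]$tm, x$eval[[1L]]$rmsd))
  invisible(x)
}

# write models, logs, restraints and a JSON manifest into a run directory
write_fold_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(run$models))
    write_structure(run$models[[k]], file.path(out_dir, sprintf("model%d.pdb", k)))
  for (r in seq_along(run$logs))
    utils::write.table(run$logs[[r]],
                       file.path(out_dir, sprintf("trajectory_run%d.tsv", r)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (nrow(run$restraints) > 0L)
    write_rr(restraints_as_map(run$restraints),
             file.path(out_dir, "selected.rr"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("confold")),
    L = run$L,
    seed = run$config$seed,
    preset = run$config$preset,
    unguided = run$unguided,
    n_restraints = nrow(run$restraints),
    n_decoys = length(run$decoys$coords),
    cluster_sizes = as.integer(run$clusters$sizes),
    config_hash = config_hash(run$config))
  if (!is.null(run$eval))
    manifest$eval <- lapply(run$eval, function(e)
      list(tm = e$tm, rmsd = e$rmsd, satisfaction = e$satisfaction))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

# order-stable hash of the configuration (provenance in the manifest)
config_hash <- function(cfg) {
  cfg$tier_params <- NULL
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v), collapse = ","),
                                ""), collapse = ";")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% .Machine$integer.max)
}
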