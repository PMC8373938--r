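# Shared fixtures, built once per test run and memoised. Everything is
# generated in code from fixed seeds; nothing is stored on disk.

.fx <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# the 52-residue three-helix bundle (3 x 14 helix + 2 x 5 loops)
bundle52 <- function() memo("bundle52", function() {
  make_toy_structure(topology_spec(c("H", "H", "H"), c(14, 14, 14), c(5, 5)),
                     seed = 3)
})

# mini fragment source library shared across tests
minilib <- function() memo("minilib", function() make_mini_library(30, seed = 99))

# threaded fragment library + profiles for the bundle
bundle_flib <- function() memo("bundle_flib", function() {
  tt <- bundle52()
  lib <- homolog_filter(minilib(), tt$structure$seq)
  gapless_thread(tt$structure$seq, paste(tt$structure$ss, collapse = ""), lib)
})

bundle_profiles <- function() memo("bundle_profiles", function()
  build_distance_profiles(bundle_flib()))

# perfect-contact restraints for the bundle (all native contacts, calibrated
# confidences)
bundle_restraints <- function() memo("bundle_restraints", function() {
  tt <- bundle52()
  cm <- corrupt_contacts(tt$native, precision = 1,
                         coverage = nrow(tt$native$predictions) / tt$structure$L,
                         seed = 5, predictor_id = "respre")
  select_restraints(list(cm), nf = 30)
})

bundle_model <- function() memo("bundle_model", function() {
  tt <- bundle52()
  energy_model(tt$structure$seq, restraints = bundle_restraints(),
               profiles = bundle_profiles(),
               ss = paste(tt$structure$ss, collapse = ""))
})

# guided desk REMC runs of the bundle for seeds 1..5 (criteria 5 and 6 reuse)
bundle_runs <- function() memo("bundle_runs", function() {
  m <- bundle_model()
  lapply(1:5, function(sd)
    run_remc(m, flib = bundle_flib(), config = remc_config("desk"), seed = sd))
})

# small random perturbed copy of a structure
jitter_coords <- function(xyz, sd = 0.2, seed = 1) {
  local_seed_test(seed, xyz + matrix(stats::rnorm(length(xyz), 0, sd),
                                     nrow(xyz), 3))
}

local_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

random_rotation <- function(seed = 1) {
  local_seed_test(seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
    matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
             2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
             2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
           3, 3, byrow = TRUE)
  })
}

initial_chain_for_test <- function(m) confold:::initial_chain(m)
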