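test_that("the temperature ladder is geometric with exact endpoints", {
  expect_equal(as.numeric(temperature_ladder(2, 1, 4)), c(1, 4))
  expect_equal(as.numeric(temperature_ladder(3, 1, 4)), c(1, 2, 4))
  tl <- as.numeric(temperature_ladder(40, 0.02, 2.5))
  expect_length(tl, 40)
  expect_true(all(diff(tl) > 0))
  expect_equal(tl[c(1, 40)], c(0.02, 2.5))
  expect_error(temperature_ladder(1, 1, 2), "replicas")
  expect_error(temperature_ladder(5, 2, 1), "T_min")
})

test_that("Metropolis acceptance matches its closed form", {
  expect_true(all(metropolis_accept(rep(-1, 100), T = 1, seed = 1)))
  expect_false(any(metropolis_accept(rep(1e6, 100), T = 1, seed = 1)))
  # dE = T log 2 accepts with probability 1/2
  acc <- metropolis_accept(rep(2 * log(2), 1e5), T = 2, seed = 42)
  expect_equal(mean(acc), 0.5, tolerance = 0.01)
})

test_that("replica swaps follow the two-temperature Metropolis criterion", {
  # uphill state at the colder temperature: always swap
  sw <- replica_swap(c(5, 1), c(1, 2), seed = 1)
  expect_true(sw$swapped[1])
  # equal energies: exponent 0, always swap
  expect_true(replica_swap(c(3, 3), c(1, 2), seed = 2)$swapped[1])
  # arg = -log 2: empirical swap rate 1/2
  T1 <- 1; T2 <- 2
  dE <- -log(2) / (1 / T1 - 1 / T2)
  hits <- vapply(1:1e5, function(s)
    replica_swap(c(dE, 0), c(T1, T2), seed = s)$swapped[1], TRUE)
  expect_equal(mean(hits), 0.5, tolerance = 0.01)
})

test_that("torsion moves change only downstream coordinates", {
  tt <- bundle52()
  m <- bundle_model()
  s <- tt$structure
  for (seed in 1:20) {
    mv <- propose_move(s, 1, m, seed = seed)
    if (!mv$ok) next
    a <- mv$window[1]
    if (a > 1)
      expect_lt(max(abs(mv$coords[1:(a - 1), ] - s$xyz[1:(a - 1), ])), 1e-12)
    expect_gt(max(abs(mv$coords[a:s$L, ] - s$xyz[a:s$L, ])), 0)
  }
})

test_that("tail hinge rotations keep the tail internally rigid", {
  tt <- bundle52()
  m <- bundle_model()
  s <- tt$structure
  found <- 0
  for (seed in 1:10) {
    mv <- propose_move(s, 9, m, seed = seed)
    if (!mv$ok) next
    found <- found + 1
    idx <- mv$window[1]:mv$window[2]
    d0 <- as.matrix(dist(s$xyz[idx, , drop = FALSE]))
    d1 <- as.matrix(dist(mv$coords[idx, , drop = FALSE]))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
  expect_gt(found, 0)
})

test_that("fragment substitution preserves the bond-length invariant", {
  tt <- bundle52()
  m <- bundle_model()
  s <- tt$structure
  flib <- bundle_flib()
  ok <- 0
  for (seed in 1:40) {
    mv <- propose_move(s, 5, m, flib = flib, seed = seed)
    if (!mv$ok) next
    ok <- ok + 1
    bd <- sqrt(rowSums((mv$coords[-1, ] - mv$coords[-s$L, ])^2))
    expect_true(all(bd >= 3.4 - 1e-9 & bd <= 4.2 + 1e-9))
  }
  expect_gt(ok, 0)
})

test_that("every accepted move keeps bonds inside the chain invariant", {
  # flat energy: all proposals that pass their internal checks are accepted
  tt <- bundle52()
  m0 <- energy_model(tt$structure$seq, ss = paste(tt$structure$ss, collapse = ""),
                     weights = rep(0, 6))
  flib <- bundle_flib()
  x <- tt$structure$xyz
  n_acc <- 0
  for (k in 1:2000) {
    mv <- propose_move(coarse_structure(x, tt$structure$seq),
                       ((k - 1) %% 11) + 1, m0, flib = flib, seed = k)
    if (!mv$ok) next
    dE <- delta_energy(x, mv$coords, mv$window, m0)
    expect_equal(dE, 0)  # flat field: every proposal is free
    x <- mv$coords
    n_acc <- n_acc + 1
    if (n_acc %% 100 == 0) {
      bd <- sqrt(rowSums((x[-1, ] - x[-nrow(x), ])^2))
      expect_true(all(bd >= 3.4 - 1e-9 & bd <= 4.2 + 1e-9))
    }
  }
  expect_gt(n_acc, 1000)
  bd <- sqrt(rowSums((x[-1, ] - x[-nrow(x), ])^2))
  expect_true(all(bd >= 3.4 - 1e-9 & bd <= 4.2 + 1e-9))
})

test_that("REMC runs are deterministic, sized as configured, and re-evaluable", {
  m <- bundle_model()
  cfg <- remc_config("desk")
  cfg$n_cycles <- 12L
  d1 <- run_remc(m, config = cfg, seed = 7)
  d2 <- run_remc(m, config = cfg, seed = 7)
  expect_identical(d1$coords, d2$coords)          # bitwise determinism
  expect_identical(d1$log, d2$log)
  d3 <- run_remc(m, config = cfg, seed = 8)
  expect_false(identical(d1$coords, d3$coords))
  # snapshot energies match re-evaluation
  for (k in seq_len(min(5, length(d1$coords))))
    expect_equal(d1$energy[k], total_energy(d1$coords[[k]], m)$total,
                 tolerance = 1e-6)
  # moves per cycle follow 30 sqrt(L)
  expect_equal(as.integer(round(30 * sqrt(m$L))), 216L)
})

test_that("zero-cycle runs return no snapshots and the initial chain as final", {
  m <- bundle_model()
  cfg <- remc_config("desk")
  cfg$n_cycles <- 0L
  d <- run_remc(m, config = cfg, seed = 1)
  expect_length(d$coords, 0L)
  expect_equal(d$final, initial_chain_for_test(m))
})

test_that("replica energies rise with temperature after burn-in", {
  tt <- bundle52()
  m <- bundle_model()
  cfg <- remc_config("desk")
  cfg$n_cycles <- 60L
  cfg$stride <- 1L
  cfg$snap_burnin <- 0.5
  d <- run_remc(m, config = cfg, seed = 3)
  me <- tapply(d$energy, d$replica, mean)
  expect_true(all(diff(me[order(as.integer(names(me)))]) > -1))
  # lowest replica clearly below the warmest sampled one
  expect_lt(me[["1"]], me[[as.character(max(d$replica))]])
})
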