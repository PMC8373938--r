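test_that("the contact well reproduces its printed branch values", {
  # U = 1, d_b = 6 => D = 14
  expect_equal(econ(5, 1, 6), -1)
  expect_equal(econ(11, 1, 6), -0.5)          # midpoint of the strong bridge
  expect_equal(econ(47, 1, 6), 0.5)           # midpoint of the weak bridge
  expect_equal(econ(14, 1, 6), 0)             # both bridges meet at zero
  expect_equal(econ(81, 1, 6), 1)
})

test_that("the contact well is continuous, smooth and monotone for all params", {
  for (U in c(0.1, 1, 5)) {
    for (db in c(6, 9, 12)) {
      D <- 8 + db
      h <- 1e-7
      for (pt in c(8, D, 80)) {
        expect_lt(abs(econ(pt - h, U, db) - econ(pt + h, U, db)), 1e-6 * U)
        deriv <- (econ(pt + h, U, db) - econ(pt - h, U, db)) / (2 * h)
        expect_lt(abs(deriv), 1e-6 * U)
      }
      d <- seq(8, 80, by = 0.01)
      e <- econ(d, U, db)
      expect_true(all(diff(e) >= -1e-12))
      expect_true(all(e >= -U - 1e-12 & e <= U + 1e-12))
    }
  }
})

test_that("the strong bridge pulls harder than the weak one", {
  U <- 1; db <- 6; D <- 8 + db
  off <- seq(0.05, 0.45, by = 0.05)
  f_strong <- abs(econ(8 + off * (D - 8) + 1e-5, U, db) -
                    econ(8 + off * (D - 8) - 1e-5, U, db)) / 2e-5
  f_weak <- abs(econ(D + off * (80 - D) + 1e-5, U, db) -
                  econ(D + off * (80 - D) - 1e-5, U, db)) / 2e-5
  expect_true(all(f_strong > f_weak))
})

test_that("gradient width follows the length schedule", {
  expect_equal(gradient_width(80), 6)
  expect_equal(gradient_width(250), 12)
  expect_equal(gradient_width(150), 9)
  Ls <- seq(50, 280, by = 5)
  expect_true(all(diff(gradient_width(Ls)) >= 0))
})

test_that("the adjacent-bond penalty ramps quadratically above 4 A", {
  expect_equal(e_ca(3.8), 0)
  expect_equal(e_ca(4.0), 0)
  expect_equal(e_ca(5.0), 1.0)
  expect_equal(e_ca(6.0, w_ca = 2), 8.0)
})

test_that("profile energies are zero at the mode and bounded by the support", {
  counts <- numeric(80)
  counts[11] <- 200                       # isolated peak at 5.25 A
  counts[30] <- 3
  prof <- list(counts = counts, usable = TRUE)
  expect_equal(e_dp(5.25, prof), 0)
  # empty in-support bin: -log(eps / (hmax + eps))
  expect_equal(e_dp(10.2, prof), -log(1e-3 / 200.001), tolerance = 1e-6)
  expect_equal(e_dp(25, prof), 0)         # beyond the 20 A support cap
  expect_equal(e_dp(1.0, prof), 0)        # below the first occupied bin
  expect_error(e_dp(5, list(counts = counts, usable = FALSE)), "usable")
})

test_that("total energy reduces to the restraint sum in a pure-contact model", {
  tt <- bundle52()
  s <- tt$structure
  rs <- bundle_restraints()
  m <- energy_model(s$seq, restraints = rs,
                    weights = c(1, 0, 0, 0, 0, 0))
  eb <- total_energy(s, m)
  expect_equal(eb$total, -sum(rs$U))  # every restrained pair is native (< 8 A)
  expect_equal(eb$total, eb$con)

  m0 <- energy_model(s$seq, restraints = rs, weights = rep(0, 6))
  expect_equal(total_energy(s, m0)$total, 0)
})

test_that("the energy breakdown matches a direct R evaluation", {
  tt <- bundle52()
  m <- bundle_model()
  for (seed in 1:3) {
    x <- jitter_coords(tt$structure$xyz, 0.5, seed)
    eb <- total_energy(x, m)
    expect_equal(eb$total, eb$con + eb$dp + eb$ca + eb$ev + eb$ss + eb$rg,
                 tolerance = 1e-9)
    expect_equal(eb$total, oracle_energy(x, m), tolerance = 1e-8)
  }
})

test_that("total energy is invariant under rigid motions", {
  tt <- bundle52()
  m <- bundle_model()
  e0 <- total_energy(tt$structure, m)$total
  R <- random_rotation(5)
  moved <- sweep(tt$structure$xyz %*% R, 2, c(13.1, -4.7, 22.2), "+")
  expect_equal(total_energy(moved, m)$total, e0, tolerance = 1e-8)
})

test_that("incremental energies equal full recomputation over random moves", {
  tt <- bundle52()
  m <- bundle_model()
  flib <- bundle_flib()
  x <- initial_chain_for_test(m)
  worst <- 0
  n_checked <- 0
  for (k in 1:300) {
    mv <- propose_move(coarse_structure(x, tt$structure$seq),
                       ((k - 1) %% 11) + 1, m, flib = flib, seed = k)
    if (!mv$ok) next
    d_inc <- delta_energy(x, mv$coords, mv$window, m)
    d_full <- total_energy(mv$coords, m)$total - total_energy(x, m)$total
    worst <- max(worst, abs(d_inc - d_full))
    n_checked <- n_checked + 1
    x <- mv$coords
  }
  expect_gt(n_checked, 150)
  expect_lt(worst, 1e-8)
  # null move
  expect_equal(delta_energy(x, x, c(5, 10), m), 0)
})
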