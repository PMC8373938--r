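test_that("superposition RMSD matches the quaternion oracle and is invariant", {
  tt <- bundle52()
  x <- tt$structure$xyz
  expect_equal(kabsch_rmsd(x, x), 0, tolerance = 1e-9)
  R <- random_rotation(2)
  expect_lt(kabsch_rmsd(sweep(x %*% R, 2, c(5, -3, 11), "+"), x), 1e-6)
  for (seed in 1:50) {
    a <- jitter_coords(x, 1.5, seed)
    b <- jitter_coords(x, 1.5, seed + 100)
    expect_equal(kabsch_rmsd(a, b), quaternion_rmsd(a, b), tolerance = 1e-6)
  }
})

test_that("TM-score agrees with the exhaustive-seed oracle", {
  spec <- topology_spec(c("H", "H"), c(14, 14), 6)
  tt <- make_toy_structure(spec, seed = 31)
  x <- tt$structure$xyz
  expect_equal(tm_score(x, x), 1.0, tolerance = 1e-9)
  R <- random_rotation(9)
  expect_equal(tm_score(sweep(x %*% R, 2, c(1, 2, 3), "+"), x), 1.0,
               tolerance = 1e-6)
  expect_equal(tm_d0(100), 1.24 * 85^(1 / 3) - 1.8, tolerance = 1e-9)
  sds <- seq(0.5, 3.5, length.out = 20)
  for (seed in 1:20) {
    a <- jitter_coords(x, sds[seed], seed)
    fast <- tm_score(a, x)
    slow <- oracle_tm(a, x)
    expect_equal(fast, slow, tolerance = 1e-3)
  }
})

test_that("TM-score is symmetric at common length and beats one superposition", {
  tt <- bundle52()
  x <- tt$structure$xyz
  for (seed in 1:5) {
    y <- jitter_coords(x, 2.5, seed)
    expect_equal(tm_score(x, y), tm_score(y, x), tolerance = 1e-3)
    # lower bound: score of the single global superposition
    fit <- confold:::cpp_kabsch_fit(y, x)
    d2 <- rowSums((fit - x)^2)
    lower <- mean(1 / (1 + d2 / tm_d0(nrow(x))^2))
    expect_gte(tm_score(y, x) + 1e-9, lower)
  }
})

test_that("satisfaction and precision reproduce hand-counted toy cases", {
  # three restrained pairs at model C-beta distances (7, 9, 6): rate 2/3
  xyz <- matrix(0, 30, 3)
  xyz[, 1] <- seq(0, by = 3.8, length.out = 30)
  s <- coarse_structure(xyz, seq = rep("G", 30))  # glycine: C-beta = C-alpha
  # place three extra points by hand through contacts at separations >= 6
  s$xyz[10, ] <- s$xyz[2, ] + c(7, 0, 0)
  s$xyz[20, ] <- s$xyz[3, ] + c(9, 0, 0)
  s$xyz[29, ] <- s$xyz[4, ] + c(6, 0, 0)
  rs <- data.frame(i = c(2, 3, 4), j = c(10, 20, 29))
  expect_equal(satisfaction_rate(rs, s), 2 / 3)
  expect_error(satisfaction_rate(data.frame(i = integer(), j = integer()), s),
               "empty")

  # top-5 list with 2 native entries scores 0.4
  tt <- bundle52()
  nat <- tt$native$predictions
  native_pairs <- nat[1:2, c("i", "j")]
  decoys <- data.frame(i = c(1, 1, 2, 2) + 0L, j = c(40, 45, 44, 48))
  key <- paste(nat$i, nat$j)
  decoys <- decoys[!(paste(decoys$i, decoys$j) %in% key), ][1:3, ]
  pred <- contact_map(tt$structure$L,
                      data.frame(i = c(native_pairs$i, decoys$i),
                                 j = c(native_pairs$j, decoys$j),
                                 confidence = c(0.9, 0.8, 0.7, 0.6, 0.5)))
  res <- contact_precision(pred, tt$structure, top_k = 5)
  expect_equal(res$precision, 0.4)
  expect_equal(res$k, 5L)

  # predictions identical to the native set: precision 1 in every class
  for (cls in c("short", "medium", "long", "all")) {
    res <- contact_precision(tt$native, tt$structure, range_class = cls)
    if (res$k > 0) expect_equal(res$precision, 1.0)
  }
})

test_that("precision and satisfaction are invariant under rigid motions", {
  tt <- bundle52()
  s <- tt$structure
  rs <- bundle_restraints()
  R <- random_rotation(4)
  moved <- coarse_structure(sweep(s$xyz %*% R, 2, c(-8, 2, 30), "+"),
                            seq = s$seq)
  expect_equal(satisfaction_rate(rs, moved), satisfaction_rate(rs, s))
  expect_equal(contact_precision(rs, moved)$precision,
               contact_precision(rs, s)$precision)
})

test_that("clustering recovers a planted 70/30 two-conformation mixture", {
  tt <- bundle52()
  a <- tt$structure$xyz
  b <- initial_chain_for_test(bundle_model())  # far from the native fold
  decoys <- c(lapply(1:70, function(k) jitter_coords(a, 0.5, k)),
              lapply(1:30, function(k) jitter_coords(b, 0.5, 1000 + k)))
  cl <- cluster_decoys(decoys)
  expect_equal(cl$sizes[1:2], c(70L, 30L))
  expect_true(all(cl$members[[1]] <= 70))
  expect_true(all(cl$members[[2]] > 70))
  # centroid of the top cluster belongs to the planted basin
  expect_lt(kabsch_rmsd(cl$centroid_coords[[1]], a), 1.0)
})

test_that("clustering handles degenerate decoy sets", {
  tt <- bundle52()
  a <- tt$structure$xyz
  same <- lapply(1:40, function(k) a)
  cl <- cluster_decoys(same)
  expect_equal(cl$sizes[1], 40L)
  single <- cluster_decoys(list(a))
  expect_equal(single$sizes, 1L)
  expect_equal(single$centroid_coords[[1]], a)
})

test_that("cluster ranking breaks size ties by lower mean energy", {
  tt <- bundle52()
  a <- tt$structure$xyz
  b <- initial_chain_for_test(bundle_model())
  decoys <- c(lapply(1:20, function(k) jitter_coords(a, 0.3, k)),
              lapply(1:20, function(k) jitter_coords(b, 0.3, 500 + k)))
  energies <- c(rep(5, 20), rep(-5, 20))
  cl <- cluster_decoys(decoys, energies)
  expect_equal(cl$sizes[1:2], c(20L, 20L))
  expect_true(all(cl$members[[1]] > 20))  # lower-energy basin ranks first
})
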