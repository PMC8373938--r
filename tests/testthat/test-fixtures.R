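test_that("toy folds have ideal bonds, planned SSEs and tertiary contacts", {
  tt <- bundle52()
  s <- tt$structure
  expect_equal(s$L, 52L)
  bd <- sqrt(rowSums((s$xyz[-1, ] - s$xyz[-s$L, ])^2))
  expect_true(all(abs(bd - 3.8) < 0.01))
  expect_equal(sum(s$ss == "H"), 42L)
  # at least one long-range contact between the first and third helix
  nat <- tt$native$predictions
  expect_gt(sum(nat$i <= 14 & nat$j >= 39), 0)
  # no steric clashes in the generated fold
  D <- as.matrix(dist(s$xyz))
  sep <- abs(row(D) - col(D))
  expect_true(all(D[sep >= 2] >= 3.6 - 1e-9))
})

test_that("a single helix has medium-range contacts but no long-range ones", {
  tt <- make_toy_structure(topology_spec("H", 20), seed = 2)
  sep <- tt$native$predictions$j - tt$native$predictions$i
  expect_true(all(sep < 24))
})

test_that("toy structures are bit-reproducible per (spec, seed)", {
  spec <- topology_spec(c("H", "E", "E"), c(12, 6, 6), c(4, 4))
  t1 <- make_toy_structure(spec, seed = 5)
  t2 <- make_toy_structure(spec, seed = 5)
  expect_identical(t1$structure$xyz, t2$structure$xyz)
  expect_identical(t1$structure$seq, t2$structure$seq)
  t3 <- make_toy_structure(spec, seed = 6)
  expect_false(identical(t1$structure$xyz, t3$structure$xyz))
})

test_that("contact corruption plants exact composition at every precision", {
  tt <- bundle52()
  L <- tt$structure$L
  nat_key <- paste(tt$native$predictions$i, tt$native$predictions$j)
  for (p in c(1.0, 0.3, 0.0)) {
    cov <- if (p > 0) min(2.4, length(nat_key) / (p * L)) else 2.4
    cm <- corrupt_contacts(tt$native, p, cov, seed = 31)
    n <- round(cov * L)
    expect_equal(nrow(cm$predictions), n)
    hits <- sum(paste(cm$predictions$i, cm$predictions$j) %in% nat_key)
    expect_equal(hits, round(p * n))
    expect_true(all(cm$predictions$j - cm$predictions$i >= 6))
  }
  expect_error(corrupt_contacts(tt$native, 1, 2.4, seed = 1), "infeasible")
})

test_that("emitted confidences are calibrated: truth rate rises across bins", {
  tt <- bundle52()
  L <- tt$structure$L
  nat_key <- paste(tt$native$predictions$i, tt$native$predictions$j)
  # pool several seeds for a stable calibration estimate
  preds <- do.call(rbind, lapply(1:8, function(sd)
    corrupt_contacts(tt$native, 0.5, 0.8, slope = 2, seed = sd)$predictions))
  correct <- paste(preds$i, preds$j) %in% nat_key
  bins <- cut(preds$confidence, breaks = c(0, 0.25, 0.5, 0.75, 1))
  rate <- tapply(correct, bins, mean)
  expect_true(all(diff(rate) >= -0.02))
  expect_gt(rate[[4]], rate[[1]])
})

test_that("decoy pairs mimic the native separation distribution", {
  tt <- bundle52()
  nat <- tt$native$predictions
  nat_key <- paste(nat$i, nat$j)
  cm <- corrupt_contacts(tt$native, 0.5, 0.8, seed = 13)
  p <- cm$predictions
  fake <- p[!(paste(p$i, p$j) %in% nat_key), ]
  # all decoy separations are drawn from the native separation support
  expect_true(all((fake$j - fake$i) %in% (nat$j - nat$i)))
})

test_that("predictor ensembles order measured precision by tier", {
  tt <- make_toy_structure(topology_spec(c("H", "H", "H", "H"),
                                         c(16, 16, 16, 16), c(6, 6, 6)),
                           seed = 11)
  ens <- make_predictor_ensemble(tt$native,
                                 tier_profile = data.frame(
                                   tier = c("very_high", "high", "medium", "low"),
                                   precision = c(0.7, 0.55, 0.45, 0.30),
                                   coverage = 0.9),
                                 seed = 6)
  expect_length(ens, 4L)
  prec <- vapply(ens, function(cm)
    contact_precision(cm, tt$structure)$precision, 1.0)
  expect_true(all(diff(prec) < 0))
  expect_equal(unname(assign_tiers(vapply(ens, `[[`, "", "predictor_id"))),
               c("very_high", "high", "medium", "low"))
  # same seed reproduces the ensemble exactly
  ens2 <- make_predictor_ensemble(tt$native,
                                  tier_profile = data.frame(
                                    tier = c("very_high", "high", "medium", "low"),
                                    precision = c(0.7, 0.55, 0.45, 0.30),
                                    coverage = 0.9),
                                  seed = 6)
  expect_identical(lapply(ens, `[[`, "predictions"),
                   lapply(ens2, `[[`, "predictions"))
})

test_that("synthetic alignments hit their target depth", {
  msa <- make_synthetic_msa(100, target_nf = 15, seed = 3)
  nf <- compute_nf(msa)$nf
  expect_gte(nf, 13.5)
  expect_lte(nf, 16.5)
  expect_equal(compute_nf(make_synthetic_msa(64, 1 / 8, seed = 1))$N, 1L)
  expect_error(make_synthetic_msa(100, 1e5, seed = 1, max_rows = 100),
               "unreachable")
})

test_that("the mini library writes readable PDB structures", {
  lib <- make_mini_library(6, seed = 17, write_dir = withr::local_tempdir())
  expect_length(lib, 6L)
  for (s in lib) {
    expect_s3_class(s, "coarse_structure")
    bd <- sqrt(rowSums((s$xyz[-1, ] - s$xyz[-s$L, ])^2))
    expect_true(all(abs(bd - 3.8) < 0.01))
  }
})

test_that("written mini-library files round-trip through read_structure", {
  dir <- withr::local_tempdir()
  lib <- make_mini_library(4, seed = 23, write_dir = dir)
  files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
  expect_length(files, 4L)
  for (k in seq_along(files)) {
    back <- read_structure(files[k])
    expect_equal(back$L, lib[[k]]$L)
    expect_lt(max(abs(back$xyz - lib[[k]]$xyz)), 1e-3)
  }
})
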