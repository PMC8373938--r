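test_that("RR parsing canonicalises pairs, collapses duplicates and validates", {
  f <- withr::local_tempfile(fileext = ".rr")
  writeLines(c("PFRMAT RR", "MKLVFFAEDV", "1 9 0 8 0.9", "9 1 0 8 0.4",
               "2 8 0.7", "END"), f)
  cm <- read_rr(f, L = 10, predictor_id = "toy")
  expect_s3_class(cm, "contact_map")
  expect_equal(nrow(cm$predictions), 2L)
  rec <- cm$predictions[cm$predictions$i == 1, ]
  expect_equal(rec$j, 9L)
  expect_equal(rec$confidence, 0.9)  # duplicate keeps max confidence

  writeLines(c("PFRMAT RR", "END"), f)
  expect_equal(nrow(read_rr(f, L = 50)$predictions), 0L)

  writeLines("3 70 0 8 0.5", f)
  expect_error(read_rr(f, L = 60), "outside")

  writeLines("1 x 0 8 0.5", f)
  expect_error(read_rr(f, L = 60), "line 1")
})

test_that("RR round-trip is the identity on canonical maps", {
  f <- withr::local_tempfile(fileext = ".rr")
  cm <- contact_map(40, data.frame(i = c(5, 2, 9), j = c(20, 31, 15),
                                   confidence = c(0.5, 0.91, 0.13)), "p1")
  write_rr(cm, f)
  back <- read_rr(f, 40, "p1")
  expect_equal(back$predictions$i, cm$predictions$i)
  expect_equal(back$predictions$j, cm$predictions$j)
  expect_equal(back$predictions$confidence, cm$predictions$confidence,
               tolerance = 1e-6)
})

test_that("Nf matches closed forms on degenerate alignments", {
  q <- paste(rep("A", 100), collapse = "")
  expect_equal(compute_nf(q)$nf, 0.1)                  # single query: 1/sqrt(L)
  expect_equal(compute_nf(rep(q, 10))$nf, 0.1)         # 10 identical rows
  rows <- make_synthetic_msa(100, target_nf = 1.0, seed = 2)
  expect_equal(compute_nf(rows)$nf, 1.0, tolerance = 1e-9)  # 10 dissimilar rows
  expect_equal(compute_nf(rows)$N, 10L)
})

test_that("Nf is permutation-invariant and monotone under dissimilar rows", {
  rows <- make_synthetic_msa(64, target_nf = 0.8, seed = 7)
  ref <- compute_nf(rows)$nf
  expect_equal(compute_nf(rev(rows))$nf, ref)
  grown <- c(rows, paste(sample(LETTERS[1:20], 64, replace = TRUE), collapse = ""))
  expect_gte(compute_nf(grown)$nf, ref)
  expect_error(compute_nf(character(0)), "empty")
  expect_error(compute_nf(c("AAAA", "AAA")), "unequal")
})

test_that("identity for Nf clustering ignores columns gapped in either row", {
  # two rows identical on the 60 mutually aligned columns -> neighbours
  a <- paste(c(rep("A", 80), rep("-", 20)), collapse = "")
  b <- paste(c(rep("A", 60), rep("-", 20), rep("W", 20)), collapse = "")
  expect_equal(compute_nf(c(a, b))$nf, (1 / 2 + 1 / 2) / 10)
  # fewer than L/2 mutually aligned columns -> non-neighbours even if identical
  c1 <- paste(c(rep("A", 40), rep("-", 60)), collapse = "")
  c2 <- paste(c(rep("-", 60), rep("A", 40)), collapse = "")
  expect_equal(compute_nf(c(c1, c2))$nf, 2 / 10)
})

test_that("SS2 parsing reads states and probabilities, rejecting bad rows", {
  f <- withr::local_tempfile(fileext = ".ss2")
  writeLines(c("# PSIPRED VFORMAT", "",
               "   1 M C  0.900 0.050 0.050",
               "   2 K H  0.100 0.850 0.050"), f)
  ss <- read_ss2(f)
  expect_equal(ss$state, c("C", "H"))
  expect_equal(ss$p_c[1], 0.9)
  writeLines("   1 M C  0.500 0.100 0.100", f)  # sums to 0.7
  expect_error(read_ss2(f), "sum")
})

test_that("SS2 writer round-trips through the parser", {
  f <- withr::local_tempfile(fileext = ".ss2")
  write_ss2("MKLV", "CHHC", f, conf = 0.8)
  ss <- read_ss2(f)
  expect_equal(ss$state, c("C", "H", "H", "C"))
  expect_equal(ss$p_h[2], 0.8)
})

test_that("PDB structures round-trip through write/read to 1e-3 A", {
  tt <- bundle52()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tt$structure, f, with_cbeta = TRUE)
  back <- read_structure(f)
  expect_equal(back$L, tt$structure$L)
  expect_lt(max(abs(back$xyz - tt$structure$xyz)), 1e-3)
  expect_equal(back$seq, tt$structure$seq)
})

test_that("PDB reader names the residue that lacks a C-alpha", {
  f <- withr::local_tempfile(fileext = ".pdb")
  tt <- make_toy_structure(topology_spec("H", 20), seed = 1)
  write_structure(tt$structure, f, with_cbeta = TRUE)
  lines <- readLines(f)
  # drop the CA record of residue 5
  lines <- lines[!grepl("^ATOM.*CA  ... A   5", lines)]
  writeLines(lines, f)
  expect_error(read_structure(f), "residue 5")
})

test_that("A3M reading drops lowercase insert columns", {
  f <- withr::local_tempfile(fileext = ".a3m")
  writeLines(c(">query", "MKLVAE", ">hit", "MKlvLVAE"), f)
  msa <- read_msa(f)
  expect_equal(unname(nchar(msa)), c(6L, 6L))
  expect_equal(unname(msa[2]), "MKLVAE")
})

test_that("contact_map enforces its invariants", {
  expect_error(contact_map(10, data.frame(i = 1, j = 12, confidence = 0.5)),
               "outside")
  expect_error(contact_map(10, data.frame(i = 3, j = 3, confidence = 0.5)),
               "self-contact")
  expect_error(contact_map(10, data.frame(i = 1, j = 5, confidence = 1.2)),
               "confidence")
  # swapped indices are canonicalised
  cm <- contact_map(10, data.frame(i = 7, j = 2, confidence = 0.4))
  expect_equal(cm$predictions$i, 2L)
})
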