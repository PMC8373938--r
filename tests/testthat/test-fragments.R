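test_that("gapless threading ranks an exact self-window at the top of its slot", {
  tt <- bundle52()
  s <- tt$structure
  lib <- c(minilib()[1:5], list(s))  # plant the query itself as source 6
  flib <- gapless_thread(s$seq, paste(s$ss, collapse = ""), lib,
                         lengths = 9L, topk = 50L)
  sl <- flib$slots
  for (p in c(3L, 20L, 40L)) {
    top <- sl[sl$pos == p & sl$rank == 1, ]
    slot <- sl[sl$pos == p, ]
    self_score <- slot$score[slot$source == 6 & slot$sstart == p]
    expect_equal(top$score, max(slot$score))
    expect_equal(self_score, top$score)  # self-match attains the maximum
  }
})

test_that("slot sizes equal the available window count when below the cap", {
  lib <- minilib()[1:3]
  Ls <- vapply(lib, function(s) s$L, 1L)
  q <- paste(rep("A", 30), collapse = "")
  flib <- gapless_thread(q, paste(rep("C", 30), collapse = ""), lib,
                         lengths = 9L, topk = 200L)
  expected <- sum(pmax(Ls - 9L + 1L, 0L))
  counts <- table(flib$slots$pos)
  expect_true(all(counts == min(200L, expected)))
  expect_error(gapless_thread(q, q, list()), "empty")
})

test_that("single-residue slots rank by substitution plus SS match", {
  lib <- minilib()[1:2]
  q <- "WWWW"
  flib <- gapless_thread(q, "CCCC", lib, lengths = 1L, topk = 5L)
  sl <- flib$slots[flib$slots$pos == 1, ]
  expect_true(all(diff(sl$score) <= 0))
})

test_that("the homolog filter removes the query and respects the 30% boundary", {
  tt <- bundle52()
  s <- tt$structure
  lib <- c(minilib()[1:4], list(s))
  filtered <- homolog_filter(lib, s$seq)
  expect_true(5L %in% attr(filtered, "removed"))  # the query itself (100%)
  ident <- attr(filtered, "identity")
  expect_equal(ident[5], 1.0)
  # structures at or below the threshold are retained
  kept <- setdiff(seq_along(lib), attr(filtered, "removed"))
  expect_true(all(ident[setdiff(kept, 5)] <= 0.30))
})

test_that("no sampled fragment originates from a filtered structure", {
  tt <- bundle52()
  s <- tt$structure
  lib <- c(minilib()[1:5], list(s))
  filtered <- homolog_filter(lib, s$seq)
  flib <- gapless_thread(s$seq, paste(s$ss, collapse = ""), filtered,
                         lengths = c(6L, 9L), topk = 20L)
  # source indices refer to the filtered library, which excludes the query
  expect_lte(max(flib$slots$source), length(filtered))
  for (src in unique(flib$slots$source)) {
    sseq <- paste(filtered[[src]]$seq, collapse = "")
    expect_false(identical(sseq, paste(s$seq, collapse = "")))
  }
})

test_that("distance profiles require shared sources and flag peaks below 9 A", {
  # two structures with disjoint slots can never pair
  tt <- bundle52()
  s <- tt$structure
  flib <- bundle_flib()
  pr <- build_distance_profiles(flib)
  expect_gt(nrow(pr$pairs), 0)
  expect_true(all(pr$pairs$peak[pr$pairs$usable] < 9))
  expect_true(all(pr$pairs$i < pr$pairs$j))
  # profile lookup is symmetric
  k <- which(pr$pairs$usable)[1]
  i <- pr$pairs$i[k]; j <- pr$pairs$j[k]
  expect_identical(get_profile(pr, i, j)$counts, get_profile(pr, j, i)$counts)
})

test_that("a planted single-source library yields profiles at source geometry", {
  # library = one helix bundle; thread a same-SS query so every top fragment
  # comes from that single source with one register
  src <- make_toy_structure(topology_spec(c("H", "H"), c(14, 14), 5), seed = 21)
  q <- make_toy_structure(topology_spec(c("H", "H"), c(14, 14), 5), seed = 22)
  flib <- gapless_thread(q$structure$seq, paste(q$structure$ss, collapse = ""),
                         list(src$structure), lengths = 9L, topk = 10L)
  pr <- build_distance_profiles(flib, min_obs = 1L)
  u <- pr$pairs
  # profiles must reproduce the source's own distances at matching offsets
  k <- which(u$usable & u$j - u$i == 4 & u$i >= 2 & u$j <= 13)[1]
  expect_false(is.na(k))
  d_src <- sqrt(sum((src$structure$xyz[u$i[k], ] - src$structure$xyz[u$j[k], ])^2))
  expect_lt(abs(u$peak[k] - d_src), 0.5)
})

test_that("profile TSV serialisation writes one row per occupied bin", {
  pr <- bundle_profiles()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(pr, f)
  tab <- utils::read.delim(f)
  expect_named(tab, c("i", "j", "bin_center", "count", "usable"))
  expect_equal(sum(tab$count), sum(pr$counts))
})
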