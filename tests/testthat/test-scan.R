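# Core repeat scan: planted-pair recovery, filtering, extension semantics,
# the generalized wildcard mode, and agreement with the brute-force oracle.

test_that("a planted TR/VR pair is recovered exactly and matches the oracle", {
  bg <- rand_seq(2000, gc = 0.4, seed = 7)
  p <- plant_pair(bg, tr_at = 101, vr_at = 401, tr_len = 50, n_a = 12, n_sub = 8)
  hits <- scan_region(p$seq)
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$tr_start, hits$tr_end), p$tr)
  expect_equal(c(hits$vr_start, hits$vr_end), p$vr)
  expect_equal(hits$n_substitutions, 8L)
  expect_equal(hits$strand_relation, "same")
  # every substitution is at a TR adenine, VR base differs and is not A
  subs <- hits$substitutions[[1]]
  expect_equal(nrow(subs), 8L)
  expect_true(all(subs$tr_base == "A"))
  expect_true(all(subs$vr_base != "A"))
  expect_equal(hits_to_oracle_shape(hits), oracle_scan(p$seq))
})

test_that("exact duplications and low-substitution repeats are filtered out", {
  bg <- rand_seq(1500, seed = 3)
  block <- rand_seq(60, seed = 4)
  dup <- paste0(substr(bg, 1, 200), block, substr(bg, 201, 700), block,
                substr(bg, 701, 1500))
  expect_equal(nrow(scan_region(dup)), 0L)

  p6 <- plant_pair(rand_seq(1500, seed = 5), tr_at = 101, vr_at = 501,
                   n_a = 12, n_sub = 6)
  expect_equal(nrow(scan_region(p6$seq)), 0L)
  relaxed <- scan_region(p6$seq, dgr_scan_params(min_substitutions = 5))
  expect_equal(nrow(relaxed), 1L)
  expect_equal(relaxed$n_substitutions, 6L)
})

test_that("the adenine-count filter applies to the extended TR", {
  p9 <- plant_pair(rand_seq(1500, seed = 6), tr_at = 101, vr_at = 501,
                   n_a = 9, n_sub = 7)
  expect_equal(nrow(scan_region(p9$seq)), 0L)
  expect_equal(nrow(scan_region(p9$seq,
                                dgr_scan_params(min_wildcard_in_tr = 9))), 1L)
})

test_that("extension is maximal and respects boundaries and disjointness", {
  # seed flanked by hard mismatches on both sides: unchanged
  bg <- rand_seq(800, seed = 8)
  p <- plant_pair(bg, tr_at = 51, vr_at = 301, tr_len = 50, n_a = 12, n_sub = 8)
  r <- extend_match(p$seq, p$tr[1], p$vr[1], 50)
  expect_equal(unname(r), c(p$tr[1], p$vr[1], 50L))

  # left flank continues matching for 13 positions (exact + A-substitution mix)
  left_tr <- "GATTACCAGGTAC"          # 13 nt, As at positions 2,5,6
  left_vr <- "GCTTACCAGGTAC"          # one A-substitution, rest equal
  core <- rand_seq(50, seed = 9)
  s <- paste0("T", left_tr, core, "G", rand_seq(150, seed = 10),
              "G", left_vr, core, "C", rand_seq(100, seed = 12))
  tr_seed <- 1 + 13 + 1               # core starts after "T" + left_tr
  vr_seed <- 1 + 13 + 50 + 1 + 150 + 1 + 13 + 1
  r2 <- extend_match(s, tr_seed, vr_seed, 50)
  expect_equal(unname(r2["length"]), 50L + 13L)

  # tandem periodic run: extension stops before TR and VR would overlap
  unit <- rand_seq(60, seed = 13)
  tandem <- paste0(rand_seq(100, seed = 14), strrep(unit, 3),
                   rand_seq(100, seed = 15))
  r3 <- extend_match(tandem, 101, 161, 50)
  expect_equal(unname(r3["length"]), 60L)   # capped at the offset
  expect_true(r3["vr_start"] - r3["tr_start"] >= r3["length"])
})

test_that("scan output is deterministic and role assignment is asymmetric", {
  bg <- rand_seq(1200, seed = 16)
  p <- plant_pair(bg, tr_at = 101, vr_at = 601, n_a = 14, n_sub = 9, seed = 2)
  h1 <- scan_region(p$seq)
  h2 <- scan_region(p$seq)
  expect_identical(h1, h2)
  # the reversed assignment is never reported
  expect_false(any(h1$tr_start %in% h1$vr_start & h1$vr_start %in% h1$tr_start &
                     h1$tr_start > h1$vr_start))
  expect_equal(nrow(h1), 1L)
  expect_true(h1$tr_start < h1$vr_start)
})

test_that("random sequences yield no hits at default thresholds", {
  for (s in 1:10) {
    expect_equal(nrow(scan_region(rand_seq(2000, gc = 0.5, seed = 100 + s))), 0L)
  }
})

test_that("a short region returns an empty result with a notice, not an error", {
  expect_message(h <- scan_region(rand_seq(30, seed = 1)), "shorter")
  expect_equal(nrow(h), 0L)
})

test_that("N positions match nothing and break extension", {
  bg <- rand_seq(1000, seed = 20)
  p <- plant_pair(bg, tr_at = 101, vr_at = 501, tr_len = 60, n_a = 15, n_sub = 9)
  # N in the middle of the TR splits the repeat into halves below the window
  chars <- strsplit(p$seq, "")[[1]]
  chars[p$tr[1] + 30] <- "N"
  expect_equal(nrow(scan_region(paste(chars, collapse = ""))), 0L)
})

test_that("generalized wildcard scan mirrors a reverse-complemented element", {
  bg <- rand_seq(1200, gc = 0.4, seed = 21)
  p <- plant_pair(bg, tr_at = 101, vr_at = 601, n_a = 13, n_sub = 8, seed = 3)
  fwdA <- scan_region(p$seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(p$seq)))
  rcT <- scan_generalized(rc, dgr_scan_params(wildcard_base = "T"))
  expect_equal(nrow(fwdA), 1L)
  expect_equal(nrow(rcT), 1L)
  expect_equal(rcT$strand_relation, "inverted")
  L <- nchar(p$seq)
  # intervals map through reverse-complement coordinates
  expect_equal(c(L - rcT$tr_end + 1L, L - rcT$tr_start + 1L),
               c(fwdA$tr_start, fwdA$tr_end))
  expect_equal(c(L - rcT$vr_end + 1L, L - rcT$vr_start + 1L),
               c(fwdA$vr_start, fwdA$vr_end))
  expect_equal(rcT$n_substitutions, fwdA$n_substitutions)
  # an ordinary same-strand element is invisible to the T/C/G sweeps
  for (w in c("T", "C", "G")) {
    expect_equal(nrow(scan_generalized(p$seq, dgr_scan_params(wildcard_base = w))),
                 0L, info = w)
  }
})

test_that("alignment rendering marks substitutions and round-trips", {
  bg <- rand_seq(1000, seed = 22)
  p <- plant_pair(bg, tr_at = 101, vr_at = 501, n_a = 12, n_sub = 8)
  hits <- scan_region(p$seq)
  aln <- align_pair(p$seq, hits[1, ], width = 60)
  marks <- paste(aln[seq(2, length(aln), by = 4)], collapse = "")
  expect_equal(lengths(regmatches(marks, gregexpr("\\*", marks))), 8L)
  back <- dgrscan:::parse_alignment(aln)
  expect_equal(back, hits$substitutions[[1]])
  # narrow wrap still renders and parses
  aln2 <- align_pair(p$seq, hits[1, ], width = 15)
  expect_equal(dgrscan:::parse_alignment(aln2), hits$substitutions[[1]])
})

test_that("maximality holds: no reported hit can be extended by one position", {
  bg <- rand_seq(1500, gc = 0.45, seed = 23)
  p <- plant_pair(bg, tr_at = 201, vr_at = 801, tr_len = 80, n_a = 20,
                  n_sub = 10, seed = 4)
  hits <- scan_region(p$seq)
  chars <- strsplit(p$seq, "")[[1]]
  hard <- function(a, b) (a == "N" | b == "N") | (a != "A" & a != b)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    d <- abs(h$vr_start - h$tr_start)
    if (h$tr_start > 1 && h$vr_start > 1 && h$length < d) {
      expect_true(hard(chars[h$tr_start - 1], chars[h$vr_start - 1]))
    }
    if (h$tr_end < nchar(p$seq) && h$vr_end < nchar(p$seq) && h$length < d) {
      expect_true(hard(chars[h$tr_end + 1], chars[h$vr_end + 1]))
    }
  }
})
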