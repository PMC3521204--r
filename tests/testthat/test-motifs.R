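# RT motif annotation: YxDD, the region-4 heptamer and the charge patch.

test_that("find_ydd locates the first YxDD/FxDD and reports its residues", {
  y <- find_ydd("MSTAYMDDLLK")
  expect_true(y$found)
  expect_equal(y$tetramer, "YMDD")
  expect_equal(c(y$pos1, y$pos2), c("Y", "M"))
  f <- find_ydd("MSTAFVDDLLK")
  expect_equal(c(f$tetramer, f$pos1, f$pos2), c("FVDD", "F", "V"))
  expect_false(find_ydd("MSTAGLLK")$found)
  # first match wins; X never fills the variable position
  two <- find_ydd("MAYADDQQQFVDD")
  expect_equal(two$offset, 3L)
  expect_false(find_ydd("MAYXDDQQQ")$found)
  expect_error(find_ydd(""), "empty")
})

test_that("find_motif4 classifies the heptamer dipeptide", {
  pad <- strrep("T", 30)
  mk <- function(hept) paste0("M", pad, hept, strrep("T", 60), "YMDD",
                              strrep("S", 30))
  canon <- motif_report(c(p = mk("LGAPRSQ")))
  expect_equal(canon$motif4_class, "canonical-SQ")
  expect_equal(canon$motif4_heptamer, "LGAPRSQ")
  sp <- motif_report(c(p = mk("IGTPKSP")))
  expect_equal(sp$motif4_class, "SP")
  other <- motif_report(c(p = mk("VGTPKWW")))
  expect_equal(other$motif4_class, "other")
  # retroviral-type QGxxxSP has no [ILV]G heptamer: class absent
  absent <- motif_report(c(p = mk("QGDTGSP")))
  expect_equal(absent$motif4_class, "absent")
  # among several candidates the one nearest YxDD wins
  near <- find_motif4(paste0("M", pad, "LGAAASQ", strrep("T", 20), "IGAAASP",
                             strrep("T", 20), "YMDDSSSSSSSSSSSSSSSSSSSSSS"))
  expect_equal(near$class, "SP")
})

test_that("motif4 search window is the 100 residues preceding YxDD", {
  far <- paste0("M", "LGAPRSQ", strrep("T", 150), "YMDD", strrep("S", 30))
  expect_equal(find_motif4(far)$class, "absent")
  near <- paste0("M", strrep("T", 100), "LGAPRSQ", strrep("T", 50), "YMDD",
                 strrep("S", 30))
  expect_equal(find_motif4(near)$class, "canonical-SQ")
})

test_that("charge_patch maximizes R/K in 20-aa windows after YxDD", {
  tail11 <- paste0(strrep("S", 10), "RKRKRKRKRKR", strrep("G", 9), strrep("S", 10))
  p <- paste0("M", strrep("A", 50), "YMDD", tail11)
  y <- find_ydd(p)
  cp <- charge_patch(p, y$offset)
  expect_equal(cp$rk_count, 11L)
  expect_equal(cp$fraction, 0.55)
  expect_true(cp$positive_patch)
  # poly-G tail: zero and no flag
  pg <- paste0("M", strrep("A", 50), "YMDD", strrep("G", 40))
  cp0 <- charge_patch(pg, find_ydd(pg)$offset)
  expect_equal(cp0$rk_count, 0L)
  expect_false(cp0$positive_patch)
  # tail shorter than one window: absent with flag
  short <- paste0("M", strrep("A", 50), "YMDDRRRRR")
  expect_false(charge_patch(short, find_ydd(short)$offset)$found)
})

test_that("charge_patch agrees with exhaustive window enumeration", {
  for (s in 1:20) {
    p <- withr::with_seed(s, paste(
      c("M", sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120,
                    replace = TRUE), "YMDD",
        sample(c("R", "K", "S", "G", "T"), 60, replace = TRUE)),
      collapse = ""))
    y <- find_ydd(p)
    cp <- charge_patch(p, y$offset)
    chars <- strsplit(substr(p, y$offset, nchar(p)), "")[[1]]
    brute <- vapply(seq_len(length(chars) - 19L), function(i)
      sum(chars[i:(i + 19L)] %in% c("R", "K")), integer(1))
    expect_equal(cp$rk_count, max(brute))
    expect_equal(cp$offset, y$offset + which.max(brute) - 1L)
  }
})

test_that("synthetic RT proteins embed the requested motif profile", {
  for (prof in c("canonical", "SP", "NQ", "VQ")) {
    p <- make_rt_protein(prof, seed = 17)
    rep <- motif_report(setNames(p, prof))
    expect_true(rep$ydd_found)
    expect_equal(rep$motif4_class,
                 if (prof == "canonical") "canonical-SQ" else prof, info = prof)
    expect_true(rep$positive_patch)
    expect_true(rep$rt_length >= 260 && rep$rt_length <= 527)
    expect_true(rep$motif4_offset < rep$ydd_offset)
  }
  trunc <- motif_report(c(t = make_rt_protein("truncated", seed = 18)))
  expect_false(trunc$ydd_found)
  nomot <- motif_report(c(n = make_rt_protein("no-motif", seed = 19)))
  expect_false(nomot$ydd_found)
  expect_equal(nomot$motif4_class, "absent")
  expect_error(make_rt_protein("weird"), "unknown")
  expect_identical(make_rt_protein("canonical", seed = 5),
                   make_rt_protein("canonical", seed = 5))
})

test_that("summaries aggregate lengths and motif fractions", {
  pad <- strrep("T", 40)
  mk <- function(n, hept) paste0("M", pad, hept, strrep("T", 60), "YMDD",
                                 strrep("S", max(0, n - 112)))
  reps <- motif_report(c(a = mk(300, "LGAPRSQ"), b = mk(378, "LGAPRSQ"),
                         c = mk(456, "LGAPRSQ")))
  s <- summarize_rts(reps)
  expect_equal(s$length_mean, 378)
  expect_equal(s$frac_canonical_sq, 1.0)
  expect_equal(unname(s$ydd_pos2_dist[[1]][["M"]]), 1.0)
})

test_that("a 90% canonical cohort yields a fraction inside the binomial CI", {
  n <- 1000
  profs <- withr::with_seed(99, sample(c("canonical", "SP"), n, replace = TRUE,
                                       prob = c(0.9, 0.1)))
  prots <- vapply(seq_len(n), function(i) make_rt_protein(profs[i], seed = 2000 + i),
                  character(1))
  s <- summarize_rts(motif_report(setNames(prots, paste0("rt", seq_len(n)))))
  ci <- qbinom(c(0.005, 0.995), n, 0.9) / n
  expect_gte(s$frac_canonical_sq, ci[1])
  expect_lte(s$frac_canonical_sq, ci[2])
  expect_true(all(s$length_min >= 260, s$length_max <= 527))
})
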