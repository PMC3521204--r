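# Cassette assembly, target assignment and structure classification.

# convenience: full pipeline from a synthetic genome to classified cassettes
classify_genome <- function(spec, wildcard = "A") {
  g <- make_genome(spec)
  anchors <- find_rt_anchors(g$record)
  region <- extract_region(g$record, anchors)
  hits <- if (wildcard == "A") scan_region(region)
          else scan_generalized(region, dgr_scan_params(wildcard_base = wildcard))
  cas <- group_cassettes(hits, anchors)
  cas <- assign_targets(cas, g$record$features)
  list(g = g, hits = hits, cassettes = classify_structure(cas))
}

test_that("hits sharing a TR merge into one multi-VR cassette", {
  res <- classify_genome(plant_spec(seed = 81, n_vr = 2, n_adenines_tr = 30,
                                    substitutions_per_vr = 10))
  tr_start <- res$g$truth$start[res$g$truth$kind == "TR"]
  planted <- res$hits[res$hits$tr_start_parent == tr_start, ]
  cas <- classify_structure(group_cassettes(planted, find_rt_anchors(res$g$record)))
  expect_equal(nrow(cas), 1L)
  expect_equal(cas$n_vr, 2L)
  truth_vrs <- res$g$truth[res$g$truth$kind == "VR", ]
  expect_equal(cas$vrs[[1]]$vr_start, sort(truth_vrs$start))
})

test_that("disjoint TRs yield separate cassettes and the partition holds", {
  anchor <- tibble::tibble(sequence_id = "s", start = 8000L, end = 9200L,
                           strand = "+", label = "rt1")
  mk_hit <- function(ts, te, vs, ve) tibble::tibble(
    sequence_id = "s", anchor = "rt1", tr_start = ts, tr_end = te,
    vr_start = vs, vr_end = ve, length = te - ts + 1L,
    tr_start_parent = ts, tr_end_parent = te, vr_start_parent = vs,
    vr_end_parent = ve, strand = "+", strand_relation = "same",
    wildcard = "A", n_wildcard_tr = 15L, n_substitutions = 8L,
    sub_A = 0L, sub_C = 2L, sub_G = 4L, sub_T = 2L,
    substitutions = list(tibble::tibble(offset = integer(),
                                        tr_base = character(),
                                        vr_base = character())))
  hits <- dplyr::bind_rows(mk_hit(1000, 1100, 2000, 2100),
                           mk_hit(4000, 4100, 5000, 5100),
                           mk_hit(1000, 1100, 3000, 3100))
  cas <- group_cassettes(hits, anchor)
  expect_equal(nrow(cas), 2L)
  expect_equal(sum(cas$n_vr), 3L)   # every distinct VR appears exactly once
  expect_equal(cas$n_vr[cas$tr_start == 1000], 2L)
})

test_that("four planted VRs off one TR give n_vr = 4", {
  res <- classify_genome(plant_spec(seed = 82, n_vr = 4, n_adenines_tr = 32,
                                    substitutions_per_vr = c(8, 14),
                                    background_length = 18000))
  tr_start <- res$g$truth$start[res$g$truth$kind == "TR"]
  planted <- res$hits[res$hits$tr_start_parent == tr_start, ]
  cas <- group_cassettes(planted, find_rt_anchors(res$g$record))
  expect_equal(cas$n_vr, 4L)
})

test_that("VR-to-ORF assignment requires containment on the CDS strand", {
  res <- classify_genome(plant_spec(seed = 83))
  cas <- res$cassettes
  expect_equal(nrow(cas), 1L)
  expect_equal(cas$vrs[[1]]$target, "target1")
  expect_false(cas$unassigned_vr)

  # strip the target CDS: the VR becomes intergenic and is flagged
  feats <- res$g$record$features
  no_target <- feats[!grepl("target", vapply(feats$qualifiers, function(q)
    paste(q, collapse = " "), character(1))), ]
  cas2 <- assign_targets(group_cassettes(res$hits, find_rt_anchors(res$g$record)),
                         no_target)
  expect_true(is.na(cas2$vrs[[1]]$target))
  expect_true(cas2$unassigned_vr)

  # a CDS that only partially covers the VR does not count
  vr <- res$g$truth[res$g$truth$kind == "VR", ]
  straddle <- tibble::tibble(kind = "CDS", start = vr$start + 10L,
                             end = vr$end + 500L, strand = "+",
                             qualifiers = list(c(locus_tag = "partial")))
  cas3 <- assign_targets(group_cassettes(res$hits, find_rt_anchors(res$g$record)),
                         straddle)
  expect_true(is.na(cas3$vrs[[1]]$target))
  # and the same CDS on the wrong strand does not count either
  wrong <- tibble::tibble(kind = "CDS", start = vr$start - 50L,
                          end = vr$end + 50L, strand = "-",
                          qualifiers = list(c(locus_tag = "antisense")))
  cas4 <- assign_targets(group_cassettes(res$hits, find_rt_anchors(res$g$record)),
                         wrong)
  expect_true(is.na(cas4$vrs[[1]]$target))
})

test_that("groups 1-4 classify by TR/RT arrangement with strand precedence", {
  res1 <- classify_genome(plant_spec(seed = 84, group = 1))
  expect_equal(res1$cassettes$group, 1L)
  expect_equal(res1$cassettes$subgroup, "a")   # VR-TR-RT prototype

  res2 <- classify_genome(plant_spec(seed = 85, group = 2))
  expect_equal(res2$cassettes$group, 2L)

  res3 <- classify_genome(plant_spec(seed = 86, group = 3,
                                     substitutions_per_vr = 10))
  expect_equal(res3$cassettes$group, 3L)
  expect_false(res3$cassettes$tr_inside_rt)    # straddles the RT start

  res4 <- classify_genome(plant_spec(seed = 87, group = 4, tr_length = 135,
                                     n_adenines_tr = 35,
                                     substitutions_per_vr = 20),
                          wildcard = "T")
  expect_equal(res4$cassettes$group, 4L)

  # a TR fully inside the RT CDS folds into group 3 with a flag
  anchor <- tibble::tibble(sequence_id = "s", start = 1000L, end = 2200L,
                           strand = "+", label = "rt1")
  cs <- tibble::tibble(
    sequence_id = "s", anchor = "rt1", rt_start = 1000L, rt_end = 2200L,
    rt_strand = "+", tr_start = 1400L, tr_end = 1500L, tr_strand = "+",
    n_vr = 1L,
    vrs = list(tibble::tibble(vr_start = 3000L, vr_end = 3100L, strand = "+",
                              n_substitutions = 8L)),
    n_wildcard_tr = 15L, group = NA_integer_, subgroup = NA_character_,
    unassigned_vr = NA, tr_inside_rt = FALSE)
  out <- classify_structure(cs)
  expect_equal(out$group, 3L)
  expect_true(out$tr_inside_rt)
})

test_that("classification is stable under hit-order permutation", {
  res <- classify_genome(plant_spec(seed = 88, n_vr = 3, n_adenines_tr = 30,
                                    substitutions_per_vr = 9))
  anchors <- find_rt_anchors(res$g$record)
  base <- classify_structure(group_cassettes(res$hits, anchors))
  for (s in 1:5) {
    perm <- withr::with_seed(s, res$hits[sample.int(nrow(res$hits)), ])
    again <- classify_structure(group_cassettes(perm, anchors))
    expect_equal(again$group, base$group)
    expect_equal(again$subgroup, base$subgroup)
    expect_equal(again$n_vr, base$n_vr)
    expect_equal(again$vrs, base$vrs)
  }
})

test_that("subgroup letters enumerate deterministically", {
  expect_equal(dgrscan:::letter_code(1), "a")
  expect_equal(dgrscan:::letter_code(26), "z")
  expect_equal(dgrscan:::letter_code(27), "aa")
  # one VR: placements U, B, D map to a, b, c
  mk <- function(vr_start, vr_end) tibble::tibble(
    sequence_id = "s", anchor = "rt1", rt_start = 8000L, rt_end = 9200L,
    rt_strand = "+", tr_start = 6000L, tr_end = 6100L, tr_strand = "+",
    n_vr = 1L,
    vrs = list(tibble::tibble(vr_start = vr_start, vr_end = vr_end,
                              strand = "+", n_substitutions = 8L)),
    n_wildcard_tr = 15L, group = NA_integer_, subgroup = NA_character_,
    unassigned_vr = NA, tr_inside_rt = FALSE)
  expect_equal(classify_structure(mk(2000L, 2100L))$subgroup, "a")
  expect_equal(classify_structure(mk(7000L, 7100L))$subgroup, "b")
  expect_equal(classify_structure(mk(9500L, 9600L))$subgroup, "c")
  # two VRs both upstream: first tuple of the n_vr = 2 block
  two <- mk(2000L, 2100L)
  two$vrs <- list(tibble::tibble(vr_start = c(2000L, 3000L),
                                 vr_end = c(2100L, 3100L), strand = "+",
                                 n_substitutions = 8L))
  two$n_vr <- 2L
  expect_equal(classify_structure(two)$subgroup, "e")
})

test_that("whole-record rescan finds wildcard-perfect distal VR copies", {
  g <- make_genome(plant_spec(seed = 89))
  truth <- g$truth
  tr <- substr(g$record$residues, truth$start[truth$kind == "TR"],
               truth$end[truth$kind == "TR"])
  hitset <- find_distal_targets(g$record, tr, min_substitutions = 1)
  vr <- truth[truth$kind == "VR", ]
  expect_true(any(hitset$match_start == vr$start & hitset$match_end == vr$end))
  # the copy inside the target CDS carries the planted substitution count
  row <- hitset[hitset$match_start == vr$start, ]
  expect_equal(row$n_substitutions[1], vr$n_substitutions)
})
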