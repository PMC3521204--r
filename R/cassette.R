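# Cassette assembly and architecture classification. Hits from one region
# are merged into cassettes (one TR, one or more VRs), VRs are assigned to
# target ORFs by strand-aware containment, and each cassette is classified
# into structural groups 1-4 with a deterministic subgroup letter.

empty_cassettes <- function() {
  tibble(sequence_id = character(), anchor = character(),
         rt_start = integer(), rt_end = integer(), rt_strand = character(),
         tr_start = integer(), tr_end = integer(), tr_strand = character(),
         n_vr = integer(), vrs = list(), n_wildcard_tr = integer(),
         group = integer(), subgroup = character(),
         unassigned_vr = logical(), tr_inside_rt = logical())
}

#' Assemble hits into DGR cassettes
#'
#' Hits whose TR intervals reciprocally overlap by at least 90% are merged
#' into one cassette whose TR is the union interval and whose VRs are the
#' distinct VR intervals sorted by position; disjoint TRs yield separate
#' cassettes. Coordinates are parent coordinates.
#'
#' @param hits hit tibble from [scan_region()] (one region).
#' @param anchor the region's one-row anchor tibble.
#' @param min_reciprocal_overlap TR merge threshold (fraction of each TR).
#' @return cassette tibble: TR interval/strand, `n_vr`, a `vrs` list column
#'   (per-VR interval, strand, substitution count), plus empty
#'   classification columns filled by [classify_structure()].
#' @export
group_cassettes <- function(hits, anchor, min_reciprocal_overlap = 0.9) {
  anchor <- as_tibble(anchor)
  stopifnot(nrow(anchor) == 1L)
  if (!nrow(hits)) return(empty_cassettes())
  n <- nrow(hits)
  ts <- hits$tr_start_parent; te <- hits$tr_end_parent
  # connected components under reciprocal-overlap >= threshold
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (comp[i] == comp[j]) next
        ov <- min(te[i], te[j]) - max(ts[i], ts[j]) + 1L
        if (ov <= 0) next
        if (ov / (te[i] - ts[i] + 1L) >= min_reciprocal_overlap &&
            ov / (te[j] - ts[j] + 1L) >= min_reciprocal_overlap &&
            hits$strand[i] == hits$strand[j]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  anc <- anchor  # avoid masking by the `anchor` column inside tibble()
  rows <- lapply(unique(comp), function(cc) {
    h <- hits[comp == cc, , drop = FALSE]
    vrs <- dplyr::distinct(
      tibble(vr_start = h$vr_start_parent, vr_end = h$vr_end_parent,
             strand = h$strand, n_substitutions = h$n_substitutions))
    vrs <- dplyr::arrange(vrs, .data$vr_start)
    tibble(sequence_id = h$sequence_id[1], anchor = anc$label,
           rt_start = anc$start, rt_end = anc$end,
           rt_strand = anc$strand,
           tr_start = min(h$tr_start_parent), tr_end = max(h$tr_end_parent),
           tr_strand = h$strand[1],
           n_vr = nrow(vrs), vrs = list(vrs),
           n_wildcard_tr = max(h$n_wildcard_tr),
           group = NA_integer_, subgroup = NA_character_,
           unassigned_vr = NA, tr_inside_rt = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$tr_start)
}

#' Assign VRs to target ORFs
#'
#' A VR is assigned to a CDS when its interval is fully contained in the CDS
#' interval on the CDS strand; otherwise its target is `NA` and the cassette
#' is flagged `unassigned_vr` (partial overlaps are reported, not resolved).
#' The RT CDS itself is not a target candidate.
#'
#' @param cassettes cassette tibble from [group_cassettes()].
#' @param features feature tibble of the parent record (`kind == "CDS"` rows
#'   are used).
#' @return cassettes with per-VR `target` filled inside the `vrs` list column
#'   and the `unassigned_vr` flag set.
#' @export
assign_targets <- function(cassettes, features) {
  if (!nrow(cassettes)) return(cassettes)
  cds <- features[features$kind == "CDS", , drop = FALSE]
  for (i in seq_len(nrow(cassettes))) {
    vrs <- cassettes$vrs[[i]]
    is_rt <- cds$start == cassettes$rt_start[i] & cds$end == cassettes$rt_end[i] &
      cds$strand == cassettes$rt_strand[i]
    cand <- cds[!is_rt, , drop = FALSE]
    target <- rep(NA_character_, nrow(vrs))
    if (nrow(vrs) && nrow(cand)) {
      for (v in seq_len(nrow(vrs))) {
        hit <- which(cand$start <= vrs$vr_start[v] & cand$end >= vrs$vr_end[v] &
                       cand$strand == vrs$strand[v])
        if (length(hit)) {
          q <- cand$qualifiers[[hit[1]]]
          lab <- NA_character_
          for (k in c("locus_tag", "label", "gene", "product")) {
            if (!is.null(q[k]) && !is.na(q[k]) && nzchar(q[k])) { lab <- unname(q[k]); break }
          }
          if (is.na(lab)) lab <- sprintf("CDS:%d-%d", cand$start[hit[1]], cand$end[hit[1]])
          target[v] <- lab
        }
      }
    }
    vrs$target <- target
    cassettes$vrs[[i]] <- vrs
    cassettes$unassigned_vr[i] <- anyNA(target)
  }
  cassettes
}

#' Classify cassette architecture
#'
#' Groups follow the relative position of TR and RT, evaluated in RT-coding
#' orientation: group 1 — TR upstream (5') of the RT; group 2 — TR
#' downstream; group 3 — TR overlaps the RT ORF (a TR fully inside the RT
#' CDS is folded into group 3 and flagged `tr_inside_rt`); group 4 — TR and
#' RT on different strands (the strand test takes precedence). The subgroup
#' letter is a deterministic enumeration of `(n_vr, per-VR placement)`
#' pinned so that the prototypical VR-TR-RT arrangement is subgroup "a" of
#' group 1 (see the methods vignette for the mapping).
#'
#' @param cassettes cassette tibble from [group_cassettes()].
#' @return cassettes with `group`, `subgroup` and `tr_inside_rt` filled.
#' @export
classify_structure <- function(cassettes) {
  if (!nrow(cassettes)) return(cassettes)
  for (i in seq_len(nrow(cassettes))) {
    cs <- cassettes[i, ]
    if (is.na(cs$tr_strand) || !cs$tr_strand %in% c("+", "-")) {
      stop("cassette TR strand undefined; cannot classify", call. = FALSE)
    }
    if (cs$tr_strand != cs$rt_strand) {
      group <- 4L
    } else if (cs$tr_start <= cs$rt_end && cs$tr_end >= cs$rt_start) {
      group <- 3L
      cassettes$tr_inside_rt[i] <- cs$tr_start >= cs$rt_start && cs$tr_end <= cs$rt_end
    } else {
      upstream <- if (cs$rt_strand == "+") cs$tr_end < cs$rt_start
                  else cs$tr_start > cs$rt_end
      group <- if (upstream) 1L else 2L
    }
    cassettes$group[i] <- group
    cassettes$subgroup[i] <- subgroup_letter(cs)
  }
  cassettes
}

# Placement of each VR in RT-coding 5'->3' orientation relative to the TR and
# RT intervals: "U" before both, "B" between them, "D" after both, "O"
# overlapping the RT ORF. The subgroup letter indexes the canonical
# enumeration of (n_vr, placement tuple): n_vr ascending, placements in
# lexicographic order over U < B < D < O.
vr_placements <- function(cs) {
  sign <- if (cs$rt_strand == "+") 1 else -1
  ax <- function(s, e) sort(sign * c(s, e))
  rt <- ax(cs$rt_start, cs$rt_end)
  tr <- ax(cs$tr_start, cs$tr_end)
  lo <- min(rt[1], tr[1]); hi <- max(rt[2], tr[2])
  vrs <- cs$vrs[[1]]
  vapply(seq_len(nrow(vrs)), function(v) {
    iv <- ax(vrs$vr_start[v], vrs$vr_end[v])
    if (iv[2] >= rt[1] && iv[1] <= rt[2]) return("O")
    mid <- mean(iv)
    if (mid < lo) "U" else if (mid > hi) "D" else "B"
  }, character(1))
}

subgroup_letter <- function(cs) {
  # VRs sorted 5'->3' in RT-coding orientation
  vrs <- cs$vrs[[1]]
  sign <- if (cs$rt_strand == "+") 1 else -1
  ord <- order(sign * vrs$vr_start)
  cs$vrs[[1]] <- vrs[ord, , drop = FALSE]
  p <- match(vr_placements(cs), c("U", "B", "D", "O"))
  k <- length(p)
  if (!k) return("a")
  prior <- if (k > 1) sum(4^seq_len(k - 1)) else 0
  idx <- sum((p - 1) * 4^(k - seq_len(k))) + 1
  letter_code(prior + idx)
}

# 1 -> "a", 26 -> "z", 27 -> "aa", ...
letter_code <- function(n) {
  out <- character()
  while (n > 0) {
    r <- (n - 1) %% 26
    out <- c(letters[r + 1], out)
    n <- (n - 1) %/% 26
  }
  paste(out, collapse = "")
}

#' Search a whole record's CDS features for distal VR copies
#'
#' Scans every CDS of the full record (both orientations) for placements of
#' a detected TR whose non-wildcard bases match perfectly — the whole-genome
#' rescan for target ORFs beyond the flank-limited scan region.
#'
#' @param record the parent [dgr_record()].
#' @param tr_seq TR sequence (RT-coding orientation).
#' @param wildcard_base wildcard base.
#' @param min_substitutions minimum wildcard-position substitutions for a
#'   placement to be reported (0 reports perfect copies too).
#' @return tibble of matches: CDS interval, strand searched, match interval
#'   on the parent, substitution count.
#' @export
find_distal_targets <- function(record, tr_seq, wildcard_base = "A",
                                min_substitutions = 1) {
  cds <- record$features[record$features$kind == "CDS", , drop = FALSE]
  out <- list()
  tr_codes <- dna_encode(clean_residues(tr_seq))
  wc <- match(wildcard_base, DNA_BASES) - 1L
  len <- length(tr_codes)
  for (i in seq_len(nrow(cds))) {
    slice <- subseq_str(record$residues, cds$start[i], cds$end[i])
    for (strand in c("+", "-")) {
      s <- if (strand == "+") slice else revcomp(slice)
      if (nchar(s) < len) next
      codes <- dna_encode(s)
      for (off in seq_len(nchar(s) - len + 1L)) {
        win <- codes[off:(off + len - 1L)]
        hard <- (win == 4L | tr_codes == 4L) |
          (tr_codes != wc & tr_codes != win)
        if (any(hard)) next
        n_sub <- sum(tr_codes == wc & win != wc)
        if (n_sub < min_substitutions) next
        ms <- if (strand == "+") cds$start[i] + off - 1L
              else cds$end[i] - (off + len - 1L) + 1L
        out[[length(out) + 1]] <- tibble(
          cds_start = cds$start[i], cds_end = cds$end[i], strand = strand,
          match_start = ms, match_end = ms + len - 1L, n_substitutions = n_sub)
      }
    }
  }
  if (!length(out)) {
    return(tibble(cds_start = integer(), cds_end = integer(),
                  strand = character(), match_start = integer(),
                  match_end = integer(), n_substitutions = integer()))
  }
  dplyr::bind_rows(out)
}

#' Write the cassette report
#'
#' One row per cassette: label, group/subgroup, VR count, per-VR target
#' locus tags and flags.
#'
#' @param cassettes classified cassette tibble.
#' @param path TSV path.
#' @export
write_cassettes_tsv <- function(cassettes, path) {
  flat <- dplyr::mutate(cassettes,
    vr_intervals = vapply(.data$vrs, function(v)
      paste(sprintf("%d-%d(%s)", v$vr_start, v$vr_end, v$strand), collapse = ","),
      character(1)),
    vr_targets = vapply(.data$vrs, function(v)
      if (is.null(v$target)) "" else paste(ifelse(is.na(v$target), ".", v$target),
                                           collapse = ","),
      character(1)))
  flat <- dplyr::select(flat, -"vrs")
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
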