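# The core repeat scan: sliding 50-nt windows over an RT-centred region are
# taken as template-repeat candidates and matched everywhere else in the
# region under the wildcard rule (all non-wildcard bases must match exactly;
# wildcard positions — adenines by default — are free). Matches are extended
# to maximal length, deduplicated, and filtered on the adenine count of the
# TR and the number of wildcard-position substitutions in the VR.

#' Scan parameters
#'
#' Defaults follow the original screen: 50-nt windows at step 1, 5-kb flanks,
#' wildcard base A, at least 10 adenines in the (extended) TR and at least 7
#' A-to-B substitutions (B = C, G or T) in the VR.
#'
#' @param window_size seed window length in nt.
#' @param step window start increment in nt.
#' @param flank region flank used upstream in [extract_region()].
#' @param wildcard_base the base exempt from the exact-match rule. `"A"` is
#'   the biological default; `"T"` reveals inverted cassettes (element on the
#'   opposite strand); `"C"`/`"G"` are negative-control sweeps.
#' @param min_wildcard_in_tr minimum count of the wildcard base in the
#'   extended TR.
#' @param min_substitutions minimum number of wildcard-position substitutions
#'   in the extended pair.
#' @param scan_reverse whether [cmd_scan()] additionally runs the generalized
#'   wildcard sweep (T, C, G) to pick up inverted elements.
#' @return a `dgr_scan_params` list.
#' @export
dgr_scan_params <- function(window_size = 50, step = 1, flank = 5000,
                            wildcard_base = "A", min_wildcard_in_tr = 10,
                            min_substitutions = 7, scan_reverse = FALSE) {
  wildcard_base <- match.arg(wildcard_base, DNA_BASES)
  stopifnot(window_size >= 10, step >= 1, min_substitutions >= 1,
            min_wildcard_in_tr >= min_substitutions, flank >= 0)
  structure(list(window_size = as.integer(window_size), step = as.integer(step),
                 flank = as.integer(flank), wildcard_base = wildcard_base,
                 min_wildcard_in_tr = as.integer(min_wildcard_in_tr),
                 min_substitutions = as.integer(min_substitutions),
                 scan_reverse = isTRUE(scan_reverse)),
            class = "dgr_scan_params")
}

empty_hits <- function() {
  tibble(sequence_id = character(), anchor = character(),
         tr_start = integer(), tr_end = integer(),
         vr_start = integer(), vr_end = integer(), length = integer(),
         tr_start_parent = integer(), tr_end_parent = integer(),
         vr_start_parent = integer(), vr_end_parent = integer(),
         strand = character(), strand_relation = character(),
         wildcard = character(), n_wildcard_tr = integer(),
         n_substitutions = integer(),
         sub_A = integer(), sub_C = integer(), sub_G = integer(),
         sub_T = integer(), substitutions = list())
}

#' Scan a region for TR/VR repeat pairs
#'
#' Runs the sliding-window wildcard repeat search over a region (RT-coding
#' strand). Every window start is a TR candidate; every placement at least a
#' window away is checked for a match of all non-wildcard bases, maximally
#' extended (stopping at region boundaries and before the two intervals would
#' overlap), deduplicated to unique maximal pairs, stripped of pairs strictly
#' contained in another pair, and filtered by `min_wildcard_in_tr` and
#' `min_substitutions`.
#'
#' @param region a [extract_region()] result, or a bare DNA string (then
#'   parent coordinates equal region coordinates).
#' @param params a [dgr_scan_params()].
#' @return tibble of hits sorted by TR start, one row per TR/VR pair, with
#'   region and parent coordinates (1-based inclusive), the element strand on
#'   the parent, counts, and a `substitutions` list column of
#'   `(offset, tr_base, vr_base)` tibbles.
#' @export
scan_region <- function(region, params = dgr_scan_params()) {
  stopifnot(inherits(params, "dgr_scan_params"))
  bare <- !inherits(region, "dgr_region")
  residues <- if (bare) clean_residues(region) else region$residues
  if (nchar(residues) < params$window_size) {
    message("region shorter than the scan window; returning no hits")
    return(empty_hits())
  }
  codes <- dna_encode(residues)
  wc <- match(params$wildcard_base, DNA_BASES) - 1L
  pairs <- scan_pairs_cpp(codes, params$window_size, params$step, wc)
  pairs$tr_start <- pairs$tr_start + 1L  # to 1-based
  pairs$vr_start <- pairs$vr_start + 1L
  pairs <- drop_contained(pairs)
  hits <- hit_details(residues, pairs, params$wildcard_base)
  hits <- hits[hits$n_wildcard_tr >= params$min_wildcard_in_tr &
                 hits$n_substitutions >= params$min_substitutions, , drop = FALSE]
  hits <- dplyr::arrange(hits, .data$tr_start, .data$vr_start)
  if (bare) {
    region <- NULL
  }
  finalize_hits(hits, region, params$wildcard_base)
}

#' Generalized wildcard scan
#'
#' The same algorithm with the wildcard role reassigned to C, G or T. A hit
#' under wildcard T on the RT-coding strand is the mirror image of an
#' adenine-specific element on the opposite strand and is reported with
#' `strand_relation = "inverted"` (and opposite element strand on the
#' parent); C and G sweeps are negative controls and are reported as-is.
#'
#' @inheritParams scan_region
#' @export
scan_generalized <- function(region, params = dgr_scan_params(wildcard_base = "T")) {
  stopifnot(inherits(params, "dgr_scan_params"))
  if (params$wildcard_base == "A") {
    stop("scan_generalized() expects a non-A wildcard; use scan_region() for A",
         call. = FALSE)
  }
  scan_region(region, params)
}

# drop pairs strictly contained in another pair (both intervals contained)
drop_contained <- function(pairs) {
  n <- nrow(pairs)
  if (n <= 1) return(pairs)
  ts <- pairs$tr_start; te <- pairs$tr_start + pairs$length - 1L
  vs <- pairs$vr_start; ve <- pairs$vr_start + pairs$length - 1L
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    contained <- ts >= ts[i] & te <= te[i] & vs >= vs[i] & ve <= ve[i] &
      !(ts == ts[i] & te == te[i] & vs == vs[i] & ve == ve[i])
    keep[contained] <- FALSE
  }
  pairs[keep, , drop = FALSE]
}

hit_details <- function(residues, pairs, wildcard_base) {
  n <- nrow(pairs)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ts <- pairs$tr_start[i]; vs <- pairs$vr_start[i]; len <- pairs$length[i]
    tr_seq <- strsplit(subseq_str(residues, ts, ts + len - 1L), "")[[1]]
    vr_seq <- strsplit(subseq_str(residues, vs, vs + len - 1L), "")[[1]]
    is_sub <- tr_seq == wildcard_base & vr_seq != wildcard_base
    subs <- tibble(offset = which(is_sub), tr_base = tr_seq[is_sub],
                   vr_base = vr_seq[is_sub])
    cnt <- table(factor(subs$vr_base, levels = DNA_BASES))
    rows[[i]] <- tibble(
      tr_start = ts, tr_end = ts + len - 1L,
      vr_start = vs, vr_end = vs + len - 1L, length = len,
      n_wildcard_tr = sum(tr_seq == wildcard_base),
      n_substitutions = nrow(subs),
      sub_A = as.integer(cnt[["A"]]), sub_C = as.integer(cnt[["C"]]),
      sub_G = as.integer(cnt[["G"]]), sub_T = as.integer(cnt[["T"]]),
      substitutions = list(subs))
  }
  if (!n) return(hit_details_empty())
  dplyr::bind_rows(rows)
}

hit_details_empty <- function() {
  dplyr::select(empty_hits(), -"sequence_id", -"anchor", -"strand",
                -"strand_relation", -"wildcard",
                -dplyr::ends_with("_parent"))
}

finalize_hits <- function(hits, region, wildcard_base) {
  relation <- if (wildcard_base == "T") "inverted" else "same"
  n <- nrow(hits)
  if (is.null(region)) {
    out <- dplyr::mutate(hits,
      sequence_id = rep("region", n), anchor = rep("region", n),
      tr_start_parent = .data$tr_start, tr_end_parent = .data$tr_end,
      vr_start_parent = .data$vr_start, vr_end_parent = .data$vr_end,
      strand = rep(if (relation == "inverted") "-" else "+", n),
      strand_relation = rep(relation, n), wildcard = rep(wildcard_base, n))
  } else {
    anchor_strand <- region$anchor$strand
    elem_strand <- if (relation == "inverted") flip_strand(anchor_strand) else anchor_strand
    tr_p <- lapply(seq_len(n), function(i)
      region_to_parent_interval(region, hits$tr_start[i], hits$tr_end[i]))
    vr_p <- lapply(seq_len(n), function(i)
      region_to_parent_interval(region, hits$vr_start[i], hits$vr_end[i]))
    out <- dplyr::mutate(hits,
      sequence_id = rep(region$sequence_id, n),
      anchor = rep(region$anchor$label, n),
      tr_start_parent = vapply(tr_p, `[`, integer(1), 1),
      tr_end_parent = vapply(tr_p, `[`, integer(1), 2),
      vr_start_parent = vapply(vr_p, `[`, integer(1), 1),
      vr_end_parent = vapply(vr_p, `[`, integer(1), 2),
      strand = rep(elem_strand, n),
      strand_relation = rep(relation, n), wildcard = rep(wildcard_base, n))
  }
  dplyr::select(out, dplyr::all_of(names(empty_hits())))
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Maximal extension of a matching pair
#'
#' Extends a wildcard-matching (TR, VR) seed leftward first, then rightward,
#' one position at a time, while the match rule holds and neither interval
#' crosses a sequence boundary or the other interval. The result is maximal:
#' no further single-position extension is valid.
#'
#' @param residues DNA string.
#' @param tr_start,vr_start 1-based starts of the seed pair.
#' @param length seed length.
#' @param wildcard_base wildcard base (default `"A"`).
#' @return named integer vector `tr_start`, `vr_start`, `length`.
#' @export
extend_match <- function(residues, tr_start, vr_start, length,
                         wildcard_base = "A") {
  codes <- dna_encode(clean_residues(residues))
  wc <- match(wildcard_base, DNA_BASES) - 1L
  r <- extend_pair_cpp(codes, tr_start - 1L, vr_start - 1L, length, wc)
  c(tr_start = r[1] + 1L, vr_start = r[2] + 1L, length = r[3])
}

#' Render a TR/VR alignment
#'
#' Three-line blocks (TR, match line, VR), width-wrapped. Exact matches are
#' marked `|`; wildcard-position substitutions are marked `*`.
#'
#' @param region the scanned region (or a bare DNA string).
#' @param hit one hit row from [scan_region()].
#' @param width alignment columns per block.
#' @return character vector of lines.
#' @export
align_pair <- function(region, hit, width = 60) {
  residues <- if (inherits(region, "dgr_region")) region$residues else clean_residues(region)
  stopifnot(nrow(hit) == 1L, width >= 10)
  tr <- subseq_str(residues, hit$tr_start, hit$tr_end)
  vr <- subseq_str(residues, hit$vr_start, hit$vr_end)
  trc <- strsplit(tr, "")[[1]]; vrc <- strsplit(vr, "")[[1]]
  marks <- ifelse(trc == vrc, "|",
                  ifelse(trc == hit$wildcard & vrc != hit$wildcard, "*", " "))
  lines <- character()
  for (p in seq(1L, hit$length, by = width)) {
    q <- min(p + width - 1L, hit$length)
    lines <- c(lines,
      sprintf("TR %6d %s %d", hit$tr_start + p - 1L,
              paste(trc[p:q], collapse = ""), hit$tr_start + q - 1L),
      sprintf("          %s", paste(marks[p:q], collapse = "")),
      sprintf("VR %6d %s %d", hit$vr_start + p - 1L,
              paste(vrc[p:q], collapse = ""), hit$vr_start + q - 1L),
      "")
  }
  lines
}

# inverse of align_pair: recover (offset, tr_base, vr_base) from rendered text
parse_alignment <- function(lines) {
  tr_lines <- grep("^TR ", lines, value = TRUE)
  vr_lines <- grep("^VR ", lines, value = TRUE)
  mark_lines <- lines[grep("^TR ", lines) + 1L]
  tr <- paste(vapply(strsplit(tr_lines, " +"), `[`, "", 3), collapse = "")
  vr <- paste(vapply(strsplit(vr_lines, " +"), `[`, "", 3), collapse = "")
  marks <- paste(substr(mark_lines, 11, nchar(mark_lines)), collapse = "")
  off <- which(strsplit(marks, "")[[1]] == "*")
  tibble(offset = off,
         tr_base = strsplit(tr, "")[[1]][off],
         vr_base = strsplit(vr, "")[[1]][off])
}

#' Write / read the tab-separated hit report
#'
#' One row per hit with parent-coordinate intervals, length, adenine count
#' and substitution counts by target base; the substitution list is
#' serialized as `offset:TR>VR` triples so the report round-trips.
#'
#' @param hits hit tibble.
#' @param path TSV path.
#' @return `path` (write) / hit tibble (read).
#' @export
write_hits_tsv <- function(hits, path) {
  flat <- dplyr::mutate(hits, substitutions = vapply(
    .data$substitutions,
    function(s) paste(sprintf("%d:%s>%s", s$offset, s$tr_base, s$vr_base),
                      collapse = ","),
    character(1)))
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  if (!file.exists(path)) stop("cannot read hit report: ", path, call. = FALSE)
  flat <- read.table(path, sep = "\t", header = TRUE,
                     colClasses = c(substitutions = "character"),
                     stringsAsFactors = FALSE)
  flat <- as_tibble(flat)
  if (!nrow(flat)) return(empty_hits())
  flat$substitutions <- lapply(flat$substitutions, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(tibble(offset = integer(), tr_base = character(),
                    vr_base = character()))
    }
    parts <- strsplit(strsplit(s, ",")[[1]], "[:>]")
    tibble(offset = as.integer(vapply(parts, `[`, "", 1)),
           tr_base = vapply(parts, `[`, "", 2),
           vr_base = vapply(parts, `[`, "", 3))
  })
  flat
}
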