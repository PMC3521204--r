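# DGR-diagnostic motif annotation of RT proteins: the region-4
# (I/V/L)GxxxSQ heptamer and its named variants, the domain-5 YxDD catalytic
# tetramer, and the positively charged C-terminal patch. All scans are pure
# functions of the protein string; X never matches any pattern position.

AA20 <- "ACDEFGHIKLMNPQRSTVWY"
AA_CLASS <- paste0("[", AA20, "]")
MOTIF4_VARIANTS <- c("SP", "SH", "NQ", "PA", "AQ", "VQ")

#' Find the YxDD catalytic motif
#'
#' First N-to-C match of `[YF]xDD` (x = any standard residue). The tyrosine
#' may be replaced by phenylalanine; the second position is variable (M and
#' V are the common residues in DGR RTs).
#'
#' @param protein amino-acid string (X tolerated, never matched).
#' @return one-row tibble: `found`, `offset` (1-based position of the Y/F),
#'   `tetramer`, `pos1` (`"Y"`/`"F"`), `pos2` (variable residue).
#' @export
find_ydd <- function(protein) {
  protein <- toupper(protein)
  if (!nchar(protein)) stop("empty protein sequence", call. = FALSE)
  pat <- paste0("[YF]", AA_CLASS, "DD")
  m <- regexpr(pat, protein)
  if (m < 0) {
    return(tibble(found = FALSE, offset = NA_integer_, tetramer = NA_character_,
                  pos1 = NA_character_, pos2 = NA_character_))
  }
  tet <- substr(protein, m, m + 3L)
  tibble(found = TRUE, offset = as.integer(m), tetramer = tet,
         pos1 = substr(tet, 1, 1), pos2 = substr(tet, 2, 2))
}

#' Find and classify the region-4 heptamer
#'
#' Searches for heptamers matching `[ILV]Gxxx??` within the 100 residues
#' preceding the YxDD motif (whole protein when YxDD is absent). The final
#' dipeptide is classified: `SQ` is canonical; `SP`, `SH`, `NQ`, `PA`, `AQ`,
#' `VQ` are the named variants; anything else is `"other"`. Among several
#' candidates the one nearest YxDD wins. No `[ILV]G...` heptamer at all
#' yields class `"absent"` (the retroviral-type `QGxxxSP` does not qualify).
#'
#' @param protein amino-acid string.
#' @param ydd_offset offset from [find_ydd()], or `NULL` to locate it here.
#' @return one-row tibble: `offset`, `heptamer`, `dipeptide`, `class`
#'   (`"canonical-SQ"`, a variant code, `"other"` or `"absent"`).
#' @export
find_motif4 <- function(protein, ydd_offset = NULL) {
  protein <- toupper(protein)
  if (!nchar(protein)) stop("empty protein sequence", call. = FALSE)
  if (is.null(ydd_offset)) {
    ydd <- find_ydd(protein)
    ydd_offset <- if (ydd$found) ydd$offset else NA_integer_
  }
  if (!is.na(ydd_offset)) {
    lo <- max(1L, ydd_offset - 100L)
    hi <- ydd_offset - 1L
  } else {
    lo <- 1L
    hi <- nchar(protein)
  }
  absent <- tibble(offset = NA_integer_, heptamer = NA_character_,
                   dipeptide = NA_character_, class = "absent")
  if (hi - lo + 1L < 7L) return(absent)
  window <- substr(protein, lo, hi)
  pat <- paste0("(?=([ILV]G", AA_CLASS, AA_CLASS, AA_CLASS, AA_CLASS, AA_CLASS, "))")
  m <- gregexpr(pat, window, perl = TRUE)[[1]]
  if (m[1] < 0) return(absent)
  starts <- as.integer(m) + lo - 1L
  # nearest to YxDD = latest start (candidates all precede ydd)
  off <- if (!is.na(ydd_offset)) max(starts) else min(starts)
  hept <- substr(protein, off, off + 6L)
  dip <- substr(hept, 6, 7)
  cls <- if (dip == "SQ") "canonical-SQ"
         else if (dip %in% MOTIF4_VARIANTS) dip else "other"
  tibble(offset = off, heptamer = hept, dipeptide = dip, class = cls)
}

#' Locate the positively charged C-terminal patch
#'
#' Over all 20-residue windows from the YxDD motif to the C-terminus,
#' returns the window maximizing the count of R and K (histidine is not
#' counted); ties break to the smallest offset. The `positive_patch` flag is
#' set when the count reaches 10 (50% of the window).
#'
#' @param protein amino-acid string.
#' @param ydd_offset offset of the YxDD motif.
#' @return one-row tibble: `found`, `offset`, `rk_count`, `fraction`,
#'   `positive_patch`.
#' @export
charge_patch <- function(protein, ydd_offset) {
  protein <- toupper(protein)
  if (!nchar(protein)) stop("empty protein sequence", call. = FALSE)
  stopifnot(!is.na(ydd_offset), ydd_offset >= 1)
  tail_len <- nchar(protein) - ydd_offset + 1L
  if (tail_len < 20L) {
    return(tibble(found = FALSE, offset = NA_integer_, rk_count = NA_integer_,
                  fraction = NA_real_, positive_patch = FALSE))
  }
  chars <- strsplit(substr(protein, ydd_offset, nchar(protein)), "")[[1]]
  is_rk <- as.integer(chars %in% c("R", "K"))
  cs <- c(0L, cumsum(is_rk))
  nw <- length(chars) - 20L + 1L
  counts <- cs[(1:nw) + 20L] - cs[1:nw]
  best <- which.max(counts)  # first maximum = smallest offset
  tibble(found = TRUE, offset = ydd_offset + best - 1L,
         rk_count = as.integer(counts[best]),
         fraction = counts[best] / 20,
         positive_patch = counts[best] >= 10L)
}

#' Motif report for a set of RT proteins
#'
#' Runs [find_ydd()], [find_motif4()] and [charge_patch()] over each protein
#' and returns one row per protein.
#'
#' @param proteins named character vector of amino-acid strings, an
#'   `AAStringSet`, or a path to a protein FASTA file.
#' @return tibble with label, length, YxDD fields, motif-4 fields and
#'   charge-patch fields.
#' @export
motif_report <- function(proteins) {
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins)) {
    proteins <- Biostrings::readAAStringSet(proteins)
  }
  if (methods::is(proteins, "AAStringSet")) {
    proteins <- setNames(as.character(proteins), sub("\\s.*$", "", names(proteins)))
  }
  stopifnot(is.character(proteins), length(proteins) >= 1L)
  if (is.null(names(proteins))) names(proteins) <- paste0("rt", seq_along(proteins))
  rows <- lapply(seq_along(proteins), function(i) {
    p <- toupper(gsub("\\*$", "", proteins[[i]]))
    ydd <- find_ydd(p)
    m4 <- find_motif4(p, if (ydd$found) ydd$offset else NA_integer_)
    cp <- if (ydd$found) charge_patch(p, ydd$offset) else
      tibble(found = FALSE, offset = NA_integer_, rk_count = NA_integer_,
             fraction = NA_real_, positive_patch = FALSE)
    tibble(rt_label = names(proteins)[i], rt_length = nchar(p),
           ydd_found = ydd$found, ydd_offset = ydd$offset,
           ydd_tetramer = ydd$tetramer, ydd_pos1 = ydd$pos1, ydd_pos2 = ydd$pos2,
           motif4_offset = m4$offset, motif4_heptamer = m4$heptamer,
           motif4_class = m4$class,
           patch_offset = cp$offset, patch_rk_count = cp$rk_count,
           patch_fraction = cp$fraction, positive_patch = cp$positive_patch)
  })
  dplyr::bind_rows(rows)
}

#' Summarize a motif report
#'
#' Length range and mean, fraction of canonical SQ motifs, and the
#' distribution of the YxDD second-position residue.
#'
#' @param reports tibble from [motif_report()].
#' @return one-row tibble; the `ydd_pos2_dist` column is a list of named
#'   fractions.
#' @export
summarize_rts <- function(reports) {
  stopifnot(nrow(reports) >= 1L)
  pos2 <- table(reports$ydd_pos2[!is.na(reports$ydd_pos2)])
  tibble(n = nrow(reports),
         length_min = min(reports$rt_length),
         length_max = max(reports$rt_length),
         length_mean = mean(reports$rt_length),
         frac_canonical_sq = mean(reports$motif4_class == "canonical-SQ"),
         frac_ydd_found = mean(reports$ydd_found),
         frac_positive_patch = mean(reports$positive_patch),
         ydd_pos2_dist = list(prop.table(pos2)))
}
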