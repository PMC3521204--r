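# RT anchors and RT-centred scan regions. A region is the subsequence
# flanking an RT gene, represented on the RT-coding strand (the scan frame:
# the search only analyses the strand coding for the RT), with an exact,
# invertible affine map back to parent coordinates.

#' Read an RT anchor table
#'
#' Reads a tab-separated table of RT gene locations with columns
#' `sequence_id`, `start`, `end`, `strand`, `label` (1-based inclusive,
#' strand `+`/`-`). This is the FASTA-input companion: it supplies the scan
#' origins that GenBank CDS features would otherwise provide.
#'
#' @param path TSV path. A header line is optional (detected by column names).
#' @return tibble of anchors with columns as above.
#' @export
read_rt_table <- function(path) {
  if (!file.exists(path)) stop("cannot read anchor table: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_anchors())
  if (grepl("^sequence_id\\b", lines[1])) lines <- lines[-1]
  if (!length(lines)) return(empty_anchors())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t| +")[[1]]
    if (length(f) < 5) {
      stop(sprintf("anchor table line %d: expected 5 columns, got %d", i, length(f)),
           call. = FALSE)
    }
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e)) {
      stop(sprintf("anchor table line %d: non-integer coordinate", i), call. = FALSE)
    }
    if (s > e) {
      stop(sprintf("anchor table line %d: start > end", i), call. = FALSE)
    }
    if (!f[4] %in% c("+", "-")) {
      stop(sprintf("anchor table line %d: strand must be + or -", i), call. = FALSE)
    }
    tibble(sequence_id = f[1], start = s, end = e, strand = f[4], label = f[5])
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$label)) {
    stop("anchor labels must be unique per run", call. = FALSE)
  }
  out
}

empty_anchors <- function() {
  tibble(sequence_id = character(), start = integer(), end = integer(),
         strand = character(), label = character())
}

#' Derive RT anchors from a record's CDS features
#'
#' Selects CDS features whose `/product`, `/note` or `/label` qualifier
#' matches `pattern` (default: "reverse transcriptase" or an `RT` label) and
#' returns them as an anchor tibble.
#'
#' @param record a [dgr_record()].
#' @param pattern regular expression matched case-insensitively against the
#'   qualifier values.
#' @return anchor tibble (see [read_rt_table()]).
#' @export
find_rt_anchors <- function(record, pattern = "reverse transcriptase|\\bRT\\b") {
  feats <- record$features
  feats <- feats[feats$kind == "CDS", , drop = FALSE]
  if (!nrow(feats)) return(empty_anchors())
  is_rt <- vapply(feats$qualifiers, function(q) {
    any(grepl(pattern, unlist(q), ignore.case = TRUE)) ||
      any(grepl(pattern, names(q), ignore.case = TRUE))
  }, logical(1))
  feats <- feats[is_rt, , drop = FALSE]
  if (!nrow(feats)) return(empty_anchors())
  labs <- vapply(seq_len(nrow(feats)), function(i) {
    q <- feats$qualifiers[[i]]
    for (k in c("locus_tag", "label", "gene")) {
      if (!is.null(q[k]) && !is.na(q[k]) && nzchar(q[k])) return(unname(q[k]))
    }
    sprintf("%s_rt%d", record$id, i)
  }, character(1))
  labs <- make.unique(labs)
  tibble(sequence_id = record$id, start = feats$start, end = feats$end,
         strand = feats$strand, label = labs)
}

#' Extract the RT-centred scan region
#'
#' Cuts the RT CDS plus `flank` nucleotides to either side (default 5000,
#' i.e. ~11 kb of input around a typical RT gene), clipped to the parent
#' sequence, and orients the residues on the RT-coding strand: for a
#' minus-strand RT the slice is reverse-complemented, so downstream scanning
#' always works in the RT's own reading orientation.
#'
#' @param record a [dgr_record()].
#' @param anchor one-row anchor tibble (see [read_rt_table()]).
#' @param flank nucleotides retained on each side of the CDS.
#' @return an object of class `dgr_region`: anchor, parent interval,
#'   oriented residues and the coordinate map.
#' @export
extract_region <- function(record, anchor, flank = 5000) {
  stopifnot(inherits(record, "dgr_record"), flank >= 0)
  anchor <- as_tibble(anchor)
  stopifnot(nrow(anchor) == 1L)
  L <- nchar(record$residues)
  if (anchor$start < 1 || anchor$end > L || anchor$start > anchor$end) {
    stop(sprintf("anchor %s lies outside sequence %s", anchor$label, record$id),
         call. = FALSE)
  }
  ps <- max(1L, as.integer(anchor$start) - as.integer(flank))
  pe <- min(L, as.integer(anchor$end) + as.integer(flank))
  residues <- subseq_str(record$residues, ps, pe)
  if (anchor$strand == "-") residues <- revcomp(residues)
  structure(
    list(anchor = anchor, parent_start = ps, parent_end = pe,
         parent_length = L, residues = residues,
         sequence_id = record$id),
    class = "dgr_region"
  )
}

#' @export
print.dgr_region <- function(x, ...) {
  cat(sprintf("<dgr_region> %s [%d-%d] on %s (%s strand RT '%s'), %d bp\n",
              x$sequence_id, x$parent_start, x$parent_end, x$sequence_id,
              x$anchor$strand, x$anchor$label, nchar(x$residues)))
  invisible(x)
}

#' Map positions between region and parent coordinates
#'
#' The region lives on the RT-coding strand; these maps are exact inverses
#' of each other for every position of the region.
#'
#' @param region a `dgr_region`.
#' @param pos position vector (1-based).
#' @return mapped position vector.
#' @export
region_to_parent <- function(region, pos) {
  if (region$anchor$strand == "+") {
    region$parent_start + pos - 1L
  } else {
    region$parent_end - pos + 1L
  }
}

#' @rdname region_to_parent
#' @export
parent_to_region <- function(region, pos) {
  if (region$anchor$strand == "+") {
    pos - region$parent_start + 1L
  } else {
    region$parent_end - pos + 1L
  }
}

# interval version: returns c(start, end) in region coordinates
parent_to_region_interval <- function(region, start, end) {
  p <- sort(parent_to_region(region, c(start, end)))
  c(p[1], p[2])
}

region_to_parent_interval <- function(region, start, end) {
  p <- sort(region_to_parent(region, c(start, end)))
  c(p[1], p[2])
}
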