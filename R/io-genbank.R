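# GenBank flat-file reading and writing, plus the annotated-sequence record
# container. Only the subset of the format this tool consumes and emits is
# supported: single-interval and complement() feature locations. Compound
# join() locations are rejected with a clear error rather than silently
# mis-read.

#' Annotated sequence record
#'
#' Lightweight container for one DNA record: identifier, residues and a
#' feature table. This is what [read_sequences()] returns and what the
#' synthetic-genome generator produces.
#'
#' @param id record identifier (accession or FASTA header word).
#' @param residues DNA string over `{A,C,G,T,N}` (cleaned via
#'   [clean_residues()]).
#' @param features tibble with columns `kind` (e.g. `"CDS"`,
#'   `"misc_feature"`), `start`, `end` (1-based inclusive), `strand`
#'   (`"+"`/`"-"`) and `qualifiers` (list column of named character vectors).
#' @param definition free-text description.
#' @param source named list of source metadata (e.g. `organism`).
#' @return an object of class `dgr_record`.
#' @export
dgr_record <- function(id, residues, features = empty_features(),
                       definition = "", source = list()) {
  residues <- clean_residues(residues, id = id)
  stopifnot(nchar(residues) > 0L)
  features <- as_tibble(features)
  if (nrow(features) > 0) {
    stopifnot(all(features$start >= 1L),
              all(features$end <= nchar(residues)),
              all(features$start <= features$end),
              all(features$strand %in% c("+", "-")))
  }
  structure(
    list(id = id, residues = residues, features = features,
         definition = definition, source = source),
    class = "dgr_record"
  )
}

#' @export
print.dgr_record <- function(x, ...) {
  cat(sprintf("<dgr_record> %s: %d bp, %d feature(s)\n",
              x$id, nchar(x$residues), nrow(x$features)))
  invisible(x)
}

#' @rdname dgr_record
#' @export
empty_features <- function() {
  tibble(kind = character(), start = integer(), end = integer(),
         strand = character(), qualifiers = list())
}

#' Read DNA sequence records
#'
#' Reads a GenBank flat file (with features) or a FASTA file (features
#' empty) into a list of [dgr_record()] objects. Coordinates are kept
#' 1-based inclusive, the convention of both formats and of this package.
#'
#' @param path file path.
#' @param format `"genbank"` or `"fasta"`; defaults from the file extension.
#' @return list of `dgr_record`.
#' @export
read_sequences <- function(path, format = NULL) {
  if (!file.exists(path)) stop("cannot read input file: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  format <- match.arg(format, c("genbank", "fasta"))
  if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    lapply(seq_along(set), function(i) {
      dgr_record(id = ids[i], residues = as.character(set[[i]]),
                 definition = names(set)[i])
    })
  } else {
    read_genbank(path)
  }
}

# --- GenBank reader ---------------------------------------------------------

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, "LOCUS"))) {
    stop("malformed GenBank file (no LOCUS line): ", path, call. = FALSE)
  }
  starts <- which(startsWith(lines, "LOCUS"))
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i) {
    parse_genbank_record(lines[starts[i]:ends[i]], path)
  })
}

parse_genbank_record <- function(lines, path) {
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- if (length(locus) >= 2) locus[2] else "unnamed"
  acc_line <- grep("^ACCESSION", lines, value = TRUE)
  id <- if (length(acc_line)) strsplit(trimws(acc_line[1]), "\\s+")[[1]][2] else name
  if (is.na(id)) id <- name
  def_i <- grep("^DEFINITION", lines)
  definition <- if (length(def_i)) trimws(sub("^DEFINITION", "", lines[def_i[1]])) else ""
  org_line <- grep("^\\s+ORGANISM", lines, value = TRUE)
  source <- list()
  if (length(org_line)) source$organism <- trimws(sub("^\\s+ORGANISM", "", org_line[1]))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) {
    stop(sprintf("malformed GenBank record '%s' in %s: no ORIGIN section", name, path),
         call. = FALSE)
  }
  features <- if (length(feat_i)) {
    parse_feature_block(lines[(feat_i[1] + 1L):(orig_i[1] - 1L)], name)
  } else {
    empty_features()
  }
  end_i <- grep("^//", lines)
  seq_last <- if (length(end_i)) end_i[1] - 1L else length(lines)
  seq_lines <- lines[(orig_i[1] + 1L):seq_last]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nchar(residues)) {
    stop(sprintf("malformed GenBank record '%s' in %s: empty sequence", name, path),
         call. = FALSE)
  }
  features <- features[features$kind != "source", , drop = FALSE]
  dgr_record(id = id, residues = residues, features = features,
             definition = definition, source = source)
}

parse_feature_block <- function(lines, record_name) {
  # a new feature starts with a non-blank key in columns 6-20
  keys <- substr(lines, 6, 20)
  is_new <- trimws(keys) != "" & substr(lines, 1, 5) == "     "
  if (!any(is_new)) return(empty_features())
  idx <- which(is_new)
  ends <- c(idx[-1] - 1L, length(lines))
  rows <- lapply(seq_along(idx), function(i) {
    block <- lines[idx[i]:ends[i]]
    parse_one_feature(block, record_name)
  })
  dplyr::bind_rows(rows)
}

parse_one_feature <- function(block, record_name) {
  kind <- trimws(substr(block[1], 6, 20))
  body <- trimws(substr(block, 21, nchar(block)))
  # location may continue over lines until the first qualifier
  qual_start <- which(startsWith(body, "/"))[1]
  loc_lines <- if (is.na(qual_start)) body else body[seq_len(qual_start - 1L)]
  location <- paste(loc_lines, collapse = "")
  loc <- parse_location(location, record_name)
  quals <- character()
  if (!is.na(qual_start)) {
    qlines <- body[qual_start:length(body)]
    # merge continuation lines (those not starting with "/") into the previous
    grp <- cumsum(startsWith(qlines, "/"))
    merged <- vapply(split(qlines, grp), paste, "", collapse = " ")
    for (q in merged) {
      q <- sub("^/", "", q)
      if (grepl("=", q)) {
        key <- sub("=.*$", "", q)
        val <- sub("^[^=]*=", "", q)
        val <- gsub("^\"|\"$", "", val)
      } else {
        key <- q
        val <- ""
      }
      quals[key] <- val
    }
  }
  tibble(kind = kind, start = loc$start, end = loc$end, strand = loc$strand,
         qualifiers = list(quals))
}

parse_location <- function(location, record_name) {
  location <- gsub("\\s", "", location)
  if (grepl("join|order", location)) {
    stop(sprintf("record '%s': compound feature location not supported: %s",
                 record_name, location), call. = FALSE)
  }
  strand <- "+"
  if (grepl("^complement\\(", location)) {
    strand <- "-"
    location <- sub("^complement\\((.*)\\)$", "\\1", location)
  }
  location <- gsub("[<>]", "", location)
  if (grepl("^[0-9]+\\.\\.[0-9]+$", location)) {
    parts <- as.integer(strsplit(location, "\\.\\.")[[1]])
  } else if (grepl("^[0-9]+$", location)) {
    parts <- rep(as.integer(location), 2L)
  } else {
    stop(sprintf("record '%s': cannot parse feature location: %s",
                 record_name, location), call. = FALSE)
  }
  if (parts[1] > parts[2]) {
    stop(sprintf("record '%s': feature location start > end: %s",
                 record_name, location), call. = FALSE)
  }
  list(start = parts[1], end = parts[2], strand = strand)
}

# --- GenBank writer ---------------------------------------------------------

#' Write a record as a GenBank flat file
#'
#' Emits a minimal, Artemis-compatible GenBank flat file: LOCUS line,
#' feature table (1-based inclusive coordinates, `complement()` for the
#' minus strand) and the ORIGIN sequence block.
#'
#' @param record a [dgr_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "dgr_record"))
  len <- nchar(record$residues)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %-16s %11d bp    DNA     linear   BCT 01-JAN-2026",
    substr(record$id, 1, 16), len)
  if (nzchar(record$definition)) w("DEFINITION  %s", record$definition)
  w("ACCESSION   %s", record$id)
  if (!is.null(record$source$organism)) {
    w("SOURCE      %s", record$source$organism)
    w("  ORGANISM  %s", record$source$organism)
  }
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", len)
  feats <- record$features
  if (nrow(feats)) {
    for (i in seq_len(nrow(feats))) {
      loc <- sprintf("%d..%d", feats$start[i], feats$end[i])
      if (feats$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      w("     %-15s %s", feats$kind[i], loc)
      quals <- feats$qualifiers[[i]]
      for (k in names(quals)) {
        if (nzchar(quals[[k]])) {
          w("                     /%s=\"%s\"", k, quals[[k]])
        } else {
          w("                     /%s", k)
        }
      }
    }
  }
  w("ORIGIN")
  seq_lower <- tolower(record$residues)
  pos <- seq(1L, len, by = 60L)
  for (p in pos) {
    chunk <- substr(seq_lower, p, min(p + 59L, len))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    w("%9d %s", p, paste(groups, collapse = " "))
  }
  w("//")
  invisible(path)
}

#' Write scan results as an annotated GenBank file
#'
#' Writes the scan region's residues with the RT gene as a `CDS` feature and
#' the TR and VRs as `misc_feature`s labelled `TR`/`VR1`... (Artemis shows
#' `/label` by default); `/note` carries the substitution and adenine counts.
#' Coordinates are region-local, 1-based inclusive.
#'
#' @param region a [extract_region()] result.
#' @param hits hit tibble from [scan_region()] restricted to this region.
#' @param cassette optional single-row cassette tibble from
#'   [group_cassettes()]; when given, its TR/VR layout is used.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(region, hits, cassette = NULL, path) {
  stopifnot(inherits(region, "dgr_region"))
  L <- nchar(region$residues)
  feats <- list()
  cds <- parent_to_region_interval(region, region$anchor$start, region$anchor$end)
  feats[[1]] <- tibble(kind = "CDS", start = cds[1], end = cds[2], strand = "+",
                       qualifiers = list(c(label = "RT",
                                           product = "reverse transcriptase")))
  if (nrow(hits)) {
    bad <- hits$tr_start < 1 | hits$tr_end > L | hits$vr_start < 1 | hits$vr_end > L
    if (any(bad)) stop("hit coordinates fall outside the region", call. = FALSE)
    trs <- dplyr::distinct(hits, .data$tr_start, .data$tr_end, .data$strand_relation,
                           .data$n_wildcard_tr)
    trs <- dplyr::arrange(trs, .data$tr_start)
    for (i in seq_len(nrow(trs))) {
      lab <- if (i == 1) "TR" else paste0("TR", i)
      feats[[length(feats) + 1]] <- tibble(
        kind = "misc_feature", start = trs$tr_start[i], end = trs$tr_end[i],
        strand = if (trs$strand_relation[i] == "inverted") "-" else "+",
        qualifiers = list(c(label = lab,
                            note = sprintf("template repeat; adenines=%d",
                                           trs$n_wildcard_tr[i]))))
    }
    vrs <- dplyr::arrange(hits, .data$vr_start)
    for (i in seq_len(nrow(vrs))) {
      feats[[length(feats) + 1]] <- tibble(
        kind = "misc_feature", start = vrs$vr_start[i], end = vrs$vr_end[i],
        strand = if (vrs$strand_relation[i] == "inverted") "-" else "+",
        qualifiers = list(c(label = paste0("VR", i),
                            note = sprintf("variable repeat; substitutions=%d; adenines=%d",
                                           vrs$n_substitutions[i], vrs$n_wildcard_tr[i]))))
    }
  }
  rec <- dgr_record(
    id = paste0(region$anchor$label, "_region"),
    residues = region$residues,
    features = dplyr::bind_rows(feats),
    definition = sprintf("DGR scan region around RT %s (%s:%d-%d)",
                         region$anchor$label, region$anchor$sequence_id,
                         region$parent_start, region$parent_end))
  write_genbank(rec, path)
}
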