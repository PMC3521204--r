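# Synthetic bacterial contigs with planted DGR cassettes, decoy repeats and
# a machine-readable truth table. The generator is the test bed for every
# other module: background is i.i.d. at a configurable GC fraction, the RT
# ORF encodes a protein with the requested motif profile, the TR carries a
# chosen adenine count and each VR differs from it at exactly the requested
# number of adenine positions. Guard bases (a C/G mismatch pair) border each
# planted repeat so that maximal extension stops exactly at the planted
# coordinates.

#' Specification of a synthetic genome
#'
#' @param background_length contig length in nt.
#' @param gc_fraction background GC content (defaults to a moderately
#'   AT-rich bacterial contig).
#' @param tr_length template-repeat length in nt (typical VRs are 100 +/- 50
#'   nt and never exceed ~180).
#' @param n_adenines_tr adenine count designed into the TR (ignored for
#'   group 3, where the TR is the natural sequence straddling the RT start).
#' @param n_vr number of VR copies.
#' @param substitutions_per_vr substitutions per VR: a single count or a
#'   `c(min, max)` range sampled per VR.
#' @param substitution_bias relative weights of the C, G, T target bases
#'   (default reflects the observed spectrum: G commonest, C rarest).
#' @param group cassette arrangement: 1 (TR upstream of RT; the VR-TR-RT
#'   prototype), 2 (TR downstream), 3 (TR straddling the RT start), 4
#'   (TR/VR/target on the opposite strand), or 0 for a decoy-only contig.
#' @param rt_motif_profile profile passed to [make_rt_protein()].
#' @param decoys subset of `"exact_duplicate"`, `"low_substitution"`,
#'   `"non_a_mismatch"`, `"homopolymer"`.
#' @param seed integer seed; recorded in the output.
#' @return a `dgr_plant_spec` list.
#' @export
plant_spec <- function(background_length = 16000, gc_fraction = 0.4,
                       tr_length = 110, n_adenines_tr = 33, n_vr = 1,
                       substitutions_per_vr = 12,
                       substitution_bias = c(C = 1, G = 3, T = 2),
                       group = 1, rt_motif_profile = "canonical",
                       decoys = c("exact_duplicate", "low_substitution",
                                  "non_a_mismatch", "homopolymer"),
                       seed = 1) {
  stopifnot(n_adenines_tr <= tr_length, tr_length >= 10,
            all(substitutions_per_vr <= n_adenines_tr),
            length(substitutions_per_vr) %in% 1:2,
            group %in% 0:4, n_vr >= 1,
            gc_fraction > 0, gc_fraction < 1,
            all(decoys %in% c("exact_duplicate", "low_substitution",
                              "non_a_mismatch", "homopolymer")))
  structure(list(background_length = as.integer(background_length),
                 gc_fraction = gc_fraction, tr_length = as.integer(tr_length),
                 n_adenines_tr = as.integer(n_adenines_tr),
                 n_vr = as.integer(n_vr),
                 substitutions_per_vr = as.integer(substitutions_per_vr),
                 substitution_bias = substitution_bias,
                 group = as.integer(group),
                 rt_motif_profile = rt_motif_profile,
                 decoys = decoys, seed = as.integer(seed)),
            class = "dgr_plant_spec")
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rand_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# TR with exactly n_a adenines; non-A bases drawn C/G/T by GC weight
design_tr <- function(len, n_a, gc) {
  chars <- sample(c("C", "G", "T"), len, replace = TRUE,
                  prob = c(gc / 2, gc / 2, (1 - gc) / 2))
  chars[sample.int(len, n_a)] <- "A"
  paste(chars, collapse = "")
}

# VR = TR with exactly k substitutions at adenine positions (bias over C,G,T).
# Target draws are constrained so that no 7 consecutive substitutions share
# one target base: real VRs mix their targets (no wildcard-C/G/T-coherent
# stretch exists in them, which is why cross-wildcard sweeps of genuine
# elements come back empty), and a same-target run of filter length would
# legitimately mirror-match under that base's wildcard.
mutate_tr <- function(tr, k, bias) {
  chars <- strsplit(tr, "")[[1]]
  a_pos <- which(chars == "A")
  stopifnot(k <= length(a_pos))
  pos <- sort(sample(a_pos, k))
  for (try in 1:100) {
    targets <- sample(names(bias), k, replace = TRUE, prob = bias)
    if (k < 7L || max(rle(targets)$lengths) < 7L) break
  }
  chars[pos] <- targets
  list(vr = paste(chars, collapse = ""), positions = pos, targets = targets)
}

# single-codon-per-residue reverse translation
.codon_of <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
               M = "ATG", N = "AAT", P = "CCG", Q = "CAA", R = "CGT",
               S = "TCT", T = "ACA", V = "GTG", W = "TGG", Y = "TAT",
               X = "NNN")
reverse_translate <- function(protein) {
  paste(.codon_of[strsplit(toupper(protein), "")[[1]]], collapse = "")
}

#' Generate a synthetic RT protein
#'
#' Builds a protein of length uniform in 260-527 aa embedding the requested
#' region-4 heptamer 60-90 residues upstream of a YMDD motif and an R/K-rich
#' 20-residue window near the C-terminus. The background is scrubbed of
#' accidental `[YF]xDD` and `[ILV]G` patterns so the planted motifs are the
#' ones the annotators find.
#'
#' @param profile `"canonical"`, a variant dipeptide code (`"SP"`, `"SH"`,
#'   `"NQ"`, `"PA"`, `"AQ"`, `"VQ"`), `"no-motif"` or `"truncated"` (stop
#'   before YxDD).
#' @param seed optional integer seed.
#' @param rk_count R/K residues planted in the charge-patch window.
#' @return amino-acid string.
#' @export
make_rt_protein <- function(profile = "canonical", seed = NULL, rk_count = 11) {
  ok <- c("canonical", MOTIF4_VARIANTS, "no-motif", "truncated")
  if (!profile %in% ok) {
    stop("unknown RT motif profile: ", profile, call. = FALSE)
  }
  build <- function() {
    n <- sample(260:527, 1)
    aa <- sample(strsplit(AA20, "")[[1]], n, replace = TRUE)
    aa[1] <- "M"
    # scrub accidental motifs from the background
    repeat {
      s <- paste(aa, collapse = "")
      m <- regexpr(paste0("[YF]", AA_CLASS, "DD"), s)
      if (m < 0) break
      aa[as.integer(m)] <- "L"
    }
    ig <- which(aa %in% c("I", "L", "V"))
    ig <- ig[ig < length(aa) & aa[pmin(ig + 1, length(aa))] == "G"]
    aa[ig + 1] <- "A"
    if (profile == "no-motif") return(paste(aa, collapse = ""))
    ydd_offset <- n - 40L
    aa[ydd_offset:(ydd_offset + 3L)] <- c("Y", "M", "D", "D")
    gap <- sample(60:90, 1)
    m4 <- ydd_offset - gap
    safe <- c("A", "S", "T", "E", "P", "Q", "N")
    dip <- if (profile %in% c("canonical", "truncated")) c("S", "Q")
           else strsplit(profile, "")[[1]]
    aa[m4:(m4 + 6L)] <- c(sample(c("I", "L", "V"), 1), "G",
                          sample(safe, 3, replace = TRUE), dip)
    # controlled charge patch: clear stray R/K after ydd, then plant the window
    tail_idx <- (ydd_offset + 4L):n
    aa[tail_idx][aa[tail_idx] %in% c("R", "K")] <- "S"
    win <- (n - 24L):(n - 5L)
    aa[win] <- sample(c("S", "T", "G"), 20, replace = TRUE)
    aa[sample(win, rk_count)] <- sample(c("R", "K"), rk_count, replace = TRUE)
    if (profile == "truncated") aa <- aa[seq_len(ydd_offset - 1L)]
    paste(aa, collapse = "")
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# --- genome assembly --------------------------------------------------------

#' Generate a synthetic annotated contig with truth table
#'
#' Assembles a contig at the spec's GC content with an RT ORF (CDS feature,
#' product "reverse transcriptase"), a planted TR and VR(s) per the
#' arrangement group (each VR inside its own target CDS), the requested
#' decoy repeats, and background. Planted intervals are pairwise disjoint
#' and guard bases pin maximal extension to the planted coordinates. The
#' truth table lists every planted interval with strand, substitution
#' positions and expected detectability at default thresholds.
#'
#' @param spec a [plant_spec()].
#' @return list with `record` (a [dgr_record()]), `truth` (tibble) and
#'   `spec`.
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "dgr_plant_spec"))
  with_seed(spec$seed, build_genome(spec))
}

build_genome <- function(spec) {
  gc <- spec$gc_fraction
  parts <- list()    # list of (label, content, truth rows relative to part)
  truth <- list()
  feats <- list()
  pos <- 0L          # cursor: end of assembled sequence
  pieces <- character()

  append_part <- function(content) {
    pieces[[length(pieces) + 1L]] <<- content
    start <- pos + 1L
    pos <<- pos + nchar(content)
    c(start = start, end = pos)
  }
  gap <- function() append_part(rand_dna(sample(150:300, 1), gc))

  truth_row <- function(kind, label, start, end, strand, n_adenines = NA_integer_,
                        n_substitutions = NA_integer_, sub_positions = "",
                        detectable = FALSE, detect_wildcard = NA_character_) {
    truth[[length(truth) + 1L]] <<- tibble(
      kind = kind, label = label, start = as.integer(start),
      end = as.integer(end), strand = strand, length = as.integer(end - start + 1L),
      n_adenines = as.integer(n_adenines),
      n_substitutions = as.integer(n_substitutions),
      sub_positions = sub_positions, detectable = detectable,
      detect_wildcard = detect_wildcard)
  }
  cds_feat <- function(start, end, strand, label, product) {
    feats[[length(feats) + 1L]] <<- tibble(
      kind = "CDS", start = as.integer(start), end = as.integer(end),
      strand = strand,
      qualifiers = list(c(locus_tag = label, product = product)))
  }

  # --- components -----------------------------------------------------------
  rt_protein <- make_rt_protein(spec$rt_motif_profile)
  rt_dna <- paste0(reverse_translate(rt_protein), "TAA")

  draw_subs <- function() {
    if (length(spec$substitutions_per_vr) == 2L)
      sample(spec$substitutions_per_vr[1]:spec$substitutions_per_vr[2], 1)
    else spec$substitutions_per_vr
  }

  # VR inside a target ORF, with guard bases G flanking the VR
  embed_in_cds <- function(vr_seq) {
    lp <- 12L
    core <- 3L + lp + 1L + nchar(vr_seq) + 1L
    rp <- 9L + (3L - (core + 9L + 3L) %% 3L) %% 3L
    cds <- paste0("ATG", rand_dna(lp, gc), "G", vr_seq, "G", rand_dna(rp, gc), "TAA")
    list(cds = cds, vr_offset = 3L + lp + 1L + 1L)  # VR start within cds
  }

  element_truth <- function(tr_iv, tr_seq, vr_list, strand, wildcard) {
    nA <- count_base(tr_seq, "A")
    det_any <- FALSE
    for (i in seq_along(vr_list)) {
      v <- vr_list[[i]]
      det <- nA >= 10L && length(v$positions) >= 7L && nchar(tr_seq) >= 50L
      det_any <- det_any || det
      truth_row("VR", paste0("VR", i), v$iv[1], v$iv[2], strand,
                n_adenines = nA, n_substitutions = length(v$positions),
                sub_positions = paste(v$positions, collapse = ","),
                detectable = det, detect_wildcard = wildcard)
    }
    truth_row("TR", "TR", tr_iv[1], tr_iv[2], strand, n_adenines = nA,
              n_substitutions = NA_integer_, detectable = det_any,
              detect_wildcard = wildcard)
  }

  place_decoys <- function() {
    for (d in spec$decoys) {
      if (d == "exact_duplicate") {
        # guarded like the elements: without flanking mismatches, maximal
        # extension of the duplicate walks into the A-rich background and can
        # accumulate enough wildcard-column "substitutions" to pass the filter
        block <- design_tr(80L, 24L, gc)
        iv1 <- append_part(paste0("C", block, "C"))
        append_part(rand_dna(120L, gc))
        iv2 <- append_part(paste0("G", block, "G"))
        truth_row("decoy_exact_duplicate", "dup", iv1[1] + 1L, iv2[2] - 1L, "+")
      } else if (d == "low_substitution") {
        block <- design_tr(80L, 12L, gc)
        mut <- mutate_tr(block, 6L, spec$substitution_bias)
        iv1 <- append_part(paste0("C", block, "C"))
        append_part(rand_dna(120L, gc))
        iv2 <- append_part(paste0("G", mut$vr, "G"))
        truth_row("decoy_low_substitution", "lowsub_tr", iv1[1] + 1L, iv1[2] - 1L,
                  "+", n_adenines = 12L, n_substitutions = 6L,
                  sub_positions = paste(mut$positions, collapse = ","))
        truth_row("decoy_low_substitution", "lowsub_vr", iv2[1] + 1L, iv2[2] - 1L,
                  "+", n_adenines = 12L, n_substitutions = 6L)
      } else if (d == "non_a_mismatch") {
        block <- design_tr(80L, 20L, gc)
        chars <- strsplit(block, "")[[1]]
        non_a <- which(chars != "A")
        flip <- sort(sample(non_a, 3L))
        for (p in flip) chars[p] <- setdiff(c("C", "G", "T"), chars[p])[1]
        iv1 <- append_part(paste0("C", block, "C"))
        append_part(rand_dna(120L, gc))
        iv2 <- append_part(paste0("G", paste(chars, collapse = ""), "G"))
        truth_row("decoy_non_a_mismatch", "nam", iv1[1] + 1L, iv2[2] - 1L, "+",
                  n_substitutions = 0L)
      } else if (d == "homopolymer") {
        # kept below the window size: a tract at or above the window length
        # is degenerate under its own base's wildcard (every position exempt)
        iv <- append_part(strrep("C", 30L))
        truth_row("decoy_homopolymer", "polyC", iv[1], iv[2], "+")
      }
      gap()
    }
  }

  # --- arrangement layouts (RT always on the + strand) ----------------------
  place_vr_cds <- function(vr, i, minus = FALSE) {
    emb <- embed_in_cds(vr$vr)
    content <- if (minus) revcomp(emb$cds) else emb$cds
    iv <- append_part(content)
    if (minus) {
      vr_end <- iv[2] - emb$vr_offset + 1L
      vr_iv <- c(vr_end - nchar(vr$vr) + 1L, vr_end)
    } else {
      vr_iv <- c(iv[1] + emb$vr_offset - 1L,
                 iv[1] + emb$vr_offset + nchar(vr$vr) - 2L)
    }
    cds_feat(iv[1], iv[2], if (minus) "-" else "+", sprintf("target%d", i),
             "hypothetical VR-containing protein")
    gap()
    list(iv = vr_iv, positions = vr$positions, targets = vr$targets)
  }

  place_rt <- function() {
    iv <- append_part(rt_dna)
    cds_feat(iv[1], iv[2], "+", "rt1", "reverse transcriptase")
    truth_row("RT", "rt1", iv[1], iv[2], "+")
    iv
  }

  group <- spec$group
  gap()
  if (group == 0L) {
    place_rt(); gap()
    place_decoys()
  } else if (group %in% c(1L, 2L, 4L)) {
    minus <- group == 4L
    tr <- design_tr(spec$tr_length, spec$n_adenines_tr, gc)
    vrs <- lapply(seq_len(spec$n_vr), function(i)
      mutate_tr(tr, draw_subs(), spec$substitution_bias))
    # guard bases are chosen in the parent frame (the scan frame): the TR
    # flank and VR flank must differ and neither may be a wildcard candidate
    tr_content <- if (minus) paste0("G", revcomp(tr), "G") else paste0("C", tr, "C")
    if (group %in% c(1L, 4L)) {
      placed <- lapply(seq_along(vrs), function(i) place_vr_cds(vrs[[i]], i, minus))
      tr_iv_outer <- append_part(tr_content); gap()
      rt_iv <- place_rt(); gap()
      place_decoys()
    } else { # group 2: RT, then TR, then VRs downstream
      place_decoys()
      rt_iv <- place_rt(); gap()
      tr_iv_outer <- append_part(tr_content); gap()
      placed <- lapply(seq_along(vrs), function(i) place_vr_cds(vrs[[i]], i, minus))
    }
    tr_iv <- c(tr_iv_outer[1] + 1L, tr_iv_outer[2] - 1L)
    element_truth(tr_iv, tr, placed, if (minus) "-" else "+",
                  if (minus) "T" else "A")
  } else { # group 3: TR straddles the RT CDS start
    tr_len <- spec$tr_length
    half <- tr_len %/% 2L
    pre_iv <- append_part(rand_dna(max(half + 40L, 190L), gc))
    rt_iv <- place_rt(); gap()
    place_decoys()
    tr_iv <- c(rt_iv[1] - half, rt_iv[1] - half + tr_len - 1L)
    seq_now <- paste(pieces, collapse = "")
    # guard bases just outside the TR interval
    seq_now <- splice_str(seq_now, tr_iv[1] - 1L, "C")
    seq_now <- splice_str(seq_now, tr_iv[2] + 1L, "C")
    tr <- subseq_str(seq_now, tr_iv[1], tr_iv[2])
    pieces <- list(seq_now)
    vrs <- lapply(seq_len(spec$n_vr), function(i)
      mutate_tr(tr, min(draw_subs(), count_base(tr, "A")),
                spec$substitution_bias))
    placed <- lapply(seq_along(vrs), function(i) place_vr_cds(vrs[[i]], i, FALSE))
    element_truth(tr_iv, tr, placed, "+", "A")
  }

  contig <- paste(unlist(pieces), collapse = "")
  if (nchar(contig) > spec$background_length) {
    stop(sprintf("planted content (%d nt) does not fit in background_length (%d nt)",
                 nchar(contig), spec$background_length), call. = FALSE)
  }
  contig <- paste0(contig, rand_dna(spec$background_length - nchar(contig), gc))

  record <- dgr_record(
    id = sprintf("synth_g%d_s%d", spec$group, spec$seed),
    residues = contig,
    features = dplyr::bind_rows(feats),
    definition = sprintf("synthetic contig, arrangement group %d, seed %d",
                         spec$group, spec$seed),
    source = list(organism = "synthetic construct"))
  truth <- dplyr::bind_rows(truth)
  list(record = record, truth = truth, spec = spec)
}

#' Write / read a truth table
#'
#' Plain TSV with the same 1-based inclusive coordinate convention as the
#' hit reports.
#'
#' @param truth truth tibble from [make_genome()].
#' @param path TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path) {
  as_tibble(read.table(path, sep = "\t", header = TRUE,
                       colClasses = c(sub_positions = "character"),
                       stringsAsFactors = FALSE))
}
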