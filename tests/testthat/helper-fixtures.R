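# Small fixture builders used across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

rand_seq <- function(n, gc = 0.4, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                                  prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                           (1 - gc) / 2)),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# plant a TR/VR pair into a background string: TR at tr_at, VR at vr_at,
# exactly n_sub substitutions at adenine positions, guard mismatch bases
# (C around the TR, G around the VR) so extension stops at the planted ends
plant_pair <- function(background, tr_at, vr_at, tr_len = 50, n_a = 12,
                       n_sub = 8, seed = 1) {
  withr::with_seed(seed, {
    chars <- sample(c("C", "G", "T"), tr_len, replace = TRUE)
    chars[sample.int(tr_len, n_a)] <- "A"
    tr <- paste(chars, collapse = "")
    a_pos <- which(chars == "A")
    sub_at <- sort(sample(a_pos, n_sub))
    vchars <- chars
    vchars[sub_at] <- sample(c("C", "G", "T"), n_sub, replace = TRUE)
    vr <- paste(vchars, collapse = "")
  })
  put <- function(s, at, val) {
    paste0(substr(s, 1, at - 1), val, substr(s, at + nchar(val), nchar(s)))
  }
  background <- put(background, tr_at - 1, paste0("C", tr, "C"))
  background <- put(background, vr_at - 1, paste0("G", vr, "G"))
  list(seq = background, tr = c(tr_at, tr_at + tr_len - 1),
       vr = c(vr_at, vr_at + tr_len - 1), n_sub = n_sub, sub_at = sub_at)
}

# a minimal record with one RT CDS for region/anchor tests
toy_record <- function(len = 20000, cds = c(6001, 7200), strand = "+",
                       seed = 11) {
  dgr_record(
    id = "toy1",
    residues = rand_seq(len, seed = seed),
    features = tibble::tibble(
      kind = "CDS", start = cds[1], end = cds[2], strand = strand,
      qualifiers = list(c(locus_tag = "rt1", product = "reverse transcriptase"))))
}

scan_fast <- function(residues, ...) {
  scan_region(residues, dgr_scan_params(...))
}
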