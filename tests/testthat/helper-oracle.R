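# Independent brute-force oracle for the repeat scan, written as a per-shift
# mismatch-vector enumeration in pure R (the package's implementation is a
# seed-and-extend double loop in C++). For every shift d and both TR/VR role
# assignments it computes the hard-mismatch vector, finds seed windows by
# cumulative sums, extends each seed greedily (leftward first), and applies
# the same dedup / containment / filter semantics.

oracle_scan <- function(residues, window = 50, step = 1, wildcard = "A",
                        min_wc = 10, min_sub = 7) {
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  pairs <- list()
  if (L >= 2 * window) {
    for (d in window:(L - window)) {
      n <- L - d
      a <- chars[1:n]
      b <- chars[(1 + d):L]
      diffn <- a != b | a == "N" | b == "N"
      for (role in 1:2) {
        # role 1: TR at left position i, VR at i+d; role 2: reversed
        tr_base <- if (role == 1) a else b
        h <- diffn & tr_base != wildcard
        cs <- c(0, cumsum(h))
        starts <- seq(1, n - window + 1, by = step)
        seed_ok <- (cs[starts + window] - cs[starts]) == 0
        for (t in starts[seed_ok]) {
          ts <- t
          len <- window
          while (len < d && ts > 1 && !h[ts - 1]) {
            ts <- ts - 1
            len <- len + 1
          }
          while (len < d && ts + len <= n && !h[ts + len]) {
            len <- len + 1
          }
          pairs[[length(pairs) + 1]] <-
            if (role == 1) c(ts, ts + d, len) else c(ts + d, ts, len)
        }
      }
    }
  }
  if (!length(pairs)) return(oracle_empty())
  m <- unique(do.call(rbind, pairs))
  ts <- m[, 1]; vs <- m[, 2]; len <- m[, 3]
  te <- ts + len - 1L; ve <- vs + len - 1L
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    inside <- ts >= ts[i] & te <= te[i] & vs >= vs[i] & ve <= ve[i] &
      !(ts == ts[i] & te == te[i] & vs == vs[i] & ve == ve[i])
    keep[inside] <- FALSE
  }
  m <- m[keep, , drop = FALSE]
  rows <- lapply(seq_len(nrow(m)), function(i) {
    tr <- chars[m[i, 1]:(m[i, 1] + m[i, 3] - 1)]
    vr <- chars[m[i, 2]:(m[i, 2] + m[i, 3] - 1)]
    n_wc <- sum(tr == wildcard)
    n_sub <- sum(tr == wildcard & vr != wildcard & tr != vr)
    data.frame(tr_start = m[i, 1], vr_start = m[i, 2], length = m[i, 3],
               n_wildcard_tr = n_wc, n_substitutions = n_sub)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_wildcard_tr >= min_wc & out$n_substitutions >= min_sub, ,
             drop = FALSE]
  out <- out[order(out$tr_start, out$vr_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_empty <- function() {
  data.frame(tr_start = integer(), vr_start = integer(), length = integer(),
             n_wildcard_tr = integer(), n_substitutions = integer())
}

# hit tibble -> comparable data frame in the oracle's shape
hits_to_oracle_shape <- function(hits) {
  out <- as.data.frame(hits[, c("tr_start", "vr_start", "length",
                                "n_wildcard_tr", "n_substitutions")])
  out <- out[order(out$tr_start, out$vr_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
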