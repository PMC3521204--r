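# Adenine-substitution statistics: per-element base frequencies at
# TR-adenine positions, the 4^n repertoire bound, and the chi-square tests
# of target-base uniformity and proportionality.

#' Substitution profile across elements
#'
#' For each hit (element), counts the bases observed at TR-adenine
#' positions in the VR: unchanged A plus substitutions to C, G, T. Per-element
#' frequencies are aggregated as unweighted means with standard deviations
#' (each element counts once). Unchanged-A positions are reported but are
#' mechanistically uninterpretable: exact base pairing and random
#' re-incorporation of A are indistinguishable.
#'
#' @param hits hit tibble from [scan_region()]; all hits must share
#'   wildcard base A.
#' @return object of class `dgr_substitution_profile`: `per_element` tibble
#'   (counts and frequencies), `summary` tibble (mean and sd per base),
#'   `n_elements`.
#' @export
substitution_profile <- function(hits) {
  if (!nrow(hits)) stop("no hits to profile", call. = FALSE)
  if (length(unique(hits$wildcard)) > 1L || hits$wildcard[1] != "A") {
    stop("substitution_profile() requires hits with wildcard base A",
         call. = FALSE)
  }
  per <- tibble(
    element = paste0(hits$anchor, ":", hits$tr_start_parent, "-",
                     hits$tr_end_parent, "/", hits$vr_start_parent),
    n_a_tr = hits$n_wildcard_tr,
    count_A = hits$n_wildcard_tr - hits$n_substitutions,
    count_C = hits$sub_C, count_G = hits$sub_G, count_T = hits$sub_T)
  per <- dplyr::mutate(per,
    freq_A = .data$count_A / .data$n_a_tr, freq_C = .data$count_C / .data$n_a_tr,
    freq_G = .data$count_G / .data$n_a_tr, freq_T = .data$count_T / .data$n_a_tr,
    mutation_rate = 1 - .data$freq_A)
  summ <- tibble(
    base = DNA_BASES,
    mean_freq = c(mean(per$freq_A), mean(per$freq_C),
                  mean(per$freq_G), mean(per$freq_T)),
    sd_freq = c(sd(per$freq_A), sd(per$freq_C), sd(per$freq_G), sd(per$freq_T)))
  structure(list(per_element = per, summary = summ, n_elements = nrow(per)),
            class = "dgr_substitution_profile")
}

#' @export
print.dgr_substitution_profile <- function(x, ...) {
  cat(sprintf("<dgr_substitution_profile> %d element(s)\n", x$n_elements))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.dgr_substitution_profile <- function(x, ...) {
  tidyr::pivot_longer(x$per_element,
                      cols = dplyr::starts_with("freq_"),
                      names_to = "base", names_prefix = "freq_",
                      values_to = "frequency")
}

#' @export
glance.dgr_substitution_profile <- function(x, ...) {
  s <- x$summary
  tibble(n_elements = x$n_elements,
         mean_freq_A = s$mean_freq[s$base == "A"],
         mean_freq_C = s$mean_freq[s$base == "C"],
         mean_freq_G = s$mean_freq[s$base == "G"],
         mean_freq_T = s$mean_freq[s$base == "T"],
         mean_mutation_rate = mean(x$per_element$mutation_rate))
}

#' Repertoire diversity bound
#'
#' A TR with `n` adenines can give rise to `4^n` VR sequences (each mutable
#' position admits any of the four bases). Exact as an integer for
#' `n <= 26` (the double-precision limit); a TR below 10 adenines bounds the
#' repertoire under 2.6e5.
#'
#' @param n_adenines adenine count (non-negative integer vector).
#' @return `4^n` as a double.
#' @export
diversity <- function(n_adenines) {
  if (any(n_adenines < 0)) stop("adenine count must be non-negative", call. = FALSE)
  4^as.numeric(n_adenines)
}

#' Chi-square test of substitution-target uniformity
#'
#' Goodness-of-fit test of the three substitution-target counts (C, G, T for
#' wildcard A) against equal expectation, df = 2. For df = 2 the p-value has
#' the closed form `exp(-statistic / 2)`.
#'
#' @param counts named or unnamed numeric vector of three target-base counts.
#' @return object of class `dgr_chisq`: `statistic`, `df`, `p.value`,
#'   `observed`, `expected`.
#' @export
chisq_uniform <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L)
  if (sum(counts) < 1) stop("all-zero counts: test undefined", call. = FALSE)
  expected <- rep(sum(counts) / 3, 3)
  statistic <- sum((counts - expected)^2 / expected)
  structure(list(statistic = statistic, df = 2L,
                 p.value = pchisq(statistic, df = 2, lower.tail = FALSE),
                 observed = counts, expected = expected,
                 method = "chi-square goodness of fit against uniform targets"),
            class = "dgr_chisq")
}

#' @export
print.dgr_chisq <- function(x, ...) {
  cat(sprintf("%s\nX-squared = %.4g, df = %d, p = %.4g\n",
              x$method, x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @export
tidy.dgr_chisq <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value,
         method = x$method)
}

#' Chi-square test of proportionality to TR adenine content
#'
#' Under no target selectivity, the number of changes to a given base in an
#' element is proportional to the element's TR adenine count. For each base
#' b in C, G, T the observed per-element counts are compared with
#' `total_b * n_a_tr / sum(n_a_tr)`; cells with expected count below 1 are
#' pooled into one cell; df = cells - 1.
#'
#' @param elements tibble with columns `n_a_tr`, `count_C`, `count_G`,
#'   `count_T` (e.g. `substitution_profile(hits)$per_element`).
#' @return tibble with one row per base: `base`, `statistic`, `df`,
#'   `p.value`.
#' @export
chisq_proportional <- function(elements) {
  stopifnot(nrow(elements) >= 2L,
            all(c("n_a_tr", "count_C", "count_G", "count_T") %in% names(elements)))
  rows <- lapply(c("C", "G", "T"), function(b) {
    obs <- elements[[paste0("count_", b)]]
    total <- sum(obs)
    expected <- total * elements$n_a_tr / sum(elements$n_a_tr)
    pool <- expected < 1
    if (all(pool)) stop("degenerate table: all expected counts below 1", call. = FALSE)
    if (any(pool)) {
      obs <- c(obs[!pool], sum(obs[pool]))
      expected <- c(expected[!pool], sum(expected[pool]))
      # if the pooled cell is still below 1, fold it into the smallest kept cell
      k <- length(obs)
      if (expected[k] < 1 && k > 1) {
        j <- which.min(expected[-k])
        obs[j] <- obs[j] + obs[k]
        expected[j] <- expected[j] + expected[k]
        obs <- obs[-k]
        expected <- expected[-k]
      }
    }
    if (length(obs) < 2L) stop("degenerate single-cell table", call. = FALSE)
    statistic <- sum((obs - expected)^2 / expected)
    df <- length(obs) - 1L
    tibble(base = b, statistic = statistic, df = df,
           p.value = pchisq(statistic, df = df, lower.tail = FALSE))
  })
  dplyr::bind_rows(rows)
}

#' Write the profile and test reports
#'
#' @param profile a `dgr_substitution_profile`.
#' @param path_profile,path_tests TSV paths (either may be `NULL`).
#' @export
write_stats_tsv <- function(profile, path_profile = NULL, path_tests = NULL) {
  if (!is.null(path_profile)) {
    write.table(profile$per_element, path_profile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(path_tests)) {
    agg <- chisq_uniform(c(sum(profile$per_element$count_C),
                           sum(profile$per_element$count_G),
                           sum(profile$per_element$count_T)))
    tests <- tidy(agg)
    tests$test <- "uniform_targets"
    if (nrow(profile$per_element) >= 2L) {
      prop <- tryCatch(chisq_proportional(profile$per_element),
                       error = function(e) NULL)  # too sparse for the test
      if (!is.null(prop)) {
        prop$test <- paste0("proportional_", prop$base)
        tests <- dplyr::bind_rows(tests,
                                  dplyr::select(prop, -"base"))
      }
    }
    write.table(tests, path_tests, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(profile)
}
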