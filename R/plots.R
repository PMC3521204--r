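# ggplot2 graphics: the substitution spectrum and the cassette map.

#' @export
autoplot.dgr_substitution_profile <- function(object, ...) {
  s <- object$summary
  s$base <- factor(s$base, levels = DNA_BASES)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$base, y = .data$mean_freq)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, .data$mean_freq - .data$sd_freq),
                                        ymax = pmin(1, .data$mean_freq + .data$sd_freq)),
                           width = 0.2) +
    ggplot2::labs(x = "base at TR-adenine positions in the VR",
                  y = "mean frequency across elements",
                  title = sprintf("Adenine substitution spectrum (%d elements)",
                                  object$n_elements)) +
    ggplot2::theme_minimal()
}

#' Plot a cassette map
#'
#' Draws RT, TR and VRs of classified cassettes as strand-aware segments
#' along the parent coordinate axis, one row per cassette.
#'
#' @param cassettes classified cassette tibble from [classify_structure()].
#' @return a ggplot object.
#' @export
plot_cassette_map <- function(cassettes) {
  stopifnot(nrow(cassettes) >= 1L)
  rows <- lapply(seq_len(nrow(cassettes)), function(i) {
    cs <- cassettes[i, ]
    vrs <- cs$vrs[[1]]
    dplyr::bind_rows(
      tibble(cassette = i, part = "RT", start = cs$rt_start, end = cs$rt_end,
             strand = cs$rt_strand),
      tibble(cassette = i, part = "TR", start = cs$tr_start, end = cs$tr_end,
             strand = cs$tr_strand),
      tibble(cassette = i, part = paste0("VR", seq_len(nrow(vrs))),
             start = vrs$vr_start, end = vrs$vr_end, strand = vrs$strand))
  })
  d <- dplyr::bind_rows(rows)
  d$y <- d$cassette + ifelse(d$strand == "+", 0.15, -0.15)
  labels <- sprintf("%s: group %d%s", cassettes$anchor, cassettes$group,
                    cassettes$subgroup)
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$y, yend = .data$y,
                                       colour = sub("[0-9]+$", "", .data$part)),
                          linewidth = 4) +
    ggplot2::geom_text(ggplot2::aes(x = (.data$start + .data$end) / 2,
                                    y = .data$y + 0.22, label = .data$part),
                       size = 2.8) +
    ggplot2::scale_y_continuous(breaks = seq_len(nrow(cassettes)),
                                labels = labels) +
    ggplot2::labs(x = "parent coordinate (bp)", y = NULL, colour = "component") +
    ggplot2::theme_minimal()
}
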