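#' Plot rare/common variant shares per region
#'
#' Stacked-bar view of the per-region rare and common variant shares in each
#' group (unknown-rarity variants excluded from the shares).
#'
#' @param spectrum Output of [rarity_spectrum()].
#' @return A ggplot object.
#' @export
plot_rarity_spectrum <- function(spectrum) {
  d <- tidyr::pivot_longer(
    spectrum[, c("region", "group", "share_rare", "share_common")],
    cols = c("share_rare", "share_common"),
    names_to = "class", values_to = "share"
  )
  d$class <- ifelse(d$class == "share_rare", "rare (<=0.5%)", "common (>0.5%)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$share,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~region, nrow = 1) +
    ggplot2::scale_fill_manual(values = c("rare (<=0.5%)" = "#d95f02",
                                          "common (>0.5%)" = "#7570b3")) +
    ggplot2::labs(x = NULL, y = "share of classified variants", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-subject variant load distributions
#'
#' @param loads Per-subject load tibble from [compute_loads()] or
#'   `compare_loads()$loads`.
#' @return A ggplot object.
#' @export
plot_variant_loads <- function(loads) {
  d <- tidyr::pivot_longer(
    loads[, c("subject_id", "group", "total_load", "threshold_load")],
    cols = c("total_load", "threshold_load"),
    names_to = "load", values_to = "value"
  )
  d$load <- ifelse(d$load == "total_load", "total", "score > 0.5")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~load, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "pathogenicity variant load") +
    ggplot2::theme_minimal()
}
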