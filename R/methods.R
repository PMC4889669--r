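# broom-style and ggplot2 methods for scan results.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline
#'   geom_errorbar geom_tile facet_wrap labs theme_minimal scale_shape_manual
#'   position_dodge geom_text scale_fill_gradient
#' @export
ggplot2::autoplot

#' Summarise a single-locus scan
#'
#' @param x A `dmi_scan_single` tibble from [scan_single_locus()].
#' @param ... Unused.
#' @return A one-row tibble: `n_markers`, `n_rows`, `bonferroni_alpha`,
#'   `n_significant`, `min_p`.
#' @exportS3Method generics::glance
glance.dmi_scan_single <- function(x, ...) {
  tibble(
    n_markers = dplyr::n_distinct(x$marker_id),
    n_rows = nrow(x),
    bonferroni_alpha = x$bonferroni_alpha[1],
    n_significant = sum(x$significant, na.rm = TRUE),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE))
  )
}

#' Summarise an interaction scan
#'
#' @param x A `dmi_scan_interaction` tibble from [scan_interactions()].
#' @param ... Unused.
#' @return A one-row tibble: `n_tests`, `n_rows`, `alpha_bonf`,
#'   `n_significant_bonf`, `n_significant_p001`, `max_chi2`.
#' @exportS3Method generics::glance
glance.dmi_scan_interaction <- function(x, ...) {
  tibble(
    n_tests = x$n_tests[1],
    n_rows = nrow(x),
    alpha_bonf = x$alpha_bonf[1],
    n_significant_bonf = sum(x$significant_bonf, na.rm = TRUE),
    n_significant_p001 = sum(x$significant_p001, na.rm = TRUE),
    max_chi2 = suppressWarnings(max(x$chi2, na.rm = TRUE))
  )
}

#' Plot relative viabilities along the genome
#'
#' One point per marker and homozygote class: the relative viability of
#' the P1/P1 (triangles) and P2/P2 (squares) classes against the
#' heterozygote reference, with delta-method error bars, the Mendelian
#' expectation of 1 as a horizontal line, and an asterisk over markers
#' whose genotype ratios deviate significantly at the Bonferroni-corrected
#' threshold. Facets by stratum when the scan was stratified.
#'
#' @param object A `dmi_scan_single` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dmi_scan_single <- function(object, ...) {
  strat_cols <- intersect(META_COLS, names(object))
  d <- as_tibble(object)
  d$marker_id <- factor(d$marker_id, levels = unique(d$marker_id))
  long <- tidyr::pivot_longer(
    d,
    cols = c("w_p1", "w_p2"), names_to = "class", values_to = "w"
  )
  long$se <- ifelse(long$class == "w_p1", long$se_p1, long$se_p2)
  long$class <- ifelse(long$class == "w_p1", "P1/P1", "P2/P2")
  p <- ggplot(long, aes(x = .data$marker_id, y = .data$w,
                        shape = .data$class, colour = .data$class)) +
    geom_hline(yintercept = 1, colour = "red", linewidth = 0.3) +
    geom_errorbar(
      aes(ymin = pmax(.data$w - .data$se, 0), ymax = .data$w + .data$se),
      width = 0.2, na.rm = TRUE, position = position_dodge(width = 0.4)
    ) +
    geom_point(na.rm = TRUE, position = position_dodge(width = 0.4)) +
    geom_text(
      data = dplyr::filter(d, !is.na(.data$significant) & .data$significant),
      aes(x = .data$marker_id, y = Inf, label = "*"),
      inherit.aes = FALSE, vjust = 1.2, size = 5
    ) +
    scale_shape_manual(values = c("P1/P1" = 17, "P2/P2" = 15)) +
    labs(x = "marker", y = "relative viability vs heterozygote",
         shape = "homozygote class", colour = "homozygote class") +
    theme_minimal()
  if (length(strat_cols) > 0) {
    p <- p + facet_wrap(strat_cols)
  }
  p
}

#' Plot an interaction scan as a chi-squared heat map
#'
#' Order-2 scans are drawn as a marker-by-marker tile map of the
#' nonindependence chi-squared; order-3 scans as a ranked dot plot of the
#' largest statistics (a 3-way scan has no natural two-axis layout).
#'
#' @param object A `dmi_scan_interaction` tibble.
#' @param top For order-3 scans, how many top tuples to show; default 30.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dmi_scan_interaction <- function(object, top = 30, ...) {
  d <- as_tibble(object)
  if (!"locus3" %in% names(d)) {
    p <- ggplot(d, aes(x = .data$locus1, y = .data$locus2,
                       fill = .data$chi2)) +
      geom_tile() +
      scale_fill_gradient(low = "grey95", high = "firebrick",
                          na.value = "white") +
      labs(x = NULL, y = NULL, fill = "chi-squared") +
      theme_minimal()
  } else {
    d <- utils::head(arrange(d, dplyr::desc(.data$chi2)), top)
    d$tuple <- paste(d$locus1, d$locus2, d$locus3, sep = ":")
    d$tuple <- factor(d$tuple, levels = rev(d$tuple))
    p <- ggplot(d, aes(x = .data$chi2, y = .data$tuple)) +
      geom_point() +
      labs(x = "chi-squared", y = NULL) +
      theme_minimal()
  }
  p
}
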