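#' Plot genotype segments of a population
#'
#' One horizontal track per line per chromosome, coloured by genotype state —
#' the standard introgression-map view of a backcross population.
#'
#' @param segments Segment tibble (`line_id`, `chrom`, `start_bp`, `end_bp`,
#'   `state`).
#' @param states States to colour (default all three).
#' @return A ggplot object.
#' @export
plot_genotypes <- function(segments, states = c("M82", "HET", "PEN")) {
  d <- dplyr::filter(segments, .data$state %in% states)
  d$line_id <- factor(d$line_id, levels = rev(sort(unique(d$line_id))))
  ggplot2::ggplot(d) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6,
      ymin = as.integer(.data$line_id) - 0.4,
      ymax = as.integer(.data$line_id) + 0.4,
      fill = .data$state
    )) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(M82 = "grey85", HET = "black",
                                          PEN = "forestgreen")) +
    ggplot2::scale_y_continuous(
      breaks = seq_along(levels(d$line_id)), labels = levels(d$line_id)
    ) +
    ggplot2::labs(x = "position (Mb)", y = NULL, fill = "genotype") +
    ggplot2::theme_minimal(base_size = 9)
}

#' @rdname tidy.sparsenet_qtl
#' @param bins Optional bin tibble; when given, bins are placed at their
#'   genomic midpoints and panels follow chromosomes.
#' @export
autoplot.marginal_scan <- function(object, bins = NULL, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$testable, , drop = FALSE]
  if (!is.null(bins)) {
    idx <- match(d$bin, bins$bin_id)
    d$x <- (bins$start_bp[idx] + bins$end_bp[idx]) / 2e6
    d$chrom <- bins$chrom[idx]
  } else {
    d$x <- seq_len(nrow(d))
    d$chrom <- "bins"
  }
  thr <- attr(object, "q_threshold") %||% 0.001
  ggplot2::ggplot(d, ggplot2::aes(.data$x, -log10(.data$q))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = 2) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = if (is.null(bins)) "bin index" else "position (Mb)",
                  y = expression(-log[10](q)), colour = "significant") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Tidy and summary methods for QTL mapping results
#'
#' `tidy()` returns one row per selected effect (with interval sizes for the
#' bins involved); `glance()` returns the one-row model summary with the
#' tuning values and model-space dimensions. `autoplot()` draws the selected
#' effects (for `sparsenet_qtl`) or the scan profile (for `marginal_scan`).
#'
#' @param x,object A `sparsenet_qtl` or `marginal_scan` object.
#' @param ... Unused.
#' @return A tibble (`tidy`, `glance`) or ggplot (`autoplot`).
#' @export
tidy.sparsenet_qtl <- function(x, ...) {
  eff <- x$effects
  iv <- stats::setNames(x$intervals$interval_size, x$intervals$selected_bin)
  eff$interval_size_a <- unname(iv[eff$bin_a])
  eff$interval_size_b <- unname(iv[eff$bin_b])
  dplyr::arrange(eff, dplyr::desc(abs(.data$coefficient)))
}

#' @rdname tidy.sparsenet_qtl
#' @export
glance.sparsenet_qtl <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_lines = x$n_lines,
    n_effects = nrow(x$effects),
    n_additive = sum(x$effects$type == "additive"),
    n_epistatic = sum(x$effects$type == "epistatic"),
    alpha = x$tuning$alpha,
    gamma = x$tuning$gamma
  )
}

#' @rdname tidy.sparsenet_qtl
#' @export
tidy.marginal_scan <- function(x, ...) {
  dplyr::arrange(tibble::as_tibble(x), .data$q)
}

#' @rdname tidy.sparsenet_qtl
#' @export
glance.marginal_scan <- function(x, ...) {
  tibble::tibble(
    n_bins = nrow(x),
    n_testable = sum(x$testable),
    n_significant = sum(x$significant, na.rm = TRUE),
    q_threshold = attr(x, "q_threshold") %||% 0.001
  )
}

#' @rdname tidy.sparsenet_qtl
#' @export
autoplot.sparsenet_qtl <- function(object, ...) {
  d <- tidy(object)
  d$effect <- factor(d$effect, levels = d$effect[order(abs(d$coefficient))])
  ggplot2::ggplot(d, ggplot2::aes(.data$coefficient, .data$effect,
                                  colour = .data$type)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$coefficient,
                                       yend = .data$effect)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "coefficient", y = NULL, colour = "effect type") +
    ggplot2::theme_minimal(base_size = 9)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL
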