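#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for ABC model-choice results
#'
#' `tidy()` returns the per-scenario probability table; `glance()` a
#' one-row summary with the best-supported scenario.
#'
#' @param x an `abc_result` from [abc_direct()] or [abc_logistic()]
#' @param ... unused
#' @return a tibble
#' @export
tidy.abc_result <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(method = attr(x, "method"), .before = 1)
}

#' @rdname tidy.abc_result
#' @export
glance.abc_result <- function(x, ...) {
  best <- which.max(x$probability)
  tibble::tibble(
    method = attr(x, "method"),
    n_retained = attr(x, "n_closest") %||% attr(x, "n_retained"),
    n_scenarios = nrow(x),
    best_scenario = x$scenario[best],
    best_probability = x$probability[best]
  )
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("<abc_result> %s estimation (%d retained simulations)\n",
              attr(x, "method"),
              attr(x, "n_closest") %||% attr(x, "n_retained")))
  NextMethod()
}

#' Tidiers for saturation curves
#'
#' `tidy()` returns the curve (`L`, `group`, `mean`, `sd`); `glance()` one
#' row per group with its convergence point.
#'
#' @param x a `saturation_curve` from [het_saturation()] or
#'   [topology_saturation()]
#' @param ... unused
#' @return a tibble
#' @export
tidy.saturation_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.saturation_curve
#' @export
glance.saturation_curve <- function(x, ...) {
  conv <- attr(x, "convergence")
  tibble::tibble(
    level = attr(x, "level"),
    reps = attr(x, "reps"),
    group = if (is.null(conv)) unique(x$group) else names(conv),
    convergence_L = if (is.null(conv)) NA_real_ else unname(conv)
  )
}

#' Plot a saturation curve
#'
#' Mean statistic per subsample size with a +/- SD ribbon, one panel colour
#' per group (region, individual or topology).
#'
#' @param object a `saturation_curve`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.saturation_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$L, y = .data$mean,
                               colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "number of subsampled loci", y = "statistic",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ABC model-choice result
#'
#' @param object an `abc_result`
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.abc_result <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$scenario, y = .data$probability)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.2) +
    ggplot2::labs(x = NULL, y = "posterior probability",
                  title = paste(attr(object, "method"), "estimation")) +
    ggplot2::theme_minimal()
}

#' Plot a haplotype network
#'
#' Fruchterman-Reingold layout; node area is proportional to haplotype
#' frequency, edge labels give the mutational steps for multi-step links.
#'
#' @param object a `haplotype_network`
#' @param seed layout seed
#' @param ... unused
#' @return a ggplot object
#' @export
autoplot.haplotype_network <- function(object, seed = 1, ...) {
  g <- network_igraph(object)
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  nodes <- tibble::as_tibble(object$nodes)
  nodes$x <- xy[, 1]
  nodes$y <- xy[, 2]
  edges <- tibble::as_tibble(object$edges)
  edges$x <- nodes$x[match(edges$from, nodes$haplotype)]
  edges$y <- nodes$y[match(edges$from, nodes$haplotype)]
  edges$xend <- nodes$x[match(edges$to, nodes$haplotype)]
  edges$yend <- nodes$y[match(edges$to, nodes$haplotype)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$over_limit)
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$n),
      shape = 21, fill = "steelblue"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$haplotype),
      vjust = -1.2, size = 3
    ) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::guides(linetype = "none") +
    ggplot2::theme_void()
  multi <- edges[edges$steps > 1, ]
  if (nrow(multi)) {
    p <- p + ggplot2::geom_text(
      data = multi,
      ggplot2::aes(x = (.data$x + .data$xend) / 2,
                   y = (.data$y + .data$yend) / 2,
                   label = .data$steps),
      size = 3, colour = "grey30"
    )
  }
  p
}

#' Combined diversity report for both markers
#'
#' Region-level heterozygosity from the RAD catalog together with haplotype
#' and nucleotide diversity from the mitochondrial alignment.
#'
#' @param catalog a [locus_catalog()] (or `NULL`)
#' @param alignment alignment tibble (or `NULL`)
#' @param popmap_rad,popmap_mito population maps for the two markers
#' @return tibble keyed by `region`
#' @export
diversity_report <- function(catalog = NULL, alignment = NULL,
                             popmap_rad = NULL, popmap_mito = NULL) {
  out <- NULL
  if (!is.null(catalog)) {
    out <- region_heterozygosity(catalog, popmap_rad)
  }
  if (!is.null(alignment)) {
    tab <- collapse_haplotypes(alignment, popmap_mito)
    hd <- haplotype_diversity(tab)
    nd <- nucleotide_diversity(alignment, popmap_mito)
    mito <- dplyr::full_join(hd, nd[, c("region", "pi")], by = "region")
    out <- if (is.null(out)) mito else {
      dplyr::full_join(out, mito, by = "region")
    }
  }
  out
}
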