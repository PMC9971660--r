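# broom-style accessors and standard plots for report objects and stores.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_rect geom_point
#'   labs scale_x_log10 scale_y_log10
#' @export
ggplot2::autoplot

#' @exportS3Method generics::tidy
tidy.taxatlas_report_xPerRank <- function(x, ...) x$payload

#' @exportS3Method generics::tidy
tidy.taxatlas_report_arc <- function(x, ...) {
  tibble(x_count = x$payload$x_count, y_count = x$payload$y_count,
         ratio = x$payload$ratio)
}

#' @exportS3Method generics::tidy
tidy.taxatlas_report_histogram <- function(x, ...) x$payload$bins

#' @exportS3Method generics::tidy
tidy.taxatlas_report_scatter <- function(x, ...) {
  if (x$payload$mode == "points") x$payload$points else x$payload$cells
}

#' @exportS3Method generics::tidy
tidy.taxatlas_report_tree <- function(x, ...) x$payload$nodes

#' @exportS3Method generics::glance
glance.taxatlas_report <- function(x, ...) {
  tibble(report_type = x$report_type,
         queries = paste(x$queries, collapse = " | "))
}

#' One-row overview of a store
#'
#' @param x a [taxatlas_store()]; @param ... ignored.
#' @return tibble with taxon, assembly, attribute, raw-value and estimate
#'   counts.
#' @exportS3Method generics::glance
glance.taxatlas_store <- function(x, ...) {
  raw_n <- sum(vapply(ls(x$raws), function(k) nrow(x$raws[[k]]), 0L))
  est_n <- sum(vapply(ls(x$slots), function(k)
    sum(x$slots[[k]]$provenance != "direct"), 0L))
  dir_n <- sum(vapply(ls(x$slots), function(k)
    sum(x$slots[[k]]$provenance == "direct"), 0L))
  tibble(n_taxa = n_taxa(x), n_assemblies = nrow(x$assemblies),
         n_attributes = length(x$attr_defs), n_raw_values = raw_n,
         n_direct_summaries = dir_n, n_estimates = est_n)
}

#' @exportS3Method ggplot2::autoplot
autoplot.taxatlas_report_xPerRank <- function(object, ...) {
  d <- tidy(object)
  d$rank <- factor(d$rank, levels = d$rank)
  ggplot(d, aes(x = .data$rank, y = .data$count)) +
    geom_col() +
    labs(x = NULL, y = "matching documents")
}

#' @exportS3Method ggplot2::autoplot
autoplot.taxatlas_report_histogram <- function(object, ...) {
  d <- tidy(object)
  if ("category" %in% names(d)) {
    ggplot(d, aes(xmin = .data$bin_lo, xmax = .data$bin_hi, ymin = 0,
                  ymax = .data$count, fill = .data$category)) +
      geom_rect(alpha = 0.7) +
      labs(x = "value", y = "count")
  } else {
    ggplot(d, aes(xmin = .data$bin_lo, xmax = .data$bin_hi, ymin = 0,
                  ymax = .data$count)) +
      geom_rect() +
      labs(x = "value", y = "count")
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.taxatlas_report_scatter <- function(object, ...) {
  d <- tidy(object)
  if (object$payload$mode == "points") {
    mapping <- if ("category" %in% names(d)) {
      aes(x = .data$x, y = .data$y, colour = .data$category)
    } else aes(x = .data$x, y = .data$y)
    ggplot(d, mapping) + geom_point(alpha = 0.6) +
      labs(x = "x", y = "y")
  } else {
    ggplot(d, aes(xmin = .data$x_lo, xmax = .data$x_hi, ymin = .data$y_lo,
                  ymax = .data$y_hi, fill = .data$count)) +
      geom_rect() +
      labs(x = "x", y = "y", fill = "count")
  }
}
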