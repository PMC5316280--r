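#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a metrics report
#'
#' One row per scalar metric (`metric`, `value`), with fidelity fields
#' prefixed `fid_`.
#'
#' @param x a `cp_report`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.cp_report <- function(x, ...) {
  flat <- c(x[!purrr::map_lgl(x, is.list)],
            purrr::set_names(x$fidelity, paste0("fid_", names(x$fidelity))))
  flat <- flat[names(flat) != "name"]
  tibble(metric = names(flat),
         value = as.numeric(purrr::map_dbl(flat, function(v)
           if (is.null(v) || length(v) != 1L) NA_real_ else as.numeric(v))))
}

#' One-row summary of a metrics report
#' @inheritParams tidy.cp_report
#' @return a one-row tibble of the headline metrics.
#' @export
glance.cp_report <- function(x, ...) {
  tibble(name = x$name, n_contigs = x$n_contigs, n50_nt = x$n50_nt,
         l50_count = x$l50_count, sum_nt = x$sum_nt,
         median_len_nt = x$median_len_nt, pct_included = x$pct_included,
         pct_multi_orf = x$pct_multi_orf, pct_chimeric = x$pct_chimeric,
         pct_reads_mapped = x$pct_reads_mapped %||% NA_real_)
}

#' @export
print.cp_report <- function(x, ...) {
  cat("<cp_report> ", x$name, "\n", sep = "")
  cat(sprintf("  %d contigs | N50 %d nt | L50 %d | total %.0f nt | median %.0f nt\n",
              x$n_contigs, x$n50_nt, x$l50_count, x$sum_nt, x$median_len_nt))
  cat(sprintf("  included %.2f%% | multi-ORF %.2f%% | chimeric %.2f%%\n",
              x$pct_included, x$pct_multi_orf, x$pct_chimeric))
  if (!is.null(x$pct_reads_mapped) && !is.na(x$pct_reads_mapped)) {
    cat(sprintf("  reads mapped %.2f%%", x$pct_reads_mapped))
    if (!is.na(x$pct_properly_paired %||% NA)) {
      cat(sprintf(" | properly paired %.2f%%", x$pct_properly_paired))
    }
    cat("\n")
  }
  invisible(x)
}

#' Bar-chart overview of a metrics report
#'
#' @param object a `cp_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.cp_report <- function(object, ...) {
  df <- tidy(object)
  df <- df[grepl("^pct_|^fid_pct_", df$metric) & !is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$metric,
                                                      .data$value),
                                   y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "percent",
                  title = object$name %||% "assembly") +
    ggplot2::theme_minimal()
}

#' Contig length distributions for one or more sets
#'
#' @param ... named contig-set tibbles.
#' @return a ggplot of log-scaled length distributions.
#' @export
plot_length_distribution <- function(...) {
  sets <- list(...)
  if (is.null(names(sets))) names(sets) <- paste0("set_", seq_along(sets))
  df <- bind_rows(purrr::imap(sets, function(cs, nm)
    tibble(set = nm, len = nchar(cs$seq))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$len, colour = .data$set)) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "contig length (nt)", y = "density") +
    ggplot2::theme_minimal()
}
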