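#' Tidy a conflict analysis into per-group rows
#'
#' @param x A `conflict_analysis` from [run_conflict_analysis()].
#' @param ... Unused.
#' @return Tibble with one row per classification-status group: `group`, `n`,
#'   `n_divergent`, `pct_divergent`.
#' @export
tidy.conflict_analysis <- function(x, ...) {
  tab <- x$table
  tibble(
    group = c("conflicting", "non_conflicting"),
    n = c(tab[["a"]] + tab[["b"]], tab[["c"]] + tab[["d"]]),
    n_divergent = c(tab[["a"]], tab[["c"]]),
    pct_divergent = c(x$pct_divergent_conflicting, x$pct_divergent_non_conflicting)
  )
}

#' One-row summary of a conflict analysis
#'
#' @inheritParams tidy.conflict_analysis
#' @return One-row tibble: input size, conflicting count and percentage, the
#'   table cells and the Fisher p-value.
#' @export
glance.conflict_analysis <- function(x, ...) {
  tab <- x$table
  tibble(
    n_input = x$n_input, n_conflicting = x$n_conflicting,
    n_determinate = x$n_determinate, pct_conflicting = x$pct_conflicting,
    a = tab[["a"]], b = tab[["b"]], c = tab[["c"]], d = tab[["d"]],
    p_value = x$p_value
  )
}

#' Tidy a 2x2 contingency table
#'
#' @param x A `contingency_2x2` from [build_contingency()].
#' @param ... Unused.
#' @return Tibble in long form: `classification`, `effect`, `count`.
#' @export
tidy.contingency_2x2 <- function(x, ...) {
  tibble(
    classification = rep(c("conflicting", "non_conflicting"), each = 2),
    effect = rep(c("divergent", "non_divergent"), 2),
    count = as.integer(unclass(x))
  )
}

#' Tidy an import report
#'
#' @param x An `import_report` from [import_update_file()].
#' @param ... Unused.
#' @return The per-entry message tibble with the report mode attached.
#' @export
tidy.import_report <- function(x, ...) {
  mutate(x$messages, mode = x$mode, fatal = x$fatal)
}

#' @rdname tidy.import_report
#' @export
glance.import_report <- function(x, ...) {
  tibble(mode = x$mode, accepted = x$accepted, rejected = x$rejected,
         fatal = x$fatal, n_messages = nrow(x$messages))
}

#' Plot the divergent-effect percentages of a conflict analysis
#'
#' Bar chart of the divergent-effect percentage within the conflicting and
#' non-conflicting classification groups, annotated with the Fisher p-value.
#'
#' @param object A `conflict_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conflict_analysis <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$pct_divergent)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%% (%d/%d)",
                                                    .data$pct_divergent,
                                                    .data$n_divergent, .data$n)),
                       vjust = -0.4, size = 3.2) +
    ggplot2::scale_y_continuous(limits = c(0, 105)) +
    ggplot2::labs(
      x = "classification status", y = "divergent-effect variants (%)",
      title = "Divergent effect across two reading frames",
      subtitle = sprintf("Fisher's exact test (two-sided): p = %.2g", object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a transcript model's exon/CDS structure
#'
#' @param object A [transcript_model()].
#' @param ... Unused.
#' @return A ggplot object: exons as boxes, the CDS highlighted, introns as a
#'   line.
#' @export
autoplot.transcript_model <- function(object, ...) {
  ex <- as_tibble(object$exons, .name_repair = ~c("start", "end"))
  cds <- tibble(
    start = pmax(ex$start, object$cds_start),
    end = pmin(ex$end, object$cds_end)
  )
  cds <- cds[cds$start <= cds$end, ]
  span <- locus_span(object)
  ggplot2::ggplot() +
    ggplot2::annotate("segment", x = span[1], xend = span[2], y = 0, yend = 0,
                      colour = "grey50") +
    ggplot2::geom_rect(data = ex,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -0.2, ymax = 0.2),
                       fill = "grey80", colour = "grey30") +
    ggplot2::geom_rect(data = cds,
                       ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = -0.35, ymax = 0.35),
                       fill = "steelblue", alpha = 0.7) +
    ggplot2::labs(
      title = sprintf("%s (%s, strand %s)", object$accession,
                      object$gene_symbol, object$strand),
      x = "genomic position", y = NULL
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
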