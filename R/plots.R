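#' Exon-level profile of one gene
#'
#' Plots treatment and control mean normalized counts along a gene's exon
#' bins in transcriptional order, marking significantly elevated bins and,
#' when a call is supplied, the candidate cryptic TSS.
#'
#' @param exon_tests Exon-level results tibble from [exon_test()].
#' @param gene Gene id to plot.
#' @param call Optional `cryptic_calls` object (or calls tibble) whose
#'   entry for `gene` adds the cryptic-TSS marker.
#' @param sig_alpha Threshold used to highlight elevated bins.
#' @return A ggplot object.
#' @export
plot_gene_profile <- function(exon_tests, gene, call = NULL,
                              sig_alpha = 0.05) {
  df <- exon_tests[exon_tests$gene_id == gene, , drop = FALSE]
  if (nrow(df) == 0L) abort(paste0("no exon results for gene ", gene))
  long <- df |>
    dplyr::mutate(sig_up = .data$p < sig_alpha & .data$direction == "up") |>
    tidyr::pivot_longer(c("mean_control", "mean_treatment"),
                        names_to = "group", values_to = "mean") |>
    dplyr::mutate(group = sub("mean_", "", .data$group))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$bin_index, .data$mean,
                                          colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$sig_up), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "elevated") +
    ggplot2::scale_x_continuous(breaks = unique(long$bin_index)) +
    ggplot2::labs(x = "exon bin (5' to 3')", y = "mean normalized count",
                  colour = NULL, title = gene) +
    ggplot2::theme_minimal()
  if (!is.null(call)) {
    if (inherits(call, "cryptic_calls")) call <- call$calls
    row <- call[call$gene_id == gene, , drop = FALSE]
    if (nrow(row) == 1L && !is.na(row$ctss_index)) {
      p <- p + ggplot2::geom_vline(xintercept = row$ctss_index,
                                   linetype = "dashed") +
        ggplot2::labs(subtitle = paste0(row$decision, " (", row$reason,
                                        "), candidate TSS at bin ",
                                        row$ctss_index))
    }
  }
  p
}

#' @describeIn call_all Bar chart of call decisions by reason.
#' @param object A `cryptic_calls` object.
#' @param ... Unused.
#' @export
autoplot.cryptic_calls <- function(object, ...) {
  df <- dplyr::filter(object$summary, .data$n > 0)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$reason, -.data$n), y = .data$n,
    fill = .data$reason == "PASS"
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Cryptic-transcription call outcomes") +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_vs_truth Class-by-reason confusion plot.
#' @param object A `cryptic_eval` object.
#' @param ... Unused.
#' @export
autoplot.cryptic_eval <- function(object, ...) {
  ggplot2::ggplot(object$confusion, ggplot2::aes(
    .data$reason, .data$class, fill = .data$n
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::labs(x = "call reason", y = "true class",
                  title = "Caller outcome by simulated gene class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
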