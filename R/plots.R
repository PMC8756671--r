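#' Per-gene relative TE bars with group-average lines
#'
#' The canonical display of differential regulation: one bar per gene and
#' treatment, genes coloured by tolerance call, with horizontal lines at the
#' glucose-tolerant (red) and non-tolerant (black) group averages in each
#' treatment panel.
#'
#' @param rel Tibble from [relative_te()].
#' @param calls Tolerance calls (`gene_id`, `call`).
#' @param drop_ck Drop the control treatment panel (identically zero);
#'   default TRUE.
#' @return A ggplot object.
#' @export
plot_relative_te <- function(rel, calls, drop_ck = TRUE) {
  key <- if ("treatment" %in% names(rel)) "treatment" else "sample"
  groups <- group_summary(rel, calls)
  df <- rel |>
    inner_join(calls |> filter(.data$call != "indeterminate") |>
                 select("gene_id", "call"), by = "gene_id")
  if (drop_ck) {
    nonzero <- df |> group_by(.data[[key]]) |>
      summarise(allzero = all(.data$rel_te == 0), .groups = "drop")
    keep <- nonzero[[key]][!nonzero$allzero]
    df <- df |> filter(.data[[key]] %in% keep)
    groups <- groups |> filter(.data[[key]] %in% keep)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene_id, y = .data$rel_te,
                                   fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      data = groups |> filter(!is.na(.data$mean)),
      ggplot2::aes(yintercept = .data$mean, colour = .data$group)) +
    ggplot2::scale_colour_manual(
      values = c(glucose_tolerant = "red", non_tolerant = "black")) +
    ggplot2::scale_fill_manual(
      values = c(glucose_tolerant = "#d95f02", non_tolerant = "#7570b3")) +
    ggplot2::facet_wrap(key) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "gene", y = "relative TE",
                  colour = "group mean", fill = "call")
}

#' Plot group-average (relative) TE per treatment
#'
#' Group means with SD error bars per treatment, glucose-tolerant in red and
#' non-tolerant in black.
#'
#' @param object A `bglccr_groups` tibble from [group_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bglccr_groups
#' @export
autoplot.bglccr_groups <- function(object, ...) {
  key <- if ("treatment" %in% names(object)) "treatment" else "sample"
  ggplot2::ggplot(
    object |> filter(!is.na(.data$mean)),
    ggplot2::aes(x = .data[[key]], y = .data$mean, colour = .data$group)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(glucose_tolerant = "red", non_tolerant = "black")) +
    ggplot2::theme_bw() +
    ggplot2::labs(y = attr(object, "value_col") %||% "mean", colour = "group")
}
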