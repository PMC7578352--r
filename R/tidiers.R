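## broom-style tidiers and ggplot2 methods for the result objects.

#' Tidy a difference map
#'
#' @param x A `contact_diff` object.
#' @param ... Unused.
#' @return A plain tibble of the per-pair rows, with `res1`/`res2`
#'   identifier columns prepended.
#' @method tidy contact_diff
#' @export
tidy.contact_diff <- function(x, ...) {
  out <- as_tibble(x)
  tibble(
    res1 = res_id(out$chain1, out$resseq1, out$icode1),
    res2 = res_id(out$chain2, out$resseq2, out$icode2)
  ) |>
    dplyr::bind_cols(out)
}

#' One-row summary of a difference map
#'
#' @param x A `contact_diff` object.
#' @param ... Unused.
#' @return One-row tibble: ensemble sizes, threshold, pair counts and net
#'   contact changes.
#' @method glance contact_diff
#' @export
glance.contact_diff <- function(x, ...) {
  tibble(
    n_wt = attr(x, "n_wt") %||% NA_integer_,
    n_mut = attr(x, "n_mut") %||% NA_integer_,
    threshold = attr(x, "threshold"),
    n_pairs = nrow(x),
    n_annotated = sum(x$annotated),
    net_all = suppressWarnings(net_contact_change(x, "all")),
    net_annotated = suppressWarnings(net_contact_change(x, "annotated"))
  )
}

#' Tidy an ensemble contact-frequency map
#'
#' @param x A `contact_freq` object.
#' @param ... Unused.
#' @return Plain tibble with `res1`/`res2` identifiers prepended.
#' @method tidy contact_freq
#' @export
tidy.contact_freq <- function(x, ...) {
  out <- as_tibble(x)
  tibble(
    res1 = res_id(out$chain1, out$resseq1, out$icode1),
    res2 = res_id(out$chain2, out$resseq2, out$icode2)
  ) |>
    dplyr::bind_cols(out)
}

#' Plot a difference map
#'
#' Residue-pair scatter in sequence space, colored red (contact lost upon
#' mutation) through white to blue (gained), annotated pairs emphasized.
#'
#' @param object A `contact_diff` object.
#' @param annotated_only Show only threshold-exceeding pairs (default
#'   `FALSE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot contact_diff
#' @export
autoplot.contact_diff <- function(object, annotated_only = FALSE, ...) {
  df <- tidy(object)
  if (annotated_only) df <- df[df$annotated, , drop = FALSE]
  df$pos1 <- paste0(df$chain1, sprintf("%04d", df$resseq1), df$icode1)
  df$pos2 <- paste0(df$chain2, sprintf("%04d", df$resseq2), df$icode2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos1, y = .data$pos2)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$delta,
                                     size = abs(.data$delta))) +
    ggplot2::scale_color_gradient2(low = "blue", mid = "white",
                                   high = "red", limits = c(-1, 1),
                                   name = "Δ freq\n(WT − MUT)") +
    ggplot2::scale_size_continuous(range = c(0.5, 3), guide = "none") +
    ggplot2::labs(x = "residue 1", y = "residue 2") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
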