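#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stepwise stability ranking
#'
#' Average expression stability (M) at the round each gene was eliminated,
#' ordered least to most stable, alongside the pairwise-variation series
#' V_n/V_n+1 with the cutoff line.
#'
#' @param object A [genorm()] fit.
#' @param which `"m"` (ranking, default) or `"v"` (variation series).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genorm <- function(object, which = c("m", "v"), ...) {
  which <- match.arg(which)
  if (which == "m") {
    rk <- dplyr::arrange(object$ranking, dplyr::desc(.data$rank))
    rk$gene <- factor(rk$gene, levels = rk$gene)
    ggplot2::ggplot(rk, ggplot2::aes(x = .data$gene, y = .data$m,
      group = 1)) +
      ggplot2::geom_line(colour = "grey50") +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(
        x = "least stable → most stable",
        y = "average expression stability M",
        title = "Stepwise reference-gene stability"
      ) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
        hjust = 1))
  } else {
    v <- object$v_series
    v$label <- paste0("V", v$n, "/", v$n + 1)
    v$label <- factor(v$label, levels = v$label)
    ggplot2::ggplot(v, ggplot2::aes(x = .data$label, y = .data$v)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::geom_hline(yintercept = object$cutoff, linetype = 2) +
      ggplot2::labs(
        x = NULL, y = "pairwise variation V",
        title = "Effect of adding the next reference gene"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot model-based stability values
#'
#' Per-gene stability values rho (lower = more stable), most stable first.
#'
#' @param object A [normfinder()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.normfinder <- function(object, ...) {
  st <- object$stability
  st$gene <- factor(st$gene, levels = rev(st$gene))
  ggplot2::ggplot(st, ggplot2::aes(x = .data$rho, y = .data$gene)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = "stability value ρ (lower = more stable)", y = NULL,
      title = "Model-based reference-gene stability"
    ) +
    ggplot2::theme_minimal()
}

#' Plot normalized target-gene profiles
#'
#' Mean normalized expression (over biological replicates) of each target
#' gene per condition, faceted by normalization strategy; the visual
#' counterpart of comparing reference-gene choices.
#'
#' @param validation A [run_validation()] result.
#' @param annotation Tibble with `sample`, `condition` used to group
#'   biological replicates.
#' @param subset Which subset to plot (default the first).
#' @return A ggplot object.
#' @export
plot_normalized_profiles <- function(validation, annotation,
                                     subset = NULL) {
  assert_cols(annotation, c("sample", "condition"), "annotation")
  prof <- validation$profiles
  if (is.null(subset)) subset <- prof$subset[1L]
  prof <- dplyr::filter(prof, .data$subset == !!subset) |>
    dplyr::left_join(annotation[c("sample", "condition")], by = "sample") |>
    dplyr::group_by(.data$method, .data$gene, .data$condition) |>
    dplyr::summarise(
      mean_expr = mean(.data$normalized, na.rm = TRUE),
      sd_expr = stats::sd(.data$normalized, na.rm = TRUE),
      .groups = "drop"
    )
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$condition,
    y = .data$mean_expr, fill = .data$gene)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~method, scales = "free_y", ncol = 1) +
    ggplot2::labs(
      x = NULL, y = "normalized relative expression",
      title = paste0("Target profiles (subset: ", subset, ")")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
      hjust = 1))
}
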