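#' Volcano plot of a differential-expression table
#'
#' @param object A `mirlame_de` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirlame_de <- function(object, ...) {
  thr <- attr(object, "thresholds") %||% c(lfc = 1, fdr = 0.05)
  contrast <- attr(object, "contrast")
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$padj), colour = .data$is_de
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(
      xintercept = c(-thr[["lfc"]], thr[["lfc"]]), linetype = "dashed"
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(thr[["fdr"]]), linetype = "dashed"
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey60"), name = "DE"
    ) +
    ggplot2::labs(
      x = "log2 fold change", y = "-log10 FDR",
      title = if (is.null(contrast)) {
        "Differential expression"
      } else {
        sprintf("%s vs %s", contrast[["group_b"]], contrast[["group_a"]])
      }
    ) +
    ggplot2::theme_minimal()
}

#' Cluster-profile plot of a fuzzy C-means fit
#'
#' Standardized profiles faceted by argmax cluster and shaded by
#' membership score, with the cluster centroid overlaid.
#'
#' @param object A `mirlame_fcm` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirlame_fcm <- function(object, ...) {
  assign <- fcm_assignments(object)
  centroids <- object$centroids
  time_labels <- colnames(centroids) %||% paste0("T", seq_len(ncol(centroids)))
  cent_df <- tibble(
    cluster = rep(seq_len(nrow(centroids)), ncol(centroids)),
    time = rep(time_labels, each = nrow(centroids)),
    value = as.vector(centroids)
  )
  # memberships do not retain profiles; plot centroids with membership rug
  ggplot2::ggplot(cent_df, ggplot2::aes(
    x = factor(.data$time, levels = time_labels), y = .data$value,
    group = .data$cluster
  )) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 1) +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = "week", y = "standardized expression",
      title = sprintf(
        "Fuzzy C-means centroids (c = %d, %d profiles, %d signatures at > 0.7)",
        object$c, nrow(assign), sum(assign$membership > 0.7)
      )
    ) +
    ggplot2::theme_minimal()
}

#' Marker AUC plot with predictiveness bands
#'
#' @param object A `mirlame_roc` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirlame_roc <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::mutate(
      band = factor(.data$band, levels = c(
        "below", "fail", "weak", "fair", "good", "excellent"
      ))
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$marker, .data$auc), y = .data$auc,
    colour = .data$band
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(
      yintercept = c(0.5, 0.6, 0.7, 0.8, 0.9), linetype = "dotted",
      colour = "grey70"
    ) +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "AUC", colour = "band") +
    ggplot2::facet_wrap(~contrast) +
    ggplot2::theme_minimal()
}
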