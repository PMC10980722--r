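#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an axial slice of a prediction map
#'
#' Tile plot of the prediction-outcome correlation on one axial (k) slice,
#' outlining FDR-significant voxels.
#'
#' @param object A `prediction_map`.
#' @param slice_k Axial slice index; defaults to the slice containing the
#'   peak r.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.prediction_map <- function(object, slice_k = NULL, ...) {
  df <- tibble::as_tibble(object)
  ok <- !is.na(df$r)
  if (is.null(slice_k))
    slice_k <- df$k[ok][which.max(abs(df$r[ok]))]
  df <- df[df$k == slice_k & ok, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$fdr_sig, ], fill = NA,
                       colour = "black", linewidth = 0.4) +
    ggplot2::scale_fill_gradient2(low = "steelblue", high = "firebrick",
                                  midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Prediction-outcome r, slice k = %d",
                                  slice_k),
                  subtitle = "outline: FDR-significant centres",
                  x = "i", y = "j", fill = "r") +
    ggplot2::theme_minimal()
}

#' Plot per-group trait-coupling slopes
#'
#' Scatter of extracted cluster coupling against the trait, with one
#' least-squares line per genotype group — the standard visualization of a
#' moderated (interaction) effect.
#'
#' @param estimates Per-subject mean coupling
#'   ([extract_cluster_estimates()]).
#' @param traits Trait scores.
#' @param carriers 0/1 carrier indicator.
#' @param snp Label for the legend.
#' @return A ggplot object.
#' @export
plot_interaction <- function(estimates, traits, carriers,
                             snp = "rs2254298") {
  df <- tibble::tibble(
    trait = traits, coupling = estimates,
    group = factor(ifelse(carriers == 1, "carrier", "non-carrier")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trait, y = .data$coupling,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "ASQ total", y = "coupling (a.u.)",
                  colour = paste0(snp, " group")) +
    ggplot2::theme_minimal()
}

#' Plot a design matrix
#'
#' @param X Design matrix from [build_design_matrix()] or
#'   [build_gppi_design()].
#' @return A ggplot heat map, scans on the vertical axis.
#' @export
plot_design_matrix <- function(X) {
  df <- tibble::tibble(
    scan = rep(seq_len(nrow(X)), times = ncol(X)),
    regressor = factor(rep(colnames(X), each = nrow(X)),
                       levels = colnames(X)),
    value = as.vector(X))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$regressor, y = .data$scan,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "white", high = "grey10") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
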