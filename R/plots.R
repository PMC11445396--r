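# Lightweight ggplot2 helpers (ggplot2 is suggested, not imported).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("install ggplot2 to use the plotting helpers")
}

#' Plot a per-cell value on the tissue
#'
#' @param coords cells x 2 coordinates.
#' @param value per-cell numeric or categorical vector (e.g. a diffusion
#'   component, an imputed gene, zone labels).
#' @param name legend title.
#' @return a ggplot object.
#' @export
plot_spatial <- function(coords, value, name = "value") {
  need_ggplot()
  df <- data.frame(x = coords[, 1], y = coords[, 2], value = value)
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y,
                                   colour = value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = name) +
    ggplot2::theme_minimal()
}

#' Plot the ENVI training loss trace
#'
#' @param model a trained `envi` model.
#' @param smooth window of the running mean applied for readability.
#' @return a ggplot object.
#' @export
plot_loss <- function(model, smooth = 25) {
  need_ggplot()
  loss <- model$loss
  if (smooth > 1 && length(loss) > smooth)
    loss <- stats::filter(loss, rep(1 / smooth, smooth), sides = 1)
  df <- data.frame(step = seq_along(loss), loss = as.numeric(loss))
  ggplot2::ggplot(df[!is.na(df$loss), ],
                  ggplot2::aes(x = step, y = loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "gradient step", y = "loss") +
    ggplot2::theme_minimal()
}

#' Heatmap of a (mean) COVET matrix
#'
#' @param sigma g x g matrix, e.g. a [covet_mean()] result.
#' @return a ggplot object.
#' @export
plot_covet <- function(sigma) {
  need_ggplot()
  sigma <- as.matrix(sigma)
  g <- rownames(sigma)
  if (is.null(g)) g <- paste0("g", seq_len(nrow(sigma)))
  df <- expand.grid(row = g, col = g)
  df$value <- as.numeric(sigma)
  ggplot2::ggplot(df, ggplot2::aes(x = col, y = row,
                                   fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "covariance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
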