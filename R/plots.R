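#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_path geom_line
#'   geom_col geom_abline scale_fill_viridis_c scale_fill_gradient2
#'   scale_y_reverse coord_fixed facet_wrap labs theme_minimal
NULL

raster_tbl <- function(m, value = "value") {
  out <- tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m))
  names(out)[3] <- value
  out
}

#' Plot a set of super-resolution maps
#'
#' Density and velocity magnitude on a sequential scale; the direction map on
#' a diverging red/blue scale — red toward the transducer, blue away.
#'
#' @param object an `sr_map_set`.
#' @param which maps to show.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot sr_map_set
#' @export
autoplot.sr_map_set <- function(object,
                                which = c("density", "velocity_magnitude",
                                          "direction"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  df <- dplyr::bind_rows(lapply(which, function(nm) {
    d <- raster_tbl(object[[nm]])
    d$map <- nm
    d
  }))
  if (identical(which, "direction")) {
    ggplot(df, aes(.data$col, .data$row, fill = .data$value)) +
      geom_raster() +
      scale_fill_gradient2(low = "blue", mid = "black", high = "red") +
      scale_y_reverse() + coord_fixed() +
      labs(x = "lateral (SR px)", y = "depth (SR px)",
           fill = "signed v (mm/s)") +
      theme_minimal()
  } else {
    ggplot(df, aes(.data$col, .data$row, fill = .data$value)) +
      geom_raster() +
      scale_fill_viridis_c(option = "inferno") +
      scale_y_reverse() + coord_fixed() +
      facet_wrap(~map) +
      labs(x = "lateral (SR px)", y = "depth (SR px)", fill = NULL) +
      theme_minimal()
  }
}

#' Plot the normalized pressure map with its isobars
#'
#' @param object a `pressure_map`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot pressure_map
#' @export
autoplot.pressure_map <- function(object, ...) {
  df <- raster_tbl(object$pressure, "pressure")
  g <- ggplot(df, aes(.data$col, .data$row)) +
    geom_raster(aes(fill = .data$pressure)) +
    scale_fill_viridis_c(option = "magma", limits = c(0, 1)) +
    scale_y_reverse() + coord_fixed() +
    labs(x = "lateral (SR px)", y = "depth (SR px)",
         fill = "normalized\npressure") +
    theme_minimal()
  if (nrow(object$isobars))
    g <- g + geom_path(
      data = object$isobars,
      aes(.data$x, .data$y, group = .data$contour),
      color = "white", linewidth = 0.2)
  g
}

#' Plot a ROC curve with its Youden-optimal operating point
#'
#' @param object a `roc_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  cv <- object$curve
  ggplot(cv, aes(1 - .data$specificity, .data$sensitivity)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey60") +
    geom_path() +
    ggplot2::annotate("point",
                      x = 1 - object$specificity, y = object$sensitivity,
                      color = "red", size = 2) +
    coord_fixed() +
    labs(x = "1 - specificity", y = "sensitivity",
         title = sprintf("AUC %.3f (95%% CI %.3f-%.3f)", object$auc,
                         object$auc_ci[1], object$auc_ci[2])) +
    theme_minimal()
}

#' Plot a cohort-averaged distribution histogram
#'
#' @param distribution tibble from [cohort_histograms()] (`bin_lo`,
#'   `bin_hi`, `fraction`), optionally with a `group` column for dodged
#'   NOA/OA bars.
#' @param xlab x-axis label.
#' @return a ggplot object.
#' @export
plot_cohort_histogram <- function(distribution, xlab = "value") {
  d <- distribution
  d$mid <- (d$bin_lo + d$bin_hi) / 2
  g <- ggplot(d, aes(.data$mid, .data$fraction))
  g <- if (!is.null(d$group))
    g + geom_col(aes(fill = .data$group), position = "dodge")
  else g + geom_col()
  g + labs(x = xlab, y = "mean fraction of vessels") + theme_minimal()
}
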