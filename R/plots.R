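#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_tile geom_col
#'   geom_errorbar geom_raster scale_fill_viridis_c scale_fill_gradient2
#'   labs facet_wrap theme_minimal
NULL

#' Plot a secondary-structure propensity profile
#'
#' @param object An `ss_profile` from [ss_propensity()].
#' @param classes Classes to facet (default all five).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ss_profile
#' @export
autoplot.ss_profile <- function(object, classes = SS_CLASSES, ...) {
  d <- dplyr::filter(object, .data$class %in% classes)
  ggplot(d, aes(x = .data$residue, y = .data$mean_pct)) +
    geom_col(fill = "grey35") +
    geom_errorbar(aes(ymin = .data$mean_pct - .data$se_pct,
                      ymax = .data$mean_pct + .data$se_pct), width = 0) +
    facet_wrap(~class, ncol = 1) +
    labs(x = "residue", y = "population (%)") +
    theme_minimal()
}

#' Plot a contact map
#'
#' @param object A `contact_map`.
#' @param ... Unused.
#' @return A ggplot (probability heat map).
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(.data$res_a, .data$res_b, fill = .data$prob)) +
    geom_raster() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = "residue i", y = "residue j",
         fill = sprintf("P(contact)\n%s < %.2f nm", object$mode, object$cutoff)) +
    theme_minimal()
}

#' Plot a thresholded contact difference map
#'
#' @param object A `difference_map`.
#' @param ... Unused.
#' @method autoplot difference_map
#' @export
autoplot.difference_map <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(.data$res_a, .data$res_b, fill = .data$delta)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = "residue i", y = "residue j",
         fill = sprintf("dP (|dP| > %.2f)", object$threshold)) +
    theme_minimal()
}

#' Plot a 2D potential of mean force
#'
#' @param object A `pmf_surface`.
#' @param states Optional state rectangles to outline.
#' @param ... Unused.
#' @method autoplot pmf_surface
#' @export
autoplot.pmf_surface <- function(object, states = NULL, ...) {
  d <- tidy(object)
  p <- ggplot(d, aes(.data$nbeta, .data$ncontact, fill = .data$w)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "white", direction = -1) +
    labs(x = expression(N[beta]), y = expression(N[C]),
         fill = "PMF (kcal/mol)") +
    theme_minimal()
  if (!is.null(states)) {
    rects <- dplyr::bind_rows(lapply(states, function(s) {
      tibble::tibble(xmin = s$nbeta[1], xmax = s$nbeta[2],
                     ymin = s$ncontact[1], ymax = s$ncontact[2],
                     name = s$name)
    }))
    p <- p + ggplot2::geom_rect(
      data = rects,
      aes(xmin = .data$xmin, xmax = .data$xmax,
          ymin = .data$ymin, ymax = .data$ymax),
      inherit.aes = FALSE, fill = NA, colour = "black"
    )
  }
  p
}

#' Plot a scalar time series with its moving average
#'
#' @param object A `scalar_series` (e.g. [rmsd_series()]).
#' @param ... Unused.
#' @method autoplot scalar_series
#' @export
autoplot.scalar_series <- function(object, ...) {
  ggplot(object, aes(.data$time, .data$value)) +
    geom_line(colour = "grey70") +
    geom_line(aes(y = .data$ma), colour = "black") +
    labs(x = "time (ps)", y = "value (nm)") +
    theme_minimal()
}
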