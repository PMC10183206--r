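#' Tidy a fitted selection model
#'
#' @param x A `flocknet_model`.
#' @param effects `"fixed"`, `"random"` or `"all"`.
#' @param ... Unused.
#' @return A tibble with one row per term: posterior `mode`, `mean`, 95%
#'   HPD bounds, `significant` flag (CI excludes zero), `ess` and
#'   `lag1_autocorr`.
#' @method tidy flocknet_model
#' @export
tidy.flocknet_model <- function(x, effects = c("all", "fixed", "random"), ...) {
  effects <- match.arg(effects)
  out <- x$terms
  if (effects != "all") out <- dplyr::filter(out, .data$effect == effects)
  out
}

#' @rdname tidy.flocknet_model
#' @method glance flocknet_model
#' @export
glance.flocknet_model <- function(x, ...) {
  fd <- dplyr::filter(x$diagnostics, .data$parameter %in%
                        x$terms$term[x$terms$effect == "fixed"])
  tibble::tibble(response = x$response, family = x$family, scale = x$scale,
                 n = x$n, converged = x$converged,
                 min_ess = min(fd$ess), max_lag1 = max(abs(fd$lag1_autocorr)))
}

#' Tidy repeatability estimates
#'
#' @param x A `flocknet_repeatability`.
#' @param ... Unused.
#' @method tidy flocknet_repeatability
#' @export
tidy.flocknet_repeatability <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.flocknet_repeatability
#' @method glance flocknet_repeatability
#' @export
glance.flocknet_repeatability <- function(x, ...) {
  tibble::tibble(n_measures = nrow(x),
                 mean_R = mean(x$R),
                 min_ci_low = min(x$ci_low), max_ci_high = max(x$ci_high))
}

#' Coefficient plot of a selection model
#'
#' Posterior modes and 95% credible intervals per fixed effect, colored by
#' the direction of significant effects (the layout used to report
#' selection gradients).
#'
#' @param object A `flocknet_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot flocknet_model
#' @export
autoplot.flocknet_model <- function(object, ...) {
  d <- tidy(object, effects = "fixed") |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$significant & .data$mode > 0 ~ "positive",
      .data$significant & .data$mode < 0 ~ "negative",
      TRUE ~ "none"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mode, y = .data$term,
                                  color = .data$direction)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_color_manual(values = c(positive = "#c0392b",
                                           negative = "#2c6e9e",
                                           none = "black"), guide = "none") +
    ggplot2::labs(x = "Posterior mode (95% CI)", y = NULL,
                  title = glue::glue("{object$scale} {object$response}")) +
    ggplot2::theme_minimal()
}

#' Repeatability plot
#'
#' @param object A `flocknet_repeatability`.
#' @param ... Unused.
#' @method autoplot flocknet_repeatability
#' @export
autoplot.flocknet_repeatability <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$R, y = .data$measure)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "Repeatability R (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Network plot
#'
#' SRI-weighted network with vertices colored by sex and edge width
#' proportional to SRI.
#'
#' @param object A `flocknet_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @method autoplot flocknet_network
#' @export
autoplot.flocknet_network <- function(object, seed = 1L, ...) {
  set.seed(seed)
  lay <- igraph::layout_with_fr(object)
  verts <- tibble::tibble(x = lay[, 1], y = lay[, 2],
                          sex = factor(igraph::V(object)$sex %||%
                                         rep(NA, igraph::vcount(object)),
                                       levels = c(0, 1),
                                       labels = c("female", "male")))
  el <- igraph::as_edgelist(object, names = FALSE)
  edges <- tibble::tibble(x = lay[el[, 1], 1], y = lay[el[, 1], 2],
                          xend = lay[el[, 2], 1], yend = lay[el[, 2], 2],
                          weight = igraph::E(object)$weight)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linewidth = .data$weight),
                          color = "grey70", alpha = 0.6) +
    ggplot2::geom_point(data = verts,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$sex), size = 2) +
    ggplot2::scale_linewidth(range = c(0.1, 1.5), guide = "none") +
    ggplot2::theme_void()
}
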