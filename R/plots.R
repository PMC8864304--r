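# ggplot2 displays for fitted models and estimate cubes.

#' Plot posterior coefficient intervals of a fitted CSMF model
#'
#' Dot-and-interval display of covariate coefficients (posterior mean and
#' 95% credible interval) per cause, the standard visual check on which
#' covariates the LASSO retained.
#'
#' @param object A `csmf_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csmf_fit
#' @export
autoplot.csmf_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[!grepl("^u\\[", td$term) & td$term != "(Intercept)", ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cause) +
    ggplot2::labs(x = "posterior mean (95% CrI)", y = NULL,
                  title = "Covariate coefficients under the LASSO prior")
}

#' Plot cause-specific mortality trends from an estimate cube
#'
#' Deaths (or rates/fractions) over time with 95% uncertainty ribbons, one
#' panel per cause, for a chosen aggregation level.
#'
#' @param object An `estimate_cube` (e.g. the `global` element of a
#'   pipeline run).
#' @param measure One of `"deaths"`, `"rate"`, `"fraction"`.
#' @param iso One `iso_code`/region label to display (default the first).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot estimate_cube
#' @export
autoplot.estimate_cube <- function(object, measure = c("deaths", "rate",
                                                       "fraction"),
                                   iso = NULL, ...) {
  measure <- match.arg(measure)
  s <- summarise_cube(object)
  iso <- iso %||% s$iso_code[1]
  s <- s[s$iso_code == iso, ]
  y <- s[[measure]]
  lo <- s[[paste0(measure, "_lower")]]
  hi <- s[[paste0(measure, "_upper")]]
  ggplot2::ggplot(s, ggplot2::aes(x = .data$year, y = y)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~cause, scales = "free_y") +
    ggplot2::labs(x = NULL, y = measure,
                  title = paste0(measure, " by cause, ", iso))
}
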