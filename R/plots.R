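# ggplot2 displays for the main result types.

#' Measured versus predicted co-culture concentrations
#'
#' Scatter of observed against fitted per-peak co-culture concentrations
#' for a decomposition fit, with residual outliers beyond `outlier_z`
#' standardized residuals highlighted -- the display used to spot
#' potentially regulated volatiles.
#'
#' @param object A `decomposition_fit`.
#' @param outlier_z Standardized-residual cutoff for highlighting.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decomposition_fit <- function(object, outlier_z = 2, ...) {
  stopifnot(object$status == "ok")
  dat <- mutate(object$residuals,
                outlier = abs(.data$std_residual) > outlier_z)
  ggplot2::ggplot(dat, ggplot2::aes(.data$fitted, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$outlier)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "red"),
                                 name = paste0("|z| > ", outlier_z)) +
    ggplot2::labs(
      x = "Predicted co-culture concentration (ppbV)",
      y = "Measured co-culture concentration (ppbV)",
      title = paste0("Strain ", object$strain, ", model ", object$model))
}

#' Production/consumption heat map of calls
#'
#' Tile display of production (positive) and consumption (negative) calls
#' per group and peak at one detection threshold, with strong calls marked.
#'
#' @param calls A calls tibble from [call_production()] (one threshold).
#' @return A ggplot object.
#' @export
plot_production_heatmap <- function(calls) {
  dat <- filter(calls, .data$call != "background")
  ggplot2::ggplot(dat, ggplot2::aes(.data$group, .data$peak)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$call)) +
    ggplot2::geom_point(data = filter(dat, .data$strong), size = 0.5) +
    ggplot2::scale_fill_manual(values = c(produced = "#2166ac",
                                          consumed = "#b2182b")) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1),
                   axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "Mass peak", fill = "Call",
                  caption = "dots mark strong (>2-fold) calls")
}

#' Discriminant-space scatter of a volatilome LDA
#'
#' Projects the given rows onto the first two discriminants (or the single
#' discriminant against zero) coloured by class.
#'
#' @param object A `vol_lda` model.
#' @param corrected A corrected volatilome tibble to project.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vol_lda <- function(object, corrected, ...) {
  data <- corrected[corrected$role %in%
                      c("fungal_pure", "co_culture", "bacterial_pure"), ,
                    drop = FALSE]
  data$.class <- lda_labels(data, object$factor)
  data <- data[!is.na(data$.class), , drop = FALSE]
  sc <- lda_scores(object, data)
  dat <- tibble(class = data$.class, LD1 = sc[, 1],
                LD2 = if (ncol(sc) > 1) sc[, 2] else 0)
  ggplot2::ggplot(dat, ggplot2::aes(.data$LD1, .data$LD2,
                                    colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("LD1 (%.0f%%)", 100 * object$var_share[1]),
      y = if (ncol(sc) > 1)
        sprintf("LD2 (%.0f%%)", 100 * object$var_share[2]) else "")
}

#' Effect-size bar chart of a growth ANOVA
#'
#' @param object An `anova_table` from [fit_growth_anova()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.anova_table <- function(object, ...) {
  dat <- as_tibble(object)
  dat$term <- factor(dat$term, levels = rev(dat$term))
  ggplot2::ggplot(dat, ggplot2::aes(.data$effect_pct, .data$term)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "% of total sum of squares", y = NULL)
}
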