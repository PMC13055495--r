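#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbarh
#'   geom_rect geom_vline geom_hline geom_col geom_line labs theme_minimal
#'   scale_x_log10 facet_wrap
NULL

#' Forest plot of interaction ratios against the equivalence band
#'
#' One row per classified fit: the interaction ratio (exponentiated scale) or
#' identity-scale interaction coefficient with its confidence interval,
#' coloured by category, with the null (1 or 0) marked. Exponentiated and
#' identity-scale fits are shown in separate panels since their null values
#' and units differ.
#'
#' @param object A [classify_interaction()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stressor_classification <- function(object, ...) {
  x <- as_tibble(object)
  x$label <- paste(x$response, x$date_label, sep = " / ")
  null_at <- ifelse(x$ratio_scale == "exp", 1, 0)
  ggplot(x, aes(x = .data$ratio, y = .data$label, colour = .data$category)) +
    geom_vline(aes(xintercept = null_at), linetype = 2, colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    geom_point(size = 2) +
    facet_wrap(~ratio_scale, scales = "free_x") +
    labs(x = "interaction ratio (exp scale) / coefficient (identity scale)",
         y = NULL, colour = "category") +
    theme_minimal()
}

#' Bar chart of interaction-type frequencies
#'
#' @param object An [interaction_type_counts()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interaction_type_counts <- function(object, ...) {
  x <- as_tibble(object)
  x$code <- factor(x$code, levels = c("S+", "S-", "A+", "A-", "R+/-", "R-/+"))
  ggplot(x, aes(x = .data$code, y = .data$count)) +
    geom_col(fill = "steelblue") +
    labs(x = "interaction type", y = "significant genes",
         title = sprintf("n significant = %d", attr(object, "n_significant"))) +
    theme_minimal()
}

#' Fitted seasonal smooths per treatment combination
#'
#' @param object A [fit_season_model()] object.
#' @param ... Unused.
#' @return A ggplot object showing the smooth component of the linear
#'   predictor over the season for each treatment cell.
#' @export
autoplot.season_fit <- function(object, ...) {
  x <- dplyr::distinct(object$smooth_fitted,
                       .data$site, .data$warming, .data$day, .data$smooth)
  ggplot(x, aes(x = .data$day, y = .data$smooth, colour = .data$warming)) +
    geom_line() + geom_point(size = 1) +
    facet_wrap(~site) +
    labs(x = "days since season start",
         y = "smooth contribution (link scale)",
         title = object$response) +
    theme_minimal()
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
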