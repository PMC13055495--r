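#' Construct a table of link-scale stressor coefficients
#'
#' A coefficient table holds, for each fitted 2x2 factorial model, the
#' link-scale intercept, the two main-effect coefficients (warming and
#' pollution), the interaction coefficient, and their Wald standard errors and
#' two-sided p-values. The table is the interface between model fitting (or any
#' external fitting tool) and interaction classification.
#'
#' @param response Response name(s).
#' @param date_label Per-date label (e.g. `"June"`) or `"season"` for a
#'   season-wide model.
#' @param link Link function on which additivity is defined: `"log"`,
#'   `"logit"` or `"identity"`.
#' @param alpha Link-scale intercept (may be `NA` when only effects are known;
#'   the intercept never enters classification).
#' @param beta_w,beta_p,beta_int Link-scale coefficients for the first stressor
#'   (warming), the second stressor (pollution), and their interaction.
#' @param se_w,se_p,se_int Standard errors (strictly positive).
#' @param p_w,p_p,p_int Two-sided p-values; if `NULL`, Wald p-values are
#'   computed from the estimates and standard errors.
#' @param n_obs Number of observations behind each fit (optional).
#'
#' @return A tibble with one row per model and class `stressor_coefs`.
#' @examples
#' stressor_coefs(
#'   response = "barnacle_abundance", date_label = "June", link = "log",
#'   beta_w = -0.693, beta_p = 2.087, beta_int = 0.414,
#'   se_w = 0.149, se_p = 0.120, se_int = 0.182
#' )
#' @export
stressor_coefs <- function(response, date_label = "season", link = "log",
                           alpha = NA_real_,
                           beta_w, beta_p, beta_int,
                           se_w, se_p, se_int,
                           p_w = NULL, p_p = NULL, p_int = NULL,
                           n_obs = NA_integer_) {
  check_link(link)
  out <- tibble(
    response = as.character(response),
    date_label = as.character(date_label),
    link = link,
    alpha = as.numeric(alpha),
    beta_w = as.numeric(beta_w), se_w = as.numeric(se_w),
    beta_p = as.numeric(beta_p), se_p = as.numeric(se_p),
    beta_int = as.numeric(beta_int), se_int = as.numeric(se_int),
    p_w = if (is.null(p_w)) wald_p(beta_w, se_w) else as.numeric(p_w),
    p_p = if (is.null(p_p)) wald_p(beta_p, se_p) else as.numeric(p_p),
    p_int = if (is.null(p_int)) wald_p(beta_int, se_int) else as.numeric(p_int),
    n_obs = as.integer(n_obs)
  )
  validate_stressor_coefs(out)
}

validate_stressor_coefs <- function(x) {
  needed <- c("link", "beta_w", "beta_p", "beta_int", "se_w", "se_p", "se_int")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop_input("coefficient table is missing column(s): %s",
               paste(missing, collapse = ", "))
  }
  check_link(x$link)
  ses <- c(x$se_w, x$se_p, x$se_int)
  if (any(!is.na(ses) & ses <= 0)) {
    stop_input("standard errors must be strictly positive")
  }
  ps <- c(x$p_w, x$p_p, x$p_int)
  if (any(!is.na(ps) & (ps < 0 | ps > 1))) {
    stop_input("p-values must lie in [0, 1]")
  }
  class(x) <- unique(c("stressor_coefs", class(x)))
  x
}

#' Decompose a fitted 2x2 model into its additive null and observed effect
#'
#' On the model's link scale the additive (multiplicative-after-
#' back-transformation) null expectation for the combined treatment is the sum
#' of the main effects, `delta_add = beta_w + beta_p`; the observed combined
#' effect includes the interaction, `delta_obs = delta_add + beta_int`. The
#' identity `delta_obs - delta_add = beta_int` holds exactly.
#'
#' @param coefs A coefficient table (see [stressor_coefs()]); any data frame
#'   with `beta_w`, `beta_p`, `beta_int` columns works.
#' @return A tibble with columns `delta_add`, `delta_obs`, `beta_int` (one row
#'   per input row).
#' @examples
#' decompose_null(tibble::tibble(beta_w = -0.693, beta_p = 2.087, beta_int = 0.414))
#' @export
decompose_null <- function(coefs) {
  for (col in c("beta_w", "beta_p", "beta_int")) {
    if (is.null(coefs[[col]])) stop_input("missing column `%s`", col)
  }
  tibble(
    delta_add = coefs$beta_w + coefs$beta_p,
    delta_obs = coefs$beta_w + coefs$beta_p + coefs$beta_int,
    beta_int = coefs$beta_int
  )
}

#' Interaction ratio with back-transformed Wald confidence interval
#'
#' For log and logit links, `exp(beta_int)` is an interaction ratio: the
#' multiplicative deviation of the combined effect from the additive
#' expectation (a ratio of rate ratios for log links, a ratio of odds ratios
#' for logit links). The Wald interval `beta_int +/- z * se_int` is formed on
#' the link scale and back-transformed. For identity links the coefficient and
#' its interval are returned untransformed (`scale = "identity"`).
#'
#' @param coefs A coefficient table with `link`, `beta_int`, `se_int`.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `ratio`, `ci_low`, `ci_high`, `level`,
#'   `scale`.
#' @examples
#' interaction_ratio_ci(
#'   tibble::tibble(link = "log", beta_int = 0.507, se_int = 0.299)
#' )
#' @export
interaction_ratio_ci <- function(coefs, level = 0.95) {
  z <- zcrit(level)
  check_link(coefs$link)
  if (is.null(coefs$beta_int) || is.null(coefs$se_int)) {
    stop_input("coefficient table must contain `beta_int` and `se_int`")
  }
  exp_scale <- coefs$link %in% c("log", "logit")
  lo <- coefs$beta_int - z * coefs$se_int
  hi <- coefs$beta_int + z * coefs$se_int
  tibble(
    ratio = ifelse(exp_scale, exp(coefs$beta_int), coefs$beta_int),
    ci_low = ifelse(exp_scale, exp(lo), lo),
    ci_high = ifelse(exp_scale, exp(hi), hi),
    level = level,
    scale = ifelse(exp_scale, "exp", "identity")
  )
}

#' Equivalence band around the additive null (smallest effect of interest)
#'
#' A significant interaction whose confidence interval overlaps this band is
#' flagged as a mild deviation from the null. On the exponentiated scale (log
#' and logit links) a `percent` band of 5 gives \[0.95, 1.05\] around the null
#' ratio of 1. On the identity scale the band is `+/- (percent/100) *
#' reference_quantity` around 0; the reference quantity sets what "5%" is 5%
#' of (by default the magnitude of the additive expectation of the fit being
#' classified; see [classify_interaction()]).
#'
#' @param link Link of the model the band applies to.
#' @param percent Half-width of the band in percent (> 0); default 5.
#' @param reference_quantity Positive scalar scaling an identity-link band.
#'   Required for identity links (no default at band-construction time).
#' @return An object of class `sesoi_band`: a list with `scale`, `low`,
#'   `high`, `percent`, `reference_quantity`.
#' @examples
#' sesoi_band("log")                              # [0.95, 1.05]
#' sesoi_band("identity", reference_quantity = 0.32)  # +/- 0.016
#' @export
sesoi_band <- function(link, percent = 5, reference_quantity = NULL) {
  check_link(link)
  if (!is.numeric(percent) || length(percent) != 1L || percent <= 0) {
    stop_config("`percent` must be a single positive number")
  }
  if (link %in% c("log", "logit")) {
    band <- list(scale = "exp", low = 1 - percent / 100, high = 1 + percent / 100,
                 percent = percent, reference_quantity = NA_real_)
  } else {
    if (is.null(reference_quantity)) {
      stop_config("identity-link equivalence band needs a `reference_quantity`")
    }
    if (!is.numeric(reference_quantity) || reference_quantity <= 0) {
      stop_config("`reference_quantity` must be a positive number")
    }
    half <- (percent / 100) * reference_quantity
    band <- list(scale = "identity", low = -half, high = half,
                 percent = percent, reference_quantity = reference_quantity)
  }
  structure(band, class = "sesoi_band")
}

#' @export
print.sesoi_band <- function(x, ...) {
  cat(sprintf("<sesoi_band> %s scale: [%g, %g] (+/-%g%%)\n",
              x$scale, x$low, x$high, x$percent))
  invisible(x)
}

#' Flag mild interactions: does the interaction CI overlap the band?
#'
#' @param ratio A tibble from [interaction_ratio_ci()] (columns `ci_low`,
#'   `ci_high`, `scale`).
#' @param band A [sesoi_band()] on the same scale.
#' @return Logical vector, `TRUE` where the confidence interval intersects the
#'   band.
#' @examples
#' r <- interaction_ratio_ci(tibble::tibble(link = "log", beta_int = 0.507, se_int = 0.299))
#' flag_mild(r, sesoi_band("log"))
#' @export
flag_mild <- function(ratio, band) {
  if (!inherits(band, "sesoi_band")) stop_input("`band` must be a `sesoi_band`")
  if (any(ratio$scale != band$scale)) {
    stop_input("ratio is on the %s scale but the band is on the %s scale",
               paste(unique(ratio$scale), collapse = "/"), band$scale)
  }
  ratio$ci_low <= band$high & ratio$ci_high >= band$low
}

# Scalar classification of one coefficient triple, after the significance
# gate has passed. Returns list(category, code).
classify_one <- function(beta_w, beta_p, beta_int) {
  d_add <- beta_w + beta_p
  d_obs <- d_add + beta_int
  if (beta_int == 0) {
    return(list(category = "none", code = NA_character_))
  }
  if (d_add != 0 && d_obs != 0 && sign(d_obs) != sign(d_add)) {
    code <- if (d_add > 0) "R+/-" else "R-/+"
    return(list(category = "reversal", code = code))
  }
  if (d_add == 0 || d_obs == 0) {
    return(list(category = "indeterminate", code = NA_character_))
  }
  suffix <- if (d_obs > 0) "+" else "-"
  same_dir <- if (sign(beta_w) == sign(beta_p) && sign(beta_w) != 0) {
    sign(beta_int) == sign(beta_w)
  } else {
    # opposing or one-zero main effects: compare against the net expectation
    sign(beta_int) == sign(d_add)
  }
  if (same_dir) {
    list(category = "synergism", code = paste0("S", suffix))
  } else {
    list(category = "antagonism", code = paste0("A", suffix))
  }
}

#' Classify stressor interactions against the multiplicative null
#'
#' Applies the synergism / antagonism / reversal taxonomy to each row of a
#' coefficient table. The decision logic, in order:
#'
#' 1. if the interaction p-value is not below `alpha_sig`, the category is
#'    `"none"` (no interaction retained);
#' 2. otherwise the additive null is decomposed (`delta_add = beta_w + beta_p`,
#'    `delta_obs = delta_add + beta_int`);
#' 3. if `delta_obs` and `delta_add` are both nonzero with opposite signs, the
#'    interaction flips the direction of the combined response: a reversal
#'    (`R+/-` when the null expectation was positive, `R-/+` when negative);
#' 4. if the main effects share a sign, the interaction is a synergism when it
#'    shares that sign (pushing the combined effect beyond the null) and an
#'    antagonism otherwise; with opposing (or one-zero) main effects the
#'    interaction is a synergism when it reinforces the net expectation
#'    (`sign(beta_int) == sign(delta_add)`) and an antagonism when it
#'    counteracts it;
#' 5. exact zeros of `delta_add` or `delta_obs` are `"indeterminate"` (they do
#'    not arise from real fits).
#'
#' The `+`/`-` suffix on synergism/antagonism codes is the sign of
#' `delta_obs`: the direction of the combined-treatment response relative to
#' the double control. When a band is available, significant interactions
#' whose confidence interval overlaps it are flagged `mild`.
#'
#' @param coefs A coefficient table ([stressor_coefs()] or compatible data
#'   frame).
#' @param alpha_sig Significance gate applied to `p_int` (default 0.05).
#' @param band Optional [sesoi_band()] applied to every row (its scale must
#'   match each row's link), or `NULL`.
#' @param sesoi_percent If `band` is `NULL` and this is non-`NULL`, a per-row
#'   band of this half-width is constructed from each row's link; for identity
#'   links the reference quantity is `sesoi_reference` if given, otherwise
#'   `|delta_add|` of the same row.
#' @param sesoi_reference Optional fixed reference quantity for identity-link
#'   bands built via `sesoi_percent`.
#' @param level Confidence level for the interaction interval (default 0.95).
#' @return The input coefficient table augmented with `delta_add`,
#'   `delta_obs`, `category`, `code`, `ratio`, `ci_low`, `ci_high`,
#'   `ratio_scale` and `mild`, with class `stressor_classification`. `mild` is
#'   `NA` when no band applies or the category is `"none"`.
#' @examples
#' june <- stressor_coefs(
#'   response = "barnacle_abundance", date_label = "June", link = "log",
#'   beta_w = -0.693, beta_p = 2.087, beta_int = 0.414,
#'   se_w = 0.149, se_p = 0.120, se_int = 0.182, p_int = 0.023
#' )
#' classify_interaction(june, sesoi_percent = 5)
#' @export
classify_interaction <- function(coefs, alpha_sig = 0.05, band = NULL,
                                 sesoi_percent = NULL, sesoi_reference = NULL,
                                 level = 0.95) {
  if (!is.numeric(alpha_sig) || length(alpha_sig) != 1L ||
      alpha_sig <= 0 || alpha_sig >= 1) {
    stop_input("`alpha_sig` must lie strictly between 0 and 1")
  }
  coefs <- validate_stressor_coefs(as_tibble(coefs))
  if (is.null(coefs$p_int)) {
    coefs$p_int <- wald_p(coefs$beta_int, coefs$se_int)
  }
  dec <- decompose_null(coefs)
  ratio_tbl <- interaction_ratio_ci(coefs, level = level)

  n <- nrow(coefs)
  category <- character(n)
  code <- rep(NA_character_, n)
  mild <- rep(NA, n)
  for (i in seq_len(n)) {
    if (!is.na(coefs$p_int[i]) && coefs$p_int[i] >= alpha_sig) {
      category[i] <- "none"
      next
    }
    cl <- classify_one(coefs$beta_w[i], coefs$beta_p[i], coefs$beta_int[i])
    category[i] <- cl$category
    code[i] <- cl$code
    if (cl$category %in% c("none", "indeterminate")) next
    band_i <- band
    if (is.null(band_i) && !is.null(sesoi_percent)) {
      ref <- sesoi_reference %||%
        (if (coefs$link[i] == "identity") abs(dec$delta_add[i]) else NULL)
      band_i <- sesoi_band(coefs$link[i], percent = sesoi_percent,
                           reference_quantity = ref)
    }
    if (!is.null(band_i)) {
      mild[i] <- flag_mild(ratio_tbl[i, ], band_i)
    }
  }

  out <- dplyr::bind_cols(
    coefs,
    tibble(
      delta_add = dec$delta_add, delta_obs = dec$delta_obs,
      category = category, code = code,
      ratio = ratio_tbl$ratio, ci_low = ratio_tbl$ci_low,
      ci_high = ratio_tbl$ci_high, ratio_scale = ratio_tbl$scale, mild = mild
    )
  )
  class(out) <- unique(c("stressor_classification", class(out)))
  out
}
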