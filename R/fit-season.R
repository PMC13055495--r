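#' Fit a season-wide smooth model with plate random intercepts
#'
#' Fits a generalised additive mixed model across all survey dates for one
#' response: parametric warming, pollution and interaction terms, one
#' penalised smooth of day per treatment combination, and (optionally) a
#' plate-level random intercept. The parametric 2x2 terms are the contract —
#' they feed interaction classification exactly like per-date GLM
#' coefficients, with `date_label = "season"`.
#'
#' @param observations A survey table covering at least 3 distinct days.
#' @param response Response name.
#' @param family `"count_nb"`, `"binary"`, `"proportion"` or `"continuous"`.
#' @param link Link; defaults to the family's canonical choice.
#' @param smooth_df Basis dimension of each per-treatment smooth (default 4);
#'   must be below the number of distinct days.
#' @param random_effect Include a plate random intercept (default `TRUE`).
#' @return An object of class `season_fit`: a list with
#'   \describe{
#'     \item{coefficients}{one-row `stressor_coefs` tibble (`date_label =
#'       "season"`).}
#'     \item{smooths}{tibble of per-cell smooth summaries: effective degrees
#'       of freedom (`edf`, a wiggliness summary), smooth-term p-value, and
#'       the range of the smooth's fitted contribution.}
#'     \item{smooth_fitted}{tibble of the smooth component's fitted values per
#'       observation (`site`, `warming`, `day`, `smooth`).}
#'     \item{model}{the underlying [mgcv::gam] fit.}
#'   }
#'   Use [tidy()][generics::tidy] / [glance()][generics::glance] for tabular
#'   summaries.
#' @export
fit_season_model <- function(observations, response,
                             family = c("count_nb", "binary", "proportion",
                                        "continuous"),
                             link = NULL, smooth_df = 4, random_effect = TRUE) {
  family <- match.arg(family)
  link <- link %||% switch(family, count_nb = "log", binary = "logit",
                           proportion = "logit", continuous = "identity")
  sim_config(response_family = family, link = link)  # validates pairing
  d <- design_frame(observations, response)
  n_days <- length(unique(d$day))
  if (n_days < 3L) stop_input("season model needs >= 3 distinct days (got %d)", n_days)
  if (smooth_df >= n_days) {
    stop_config("`smooth_df` (%d) must be below the number of distinct days (%d)",
                smooth_df, n_days)
  }
  d$cell <- factor(paste(d$warming, d$site, sep = "."),
                   levels = c("ambient.non_polluted", "warmed.non_polluted",
                              "ambient.polluted", "warmed.polluted"))
  d$plate_id <- factor(d$plate_id)

  fam <- switch(family,
    count_nb = mgcv::nb(),
    binary = binomial(),
    proportion = mgcv::betar(),
    continuous = gaussian(link = link)
  )
  if (family == "proportion") {
    eps <- 1e-6
    d$value <- pmin(pmax(d$value, eps), 1 - eps)
  }
  form <- if (random_effect) {
    value ~ W * P + s(day, by = cell, k = smooth_df) + s(plate_id, bs = "re")
  } else {
    value ~ W * P + s(day, by = cell, k = smooth_df)
  }
  # select = TRUE adds a null-space penalty so smooths can shrink to zero
  # when the data carry no temporal trend
  fit <- suppressWarnings(
    mgcv::gam(form, family = fam, data = d, method = "REML", select = TRUE)
  )

  est <- coef(fit)[c("(Intercept)", "W", "P", "W:P")]
  se <- sqrt(diag(vcov(fit)))[c("(Intercept)", "W", "P", "W:P")]
  names(est) <- names(se) <- c("(Intercept)", "W", "P", "W:P")
  coefs <- coefs_from_fit(est, se, response, "season", link, nrow(d))

  sm <- summary(fit)
  terms_mat <- predict(fit, type = "terms")
  smooth_cols <- grep("^s\\(day\\)", colnames(terms_mat))
  smooth_total <- rowSums(terms_mat[, smooth_cols, drop = FALSE])
  smooth_fitted <- tibble(
    site = d$site, warming = d$warming, day = d$day, smooth = smooth_total
  )
  day_smooths <- grep("^s\\(day\\)", rownames(sm$s.table))
  smooths <- tibble(
    term = rownames(sm$s.table)[day_smooths],
    edf = sm$s.table[day_smooths, "edf"],
    p_value = sm$s.table[day_smooths, "p-value"],
    fitted_range = vapply(seq_along(day_smooths), function(i) {
      col <- smooth_cols[i]
      diff(range(terms_mat[, col]))
    }, numeric(1))
  )

  structure(
    list(coefficients = coefs, smooths = smooths,
         smooth_fitted = smooth_fitted, model = fit,
         family = family, link = link, response = response),
    class = "season_fit"
  )
}

#' @export
print.season_fit <- function(x, ...) {
  cat(sprintf("<season_fit> response '%s' (%s, %s link), n = %d\n",
              x$response, x$family, x$link, x$coefficients$n_obs))
  print(x$coefficients[, c("beta_w", "se_w", "p_w", "beta_p", "se_p", "p_p",
                           "beta_int", "se_int", "p_int")])
  invisible(x)
}

#' Tidy a season-wide model fit
#'
#' @param x A [fit_season_model()] object.
#' @param ... Unused.
#' @return For `tidy()`, a tibble with one row per parametric term (term,
#'   estimate, std.error, p.value, link); for `glance()`, a one-row model
#'   summary.
#' @export
tidy.season_fit <- function(x, ...) {
  co <- x$coefficients
  tibble(
    term = c("(Intercept)", "warming", "pollution", "warming:pollution"),
    estimate = c(co$alpha, co$beta_w, co$beta_p, co$beta_int),
    std.error = c(NA_real_, co$se_w, co$se_p, co$se_int),
    p.value = c(NA_real_, co$p_w, co$p_p, co$p_int),
    link = co$link
  )
}

#' @rdname tidy.season_fit
#' @export
glance.season_fit <- function(x, ...) {
  sm <- summary(x$model)
  tibble(
    n_obs = x$coefficients$n_obs,
    adj_r_squared = sm$r.sq,
    deviance_explained = sm$dev.expl,
    total_edf = sum(x$smooths$edf),
    family = x$family,
    link = x$link
  )
}
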