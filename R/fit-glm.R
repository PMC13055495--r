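#' Collapse an abundance response to presence/absence
#'
#' Grazer-style count responses with many zeros are analysed as occurrence:
#' any strictly positive value becomes 1, zero stays 0. All other columns are
#' unchanged.
#'
#' @param observations A survey table (see [read_survey_table()]).
#' @param response Name of the response to binarise; other responses are left
#'   untouched.
#' @return The table with binarised values for `response`. A warning is issued
#'   if the binarised response is constant (the downstream fit will be
#'   degenerate).
#' @examples
#' tbl <- tibble::tibble(
#'   plate_id = paste0("p", 1:4), site = "polluted", warming = "ambient",
#'   day = 0, response = "grazers", value = c(0, 3, 1, 0)
#' )
#' binarize_occurrence(tbl, "grazers")$value
#' @export
binarize_occurrence <- function(observations, response) {
  sel <- observations$response == response
  if (!any(sel)) stop_input("no rows with response '%s'", response)
  v <- observations$value[sel]
  if (any(v < 0)) stop_input("response '%s' has negative values; cannot binarise", response)
  bin <- as.numeric(v > 0)
  if (length(unique(bin)) == 1L) {
    warn(sprintf("binarised response '%s' is constant (%d everywhere): fits will be degenerate",
                 response, unique(bin)))
  }
  observations$value[sel] <- bin
  observations
}

# Subset a survey table to one response (and optionally one day) and attach
# 0/1 design codes with ambient / non_polluted as reference levels.
design_frame <- function(observations, response, day = NULL) {
  d <- observations[observations$response == response, , drop = FALSE]
  if (!is.null(day)) d <- d[d$day == day, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop_input("no observations for response '%s'%s", response,
               if (is.null(day)) "" else sprintf(" on day %s", day))
  }
  d$W <- as.numeric(d$warming == "warmed")
  d$P <- as.numeric(d$site == "polluted")
  cell_n <- table(paste(d$W, d$P))
  if (length(cell_n) < 4L || any(cell_n < 2L)) {
    stop_input("each of the 4 treatment cells needs >= 2 observations (got: %s)",
               paste(cell_n, collapse = ", "))
  }
  d
}

fit_family_object <- function(family, link) {
  switch(family,
    binary = binomial(link = "logit"),
    continuous = gaussian(link = link),
    NULL
  )
}

# Extract the 2x2 coefficient row from a fitted model given estimate and
# covariance, enforcing Wald self-consistency of p-values.
coefs_from_fit <- function(est, se, response, date_label, link, n_obs) {
  nm <- c("(Intercept)", "W", "P", "W:P")
  est <- est[nm]; se <- se[nm]
  stressor_coefs(
    response = response, date_label = date_label, link = link,
    alpha = est[["(Intercept)"]],
    beta_w = est[["W"]], beta_p = est[["P"]], beta_int = est[["W:P"]],
    se_w = se[["W"]], se_p = se[["P"]], se_int = se[["W:P"]],
    n_obs = n_obs
  )
}

#' Fit a per-date 2x2 factorial GLM
#'
#' Fits one generalised linear model for a single response on a single survey
#' date, with warming, pollution and their interaction as predictors
#' (treatment coding; ambient / non-polluted reference). Families: negative
#' binomial counts (log link), Bernoulli occurrence (logit; for sparse data
#' prefer [fit_firth_logistic()]), Beta proportions (logit), Gaussian
#' concentrations (identity or log).
#'
#' @param observations A survey table.
#' @param response Response name.
#' @param day Integer survey day.
#' @param family `"count_nb"`, `"binary"`, `"proportion"` or `"continuous"`.
#' @param link Link function; defaults to the family's canonical choice.
#' @return A one-row `stressor_coefs` tibble (Wald standard errors, two-sided
#'   Wald p-values on the link scale).
#' @seealso [fit_firth_logistic()], [fit_season_model()]
#' @export
fit_date_glm <- function(observations, response, day,
                         family = c("count_nb", "binary", "proportion",
                                    "continuous"),
                         link = NULL) {
  family <- match.arg(family)
  link <- link %||% switch(family, count_nb = "log", binary = "logit",
                           proportion = "logit", continuous = "identity")
  cfg <- sim_config(response_family = family, link = link)  # validates pairing
  d <- design_frame(observations, response, day)
  if (var(d$value) == 0) {
    stop_degenerate("response '%s' on day %s is constant (value = %g): no model can be fitted",
                    response, day, d$value[1])
  }
  date_label <- as.character(day)

  if (family == "count_nb") {
    # NB dispersion by pooled within-cell moments (ML theta is noisy at few
    # plates per cell and makes Wald tests anticonservative), then a
    # fixed-theta NB GLM
    cellid <- paste(d$W, d$P)
    m_c <- tapply(d$value, cellid, mean)
    v_c <- tapply(d$value, cellid, var)
    phi <- min(max(sum(v_c - m_c) / sum(m_c^2), 1e-3), 100)
    fit <- suppressWarnings(
      glm(value ~ W * P, family = MASS::negative.binomial(theta = 1 / phi),
          data = d)
    )
    est <- coef(fit)
    se <- sqrt(diag(summary(fit, dispersion = 1)$cov.scaled))
    se <- se * small_sample_factor(fit) # quasi-likelihood + t calibration
    return(coefs_from_fit(est, se, response, date_label, "log", nrow(d)))
  }

  if (family == "binary") {
    fit <- suppressWarnings(glm(value ~ W * P, family = binomial(), data = d))
    est <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    if (any(abs(est) > 15) || any(se > 50)) {
      stop_degenerate(paste0(
        "quasi-separation in binary response '%s' on day %s (unbounded estimates); ",
        "use fit_firth_logistic()"), response, day)
    }
    return(coefs_from_fit(est, se, response, date_label, "logit", nrow(d)))
  }

  if (family == "proportion") {
    fb <- fit_beta_logit(d$value, model.matrix(~ W * P, d))
    se <- fb$se * stats::qt(0.975, nrow(d) - 5) / .z975
    return(coefs_from_fit(fb$est, se, response, date_label, "logit", nrow(d)))
  }

  # continuous
  fit <- glm(value ~ W * P, family = gaussian(link = link), data = d)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit))) *
    stats::qt(0.975, fit$df.residual) / .z975
  coefs_from_fit(est, se, response, date_label, link, nrow(d))
}

# Small-sample SE calibration for quasi-likelihood date fits: inflate by the
# Pearson dispersion when it exceeds 1, and rescale by the t/normal 97.5%
# quantile ratio so that normal-reference Wald p-values behave like
# t-reference ones at the design's residual df.
small_sample_factor <- function(fit) {
  pearson_disp <- sum(residuals(fit, type = "pearson")^2) / fit$df.residual
  sqrt(max(pearson_disp, 1)) * stats::qt(0.975, fit$df.residual) / .z975
}

# Beta regression with logit mean link and constant precision, by maximum
# likelihood. y in (0, 1); boundary values are shrunk inward by half the
# smallest observed distance to the boundary.
fit_beta_logit <- function(y, X) {
  if (any(y < 0 | y > 1)) stop_input("proportion response must lie in [0, 1]")
  eps <- 1e-6
  y <- pmin(pmax(y, eps), 1 - eps)
  nll <- function(par) {
    eta <- drop(X %*% par[seq_len(ncol(X))])
    phi <- exp(par[ncol(X) + 1])
    m <- plogis(eta)
    -sum(dbeta(y, m * phi, (1 - m) * phi, log = TRUE))
  }
  start <- c(qlogis(mean(y)), rep(0, ncol(X) - 1), log(5))
  opt <- optim(start, nll, method = "BFGS", hessian = TRUE,
               control = list(maxit = 500))
  if (opt$convergence != 0) {
    stop_degenerate("beta regression failed to converge")
  }
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    stop_degenerate("beta regression information matrix is singular")
  })
  est <- opt$par[seq_len(ncol(X))]
  se <- sqrt(pmax(diag(vc)[seq_len(ncol(X))], 0))
  names(est) <- names(se) <- colnames(X)
  list(est = est, se = se, phi = exp(opt$par[ncol(X) + 1]))
}

#' Firth bias-reduced logistic regression for a 2x2 factorial
#'
#' Penalised (Jeffreys-prior) logistic fit of occurrence on warming,
#' pollution and their interaction. The Firth score modification keeps
#' estimates finite under complete or quasi-complete separation, which is
#' common for sparse presence/absence data in small factorial designs.
#'
#' @param observations A survey table whose `response` values are 0/1 (see
#'   [binarize_occurrence()]).
#' @param response Response name.
#' @param day Integer survey day; `NULL` pools all days.
#' @return A one-row `stressor_coefs` tibble with `link = "logit"`.
#' @export
fit_firth_logistic <- function(observations, response, day = NULL) {
  d <- design_frame(observations, response, day)
  if (!all(d$value %in% c(0, 1))) {
    stop_input("response '%s' is not binary; run binarize_occurrence() first", response)
  }
  X <- model.matrix(~ W * P, d)
  f <- firth_fit(d$value, X)
  coefs_from_fit(f$est, f$se, response,
                 if (is.null(day)) "pooled" else as.character(day),
                 "logit", nrow(d))
}

# Newton iteration with Firth's modified score
# U*(b) = X'(y - p + h (1/2 - p)), h = leverages of the weighted fit.
firth_fit <- function(y, X, max_iter = 100, tol = 1e-8) {
  b <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    XW <- X * sqrt(w)
    XtWX <- crossprod(XW)
    inv <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(inv)) stop_degenerate("Firth fit: singular information matrix")
    h <- rowSums((XW %*% inv) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    delta <- drop(inv %*% score)
    # step-halving for stability
    step <- 1
    while (max(abs(step * delta)) > 5) step <- step / 2
    b <- b + step * delta
    if (max(abs(step * delta)) < tol) break
  }
  eta <- drop(X %*% b)
  w <- pmax(plogis(eta) * (1 - plogis(eta)), 1e-12)
  vc <- solve(crossprod(X * sqrt(w)))
  est <- b
  se <- sqrt(diag(vc))
  names(est) <- names(se) <- colnames(X)
  list(est = est, se = se, iterations = it)
}
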