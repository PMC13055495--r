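#' Configuration for a factorial survey simulation
#'
#' Describes one response variable observed on settlement plates in a fully
#' factorial warming x pollution design, surveyed repeatedly over a season.
#' The defaults mirror a design of 6 plates per treatment cell surveyed on 7
#' fortnightly dates, with a plate-level random intercept to induce
#' repeated-measures correlation and an optional shared seasonal trend (a
#' half-period sinusoid over the date range) on the link scale.
#'
#' @param n_plates_per_cell Plates per treatment cell (default 6).
#' @param n_dates Number of fortnightly survey dates (default 7).
#' @param response_family One of `"count_nb"` (negative binomial, log link),
#'   `"binary"` (Bernoulli, logit), `"proportion"` (Beta, logit) or
#'   `"continuous"` (Gaussian, identity or log).
#' @param link Link function; must be compatible with the family.
#' @param alpha Link-scale intercept.
#' @param beta_w,beta_p,beta_int True link-scale effects of warming, pollution
#'   and their interaction.
#' @param plate_sd Standard deviation of plate random intercepts on the link
#'   scale (>= 0).
#' @param dispersion Family dispersion: NB dispersion phi in
#'   `Var = mu + phi mu^2`, Beta precision, or Gaussian residual sd (> 0).
#' @param smooth_amplitude Amplitude of the shared seasonal sinusoid on the
#'   link scale (default 0: no trend).
#' @param response Name recorded in the output's `response` column.
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_plates_per_cell = 6, n_dates = 7,
                       response_family = c("count_nb", "binary", "proportion",
                                           "continuous"),
                       link = NULL,
                       alpha = 0, beta_w = 0, beta_p = 0, beta_int = 0,
                       plate_sd = 0, dispersion = 0.5, smooth_amplitude = 0,
                       response = "response", seed = 1L) {
  response_family <- match.arg(response_family)
  default_link <- switch(response_family,
    count_nb = "log", binary = "logit", proportion = "logit",
    continuous = "identity"
  )
  link <- link %||% default_link
  check_link(link)
  allowed <- switch(response_family,
    count_nb = "log", binary = "logit", proportion = "logit",
    continuous = c("identity", "log")
  )
  if (!link %in% allowed) {
    stop_config("link '%s' is incompatible with family '%s' (allowed: %s)",
                link, response_family, paste(allowed, collapse = ", "))
  }
  if (n_plates_per_cell < 1) stop_config("`n_plates_per_cell` must be >= 1")
  if (n_dates < 1) stop_config("`n_dates` must be >= 1")
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop_config("`dispersion` must be > 0")
  }
  if (!is.numeric(plate_sd) || plate_sd < 0) stop_config("`plate_sd` must be >= 0")
  structure(
    list(
      n_plates_per_cell = as.integer(n_plates_per_cell),
      n_dates = as.integer(n_dates),
      response_family = response_family, link = link,
      alpha = alpha, beta_w = beta_w, beta_p = beta_p, beta_int = beta_int,
      plate_sd = plate_sd, dispersion = dispersion,
      smooth_amplitude = smooth_amplitude,
      response = response, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# The 2x2 design cells, reference levels first.
design_cells <- function() {
  tidyr::expand_grid(
    site = c("non_polluted", "polluted"),
    warming = c("ambient", "warmed")
  )
}

#' Simulate a factorial survey time series
#'
#' Generates one observation per plate per survey date. Each plate keeps a
#' single random intercept across all its dates; the link-scale linear
#' predictor is `alpha + beta_w*W + beta_p*P + beta_int*W*P + plate effect +
#' seasonal term`, with `W = 1` for warmed plates and `P = 1` for plates at
#' the polluted site, and the response is drawn from the configured family.
#' Draws use one child RNG stream per plate, so results are reproducible and
#' independent of generation order.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `plate_id`, `site`, `warming`, `day`,
#'   `response`, `value`.
#' @examples
#' simulate_survey(sim_config(beta_p = 2, seed = 42))
#' @export
simulate_survey <- function(config) {
  if (!inherits(config, "sim_config")) {
    config <- do.call(sim_config, as.list(config))
  }
  days <- as.integer(round(seq(0, by = 14, length.out = config$n_dates)))
  season <- if (config$n_dates > 1) {
    config$smooth_amplitude * sin(pi * days / max(days))
  } else {
    rep(0, config$n_dates)
  }

  cells <- design_cells()
  plates <- tidyr::expand_grid(cells, rep = seq_len(config$n_plates_per_cell))
  plates$plate_idx <- seq_len(nrow(plates))
  plates$plate_id <- sprintf("plate_%02d", plates$plate_idx)

  rows <- purrr::pmap(plates, function(site, warming, rep, plate_idx, plate_id) {
    w <- as.numeric(warming == "warmed")
    p <- as.numeric(site == "polluted")
    withr_seed <- child_seed(config$seed, plate_idx)
    old <- .Random.seed_exists()
    set.seed(withr_seed)
    plate_eff <- if (config$plate_sd > 0) rnorm(1, 0, config$plate_sd) else 0
    eta <- config$alpha + config$beta_w * w + config$beta_p * p +
      config$beta_int * w * p + plate_eff + season
    value <- draw_response(eta, config)
    restore_seed(old)
    tibble(plate_id = plate_id, site = site, warming = warming,
           day = days, response = config$response, value = value)
  })
  dplyr::bind_rows(rows)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

draw_response <- function(eta, config) {
  n <- length(eta)
  switch(config$response_family,
    count_nb = rnbinom(n, mu = exp(eta), size = 1 / config$dispersion),
    binary = rbinom(n, 1, plogis(eta)),
    proportion = {
      m <- plogis(eta)
      rbeta(n, shape1 = m * config$dispersion,
            shape2 = (1 - m) * config$dispersion)
    },
    continuous = {
      mu <- if (config$link == "log") exp(eta) else eta
      rnorm(n, mu, config$dispersion)
    }
  )
}

#' Configuration for a factorial RNA-seq-like count simulation
#'
#' Generates negative-binomial gene counts whose log2 mean follows the 2x2
#' factorial design, with a configurable mixture of true interaction types.
#' Effect patterns per type (in units of `effect_magnitude` m, as
#' `(lfc_w, lfc_p, lfc_int)` on log2 scale): `S+` = (m, m, m), `S-` =
#' (-m, -m, -m), `A+` = (m, m, -m/2), `A-` = (-m, -m, m/2), `R+/-` =
#' (m, m, -3m), `R-/+` = (-m, -m, 3m); `null` genes have all-zero effects.
#'
#' @param n_genes Number of genes.
#' @param n_per_cell Samples per treatment cell (>= 2; default 8).
#' @param baseline_log2_mean Mean and sd of per-gene baseline log2 expression,
#'   as `c(mean, sd)`.
#' @param nb_dispersion Lognormal parameters `c(meanlog, sdlog)` of per-gene
#'   NB dispersion phi (`Var = mu + phi mu^2`).
#' @param type_mixture Named proportions over
#'   `c("null", "A+", "A-", "S+", "S-", "R+/-", "R-/+")`; must sum to 1.
#' @param effect_magnitude Log2 fold-change scale m of non-null genes.
#' @param size_factor_sd Lognormal sd of sample-specific library size factors
#'   (exercises median-of-ratios normalisation downstream).
#' @param seed Integer RNG seed.
#' @return A validated list of class `gene_sim_config`.
#' @export
gene_sim_config <- function(n_genes = 1000, n_per_cell = 8,
                            baseline_log2_mean = c(5.5, 2),
                            nb_dispersion = c(log(0.15), 0.4),
                            type_mixture = c(null = 1),
                            effect_magnitude = 2,
                            size_factor_sd = 0.15,
                            seed = 1L) {
  codes <- c("null", "A+", "A-", "S+", "S-", "R+/-", "R-/+")
  if (n_per_cell < 2) {
    stop_config("`n_per_cell` must be >= 2: the 2x2 interaction model is unidentifiable otherwise")
  }
  if (n_genes < 1) stop_config("`n_genes` must be >= 1")
  if (is.null(names(type_mixture)) || !all(names(type_mixture) %in% codes)) {
    stop_config("`type_mixture` must be named with codes among: %s",
                paste(codes, collapse = ", "))
  }
  if (abs(sum(type_mixture) - 1) > 1e-9) {
    stop_config("`type_mixture` proportions must sum to 1 (got %g)", sum(type_mixture))
  }
  full <- setNames(rep(0, length(codes)), codes)
  full[names(type_mixture)] <- type_mixture
  structure(
    list(
      n_genes = as.integer(n_genes), n_per_cell = as.integer(n_per_cell),
      baseline_log2_mean = baseline_log2_mean, nb_dispersion = nb_dispersion,
      type_mixture = full, effect_magnitude = effect_magnitude,
      size_factor_sd = size_factor_sd, seed = as.integer(seed)
    ),
    class = "gene_sim_config"
  )
}

type_effects <- function(type, m) {
  switch(type,
    "null" = c(0, 0, 0),
    "S+" = c(m, m, m),
    "S-" = c(-m, -m, -m),
    "A+" = c(m, m, -m / 2),
    "A-" = c(-m, -m, m / 2),
    "R+/-" = c(m, m, -3 * m),
    "R-/+" = c(-m, -m, 3 * m)
  )
}

#' Simulate a factorial gene count matrix with known interaction types
#'
#' @param config A [gene_sim_config()].
#' @return A list with `counts` (integer matrix, genes x samples), `samples`
#'   (tibble: `sample_id`, `site`, `warming`) and `truth` (tibble: `gene_id`,
#'   `type`, true `lfc_w`, `lfc_p`, `lfc_int` in log2, `baseline_log2_mean`,
#'   `dispersion`). Reproducible under a fixed seed.
#' @examples
#' sim <- simulate_gene_counts(gene_sim_config(n_genes = 20, seed = 7))
#' dim(sim$counts)
#' @export
simulate_gene_counts <- function(config) {
  if (!inherits(config, "gene_sim_config")) {
    config <- do.call(gene_sim_config, as.list(config))
  }
  cells <- design_cells()
  samples <- tidyr::expand_grid(cells, rep = seq_len(config$n_per_cell))
  samples$sample_id <- sprintf("sample_%02d", seq_len(nrow(samples)))
  w <- as.numeric(samples$warming == "warmed")
  p <- as.numeric(samples$site == "polluted")

  # deterministic type allocation following the mixture
  n_by_type <- diff(c(0, round(cumsum(config$type_mixture) * config$n_genes)))
  types <- rep(names(config$type_mixture), times = n_by_type)

  old <- .Random.seed_exists()
  set.seed(child_seed(config$seed, 0L))
  sf <- exp(rnorm(nrow(samples), 0, config$size_factor_sd))

  counts <- matrix(0L, nrow = config$n_genes, ncol = nrow(samples),
                   dimnames = list(sprintf("gene_%05d", seq_len(config$n_genes)),
                                   samples$sample_id))
  truth <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    set.seed(child_seed(config$seed, g))
    b0 <- rnorm(1, config$baseline_log2_mean[1], config$baseline_log2_mean[2])
    phi <- exp(rnorm(1, config$nb_dispersion[1], config$nb_dispersion[2]))
    eff <- type_effects(types[g], config$effect_magnitude)
    log2_mu <- b0 + eff[1] * w + eff[2] * p + eff[3] * w * p
    mu <- sf * 2^log2_mu
    counts[g, ] <- rnbinom(ncol(counts), mu = mu, size = 1 / phi)
    truth[[g]] <- tibble(
      gene_id = rownames(counts)[g], type = types[g],
      lfc_w = eff[1], lfc_p = eff[2], lfc_int = eff[3],
      baseline_log2_mean = b0, dispersion = phi
    )
  }
  restore_seed(old)
  list(
    counts = counts,
    samples = as_tibble(samples[c("sample_id", "site", "warming")]),
    truth = dplyr::bind_rows(truth)
  )
}

#' Simulate tables of fitted link-scale coefficients
#'
#' Draws coefficient records directly, bypassing data simulation and model
#' fitting, for engine-level testing and calibration. Effects are Gaussian
#' and standard errors lognormal (hence strictly positive); p-values are
#' self-consistent Wald p-values, `p = 2 * (1 - Phi(|beta| / se))`.
#'
#' @param n Number of records (>= 1).
#' @param beta_w,beta_p,beta_int `c(mean, sd)` of each Gaussian effect
#'   distribution (use `c(x, 0)` to fix a value).
#' @param se_log `c(meanlog, sdlog)` of the lognormal SE distribution, shared
#'   by the three terms.
#' @param link Link recorded on every row.
#' @param response Response name recorded on every row.
#' @param wald_noise If `TRUE`, the drawn values are treated as true effects
#'   and reported estimates add Wald sampling noise (`beta + se * Z`), so
#'   that p-values are uniform under a zero true effect; if `FALSE`
#'   (default), the drawn values are reported as-is.
#' @param seed Integer RNG seed.
#' @return A `stressor_coefs` tibble with `n` rows.
#' @examples
#' simulate_coefficients(3, beta_int = c(0, 0), seed = 1)$p_int  # all 1
#' @export
simulate_coefficients <- function(n, beta_w = c(0, 1), beta_p = c(0, 1),
                                  beta_int = c(0, 1), se_log = c(-1.2, 0.4),
                                  link = "log", response = "simulated",
                                  wald_noise = FALSE, seed = 1L) {
  if (n < 1) stop_input("`n` must be >= 1")
  check_link(link)
  old <- .Random.seed_exists()
  set.seed(child_seed(seed, 0L))
  bw <- rnorm(n, beta_w[1], beta_w[2])
  bp <- rnorm(n, beta_p[1], beta_p[2])
  bi <- rnorm(n, beta_int[1], beta_int[2])
  sw <- exp(rnorm(n, se_log[1], se_log[2]))
  sp <- exp(rnorm(n, se_log[1], se_log[2]))
  si <- exp(rnorm(n, se_log[1], se_log[2]))
  if (wald_noise) {
    bw <- bw + sw * rnorm(n)
    bp <- bp + sp * rnorm(n)
    bi <- bi + si * rnorm(n)
  }
  restore_seed(old)
  stressor_coefs(
    response = response, date_label = sprintf("sim_%04d", seq_len(n)),
    link = link, alpha = 0,
    beta_w = bw, beta_p = bp, beta_int = bi,
    se_w = sw, se_p = sp, se_int = si
  )
}
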