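test_that("occurrence binarisation thresholds at strict positivity", {
  tbl <- toy_survey(list(
    "ambient.non_polluted" = c(0, 3), "warmed.non_polluted" = c(1, 0),
    "ambient.polluted" = c(0.5, 0), "warmed.polluted" = c(2, 2)
  ), n_per_cell = 2)
  out <- binarize_occurrence(tbl, "resp")
  expect_equal(out$value, c(0, 1, 1, 0, 1, 0, 1, 1))
  expect_warning(
    binarize_occurrence(dplyr::mutate(tbl, value = 0), "resp"),
    "constant"
  )
  expect_error(
    binarize_occurrence(dplyr::mutate(tbl, value = -1), "resp"),
    class = "multistress_input_error"
  )
})

test_that("treatment coding reproduces link-scale cell means exactly", {
  # saturated toy data: fitted cell means equal observed means, so the
  # coefficients must equal closed-form log cell-mean contrasts
  vals <- list(
    "ambient.non_polluted" = c(10, 12, 14), "warmed.non_polluted" = c(5, 6, 7),
    "ambient.polluted" = c(40, 44, 42), "warmed.polluted" = c(30, 29, 37)
  )
  tbl <- toy_survey(vals, n_per_cell = 3)
  co <- fit_date_glm(tbl, "resp", 0, family = "count_nb")
  mean00 <- mean(vals[["ambient.non_polluted"]])
  meanW <- mean(vals[["warmed.non_polluted"]])
  meanP <- mean(vals[["ambient.polluted"]])
  meanWP <- mean(vals[["warmed.polluted"]])
  expect_equal(co$alpha, log(mean00), tolerance = 1e-8)
  expect_equal(co$beta_w, log(meanW) - log(mean00), tolerance = 1e-8)
  expect_equal(co$beta_p, log(meanP) - log(mean00), tolerance = 1e-8)
  expect_equal(co$beta_int,
               log(meanWP) - log(meanW) - log(meanP) + log(mean00),
               tolerance = 1e-8)
  # predicted cell means on the link scale recompose additively
  expect_equal(co$alpha + co$beta_w + co$beta_p + co$beta_int, log(meanWP),
               tolerance = 1e-8)

  # binomial closed form: logit contrasts of cell occurrence probabilities
  occ <- toy_survey(list(
    "ambient.non_polluted" = c(0, 0, 0, 1, 1, 1, 1, 1),
    "warmed.non_polluted" = c(0, 0, 0, 0, 0, 1, 1, 1),
    "ambient.polluted" = c(0, 1, 1, 1, 1, 1, 1, 1),
    "warmed.polluted" = c(0, 0, 1, 1, 1, 1, 1, 1)
  ), n_per_cell = 8)
  cb <- fit_date_glm(occ, "resp", 0, family = "binary")
  expect_equal(cb$alpha, qlogis(5 / 8), tolerance = 1e-6)
  expect_equal(cb$beta_p, qlogis(7 / 8) - qlogis(5 / 8), tolerance = 1e-6)
})

test_that("emitted p-values are Wald self-consistent across families", {
  cfg <- sim_config(alpha = 2, beta_w = -0.5, beta_p = 1, beta_int = 0.3,
                    seed = 21)
  s <- simulate_survey(cfg)
  rows <- dplyr::bind_rows(
    fit_date_glm(s, "response", 0, family = "count_nb"),
    fit_season_model(s, "response", family = "count_nb")$coefficients
  )
  for (term in c("w", "p", "int")) {
    expect_equal(rows[[paste0("p_", term)]],
                 2 * pnorm(-abs(rows[[paste0("beta_", term)]] /
                                  rows[[paste0("se_", term)]])),
                 tolerance = 1e-10)
  }
})

test_that("degenerate inputs raise explicit errors, never silent garbage", {
  const <- toy_survey(list(
    "ambient.non_polluted" = c(3, 3), "warmed.non_polluted" = c(3, 3),
    "ambient.polluted" = c(3, 3), "warmed.polluted" = c(3, 3)
  ), n_per_cell = 2)
  expect_error(fit_date_glm(const, "resp", 0, family = "count_nb"),
               class = "multistress_degenerate_fit")

  # a structurally empty cell separates the standard logistic fit
  sep <- toy_survey(list(
    "ambient.non_polluted" = rep(0, 6), "warmed.non_polluted" = c(0, 1, 1, 0, 1, 0),
    "ambient.polluted" = c(1, 1, 1, 0, 1, 1), "warmed.polluted" = c(1, 0, 1, 1, 1, 0)
  ), n_per_cell = 6)
  expect_error(fit_date_glm(sep, "resp", 0, family = "binary"),
               class = "multistress_degenerate_fit")

  # too few plates per cell
  tiny <- toy_survey(list(
    "ambient.non_polluted" = 1, "warmed.non_polluted" = 2,
    "ambient.polluted" = 3, "warmed.polluted" = 4
  ), n_per_cell = 1)
  expect_error(fit_date_glm(tiny, "resp", 0, family = "count_nb"),
               class = "multistress_input_error")
})

test_that("per-date NB fits recover generating effects with near-nominal coverage", {
  truth <- c(w = -0.693, p = 2.087, int = 0.414)
  hits <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(n_plates_per_cell = 50, n_dates = 1, alpha = 3,
                      beta_w = truth["w"], beta_p = truth["p"],
                      beta_int = truth["int"], dispersion = 0.5,
                      seed = 9000 + i)
    co <- fit_date_glm(simulate_survey(cfg), "response", 0, family = "count_nb")
    z <- qnorm(0.975)
    covered <- abs(co$beta_w - truth["w"]) <= z * co$se_w &&
      abs(co$beta_p - truth["p"]) <= z * co$se_p &&
      abs(co$beta_int - truth["int"]) <= z * co$se_int
    if (covered) hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})

test_that("null simulations keep the interaction estimate near zero", {
  reps <- vapply(1:150, function(i) {
    cfg <- sim_config(n_plates_per_cell = 6, n_dates = 1, alpha = 4,
                      beta_w = 0, beta_p = 0, beta_int = 0, seed = 400 + i)
    co <- fit_date_glm(simulate_survey(cfg), "response", 0, family = "count_nb")
    c(co$beta_int, co$se_int)
  }, numeric(2))
  expect_lt(median(abs(reps[1, ])), 2 * median(reps[2, ]))
})

test_that("Firth penalisation keeps separated fits finite", {
  # one empty cell: unpenalised logistic diverges, Firth stays bounded
  sep <- toy_survey(list(
    "ambient.non_polluted" = rep(0, 6), "warmed.non_polluted" = c(0, 1, 1, 0, 1, 0),
    "ambient.polluted" = c(1, 1, 1, 0, 1, 1), "warmed.polluted" = c(1, 0, 1, 1, 1, 0)
  ), n_per_cell = 6)
  unpen <- suppressWarnings(glm(
    I(value > 0) ~ I(warming == "warmed") * I(site == "polluted"),
    family = binomial(), data = sep
  ))
  expect_gt(max(abs(coef(unpen))), 15)  # divergence of the plain fit
  ff <- fit_firth_logistic(sep, "resp", 0)
  expect_true(all(abs(c(ff$alpha, ff$beta_w, ff$beta_p, ff$beta_int)) < 20))
  expect_true(all(c(ff$se_w, ff$se_p, ff$se_int) > 0))

  expect_error(
    fit_firth_logistic(dplyr::mutate(sep, value = value + 0.5), "resp", 0),
    class = "multistress_input_error"
  )
})

test_that("Firth fits are unbiased at balanced 50% occurrence and recover strong effects", {
  flat <- simulate_survey(sim_config(
    n_plates_per_cell = 40, n_dates = 1, response_family = "binary",
    alpha = 0, seed = 61
  ))
  co <- fit_firth_logistic(flat, "response", 0)
  expect_lt(abs(co$beta_w), 3 * co$se_w)
  expect_lt(abs(co$beta_p), 3 * co$se_p)
  expect_lt(abs(co$beta_int), 3 * co$se_int)

  # recovery of a large pollution effect on occurrence
  est <- vapply(1:200, function(i) {
    s <- simulate_survey(sim_config(
      n_plates_per_cell = 30, n_dates = 1, response_family = "binary",
      alpha = -1.5, beta_p = 3.86, seed = 7000 + i
    ))
    fit_firth_logistic(s, "response", 0)$beta_p
  }, numeric(1))
  expect_equal(mean(est), 3.86, tolerance = 0.5 / 3.86)
})

test_that("beta-regression date fits recover logit-scale proportion effects", {
  s <- simulate_survey(sim_config(
    n_plates_per_cell = 60, n_dates = 1, response_family = "proportion",
    alpha = -1, beta_p = 1.2, dispersion = 30, seed = 13
  ))
  co <- fit_date_glm(s, "response", 0, family = "proportion")
  expect_equal(co$link, "logit")
  expect_lt(abs(co$beta_p - 1.2), 2.5 * co$se_p)
  expect_lt(abs(co$beta_w), 3 * co$se_w)
})
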