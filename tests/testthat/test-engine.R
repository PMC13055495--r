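june_barnacle <- stressor_coefs(
  response = "barnacle_abundance", date_label = "June", link = "log",
  beta_w = -0.693, beta_p = 2.087, beta_int = 0.414,
  se_w = 0.149, se_p = 0.120, se_int = 0.182, p_int = 0.023
)

season_barnacle <- stressor_coefs(
  response = "barnacle_abundance", date_label = "season", link = "log",
  beta_w = -0.887, beta_p = 2.087, beta_int = 0.507,
  se_w = 0.214, se_p = 0.210, se_int = 0.299, p_int = 0.090
)

test_that("null decomposition is exact arithmetic on the link scale", {
  d <- decompose_null(june_barnacle)
  expect_equal(d$delta_add, 1.394)
  expect_equal(d$delta_obs, 1.808)
  expect_equal(d$delta_obs - d$delta_add, d$beta_int, tolerance = 1e-12)

  z <- decompose_null(tibble::tibble(beta_w = 0, beta_p = 0, beta_int = 0))
  expect_equal(unlist(z), c(delta_add = 0, delta_obs = 0, beta_int = 0))

  r <- decompose_null(tibble::tibble(beta_w = -1, beta_p = -1, beta_int = 2.5))
  expect_equal(r$delta_add, -2)
  expect_equal(r$delta_obs, 0.5)
})

test_that("interaction ratio and CI reproduce back-transformed Wald bounds", {
  # amplification over the multiplicative null: ~51% in June
  r_june <- interaction_ratio_ci(june_barnacle)
  expect_equal(r_june$ratio, exp(0.414), tolerance = 1e-12)
  expect_equal(round(r_june$ratio, 3), 1.513)

  # season-wide coefficient: CI lower bound 0.924
  r_season <- interaction_ratio_ci(season_barnacle, level = 0.95)
  expect_equal(round(r_season$ci_low, 3), 0.924)
  expect_equal(r_season$scale, "exp")

  # zero interaction: ratio 1, CI symmetric on the log scale
  r0 <- interaction_ratio_ci(
    tibble::tibble(link = "log", beta_int = 0, se_int = 0.3)
  )
  expect_equal(r0$ratio, 1)
  expect_equal(log(r0$ci_high), -log(r0$ci_low), tolerance = 1e-12)

  # identity link passes the coefficient through untransformed
  r_id <- interaction_ratio_ci(
    tibble::tibble(link = "identity", beta_int = 0.086, se_int = 0.039)
  )
  expect_equal(r_id$scale, "identity")
  expect_equal(round(r_id$ci_high, 3), 0.162)

  expect_error(interaction_ratio_ci(june_barnacle, level = 1.2),
               class = "multistress_input_error")
})

test_that("ratio CI bounds are strictly increasing in beta_int at fixed SE", {
  b <- seq(-2, 2, length.out = 41)
  r <- interaction_ratio_ci(
    tibble::tibble(link = "log", beta_int = b, se_int = 0.25)
  )
  expect_true(all(diff(r$ci_low) > 0))
  expect_true(all(diff(r$ci_high) > 0))
})

test_that("equivalence band construction matches its definition", {
  b <- sesoi_band("log", percent = 5)
  expect_equal(c(b$low, b$high), c(0.95, 1.05))
  expect_equal(b$scale, "exp")

  b_id <- sesoi_band("identity", percent = 5, reference_quantity = 0.32)
  expect_equal(c(b_id$low, b_id$high), c(-0.016, 0.016))

  # band collapses toward the null point as percent -> 0
  tiny <- sesoi_band("logit", percent = 1e-8)
  expect_lt(tiny$high - tiny$low, 1e-9)
  expect_true(tiny$low < 1 && tiny$high > 1)

  expect_error(sesoi_band("identity"), class = "multistress_config_error")
  expect_error(sesoi_band("log", percent = -1), class = "multistress_config_error")
})

test_that("mild flag is CI/band interval overlap, with scale checking", {
  r <- interaction_ratio_ci(season_barnacle)
  expect_true(flag_mild(r, sesoi_band("log")))           # [0.924, 2.984] vs [0.95, 1.05]

  r_cyano <- interaction_ratio_ci(
    tibble::tibble(link = "identity", beta_int = 0.086, se_int = 0.039)
  )
  expect_true(flag_mild(r_cyano, sesoi_band("identity", reference_quantity = 0.32)))

  disjoint <- tibble::tibble(ratio = 1.4, ci_low = 1.20, ci_high = 1.60,
                             scale = "exp")
  expect_false(flag_mild(disjoint, sesoi_band("log")))

  expect_error(flag_mild(r, sesoi_band("identity", reference_quantity = 1)),
               class = "multistress_input_error")
})

test_that("published coefficient patterns classify as reported", {
  # June: opposing main effects, positive interaction reinforcing a positive
  # net expectation -> synergism (not reversal)
  cl <- classify_interaction(june_barnacle, band = sesoi_band("log"))
  expect_equal(cl$category, "synergism")
  expect_equal(cl$code, "S+")
  expect_false(cl$mild)

  # non-significant interaction is never classified
  gated <- classify_interaction(
    stressor_coefs(response = "x", link = "log",
                   beta_w = 1, beta_p = 1, beta_int = 1,
                   se_w = 1, se_p = 1, se_int = 1, p_int = 0.20)
  )
  expect_equal(gated$category, "none")
  expect_true(is.na(gated$code))

  # interaction flips a negative expectation to positive: R-/+
  rev <- classify_interaction(
    stressor_coefs(response = "x", link = "log",
                   beta_w = -1, beta_p = -1, beta_int = 2.5,
                   se_w = 0.1, se_p = 0.1, se_int = 0.1, p_int = 0.001)
  )
  expect_equal(rev$category, "reversal")
  expect_equal(rev$code, "R-/+")

  # season-wide mild synergism at a relaxed gate
  mild <- classify_interaction(season_barnacle, alpha_sig = 0.10,
                               band = sesoi_band("log"))
  expect_equal(mild$category, "synergism")
  expect_true(mild$mild)
})

test_that("classification agrees with the brute-force oracle everywhere", {
  triples <- random_triples(10000, seed = 20260928)
  coefs <- stressor_coefs(
    response = "grid", date_label = as.character(seq_len(nrow(triples))),
    link = "log",
    beta_w = triples$beta_w, beta_p = triples$beta_p,
    beta_int = triples$beta_int,
    se_w = 1, se_p = 1, se_int = 1,
    p_w = 0, p_p = 0, p_int = 0  # gate open: test the taxonomy itself
  )
  got <- classify_interaction(coefs)
  want <- purrr::pmap(triples, oracle_classify)
  expect_identical(got$category, purrr::map_chr(want, "category"))
  expect_identical(got$code, purrr::map_chr(want, "code"))
  # the identity delta_obs - delta_add = beta_int holds to rounding error
  expect_equal(got$delta_obs - got$delta_add, coefs$beta_int, tolerance = 1e-12)
})

test_that("classification is symmetric in the two stressors", {
  triples <- random_triples(400, seed = 7)
  a <- classify_interaction(stressor_coefs(
    response = "s", link = "logit",
    beta_w = triples$beta_w, beta_p = triples$beta_p, beta_int = triples$beta_int,
    se_w = 0.4, se_p = 0.9, se_int = 0.5, p_int = 0
  ))
  b <- classify_interaction(stressor_coefs(
    response = "s", link = "logit",
    beta_w = triples$beta_p, beta_p = triples$beta_w, beta_int = triples$beta_int,
    se_w = 0.9, se_p = 0.4, se_int = 0.5, p_int = 0
  ))
  expect_identical(a$category, b$category)
  expect_identical(a$code, b$code)
})

test_that("engine keeps the nominal no-interaction rate under a true null", {
  coefs <- simulate_coefficients(
    4000, beta_w = c(0.5, 0.5), beta_p = c(0.5, 0.5), beta_int = c(0, 0),
    wald_noise = TRUE, seed = 31
  )
  cl <- classify_interaction(coefs, alpha_sig = 0.05)
  rate_none <- mean(cl$category == "none")
  # binomial 99% CI around 0.95 at n = 4000 is ~ +/- 0.009
  expect_gt(rate_none, 0.935)
  expect_lt(rate_none, 0.965)
})
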