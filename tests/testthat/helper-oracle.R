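# Independent brute-force oracle for the interaction taxonomy, formulated
# from the magnitude of the combined effect rather than the sign rules used
# by the implementation:
#   - reversal  : combined effect and null expectation have opposite signs
#   - synergism : same sign, combined effect further from zero than the null
#   - antagonism: same sign, combined effect closer to zero than the null
oracle_classify <- function(beta_w, beta_p, beta_int) {
  d_add <- beta_w + beta_p
  d_obs <- d_add + beta_int
  if (beta_int == 0) return(list(category = "none", code = NA_character_))
  if (d_add != 0 && d_obs != 0 && sign(d_obs) != sign(d_add)) {
    return(list(category = "reversal",
                code = if (d_add > 0) "R+/-" else "R-/+"))
  }
  if (d_add == 0 || d_obs == 0) {
    return(list(category = "indeterminate", code = NA_character_))
  }
  suffix <- if (d_obs > 0) "+" else "-"
  if (abs(d_obs) > abs(d_add)) {
    list(category = "synergism", code = paste0("S", suffix))
  } else {
    list(category = "antagonism", code = paste0("A", suffix))
  }
}

# Random coefficient triples spanning all 27 sign patterns of
# (beta_w, beta_p, beta_int) and both |beta_int| smaller/larger than |d_add|.
random_triples <- function(n, seed) {
  set.seed(seed)
  signs <- sample(c(-1, 0, 1), 3 * n, replace = TRUE,
                  prob = c(0.45, 0.1, 0.45))
  mag <- function(k) exp(runif(k, log(0.01), log(5)))
  tibble::tibble(
    beta_w = signs[seq_len(n)] * mag(n),
    beta_p = signs[n + seq_len(n)] * mag(n),
    beta_int = signs[2 * n + seq_len(n)] * mag(n)
  )
}

# Minimal balanced survey table for fitting tests: one value per plate.
toy_survey <- function(values_by_cell, n_per_cell, day = 0,
                       response = "resp") {
  cells <- expand.grid(
    site = c("non_polluted", "polluted"),
    warming = c("ambient", "warmed"),
    stringsAsFactors = FALSE
  )
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    key <- paste(cells$warming[i], cells$site[i], sep = ".")
    tibble::tibble(
      plate_id = sprintf("p_%s_%02d", key, seq_len(n_per_cell)),
      site = cells$site[i], warming = cells$warming[i],
      day = day, response = response,
      value = values_by_cell[[key]]
    )
  })
  dplyr::bind_rows(rows)
}
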