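#' Packaged example coefficient table: rocky-shore warming x pollution study
#'
#' Link-scale coefficients from a published in-situ 2x2 factorial experiment
#' crossing passive plate warming with a sewage-pollution site contrast on a
#' temperate rocky shore: a per-date negative-binomial GLM of barnacle
#' abundance in June, plus season-wide GAMM parametric terms for barnacle
#' abundance (log link), grazer occurrence (logit), macroalgal cover (logit),
#' and cyanobacteria and diatom concentrations (identity). `beta_w` is the
#' warming effect, `beta_p` the polluted-site contrast, `beta_int` their
#' interaction; p-values are as reported (Wald-computed where only a bound
#' was reported). Intercepts were not reported and are `NA` — they never
#' enter interaction classification.
#'
#' @return A `stressor_coefs` tibble with 6 rows.
#' @examples
#' classify_interaction(published_coefficients(), sesoi_percent = 5)
#' @export
published_coefficients <- function() {
  path <- system.file("extdata", "published_coefficients.tsv",
                      package = "multistress", mustWork = TRUE)
  read_coefficient_table(path)
}
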