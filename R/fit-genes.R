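#' Median-of-ratios size factors
#'
#' Standard library-size normalisation for count matrices: each sample's size
#' factor is the median across genes of the ratio of its count to the gene's
#' geometric mean across samples (genes with a zero anywhere are skipped, as
#' their geometric mean is zero).
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors_mor <- function(counts) {
  if (any(counts < 0)) stop_input("counts must be non-negative")
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) stop_input("no gene has all-positive counts; cannot compute size factors")
  sf <- apply(counts[use, , drop = FALSE], 2, function(cnt) {
    exp(median(log(cnt) - log_geo[use]))
  })
  if (any(!is.finite(sf) | sf <= 0)) {
    stop_input("degenerate size factors; check the count matrix")
  }
  sf
}

# Per-gene NB dispersion: design-aware method-of-moments on normalised
# counts (within-cell moments pooled across the 4 treatment cells, so true
# fold-changes do not masquerade as dispersion), shrunk in log space toward
# a mean-dispersion trend fitted by lowess. A simplified alternative to full
# empirical-Bayes shrinkage.
estimate_dispersions <- function(counts, sf, cell) {
  norm <- sweep(counts, 2, sf, "/")
  cells <- unique(cell)
  num <- matrix(0, nrow(counts), length(cells))  # per-cell (v - m)
  den <- matrix(0, nrow(counts), length(cells))  # per-cell m^2
  for (j in seq_along(cells)) {
    idx <- which(cell == cells[j])
    m_c <- rowMeans(norm[, idx, drop = FALSE])
    v_c <- apply(norm[, idx, drop = FALSE], 1, var)
    num[, j] <- v_c - m_c
    den[, j] <- m_c^2
  }
  phi_raw <- pmax(rowSums(num) / pmax(rowSums(den), 1e-8), 1e-8)
  m <- rowMeans(norm)
  ok <- m > 0
  trend <- lowess(log(m[ok]), log(phi_raw[ok]), f = 0.5)
  phi_trend <- exp(approx(trend$x, trend$y, xout = log(pmax(m, min(m[ok]))),
                          rule = 2)$y)
  phi <- exp(0.5 * log(phi_raw) + 0.5 * log(phi_trend))
  pmin(pmax(phi, 1e-8), 100)
}

#' Fit per-gene factorial negative-binomial models
#'
#' For each gene, fits an NB GLM (log link) of counts on warming, pollution
#' and their interaction with log size-factor offsets (median-of-ratios
#' normalisation) and a per-gene moment dispersion estimate shrunk toward a
#' mean-dispersion trend. Genes with fewer than `min_total` total counts are
#' removed before fitting. Wald tests per term; log-fold-changes are reported
#' in log2 units.
#'
#' @param counts Non-negative integer matrix, genes x samples (rownames =
#'   gene ids).
#' @param samples Metadata tibble with `sample_id`, `site`
#'   (`non_polluted`/`polluted`), `warming` (`ambient`/`warmed`), matching
#'   the columns of `counts`.
#' @param min_total Low-count filter threshold (default 10 total counts).
#' @return A tibble (one row per retained, fitted gene) with `gene_id`,
#'   `lfc_w`, `lfc_p`, `lfc_int` (log2), their standard errors and two-sided
#'   Wald p-values. Attribute `n_filtered` records genes dropped by the
#'   low-count filter and `n_failed` genes whose fit did not converge.
#' @export
fit_gene_models <- function(counts, samples, min_total = 10) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))
  }
  samples <- as_tibble(samples)
  if (!all(c("sample_id", "site", "warming") %in% names(samples))) {
    stop_input("`samples` needs columns sample_id, site, warming")
  }
  if (!is.null(colnames(counts))) {
    if (!setequal(colnames(counts), samples$sample_id)) {
      stop_input("count matrix columns do not match samples$sample_id")
    }
    counts <- counts[, samples$sample_id, drop = FALSE]
  }
  w <- as.numeric(samples$warming == "warmed")
  p <- as.numeric(samples$site == "polluted")
  cell_n <- table(paste(w, p))
  if (length(cell_n) < 4L || any(cell_n < 2L)) {
    stop_input("every treatment cell needs >= 2 samples")
  }

  keep <- rowSums(counts) >= min_total
  n_filtered <- sum(!keep)
  counts <- counts[keep, , drop = FALSE]
  if (nrow(counts) == 0L) stop_input("no genes survive the low-count filter")

  sf <- size_factors_mor(counts)
  phi <- estimate_dispersions(counts, sf, paste(w, p))
  off <- log(sf)
  X <- model.matrix(~ w * p)
  ln2 <- log(2)

  fit_one <- function(y, phi_g) {
    fam <- MASS::negative.binomial(theta = 1 / phi_g)
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = fam, offset = off)),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) return(NULL)
    # Wald covariance at fixed dispersion (scale 1)
    wts <- fit$weights
    vc <- tryCatch(solve(crossprod(X * sqrt(wts))), error = function(e) NULL)
    if (is.null(vc)) return(NULL)
    est <- fit$coefficients
    se <- sqrt(diag(vc))
    c(est[2], est[3], est[4], se[2], se[3], se[4])
  }

  res <- matrix(NA_real_, nrow(counts), 6)
  for (g in seq_len(nrow(counts))) {
    r <- fit_one(counts[g, ], phi[g])
    if (!is.null(r)) res[g, ] <- r
  }
  ok <- !is.na(res[, 1])
  n_failed <- sum(!ok)
  if (n_failed > 0) {
    warn(sprintf("%d gene fit(s) failed to converge and were dropped", n_failed))
  }

  out <- tibble(
    gene_id = rownames(counts)[ok],
    lfc_w = res[ok, 1] / ln2, lfc_p = res[ok, 2] / ln2, lfc_int = res[ok, 3] / ln2,
    se_w = res[ok, 4] / ln2, se_p = res[ok, 5] / ln2, se_int = res[ok, 6] / ln2
  )
  out$p_w <- wald_p(out$lfc_w, out$se_w)
  out$p_p <- wald_p(out$lfc_p, out$se_p)
  out$p_int <- wald_p(out$lfc_int, out$se_int)
  attr(out, "n_filtered") <- n_filtered
  attr(out, "n_failed") <- n_failed
  attr(out, "size_factors") <- sf
  out
}
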