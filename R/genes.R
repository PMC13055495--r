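#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of a p-value vector (values
#' clipped to 1, monotone in the sorted order). Thin validated wrapper around
#' [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_bh <- function(pvalues) {
  if (!is.numeric(pvalues)) stop_input("p-values must be numeric")
  bad <- !is.na(pvalues) & (pvalues < 0 | pvalues > 1)
  if (any(bad)) {
    stop_input("p-values outside [0, 1] at position(s) %s",
               paste(head(which(bad), 5), collapse = ", "))
  }
  p.adjust(pvalues, method = "BH")
}

#' Classify per-gene stressor interactions
#'
#' Applies BH adjustment (per design term, across all genes) and the
#' synergism / antagonism / reversal taxonomy gene-by-gene. Genes with
#' adjusted interaction p-value below `alpha` are classified from the signs
#' of their log2 fold-changes — the taxonomy is invariant to positive
#' rescaling of all three coefficients, so log2 inputs are used directly and
#' the per-gene interaction ratio is `2^lfc_int`. Main-effect significance
#' does not gate classification; only point-estimate signs enter the sign
#' rules. All other genes are left uncoded (`code = NA`).
#'
#' @param fits Gene fit table from [fit_gene_models()] (or compatible, with
#'   `gene_id`, `lfc_w`, `lfc_p`, `lfc_int`, `se_int`, `p_w`, `p_p`,
#'   `p_int`). If `padj_*` columns are present they are used as-is;
#'   otherwise they are computed here.
#' @param alpha Significance threshold on the adjusted interaction p-value
#'   (default 0.05).
#' @param adjust `"per_term"` (default) adjusts each design term's p-values
#'   separately across genes; `"pooled"` adjusts all three columns jointly.
#' @return A tibble with one row per gene: the input columns plus `padj_w`,
#'   `padj_p`, `padj_int`, `category`, `code`, `ratio` (`2^lfc_int`), and
#'   `delta_add` / `delta_obs` on the log2 scale; class
#'   `gene_classification`. Summarise with [interaction_type_counts()].
#' @export
classify_gene_interactions <- function(fits, alpha = 0.05,
                                       adjust = c("per_term", "pooled")) {
  adjust <- match.arg(adjust)
  fits <- as_tibble(fits)
  needed <- c("gene_id", "lfc_w", "lfc_p", "lfc_int", "p_w", "p_p", "p_int")
  missing <- setdiff(needed, names(fits))
  if (length(missing)) {
    stop_input("gene fit table is missing column(s): %s (run fit_gene_models() first)",
               paste(missing, collapse = ", "))
  }
  if (!all(c("padj_w", "padj_p", "padj_int") %in% names(fits))) {
    if (adjust == "per_term") {
      fits$padj_w <- adjust_bh(fits$p_w)
      fits$padj_p <- adjust_bh(fits$p_p)
      fits$padj_int <- adjust_bh(fits$p_int)
    } else {
      all_p <- adjust_bh(c(fits$p_w, fits$p_p, fits$p_int))
      n <- nrow(fits)
      fits$padj_w <- all_p[seq_len(n)]
      fits$padj_p <- all_p[n + seq_len(n)]
      fits$padj_int <- all_p[2 * n + seq_len(n)]
    }
  }

  sig <- !is.na(fits$padj_int) & fits$padj_int < alpha
  n <- nrow(fits)
  category <- rep(NA_character_, n)
  code <- rep(NA_character_, n)
  for (i in which(sig)) {
    cl <- classify_one(fits$lfc_w[i], fits$lfc_p[i], fits$lfc_int[i])
    category[i] <- cl$category
    code[i] <- cl$code
  }
  out <- dplyr::mutate(
    fits,
    category = category, code = code,
    ratio = 2^.data$lfc_int,
    delta_add = .data$lfc_w + .data$lfc_p,
    delta_obs = .data$lfc_w + .data$lfc_p + .data$lfc_int
  )
  class(out) <- unique(c("gene_classification", class(out)))
  out
}

#' Tally interaction-type codes among significant genes
#'
#' @param typed A [classify_gene_interactions()] table.
#' @return A tibble of class `interaction_type_counts`: one row per code
#'   (`S+`, `S-`, `A+`, `A-`, `R+/-`, `R-/+`) with `count` and `proportion`
#'   of significant genes; attribute `n_significant`.
#' @export
interaction_type_counts <- function(typed) {
  codes <- c("S+", "S-", "A+", "A-", "R+/-", "R-/+")
  coded <- typed$code[!is.na(typed$code)]
  n_sig <- length(coded)
  counts <- vapply(codes, function(cd) sum(coded == cd), integer(1))
  out <- tibble(
    code = codes,
    count = counts,
    proportion = if (n_sig > 0) counts / n_sig else rep(NA_real_, length(codes))
  )
  attr(out, "n_significant") <- n_sig
  class(out) <- unique(c("interaction_type_counts", class(out)))
  out
}

#' Summarise interaction-type frequencies
#'
#' Merges per-code tallies into the three interaction categories (R = both
#' reversal codes, A = both antagonism codes, S = both synergism codes) and
#' reports per-code and per-category proportions among significant genes.
#'
#' @param counts An [interaction_type_counts()] table.
#' @return A list with `n_significant`, the per-code tibble, and a
#'   `categories` tibble (`category`, `count`, `proportion`, `percent`).
#'   Proportions are absent (`NA`) when no gene is significant.
#' @export
summarize_interaction_frequencies <- function(counts) {
  if (!inherits(counts, "interaction_type_counts")) {
    stop_input("`counts` must come from interaction_type_counts()")
  }
  n_sig <- attr(counts, "n_significant")
  cat_of <- c("S+" = "S", "S-" = "S", "A+" = "A", "A-" = "A",
              "R+/-" = "R", "R-/+" = "R")
  cats <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(as_tibble(counts), category = cat_of[.data$code]),
      .data$category
    ),
    count = sum(.data$count), .groups = "drop"
  )
  cats$proportion <- if (n_sig > 0) cats$count / n_sig else NA_real_
  cats$percent <- 100 * cats$proportion
  cats <- dplyr::arrange(cats, dplyr::desc(.data$count))
  list(n_significant = n_sig, codes = as_tibble(counts), categories = cats)
}
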