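#' Read a factorial survey table
#'
#' Reads a CSV/TSV of plate-level survey observations with columns
#' `plate_id`, `site`, `warming`, `day`, `response`, `value` (header
#' case-insensitive; `site` and `warming` values are lower-cased and checked
#' against `polluted`/`non_polluted` and `warmed`/`ambient`).
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A validated survey tibble.
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(raw) <- tolower(names(raw))
  needed <- c("plate_id", "site", "warming", "day", "response", "value")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    stop_input("survey table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  d <- raw[needed]
  d$site <- tolower(gsub("[ -]", "_", d$site))
  d$warming <- tolower(d$warming)
  bad_site <- which(!d$site %in% c("polluted", "non_polluted"))
  if (length(bad_site)) {
    stop_input("unknown site level '%s' at row %d (expected polluted/non_polluted)",
               d$site[bad_site[1]], bad_site[1])
  }
  bad_w <- which(!d$warming %in% c("warmed", "ambient"))
  if (length(bad_w)) {
    stop_input("unknown warming level '%s' at row %d (expected warmed/ambient)",
               d$warming[bad_w[1]], bad_w[1])
  }
  if (!is.numeric(d$day) || any(is.na(d$day))) {
    stop_input("`day` must be numeric with no missing values")
  }
  d$day <- as.integer(d$day)
  neg <- which(d$value < 0)
  if (length(neg)) {
    stop_input("negative value (%g) at row %d", d$value[neg[1]], neg[1])
  }
  key <- paste(d$plate_id, d$day, d$response)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_input("duplicated (plate_id, day, response) key at row %d: %s",
               dup[1], key[dup[1]])
  }
  # site/warming must be constant within plate
  chk <- dplyr::summarise(dplyr::group_by(d, .data$plate_id),
                          n_site = dplyr::n_distinct(.data$site),
                          n_w = dplyr::n_distinct(.data$warming),
                          .groups = "drop")
  if (any(chk$n_site > 1 | chk$n_w > 1)) {
    stop_input("plate(s) %s change site or warming across rows",
               paste(chk$plate_id[chk$n_site > 1 | chk$n_w > 1], collapse = ", "))
  }
  as_tibble(d)
}

#' Write a survey table to CSV
#'
#' @param observations Survey tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_survey_table <- function(observations, path) {
  readr::write_csv(observations, path, progress = FALSE)
  invisible(path)
}

#' Read / write link-scale coefficient tables
#'
#' TSV exchange format for [stressor_coefs()] tables, so the classification
#' engine can run on the output of any external fitting tool: one row per
#' (response, date_label) with columns `response`, `date_label`, `link`,
#' `alpha`, `beta_w`, `se_w`, `p_w`, `beta_p`, `se_p`, `p_p`, `beta_int`,
#' `se_int`, `p_int`, `n_obs`.
#'
#' @param path File path.
#' @return `read_coefficient_table()`: a validated `stressor_coefs` tibble.
#' @export
read_coefficient_table <- function(path) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(d) <- tolower(names(d))
  validate_stressor_coefs(as_tibble(d))
}

#' @rdname read_coefficient_table
#' @param coefs A `stressor_coefs` tibble.
#' @export
write_coefficient_table <- function(coefs, path) {
  cols <- c("response", "date_label", "link", "alpha",
            "beta_w", "se_w", "p_w", "beta_p", "se_p", "p_p",
            "beta_int", "se_int", "p_int", "n_obs")
  present <- intersect(cols, names(coefs))
  readr::write_tsv(as_tibble(coefs)[present], path, progress = FALSE)
  invisible(path)
}

#' Read a gene count matrix with sample metadata
#'
#' Reads a TSV whose first column is the gene id and remaining columns are
#' per-sample counts, plus a samples TSV (`sample_id`, `site`, `warming`).
#'
#' @param counts_path Path to the counts TSV.
#' @param samples_path Path to the samples TSV.
#' @return A list with `counts` (matrix) and `samples` (tibble).
#' @export
read_counts <- function(counts_path, samples_path) {
  for (p in c(counts_path, samples_path)) {
    if (!file.exists(p)) stop_input("file not found: %s", p)
  }
  cts <- readr::read_tsv(counts_path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(cts[-1])
  rownames(m) <- as.character(cts[[1]])
  storage.mode(m) <- "double"
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE, progress = FALSE)
  names(samples) <- tolower(names(samples))
  samples$site <- tolower(gsub("[ -]", "_", samples$site))
  samples$warming <- tolower(samples$warming)
  list(counts = m, samples = as_tibble(samples))
}

#' Write gene counts, sample metadata and the simulation truth table
#'
#' @param sim Output of [simulate_gene_counts()].
#' @param dir Output directory (created if needed); files `counts.tsv`,
#'   `samples.tsv`, `truth.tsv` are written there.
#' @return The directory, invisibly.
#' @export
write_gene_counts <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cts <- as_tibble(sim$counts, rownames = "gene_id")
  readr::write_tsv(cts, file.path(dir, "counts.tsv"), progress = FALSE)
  readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Write a classification report
#'
#' Writes interaction classifications (ecological responses and/or genes) in
#' a deterministic order (sorted by response, then date label or gene id) as
#' TSV or JSON; numeric values round-trip at full precision.
#'
#' @param classifications A `stressor_classification` or `gene_classification`
#'   tibble.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return The path, invisibly.
#' @export
write_classification_report <- function(classifications, path,
                                        format = c("tsv", "json")) {
  format <- match.arg(format)
  x <- as_tibble(classifications)
  if (nrow(x) == 0L) stop_input("nothing to report: empty classification table")
  sort_cols <- intersect(c("response", "date_label", "gene_id"), names(x))
  x <- dplyr::arrange(x, dplyr::across(dplyr::all_of(sort_cols)))
  if (format == "tsv") {
    readr::write_tsv(x, path, progress = FALSE)
  } else {
    payload <- list(records = x)
    if (inherits(classifications, "gene_classification")) {
      freq <- summarize_interaction_frequencies(
        interaction_type_counts(classifications)
      )
      payload$frequencies <- list(
        n_significant = freq$n_significant,
        codes = freq$codes,
        categories = freq$categories
      )
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read back a classification report
#'
#' @param path Report path written by [write_classification_report()].
#' @param format `"tsv"` or `"json"`.
#' @return A tibble of records.
#' @export
read_classification_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (format == "tsv") {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path)$records)
  }
}
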