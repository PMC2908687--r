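# Table readers, writers and validators shared by all modules.
#
# Canonical dialect: comma-separated, UTF-8, header required, "." decimal
# separator. Tab-separated input is accepted on read (sniffed from the
# header line).

intensity_cols <- c("individual_id", "group", "tissue", "locus",
                    "allele_a_label", "allele_b_label",
                    "intensity_a", "intensity_b")
ratio_cols <- c("individual_id", "group", "tissue", "locus",
                "score_kind", "value")
ct_cols <- c("individual_id", "group", "tissue", "gene", "ct")

read_raw_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("input file does not exist: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    progress = FALSE, show_col_types = FALSE)
}

check_schema <- function(df, expected, what) {
  unknown <- setdiff(names(df), expected)
  if (length(unknown) > 0) {
    abort(sprintf("unknown column '%s' in %s table", unknown[1], what))
  }
  missing <- setdiff(expected, names(df))
  if (length(missing) > 0) {
    abort(sprintf("missing column '%s' in %s table", missing[1], what))
  }
  df[expected]
}

check_enum <- function(values, allowed, column) {
  bad <- which(!values %in% allowed)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid %s '%s' (row %d); allowed values: %s",
      column, values[bad[1]], bad[1], paste(allowed, collapse = ", ")
    ))
  }
  values
}

parse_numeric_col <- function(values, column) {
  parsed <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(parsed) & !is.na(values))
  if (length(bad) > 0) {
    abort(sprintf("unparseable numeric '%s' in column %s (row %d)",
                  values[bad[1]], column, bad[1]))
  }
  if (anyNA(parsed)) {
    abort(sprintf("missing value in column %s (row %d)",
                  column, which(is.na(parsed))[1]))
  }
  parsed
}

#' Validate an in-memory table against a schema
#'
#' Coerces column types, checks the controlled vocabularies (`group`,
#' `tissue`, `locus`, `score_kind`, `gene`) and reports the first offending
#' row on failure. [compute_ratios()], [estimate_founders()],
#' [summarize_groups()] and [ddct()] all validate their inputs through
#' these functions, so tables from any source are checked the same way.
#'
#' @param df A data frame.
#' @return The validated tibble (columns in canonical order).
#' @export
validate_intensity <- function(df) {
  df <- check_schema(as_tibble(df), intensity_cols, "intensity")
  check_enum(df$group, ef_groups(), "group")
  check_enum(df$tissue, ef_tissues(), "tissue")
  check_enum(df$locus, ef_loci(), "locus")
  df$intensity_a <- parse_numeric_col(df$intensity_a, "intensity_a")
  df$intensity_b <- parse_numeric_col(df$intensity_b, "intensity_b")
  if (any(df$intensity_a < 0) || any(df$intensity_b < 0)) {
    abort("intensities must be non-negative")
  }
  df
}

#' @rdname validate_intensity
#' @export
validate_ratio <- function(df) {
  df <- check_schema(as_tibble(df), ratio_cols, "ratio")
  check_enum(df$group, ef_groups(), "group")
  check_enum(df$tissue, ef_tissues(), "tissue")
  check_enum(df$locus, ef_loci(), "locus")
  check_enum(df$score_kind, ef_score_kinds(), "score_kind")
  df$value <- parse_numeric_col(df$value, "value")
  if (any(df$value < 0)) abort("ratio values must be non-negative")
  xi_bad <- df$score_kind == "XI" & (df$value < 0 | df$value > 1)
  if (any(xi_bad)) {
    abort(sprintf("XI scores must lie in [0, 1] (row %d)", which(xi_bad)[1]))
  }
  df
}

#' @rdname validate_intensity
#' @export
validate_ct <- function(df) {
  df <- check_schema(as_tibble(df), ct_cols, "ct")
  check_enum(df$group, ef_groups(), "group")
  check_enum(df$tissue, ef_tissues(), "tissue")
  check_enum(df$gene, ef_genes(), "gene")
  df$ct <- parse_numeric_col(df$ct, "ct")
  if (any(!is.finite(df$ct))) abort("Ct values must be finite")
  df
}

#' Read a typed table from CSV/TSV
#'
#' Reads and validates one of the three table dialects: `intensity`
#' (per-sample allele band intensities), `ratio` (scalar allelic scores) or
#' `ct` (qPCR measurements). An empty file with only a header yields an
#' empty tibble with a warning.
#'
#' @param path Path to a CSV or TSV file with a header row.
#' @return A validated tibble.
#' @export
read_intensity_table <- function(path) {
  df <- read_raw_table(path)
  if (nrow(df) == 0) {
    warn(sprintf("%s contains a header but no rows", path))
    return(check_schema(df, intensity_cols, "intensity") |>
             dplyr::mutate(dplyr::across(c("intensity_a", "intensity_b"),
                                         as.numeric)))
  }
  validate_intensity(df)
}

#' @rdname read_intensity_table
#' @export
read_ratio_table <- function(path) {
  df <- read_raw_table(path)
  if (nrow(df) == 0) {
    warn(sprintf("%s contains a header but no rows", path))
    return(check_schema(df, ratio_cols, "ratio") |>
             dplyr::mutate(value = as.numeric(.data$value)))
  }
  validate_ratio(df)
}

#' @rdname read_intensity_table
#' @export
read_ct_table <- function(path) {
  df <- read_raw_table(path)
  if (nrow(df) == 0) {
    warn(sprintf("%s contains a header but no rows", path))
    return(check_schema(df, ct_cols, "ct") |>
             dplyr::mutate(ct = as.numeric(.data$ct)))
  }
  validate_ct(df)
}

#' Write a table to CSV
#'
#' Writes any of the package's tables in the canonical comma-separated
#' dialect, re-readable by the corresponding reader.
#'
#' @param df A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}
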