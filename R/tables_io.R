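# Tidy-table input/output and validation.
#
# All tables are plain UTF-8 CSV with a mandatory header row and "." as the
# decimal mark. Validation is total: malformed input raises an error naming
# the offending rows/columns; nothing is silently dropped. Missing values are
# rejected — the grey relational model is undefined on gapped series.

#' Default hormone vocabulary
#'
#' The closed set of hormone names accepted by [read_hormone_table()] and the
#' ratio builders: the growth promoters GA3 (gibberellin A3), IAA
#' (indole-3-acetic acid) and BR (brassinolide), and the growth
#' inhibitors SA (salicylic acid), JA (jasmonic acid) and SLs
#' (strigolactones). Concentrations are reported in ng g^-1 fresh weight
#' except SA (ug g^-1); units are never converted — every downstream
#' statistic used here is invariant to a positive per-series rescaling.
#'
#' @return Character vector of hormone names.
#' @export
#' @examples
#' hormone_vocabulary()
hormone_vocabulary <- function() {
  c("GA3", "IAA", "BR", "SA", "JA", "SLs")
}

.required_hormone_cols <- c("sample_id", "cultivar", "treatment", "tissue",
                            "hormone", "concentration")

.stop_rows <- function(what, rows) {
  stop(what, " (rows: ", paste(rows, collapse = ", "), ")", call. = FALSE)
}

.check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in '", path, "': missing required column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.check_positive_numeric <- function(x, colname) {
  bad <- which(is.na(x) | !is.finite(x) | x <= 0)
  if (length(bad) > 0) {
    .stop_rows(paste0("validation error: column '", colname,
                      "' must be positive and numeric"), bad)
  }
  invisible(x)
}

.read_csv_checked <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: '", path, "'", call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        check.names = FALSE)
  tibble::as_tibble(df)
}

.apply_schema <- function(df, schema) {
  if (is.null(schema)) return(df)
  # schema maps canonical name -> column name in the file
  for (canonical in names(schema)) {
    file_col <- schema[[canonical]]
    if (!file_col %in% names(df)) {
      stop("schema error: column '", file_col, "' (for '", canonical,
           "') not found", call. = FALSE)
    }
    names(df)[names(df) == file_col] <- canonical
  }
  df
}

#' Read and validate a long-format hormone concentration table
#'
#' One row per (sample, hormone) measurement, with cultivar, treatment and
#' tissue labels. Concentrations must be strictly positive (mean-value
#' normalization of ratios requires it) and every (sample_id, hormone) pair
#' must be unique within a tissue. Hormone names are checked against a closed
#' vocabulary.
#'
#' @param path Path to a CSV file with columns `sample_id`, `cultivar`,
#'   `treatment`, `tissue`, `hormone`, `concentration` (or renamed via
#'   `schema`).
#' @param schema Optional named character vector mapping canonical column
#'   names to the column names used in the file, e.g.
#'   `c(concentration = "conc_ng_g")`.
#' @param vocabulary Closed set of accepted hormone names; defaults to
#'   [hormone_vocabulary()].
#' @return A validated `hormone_table` tibble.
#' @export
read_hormone_table <- function(path, schema = NULL,
                               vocabulary = hormone_vocabulary()) {
  df <- .read_csv_checked(path)
  df <- .apply_schema(df, schema)
  .check_columns(df, .required_hormone_cols, path)
  df <- df[.required_hormone_cols]
  if (nrow(df) == 0) {
    warning("empty hormone table: '", path, "'", call. = FALSE)
  }
  as_hormone_table(df, vocabulary = vocabulary)
}

#' Construct a validated hormone table from a data frame
#'
#' @param df Data frame with the hormone-table columns.
#' @inheritParams read_hormone_table
#' @return A `hormone_table` tibble.
#' @export
as_hormone_table <- function(df, vocabulary = hormone_vocabulary()) {
  df <- tibble::as_tibble(df)
  .check_columns(df, .required_hormone_cols, "<data frame>")
  df$concentration <- suppressWarnings(as.numeric(df$concentration))
  .check_positive_numeric(df$concentration, "concentration")
  unknown <- which(!df$hormone %in% vocabulary)
  if (length(unknown) > 0) {
    .stop_rows(paste0("vocabulary error: unknown hormone name(s) ",
                      paste(unique(df$hormone[unknown]), collapse = ", ")),
               unknown)
  }
  key <- paste(df$tissue, df$sample_id, df$hormone, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    .stop_rows("validation error: duplicate (sample_id, hormone) within tissue",
               dup)
  }
  structure(df, class = c("hormone_table", class(df)))
}

#' Read and validate a plant-height table
#'
#' One row per sample with its cultivar, treatment and height in cm. The
#' height series is the parent (reference) sequence of the grey relational
#' model, so heights must be strictly positive and sample ids unique.
#'
#' @param path Path to a CSV file with columns `sample_id`, `cultivar`,
#'   `treatment`, `height_cm`.
#' @return A validated `height_table` tibble.
#' @export
read_height_table <- function(path) {
  df <- .read_csv_checked(path)
  .check_columns(df, c("sample_id", "cultivar", "treatment", "height_cm"),
                 path)
  if (nrow(df) == 0) {
    warning("empty height table: '", path, "'", call. = FALSE)
  }
  as_height_table(df)
}

#' Construct a validated height table from a data frame
#'
#' @param df Data frame with columns `sample_id`, `cultivar`, `treatment`,
#'   `height_cm`.
#' @return A `height_table` tibble.
#' @export
as_height_table <- function(df) {
  df <- tibble::as_tibble(df)
  .check_columns(df, c("sample_id", "cultivar", "treatment", "height_cm"),
                 "<data frame>")
  df$height_cm <- suppressWarnings(as.numeric(df$height_cm))
  .check_positive_numeric(df$height_cm, "height_cm")
  dup <- which(duplicated(df$sample_id))
  if (length(dup) > 0) {
    .stop_rows("validation error: duplicate sample_id", dup)
  }
  structure(df, class = c("height_table", class(df)))
}

#' Read a differential-protein record table
#'
#' Schema mirrors a published DEP table: KEGG orthology id, protein name,
#' fold change (blue light / darkness ratio of mean abundances), t-test
#' p-value, and optional regulation call and hormone-pathway label.
#' Duplicate (ko_id, name) rows are allowed — the same orthology entry can
#' appear for several quantified proteins.
#'
#' @param path Path to a CSV file with columns `ko_id`, `name`,
#'   `fold_change`, `p_value` and optionally `regulation`, `pathway`.
#' @return A validated `protein_table` tibble.
#' @export
read_protein_table <- function(path) {
  df <- .read_csv_checked(path)
  .check_columns(df, c("ko_id", "name", "fold_change", "p_value"), path)
  as_protein_table(df)
}

#' Construct a validated protein record table from a data frame
#'
#' @param df Data frame with columns `ko_id`, `name`, `fold_change`,
#'   `p_value` and optionally `regulation`, `pathway`.
#' @return A `protein_table` tibble.
#' @export
as_protein_table <- function(df) {
  df <- tibble::as_tibble(df)
  .check_columns(df, c("ko_id", "name", "fold_change", "p_value"),
                 "<data frame>")
  df$fold_change <- suppressWarnings(as.numeric(df$fold_change))
  df$p_value <- suppressWarnings(as.numeric(df$p_value))
  .check_positive_numeric(df$fold_change, "fold_change")
  bad_p <- which(is.na(df$p_value) | df$p_value < 0 | df$p_value > 1)
  if (length(bad_p) > 0) {
    .stop_rows("validation error: p_value must lie in [0, 1]", bad_p)
  }
  if (!"regulation" %in% names(df)) df$regulation <- NA_character_
  if (!"pathway" %in% names(df)) df$pathway <- NA_character_
  structure(df, class = c("protein_table", class(df)))
}

#' Write a ranked GRA or correlation result to CSV
#'
#' Serializes a [gra()] result (columns `ratio`, `degree` at 4 decimal
#' places, `rank`) or a [correlate_height_ratios()] result (columns `ratio`,
#' `n`, `r`, `p`, `stars`, `bh_fdr`) as a plain CSV file.
#'
#' @param result A `grey_result` or `correlation_result` object.
#' @param path Output file path.
#' @return Invisibly, the tibble that was written.
#' @export
write_ranked_table <- function(result, path) {
  out <- ranked_table(result)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(out)
}

#' Tabular form of a result object
#'
#' @param result A `grey_result` or `correlation_result`.
#' @return A tibble ready for CSV serialization.
#' @export
ranked_table <- function(result) {
  UseMethod("ranked_table")
}

#' @export
ranked_table.grey_result <- function(result) {
  nm <- names(result$degrees)
  ord <- order(result$ranks)
  tibble::tibble(
    ratio = nm[ord],
    degree = sprintf("%.4f", result$degrees[ord]),
    rank = unname(result$ranks[ord])
  )
}

#' @export
ranked_table.correlation_result <- function(result) {
  out <- tibble::as_tibble(result)
  out$r <- sprintf("%.4f", out$r)
  out$p <- signif(out$p, 4)
  out$bh_fdr <- signif(out$bh_fdr, 4)
  out
}
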