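# Differential-protein screen: fold change + t-test thresholding, from
# precomputed records or replicate abundance matrices.

#' Differential-expression thresholds
#'
#' The conventional screen for the blue-light / darkness proteome contrast:
#' keep a protein when its p-value is below `alpha` AND its fold change is
#' above `up_fc` (up-regulated) or below `down_fc` (down-regulated). All
#' three inequalities are strict; boundary values are excluded. The default
#' down threshold 0.83 is the screen's literal printed value, not 1/1.2
#' (= 0.8333); set `down_from_up = TRUE` to use the reciprocal instead.
#'
#' @param up_fc Up-regulation fold-change threshold, > 1 (default 1.2).
#' @param down_fc Down-regulation threshold, in (0, 1) (default 0.83).
#' @param alpha Significance level, in (0, 1) (default 0.05).
#' @param down_from_up Derive `down_fc` as `1 / up_fc` (default `FALSE`).
#' @return A `de_thresholds` list.
#' @export
de_thresholds <- function(up_fc = 1.2, down_fc = 0.83, alpha = 0.05,
                          down_from_up = FALSE) {
  if (isTRUE(down_from_up)) down_fc <- 1 / up_fc
  if (!is.numeric(up_fc) || up_fc <= 1) stop("up_fc must be > 1", call. = FALSE)
  if (!is.numeric(down_fc) || down_fc <= 0 || down_fc >= 1) {
    stop("down_fc must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(list(up_fc = up_fc, down_fc = down_fc, alpha = alpha),
            class = "de_thresholds")
}

#' Fold change of case over control means
#'
#' @param case_mean,control_mean Positive mean abundances.
#' @return `case_mean / control_mean`.
#' @export
#' @examples
#' fold_change(14.01, 10) # 1.401
fold_change <- function(case_mean, control_mean) {
  if (any(!is.finite(case_mean)) || any(case_mean <= 0) ||
      any(!is.finite(control_mean)) || any(control_mean <= 0)) {
    stop("means must be positive and finite", call. = FALSE)
  }
  case_mean / control_mean
}

#' Screen protein records for differential expression
#'
#' Keeps a record iff `p_value < alpha` and the fold change lies outside
#' the (`down_fc`, `up_fc`) band; the regulation call is set to `"up"`
#' (fold change above `up_fc`) or `"down"` (below `down_fc`). Records
#' failing the screen are dropped from the output. Input order is
#' preserved; duplicate entries (same KO id / name) are treated as
#' independent records — no aggregation.
#'
#' @param records A `protein_table` (see [read_protein_table()]).
#' @param thr A [de_thresholds()].
#' @return The surviving records with `regulation` set, as a
#'   `protein_table`.
#' @export
de_filter <- function(records, thr = de_thresholds()) {
  stopifnot(inherits(thr, "de_thresholds"))
  records <- as_protein_table(records)
  keep <- records$p_value < thr$alpha &
    (records$fold_change > thr$up_fc | records$fold_change < thr$down_fc)
  out <- records[keep, , drop = FALSE]
  out$regulation <- ifelse(out$fold_change > thr$up_fc, "up", "down")
  out
}

#' Differential-protein screen from replicate abundance matrices
#'
#' Per protein (row): fold change = mean(case) / mean(control), p-value
#' from a two-group t-test (Student pooled-variance by default), then the
#' fold-change + p screen of [de_filter()].
#'
#' @param case,control Numeric matrices, proteins x replicates, same row
#'   count and row names, all abundances positive; at least 2 replicates
#'   each.
#' @param thr A [de_thresholds()].
#' @param equal_var Passed to [two_group_ttest()].
#' @return Surviving records as a `protein_table` (columns `ko_id`, `name`,
#'   `fold_change`, `p_value`, `regulation`, `pathway`).
#' @export
de_from_replicates <- function(case, control, thr = de_thresholds(),
                               equal_var = TRUE) {
  case <- as.matrix(case); control <- as.matrix(control)
  if (nrow(case) != nrow(control)) {
    stop("case and control must have the same number of proteins",
         call. = FALSE)
  }
  if (ncol(case) < 2 || ncol(control) < 2) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  if (any(case <= 0) || any(control <= 0)) {
    stop("abundances must be positive", call. = FALSE)
  }
  ids <- rownames(case)
  if (is.null(ids)) ids <- paste0("P", seq_len(nrow(case)))
  fc <- fold_change(rowMeans(case), rowMeans(control))
  p <- vapply(seq_len(nrow(case)), function(i) {
    two_group_ttest(case[i, ], control[i, ], equal_var = equal_var)$p
  }, numeric(1))
  records <- as_protein_table(tibble::tibble(
    ko_id = ids, name = ids, fold_change = unname(fc), p_value = p
  ))
  de_filter(records, thr)
}

#' Packaged blue-light differential-protein table
#'
#' The 14 published hormone-pathway protein records from the blue-light vs
#' darkness soybean hypocotyl proteome contrast (KO id, protein name,
#' BL/Dark fold change, t-test p-value, regulation call, hormone pathway):
#' 6 up-regulated and 8 down-regulated at the default screen thresholds.
#' Shipped as a plain-text fixture under `inst/extdata/`.
#'
#' @return A `protein_table` of 14 records.
#' @export
#' @examples
#' nrow(blue_light_protein_table())
blue_light_protein_table <- function() {
  path <- system.file("extdata", "hormone_signaling_proteins.csv",
                      package = "greyhormone", mustWork = TRUE)
  read_protein_table(path)
}
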