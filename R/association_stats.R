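# Pearson height-ratio correlation with significance stars, two-group
# t-tests, and treatment percent-change contrasts.

#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with the usual t-based two-sided p:
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 degrees of freedom
#' (computed via [stats::cor.test()]). Perfect correlation (|r| = 1)
#' returns p = 0.
#'
#' @param x,y Numeric series of equal length n >= 3, neither constant.
#' @return List with `r`, `p` and `n`.
#' @export
#' @examples
#' pearson_with_p(c(1, 2, 3, 4), c(2, 1, 4, 3)) # r = 0.6, p ~ 0.40
pearson_with_p <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("series must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant series", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  r <- unname(ct$estimate)
  p <- if (abs(r) >= 1 - 1e-15) 0 else unname(ct$p.value)
  list(r = r, p = p, n = n)
}

#' Significance stars for a p-value
#'
#' `"***"` if p < 0.001, `"**"` if p < 0.01, `"*"` if p < 0.05, otherwise
#' `""`. Inequalities are strict: p exactly 0.05 earns no star.
#'
#' @param p Numeric p-value(s) in \[0, 1\].
#' @return Character vector of star annotations.
#' @export
#' @examples
#' star_annotation(c(0.03, 0.0005, 0.05)) # "*" "***" ""
star_annotation <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Correlate plant height with every hormone ratio
#'
#' Per ratio column: Pearson r against the height series, two-sided p,
#' significance stars, and a Benjamini-Hochberg adjusted p (`bh_fdr`, an
#' extension beyond the conventional raw-star display, clearly labelled as
#' such). Samples are aligned by `sample_id`; heights and ratios must cover
#' exactly the same samples.
#'
#' @param height A `height_table` (see [read_height_table()]).
#' @param ratios A `ratio_matrix` (see [build_ratio_matrix()]).
#' @return A `correlation_result` tibble with columns `ratio`, `n`, `r`,
#'   `p`, `stars`, `bh_fdr`, in ratio order.
#' @export
correlate_height_ratios <- function(height, ratios) {
  height <- tibble::as_tibble(height)
  ids <- rownames(ratios)
  unmatched <- c(setdiff(ids, height$sample_id),
                 setdiff(height$sample_id, ids))
  if (length(unmatched) > 0) {
    stop("unmatched sample id(s) between heights and ratios: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  h <- height$height_cm[match(ids, height$sample_id)]
  res <- lapply(colnames(ratios), function(rn) {
    pw <- pearson_with_p(h, ratios[, rn])
    tibble::tibble(ratio = rn, n = pw$n, r = pw$r, p = pw$p)
  })
  out <- dplyr::bind_rows(res)
  out$stars <- star_annotation(out$p)
  out$bh_fdr <- stats::p.adjust(out$p, method = "BH")
  structure(out, class = c("correlation_result", class(out)))
}

#' Two-group t-test
#'
#' Student's pooled-variance t-test by default (the convention for small
#' n = 3-4 treatment contrasts and the proteomics screen); Welch's
#' unequal-variance form with `equal_var = FALSE`. When both groups have
#' zero variance, equal means return t = 0, p = 1 and unequal means return
#' t = +/-Inf, p = 0 (documented conventions; the textbook statistic is
#' 0/0 or x/0 there).
#'
#' @param a,b Numeric series, each of length >= 2.
#' @param equal_var Pool variances (Student) if `TRUE` (default), Welch
#'   otherwise.
#' @return List with `t`, `p` (two-sided) and `df`.
#' @export
#' @examples
#' two_group_ttest(c(10, 11, 12), c(1, 2, 3)) # t ~ 11.02, p ~ 3.9e-4
two_group_ttest <- function(a, b, equal_var = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0, df = NA_real_))
  }
  tt <- stats::t.test(a, b, var.equal = equal_var,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = unname(tt$p.value),
       df = unname(tt$parameter))
}

#' Percent change of a treated value relative to a reference
#'
#' `(reference - treated) / reference * 100`: positive values are
#' reductions relative to the reference (e.g. blue light reducing plant
#' height relative to darkness).
#'
#' @param reference Positive reference value(s) (e.g. darkness mean).
#' @param treated Treated value(s) (e.g. blue-light mean).
#' @return Percent change (positive = reduction).
#' @export
#' @examples
#' percent_change(38.18, 13.50) # 64.64
percent_change <- function(reference, treated) {
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("reference must be positive", call. = FALSE)
  }
  (reference - treated) / reference * 100
}
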