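# Hormone-ratio feature construction: the subfactor sequences fed to the
# grey relational model and to the height-ratio correlations.

#' Define a set of named hormone ratios
#'
#' @param pairs Character vector of `"NUM/DEN"` strings, e.g.
#'   `c("GA3/JA", "IAA/SLs")`. Numerator and denominator must differ, pairs
#'   must be unique, and both hormones must belong to `vocabulary`.
#' @param vocabulary Accepted hormone names; defaults to
#'   [hormone_vocabulary()].
#' @return A `ratio_spec` tibble with columns `name`, `numerator`,
#'   `denominator`, in the given order.
#' @export
#' @examples
#' ratio_spec(c("GA3/JA", "BR/SLs"))
ratio_spec <- function(pairs, vocabulary = hormone_vocabulary()) {
  if (length(pairs) == 0) stop("ratio spec must contain at least one pair",
                               call. = FALSE)
  parts <- strsplit(pairs, "/", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad) > 0) {
    stop("malformed ratio name(s): ", paste(pairs[bad], collapse = ", "),
         " (expected \"NUM/DEN\")", call. = FALSE)
  }
  num <- vapply(parts, `[`, character(1), 1)
  den <- vapply(parts, `[`, character(1), 2)
  unknown <- setdiff(unique(c(num, den)), vocabulary)
  if (length(unknown) > 0) {
    stop("vocabulary error: unknown hormone(s) in ratio spec: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(num == den)) {
    stop("ratio numerator and denominator must differ: ",
         paste(pairs[num == den], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(pairs)) {
    stop("duplicate ratio pair(s): ",
         paste(unique(pairs[duplicated(pairs)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    tibble::tibble(name = pairs, numerator = num, denominator = den),
    class = c("ratio_spec", "tbl_df", "tbl", "data.frame")
  )
}

#' The default promoter-numerator ratio set
#'
#' All fifteen ordered ratios with a growth promoter (GA3, IAA or BR) as
#' numerator and any other hormone of the six-hormone vocabulary as
#' denominator. This is the closed superset of the ratio panels commonly
#' reported for the blue-light soybean system (GA3/SA, GA3/JA, GA3/SLs,
#' IAA/GA3, IAA/BR, IAA/SA, IAA/JA, IAA/SLs, BR/SA, BR/JA, BR/SLs, GA3/IAA,
#' GA3/BR, BR/IAA) plus BR/GA3 for closure; growth inhibitors never appear
#' as numerators.
#'
#' @return A `ratio_spec` of length 15.
#' @export
#' @examples
#' default_ratio_spec()
default_ratio_spec <- function() {
  vocab <- hormone_vocabulary()
  promoters <- c("GA3", "IAA", "BR")
  pairs <- unlist(lapply(promoters, function(num) {
    paste0(num, "/", setdiff(vocab, num))
  }))
  ratio_spec(pairs)
}

#' Build the samples x ratios feature matrix
#'
#' Computes, per sample, the concentration ratio for every pair in `spec`.
#' Row order follows `sample_order` so the matrix can be paired with a
#' height series; column order follows the spec.
#'
#' @param hormones A `hormone_table` (see [read_hormone_table()]). Every
#'   (sample, hormone) needed by the spec must be present exactly once.
#' @param spec A `ratio_spec`; defaults to [default_ratio_spec()].
#' @param sample_order Character vector of sample ids fixing row order;
#'   defaults to order of first appearance in `hormones`.
#' @return A `ratio_matrix`: a numeric matrix with `sample_order` rownames
#'   and ratio-name colnames; all entries positive and finite.
#' @export
build_ratio_matrix <- function(hormones, spec = default_ratio_spec(),
                               sample_order = NULL) {
  stopifnot(inherits(spec, "ratio_spec"))
  hormones <- tibble::as_tibble(hormones)
  if (is.null(sample_order)) sample_order <- unique(hormones$sample_id)
  needed <- unique(c(spec$numerator, spec$denominator))

  wide <- tidyr::pivot_wider(
    hormones[c("sample_id", "hormone", "concentration")],
    names_from = "hormone", values_from = "concentration"
  )
  missing_samples <- setdiff(sample_order, wide$sample_id)
  if (length(missing_samples) > 0) {
    stop("missing sample(s) in hormone table: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  wide <- wide[match(sample_order, wide$sample_id), , drop = FALSE]
  for (h in needed) {
    if (!h %in% names(wide)) {
      stop("missing hormone ", h, " for sample ", sample_order[1],
           call. = FALSE)
    }
    gaps <- which(is.na(wide[[h]]))
    if (length(gaps) > 0) {
      stop("missing hormone ", h, " for sample ",
           paste(sample_order[gaps], collapse = ", "), call. = FALSE)
    }
  }

  values <- vapply(seq_len(nrow(spec)), function(i) {
    wide[[spec$numerator[i]]] / wide[[spec$denominator[i]]]
  }, numeric(length(sample_order)))
  values <- matrix(values, nrow = length(sample_order),
                   dimnames = list(sample_order, spec$name))
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("ratio matrix contains non-positive or non-finite values",
         call. = FALSE)
  }
  structure(values, class = c("ratio_matrix", class(values)))
}
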