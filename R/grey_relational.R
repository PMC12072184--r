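# Deng's grey relational analysis.
#
# Given a parent (reference) series X_o(k) — here plant height — and named
# subfactor series X_i(k) — here hormone ratios — each series is first made
# dimensionless by dividing by its own mean:
#
#   Y(k) = X(k) / mean(X)
#
# The grey relational coefficient at point k between subfactor i and the
# parent is
#
#   delta_oi(k) = (Dmin + rho * Dmax) / (D_oi(k) + rho * Dmax)
#
# where D_oi(k) = |Y_o(k) - Y_i(k)|, Dmin and Dmax are the extrema of the
# absolute differences (by default over ALL subfactors and all k — the
# canonical two-level extremum, which makes coefficients comparable across
# subfactors), and rho in (0, 1] is the resolution coefficient,
# conventionally 0.5. The grey relational degree of subfactor i is the mean
# over k of its coefficients; subfactors are ranked by decreasing degree.

#' Grey relational analysis configuration
#'
#' @param rho Resolution coefficient, in (0, 1]; 0.5 is the conventional
#'   choice. Values above 1 are rejected unless `allow_large_rho = TRUE`
#'   (useful only for studying monotonicity in rho).
#' @param delta_scope Where the extrema Dmin/Dmax of the absolute
#'   differences are taken: `"global"` (over all subfactors and all points;
#'   the canonical definition, the default) or `"per_subfactor"` (each
#'   subfactor uses its own extrema).
#' @param allow_large_rho Permit `rho > 1` (off by default).
#' @return A `grey_config` list.
#' @export
grey_config <- function(rho = 0.5,
                        delta_scope = c("global", "per_subfactor"),
                        allow_large_rho = FALSE) {
  delta_scope <- match.arg(delta_scope)
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || rho <= 0) {
    stop("rho must be a single positive number", call. = FALSE)
  }
  if (rho > 1 && !allow_large_rho) {
    stop("rho must lie in (0, 1] (set allow_large_rho = TRUE to override)",
         call. = FALSE)
  }
  structure(list(rho = rho, delta_scope = delta_scope),
            class = "grey_config")
}

.as_positive_series <- function(x, what) {
  x <- as.numeric(x)
  if (length(x) < 1 || any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be a non-empty series of finite positive values",
         call. = FALSE)
  }
  x
}

#' Mean-value normalization of a positive series
#'
#' Divides each entry by the series mean, producing a dimensionless series
#' whose mean is exactly 1. This is the only normalization the grey
#' relational model here uses; it removes per-series scale (and hence
#' measurement units) but preserves shape.
#'
#' @param x Numeric series, all entries finite and positive.
#' @return Numeric series of the same length with mean 1.
#' @export
#' @examples
#' normalize_series(c(2, 4, 6)) # 0.5 1.0 1.5
normalize_series <- function(x) {
  x <- .as_positive_series(x, "series")
  x / mean(x)
}

.as_subfactor_matrix <- function(y_subs, m) {
  if (is.list(y_subs) && !is.data.frame(y_subs)) {
    if (is.null(names(y_subs)) || any(names(y_subs) == "")) {
      stop("subfactors must be named", call. = FALSE)
    }
    lens <- vapply(y_subs, length, integer(1))
    if (any(lens != m)) {
      stop("length mismatch: subfactor(s) ",
           paste(names(y_subs)[lens != m], collapse = ", "),
           " do not match the parent length ", m, call. = FALSE)
    }
    y_subs <- vapply(y_subs, as.numeric, numeric(m))
    if (m == 1) y_subs <- matrix(y_subs, nrow = 1,
                                 dimnames = list(NULL, names(lens)))
  }
  y_subs <- as.matrix(y_subs)
  if (nrow(y_subs) != m) {
    stop("length mismatch: subfactor matrix has ", nrow(y_subs),
         " rows, parent has ", m, call. = FALSE)
  }
  if (ncol(y_subs) == 0) stop("empty subfactor set", call. = FALSE)
  if (is.null(colnames(y_subs))) {
    stop("subfactors must be named", call. = FALSE)
  }
  y_subs
}

#' Grey relational coefficients
#'
#' Computes the absolute-difference grid `D_oi(k) = |Y_o(k) - Y_i(k)|`, its
#' extrema Dmin/Dmax, and the coefficient grid
#' `delta_oi(k) = (Dmin + rho Dmax) / (D_oi(k) + rho Dmax)` on already
#' normalized series. If Dmax is 0 (every subfactor identical to the
#' parent) every coefficient is defined as 1, the limit of vanishing
#' differences.
#'
#' @param y_o Normalized parent series.
#' @param y_subs Named list of normalized subfactor series, or an m x p
#'   matrix with column names.
#' @param cfg A [grey_config()].
#' @return List with elements `delta` (m x p matrix), `delta_min`,
#'   `delta_max` (scalars, or per-subfactor vectors when
#'   `delta_scope = "per_subfactor"`), and `coefficients` (m x p matrix,
#'   every entry in (0, 1]).
#' @export
relational_coefficients <- function(y_o, y_subs, cfg = grey_config()) {
  stopifnot(inherits(cfg, "grey_config"))
  y_o <- as.numeric(y_o)
  m <- length(y_o)
  y_subs <- .as_subfactor_matrix(y_subs, m)
  delta <- abs(y_subs - y_o)

  if (cfg$delta_scope == "global") {
    dmin <- min(delta)
    dmax <- max(delta)
    if (dmax == 0) {
      coef <- matrix(1, nrow = m, ncol = ncol(delta),
                     dimnames = dimnames(delta))
    } else {
      coef <- (dmin + cfg$rho * dmax) / (delta + cfg$rho * dmax)
    }
  } else {
    dmin <- apply(delta, 2, min)
    dmax <- apply(delta, 2, max)
    coef <- delta
    for (j in seq_len(ncol(delta))) {
      if (dmax[j] == 0) {
        coef[, j] <- 1
      } else {
        coef[, j] <- (dmin[j] + cfg$rho * dmax[j]) /
          (delta[, j] + cfg$rho * dmax[j])
      }
    }
  }
  list(delta = delta, delta_min = dmin, delta_max = dmax,
       coefficients = coef)
}

#' Grey relational degree
#'
#' The degree of each subfactor is the arithmetic mean over points k of its
#' grey relational coefficients.
#'
#' @param coefficients m x p coefficient matrix from
#'   [relational_coefficients()].
#' @return Named numeric vector of degrees, one per subfactor, each in
#'   (0, 1].
#' @export
relational_degree <- function(coefficients) {
  coefficients <- as.matrix(coefficients)
  if (length(coefficients) == 0) stop("empty coefficient grid", call. = FALSE)
  colMeans(coefficients)
}

#' Rank grey relational degrees
#'
#' Descending by degree; ties are broken by ascending subfactor name so the
#' ranking is deterministic.
#'
#' @param degrees Named numeric vector of degrees.
#' @return Named integer vector of 1-based ranks (1 = largest degree).
#' @export
rank_degrees <- function(degrees) {
  if (length(degrees) == 0) stop("no degrees to rank", call. = FALSE)
  if (is.null(names(degrees))) stop("degrees must be named", call. = FALSE)
  ord <- order(-degrees, names(degrees), method = "radix")
  ranks <- integer(length(degrees))
  ranks[ord] <- seq_along(degrees)
  stats::setNames(ranks, names(degrees))
}

#' Grey relational analysis of a parent series against named subfactors
#'
#' Composes mean-value normalization, grey relational coefficients, degrees
#' and ranks, retaining every intermediate for audit.
#'
#' @param parent Positive numeric series (e.g. plant height per sample).
#' @param subfactors Named list of positive series of the same length, or a
#'   samples x subfactors matrix with column names (e.g. a
#'   [build_ratio_matrix()] result).
#' @param cfg A [grey_config()].
#' @return A `grey_result` with elements `y_o`, `y_i`, `delta`,
#'   `delta_min`, `delta_max`, `coefficients`, `degrees`, `ranks`, `config`.
#' @export
#' @examples
#' res <- gra(c(2, 4, 6), list(f1 = c(1, 2, 3), f2 = c(3, 2, 1)))
#' res$degrees # f1 = 1, f2 = 5/9
gra <- function(parent, subfactors, cfg = grey_config()) {
  parent <- .as_positive_series(parent, "parent series")
  m <- length(parent)
  if (m < 2) stop("parent series must have length >= 2", call. = FALSE)
  subs <- .as_subfactor_matrix(subfactors, m)
  for (j in seq_len(ncol(subs))) {
    .as_positive_series(subs[, j], paste0("subfactor '", colnames(subs)[j], "'"))
  }

  y_o <- normalize_series(parent)
  y_i <- apply(subs, 2, normalize_series)
  rc <- relational_coefficients(y_o, y_i, cfg)
  degrees <- relational_degree(rc$coefficients)
  ranks <- rank_degrees(degrees)
  structure(
    list(y_o = y_o, y_i = y_i,
         delta = rc$delta, delta_min = rc$delta_min,
         delta_max = rc$delta_max, coefficients = rc$coefficients,
         degrees = degrees, ranks = ranks, config = cfg),
    class = "grey_result"
  )
}

#' @export
print.grey_result <- function(x, ...) {
  cat("Grey relational analysis (rho = ", x$config$rho,
      ", delta scope: ", x$config$delta_scope, ")\n", sep = "")
  cat("m =", length(x$y_o), "points,", length(x$degrees), "subfactors\n\n")
  ord <- order(x$ranks)
  print(data.frame(subfactor = names(x$degrees)[ord],
                   degree = round(x$degrees[ord], 4),
                   rank = unname(x$ranks[ord]),
                   row.names = NULL), ...)
  invisible(x)
}
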