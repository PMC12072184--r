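# Seeded synthetic data with the statistical structure the analysis assumes:
# two cultivars x two light treatments x six hormones, a parent plant-height
# series optionally linked to hormone ratios, and protein replicate matrices
# with planted fold changes.

#' Default per-cell hormone concentration means
#'
#' Calibration defaults on the scale of published hypocotyl hormone
#' profiles of the soybean cultivars HN60 and HN48 under darkness and
#' supplemental blue light: blue light lowers the growth promoters (GA3,
#' IAA, BR) and raises the growth inhibitors (JA, SA, SLs). Units are
#' ng g^-1 except SA (ug g^-1).
#'
#' @return Tibble with columns `cultivar`, `treatment`, `hormone`, `mean`.
#' @export
default_hormone_means <- function() {
  hormones <- hormone_vocabulary() # GA3 IAA BR SA JA SLs
  cells <- list(
    HN60_darkness = c(48.28, 55.34, 7.50, 9.47, 4.36, 128.11),
    HN60_BL       = c(41.47, 40.71, 6.19, 14.80, 5.01, 220.56),
    HN48_darkness = c(54.00, 54.87, 7.26, 10.82, 4.05, 137.70),
    HN48_BL       = c(43.71, 37.01, 5.61, 15.26, 5.58, 215.96)
  )
  dplyr::bind_rows(lapply(names(cells), function(cell) {
    parts <- strsplit(cell, "_", fixed = TRUE)[[1]]
    tibble::tibble(cultivar = parts[1], treatment = parts[2],
                   hormone = hormones, mean = cells[[cell]])
  }))
}

#' Default per-cell plant-height means (cm)
#'
#' Published-scale defaults: blue light reduces plant height by roughly
#' 64 percent in both cultivars.
#'
#' @return Tibble with columns `cultivar`, `treatment`, `mean_cm`.
#' @export
default_height_means <- function() {
  tibble::tibble(
    cultivar = c("HN60", "HN60", "HN48", "HN48"),
    treatment = c("darkness", "BL", "darkness", "BL"),
    mean_cm = c(36.90, 13.28, 38.18, 13.50)
  )
}

#' Synthetic-dataset configuration
#'
#' @param cultivars Cultivar labels (default `c("HN60", "HN48")`).
#' @param treatments Treatment labels (default `c("darkness", "BL")`).
#' @param n_per_cell Samples per cultivar x treatment cell, >= 2 (default
#'   9, giving m = 18 points per cultivar with two treatments).
#' @param hormone_means Tibble `(cultivar, treatment, hormone, mean)`;
#'   defaults to [default_hormone_means()]. Every requested cell x hormone
#'   combination must be covered.
#' @param hormone_cv Coefficient of variation of the lognormal
#'   concentration noise (default 0.05, the scale of the published
#'   SE/mean ratios).
#' @param height_means Tibble `(cultivar, treatment, mean_cm)`; defaults to
#'   [default_height_means()].
#' @param height_link Named numeric vector of ratio weights, e.g.
#'   `c("GA3/SLs" = 0.1)`: heights are multiplied by
#'   `1 + sum(w * z)` where z is the within-cell standardized value of
#'   each linked ratio, planting a height-ratio association. Default: no
#'   link.
#' @param noise_sd Additive Gaussian height noise, cm (default 1.0, the
#'   scale of published replicate SDs).
#' @param tissue Tissue label stamped on every row (default
#'   `"hypocotyl"`).
#' @param seed Integer seed; identical config + seed gives an identical
#'   dataset.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(cultivars = c("HN60", "HN48"),
                             treatments = c("darkness", "BL"),
                             n_per_cell = 9,
                             hormone_means = default_hormone_means(),
                             hormone_cv = 0.05,
                             height_means = default_height_means(),
                             height_link = NULL,
                             noise_sd = 1.0,
                             tissue = "hypocotyl",
                             seed = NULL) {
  if (!is.numeric(n_per_cell) || n_per_cell < 2) {
    stop("n_per_cell must be >= 2", call. = FALSE)
  }
  if (!is.numeric(hormone_cv) || hormone_cv < 0) {
    stop("hormone_cv must be >= 0", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  hormone_means <- tibble::as_tibble(hormone_means)
  height_means <- tibble::as_tibble(height_means)
  if (any(hormone_means$mean <= 0) || any(height_means$mean_cm <= 0)) {
    stop("configured means must be positive", call. = FALSE)
  }
  if (!is.null(height_link)) {
    if (is.null(names(height_link)) || any(names(height_link) == "")) {
      stop("height_link must be a named numeric vector of ratio weights",
           call. = FALSE)
    }
    ratio_spec(names(height_link)) # validates the ratio names
  }
  for (cv_ in cultivars) for (tr in treatments) {
    covered <- hormone_means$hormone[hormone_means$cultivar == cv_ &
                                       hormone_means$treatment == tr]
    missing <- setdiff(hormone_vocabulary(), covered)
    if (length(missing) > 0) {
      stop("hormone_means does not cover ", cv_, "/", tr, ": missing ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (!any(height_means$cultivar == cv_ & height_means$treatment == tr)) {
      stop("height_means does not cover ", cv_, "/", tr, call. = FALSE)
    }
  }
  structure(list(cultivars = cultivars, treatments = treatments,
                 n_per_cell = as.integer(n_per_cell),
                 hormone_means = hormone_means, hormone_cv = hormone_cv,
                 height_means = height_means, height_link = height_link,
                 noise_sd = noise_sd, tissue = tissue, seed = seed),
            class = "synthetic_config")
}

# Lognormal draws with a given arithmetic mean and coefficient of variation.
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.standardize_within <- function(x, group) {
  z <- numeric(length(x))
  for (g in unique(group)) {
    idx <- group == g
    s <- stats::sd(x[idx])
    z[idx] <- if (is.na(s) || s == 0) 0 else (x[idx] - mean(x[idx])) / s
  }
  z
}

.simulate_hormone_core <- function(cfg) {
  grid <- expand.grid(rep = seq_len(cfg$n_per_cell),
                      treatment = cfg$treatments,
                      cultivar = cfg$cultivars,
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_%s_%02d", grid$cultivar, grid$treatment,
                            grid$rep)
  grid$cell <- paste(grid$cultivar, grid$treatment, sep = "/")

  hormones <- dplyr::bind_rows(lapply(hormone_vocabulary(), function(h) {
    mu <- vapply(seq_len(nrow(grid)), function(i) {
      hm <- cfg$hormone_means
      hm$mean[hm$cultivar == grid$cultivar[i] &
                hm$treatment == grid$treatment[i] & hm$hormone == h][1]
    }, numeric(1))
    conc <- vapply(mu, function(m) .rlnorm_mean_cv(1, m, cfg$hormone_cv),
                   numeric(1))
    tibble::tibble(sample_id = grid$sample_id, cultivar = grid$cultivar,
                   treatment = grid$treatment, tissue = cfg$tissue,
                   hormone = h, concentration = conc)
  }))
  hormones <- as_hormone_table(hormones)

  hm <- cfg$height_means
  base <- vapply(seq_len(nrow(grid)), function(i) {
    hm$mean_cm[hm$cultivar == grid$cultivar[i] &
                 hm$treatment == grid$treatment[i]][1]
  }, numeric(1))

  mult <- rep(1, nrow(grid))
  if (!is.null(cfg$height_link) && length(cfg$height_link) > 0) {
    spec <- ratio_spec(names(cfg$height_link))
    rm_ <- build_ratio_matrix(hormones, spec, sample_order = grid$sample_id)
    for (rn in names(cfg$height_link)) {
      z <- .standardize_within(rm_[, rn], grid$cell)
      mult <- mult + cfg$height_link[[rn]] * z
    }
  }
  height_cm <- base * mult + stats::rnorm(nrow(grid), 0, cfg$noise_sd)
  if (any(height_cm <= 0)) {
    stop("simulated heights are not all positive; reduce noise_sd or ",
         "link weights", call. = FALSE)
  }
  heights <- as_height_table(tibble::tibble(
    sample_id = grid$sample_id, cultivar = grid$cultivar,
    treatment = grid$treatment, height_cm = height_cm
  ))
  list(hormones = hormones, heights = heights)
}

# Ground-truth ranking implied by the configuration alone: the grey
# relational ranking of the zero-noise dataset (cell means, no height
# noise). With a single treatment level every zero-noise series is
# constant, all degrees are 1 and the ranking is the alphabetical
# tie-break; the planted truth is then carried by the link ordering.
.planted_truth <- function(cfg, spec = default_ratio_spec()) {
  cfg0 <- cfg
  cfg0$hormone_cv <- 0
  cfg0$noise_sd <- 0
  cfg0$height_link <- NULL
  sim0 <- .simulate_hormone_core(cfg0)
  expected <- lapply(cfg$cultivars, function(cv_) {
    hsub <- sim0$heights[sim0$heights$cultivar == cv_, ]
    rmat <- build_ratio_matrix(sim0$hormones, spec,
                               sample_order = hsub$sample_id)
    res <- gra(hsub$height_cm, rmat)
    list(ranking = res$ranks, top = names(which(res$ranks == 1)),
         degrees = res$degrees)
  })
  names(expected) <- cfg$cultivars
  link_order <- if (is.null(cfg$height_link)) character(0) else
    names(sort(-abs(cfg$height_link)))
  list(link_order = link_order, expected = expected)
}

#' Simulate a hormone + height dataset with planted structure
#'
#' Concentrations are drawn lognormally around the configured cell means
#' with coefficient of variation `hormone_cv` (lognormal because
#' concentrations are strictly positive and reported as mean +/- SE).
#' Heights are the configured cell means, optionally modulated by
#' `1 + sum(w * z)` over the `height_link` ratios (z standardized within
#' each cultivar x treatment cell, so cell mean heights are preserved),
#' plus Gaussian noise. With `hormone_cv = 0` and `noise_sd = 0` every
#' value equals its configured mean exactly.
#'
#' The returned `truth` records the association structure the generator
#' planted: `link_order` (linked ratios by decreasing |weight|) and, per
#' cultivar, the zero-noise grey relational ranking implied by the
#' configured means (`expected`).
#'
#' @param cfg A [synthetic_config()].
#' @return List with `hormones` (a `hormone_table`), `heights` (a
#'   `height_table`) and `truth`.
#' @export
#' @examples
#' sim <- simulate_hormone_dataset(synthetic_config(seed = 1))
#' head(sim$hormones)
simulate_hormone_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  run <- function() .simulate_hormone_core(cfg)
  sim <- if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
  sim$truth <- .planted_truth(cfg)
  sim
}

#' Simulate protein replicate matrices with planted fold changes
#'
#' Per-protein baselines are drawn lognormally around `baseline_mean`;
#' control replicates are lognormal around the baseline with coefficient
#' of variation `cv`, and case replicates around baseline x planted fold
#' (fold 1 for unplanted proteins — the null).
#'
#' @param n_proteins Number of proteins (rows).
#' @param n_replicates Replicates per group, >= 2 (default 3, the
#'   technical-replicate convention of the proteome contrast).
#' @param planted Data frame with columns `index`, `fold` (positive), or
#'   a numeric fold vector named by row index. Default: none (all null).
#' @param cv Within-group coefficient of variation (default 0.05; the
#'   published screen detects fold changes as small as 1.25 at p = 0.001
#'   with n = 3, implying replicate CVs of a few percent).
#' @param seed Integer seed.
#' @param baseline_mean,baseline_cv Lognormal baseline abundance scale
#'   (defaults 100 and 0.5).
#' @return List with `case` and `control` matrices (proteins x
#'   replicates, rownames `P1..`) and `truth` (`up`/`down` planted index
#'   vectors and the full `fold` vector).
#' @export
simulate_protein_dataset <- function(n_proteins, n_replicates = 3,
                                     planted = NULL, cv = 0.05,
                                     seed = NULL, baseline_mean = 100,
                                     baseline_cv = 0.5) {
  if (n_proteins < 1) stop("n_proteins must be >= 1", call. = FALSE)
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  fold <- rep(1, n_proteins)
  if (!is.null(planted)) {
    if (is.data.frame(planted)) {
      idx <- planted$index; f <- planted$fold
    } else {
      idx <- as.integer(names(planted)); f <- as.numeric(planted)
    }
    if (any(is.na(idx)) || any(idx < 1) || any(idx > n_proteins)) {
      stop("planted indices out of range", call. = FALSE)
    }
    if (any(f <= 0)) stop("planted folds must be positive", call. = FALSE)
    fold[idx] <- f
  }
  run <- function() {
    baseline <- .rlnorm_mean_cv(n_proteins, baseline_mean, baseline_cv)
    control <- t(vapply(baseline, function(b)
      .rlnorm_mean_cv(n_replicates, b, cv), numeric(n_replicates)))
    case <- t(vapply(baseline * fold, function(b)
      .rlnorm_mean_cv(n_replicates, b, cv), numeric(n_replicates)))
    rownames(control) <- rownames(case) <- paste0("P", seq_len(n_proteins))
    list(case = case, control = control)
  }
  sim <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  sim$truth <- list(up = which(fold > 1), down = which(fold < 1),
                    fold = fold)
  sim
}
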