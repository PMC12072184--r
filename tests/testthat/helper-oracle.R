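# Independent naive-loop reimplementation of the grey relational model,
# used as an oracle against the package's vectorized path. Deliberately
# written with explicit loops and no shared code.

gra_naive <- function(parent, subs, rho = 0.5, scope = "global") {
  m <- length(parent)
  mean_loop <- function(x) {
    s <- 0
    for (v in x) s <- s + v
    s / length(x)
  }
  y_o <- numeric(m)
  mo <- mean_loop(parent)
  for (k in 1:m) y_o[k] <- parent[k] / mo

  p <- length(subs)
  nms <- names(subs)
  delta <- matrix(0, m, p)
  for (j in 1:p) {
    mj <- mean_loop(subs[[j]])
    for (k in 1:m) {
      yik <- subs[[j]][k] / mj
      d <- y_o[k] - yik
      if (d < 0) d <- -d
      delta[k, j] <- d
    }
  }

  degrees <- numeric(p)
  if (scope == "global") {
    dmin <- delta[1, 1]; dmax <- delta[1, 1]
    for (j in 1:p) for (k in 1:m) {
      if (delta[k, j] < dmin) dmin <- delta[k, j]
      if (delta[k, j] > dmax) dmax <- delta[k, j]
    }
    for (j in 1:p) {
      acc <- 0
      for (k in 1:m) {
        coef <- if (dmax == 0) 1 else
          (dmin + rho * dmax) / (delta[k, j] + rho * dmax)
        acc <- acc + coef
      }
      degrees[j] <- acc / m
    }
  } else {
    for (j in 1:p) {
      dmin <- delta[1, j]; dmax <- delta[1, j]
      for (k in 1:m) {
        if (delta[k, j] < dmin) dmin <- delta[k, j]
        if (delta[k, j] > dmax) dmax <- delta[k, j]
      }
      acc <- 0
      for (k in 1:m) {
        coef <- if (dmax == 0) 1 else
          (dmin + rho * dmax) / (delta[k, j] + rho * dmax)
        acc <- acc + coef
      }
      degrees[j] <- acc / m
    }
  }
  names(degrees) <- nms
  degrees
}

# Random positive GRA instance: m points, p named subfactors.
random_gra_instance <- function(seed, max_m = 18, max_p = 16) {
  set.seed(seed)
  m <- sample(3:max_m, 1)
  p <- sample(2:max_p, 1)
  list(
    parent = stats::runif(m, 0.5, 100),
    subs = stats::setNames(
      lapply(seq_len(p), function(i) stats::runif(m, 0.5, 100)),
      sprintf("f%02d", seq_len(p))
    )
  )
}

# Small valid hormone table built in code.
toy_hormone_table <- function(samples = c("s1", "s2", "s3"),
                              cultivar = "HN60", treatment = "BL") {
  set.seed(101)
  rows <- expand.grid(sample_id = samples,
                      hormone = hormone_vocabulary(),
                      stringsAsFactors = FALSE)
  rows$cultivar <- cultivar
  rows$treatment <- treatment
  rows$tissue <- "hypocotyl"
  rows$concentration <- stats::runif(nrow(rows), 1, 50)
  as_hormone_table(rows)
}
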