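write_tmp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}

test_that("hormone table reading validates schema, values and vocabulary", {
  good <- data.frame(sample_id = "s1", cultivar = "HN60", treatment = "BL",
                     tissue = "hypocotyl", hormone = "GA3",
                     concentration = 41.47)
  tab <- read_hormone_table(write_tmp_csv(good))
  expect_s3_class(tab, "hormone_table")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$concentration, 41.47)

  bad_conc <- good; bad_conc$concentration <- -1
  expect_error(read_hormone_table(write_tmp_csv(bad_conc)),
               "positive.*rows: 1")

  bad_vocab <- good; bad_vocab$hormone <- "ABA"
  expect_error(read_hormone_table(write_tmp_csv(bad_vocab)),
               "vocabulary error.*ABA")
  # but a widened vocabulary accepts it
  expect_equal(
    nrow(read_hormone_table(write_tmp_csv(bad_vocab),
                            vocabulary = c(hormone_vocabulary(), "ABA"))),
    1)

  no_col <- good[setdiff(names(good), "concentration")]
  expect_error(read_hormone_table(write_tmp_csv(no_col)),
               "schema error.*concentration")

  dup <- rbind(good, good)
  expect_error(read_hormone_table(write_tmp_csv(dup)),
               "duplicate.*rows: 2")
})

test_that("schema mapping renames file columns to canonical names", {
  df <- data.frame(id = "s1", cultivar = "HN60", treatment = "BL",
                   tissue = "hypocotyl", hormone = "GA3", conc = 41.47)
  tab <- read_hormone_table(write_tmp_csv(df),
                            schema = c(sample_id = "id",
                                       concentration = "conc"))
  expect_equal(tab$sample_id, "s1")
  expect_equal(tab$concentration, 41.47)
  expect_error(
    read_hormone_table(write_tmp_csv(df), schema = c(sample_id = "nope")),
    "schema error.*nope")
})

test_that("height table reading enforces uniqueness and positivity", {
  good <- data.frame(sample_id = "s1", cultivar = "HN60",
                     treatment = "darkness", height_cm = 36.90)
  tab <- read_height_table(write_tmp_csv(good))
  expect_equal(tab$height_cm, 36.90)

  zero <- good; zero$height_cm <- 0
  expect_error(read_height_table(write_tmp_csv(zero)), "positive")

  dup <- rbind(good, good)
  expect_error(read_height_table(write_tmp_csv(dup)), "duplicate sample_id")

  empty <- good[0, ]
  expect_warning(tab0 <- read_height_table(write_tmp_csv(empty)), "empty")
  expect_equal(nrow(tab0), 0)
})

test_that("protein table reading keeps duplicates and validates ranges", {
  good <- data.frame(ko_id = "K14508", name = "NPR1", fold_change = 1.401,
                     p_value = 0.001, regulation = "Up",
                     pathway = "Salicylic acid")
  tab <- read_protein_table(write_tmp_csv(good))
  expect_equal(tab$fold_change, 1.401)

  bad_p <- good; bad_p$p_value <- 1.5
  expect_error(read_protein_table(write_tmp_csv(bad_p)), "p_value")

  bad_fc <- good; bad_fc$fold_change <- 0
  expect_error(read_protein_table(write_tmp_csv(bad_fc)), "positive")

  dup <- rbind(good, good); dup$name <- "AOS"
  expect_equal(nrow(read_protein_table(write_tmp_csv(dup))), 2)
})

test_that("ranked-table serialization prints degrees at 4 dp with ranks", {
  res <- gra(c(2, 4, 6), list(f1 = c(1, 2, 3), f2 = c(3, 2, 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ranked_table(res, path)
  out <- utils::read.csv(path, colClasses = "character")
  expect_equal(names(out), c("ratio", "degree", "rank"))
  expect_equal(out$ratio, c("f1", "f2"))
  expect_equal(out$degree, c("1.0000", "0.5556"))
  expect_equal(out$rank, c("1", "2"))

  empty <- structure(list(degrees = stats::setNames(numeric(0), character(0)),
                          ranks = stats::setNames(integer(0), character(0))),
                     class = "grey_result")
  write_ranked_table(empty, path)
  expect_equal(nrow(utils::read.csv(path)), 0)
})

test_that("correlation results serialize with star annotations", {
  tab <- toy_hormone_table(samples = sprintf("s%d", 1:8))
  # make heights exactly proportional to the GA3/SA ratio
  wide <- tidyr::pivot_wider(tab[c("sample_id", "hormone", "concentration")],
                             names_from = "hormone",
                             values_from = "concentration")
  heights <- as_height_table(data.frame(
    sample_id = wide$sample_id, cultivar = "HN60", treatment = "BL",
    height_cm = 10 * wide$GA3 / wide$SA))
  rmat <- build_ratio_matrix(tab, ratio_spec(c("GA3/SA", "IAA/JA")),
                             sample_order = heights$sample_id)
  cres <- correlate_height_ratios(heights, rmat)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ranked_table(cres, path)
  out <- utils::read.csv(path, colClasses = "character")
  expect_true("***" %in% out$stars)
  expect_equal(out$r[out$ratio == "GA3/SA"], "1.0000")
})

test_that("write-then-read round-trips hormone and height tables", {
  sim <- simulate_hormone_dataset(synthetic_config(n_per_cell = 2, seed = 7))
  hp <- withr::local_tempfile(fileext = ".csv")
  yp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(sim$hormones, hp, row.names = FALSE)
  utils::write.csv(sim$heights, yp, row.names = FALSE)
  h2 <- read_hormone_table(hp)
  y2 <- read_height_table(yp)
  expect_equal(h2$concentration, sim$hormones$concentration, tolerance = 1e-12)
  expect_equal(y2$height_cm, sim$heights$height_cm, tolerance = 1e-12)
  expect_equal(h2$sample_id, sim$hormones$sample_id)
})
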