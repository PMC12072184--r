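# End-to-end orchestration: simulate/read -> ratios -> GRA -> Pearson ->
# DE-filter, with per-stage logging and a machine-readable report.

#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_all()]. Exactly one
#' of `paths` (CSV inputs) or `simulate` (synthetic-data settings) must be
#' given.
#'
#' @param paths List with elements `hormones`, `heights` and optionally
#'   `proteins` — CSV file paths (see [read_hormone_table()],
#'   [read_height_table()], [read_protein_table()]).
#' @param simulate List of arguments for [synthetic_config()], optionally
#'   with a `proteins` sub-list of arguments for
#'   [simulate_protein_dataset()].
#' @param ratios Character vector of `"NUM/DEN"` ratio names; defaults to
#'   [default_ratio_spec()].
#' @param gra List of arguments for [grey_config()].
#' @param de List of arguments for [de_thresholds()].
#' @param seed Integer seed applied to the simulate block (overrides any
#'   seed given there).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(paths = NULL, simulate = NULL, ratios = NULL,
                            gra = list(), de = list(), seed = NULL) {
  if (is.null(paths) == is.null(simulate)) {
    stop("config error: exactly one of 'paths' or 'simulate' must be given",
         call. = FALSE)
  }
  if (!is.null(paths) && !all(c("hormones", "heights") %in% names(paths))) {
    stop("config error: 'paths' needs elements 'hormones' and 'heights'",
         call. = FALSE)
  }
  spec <- if (is.null(ratios)) default_ratio_spec() else ratio_spec(ratios)
  sim_cfg <- NULL
  sim_proteins <- NULL
  if (!is.null(simulate)) {
    sim_proteins <- simulate$proteins
    simulate$proteins <- NULL
    if (!is.null(seed)) simulate$seed <- seed
    sim_cfg <- do.call(synthetic_config, simulate)
  }
  structure(list(paths = paths, simulate = sim_cfg,
                 simulate_proteins = sim_proteins, ratio_spec = spec,
                 grey = do.call(grey_config, gra),
                 de = do.call(de_thresholds, de), seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may contain the keys `paths`, `simulate`, `ratios`, `gra`,
#' `de` and `seed`, mirroring the arguments of [pipeline_config()].
#'
#' @param path YAML file path.
#' @param seed Optional seed overriding the file's.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  pipeline_config(
    paths = raw$paths, simulate = raw$simulate,
    ratios = if (is.null(raw$ratios)) NULL else unlist(raw$ratios),
    gra = if (is.null(raw$gra)) list() else raw$gra,
    de = if (is.null(raw$de)) list() else raw$de,
    seed = if (is.null(seed)) raw$seed else seed
  )
}

.log_line <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  writeLines(line, con)
}

#' Run the full analysis pipeline
#'
#' Simulates or reads the input tables, builds the hormone-ratio matrix,
#' and — per cultivar, mirroring the two-panel presentation conventional
#' for this system — runs grey relational analysis and Pearson
#' height-ratio correlation; if protein input is present, runs the
#' differential-protein screen. Writes, under `out_dir`:
#' `<cultivar>_ranking.csv`, `<cultivar>_correlations.csv`, optionally
#' `dep.csv`, a `pipeline.log` with one line per stage, and `report.json`
#' (config echo, seed, package version, top-3 ratios per cultivar). Any
#' stage error aborts with the stage name and removes partial outputs.
#'
#' @param config A `pipeline_config`, or a YAML file path for
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed override.
#' @return Invisibly, a list with the in-memory results (`hormones`,
#'   `heights`, `per_cultivar`, `dep`, `report`).
#' @export
run_all <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config, seed = seed)
  if (!is.null(seed) && !is.null(config$simulate)) {
    config$simulate$seed <- seed
    config$seed <- seed
  }
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wt")
  written <- c(written, log_path)
  on.exit(close(log_con), add = TRUE)

  stage <- "setup"
  result <- tryCatch({
    stage <- "input"
    truth <- NULL
    proteins <- NULL
    if (!is.null(config$simulate)) {
      sim <- simulate_hormone_dataset(config$simulate)
      hormones <- sim$hormones; heights <- sim$heights; truth <- sim$truth
      .log_line(log_con, stage, sprintf(
        "simulated %d hormone rows, %d heights (seed %s)",
        nrow(hormones), nrow(heights),
        if (is.null(config$simulate$seed)) "none" else config$simulate$seed))
      if (!is.null(config$simulate_proteins)) {
        psim <- do.call(simulate_protein_dataset, config$simulate_proteins)
        proteins <- list(case = psim$case, control = psim$control)
        .log_line(log_con, stage, sprintf(
          "simulated protein matrices: %d proteins x %d replicates",
          nrow(psim$case), ncol(psim$case)))
      }
    } else {
      hormones <- read_hormone_table(config$paths$hormones)
      heights <- read_height_table(config$paths$heights)
      .log_line(log_con, stage, sprintf("read %d hormone rows, %d heights",
                                        nrow(hormones), nrow(heights)))
      if (!is.null(config$paths$proteins)) {
        proteins <- list(records = read_protein_table(config$paths$proteins))
        .log_line(log_con, stage, sprintf("read %d protein records",
                                          nrow(proteins$records)))
      }
    }

    cultivars <- unique(heights$cultivar)
    per_cultivar <- list()
    top3 <- list()
    for (cv_ in cultivars) {
      stage <- "ratios"
      hsub <- heights[heights$cultivar == cv_, ]
      rmat <- build_ratio_matrix(hormones, config$ratio_spec,
                                 sample_order = hsub$sample_id)
      .log_line(log_con, stage, sprintf("%s: %d samples x %d ratios",
                                        cv_, nrow(rmat), ncol(rmat)))

      stage <- "gra"
      gres <- gra(hsub$height_cm, rmat, config$grey)
      rank_path <- file.path(out_dir, paste0(cv_, "_ranking.csv"))
      write_ranked_table(gres, rank_path)
      written <- c(written, rank_path)
      .log_line(log_con, stage, sprintf("%s: wrote %d ranked ratios",
                                        cv_, length(gres$degrees)))

      stage <- "correlate"
      cres <- correlate_height_ratios(hsub, rmat)
      cor_path <- file.path(out_dir, paste0(cv_, "_correlations.csv"))
      write_ranked_table(cres, cor_path)
      written <- c(written, cor_path)
      .log_line(log_con, stage, sprintf("%s: wrote %d correlations",
                                        cv_, nrow(cres)))

      per_cultivar[[cv_]] <- list(gra = gres, correlations = cres)
      top3[[cv_]] <- names(gres$ranks)[order(gres$ranks)][1:min(3, length(gres$ranks))]
    }

    dep <- NULL
    if (!is.null(proteins)) {
      stage <- "de_filter"
      dep <- if (!is.null(proteins$records)) {
        de_filter(proteins$records, config$de)
      } else {
        de_from_replicates(proteins$case, proteins$control, config$de)
      }
      dep_path <- file.path(out_dir, "dep.csv")
      utils::write.csv(dep, dep_path, row.names = FALSE, quote = TRUE,
                       fileEncoding = "UTF-8")
      written <- c(written, dep_path)
      .log_line(log_con, stage, sprintf("kept %d differential proteins",
                                        nrow(dep)))
    }

    stage <- "report"
    report <- list(
      package = "greyhormone",
      version = as.character(utils::packageVersion("greyhormone")),
      seed = config$seed,
      rho = config$grey$rho,
      delta_scope = config$grey$delta_scope,
      de_thresholds = unclass(config$de),
      ratios = config$ratio_spec$name,
      cultivars = cultivars,
      top3_ratios = top3,
      n_samples = nrow(heights),
      n_dep = if (is.null(dep)) NULL else nrow(dep),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    written <- c(written, report_path)
    .log_line(log_con, stage, "wrote report.json")

    list(hormones = hormones, heights = heights, truth = truth,
         per_cultivar = per_cultivar, dep = dep, report = report)
  }, error = function(e) {
    unlink(setdiff(written, log_path))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
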