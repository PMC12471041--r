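#' Default pipeline configuration
#'
#' A declarative run configuration: the treatments (each with its
#' calibrated generator parameters), the bootstrap replicate count, a
#' mandatory master seed, the output directory and per-stage toggles.
#' Per-stage seeds are derived from the master seed by a fixed splitting
#' rule (`seed * 131 + stage offset`, modulo 2^31 - 1) so stages can be
#' rerun in isolation.
#'
#' @param seed master seed (mandatory).
#' @param out_dir output directory.
#' @param treatments treatment labels.
#' @param n cohort size per treatment.
#' @param B bootstrap replicates.
#' @param heatmap also render the correlation heatmap image.
#' @return a named list (class `"run_config"`).
#' @export
default_run_config <- function(seed, out_dir = "twosexlt_run",
                               treatments = c("0", "3", "30", "300"),
                               n = 20L, B = 2000L, heatmap = FALSE) {
  if (missing(seed) || is.null(seed)) stop("master seed is mandatory")
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    treatments = as.character(treatments),
    n = as.integer(n),
    B = as.integer(B),
    heatmap = isTRUE(heatmap),
    stages = list(simulate = TRUE, lifetable = TRUE, bootstrap = TRUE,
                  compare = TRUE, correlate = TRUE)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unset keys fall back to [default_run_config()] values; `seed` must be
#' present in the file or supplied here.
#'
#' @param path YAML file.
#' @param seed optional master seed overriding the file.
#' @return a `"run_config"`.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (is.null(seed)) seed <- y$seed
  if (is.null(seed)) stop("master seed is mandatory (set `seed` in the config or pass --seed)")
  cfg <- default_run_config(
    seed = seed,
    out_dir = if (!is.null(y$out_dir)) y$out_dir else "twosexlt_run",
    treatments = if (!is.null(y$treatments)) as.character(y$treatments) else c("0", "3", "30", "300"),
    # the YAML key is `cohort_size`: a bare `n` key is parsed as boolean
    # FALSE under YAML 1.1 and cannot be used reliably
    n = if (!is.null(y$cohort_size)) y$cohort_size else 20L,
    B = if (!is.null(y$B)) y$B else 2000L,
    heatmap = isTRUE(y$heatmap)
  )
  if (!is.null(y$stages)) {
    for (s in names(y$stages)) cfg$stages[[s]] <- isTRUE(y$stages[[s]])
  }
  if (cfg$B < 1) stop("B must be >= 1")
  cfg
}

.stage_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 131 + offset) %% (2^31 - 1))
}

.log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> life table -> bootstrap -> group statistics ->
#' correlation as one reproducible run. Every output is a plain-text table
#' (CSV/TSV/JSON); a manifest JSON listing every file with its stage, seed
#' and content checksum is written last. The same configuration always
#' reproduces identical checksums (the heatmap image, if enabled, is listed
#' but not checksummed).
#'
#' @param config a `"run_config"` from [default_run_config()] or
#'   [read_run_config()].
#' @return the manifest, invisibly (list with `config` and `files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  add <- function(path, stage, seed = NA) {
    files[[length(files) + 1]] <<- list(
      file = basename(path), stage = stage, seed = seed,
      md5 = if (grepl("\\.png$", path)) NA_character_
            else unname(tools::md5sum(path)))
  }
  cohorts <- list()
  lts <- list()

  if (config$stages$simulate) {
    .log("simulate: ", length(config$treatments), " treatment cohorts (n = ",
         config$n, ")")
    dir.create(file.path(out, "cohorts"), showWarnings = FALSE)
    for (i in seq_along(config$treatments)) {
      trt <- config$treatments[i]
      sd_i <- .stage_seed(config$seed, i)
      co <- simulate_cohort(default_params(trt, n = config$n), seed = sd_i)
      p1 <- file.path(out, "cohorts", paste0("cohort_", trt, ".csv"))
      p2 <- file.path(out, "cohorts", paste0("fecundity_", trt, ".csv"))
      write_cohort(co, p1, p2)
      add(p1, "simulate", sd_i); add(p2, "simulate", sd_i)
      cohorts[[trt]] <- co
    }
    sd_e <- .stage_seed(config$seed, 50)
    ep <- simulate_endpoint_table(seed = sd_e)
    pe <- file.path(out, "endpoints.csv")
    utils::write.csv(ep, pe, row.names = FALSE, quote = FALSE)
    add(pe, "simulate", sd_e)
  }

  # stages rerun in isolation pick up the files of a previous run
  if (!length(cohorts) && (config$stages$lifetable || config$stages$bootstrap)) {
    for (trt in config$treatments) {
      p1 <- file.path(out, "cohorts", paste0("cohort_", trt, ".csv"))
      p2 <- file.path(out, "cohorts", paste0("fecundity_", trt, ".csv"))
      if (file.exists(p1) && file.exists(p2)) {
        cohorts[[trt]] <- read_cohort(p1, p2)
      }
    }
    if (!length(cohorts)) {
      stop("stage 'lifetable'/'bootstrap' failed: no cohorts simulated or found in ",
           file.path(out, "cohorts"))
    }
  }

  if (config$stages$lifetable) {
    .log("lifetable: computing age-stage schedules and growth parameters")
    for (trt in names(cohorts)) {
      lt <- lifetable(cohorts[[trt]])
      lts[[trt]] <- lt
      for (f in write_lifetable(lt, file.path(out, "lifetable"),
                                prefix = paste0("trt", trt))) {
        add(f, "lifetable")
      }
    }
  }

  if (config$stages$bootstrap) {
    .log("bootstrap: B = ", config$B, " individual resamples per treatment")
    dir.create(file.path(out, "bootstrap"), showWarnings = FALSE)
    for (i in seq_along(names(cohorts))) {
      trt <- names(cohorts)[i]
      sd_i <- .stage_seed(config$seed, 100 + i)
      bs <- bootstrap_lifetable(cohorts[[trt]], B = config$B, seed = sd_i,
                                keep_draws = FALSE)
      pb <- file.path(out, "bootstrap", paste0("trt", trt, "_bootstrap.tsv"))
      write_bootstrap(bs, pb)
      add(pb, "bootstrap", sd_i)
    }
  }

  if (config$stages$compare) {
    .log("compare: assumption-screened group statistics per endpoint")
    ep <- utils::read.csv(file.path(out, "endpoints.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(treatment = "character"))
    res <- compare_endpoints(ep)
    ps <- file.path(out, "comparisons.tsv")
    utils::write.table(attr(res, "summary"), ps, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    add(ps, "compare")
  }

  if (config$stages$correlate && length(lts) >= 3) {
    .log("correlate: treatment-mean Pearson matrix")
    ep <- utils::read.csv(file.path(out, "endpoints.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(treatment = "character"))
    tm <- treatment_means(ep)
    demo <- data.frame(
      r = vapply(lts, function(l) l$params$r, numeric(1)),
      F = vapply(lts, function(l) l$summary$F, numeric(1)),
      R0 = vapply(lts, function(l) l$params$R0, numeric(1)),
      ovi_days = vapply(lts, function(l) l$summary$ovi_days, numeric(1)))
    tm <- cbind(tm[names(lts), , drop = FALSE], demo[names(lts), ])
    M <- pearson_matrix(tm)
    pm <- file.path(out, "correlation.tsv")
    write_correlation(M, pm)
    add(pm, "correlate")
    if (config$heatmap) {
      ph <- file.path(out, "heatmap.png")
      export_heatmap(M, ph)
      add(ph, "correlate")
    }
  }

  manifest <- list(
    config = unclass(config)[c("seed", "treatments", "n", "B", "heatmap",
                               "stages")],
    files = files
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  .log("done: ", length(files), " output files (manifest.json written)")
  invisible(manifest)
}
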