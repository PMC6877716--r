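## Reaction-table interchange format.
##
## One row per genotyping reaction, mirroring a microfluidic platform's
## long-format "detailed results" export. RFC-4180 CSV, UTF-8, "." decimal.
## Columns: sample_id, sample_type (tissue/edna/control), extraction
## (column/chelex/none), scheme_id, assay_id, replicate, intensity_a,
## intensity_b, call. A row may omit intensities (pre-called platform
## export) or the call (to be called from intensities), but not both.

REACTION_COLUMNS <- c("sample_id", "sample_type", "extraction", "scheme_id",
                      "assay_id", "replicate", "intensity_a", "intensity_b",
                      "call")

#' Read a reaction table
#'
#' Validates while reading and fails fast: any malformed row aborts with
#' its line number(s) and no partial result. Genotype strings parse
#' case-insensitively, with `"No Call"`, `"NTC"` and the empty string
#' mapped to NOCALL; a row with neither intensities nor a call is rejected.
#'
#' @param path CSV file path.
#' @return validated reaction data.frame.
#' @export
read_reactions <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  missing <- setdiff(REACTION_COLUMNS, names(x))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- x[REACTION_COLUMNS]
  rows <- function(i) paste(i + 1L, collapse = ", ")  # data line numbers

  x$sample_type <- tolower(trimws(x$sample_type))
  bad <- which(!(x$sample_type %in% SAMPLE_TYPES))
  if (length(bad)) {
    stop("invalid sample_type at line(s) ", rows(bad), call. = FALSE)
  }
  x$extraction <- tolower(trimws(x$extraction))
  bad <- which(!(x$extraction %in% EXTRACTIONS))
  if (length(bad)) {
    stop("invalid extraction at line(s) ", rows(bad), call. = FALSE)
  }
  rep_num <- suppressWarnings(as.integer(x$replicate))
  bad <- which(is.na(rep_num) | rep_num < 1L)
  if (length(bad)) {
    stop("invalid replicate index at line(s) ", rows(bad), call. = FALSE)
  }
  x$replicate <- rep_num

  num <- function(v) suppressWarnings(as.numeric(v))
  ia <- num(x$intensity_a)
  ib <- num(x$intensity_b)
  has_int <- !is.na(ia) & !is.na(ib)
  bad <- which(has_int & (ia < 0 | ib < 0 | !is.finite(ia) | !is.finite(ib)))
  if (length(bad)) {
    stop("negative or non-finite intensities at line(s) ", rows(bad),
         call. = FALSE)
  }
  half <- which(xor(is.na(ia), is.na(ib)))
  if (length(half)) {
    stop("only one of the two intensities present at line(s) ", rows(half),
         call. = FALSE)
  }
  x$intensity_a <- ia
  x$intensity_b <- ib

  has_call <- !(is.na(x$call) | trimws(x$call) == "")
  bad <- which(!has_int & !has_call)
  if (length(bad)) {
    stop("row(s) with neither intensities nor a call at line(s) ",
         rows(bad), call. = FALSE)
  }
  x$call[has_call] <- parse_genotype(x$call[has_call])
  x$call[!has_call] <- NA_character_
  x
}

#' Write a reaction table
#'
#' Inverse of [read_reactions()]: a written table re-reads to identical
#' records.
#'
#' @param records reaction data.frame.
#' @param path output CSV path.
#' @export
write_reactions <- function(records, path) {
  utils::write.csv(records[REACTION_COLUMNS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs. With `input = NULL` the
#' pipeline generates a synthetic study from `design` and `panel`;
#' otherwise it reads the reaction CSV at `input`. A pre-called export
#' (rows with calls but no intensities) skips the calling stage
#' automatically.
#'
#' @param out_dir output directory (created if absent).
#' @param input optional reaction CSV path.
#' @param design a [study_design()] (generator settings; also validates
#'   scheme ids of an input file when supplied).
#' @param panel a [panel_spec()].
#' @param calling list of calling options: `enabled`, `k_max`, `sil_floor`,
#'   `radius_multiplier`, `nocall_radius`, `normalize` (see
#'   [call_dataset()]).
#' @param unscored_assays concordance policy, see [call_rate()].
#' @param simulation a [simulation_config()].
#' @param seed master integer seed; mandatory, every stochastic stage
#'   derives its substream from it (overrides the seeds inside `design`
#'   and `simulation`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input = NULL,
                            design = study_design(),
                            panel = default_panel(),
                            calling = list(),
                            unscored_assays = "exclude",
                            simulation = simulation_config(),
                            seed = NULL) {
  if (is.null(seed)) {
    stop("a seed is mandatory: the pipeline runs stochastic stages",
         call. = FALSE)
  }
  calling <- utils::modifyList(
    list(enabled = TRUE, k_max = 3L, sil_floor = 0.5,
         radius_multiplier = 3, nocall_radius = NULL, normalize = TRUE),
    calling)
  design$seed <- as.integer(seed)
  simulation$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, input = input, design = design,
                 panel = panel, calling = calling,
                 unscored_assays = unscored_assays,
                 simulation = simulation, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys (all optional except `seed`): `out_dir`, `input`,
#' `seed`, `n_individuals`, `n_replicates`, `n_tissue_replicates`,
#' `maf` (panel minor allele frequencies), `schemes` (list of
#' `{scheme_id, extraction, pre_sta_dilution, post_sta_dilution}`),
#' `error_models` (map scheme id to `{p_nocall, p_miscall,
#' intensity_separation, intensity_noise_sd}`), `calling` (see
#' [pipeline_config()]), `unscored_assays`, `replicate_levels`,
#' `n_scenarios`.
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when non-NULL.
#' @param seed overrides the file's `seed` when non-NULL.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  seed <- seed %||% y$seed
  panel <- if (!is.null(y$maf)) panel_spec(unlist(y$maf)) else default_panel()
  schemes <- if (!is.null(y$schemes)) {
    do.call(rbind, lapply(y$schemes, function(s)
      dilution_schemes(s$scheme_id, s$extraction,
                       s$pre_sta_dilution %||% 1, s$post_sta_dilution %||% 1)))
  } else {
    default_dilution_schemes()
  }
  ems <- if (!is.null(y$error_models)) {
    lapply(y$error_models, function(e)
      error_model(e$p_nocall %||% 0, e$p_miscall %||% 0,
                  e$intensity_separation %||% 10,
                  e$intensity_noise_sd %||% 1))
  } else {
    default_error_models()
  }
  design <- study_design(
    n_individuals = y$n_individuals %||% 6L,
    n_replicates = y$n_replicates %||% 6L,
    n_tissue_replicates = y$n_tissue_replicates %||% 3L,
    schemes = schemes, error_models = ems,
    seed = seed %||% 1L)
  pipeline_config(
    out_dir = out_dir %||% y$out_dir %||% ".",
    input = y$input,
    design = design, panel = panel,
    calling = y$calling %||% list(),
    unscored_assays = y$unscored_assays %||% "exclude",
    simulation = simulation_config(
      replicate_levels = unlist(y$replicate_levels %||% 1:3),
      n_scenarios = y$n_scenarios %||% 100L,
      seed = seed %||% 1L,
      source_replicates = y$n_replicates %||% 6L),
    seed = seed)
}

#' Replication-accuracy figure
#'
#' Per-scenario consensus accuracy by dilution scheme: one jittered point
#' per scenario at the highest simulated replication level, a black bar at
#' the scenario mean, and a red bar at the single-replicate scenario mean.
#'
#' @param sim a [run_simulation()] result.
#' @return a ggplot object.
#' @export
plot_replication_accuracy <- function(sim) {
  stopifnot(inherits(sim, "replication_sim"))
  top_r <- max(sim$summary$replicate_level)
  pts <- sim$scenarios[sim$scenarios$replicate_level == top_r, ]
  means <- sim$summary[sim$summary$replicate_level == top_r, ]
  single <- sim$summary[sim$summary$replicate_level == 1L, ]
  p <- ggplot2::ggplot(pts, ggplot2::aes(
    x = scheme_id, y = 100 * accuracy)) +
    ggplot2::geom_jitter(width = 0.2, height = 0, alpha = 0.3, size = 0.8) +
    ggplot2::geom_crossbar(
      data = means,
      ggplot2::aes(y = 100 * mean_accuracy,
                   ymin = 100 * mean_accuracy,
                   ymax = 100 * mean_accuracy),
      width = 0.6, colour = "black") +
    ggplot2::labs(
      x = "Dilution scheme",
      y = "Correct eDNA genotypes (%)",
      title = sprintf(
        "Consensus accuracy per scenario (%d replicates)", top_r)) +
    ggplot2::theme_bw()
  if (nrow(single)) {
    p <- p + ggplot2::geom_crossbar(
      data = single,
      ggplot2::aes(y = 100 * mean_accuracy,
                   ymin = 100 * mean_accuracy,
                   ymax = 100 * mean_accuracy),
      width = 0.6, colour = "red")
  }
  p
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full genotyping pipeline
#'
#' Executes generate (when no input file is configured), call, score,
#' simulate and report; writes every intermediate table as CSV, a cluster
#' model audit file, a structured log and the replication-accuracy figure
#' to `config$out_dir`. All randomness derives from the single config
#' seed, so two runs with the same config produce byte-identical CSVs.
#' While a run is in progress an `INCOMPLETE` sentinel file sits in the
#' output directory; it is removed on success.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with `records`, `called` (or NULL when calls
#'   were pre-made), `concordance`, `call_rate_summary`, `simulation`,
#'   `qc`, `truth` (when generated) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sentinel <- file.path(config$out_dir, "INCOMPLETE")
  writeLines("pipeline run in progress or aborted", sentinel)
  log_lines <- c(sprintf("pipeline seed: %d", config$seed))
  log_it <- function(...) log_lines <<- c(log_lines, sprintf(...))
  out <- function(name) file.path(config$out_dir, name)

  truth <- NULL
  if (is.null(config$input)) {
    records <- stage("generate", {
      ds <- simulate_study(config$design, config$panel)
      truth <- ds$truth
      write_reactions(ds$reactions, out("reactions.csv"))
      log_it("generate: %d reactions for %d individuals x %d SNPs x %d schemes",
             nrow(ds$reactions), config$design$n_individuals,
             config$panel$n_snps, nrow(config$design$schemes))
      ds$reactions
    })
  } else {
    records <- stage("read", {
      r <- read_reactions(config$input)
      known <- config$design$schemes$scheme_id
      unknown <- setdiff(unique(r$scheme_id), known)
      if (length(unknown)) {
        stop("unknown scheme_id in data: ", paste(unknown, collapse = ", "))
      }
      log_it("read: %d reactions from %s", nrow(r), config$input)
      r
    })
  }

  have_intensities <- !anyNA(records$intensity_a)
  called <- NULL
  if (config$calling$enabled && have_intensities) {
    called <- stage("call", {
      cd <- call_dataset(records,
                         k_max = config$calling$k_max,
                         sil_floor = config$calling$sil_floor,
                         radius_multiplier = config$calling$radius_multiplier,
                         nocall_radius = config$calling$nocall_radius,
                         normalize = config$calling$normalize,
                         seed = config$seed)
      write_reactions(cd$records, out("called_reactions.csv"))
      write_cluster_models(cd$models, out("cluster_models.yaml"))
      log_it("call: %d strata fitted, %d QC flag(s)",
             length(cd$models), nrow(cd$qc))
      cd
    })
    scored_records <- called$records
  } else {
    log_it("call: skipped (pre-made calls used)")
    scored_records <- records
  }

  conc <- stage("score", {
    ct <- suppressWarnings(
      concordance_table(scored_records,
                        unscored_assays = config$unscored_assays))
    utils::write.csv(ct, out("concordance.csv"), row.names = FALSE,
                     quote = FALSE)
    log_it("score: %d sample x scheme results", nrow(ct))
    ct
  })
  crs <- stage("score", {
    s <- summarize_call_rates(conc)
    utils::write.csv(s, out("call_rate_summary.csv"), row.names = FALSE,
                     quote = FALSE)
    log_it("score: mean call rate %.1f%% (sd %.1f, min %.1f, max %.1f)",
           s$mean_pct, s$sd_pct, s$min_pct, s$max_pct)
    s
  })

  sim <- stage("simulate", {
    s <- suppressWarnings(run_simulation(scored_records, config$simulation))
    utils::write.csv(s$scenarios, out("simulation_scenarios.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(s$summary, out("simulation_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    log_it("simulate: %d scheme x level cells, %d scenarios each",
           nrow(s$summary), config$simulation$n_scenarios)
    s
  })

  stage("report", {
    fig <- plot_replication_accuracy(sim)
    suppressMessages(ggplot2::ggsave(out("replication_accuracy.pdf"), fig,
                                     width = 7, height = 4.5))
    if (!is.null(called) && nrow(called$qc)) {
      utils::write.csv(called$qc, out("qc_flags.csv"), row.names = FALSE)
    }
    writeLines(log_lines, out("log.txt"))
  })

  unlink(sentinel)
  invisible(list(records = records, called = called, concordance = conc,
                 call_rate_summary = crs, simulation = sim,
                 qc = if (!is.null(called)) called$qc else NULL,
                 truth = truth, out_dir = config$out_dir))
}
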