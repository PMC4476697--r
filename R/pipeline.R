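# End-to-end orchestration: simulate -> design -> quantify -> respire ->
# correlate, with a serializable configuration, per-stage timing, and a
# machine-readable run report.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage's defaults filled
#' in; pass overrides as nested lists. The simulation defaults mirror the
#' study design the package models: three mtDNA targets against a nuclear
#' 16S normalizer, group means taken from the bundled reference table,
#' four animals per RNR group and five per CCI group scale, a four-step SUIT
#' plan with OXPHOS(CI+CII) 82.6 and LEAK(CI+CII) 13.97 pmol O2/s/mg, and a
#' positive delta-RQ/deficit correlation.
#'
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param output_dir Run output directory.
#' @param stages Stages to execute, in dependency order.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1, output_dir = tempfile("mitosignal_run_"),
                               stages = c("simulate", "design", "quantify",
                                          "respire", "correlate")) {
  stopifnot(.is_count(seed, min = 0))
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(
    seed = as.integer(seed),
    output_dir = output_dir,
    stages = stages,
    simulate = list(
      mito_length = 16500, nuclear_length = 200000,
      numt_specs = list(c(600, 0), c(450, 0.02), c(300, 0.05)),
      n_per_group = 4,
      cohort_n = 8, true_r = 0.8, sham_mean_flux = 82.6
    ),
    design = list(window = 100, step = 10, identity_threshold = 0.8,
                  min_region = 150),
    quantify = list(normalizer_gene = "16S", calibrator = "auto",
                    sd_limit = 0.5),
    respire = list(equilibration_s = 60, window_s = 300, smooth_window = 21),
    correlate = list(endpoint = "OXPHOS_CI+CII")
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults from
#' [default_run_config()]; the configuration round-trips losslessly through
#' serialization.
#'
#' @param path YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config(seed = user$seed %||% 1,
                            output_dir = user$output_dir %||% tempfile("mitosignal_run_"),
                            stages = user$stages %||% c("simulate", "design",
                                                        "quantify", "respire",
                                                        "correlate"))
  for (stage in c("simulate", "design", "quantify", "respire", "correlate")) {
    if (!is.null(user[[stage]])) {
      cfg[[stage]][names(user[[stage]])] <- user[[stage]]
    }
  }
  cfg
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order under
#' `config$output_dir`, writing every intermediate in the text formats of
#' [format_registry()]. Outputs carry the configuration hash and seed in the
#' run report (`report.json` plus a human-readable `summary.txt`); a stage
#' failure aborts with the stage named.
#'
#' @param config A `run_config` list from [default_run_config()] or
#'   [read_run_config()].
#' @return Invisibly, the run report list.
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(is.list(config), !is.null(config$seed), !is.null(config$output_dir))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(seed = config$seed, config_hash = .config_hash(config),
                 package_version = as.character(utils::packageVersion("mitosignal")),
                 stages = list())

  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    res$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    report$stages[[name]] <<- res
    res
  }

  if ("simulate" %in% config$stages) {
    run_stage("simulate", function() .stage_simulate(config, out_dir))
  }
  if ("design" %in% config$stages) {
    run_stage("design", function() .stage_design(config, out_dir))
  }
  if ("quantify" %in% config$stages) {
    run_stage("quantify", function() .stage_quantify(config, out_dir))
  }
  if ("respire" %in% config$stages) {
    run_stage("respire", function() .stage_respire(config, out_dir))
  }
  if ("correlate" %in% config$stages) {
    run_stage("correlate", function() .stage_correlate(config, out_dir))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(.report_summary(report), file.path(out_dir, "summary.txt"))
  invisible(report)
}

.stage_simulate <- function(config, out_dir) {
  sc <- config$simulate
  gp <- make_genome_pair(.child_seed(config$seed, 1), sc$mito_length,
                         sc$nuclear_length, sc$numt_specs)
  write_genome_fasta(gp, out_dir)
  write_numt_bed(gp$numt_truth, file.path(out_dir, "numt_truth.bed"))

  ref <- rq_reference_summary()
  gm <- data.frame(group = paste0(ref$cohort), timepoint = ref$timepoint,
                   gene = ref$gene, rq_mean = ref$mean_rq,
                   stringsAsFactors = FALSE)
  ds <- make_ct_dataset(ct_generator_params(
    gm, n_per_group = sc$n_per_group, seed = .child_seed(config$seed, 2)))
  write_ct_table(ds$ct, file.path(out_dir, "ct_table.csv"))
  jsonlite::write_json(ds$truth, file.path(out_dir, "ct_truth.json"),
                       digits = NA, dataframe = "columns")

  tr <- make_suit_trace(suit_generator_params(seed = .child_seed(config$seed, 3)))
  write_trace(tr, file.path(out_dir, "suit_trace.tsv"))
  jsonlite::write_json(attr(tr, "truth"), file.path(out_dir, "suit_truth.json"),
                       digits = NA, dataframe = "columns")

  co <- make_cohort(.child_seed(config$seed, 4), n = sc$cohort_n,
                    true_r = sc$true_r, sham_mean_flux = sc$sham_mean_flux)
  write_cohort(co, file.path(out_dir, "cohort.csv"))

  list(genomes = sprintf("mito %d bp, nuclear %d bp, %d NUMTs",
                         sc$mito_length, sc$nuclear_length, nrow(gp$numt_truth)),
       ct_rows = nrow(ds$ct), trace_samples = length(tr$time),
       cohort_n = nrow(co))
}

.stage_design <- function(config, out_dir) {
  dc <- config$design
  gp <- read_genome_fasta(file.path(out_dir, "mito.fa"),
                          file.path(out_dir, "nuclear.fa"))
  regions <- screen_unique_regions(gp, window = dc$window, step = dc$step,
                                   identity_threshold = dc$identity_threshold,
                                   min_region = dc$min_region)
  write_regions_bed(regions, file.path(out_dir, "unique_regions.bed"))
  pairs <- NULL
  if (nrow(regions)) {
    best_region <- regions[which.max(regions$length), ]
    # design within the first 1.5 kb of the widest region: amplicons are
    # 60-200 bp, so a longer tract only multiplies equivalent candidates
    design_end <- min(best_region$mito_end, best_region$mito_start + 1500)
    pairs <- tryCatch(
      suppressWarnings( # candidate thinning on long regions is expected
        design_primer_pairs(gp$mito, c(best_region$mito_start, design_end))),
      error = function(e) .empty_primer_pairs())
    if (nrow(pairs)) {
      top <- head(pairs, 20)
      spec <- do.call(rbind, lapply(seq_len(nrow(head(pairs, 3))), function(i) {
        s <- check_specificity(pairs[i, ], gp)
        s$pair_rank <- i
        s
      }))
      write.table(top, file.path(out_dir, "primer_pairs.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
      write.table(spec, file.path(out_dir, "primer_specificity.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    }
  }
  list(n_regions = nrow(regions),
       n_pairs = if (is.null(pairs)) 0L else nrow(pairs))
}

.stage_quantify <- function(config, out_dir) {
  qc <- config$quantify
  ct <- read_ct_table(file.path(out_dir, "ct_table.csv"))
  rq <- relative_quantification(ct, normalizer_gene = qc$normalizer_gene,
                                calibrator = qc$calibrator,
                                sd_limit = qc$sd_limit)
  write.csv(rq, file.path(out_dir, "rq_values.csv"), row.names = FALSE)
  pooled <- pool_rq(rq[rq$group != "calibrator", ])
  write.csv(pooled, file.path(out_dir, "rq_pooled.csv"), row.names = FALSE)
  deltas <- tryCatch(delta_rq(rq[rq$group != "calibrator", ]),
                     error = function(e) NULL)
  if (!is.null(deltas)) {
    write.csv(deltas, file.path(out_dir, "rq_deltas.csv"), row.names = FALSE)
  }
  list(n_samples = length(unique(paste(rq$animal_id, rq$timepoint))),
       pooled = pooled)
}

.stage_respire <- function(config, out_dir) {
  rc <- config$respire
  tr <- read_trace(file.path(out_dir, "suit_trace.tsv"))
  fluxes <- extract_phase_fluxes(tr, equilibration_s = rc$equilibration_s,
                                 window_s = rc$window_s,
                                 smooth_window = rc$smooth_window)
  prof <- respiratory_profile(fluxes)
  write.csv(fluxes, file.path(out_dir, "phase_fluxes.csv"), row.names = FALSE)
  jsonlite::write_json(prof[c("oxphos_ci_cii", "leak_ci_cii", "rcr", "rcr_defined")],
                       file.path(out_dir, "respiratory_profile.json"),
                       auto_unbox = TRUE, digits = NA)
  list(n_phases = nrow(fluxes), oxphos = prof$oxphos_ci_cii,
       leak = prof$leak_ci_cii, rcr = prof$rcr)
}

.stage_correlate <- function(config, out_dir) {
  cc <- config$correlate
  cohort <- read_cohort(file.path(out_dir, "cohort.csv"))
  assoc <- association_analysis(cohort, endpoint = cc$endpoint)
  res <- lapply(assoc$by_group, function(r) {
    list(r = unname(r$estimate), p = r$p.value, n = r$n,
         slope = r$slope, intercept = r$intercept)
  })
  jsonlite::write_json(res, file.path(out_dir, "association.json"),
                       auto_unbox = TRUE, digits = NA)
  p <- plot_association(assoc)
  ggplot2::ggsave(file.path(out_dir, "association.png"), p,
                  width = 6, height = 4, dpi = 150)
  list(groups = res)
}

.report_summary <- function(report) {
  lines <- c(sprintf("mitosignal run (seed %d, config %s, version %s)",
                     report$seed, report$config_hash, report$package_version))
  for (nm in names(report$stages)) {
    st <- report$stages[[nm]]
    lines <- c(lines, sprintf("- %s: done in %.3f s", nm, st$elapsed_s))
  }
  lines
}
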