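# Truth-known qPCR simulator: triplicate Ct tables for mitochondrial targets
# and a nuclear normalizer, with a calibrator sample and group-level fold
# changes, structured so the delta-delta-Ct layer can be validated exactly.

#' Parameters for the synthetic Ct table generator
#'
#' @param group_means Data frame with columns `group`, `timepoint`
#'   (`"pre"`/`"post"`), and `rq_mean` (> 0), and optionally `gene`; rows
#'   without a `gene` column apply to every target gene. `rq_mean` is the
#'   group geometric-mean relative copy number on the calibrator scale.
#' @param n_per_group Animals per group.
#' @param genes Target gene names.
#' @param normalizer Nuclear normalizer gene name.
#' @param calibrator_rq Abundance of the calibrator sample on the same scale
#'   as `rq_mean`; recorded truth RQ values are relative to it.
#' @param replicate_sd Within-triplicate Ct noise (cycles, >= 0).
#' @param animal_sd Animal-level biological spread of log2 RQ (>= 0).
#' @param sample_shift_sd Per-sample Ct shift (cycles) applied to target and
#'   normalizer alike; exercises the shift-invariance of delta Ct.
#' @param seed Integer seed.
#'
#' @return A validated parameter list of class `ct_generator_params`.
#' @export
ct_generator_params <- function(group_means, n_per_group = 4,
                                genes = c("COI-1", "COI-1A", "ND4-1"),
                                normalizer = "16S", calibrator_rq = 1,
                                replicate_sd = 0.15, animal_sd = 0.25,
                                sample_shift_sd = 0.3, seed = 1) {
  stopifnot(is.data.frame(group_means),
            all(c("group", "timepoint", "rq_mean") %in% names(group_means)))
  if (any(group_means$rq_mean <= 0)) stop("all rq_mean values must be > 0", call. = FALSE)
  if (!all(group_means$timepoint %in% c("pre", "post"))) {
    stop("group_means$timepoint must be 'pre' or 'post'", call. = FALSE)
  }
  stopifnot(.is_count(n_per_group), length(genes) >= 1,
            .is_number(calibrator_rq), calibrator_rq > 0,
            .is_number(replicate_sd), replicate_sd >= 0,
            .is_number(animal_sd), animal_sd >= 0,
            .is_number(sample_shift_sd), sample_shift_sd >= 0)
  structure(list(
    group_means = group_means, n_per_group = as.integer(n_per_group),
    genes = as.character(genes), normalizer = normalizer,
    calibrator_rq = calibrator_rq, replicate_sd = replicate_sd,
    animal_sd = animal_sd, sample_shift_sd = sample_shift_sd,
    seed = as.integer(seed)
  ), class = "ct_generator_params")
}

#' Simulate a triplicate Ct table with known relative copy numbers
#'
#' For every animal x gene x timepoint a true relative copy number is drawn
#' log2-normally around the group mean, converted into a delta-Ct offset from
#' the calibrator, and expanded into three replicate Ct values for the target
#' and three for the normalizer, with `replicate_sd` cycles of noise. The
#' calibrator sample (`animal_id = "calibrator"`) is included in the table so
#' downstream quantification can reference it explicitly. With all noise
#' terms at zero, [relative_quantification()] recovers the stored truth
#' exactly.
#'
#' @param params A [ct_generator_params()] object.
#'
#' @return An object of class `ct_dataset`: list with `ct`, a long-format
#'   data frame (`animal_id`, `group`, `timepoint`, `gene`, `replicate`,
#'   `ct`), and `truth` (`animal_id`, `group`, `timepoint`, `gene`,
#'   `true_rq`, truth RQ relative to the calibrator).
#'
#' @examples
#' gm <- data.frame(group = "RNR-6h", timepoint = c("pre", "post"),
#'                  rq_mean = c(1, 2.07))
#' ds <- make_ct_dataset(ct_generator_params(gm, n_per_group = 4, seed = 7))
#' head(ds$ct)
#' @export
make_ct_dataset <- function(params) {
  stopifnot(inherits(params, "ct_generator_params"))
  gm <- params$group_means
  has_gene <- "gene" %in% names(gm)
  genes <- params$genes
  # fixed assay baselines: per-gene delta Ct at abundance 1, normalizer Ct 20
  base_dct <- stats::setNames(2 + 0.35 * seq_along(genes), genes)
  norm_base <- 20

  withr::with_seed(params$seed, {
    ct_rows <- list()
    truth_rows <- list()
    add_sample <- function(animal_id, group, timepoint, abundance_by_gene) {
      shift <- rnorm(1, 0, params$sample_shift_sd)
      # one normalizer triplicate per sample
      ct_rows[[length(ct_rows) + 1L]] <<- data.frame(
        animal_id = animal_id, group = group, timepoint = timepoint,
        gene = params$normalizer, replicate = 1:3,
        ct = norm_base + shift + rnorm(3, 0, params$replicate_sd),
        stringsAsFactors = FALSE
      )
      for (g in genes) {
        dct <- base_dct[[g]] - log2(abundance_by_gene[[g]])
        ct_rows[[length(ct_rows) + 1L]] <<- data.frame(
          animal_id = animal_id, group = group, timepoint = timepoint,
          gene = g, replicate = 1:3,
          ct = norm_base + shift + dct + rnorm(3, 0, params$replicate_sd),
          stringsAsFactors = FALSE
        )
        truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
          animal_id = animal_id, group = group, timepoint = timepoint,
          gene = g, true_rq = abundance_by_gene[[g]] / params$calibrator_rq,
          stringsAsFactors = FALSE
        )
      }
    }

    add_sample("calibrator", "calibrator", "pre",
               stats::setNames(rep(params$calibrator_rq, length(genes)), genes))

    for (grp in unique(gm$group)) {
      for (i in seq_len(params$n_per_group)) {
        animal <- sprintf("%s_a%02d", grp, i)
        rows <- gm[gm$group == grp, , drop = FALSE]
        for (tp in unique(rows$timepoint)) {
          ab <- stats::setNames(numeric(length(genes)), genes)
          for (g in genes) {
            sub <- rows[rows$timepoint == tp, , drop = FALSE]
            if (has_gene) {
              hit <- !is.na(sub$gene) & sub$gene == g
              sub <- if (any(hit)) sub[hit, , drop = FALSE] else
                sub[is.na(sub$gene), , drop = FALSE]
            }
            if (!nrow(sub)) next
            mu <- sub$rq_mean[[1L]]
            ab[[g]] <- 2^(log2(mu) + rnorm(1, 0, params$animal_sd))
          }
          if (all(ab > 0)) add_sample(animal, grp, tp, as.list(ab))
        }
      }
    }

    ct <- do.call(rbind, ct_rows)
    truth <- do.call(rbind, truth_rows)
    rownames(ct) <- rownames(truth) <- NULL
    if (any(ct$ct <= 0 | ct$ct >= 45)) {
      stop("simulated Ct values left the plausible (0, 45) range; revisit parameters",
           call. = FALSE)
    }
    structure(list(ct = ct, truth = truth, params = params), class = "ct_dataset")
  })
}

#' @export
print.ct_dataset <- function(x, ...) {
  cat(sprintf("ct_dataset: %d samples x %d genes, %d Ct rows (triplicates)\n",
              length(unique(paste(x$ct$animal_id, x$ct$timepoint))),
              length(x$params$genes), nrow(x$ct)))
  invisible(x)
}
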