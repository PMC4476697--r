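# Comparative-Ct (delta-delta-Ct) relative quantification: triplicate
# collapsing with quality flags, RQ against a nuclear normalizer and a
# calibrator sample, group pooling, and per-animal pre/post deltas.

.CT_KEY <- c("animal_id", "group", "timepoint", "gene")

.validate_ct_table <- function(ct) {
  need <- c(.CT_KEY, "replicate", "ct")
  missing <- setdiff(need, names(ct))
  if (length(missing)) {
    stop("Ct table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(ct$ct) || any(!is.finite(ct$ct))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(ct$ct))))
    stop("non-numeric or missing Ct value(s) at row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(ct$ct <= 0 | ct$ct >= 45)) {
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  }
  invisible(ct)
}

#' Collapse replicate Ct measurements
#'
#' Averages the replicates of every animal x timepoint x gene cell and flags
#' (never drops) cells whose replicate standard deviation exceeds
#' `sd_limit` -- outliers stay visible for audit.
#'
#' @param ct Long-format Ct table with columns `animal_id`, `group`,
#'   `timepoint`, `gene`, `replicate`, `ct`.
#' @param sd_limit Replicate SD (cycles) above which a cell is flagged.
#' @param n_replicates Required replicate count per cell (assay standard: 3).
#' @return Data frame with one row per cell: key columns plus `mean_ct`,
#'   `sd_ct`, `n`, `flagged`.
#' @export
collapse_replicates <- function(ct, sd_limit = 0.5, n_replicates = 3) {
  .validate_ct_table(ct)
  key <- interaction(ct[.CT_KEY], drop = TRUE, sep = "\r")
  n_by <- tapply(ct$ct, key, length)
  if (any(n_by != n_replicates)) {
    bad <- names(n_by)[n_by != n_replicates]
    stop(sprintf("expected exactly %d replicates; offending cell(s): %s",
                 n_replicates,
                 paste(gsub("\r", "/", head(bad, 5)), collapse = "; ")),
         call. = FALSE)
  }
  agg <- aggregate(ct["ct"], ct[.CT_KEY], function(x) c(mean(x), sd(x), length(x)))
  out <- data.frame(agg[.CT_KEY],
                    mean_ct = agg$ct[, 1], sd_ct = agg$ct[, 2],
                    n = as.integer(agg$ct[, 3]),
                    stringsAsFactors = FALSE)
  out$flagged <- out$sd_ct > sd_limit
  out[order(out$animal_id, out$timepoint, out$gene), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}

#' Relative mtDNA copy number by comparative Ct
#'
#' Computes, per sample and target gene,
#' `dCt = Ct_target - Ct_normalizer`,
#' `ddCt = dCt_sample - dCt_calibrator`, and `RQ = efficiency^(-ddCt)`
#' (efficiency 2 = perfect doubling). The calibrator reference `dCt` per
#' gene is either taken from an explicit sample (`calibrator = <animal_id>`)
#' or, with `calibrator = "auto"`, set to the mean `dCt` of all pre-injury
#' samples so that pre-injury RQ centres near 1. RQ is invariant under any
#' constant shift of a sample's Ct values, and the explicit calibrator's own
#' RQ is exactly 1 for every gene.
#'
#' @inheritParams collapse_replicates
#' @param normalizer_gene Nuclear normalizer gene name.
#' @param calibrator `"auto"` or the `animal_id` of the reference sample.
#' @param efficiency Amplification efficiency (fold change per cycle).
#' @return Data frame of class `rq_values`: key columns plus `dct`, `ddct`,
#'   `rq`, `flagged` (replicate-quality flag of target or normalizer).
#' @export
relative_quantification <- function(ct, normalizer_gene = "16S",
                                    calibrator = "auto", sd_limit = 0.5,
                                    efficiency = 2) {
  stopifnot(.is_number(efficiency), efficiency > 1)
  coll <- collapse_replicates(ct, sd_limit = sd_limit)
  norm <- coll[coll$gene == normalizer_gene, , drop = FALSE]
  targ <- coll[coll$gene != normalizer_gene, , drop = FALSE]
  if (!nrow(norm)) {
    stop(sprintf("normalizer gene '%s' absent from the table", normalizer_gene),
         call. = FALSE)
  }
  skey <- function(d) paste(d$animal_id, d$timepoint, sep = "\r")
  norm_ct <- stats::setNames(norm$mean_ct, skey(norm))
  norm_flag <- stats::setNames(norm$flagged, skey(norm))
  miss <- setdiff(unique(skey(targ)), names(norm_ct))
  if (length(miss)) {
    stop("sample(s) missing normalizer Ct: ",
         paste(gsub("\r", "/", miss), collapse = "; "), call. = FALSE)
  }
  targ$dct <- targ$mean_ct - norm_ct[skey(targ)]
  targ$flagged <- targ$flagged | norm_flag[skey(targ)]

  genes <- unique(targ$gene)
  if (identical(calibrator, "auto")) {
    pre <- targ[targ$timepoint == "pre", , drop = FALSE]
    if (!nrow(pre)) stop("no pre-injury samples available for the auto calibrator",
                         call. = FALSE)
    ref <- tapply(pre$dct, pre$gene, mean)
  } else {
    cal <- targ[targ$animal_id == calibrator, , drop = FALSE]
    miss <- setdiff(genes, unique(cal$gene))
    if (!nrow(cal) || length(miss)) {
      stop(sprintf("calibrator '%s' missing for gene(s): %s", calibrator,
                   paste(if (nrow(cal)) miss else genes, collapse = ", ")),
           call. = FALSE)
    }
    ref <- tapply(cal$dct, cal$gene, mean)
  }
  targ$ddct <- targ$dct - as.numeric(ref[targ$gene])
  targ$rq <- efficiency^(-targ$ddct)
  out <- targ[, c(.CT_KEY, "mean_ct", "sd_ct", "dct", "ddct", "rq", "flagged")]
  rownames(out) <- NULL
  class(out) <- c("rq_values", "data.frame")
  out
}

#' Pool relative copy numbers into group summaries
#'
#' Pools RQ values over all gene x animal entries of each group (each
#' gene x animal contributes one value) and reports mean, SEM
#' (`sd/sqrt(n)`, sample SD; 0 when `n = 1`) and n.
#'
#' @param rq An `rq_values` data frame (or any data frame with an `rq`
#'   column and the grouping columns).
#' @param by Character vector of grouping columns.
#' @return Data frame with `label`, `mean`, `sem`, `n`.
#' @export
pool_rq <- function(rq, by = c("group", "timepoint")) {
  stopifnot(is.data.frame(rq), "rq" %in% names(rq), all(by %in% names(rq)))
  if (!nrow(rq)) stop("cannot pool an empty set of RQ values", call. = FALSE)
  key <- interaction(rq[by], drop = TRUE, sep = " / ")
  out <- do.call(rbind, lapply(levels(key), function(lv) {
    v <- rq$rq[key == lv]
    data.frame(label = lv, mean = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pool published group means weighted by group size
#'
#' Reproduces pooled summary levels from per-gene group means: each
#' gene x group mean enters with weight equal to the number of animals in
#' its group, i.e. `sum(mean * n_animals) / sum(n_animals)` over the rows.
#'
#' @param summary_df Data frame with columns `mean_rq` and `n_animals`
#'   (one row per gene x group).
#' @return List with `mean` (the pooled value) and `n` (total gene x animal
#'   values pooled).
#' @export
pool_group_means <- function(summary_df) {
  stopifnot(is.data.frame(summary_df),
            all(c("mean_rq", "n_animals") %in% names(summary_df)),
            nrow(summary_df) >= 1)
  list(mean = stats::weighted.mean(summary_df$mean_rq, summary_df$n_animals),
       n = sum(summary_df$n_animals))
}

#' Per-animal pre-to-post RQ deltas
#'
#' Matches pre and post RQ values on animal x gene and returns
#' `delta = post - pre`. Unmatched keys are reported in the
#' `unmatched` attribute (with a warning); no matches at all is an error.
#'
#' @param rq An `rq_values` data frame containing both timepoints.
#' @return Data frame `animal_id`, `group`, `gene`, `pre`, `post`, `delta`.
#' @export
delta_rq <- function(rq) {
  stopifnot(is.data.frame(rq), all(c(.CT_KEY, "rq") %in% names(rq)))
  pre <- rq[rq$timepoint == "pre", c("animal_id", "group", "gene", "rq")]
  post <- rq[rq$timepoint == "post", c("animal_id", "gene", "rq")]
  names(pre)[4] <- "pre"; names(post)[3] <- "post"
  m <- merge(pre, post, by = c("animal_id", "gene"))
  if (!nrow(m)) stop("no animal x gene keys with both pre and post values",
                     call. = FALSE)
  m$delta <- m$post - m$pre
  all_keys <- unique(rbind(pre[c("animal_id", "gene")], post[c("animal_id", "gene")]))
  un <- all_keys[!paste(all_keys$animal_id, all_keys$gene) %in%
                   paste(m$animal_id, m$gene), , drop = FALSE]
  if (nrow(un)) {
    warning(sprintf("%d animal x gene key(s) lacked a matching timepoint", nrow(un)))
  }
  m <- m[order(m$animal_id, m$gene), c("animal_id", "group", "gene", "pre", "post", "delta")]
  rownames(m) <- NULL
  attr(m, "unmatched") <- un
  m
}

#' Bundled reference table of group-level RQ summaries
#'
#' Group-mean relative mtDNA copy numbers (with SEM and group sizes) for a
#' porcine TBI cohort measured with this assay design: three mitochondrial
#' targets, pre-injury and post-injury, for diffuse rotational (RNR, 6 h and
#' 25 h survival) and focal impact (CCI, 25 h) injuries. Shipped so pooled
#' reference levels can be recomputed without external data.
#'
#' @return Data frame with columns `cohort`, `timepoint`, `gene`, `mean_rq`,
#'   `sem_rq`, `n_animals`.
#' @export
rq_reference_summary <- function() {
  path <- system.file("extdata", "rq_group_means.csv", package = "mitosignal",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Pooled reference RQ levels
#'
#' Applies [pool_group_means()] to the bundled [rq_reference_summary()]
#' table: all nine pre-injury gene x group means pooled together (weighted
#' by group size), and each post-injury cohort x timepoint pooled across its
#' three genes.
#'
#' @return Data frame with `label`, `mean`, `n`.
#' @export
pooled_reference_rq <- function() {
  s <- rq_reference_summary()
  pre <- pool_group_means(s[s$timepoint == "pre", ])
  rows <- list(data.frame(label = "pre-injury (all cohorts)",
                          mean = pre$mean, n = pre$n, stringsAsFactors = FALSE))
  post <- s[s$timepoint == "post", ]
  for (ch in unique(post$cohort)) {
    p <- pool_group_means(post[post$cohort == ch, ])
    rows[[length(rows) + 1L]] <- data.frame(
      label = paste0(ch, " post-injury"), mean = p$mean, n = p$n,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
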