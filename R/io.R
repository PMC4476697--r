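# File-format layer: FASTA via Biostrings, BED6 via rtracklayer (0-based
# half-open at the interface), strict CSV/TSV dialects with line-numbered
# errors, and JSON sidecars. The '.' token denotes a missing value in
# text tables.

#' Write / read genome FASTA files
#'
#' Sequences are wrapped at 60 columns. `write_genome_fasta` writes the
#' mitochondrial and nuclear sequences of a [make_genome_pair()] object to
#' `mito.fa` and `nuclear.fa` under `dir`.
#'
#' @param genomes A `genome_pair` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_genome_fasta <- function(genomes, dir) {
  stopifnot(inherits(genomes, "genome_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(mito = file.path(dir, "mito.fa"), nuclear = file.path(dir, "nuclear.fa"))
  Biostrings::writeXStringSet(genomes$mito, paths[["mito"]], width = 60)
  Biostrings::writeXStringSet(genomes$nuclear, paths[["nuclear"]], width = 60)
  invisible(paths)
}

#' @rdname write_genome_fasta
#' @param mito_fa,nuclear_fa FASTA paths.
#' @export
read_genome_fasta <- function(mito_fa, nuclear_fa) {
  structure(list(
    mito = Biostrings::readDNAStringSet(mito_fa),
    nuclear = Biostrings::readDNAStringSet(nuclear_fa),
    numt_truth = NULL, seed = NA_integer_
  ), class = "genome_pair")
}

#' Write / read interval tables as BED6
#'
#' Coordinates are 0-based half-open at the package interface, matching BED
#' natively. NUMT truth tables use the interval name to carry the source
#' mitochondrial interval and the score column for divergence in permille.
#'
#' @param truth A `numt_truth` data frame from [make_genome_pair()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_numt_bed <- function(truth, file) {
  gr <- GenomicRanges::GRanges(
    seqnames = truth$contig_id,
    ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end),
    strand = truth$strand
  )
  names(gr) <- sprintf("numt_%d|mito:%d-%d", seq_len(nrow(truth)),
                       truth$mito_start, truth$mito_end)
  GenomicRanges::mcols(gr)$score <- round(truth$divergence * 1000)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname write_numt_bed
#' @export
read_numt_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  nm <- if (!is.null(gr$name)) gr$name else names(gr)
  mito <- regmatches(nm, regexec("mito:(\\d+)-(\\d+)", nm))
  data.frame(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    mito_start = vapply(mito, function(m) as.integer(m[2]), integer(1)),
    mito_end = vapply(mito, function(m) as.integer(m[3]), integer(1)),
    strand = as.character(GenomicRanges::strand(gr)),
    divergence = gr$score / 1000,
    stringsAsFactors = FALSE
  )
}

#' Write unique regions as BED6
#'
#' @param regions A [screen_unique_regions()] result.
#' @param file Output path.
#' @param mito_name Sequence name for the BED chrom column.
#' @export
write_regions_bed <- function(regions, file, mito_name = "chrM") {
  gr <- GenomicRanges::GRanges(
    seqnames = mito_name,
    ranges = IRanges::IRanges(start = regions$mito_start + 1L,
                              end = regions$mito_end),
    strand = "+"
  )
  names(gr) <- sprintf("unique_region_%d", seq_len(nrow(regions)))
  GenomicRanges::mcols(gr)$score <-
    round(pmin(1, regions$max_nuclear_identity) * 1000)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

.read_text_table <- function(file, sep, required, numeric_cols) {
  df <- tryCatch(
    read.delim(file, sep = sep, stringsAsFactors = FALSE,
               na.strings = ".", check.names = FALSE),
    error = function(e) stop(sprintf("%s: parse error: %s", file, conditionMessage(e)),
                             call. = FALSE)
  )
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", file, paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad)) {
        stop(sprintf("%s: non-numeric value in column '%s' at data row(s) %s",
                     file, col, paste(head(bad, 5), collapse = ", ")),
             call. = FALSE)
      }
      df[[col]] <- vn
    }
    na_rows <- which(is.na(df[[col]]))
    if (length(na_rows)) {
      stop(sprintf("%s: missing value in required column '%s' at data row(s) %s",
                   file, col, paste(head(na_rows, 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  df
}

#' Write / read the long-format Ct table CSV
#'
#' Columns: `animal_id`, `group`, `timepoint`, `gene`, `replicate`, `ct`.
#' Parsing is strict: missing or non-numeric Ct cells raise an error naming
#' the offending row.
#'
#' @param ct Ct data frame (e.g. `make_ct_dataset(...)$ct`).
#' @param file Path.
#' @export
write_ct_table <- function(ct, file) {
  .validate_ct_table(ct)
  write.csv(ct, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(file) {
  df <- .read_text_table(file, ",",
                         required = c(.CT_KEY, "replicate", "ct"),
                         numeric_cols = c("replicate", "ct"))
  .validate_ct_table(df)
  df
}

#' Write / read oxygraph traces as TSV
#'
#' Columns: `time_s`, `o2_uM`, `event` (titration label at phase starts,
#' `.` elsewhere). Chamber metadata (sample concentration, temperature,
#' solubility factor) travels in a JSON sidecar `<file>.meta.json`.
#'
#' @param trace An [oxygraph_trace()] object.
#' @param file Path of the TSV.
#' @export
write_trace <- function(trace, file) {
  stopifnot(inherits(trace, "oxygraph_trace"))
  ev <- rep(".", length(trace$time))
  if (nrow(trace$events)) {
    idx <- vapply(trace$events$time, function(t) which.min(abs(trace$time - t)),
                  integer(1))
    ev[idx] <- trace$events$label
  }
  df <- data.frame(time_s = trace$time, o2_uM = trace$o2, event = ev)
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(sample_conc = trace$sample_conc, temperature = trace$temperature,
         solubility_factor = trace$solubility_factor),
    paste0(file, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_trace
#' @param sample_conc,temperature,solubility_factor Chamber metadata used
#'   when no sidecar is present.
#' @export
read_trace <- function(file, sample_conc = 1, temperature = 37,
                       solubility_factor = 0.92) {
  df <- .read_text_table(file, "\t", required = c("time_s", "o2_uM", "event"),
                         numeric_cols = c("time_s", "o2_uM"))
  meta_file <- paste0(file, ".meta.json")
  if (file.exists(meta_file)) {
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    sample_conc <- meta$sample_conc %||% sample_conc
    temperature <- meta$temperature %||% temperature
    solubility_factor <- meta$solubility_factor %||% solubility_factor
  }
  has_ev <- !is.na(df$event) & df$event != "."
  oxygraph_trace(
    time = df$time_s, o2 = df$o2_uM,
    events = data.frame(time = df$time_s[has_ev], label = df$event[has_ev],
                        stringsAsFactors = FALSE),
    sample_conc = sample_conc, temperature = temperature,
    solubility_factor = solubility_factor
  )
}

#' Write / read the cohort sheet CSV
#'
#' Columns: `animal_id`, `group`, `endpoint`, `delta_rq`, `post_resp`,
#' `sham_mean`. The respiration deficit is always recomputed as
#' `sham_mean - post_resp`, never stored.
#'
#' @param cohort Cohort data frame.
#' @param file Path.
#' @export
write_cohort <- function(cohort, file) {
  need <- c("animal_id", "group", "endpoint", "delta_rq", "post_resp", "sham_mean")
  stopifnot(all(need %in% names(cohort)))
  write.csv(as.data.frame(cohort)[need], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  .read_text_table(file, ",",
                   required = c("animal_id", "group", "endpoint", "delta_rq",
                                "post_resp", "sham_mean"),
                   numeric_cols = c("delta_rq", "post_resp", "sham_mean"))
}

#' Registry of the file formats the pipeline speaks
#'
#' @return Data frame listing each format with its reader and writer.
#' @export
format_registry <- function() {
  data.frame(
    format = c("FASTA (60-col)", "BED6 (0-based half-open)", "Ct table CSV",
               "oxygraph TSV + JSON sidecar", "cohort CSV", "JSON"),
    reader = c("read_genome_fasta", "read_numt_bed", "read_ct_table",
               "read_trace", "read_cohort", "jsonlite::read_json"),
    writer = c("write_genome_fasta", "write_numt_bed/write_regions_bed",
               "write_ct_table", "write_trace", "write_cohort",
               "jsonlite::write_json"),
    stringsAsFactors = FALSE
  )
}
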