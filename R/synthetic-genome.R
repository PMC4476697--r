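# Truth-known genome simulator: a random circular mitochondrial genome plus
# nuclear contigs carrying planted, partially diverged mtDNA insertions
# (NUMTs). Used to validate the uniqueness screen against a known answer.

#' Simulate a mitochondrial/nuclear genome pair with planted NUMTs
#'
#' Generates a random-composition circular mitochondrial genome and a nuclear
#' contig into which copies of randomly chosen mitochondrial intervals are
#' planted (substitution-only divergence, both strands). Each planted segment
#' replaces the nuclear bases at a non-overlapping locus, so the contig
#' length is unchanged. The returned truth table describes every planted
#' edit exactly.
#'
#' @param seed Integer seed; the generator is a pure function of `seed` and
#'   its parameters.
#' @param mito_length Length of the mitochondrial genome in bases.
#' @param nuclear_length Length of the nuclear contig in bases.
#' @param numt_specs List of NUMT specifications. Each element is either a
#'   numeric vector `c(length, divergence)` or a list with elements `length`,
#'   `divergence`, and optionally `strand` (`"+"` or `"-"`; random when
#'   omitted). `divergence` is the fraction of substituted bases in `[0, 1]`;
#'   exactly `round(length * divergence)` positions are substituted.
#' @param contig_id Name of the nuclear contig.
#'
#' @return An object of class `genome_pair`: a list with elements
#'   `mito` (a named [Biostrings::DNAStringSet] of length 1), `nuclear`
#'   (a [Biostrings::DNAStringSet]), and `numt_truth`, a data frame with
#'   columns `contig_id`, `start`, `end` (0-based half-open on the contig),
#'   `mito_start`, `mito_end` (source interval), `strand`, `divergence`, and
#'   `n_sub`, sorted by position.
#'
#' @examples
#' gp <- make_genome_pair(1, mito_length = 2000, nuclear_length = 10000,
#'                        numt_specs = list(c(300, 0.02)))
#' gp$numt_truth
#' @export
make_genome_pair <- function(seed, mito_length = 16500, nuclear_length = 200000,
                             numt_specs = list(), contig_id = "nuc1") {
  stopifnot(.is_count(seed, min = 0), .is_count(mito_length), .is_count(nuclear_length))
  specs <- lapply(numt_specs, .normalize_numt_spec)
  lens <- vapply(specs, `[[`, numeric(1), "length")
  if (length(lens) && max(lens) > mito_length) {
    stop("NUMT length exceeds the mitochondrial genome length", call. = FALSE)
  }
  if (sum(lens) > nuclear_length) {
    stop("infeasible NUMT packing: combined NUMT length exceeds the nuclear contig",
         call. = FALSE)
  }

  withr::with_seed(as.integer(seed), {
    mito <- .random_dna(mito_length)
    nuclear <- .random_dna(nuclear_length)

    truth <- vector("list", length(specs))
    occupied <- matrix(numeric(0), ncol = 2) # existing [start, end) intervals
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      L <- sp$length
      mito_start <- sample.int(mito_length - L + 1L, 1L) - 1L
      fragment <- substr(mito, mito_start + 1L, mito_start + L)
      strand <- sp$strand
      if (is.na(strand)) strand <- sample(c("+", "-"), 1L)
      if (strand == "-") fragment <- .revcomp(fragment)

      n_sub <- round(L * sp$divergence)
      if (n_sub > 0) {
        ch <- strsplit(fragment, "", fixed = TRUE)[[1L]]
        pos <- sample.int(L, n_sub)
        for (p in pos) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        }
        fragment <- paste(ch, collapse = "")
      }

      start <- .place_interval(nuclear_length, L, occupied)
      if (is.na(start)) {
        stop(sprintf("infeasible NUMT packing: could not place NUMT %d (length %d) without overlap",
                     i, L), call. = FALSE)
      }
      occupied <- rbind(occupied, c(start, start + L))
      substr(nuclear, start + 1L, start + L) <- fragment
      truth[[i]] <- data.frame(
        contig_id = contig_id, start = start, end = start + L,
        mito_start = mito_start, mito_end = mito_start + L,
        strand = strand, divergence = sp$divergence, n_sub = n_sub,
        stringsAsFactors = FALSE
      )
    }
    truth <- if (length(truth)) do.call(rbind, truth) else data.frame(
      contig_id = character(), start = integer(), end = integer(),
      mito_start = integer(), mito_end = integer(), strand = character(),
      divergence = numeric(), n_sub = integer(), stringsAsFactors = FALSE
    )
    truth <- truth[order(truth$contig_id, truth$start), , drop = FALSE]
    rownames(truth) <- NULL

    structure(list(
      mito = Biostrings::DNAStringSet(stats::setNames(mito, "chrM")),
      nuclear = Biostrings::DNAStringSet(stats::setNames(nuclear, contig_id)),
      numt_truth = truth,
      seed = as.integer(seed)
    ), class = "genome_pair")
  })
}

.normalize_numt_spec <- function(sp) {
  if (is.numeric(sp) && length(sp) == 2L) {
    sp <- list(length = sp[[1L]], divergence = sp[[2L]])
  }
  if (!is.list(sp) || is.null(sp$length) || is.null(sp$divergence)) {
    stop("each NUMT spec must be c(length, divergence) or list(length=, divergence=)",
         call. = FALSE)
  }
  if (!.is_count(sp$length)) stop("NUMT length must be a positive integer", call. = FALSE)
  if (!.is_number(sp$divergence) || sp$divergence < 0 || sp$divergence > 1) {
    stop("NUMT divergence must lie in [0, 1]", call. = FALSE)
  }
  sp$strand <- if (is.null(sp$strand)) NA_character_ else match.arg(sp$strand, c("+", "-"))
  sp$length <- as.integer(sp$length)
  sp
}

# Rejection-sample a 0-based start for an interval of length L avoiding
# existing [start, end) rows; NA when no placement is found.
.place_interval <- function(total, L, occupied, max_tries = 2000L) {
  for (t in seq_len(max_tries)) {
    s <- sample.int(total - L + 1L, 1L) - 1L
    if (!nrow(occupied) ||
        all(s + L <= occupied[, 1L] | s >= occupied[, 2L])) {
      return(s)
    }
  }
  NA_integer_
}

#' @export
print.genome_pair <- function(x, ...) {
  cat(sprintf("genome_pair: mito %d bp (circular), %d nuclear contig(s) totalling %d bp, %d planted NUMT(s)\n",
              Biostrings::width(x$mito)[1L], length(x$nuclear),
              sum(Biostrings::width(x$nuclear)), nrow(x$numt_truth)))
  invisible(x)
}
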