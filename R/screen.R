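# mtDNA uniqueness screen: find regions of the circular mitochondrial genome
# with no near-identical nuclear copy (NUMT-free), by exact k-mer seeding and
# ungapped window extension against both strands of every nuclear contig.

#' Screen the mitochondrial genome for NUMT-free regions
#'
#' Slides windows of `window` bases (step `step`) over the circular
#' mitochondrial genome and, for each, finds the best ungapped full-window
#' identity against any position of any nuclear contig, on either strand.
#' Candidate alignments are located by exact `k`-mer seeding; a window with
#' no seed hit is scored 0 (its true best identity is necessarily far below
#' any useful threshold). Unique regions are the maximal stretches of the
#' circle not covered by any window whose identity reaches
#' `identity_threshold`, so no returned region overlaps a NUMT-like segment.
#'
#' With an empty nuclear genome the entire mitochondrial genome is returned
#' as a single region (documented behaviour, not an error).
#'
#' @param genomes A [make_genome_pair()] object, or any list with elements
#'   `mito` and `nuclear` coercible to sequences.
#' @param window Window length in bases (>= 15; must not exceed the
#'   mitochondrial genome length).
#' @param step Step between window starts.
#' @param identity_threshold Fraction; a window whose best nuclear identity
#'   reaches this value is considered NUMT-like.
#' @param min_region Minimum region length (bases) to report.
#' @param k Seed k-mer length (<= window).
#'
#' @return Data frame of class `unique_regions` with columns `mito_start`,
#'   `mito_end` (0-based half-open, never exceeding the genome length),
#'   `length`, `max_nuclear_identity` (highest identity among windows
#'   starting inside the region; a seeded lower bound, approximately the
#'   random background when no NUMT is near), and `origin_wrap` (`TRUE` for
#'   the two rows of a region spanning the circular origin).
#'
#' @examples
#' gp <- make_genome_pair(1, mito_length = 2000, nuclear_length = 8000,
#'                        numt_specs = list(c(400, 0)))
#' screen_unique_regions(gp, window = 100, step = 10)
#' @export
screen_unique_regions <- function(genomes, window = 100, step = 10,
                                  identity_threshold = 0.8, min_region = 100,
                                  k = 15) {
  mito <- .as_dna_string(genomes$mito, "mito")
  L <- nchar(mito)
  if (!.is_count(window) || window < 15) stop("'window' must be >= 15", call. = FALSE)
  if (window > L) stop("'window' exceeds the mitochondrial genome length", call. = FALSE)
  if (!.is_number(identity_threshold) || identity_threshold <= 0 || identity_threshold > 1) {
    stop("'identity_threshold' must be in (0, 1]", call. = FALSE)
  }
  stopifnot(.is_count(step), .is_count(k), k <= window)

  subjects <- .nuclear_strands(genomes$nuclear)
  starts0 <- seq.int(0L, L - 1L, by = step) # 0-based window starts
  best <- numeric(length(starts0))

  mext <- paste0(mito, substr(mito, 1L, window - 1L)) # circular extension
  mv <- strsplit(mext, "", fixed = TRUE)[[1L]]
  mk <- substring(mext, seq_len(L), seq_len(L) + k - 1L)

  for (subj in subjects) {
    ids <- .window_identities(mv, mk, subj, starts0, window, k)
    best <- pmax(best, ids)
  }

  above <- best >= identity_threshold
  covered <- logical(L)
  for (s in starts0[above]) {
    covered[(s + seq_len(window) - 1L) %% L + 1L] <- TRUE
  }

  regions <- .circular_uncovered_runs(covered, min_region)
  if (nrow(regions)) {
    regions$max_nuclear_identity <- vapply(seq_len(nrow(regions)), function(i) {
      sel <- starts0 >= regions$mito_start[i] & starts0 < regions$mito_end[i]
      if (!any(sel)) return(0)
      max(best[sel])
    }, numeric(1))
  } else {
    regions$max_nuclear_identity <- numeric(0)
  }
  regions <- regions[, c("mito_start", "mito_end", "length",
                         "max_nuclear_identity", "origin_wrap")]
  class(regions) <- c("unique_regions", "data.frame")
  attr(regions, "window_identity") <- data.frame(start = starts0, identity = best)
  attr(regions, "params") <- list(window = window, step = step,
                                  identity_threshold = identity_threshold,
                                  min_region = min_region, k = k)
  regions
}

# Forward and reverse-complement character strings of every nuclear contig.
.nuclear_strands <- function(nuclear) {
  if (is.null(nuclear)) return(character(0))
  if (inherits(nuclear, "DNAStringSet")) {
    seqs <- as.character(nuclear)
  } else if (is.character(nuclear)) {
    seqs <- toupper(nuclear)
  } else {
    seqs <- vapply(nuclear, .as_dna_string, character(1))
  }
  seqs <- seqs[nchar(seqs) > 0]
  if (!length(seqs)) return(character(0))
  c(seqs, vapply(seqs, .revcomp, character(1), USE.NAMES = FALSE))
}

# Best full-window identity of each mito window against one subject string.
# mv: extended mito char vector; mk: k-mers at every mito position (1-based).
.window_identities <- function(mv, mk, subj, starts0, window, k) {
  S <- nchar(subj)
  out <- numeric(length(starts0))
  if (S < window) return(out)
  sv <- strsplit(subj, "", fixed = TRUE)[[1L]]
  sk <- substring(subj, seq_len(S - k + 1L), seq_len(S - k + 1L) + k - 1L)
  u <- unique(sk)
  pos_by <- split(seq_along(sk), factor(match(sk, u), levels = seq_along(u)))
  mi <- match(mk, u)

  hit_p <- which(!is.na(mi))
  if (!length(hit_p)) return(out)
  hits <- pos_by[mi[hit_p]]
  P <- rep.int(hit_p, lengths(hits))           # 1-based mito seed position
  D <- unlist(hits, use.names = FALSE) - P     # diagonal offset

  ord <- order(P)
  P <- P[ord]; D <- D[ord]

  for (w in seq_along(starts0)) {
    s <- starts0[w] + 1L # 1-based window start in extended mito
    lo <- findInterval(s - 1L, P) + 1L
    hi <- findInterval(s + window - k, P)
    if (lo > hi) next
    for (d in unique(D[lo:hi])) {
      qs <- s + d
      if (qs < 1L || qs + window - 1L > S) next
      idv <- sum(mv[s:(s + window - 1L)] == sv[qs:(qs + window - 1L)]) / window
      if (idv > out[w]) out[w] <- idv
    }
  }
  out
}

# Maximal runs of uncovered bases on the circle, as 0-based half-open rows;
# a run crossing the origin is emitted as two rows flagged origin_wrap.
.circular_uncovered_runs <- function(covered, min_region) {
  L <- length(covered)
  empty <- data.frame(mito_start = integer(), mito_end = integer(),
                      length = integer(), origin_wrap = logical())
  if (!any(covered)) {
    if (L < min_region) return(empty)
    return(data.frame(mito_start = 0L, mito_end = L, length = L,
                      origin_wrap = FALSE))
  }
  if (all(covered)) return(empty)
  r <- rle(!covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths # 0-based
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  wrap <- FALSE
  if (nrow(runs) >= 2 && runs$start[1] == 0 && runs$end[nrow(runs)] == L) {
    wrap <- TRUE
  }
  rows <- list()
  idx <- seq_len(nrow(runs))
  if (wrap) {
    first <- runs[1, ]; last <- runs[nrow(runs), ]
    idx <- idx[-c(1, nrow(runs))]
    total <- (first$end - first$start) + (last$end - last$start)
    if (total >= min_region) {
      rows[[length(rows) + 1L]] <- data.frame(
        mito_start = c(last$start, first$start),
        mito_end = c(last$end, first$end),
        length = c(last$end - last$start, first$end - first$start),
        origin_wrap = TRUE)
    }
  }
  for (i in idx) {
    len <- runs$end[i] - runs$start[i]
    if (len >= min_region) {
      rows[[length(rows) + 1L]] <- data.frame(
        mito_start = runs$start[i], mito_end = runs$end[i],
        length = len, origin_wrap = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$mito_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.unique_regions <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("unique_regions: %d region(s) (window %d, step %d, identity threshold %.2f)\n",
              nrow(x), p$window, p$step, p$identity_threshold))
  print.data.frame(x, ...)
  invisible(x)
}
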