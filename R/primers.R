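# Primer/probe enumeration inside NUMT-free regions, and exhaustive nuclear
# specificity checking. Primers are deliberately long (25-30 nt) so that even
# a diverged nuclear copy cannot prime efficiently.

#' Constraint set for primer pair design
#'
#' @param primer_len Allowed primer length range (nt). The 25-30 nt floor is
#'   the assay's specificity guard: longer primers tolerate fewer nuclear
#'   mismatches before priming fails.
#' @param gc Allowed primer GC fraction range.
#' @param tm Allowed primer melting temperature window (degrees C, by
#'   [melting_temperature()] at its defaults).
#' @param tm_target Target Tm used in ranking.
#' @param amplicon Allowed amplicon length range (bases, forward start to
#'   reverse end).
#' @param probe_len Allowed hydrolysis probe length range (nt).
#' @param probe_gc Allowed probe GC fraction range.
#' @param probe Logical; require a probe strictly between the primers
#'   (pairs without room for one are dropped).
#' @param max_pairs Cap on candidate pairs evaluated before thinning forward
#'   starts (guards against quadratic blow-up on long regions).
#' @param max_report Number of top-ranked pairs returned (probes are chosen
#'   for these only).
#' @return A list of class `primer_constraints`.
#' @export
primer_constraints <- function(primer_len = c(25, 30), gc = c(0.30, 0.70),
                               tm = c(55, 66), tm_target = 60,
                               amplicon = c(60, 200), probe_len = c(18, 25),
                               probe_gc = c(0.30, 0.70), probe = TRUE,
                               max_pairs = 2e5, max_report = 500) {
  stopifnot(length(primer_len) == 2, primer_len[1] <= primer_len[2],
            length(gc) == 2, length(tm) == 2, length(amplicon) == 2,
            length(probe_len) == 2)
  structure(list(primer_len = as.integer(primer_len), gc = gc, tm = tm,
                 tm_target = tm_target, amplicon = as.integer(amplicon),
                 probe_len = as.integer(probe_len), probe_gc = probe_gc,
                 probe = isTRUE(probe), max_pairs = max_pairs,
                 max_report = max_report),
            class = "primer_constraints")
}

# Enumerate oligo candidates on the forward strand of `seq`: 0-based start,
# length, sequence, gc, tm; filtered by gc and tm windows.
.oligo_candidates <- function(seq, len_range, gc_range, tm_range) {
  rl <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  gc_cum <- c(0L, cumsum(ch %in% c("G", "C")))
  rows <- list()
  for (len in seq.int(len_range[1L], len_range[2L])) {
    if (len > rl) next
    starts <- seq_len(rl - len + 1L) # 1-based
    gc <- (gc_cum[starts + len] - gc_cum[starts]) / len
    keep <- gc >= gc_range[1L] & gc <= gc_range[2L]
    if (!any(keep)) next
    starts <- starts[keep]
    gc <- gc[keep]
    seqs <- substring(seq, starts, starts + len - 1L)
    tm <- vapply(seqs, melting_temperature, numeric(1), USE.NAMES = FALSE)
    ok <- tm >= tm_range[1L] & tm <= tm_range[2L]
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <- data.frame(
      start0 = starts[ok] - 1L, len = len, seq = seqs[ok],
      gc = gc[ok], tm = tm[ok], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(start0 = integer(), len = integer(), seq = character(),
                      gc = numeric(), tm = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Design ranked primer pairs inside a unique region
#'
#' Enumerates every forward primer, reverse primer (reverse complement of a
#' downstream interval), and hydrolysis probe satisfying the constraints, and
#' ranks pairs by a transparent penalty:
#' `|Tm_f - Tm_r| + |Tm_f - target| + |Tm_r - target| + 5(|GC_f - 0.5| + |GC_r - 0.5|)`.
#' Ties break on `(penalty, forward_start)` so results are reproducible. The
#' probe (forward strand) must lie strictly between the primers and is chosen
#' to match the primer mean Tm as closely as possible. An empty result is a
#' valid outcome (e.g. a homopolymeric region fails the GC constraint).
#'
#' @param mito_seq The mitochondrial genome (character, `DNAString`(Set), or
#'   a [make_genome_pair()] object).
#' @param region One row of a [screen_unique_regions()] result, or a numeric
#'   `c(mito_start, mito_end)` (0-based half-open).
#' @param constraints A [primer_constraints()] object.
#'
#' @return Data frame of class `primer_pairs`: `forward_seq`, `reverse_seq`,
#'   `probe_seq`, `forward_start`, `reverse_end` (0-based mito coordinates),
#'   `amplicon_length`, `tm_forward`, `tm_reverse`, `tm_probe`, `gc_forward`,
#'   `gc_reverse`, `penalty`, ranked best-first.
#' @export
design_primer_pairs <- function(mito_seq, region, constraints = primer_constraints()) {
  if (inherits(mito_seq, "genome_pair")) mito_seq <- mito_seq$mito
  mito <- .as_dna_string(mito_seq, "mito_seq")
  cn <- constraints
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1)
    rs <- region$mito_start[1L]; re <- region$mito_end[1L]
  } else {
    stopifnot(is.numeric(region), length(region) == 2)
    rs <- region[1L]; re <- region[2L]
  }
  stopifnot(rs >= 0, re <= nchar(mito), re > rs)
  rlen <- re - rs
  min_needed <- cn$amplicon[1L] + 2L * cn$primer_len[1L]
  if (rlen < min_needed) {
    stop(sprintf("region [%d,%d) is %d bp, shorter than the %d bp needed for design",
                 rs, re, rlen, min_needed), call. = FALSE)
  }
  seq <- substr(mito, rs + 1L, re)

  # one candidate tract table serves both orientations: a reverse primer is
  # the reverse complement of a tract, whose duplex Tm and GC are unchanged
  cand <- .oligo_candidates(seq, cn$primer_len, cn$gc, cn$tm)
  if (!nrow(cand)) return(.empty_primer_pairs())
  cand$end0 <- cand$start0 + cand$len

  if (nrow(cand)^2 > cn$max_pairs) {
    thin <- ceiling(sqrt(nrow(cand)^2 / cn$max_pairs))
    warning(sprintf("thinning candidate starts by %d to respect max_pairs", thin))
    cand <- cand[cand$start0 %% thin == 0L, , drop = FALSE]
    if (!nrow(cand)) return(.empty_primer_pairs())
  }

  probes <- if (cn$probe) {
    .oligo_candidates(seq, cn$probe_len, cn$probe_gc, c(-Inf, Inf))
  } else NULL
  if (cn$probe && !nrow(probes)) return(.empty_primer_pairs())
  # shortest probe end achievable starting at or after each position
  if (cn$probe) {
    ord <- order(probes$start0)
    p_start <- probes$start0[ord]
    p_end_min <- rev(cummin(rev(probes$start0[ord] + probes$len[ord])))
  }

  # vectorized pair expansion: forward i x reverse j
  nf <- nrow(cand)
  fi <- rep(seq_len(nf), each = nf)
  ri <- rep(seq_len(nf), times = nf)
  amp <- cand$end0[ri] - cand$start0[fi]
  keep <- amp >= cn$amplicon[1L] & amp <= cn$amplicon[2L] &
    cand$start0[ri] >= cand$end0[fi]
  fi <- fi[keep]; ri <- ri[keep]; amp <- amp[keep]
  if (!length(fi)) return(.empty_primer_pairs())

  if (cn$probe) {
    ins_lo <- cand$end0[fi]
    ins_hi <- cand$start0[ri]
    idx <- findInterval(ins_lo - 1L, p_start) + 1L # first probe start >= ins_lo
    feasible <- idx <= length(p_start) & p_end_min[pmin(idx, length(p_start))] <= ins_hi
    fi <- fi[feasible]; ri <- ri[feasible]; amp <- amp[feasible]
    if (!length(fi)) return(.empty_primer_pairs())
  }

  penalty <- abs(cand$tm[fi] - cand$tm[ri]) +
    abs(cand$tm[fi] - cn$tm_target) + abs(cand$tm[ri] - cn$tm_target) +
    5 * (abs(cand$gc[fi] - 0.5) + abs(cand$gc[ri] - 0.5))
  ord <- order(penalty, cand$start0[fi])
  ord <- head(ord, cn$max_report)
  fi <- fi[ord]; ri <- ri[ord]; amp <- amp[ord]; penalty <- penalty[ord]

  probe_seq <- rep(NA_character_, length(fi))
  probe_tm <- rep(NA_real_, length(fi))
  if (cn$probe) {
    pr_start <- probes$start0
    pr_end <- probes$start0 + probes$len
    for (i in seq_along(fi)) {
      ok <- which(pr_start >= cand$end0[fi[i]] & pr_end <= cand$start0[ri[i]])
      target_tm <- (cand$tm[fi[i]] + cand$tm[ri[i]]) / 2
      best <- ok[order(abs(probes$tm[ok] - target_tm), pr_start[ok])[1L]]
      probe_seq[i] <- probes$seq[best]
      probe_tm[i] <- probes$tm[best]
    }
  }

  out <- data.frame(
    forward_seq = cand$seq[fi],
    reverse_seq = vapply(cand$seq[ri], .revcomp, character(1), USE.NAMES = FALSE),
    probe_seq = probe_seq,
    forward_start = rs + cand$start0[fi], reverse_end = rs + cand$end0[ri],
    amplicon_length = amp,
    tm_forward = cand$tm[fi], tm_reverse = cand$tm[ri], tm_probe = probe_tm,
    gc_forward = cand$gc[fi], gc_reverse = cand$gc[ri], penalty = penalty,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("primer_pairs", "data.frame")
  out
}

.empty_primer_pairs <- function() {
  out <- data.frame(forward_seq = character(), reverse_seq = character(),
                    probe_seq = character(), forward_start = integer(),
                    reverse_end = integer(), amplicon_length = integer(),
                    tm_forward = numeric(), tm_reverse = numeric(),
                    tm_probe = numeric(), gc_forward = numeric(),
                    gc_reverse = numeric(), penalty = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("primer_pairs", "data.frame")
  out
}

#' Exhaustive nuclear specificity check for primers
#'
#' Slides each oligo over every position of every nuclear contig, on both
#' strands, recording the best full-length identity and whether any site
#' both matches the oligo's five 3'-terminal bases exactly and reaches 90%
#' full-length identity (`perfect_3prime_match`) -- the configuration most
#' likely to misprime.
#'
#' @param pair A `primer_pairs` row (its forward and reverse primers are
#'   checked), or a named character vector / list of oligo sequences.
#' @param genomes A [make_genome_pair()] object or any list with a `nuclear`
#'   element.
#' @param full_identity_min Full-length identity required (with the 3' anchor)
#'   to flag a site.
#' @return Data frame of class `specificity_report`: `primer_id`,
#'   `best_identity`, `perfect_3prime_match`, `contig`, `strand`, `position`
#'   (0-based start of the best site).
#' @export
check_specificity <- function(pair, genomes, full_identity_min = 0.9) {
  oligos <- if (is.data.frame(pair)) {
    stopifnot(nrow(pair) == 1)
    c(forward = pair$forward_seq[1L], reverse = pair$reverse_seq[1L])
  } else {
    unlist(pair)
  }
  if (is.null(names(oligos)) || any(!nzchar(names(oligos)))) {
    names(oligos) <- paste0("oligo", seq_along(oligos))
  }

  contigs <- if (inherits(genomes$nuclear, "DNAStringSet")) {
    as.character(genomes$nuclear)
  } else if (is.character(genomes$nuclear)) {
    stats::setNames(toupper(genomes$nuclear),
                    names(genomes$nuclear) %||% paste0("contig", seq_along(genomes$nuclear)))
  } else character(0)

  out <- lapply(names(oligos), function(id) {
    o <- .as_dna_string(oligos[[id]], id)
    best <- list(identity = 0, anchored = FALSE, contig = NA_character_,
                 strand = NA_character_, position = NA_integer_)
    for (cg in names(contigs)) {
      for (strand in c("+", "-")) {
        subj <- if (strand == "+") contigs[[cg]] else .revcomp(contigs[[cg]])
        hit <- .best_oligo_site(o, subj, full_identity_min)
        if (!is.null(hit)) {
          if (hit$identity > best$identity || (hit$anchored && !best$anchored)) {
            best <- c(hit, list(contig = cg, strand = strand))
          }
          best$anchored <- best$anchored || hit$anchored
        }
      }
    }
    data.frame(primer_id = id, best_identity = best$identity,
               perfect_3prime_match = best$anchored, contig = best$contig,
               strand = best$strand, position = best$position,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("specificity_report", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Best alignment of oligo against one subject strand: identity at every
# offset via per-position vector comparison.
.best_oligo_site <- function(oligo, subj, full_identity_min) {
  n <- nchar(oligo)
  S <- nchar(subj)
  if (S < n) return(NULL)
  ov <- strsplit(oligo, "", fixed = TRUE)[[1L]]
  sv <- strsplit(subj, "", fixed = TRUE)[[1L]]
  m <- S - n + 1L
  tot <- integer(m)
  anchor <- rep(TRUE, m)
  for (j in seq_len(n)) {
    eq <- sv[j:(m + j - 1L)] == ov[j]
    tot <- tot + eq
    if (j > n - 5L) anchor <- anchor & eq
  }
  idv <- tot / n
  bi <- which.max(idv)
  list(identity = idv[bi],
       anchored = any(anchor & idv >= full_identity_min),
       position = bi - 1L)
}
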