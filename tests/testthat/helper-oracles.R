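# Independent oracles used across the suite. These deliberately share no
# code with the package: the uniqueness screen is checked against a
# diagonal-sweep brute force, the exact rank tests against literal
# enumeration of the null, and Pearson p-values against label permutation.

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

# Brute-force best full-window identity for every mito window start against
# every offset of every subject strand (O(n*m) diagonal sweep with running
# window sums; no seeding, no heuristics).
oracle_window_identity <- function(mito, subjects, window, step) {
  L <- nchar(mito)
  mext <- paste0(mito, substr(mito, 1, window - 1))
  mv <- strsplit(mext, "", fixed = TRUE)[[1L]]
  starts0 <- seq.int(0L, L - 1L, by = step)
  best <- numeric(length(starts0))
  widx <- integer(L) # window index per 1-based window start, 0 = not a start
  widx[starts0 + 1L] <- seq_along(starts0)
  for (subj in subjects) {
    sv <- strsplit(subj, "", fixed = TRUE)[[1L]]
    S <- length(sv)
    if (S < window) next
    for (d in seq.int(1L - L, S - window)) {
      smin <- max(1L, 1L - d)
      smax <- min(L, S - d - window + 1L)
      if (smin > smax) next
      i <- smin:(smax + window - 1L)
      z <- mv[i] == sv[i + d]
      cz <- c(0, cumsum(z))
      ws <- smin:smax
      sums <- cz[ws - smin + 1L + window] - cz[ws - smin + 1L]
      sel <- widx[ws] > 0L
      if (any(sel)) {
        k <- widx[ws[sel]]
        best[k] <- pmax(best[k], sums[sel] / window)
      }
    }
  }
  list(starts0 = starts0, identity = best)
}

# Count perfect full-length alignments of any mito window of size `window`
# anywhere in the subject strands, returning their (mito_start0, subj_start0).
oracle_perfect_hits <- function(mito, subjects, window) {
  L <- nchar(mito)
  hits <- list()
  for (si in seq_along(subjects)) {
    sv <- strsplit(subjects[[si]], "", fixed = TRUE)[[1L]]
    mv <- strsplit(mito, "", fixed = TRUE)[[1L]]
    S <- length(sv)
    for (d in seq.int(1L - L, S - window)) {
      smin <- max(1L, 1L - d)
      smax <- min(L - window + 1L, S - d - window + 1L)
      if (smin > smax) next
      i <- smin:(smax + window - 1L)
      z <- mv[i] == sv[i + d]
      cz <- c(0, cumsum(z))
      ws <- smin:smax
      sums <- cz[ws - smin + 1L + window] - cz[ws - smin + 1L]
      for (s in ws[sums == window]) {
        hits[[length(hits) + 1L]] <- c(strand = si, mito_start0 = s - 1L,
                                       subj_start0 = s + d - 1L)
      }
    }
  }
  hits
}

# Independent region assembly: complement of the union of above-threshold
# windows on the circle, maximal runs, min-length filter, origin split.
oracle_regions <- function(above_starts0, window, L, min_region) {
  covered <- logical(L)
  for (s in above_starts0) covered[(s + seq_len(window) - 1L) %% L + 1L] <- TRUE
  uncov <- which(!covered)
  if (!length(uncov)) {
    return(data.frame(mito_start = integer(), mito_end = integer(),
                      origin_wrap = logical()))
  }
  if (length(uncov) == L) {
    return(data.frame(mito_start = 0L, mito_end = L, origin_wrap = FALSE))
  }
  runs <- split(uncov, cumsum(c(1L, diff(uncov) != 1L)))
  df <- data.frame(mito_start = vapply(runs, min, 1L) - 1L,
                   mito_end = vapply(runs, max, 1L))
  wraps <- nrow(df) >= 2 && df$mito_start[1] == 0L && df$mito_end[nrow(df)] == L
  df$origin_wrap <- FALSE
  keep <- rep(TRUE, nrow(df))
  if (wraps) {
    comb <- (df$mito_end[1] - df$mito_start[1]) +
      (df$mito_end[nrow(df)] - df$mito_start[nrow(df)])
    df$origin_wrap[c(1, nrow(df))] <- TRUE
    keep[c(1, nrow(df))] <- comb >= min_region
  }
  len <- df$mito_end - df$mito_start
  keep <- keep & (df$origin_wrap | len >= min_region)
  out <- df[keep, , drop = FALSE]
  out <- out[order(out$mito_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All covered positions (0-based) of a unique_regions table.
region_positions <- function(regions) {
  if (!nrow(regions)) return(integer())
  sort(unlist(Map(function(s, e) s:(e - 1L), regions$mito_start, regions$mito_end)))
}

any_region_overlap <- function(regions, s, e) {
  any(pmax(regions$mito_start, s) < pmin(regions$mito_end, e))
}

# Literal 2^m enumeration of the Wilcoxon signed-rank null (Pratt zeros).
enum_wilcoxon_p <- function(pre, post) {
  d <- post - pre
  r <- rank(abs(d))
  nz <- d != 0
  rnz <- r[nz]
  m <- sum(nz)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  W <- as.vector(signs %*% rnz)
  w <- sum(rnz[d[nz] > 0])
  min(1, 2 * min(mean(W <= w + 1e-9), mean(W >= w - 1e-9)))
}

# Literal C(N, n1) enumeration of the Mann-Whitney U null (midranks).
enum_mwu_p <- function(a, b) {
  n1 <- length(a); N <- n1 + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- combn(N, n1)
  U <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(U <= u_obs + 1e-9), mean(U >= u_obs - 1e-9)))
}

perm_pearson_p <- function(x, y, n_perm = 2e4, seed = 1) {
  r_obs <- abs(cor(x, y))
  withr::with_seed(seed, {
    mean(replicate(n_perm, abs(cor(x, sample(y)))) >= r_obs - 1e-12)
  })
}

# Small genome fixture shared by screen tests.
screen_fixture <- function(seed, mito_length, nuclear_length, numt_specs) {
  gp <- make_genome_pair(seed, mito_length = mito_length,
                         nuclear_length = nuclear_length,
                         numt_specs = numt_specs)
  nuc <- as.character(gp$nuclear[[1L]])
  list(gp = gp, mito = as.character(gp$mito[[1L]]),
       strands = c(nuc, revcomp_chr(nuc)))
}
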