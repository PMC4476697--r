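# Small-sample statistics layer: exact Wilcoxon signed-rank and
# Mann-Whitney U tests (full null enumeration, with midranks for ties and
# Pratt handling of zero differences), one-way repeated-measures ANOVA, and
# Pearson correlation for the sham-referenced delta association.

# Null distribution of 2*W+ over all sign assignments of the given ranks
# (doubled so midranks become integers), by generating-function convolution
# -- algebraically identical to enumerating all 2^m assignments.
.signed_rank_null <- function(ranks2) {
  f <- 1
  for (r in ranks2) {
    g <- c(f, numeric(r))
    g[(r + 1L):(r + length(f))] <- g[(r + 1L):(r + length(f))] + f
    f <- g
  }
  f / sum(f) # P(2W+ = 0..sum(ranks2))
}

.double_tail <- function(cdf_lo, cdf_hi) min(1, 2 * min(cdf_lo, cdf_hi))

#' Exact Wilcoxon matched-pair signed-rank test
#'
#' Two-sided paired test of `post` vs `pre`. In exact mode the null
#' distribution of the positive-rank sum `W+` is obtained by enumerating all
#' `2^m` sign assignments of the ranked absolute differences (midranks under
#' ties), so it stays exact when ties are present. Zero differences follow
#' the Pratt rule by default (zeros are ranked, then their sign contribution
#' is dropped) or can be discarded (`zero_policy = "drop"`). The p-value
#' doubles the smaller tail, capped at 1. The approximate mode uses the
#' normal approximation with tie-adjusted variance and continuity
#' correction.
#'
#' @param pre,post Paired measurement vectors of equal length.
#' @param zero_policy `"pratt"` (default) or `"drop"`.
#' @param mode `"exact"`, `"approx"`, or `"auto"` (exact up to `max_exact`
#'   non-zero differences).
#' @param max_exact Largest m for which the exact null is enumerated.
#' @return An object of classes `mito_htest`/`htest`: `statistic` (`V`, the
#'   positive-rank sum), `p.value`, `n` (pairs), `m` (non-zero differences),
#'   and `method` recording the mode used.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7))$p.value # 2/64
#' @export
wilcoxon_signed_rank <- function(pre, post, zero_policy = c("pratt", "drop"),
                                 mode = c("auto", "exact", "approx"),
                                 max_exact = 25) {
  zero_policy <- match.arg(zero_policy)
  mode <- match.arg(mode)
  stopifnot(is.numeric(pre), is.numeric(post), length(pre) == length(post),
            length(pre) >= 1, all(is.finite(pre)), all(is.finite(post)))
  d <- post - pre
  n <- length(d)

  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(.mk_htest("Wilcoxon matched-pair signed-rank test",
                     statistic = c(V = 0), p.value = 1, n = n, m = 0L,
                     mode = "degenerate"))
  }
  if (zero_policy == "drop") d <- d[d != 0]
  r <- rank(abs(d)) # midranks; under Pratt, zeros consume low ranks
  nz <- d != 0
  r_nz <- r[nz]
  m <- sum(nz)
  W <- sum(r_nz[d[nz] > 0])

  use_exact <- mode == "exact" || (mode == "auto" && m <= max_exact)
  if (use_exact && m > 30) {
    stop("exact enumeration requested for m > 30 non-zero differences", call. = FALSE)
  }
  if (use_exact) {
    ranks2 <- as.integer(round(2 * r_nz))
    pr <- .signed_rank_null(ranks2)
    w2 <- as.integer(round(2 * W))
    cdf <- cumsum(pr)
    p_lo <- cdf[w2 + 1L]
    p_hi <- 1 - if (w2 >= 1L) cdf[w2] else 0
    p <- .double_tail(p_lo, p_hi)
    method <- "exact (sign enumeration)"
  } else {
    mu <- sum(r_nz) / 2
    sig <- sqrt(sum(r_nz^2) / 4)
    z <- (W - mu - sign(W - mu) * 0.5) / sig
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approx"
  }
  .mk_htest("Wilcoxon matched-pair signed-rank test",
            statistic = c(V = W), p.value = p, n = n, m = m, mode = method)
}

# Exact null distribution of U for group sizes m, n without ties, over all
# C(m + n, m) equally likely group assignments, by the classic two-sample
# recursion N(u; m, n) = N(u - n; m - 1, n) + N(u; m, n - 1).
.mwu_null <- function(m, n) {
  umax <- m * n
  C <- array(0, dim = c(m + 1L, n + 1L, umax + 1L))
  C[1L, , 1L] <- 1 # no A items: U = 0
  C[, 1L, 1L] <- 1 # no B items: U = 0
  for (mi in seq_len(m)) {
    for (ni in seq_len(n)) {
      with_last_a <- c(numeric(ni), C[mi, ni + 1L, seq_len(umax + 1L - ni)])
      C[mi + 1L, ni + 1L, ] <- with_last_a + C[mi + 1L, ni, ]
    }
  }
  f <- C[m + 1L, n + 1L, ]
  f / sum(f)
}

#' Exact Mann-Whitney U test
#'
#' Two-sided two-sample rank test. Without ties the exact null distribution
#' of `U` is built by combinatorial recursion over all `C(n1+n2, n1)` group
#' assignments; with ties, midranks are used and the null is enumerated over
#' all label permutations (falling back to the tie-corrected normal
#' approximation when the enumeration would exceed `max_enum` splits). The
#' statistic reported is `U1`, the number of (a, b) pairs with `a > b`
#' (+1/2 per tie); the p-value doubles the smaller tail, capped at 1.
#'
#' @param a,b Sample vectors.
#' @param mode `"exact"`, `"approx"`, or `"auto"` (exact while
#'   `n1 + n2 <= max_exact_n`).
#' @param max_exact_n Largest combined sample size for the exact null.
#' @param max_enum Largest number of splits enumerated when ties force full
#'   permutation.
#' @return `mito_htest`/`htest` object with `statistic` (`U`), `p.value`,
#'   `n1`, `n2`, and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p.value # 2/20
#' @export
mann_whitney_u <- function(a, b, mode = c("auto", "exact", "approx"),
                           max_exact_n = 25, max_enum = 2e5) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 1, length(b) >= 1,
            all(is.finite(a)), all(is.finite(b)))
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0

  use_exact <- mode == "exact" || (mode == "auto" && N <= max_exact_n)
  if (use_exact && !ties) {
    pr <- .mwu_null(n1, n2)
    u <- as.integer(round(U))
    cdf <- cumsum(pr)
    p <- .double_tail(cdf[u + 1L], 1 - if (u >= 1L) cdf[u] else 0)
    method <- "exact (combinatorial recursion)"
  } else if (use_exact && choose(N, n1) <= max_enum) {
    splits <- combn(N, n1)
    u_all <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- .double_tail(mean(u_all <= U + 1e-9), mean(u_all >= U - 1e-9))
    method <- "exact (tie permutation)"
  } else {
    if (use_exact) {
      warning("ties with too many splits to enumerate; using the normal approximation")
    }
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    mu <- n1 * n2 / 2
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approx"
  }
  .mk_htest("Mann-Whitney U test", statistic = c(U = U), p.value = p,
            n1 = n1, n2 = n2, mode = method)
}

#' One-way repeated-measures ANOVA across genes
#'
#' Tests whether per-animal deltas differ across genes with animal as the
#' repeated-measures blocking factor:
#' `F = MS_gene / MS_(gene x animal)` on `(g - 1, (g - 1)(a - 1))` degrees
#' of freedom. Adding a constant to one animal's whole row leaves F
#' unchanged (the subject effect is removed). No sphericity correction is
#' applied. When the between-gene sum of squares is (numerically) zero the
#' test degenerates to `F = 0, p = 1`.
#'
#' @param deltas Numeric matrix or data frame, animals in rows, genes in
#'   columns; complete (no `NA`: missing cells are an error, not imputed).
#' @return `mito_htest`/`htest` object with `statistic` (`F`), `parameter`
#'   (df), and `p.value`.
#' @export
rm_anova_genes <- function(deltas) {
  m <- as.matrix(deltas)
  if (!is.numeric(m)) stop("'deltas' must be numeric", call. = FALSE)
  if (any(is.na(m))) stop("missing cells in the animal x gene matrix", call. = FALSE)
  a <- nrow(m); g <- ncol(m)
  if (a < 2 || g < 2) stop("need >= 2 animals and >= 2 genes", call. = FALSE)
  grand <- mean(m)
  ss_subj <- g * sum((rowMeans(m) - grand)^2)
  ss_gene <- a * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_gene
  df1 <- g - 1; df2 <- (g - 1) * (a - 1)
  scale <- max(ss_tot, 1)
  if (ss_gene / scale < 1e-12) {
    f <- 0; p <- 1
  } else {
    f <- (ss_gene / df1) / (ss_err / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }
  out <- .mk_htest("One-way repeated-measures ANOVA (gene within animal)",
                   statistic = c(F = f), p.value = p,
                   parameter = c(df1 = df1, df2 = df2), mode = "F-distribution")
  out$ss <- c(gene = ss_gene, subject = ss_subj, error = ss_err)
  out
}

#' Pearson correlation with regression line
#'
#' Product-moment correlation with the two-sided t-test p-value
#' `t = r sqrt((n - 2) / (1 - r^2))` and the least-squares line for
#' plotting. `|r| = 1` is handled as the limit `p = 0`.
#'
#' @param x,y Numeric vectors, `n >= 3`, each with non-zero variance
#'   (zero variance is an error).
#' @return Object of classes `correlation_result`/`mito_htest`/`htest`:
#'   `estimate` (`r`), `statistic` (`t`), `parameter` (df), `p.value`, `n`,
#'   `slope`, `intercept`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined", call. = FALSE)
  }
  r <- cor(x, y)
  df <- n - 2
  if (abs(r) >= 1 - 1e-15) {
    t <- sign(r) * Inf; p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(t), df)
  }
  slope <- r * sd(y) / sd(x)
  out <- .mk_htest("Pearson product-moment correlation",
                   statistic = c(t = t), p.value = p,
                   parameter = c(df = df), mode = "t-distribution")
  out$estimate <- c(r = r)
  out$n <- n
  out$slope <- slope
  out$intercept <- mean(y) - slope * mean(x)
  class(out) <- c("correlation_result", class(out))
  out
}

#' Correlate blood mtDNA deltas with sham-referenced respiration deficits
#'
#' For each group, runs [pearson_cor()] of `delta_rq` (post - pre change in
#' relative mtDNA copy number, per animal) against
#' `delta_resp = sham_mean - post_resp` (the respiration deficit relative to
#' the sham group mean; positive = lower than sham). Under this fixed sign
#' convention a positive r means that larger blood mtDNA increases accompany
#' larger cerebral bioenergetic deficits. One respiration endpoint per run;
#' mixed endpoints are an error.
#'
#' @param cohort Data frame (e.g. from [make_cohort()] or [read_cohort()])
#'   with columns `animal_id`, `group`, `endpoint`, `delta_rq`, `post_resp`,
#'   `sham_mean` (one row per animal).
#' @param endpoint Optional endpoint filter applied before checking
#'   consistency.
#' @return Object of class `association_analysis`: list with `endpoint`,
#'   `by_group` (named list of [pearson_cor()] results), and `data` (the
#'   cohort with `delta_resp` added).
#' @export
association_analysis <- function(cohort, endpoint = NULL) {
  need <- c("animal_id", "group", "endpoint", "delta_rq", "post_resp", "sham_mean")
  stopifnot(is.data.frame(cohort), all(need %in% names(cohort)))
  if (!is.null(endpoint)) cohort <- cohort[cohort$endpoint == endpoint, , drop = FALSE]
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  eps <- unique(cohort$endpoint)
  if (length(eps) != 1) {
    stop("mixed respiration endpoints in one run: ",
         paste(eps, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(cohort$animal_id)) {
    stop("expected one record per animal", call. = FALSE)
  }
  cohort$delta_resp <- cohort$sham_mean - cohort$post_resp
  by_group <- lapply(split(cohort, cohort$group), function(d) {
    pearson_cor(d$delta_rq, d$delta_resp)
  })
  structure(list(endpoint = eps, by_group = by_group, data = cohort),
            class = "association_analysis")
}

#' @export
print.association_analysis <- function(x, ...) {
  cat(sprintf("association_analysis (endpoint: %s)\n", x$endpoint))
  for (g in names(x$by_group)) {
    r <- x$by_group[[g]]
    cat(sprintf("  %s: r = %.3f, n = %d, p = %.4g\n",
                g, unname(r$estimate), r$n, r$p.value))
  }
  invisible(x)
}

#' Scatter report of an association analysis
#'
#' @param x An [association_analysis()] result.
#' @return A ggplot object: delta RQ vs respiration deficit per group with
#'   the fitted least-squares line.
#' @export
plot_association <- function(x) {
  stopifnot(inherits(x, "association_analysis"))
  d <- x$data
  ggplot2::ggplot(d, ggplot2::aes(x = delta_rq, y = delta_resp)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::facet_wrap(~group, scales = "free") +
    ggplot2::labs(
      x = "Change in relative mtDNA copy number (post - pre)",
      y = sprintf("Respiration deficit vs sham (%s)", x$endpoint)
    ) +
    ggplot2::theme_bw()
}

utils::globalVariables(c("delta_rq", "delta_resp"))

.mk_htest <- function(method, statistic, p.value, mode, ...) {
  structure(c(list(statistic = statistic, p.value = p.value,
                   method = paste0(method, " [", mode, "]"),
                   mode = mode, data.name = "supplied data"),
              list(...)),
            class = c("mito_htest", "htest"))
}
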