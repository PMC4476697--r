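# Exact nonparametric tests against literal enumeration, RM-ANOVA against
# hand arithmetic and stats::aov, Pearson against cor.test and permutation,
# and the sham-referenced association layer.

test_that("exact Wilcoxon matches closed forms, enumeration, and wilcox.test", {
  # all-positive shift with n = 6: two-sided p = 2 * (1/2)^6
  expect_equal(wilcoxon_signed_rank(1:6, 1:6 + 3)$p.value, 2 / 64)
  # antisymmetry: swapping pre and post leaves the two-sided p unchanged
  set.seed(1)
  x <- rnorm(9); y <- rnorm(9)
  expect_equal(wilcoxon_signed_rank(x, y)$p.value,
               wilcoxon_signed_rank(y, x)$p.value)

  # full-enumeration oracle, including ties and zero differences (Pratt)
  cases <- list(
    list(pre = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12),
         post = c(3, 1, 4, 6, 4, 8, 6, 9, 11, 12, 10, 15)),
    list(pre = c(1, 2, 3, 4, 5), post = c(1, 4, 2, 8, 5)), # zeros + ties
    list(pre = round(rnorm(10), 1), post = round(rnorm(10), 1))
  )
  for (cs in cases) {
    expect_equal(wilcoxon_signed_rank(cs$pre, cs$post)$p.value,
                 enum_wilcoxon_p(cs$pre, cs$post))
  }

  # agreement with base R's exact test when no ties or zeros are present
  set.seed(7)
  for (i in 1:4) {
    x <- rnorm(11); y <- rnorm(11)
    expect_equal(wilcoxon_signed_rank(x, y)$p.value,
                 wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value)
  }

  expect_warning(res <- wilcoxon_signed_rank(c(1, 2), c(1, 2)), "all paired")
  expect_equal(res$p.value, 1)

  # approximate mode tracks the exact one at moderate n
  set.seed(2)
  x <- rnorm(20); y <- rnorm(20) + 0.5
  pe <- wilcoxon_signed_rank(x, y, mode = "exact")$p.value
  pa <- wilcoxon_signed_rank(x, y, mode = "approx")$p.value
  expect_lt(abs(pe - pa), 0.02)
})

test_that("Wilcoxon and Mann-Whitney p-values survive monotone transforms", {
  set.seed(3)
  x <- abs(rnorm(10)) + 0.1; y <- abs(rnorm(10)) + 0.1
  f <- function(v) exp(v) # strictly monotone
  expect_equal(mann_whitney_u(x, y)$p.value, mann_whitney_u(f(x), f(y))$p.value)
  # signed-rank invariance needs a monotone odd transform of the differences;
  # rank order of |d| is what matters, so scale by a positive constant
  expect_equal(wilcoxon_signed_rank(x, y)$p.value,
               wilcoxon_signed_rank(3 * x, 3 * y)$p.value)
})

test_that("exact Mann-Whitney matches closed forms, enumeration, and wilcox.test", {
  # complete separation at n1 = n2 = 3: U = 0, p = 2 / C(6, 3)
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 0.1)
  # identical multisets: p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(3, 1, 2))$p.value, 1)

  set.seed(11)
  for (i in 1:3) { # no ties: recursion vs literal enumeration
    a <- rnorm(5); b <- rnorm(7)
    expect_equal(mann_whitney_u(a, b)$p.value, enum_mwu_p(a, b))
    expect_equal(mann_whitney_u(a, b)$p.value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
  }
  for (i in 1:3) { # ties: permutation path vs literal enumeration
    a <- sample(1:4, 5, replace = TRUE); b <- sample(1:4, 6, replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$p.value, enum_mwu_p(a, b))
  }
})

test_that("repeated-measures ANOVA matches hand arithmetic and stats::aov", {
  # identical genes within each animal: F = 0, p = 1
  m0 <- matrix(rep(c(1, 2, 5), 4), nrow = 3)
  expect_equal(unname(rm_anova_genes(m0)$statistic), 0)
  expect_equal(rm_anova_genes(m0)$p.value, 1)

  # hand-computed 3 animals x 4 genes example
  m <- matrix(c(1, 2, 3,
                2, 4, 3,
                3, 3, 5,
                2, 5, 6), nrow = 3) # columns are genes
  # grand mean = 39/12 = 3.25; row means (animals): 2, 3.5, 4.25;
  # col means (genes): 2, 3, 11/3, 13/3
  # SS_subject = 4 * ((2-3.25)^2 + (3.5-3.25)^2 + (4.25-3.25)^2) = 10.5
  # SS_gene    = 3 * ((2-3.25)^2 + (3-3.25)^2 + (11/3-3.25)^2 + (13/3-3.25)^2)
  #            = 3 * (1.5625 + 0.0625 + 0.173611... + 1.173611...) = 8.916666...
  # SS_total   = 151 - 12 * 3.25^2 = 24.25
  # SS_err     = 24.25 - 10.5 - 8.916666... = 4.833333...
  # F = (8.916666/3) / (4.833333/6) = 2.972222 / 0.805555 = 3.68965517...
  res <- rm_anova_genes(m)
  expect_equal(unname(res$statistic), 3.689655172, tolerance = 1e-9)
  expect_equal(unname(res$parameter), c(3, 6))

  # cross-check against stats::aov with an Error(animal) stratum
  d <- data.frame(v = as.vector(m), animal = factor(rep(1:3, 4)),
                  gene = factor(rep(1:4, each = 3)))
  tab <- summary(aov(v ~ gene + Error(animal), data = d))[["Error: Within"]][[1]]
  expect_equal(unname(res$statistic), tab[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p.value, tab[["Pr(>F)"]][1], tolerance = 1e-10)

  # adding a constant to one animal's entire row leaves F unchanged
  m2 <- m; m2[2, ] <- m2[2, ] + 100
  expect_equal(rm_anova_genes(m2)$statistic, res$statistic)

  m3 <- m; m3[1, 2] <- NA
  expect_error(rm_anova_genes(m3), "missing cells")
})

test_that("Pearson correlation matches cor.test and a permutation oracle", {
  x <- c(1, 2, 4, 5, 7)
  res <- pearson_cor(x, 2 * x + 1)
  expect_equal(unname(res$estimate), 1)
  expect_equal(res$p.value, 0)
  expect_equal(res$slope, 2)
  expect_equal(res$intercept, 1)
  expect_equal(unname(pearson_cor(x, -x)$estimate), -1)

  set.seed(13)
  a <- rnorm(30); b <- 0.4 * a + rnorm(30)
  ct <- cor.test(a, b)
  mine <- pearson_cor(a, b)
  expect_equal(unname(mine$estimate), unname(ct$estimate))
  expect_equal(mine$p.value, ct$p.value)
  # permutation oracle within Monte-Carlo + t-approximation error
  expect_lt(abs(mine$p.value - perm_pearson_p(a, b, n_perm = 2e4)), 0.02)

  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
})

test_that("association analysis recovers the planted correlation and signs", {
  co <- make_cohort(3, n = 100, true_r = 0.9)
  res <- association_analysis(co)
  r_hat <- unname(res$by_group[["RNR-6h"]]$estimate)
  expect_lt(abs(r_hat - 0.9), 0.08)
  expect_equal(res$data$delta_resp, res$data$sham_mean - res$data$post_resp)

  # sham references are carried verbatim into the analysis data
  for (sham in c(82.6, 5.91, 76.0)) {
    co2 <- make_cohort(4, n = 10, true_r = 0.5, sham_mean_flux = sham)
    res2 <- association_analysis(co2)
    expect_equal(unique(res2$data$sham_mean), sham)
  }

  # all post_resp equal to sham: zero-variance deficit is an error
  co3 <- make_cohort(5, n = 10, true_r = 0.5,
                     effect_scales = list(delta_rq_mean = 1, delta_rq_sd = 0.5,
                                          delta_resp_mean = 0, delta_resp_sd = 0))
  expect_error(association_analysis(co3), "zero variance")

  # mixed endpoints in one run are rejected
  co4 <- rbind(make_cohort(6, n = 5, true_r = 0.5),
               make_cohort(7, n = 5, true_r = 0.5, endpoint = "RCR",
                           group = "RNR-25h"))
  expect_error(association_analysis(co4), "mixed")
  # but filtering by endpoint runs
  expect_s3_class(association_analysis(co4, endpoint = "RCR"),
                  "association_analysis")

  p <- plot_association(association_analysis(co))
  expect_s3_class(p, "ggplot")
})
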