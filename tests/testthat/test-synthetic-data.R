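# Generators: determinism, truth fidelity, and the arithmetic identities
# each downstream stage relies on.

test_that("genome pair with no NUMT specs has empty truth and is deterministic", {
  gp1 <- make_genome_pair(7, mito_length = 1000, nuclear_length = 4000)
  gp2 <- make_genome_pair(7, mito_length = 1000, nuclear_length = 4000)
  expect_equal(nrow(gp1$numt_truth), 0)
  expect_identical(as.character(gp1$mito), as.character(gp2$mito))
  expect_identical(as.character(gp1$nuclear), as.character(gp2$nuclear))

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome_fasta(gp1, d1); write_genome_fasta(gp2, d2)
  expect_identical(readLines(file.path(d1, "nuclear.fa")),
                   readLines(file.path(d2, "nuclear.fa")))
})

test_that("planted NUMT truth describes the edits exactly (direct sequence diff)", {
  gp <- make_genome_pair(11, mito_length = 2000, nuclear_length = 9000,
                         numt_specs = list(c(400, 0.05), c(250, 0),
                                           list(length = 300, divergence = 0.1,
                                                strand = "-")))
  expect_equal(nrow(gp$numt_truth), 3)
  expect_false(is.unsorted(gp$numt_truth$start))
  mito <- as.character(gp$mito[[1]])
  nuc <- as.character(gp$nuclear[[1]])
  for (i in seq_len(nrow(gp$numt_truth))) {
    tr <- gp$numt_truth[i, ]
    expect_equal(tr$end - tr$start, tr$mito_end - tr$mito_start) # no indels
    planted <- substr(nuc, tr$start + 1, tr$end)
    src <- substr(mito, tr$mito_start + 1, tr$mito_end)
    if (tr$strand == "-") src <- revcomp_chr(src)
    diffs <- sum(strsplit(planted, "")[[1]] != strsplit(src, "")[[1]])
    expect_equal(diffs, tr$n_sub)
    expect_equal(tr$n_sub, round((tr$end - tr$start) * tr$divergence))
  }
  # placements never overlap
  o <- order(gp$numt_truth$start)
  expect_true(all(diff(gp$numt_truth$start[o]) >=
                    (gp$numt_truth$end - gp$numt_truth$start)[o][-3]))
})

test_that("infeasible NUMT packing raises an explicit error", {
  expect_error(make_genome_pair(1, mito_length = 500, nuclear_length = 900,
                                numt_specs = list(c(500, 0), c(450, 0))),
               "infeasible")
  expect_error(make_genome_pair(1, mito_length = 200, nuclear_length = 900,
                                numt_specs = list(c(500, 0))),
               "exceeds the mitochondrial")
})

test_that("a (500, 0) NUMT is the unique perfect-identity alignment", {
  fx <- screen_fixture(3, 1200, 5000, list(c(500, 0)))
  tr <- fx$gp$numt_truth
  hits <- oracle_perfect_hits(fx$mito, fx$strands, 500)
  hm <- do.call(rbind, hits)
  expect_gte(nrow(hm), 1)
  # every perfect window lies on the truth diagonal (the flanks can extend a
  # 100%-identity window by a base or two by chance, but never move it)
  strand_idx <- if (tr$strand == "+") 1 else 2
  expect_true(all(hm[, "strand"] == strand_idx))
  expect_true(all(hm[, "subj_start0"] - hm[, "mito_start0"] ==
                    hm[1, "subj_start0"] - hm[1, "mito_start0"]))
  expect_true(all(abs(hm[, "mito_start0"] - tr$mito_start) <= 10))
  # the exact truth alignment is among the hits
  pos0 <- if (tr$strand == "+") tr$start else 5000 - tr$end
  expect_true(any(hm[, "mito_start0"] == tr$mito_start &
                    hm[, "subj_start0"] == pos0))
})

test_that("null-effect Ct dataset quantifies to exactly 1 and zero noise gives SD 0", {
  gm <- data.frame(group = "G", timepoint = c("pre", "post"), rq_mean = c(1, 1))
  ds <- make_ct_dataset(ct_generator_params(gm, n_per_group = 3,
                                            replicate_sd = 0, animal_sd = 0,
                                            seed = 5))
  coll <- collapse_replicates(ds$ct)
  expect_true(all(coll$sd_ct == 0))
  rq <- relative_quantification(ds$ct, calibrator = "calibrator")
  expect_equal(rq$rq, rep(1, nrow(rq)))
})

test_that("pooled estimates recover generator truth at table-scale effect sizes", {
  ref <- rq_reference_summary()
  gm_all <- data.frame(group = ref$cohort, timepoint = ref$timepoint,
                       gene = ref$gene, rq_mean = ref$mean_rq)
  n10 <- c("RNR-6h" = 40, "RNR-25h" = 40, "CCI-25h" = 50) # 10x study scale
  pre_vals <- NULL; truth_pre <- NULL
  for (g in names(n10)) {
    ds <- make_ct_dataset(ct_generator_params(
      gm_all[gm_all$group == g, ], n_per_group = n10[[g]],
      seed = 100 + match(g, names(n10))))
    rq <- relative_quantification(ds$ct, calibrator = "calibrator")
    pre_vals <- c(pre_vals, rq$rq[rq$timepoint == "pre" & rq$group != "calibrator"])
    truth_pre <- c(truth_pre, ds$truth$true_rq[ds$truth$timepoint == "pre" &
                                                 ds$truth$group != "calibrator"])
  }
  est <- mean(pre_vals)
  expect_equal(length(pre_vals), 390) # 10x the 39 study values
  # generator truth as oracle: the estimate differs from the truth mean only
  # through replicate noise, including the common-mode noise of each
  # calibrator reference (~1% per gene x dataset, 9 references); 0.03 is a
  # ~3-sigma bound on that combination
  expect_lt(abs(est - mean(truth_pre)), 0.03)
  # and it sits near the parameterized pooled level (log2-normal draws put
  # the arithmetic mean ~1.5% above the geometric-mean parameter)
  expect_lt(abs(est - 0.84), 0.06)
})

test_that("SUIT trace slopes, flatness, and integral match the phase plan", {
  # flat trace at zero flux, zero noise
  p0 <- suit_generator_params(
    phase_plan = data.frame(state = "S", flux = 0, duration = 300),
    noise_sd = 0, artifact_magnitude = 0, seed = 1)
  tr0 <- make_suit_trace(p0)
  expect_equal(tr0$o2, rep(250, length(tr0$o2)))

  # unit arithmetic: 80 pmol/s/mg at 1 mg/ml -> -0.080 uM/s exactly
  p1 <- suit_generator_params(
    phase_plan = data.frame(state = "S", flux = 80, duration = 300),
    noise_sd = 0, artifact_magnitude = 0, seed = 1)
  tr1 <- make_suit_trace(p1)
  expect_equal(unique(round(diff(tr1$o2), 12)), -0.080)

  # integral: total O2 consumed equals sum(flux * duration * conc) / 1000
  pp <- default_suit_plan()
  p2 <- suit_generator_params(phase_plan = pp, noise_sd = 0,
                              artifact_magnitude = 0, seed = 1)
  tr2 <- make_suit_trace(p2)
  expect_equal(tr2$o2[1] - tr2$o2[length(tr2$o2)],
               sum(pp$flux * pp$duration) / 1000, tolerance = 1e-9)

  # determinism
  tr3 <- make_suit_trace(suit_generator_params(seed = 9))
  tr4 <- make_suit_trace(suit_generator_params(seed = 9))
  expect_identical(tr3$o2, tr4$o2)

  # O2 crossing zero names the offending phase
  expect_error(make_suit_trace(suit_generator_params(
    phase_plan = data.frame(state = c("A", "B"), flux = c(100, 400),
                            duration = c(600, 900)),
    o2_start = 150, seed = 1)), "phase 'B'")
})

test_that("cohort generator honours its correlation contract", {
  # noise-free perfect correlation
  co <- make_cohort(1, n = 10, true_r = 1)
  expect_equal(cor(co$delta_rq, co$sham_mean - co$post_resp), 1, tolerance = 1e-12)

  expect_error(make_cohort(1, n = 10, true_r = 1.2), "\\[-1, 1\\]")
  expect_error(make_cohort(1, n = 2, true_r = 0.5))

  # Monte Carlo: r_hat within +/-0.1 of -0.9 for >= 95% of seeds at n = 200
  r_hat <- vapply(1:500, function(s) {
    co <- make_cohort(s, n = 200, true_r = -0.9)
    cor(co$delta_rq, co$sham_mean - co$post_resp)
  }, numeric(1))
  expect_gte(mean(abs(r_hat + 0.9) < 0.1), 0.95)

  # null case: |r| < 0.28 in about 95% of seeds at n = 50 (Fisher z)
  r_null <- vapply(1:500, function(s) {
    co <- make_cohort(1000 + s, n = 50, true_r = 0)
    cor(co$delta_rq, co$sham_mean - co$post_resp)
  }, numeric(1))
  expect_gte(mean(abs(r_null) < 0.28), 0.90)
  expect_lte(mean(abs(r_null) < 0.28), 0.99)
})
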