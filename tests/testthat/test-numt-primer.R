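# Uniqueness screen vs brute-force oracle, melting temperature, primer
# enumeration constraints, and nuclear specificity checking.

test_that("screen equals the brute-force window-identity oracle on planted NUMTs", {
  fx <- screen_fixture(21, 1500, 6000,
                       list(c(300, 0), c(250, 0.02), c(200, 0.02)))
  window <- 100; step <- 10; thr <- 0.8; min_region <- 100
  reg <- screen_unique_regions(fx$gp, window = window, step = step,
                               identity_threshold = thr, min_region = min_region)
  orc <- oracle_window_identity(fx$mito, fx$strands, window, step)
  impl <- attr(reg, "window_identity")

  # identical above/below-threshold classification of every window
  expect_equal(impl$identity >= thr, orc$identity >= thr)
  # where a window is NUMT-like, the seeded identity is the true optimum
  hot <- orc$identity >= thr
  expect_equal(impl$identity[hot], orc$identity[hot])

  # identical maximal regions
  exp_reg <- oracle_regions(orc$starts0[hot], window, nchar(fx$mito), min_region)
  expect_equal(reg$mito_start, exp_reg$mito_start)
  expect_equal(reg$mito_end, exp_reg$mito_end)
  expect_equal(reg$origin_wrap, exp_reg$origin_wrap)
  expect_true(all(reg$max_nuclear_identity < thr))
  # no region touches any divergence-0 planted locus
  perfect <- fx$gp$numt_truth[fx$gp$numt_truth$divergence == 0, ]
  for (i in seq_len(nrow(perfect))) {
    expect_false(any_region_overlap(reg, perfect$mito_start[i], perfect$mito_end[i]))
  }
})

test_that("with no nuclear NUMT the whole genome is one region", {
  gp <- make_genome_pair(4, mito_length = 1200, nuclear_length = 5000)
  reg <- screen_unique_regions(gp, window = 100, step = 10)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$mito_start, 0)
  expect_equal(reg$mito_end, 1200)
  expect_lt(reg$max_nuclear_identity, 0.8)

  # empty nuclear genome: documented behaviour, not an error
  gp$nuclear <- Biostrings::DNAStringSet()
  reg2 <- screen_unique_regions(gp, window = 100, step = 10)
  expect_equal(reg2$mito_end - reg2$mito_start, 1200)

  expect_error(screen_unique_regions(gp, window = 2000), "exceeds")
})

test_that("reverse-strand NUMTs are excluded exactly like forward-strand ones", {
  for (strand in c("+", "-")) {
    gp <- make_genome_pair(31, mito_length = 1500, nuclear_length = 6000,
                           numt_specs = list(list(length = 400, divergence = 0,
                                                  strand = strand)))
    reg <- screen_unique_regions(gp, window = 100, step = 10)
    tr <- gp$numt_truth
    expect_false(any_region_overlap(reg, tr$mito_start, tr$mito_end))
  }
})

test_that("rotating the mito genome rotates unique coverage (circularity)", {
  # the rotation must respect the window-start grid (k a multiple of step),
  # otherwise window phasing, not the screen, changes region edges
  gp <- make_genome_pair(13, mito_length = 1500, nuclear_length = 6000,
                         numt_specs = list(c(350, 0.01)))
  L <- 1500; k <- 440
  reg <- screen_unique_regions(gp, window = 100, step = 10)
  mito_rot <- paste0(substr(as.character(gp$mito[[1]]), k + 1, L),
                     substr(as.character(gp$mito[[1]]), 1, k))
  gp_rot <- list(mito = mito_rot, nuclear = gp$nuclear)
  reg_rot <- screen_unique_regions(gp_rot, window = 100, step = 10)
  expect_setequal((region_positions(reg) - k) %% L, region_positions(reg_rot))
})

test_that("melting temperature matches the reference parameter set and its symmetries", {
  # frozen values computed independently with the same nearest-neighbor
  # table (Allawi-SantaLucia 1997), saltcorr dS + 0.368(N-1)ln[Na+], CT/4
  frozen <- c(ATAGCCTATCCATTCCTCATGCTTT = 55.721745,
              GTGTACTCGTTCATAGTTAGTGTTGG = 55.541653,
              AACTGACTCGTACCGCTAATAATCG = 56.712322,
              TGAGGATGCCAGAAGTAATAGGAAG = 55.720420,
              ACGTACGTACGTACGT = 48.826011,
              CTTTCCACGTATAAACAAC = 46.051732)
  for (s in names(frozen)) {
    expect_equal(melting_temperature(s), unname(frozen[[s]]), tolerance = 0.01)
  }
  # duplex symmetry and GC monotonicity
  s <- "AACTGACTCGTACCGCTAATAATCG"
  expect_equal(melting_temperature(s), melting_temperature(revcomp_chr(s)))
  expect_gt(melting_temperature(strrep("G", 25)), melting_temperature(strrep("A", 25)))
  expect_error(melting_temperature("ACGTNACGT"), "other than")
  expect_error(melting_temperature("ACGTA"), "at least 8")
})

test_that("designed pairs satisfy every constraint and the documented ranking", {
  fx <- screen_fixture(5, 3000, 12000, list(c(400, 0.02)))
  reg <- screen_unique_regions(fx$gp, window = 100, step = 10)
  r1 <- reg[which.max(reg$length), ]
  pp <- design_primer_pairs(fx$gp, c(r1$mito_start, r1$mito_start + 400),
                            primer_constraints(max_pairs = 1e7))
  expect_gt(nrow(pp), 0)
  expect_true(all(nchar(pp$forward_seq) >= 25 & nchar(pp$forward_seq) <= 30))
  expect_true(all(nchar(pp$reverse_seq) >= 25 & nchar(pp$reverse_seq) <= 30))
  expect_true(all(pp$gc_forward >= 0.30 & pp$gc_forward <= 0.70))
  expect_true(all(pp$tm_forward >= 55 & pp$tm_forward <= 66))
  expect_true(all(pp$amplicon_length >= 60 & pp$amplicon_length <= 200))
  expect_equal(pp$amplicon_length, pp$reverse_end - pp$forward_start)
  expect_false(is.unsorted(pp$penalty))

  mito <- fx$mito
  for (i in c(1L, nrow(pp))) {
    # reverse primer is the reverse complement of the downstream interval
    rseq <- pp$reverse_seq[i]
    tract <- substr(mito, pp$reverse_end[i] - nchar(rseq) + 1, pp$reverse_end[i])
    expect_identical(revcomp_chr(rseq), tract)
    # forward primer sits at its coordinate
    expect_identical(substr(mito, pp$forward_start[i] + 1,
                            pp$forward_start[i] + nchar(pp$forward_seq[i])),
                     pp$forward_seq[i])
    # probe strictly between the primers, on the forward strand
    ppos <- regexpr(pp$probe_seq[i], substr(mito, pp$forward_start[i] + 1,
                                            pp$reverse_end[i]), fixed = TRUE)
    expect_gt(ppos, nchar(pp$forward_seq[i]))
    expect_lte(ppos - 1 + nchar(pp$probe_seq[i]),
               pp$amplicon_length[i] - nchar(rseq))
  }
})

test_that("design feasibility floor and degenerate regions behave as documented", {
  # 110-base half-GC region admits at least one pair (amplicon range 60-200)
  set.seed(19)
  region_seq <- paste(sample(rep(c("A", "C", "G", "T"), length.out = 110)),
                      collapse = "")
  pp <- design_primer_pairs(region_seq, c(0, 110),
                            primer_constraints(max_pairs = 1e7))
  expect_gt(nrow(pp), 0)

  # homopolymer fails the GC constraint -> empty result, not an error
  expect_equal(nrow(design_primer_pairs(strrep("A", 300), c(0, 300))), 0)

  # region below the feasibility floor errors, naming the region
  expect_error(design_primer_pairs(region_seq, c(0, 100)), "\\[0,100\\)")
})

test_that("specificity scan finds planted primers and clears random ones", {
  gp <- make_genome_pair(8, mito_length = 1000, nuclear_length = 50000)
  nuc <- as.character(gp$nuclear[[1]])
  primer <- "ATAGCCTATCCATTCCTCATGCTTT"
  substr(nuc, 20001, 20000 + nchar(primer)) <- primer
  gp_planted <- list(nuclear = Biostrings::DNAStringSet(c(nuc1 = nuc)))
  rep1 <- check_specificity(list(fwd = primer), gp_planted)
  expect_equal(rep1$best_identity, 1.0)
  expect_true(rep1$perfect_3prime_match)
  expect_equal(rep1$position, 20000)

  # planted on the reverse strand is found equally
  nuc2 <- as.character(gp$nuclear[[1]])
  substr(nuc2, 30001, 30000 + nchar(primer)) <- revcomp_chr(primer)
  rep2 <- check_specificity(list(fwd = primer),
                            list(nuclear = Biostrings::DNAStringSet(c(n = nuc2))))
  expect_equal(rep2$best_identity, 1.0)
  expect_true(rep2$perfect_3prime_match)

  # random 25-mers against a random contig stay far from priming identity
  withr::with_seed(77, {
    for (i in 1:3) {
      oligo <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                     collapse = "")
      rep3 <- check_specificity(list(o = oligo), gp)
      expect_lt(rep3$best_identity, 0.9)
    }
  })

  # empty nuclear genome: identity 0, no flag
  rep4 <- check_specificity(list(o = primer),
                            list(nuclear = Biostrings::DNAStringSet()))
  expect_equal(rep4$best_identity, 0)
  expect_false(rep4$perfect_3prime_match)
})
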