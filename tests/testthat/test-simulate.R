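test_that("random sequences are seeded, composition-controlled draws", {
  expect_identical(random_sequence(0), "")
  expect_identical(random_sequence(5, base_probs = c(1, 0, 0, 0)), "AAAAA")
  expect_identical(random_sequence(200, seed = 7), random_sequence(200, seed = 7))
  expect_false(random_sequence(200, seed = 7) == random_sequence(200, seed = 8))
  # GC fraction within 3 standard errors at probs (.2, .3, .3, .2)
  n <- 100000
  s <- random_sequence(n, base_probs = c(0.2, 0.3, 0.3, 0.2), seed = 99)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / n
  se <- sqrt(0.6 * 0.4 / n)
  expect_lt(abs(gc - 0.6), 3 * se)
  expect_error(random_sequence(10, base_probs = c(-1, 1, 1, 1)), "nonnegative")
})

test_that("planting overwrites exactly the motif window", {
  m <- default_demo_pwm()
  s <- random_sequence(100, seed = 5)
  out <- plant_motif(s, m, 40)
  expect_identical(nchar(out$sequence), 100L)
  expect_identical(substr(out$sequence, 41, 46), pwm_consensus(m))
  expect_identical(substr(out$sequence, 1, 40), substr(s, 1, 40))
  expect_identical(substr(out$sequence, 47, 100), substr(s, 47, 100))
  expect_error(plant_motif(s, m, 97), "does not fit")
  # sampled mode with a point-mass matrix is consensus mode
  pm <- pwm(rbind(c(1, 0, 0, 0), c(0, 0, 0, 1)))
  expect_identical(plant_motif(s, pm, 10, mode = "sampled", seed = 1)$truth$planted_kmer,
                   "AT")
})

test_that("sampled plants hit the brute-force expected dissimilarity (L <= 4)", {
  withr::with_seed(53, {
    freq <- random_freq_matrix(3)
    m <- pwm(freq)
    # exhaustive expectation over all k-mers under the matrix distribution
    kmers <- apply(do.call(expand.grid, rep(list(BASES), 3)), 1, paste,
                   collapse = "")
    probs <- vapply(kmers, function(k) {
      ch <- strsplit(k, "")[[1]]
      prod(vapply(1:3, function(i) freq[i, match(ch[i], BASES)], numeric(1)))
    }, numeric(1))
    diss <- vapply(kmers, oracle_dissimilarity, numeric(1), freq = freq)
    expected <- sum(probs * diss)
    sd_diss <- sqrt(sum(probs * (diss - expected)^2))
    s <- random_sequence(20, seed = 1)
    draws <- vapply(1:1000, function(i) {
      k <- plant_motif(s, m, 5, mode = "sampled")$truth$planted_kmer
      oracle_dissimilarity(freq, k)
    }, numeric(1))
    expect_lt(abs(mean(draws) - expected), 4 * sd_diss / sqrt(1000))
  })
})

test_that("simulated Ct tables invert to the true RQ", {
  noiseless <- simulate_ct_table(true_rq = 2, noise_sd = 0, n_replicates = 3)
  expect_equal(rq_from_ct(noiseless)$rq, rep(2, 3), tolerance = 1e-12)
  null_tbl <- simulate_ct_table(true_rq = 1, noise_sd = 0, n_replicates = 3)
  expect_equal(log2_rq_test(rq_from_ct(null_tbl)$rq)$p_value, 1)
  # efficiency-corrected inversion with non-ideal efficiencies
  eff <- simulate_ct_table(true_rq = 3, e_target = 1.8, e_reference = 1.95,
                           noise_sd = 0, n_replicates = 2)
  expect_equal(rq_from_ct(eff)$rq, rep(3, 2), tolerance = 1e-9)
  # mean recovered RQ within 5% of truth under noise, n = 50
  noisy <- simulate_ct_table(true_rq = 2, noise_sd = 0.1, n_replicates = 50,
                             seed = 101)
  expect_lt(abs(mean(rq_from_ct(noisy)$rq) - 2) / 2, 0.05)
})

test_that("simulated ChIP tables invert to the true percent input", {
  tbl <- simulate_chip_table(c(a = 5, b = 0.5), noise_sd = 0)
  got <- percent_input(tbl)
  expect_equal(got$percent_input, c(5, 0.5), tolerance = 1e-12)
})

test_that("expression simulation allocates classes exactly and recovers labels", {
  all_down <- simulate_expression(10, fractions = c(down_2to5 = 1))
  expect_identical(unique(all_down$true_class), "down_2to5")
  expect_identical(
    classify_regulation(all_down$log2fc, all_down$fdr_adjusted_p),
    all_down$true_class
  )
  empty <- simulate_expression(0)
  expect_equal(nrow(empty), 0)
  mix <- simulate_expression(
    200, fractions = c(down_2to5 = 0.5, down_gt5 = 0.2, up_2to5 = 0.1),
    seed = 3
  )
  counts <- table(mix$true_class)
  expect_equal(unname(counts[c("down_2to5", "down_gt5", "up_2to5",
                               "not_significant")]),
               c(100L, 40L, 20L, 40L), ignore_attr = TRUE)
  expect_identical(classify_regulation(mix$log2fc, mix$fdr_adjusted_p),
                   mix$true_class)
  expect_error(simulate_expression(10, fractions = c(bogus = 1)), "classes")
  expect_error(simulate_expression(10, fractions = c(down_2to5 = 1.2)),
               "at most 1")
})

test_that("generators are bit-reproducible under a fixed seed", {
  m <- default_demo_pwm()
  a <- simulate_promoters(m, n = 10, length = 80, n_planted = 4, seed = 77)
  b <- simulate_promoters(m, n = 10, length = 80, n_planted = 4, seed = 77)
  expect_identical(a, b)
  expect_identical(simulate_expression(30, seed = 5), simulate_expression(30, seed = 5))
  expect_identical(simulate_ct_table(seed = 9), simulate_ct_table(seed = 9))
})

test_that("fixture bundles are written complete and reproducibly", {
  m <- default_demo_pwm()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- write_fixture_bundle(d1, m, seed = 7, n = 12, length = 120, n_planted = 5)
  f2 <- write_fixture_bundle(d2, m, seed = 7, n = 12, length = 120, n_planted = 5)
  expect_true(all(file.exists(f1)))
  for (name in c("promoters.fa", "truth.tsv", "matrix.tsv", "qpcr.tsv",
                 "chip.tsv", "expression.tsv")) {
    expect_identical(readLines(file.path(d1, name)),
                     readLines(file.path(d2, name)),
                     info = name)
  }
  # manifests differ at most on the timestamp line
  m1 <- readLines(file.path(d1, "manifest.txt"))
  m2 <- readLines(file.path(d2, "manifest.txt"))
  keep <- !startsWith(m1, "timestamp=")
  expect_identical(m1[keep], m2[keep])
  # planted truths scan back at 0%
  proms <- read_fasta(file.path(d1, "promoters.fa"))
  truth <- readr::read_tsv(file.path(d1, "truth.tsv"), col_types = readr::cols())
  summ <- scan_summary(proms, m, max_dissimilarity = 5)
  planted_best <- summ$best_dissimilarity[summ$promoter_id %in% truth$promoter_id]
  expect_true(all(planted_best == 0))
})
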