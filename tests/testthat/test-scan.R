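test_that("a planted consensus is recovered at 0% dissimilarity", {
  m <- default_demo_pwm()
  bg <- random_sequence(1000, seed = 42)
  planted <- plant_motif(bg, m, 137)
  hits <- scan_sequence(m, planted$sequence, max_dissimilarity = 5)
  at_site <- hits[hits$offset == 137 & hits$strand == "+", ]
  expect_equal(nrow(at_site), 1L)
  expect_identical(at_site$dissimilarity, 0)
  expect_identical(attr(hits, "best_dissimilarity"), 0)
})

test_that("short sequences and all-N sequences yield no hits", {
  m <- default_demo_pwm()
  short <- scan_sequence(m, "ACG")
  expect_equal(nrow(short), 0L)
  allN <- scan_sequence(m, strrep("N", 50))
  expect_equal(nrow(allN), 0L)
  expect_identical(attr(allN, "best_dissimilarity"), NA_real_)
  expect_equal(attr(allN, "skipped_windows"), 45L)
})

test_that("scan matches the brute-force oracle on both strands", {
  withr::with_seed(17, {
    for (case in 1:40) {
      L <- sample(2:6, 1)
      freq <- random_freq_matrix(L)
      m <- pwm(freq)
      seq <- random_dna(50)
      thr <- runif(1, 0, 100)
      for (strands in c("both", "plus")) {
        got <- scan_sequence(m, seq, max_dissimilarity = thr, strands = strands)
        want <- oracle_scan(freq, seq, thr, strands = strands)
        expect_equal(nrow(got), nrow(want))
        expect_equal(got$offset, want$offset)
        expect_equal(got$strand, want$strand)
        expect_equal(got$kmer, want$kmer)
        expect_equal(got$dissimilarity, want$dissimilarity, tolerance = 1e-9)
      }
    }
  })
})

test_that("windows containing N are skipped but tallied", {
  m <- pwm(rbind(c(1, 0, 0, 0), c(0, 0, 1, 0)))  # "AG"
  hits <- scan_sequence(m, "AGNAG", max_dissimilarity = 100)
  # windows at offsets 1, 2 contain the N
  expect_equal(attr(hits, "skipped_windows"), 2L)
  expect_setequal(hits$offset[hits$strand == "+"], c(0L, 3L))
})

test_that("scanning both strands is invariant under reverse complement", {
  withr::with_seed(23, {
    m <- pwm(random_freq_matrix(4))
    for (i in 1:10) {
      seq <- random_dna(60)
      a <- scan_sequence(m, seq, 100, "both")
      b <- scan_sequence(m, oracle_revcomp(seq), 100, "both")
      expect_equal(sort(a$matching_score), sort(b$matching_score),
                   tolerance = 1e-12)
    }
  })
})

test_that("sub-threshold hit counts are monotone in the threshold and exact at 0+", {
  withr::with_seed(29, {
    m <- default_demo_pwm()
    cons <- pwm_consensus(m)
    seq <- random_dna(400)
    thresholds <- c(0, 0.5, 1, 2, 5, 10, 25, 50, 100)
    counts <- vapply(thresholds, function(t) {
      nrow(scan_sequence(m, seq, max_dissimilarity = t))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
    # just above 0: only exact consensus occurrences, vs brute force
    eps_hits <- scan_sequence(m, seq, max_dissimilarity = 1e-9)
    want <- oracle_scan(pwm_frequencies(m)$values, seq, 1e-9, "both")
    expect_equal(nrow(eps_hits), nrow(want))
    expect_true(all(eps_hits$kmer == cons))
  })
})

test_that("per-promoter summaries count strict sub-threshold hits and the best score", {
  m <- default_demo_pwm()
  proms <- tibble::tibble(
    promoter_id = c("p1", "p2"),
    gene_id = c("g1", "g2"),
    sequence = c(plant_motif(random_sequence(300, seed = 4), m, 50)$sequence,
                 strrep("N", 100))
  )
  summ <- scan_summary(proms, m, max_dissimilarity = 5)
  expect_equal(summ$best_dissimilarity[1], 0)
  expect_gte(summ$n_hits[1], 1L)
  expect_true(is.na(summ$best_dissimilarity[2]))
  expect_equal(summ$n_hits[2], 0L)
})

test_that("candidate classification is strict and any-promoter", {
  summaries <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g3", "g4"),
    promoter_id = paste0("p", 1:5),
    best_dissimilarity = c(0.63, 5.0, 12, 4.99, NA),
    n_hits = c(1L, 1L, 0L, 1L, 0L),
    skipped_windows = 0L
  )
  expect_identical(classify_candidates(summaries, 5), c("g1", "g3"))
  expect_identical(classify_candidates(summaries, 100), c("g1", "g2", "g3"))
  expect_identical(classify_candidates(summaries, 0), character(0))
})

test_that("the two-species filter requires both scores present and below threshold", {
  rows <- tibble::tibble(
    gene_symbol = c("A", "B", "C", "D"),
    gene_name = "x", accession = "1",
    score_a = c(0, 0.63, NA, 4.99),
    score_b = c(0, 0.43, 1, 5.0),
    annotation = NA_character_
  )
  expect_identical(both_species_filter(rows, 5), c("A", "B"))
  # monotone non-decreasing in the threshold
  withr::with_seed(37, {
    rnd <- tibble::tibble(
      gene_symbol = paste0("g", 1:50), gene_name = "x", accession = "1",
      score_a = ifelse(runif(50) < 0.2, NA, runif(50, 0, 12)),
      score_b = ifelse(runif(50) < 0.2, NA, runif(50, 0, 12)),
      annotation = NA_character_
    )
    sizes <- vapply(c(0, 1, 2, 5, 10, 100),
                    function(t) length(both_species_filter(rnd, t)), numeric(1))
    expect_true(all(diff(sizes) >= 0))
  })
})

test_that("overlap partitions normalised symbol sets", {
  ov <- overlap_sets(c("A", "b", "C"), c("B", "c", "D"))
  expect_identical(ov$shared, c("B", "C"))
  expect_identical(ov$only_a, "A")
  expect_identical(ov$only_b, "D")
  same <- overlap_sets(c("x", "y"), c("Y", "X"))
  expect_identical(same$only_a, character(0))
  expect_identical(same$only_b, character(0))
  withr::with_seed(41, {
    for (i in 1:10) {
      a <- unique(sample(LETTERS, sample(3:20, 1)))
      b <- unique(sample(LETTERS, sample(3:20, 1)))
      ov <- overlap_sets(a, b)
      expect_equal(length(ov$only_a) + length(ov$shared), length(a))
      expect_equal(length(ov$only_b) + length(ov$shared), length(b))
      expect_length(intersect(ov$only_a, ov$only_b), 0)
    }
  })
  td <- tidy(ov)
  expect_equal(nrow(td), length(ov$shared) + length(ov$only_a) + length(ov$only_b))
})
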