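# brute-force PSM oracle: count kmers by scanning strings directly
oracle_psm_entry <- function(real, false, kmer, start_idx, alpha = 1) {
  k <- nchar(kmer)
  cnt <- function(seqs) {
    sum(vapply(seqs, function(s) {
      substr(s, start_idx, start_idx + k - 1) == kmer
    }, logical(1)))
  }
  nk <- 4^k
  log2(((cnt(real) + alpha) / (length(real) + alpha * nk)) /
         ((cnt(false) + alpha) / (length(false) + alpha * nk)))
}

test_that("identical real and false datasets give an all-zero PSM", {
  d <- toy_dataset(c("ACGTACGTAC", "TTGACCGTAA"))
  psm <- pa_psm(d, d, k = 2, region = pa_dataset_region(d))
  expect_true(all(psm$values == 0))
  expect_equal(pa_psm_score(psm, d$sequence), c(0, 0))
})

test_that("PSM dimensions and the smoothed-frequency entry formula", {
  set.seed(1)
  real <- pa_trim(pa_simulate(pa_profile(), 20, 0, seed = 1),
                  pa_region(-100L, 100L))
  mk <- pa_fit_markov(pa_simulate(pa_profile(), 20, 0, seed = 2))
  false <- pa_sample_negatives(mk, 30, length = 200,
                               region = pa_region(-100L, 100L), seed = 3)
  psm <- pa_psm(real, false, k = 3)
  expect_equal(dim(psm$values), c(64L, 198L))
  expect_equal(colnames(psm$values)[1], "-100")

  # every entry matches the brute-force counter
  for (kmer in c("AAT", "CGC", "TTT")) {
    for (j in c(1L, 81L, 198L)) {
      expect_equal(unname(psm$values[kmer, j]),
                   oracle_psm_entry(real$sequence, false$sequence, kmer, j),
                   tolerance = 1e-12)
    }
  }
})

test_that("two-sequence worked example gives log2(3)", {
  r2 <- pa_region(-1L, 1L)
  real <- pa_dataset(c("r1", "r2"), c("AA", "AA"), "real", r2)
  false <- pa_dataset(c("f1", "f2"), c("AC", "AC"), "false", r2)
  psm <- pa_psm(real, false, k = 2, region = r2, alpha = 1)
  expect_equal(unname(psm$values["AA", 1]), log2(3), tolerance = 1e-12)
  expect_equal(pa_psm_score(psm, "AA"), log2(3), tolerance = 1e-12)
})

test_that("class swap negates every entry exactly", {
  set.seed(2)
  a <- pa_simulate(pa_profile(), 25, 0, seed = 4)
  b <- pa_simulate(pa_profile(dse_enabled = FALSE), 35, 0, seed = 5)
  p1 <- pa_psm(a, b, k = 2)
  p2 <- pa_psm(b, a, k = 2)
  expect_equal(p1$values, -p2$values, tolerance = 1e-12)
})

test_that("frequency normalization is invariant to duplicating sequences", {
  a <- pa_simulate(pa_profile(), 15, 0, seed = 6)
  b <- pa_simulate(pa_profile(dse_enabled = FALSE), 15, 0, seed = 7)
  dup <- function(d) {
    out <- pa_bind(d, d)
    out$id <- paste0(out$id, "_", seq_len(nrow(out)))
    out
  }
  p1 <- pa_psm(a, b, k = 2, alpha = 0.5)
  p2 <- pa_psm(dup(a), dup(b), k = 2, alpha = 1)  # alpha scales with size
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
})

test_that("subregion scoring keeps only fully contained kmers", {
  region <- pa_region(-100L, 100L)
  d <- pa_trim(pa_simulate(pa_profile(), 10, 0, seed = 8), region)
  mk <- pa_fit_markov(pa_simulate(pa_profile(), 10, 0, seed = 9))
  f <- pa_sample_negatives(mk, 10, length = 200, region = region, seed = 10)
  psm3 <- pa_psm(d, f, k = 3)
  psm2 <- pa_psm(d, f, k = 2)
  # kmer counts per subregion: 98 trimers upstream, 48 downstream, 19 dimers
  expect_length(polyasite:::subregion_start_indices(
    region, pa_region(-100L, -1L), 3L), 98L)
  expect_length(polyasite:::subregion_start_indices(
    region, pa_region(1L, 50L), 3L), 48L)
  expect_length(polyasite:::subregion_start_indices(
    region, pa_region(-10L, 10L), 2L), 19L)

  # additivity: <-100,+1> and <-1,+100> split the trimer starts disjointly
  s_full <- pa_psm_score(psm3, d$sequence)
  s_a <- pa_psm_score(psm3, d$sequence, pa_region(-100L, 1L))
  s_b <- pa_psm_score(psm3, d$sequence, pa_region(-1L, 100L))
  expect_equal(s_full, s_a + s_b, tolerance = 1e-10)

  expect_error(pa_psm_score(psm2, d$sequence, pa_region(-150L, 10L)),
               "not contained")
})

test_that("ambiguous bases contribute zero to scores", {
  r2 <- pa_region(-2L, 2L)
  real <- pa_dataset("r", "AAAA", "real", r2)
  false <- pa_dataset("f", "CCCC", "false", r2)
  psm <- pa_psm(real, false, k = 2, region = r2)
  sN <- pa_psm_score(psm, "AANA")   # only the leading AA window is intact
  expect_equal(sN, unname(psm$values["AA", 1]))
})

test_that("zero pseudocount is rejected when entries would be infinite", {
  r2 <- pa_region(-1L, 1L)
  real <- pa_dataset("r", "AA", "real", r2)
  false <- pa_dataset("f", "AC", "false", r2)
  expect_error(pa_psm(real, false, k = 2, region = r2, alpha = 0),
               "pseudocount")
})

test_that("real sequences outscore negatives on held-out data", {
  prof <- pa_profile()
  train_r <- pa_simulate(prof, 500, 0, seed = 11)
  mk <- pa_fit_markov(train_r)
  train_f <- pa_sample_negatives(mk, 500, length = 600, seed = 12)
  psm <- pa_psm(train_r, train_f, k = 3)
  test_r <- pa_trim(pa_simulate(prof, 1000, 0, seed = 13),
                    pa_region(-100L, 100L))
  test_f <- pa_sample_negatives(mk, 1000, length = 200,
                                region = pa_region(-100L, 100L), seed = 14)
  expect_gt(mean(pa_psm_score(psm, test_r$sequence)),
            mean(pa_psm_score(psm, test_f$sequence)))
})
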