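test_that("confusion metrics follow the exact formulas", {
  perfect <- pa_confusion(rep(c("real", "false"), 10),
                          rep(c("real", "false"), 10))
  expect_equal(perfect$sn, 100)
  expect_equal(perfect$sp, 100)
  expect_equal(perfect$mcc, 1)

  m <- pa_confusion_counts(tp = 85, fn = 15, tn = 93, fp = 7)
  expect_equal(m$sn, 85)
  expect_equal(m$sp, 93)
  expect_equal(round(m$mcc, 2), 0.78)

  # all-positive predictor: denominator factor 0 -> MCC 0 by convention
  allpos <- pa_confusion(rep("real", 10),
                         rep(c("real", "false"), 5))
  expect_equal(allpos$mcc, 0)
  expect_error(pa_confusion(character(0), character(0)), "nonempty")
})

test_that("published per-species Sn/Sp pairs reproduce the printed MCC", {
  perf <- pa_benchmark_performance()
  # equal-class reading: per 100 positives and 100 negatives
  recomputed <- mapply(function(sn, sp) {
    pa_confusion_counts(tp = sn, fn = 100 - sn, tn = sp, fp = 100 - sp)$mcc
  }, perf$sn, perf$sp)
  checks <- tibble::tibble(species = perf$species, method = perf$method,
                           printed = perf$mcc,
                           recomputed = round(recomputed, 2))
  key <- checks[
    (checks$species %in% c("human", "mouse", "chicken", "c.elegans") &
       checks$method == "lda") |
      (checks$species == "mouse" & checks$method == "lr"), ]
  expect_equal(key$recomputed, key$printed)
})

test_that("cross-validation partitions correctly and counts 200 fits", {
  f <- local({
    set.seed(1)
    x <- matrix(rnorm(120 * 4), ncol = 4,
                dimnames = list(NULL, c("f_up3", "f_down3", "f_cs2",
                                        "f_nom")))
    x[1:60, 1] <- x[1:60, 1] + 3
    out <- tibble::as_tibble(as.data.frame(x))
    out$label <- rep(c("real", "false"), each = 60)
    out
  })
  cv <- pa_cross_validate(f, "lr", repetitions = 20, folds = 10, seed = 2)
  expect_equal(attr(cv, "n_fits"), 200L)
  reps <- attr(cv, "repetitions")
  expect_equal(nrow(reps), 20L)
  # every record tested exactly once per repetition:
  # counts per repetition sum to the dataset size
  expect_true(all(reps$tp + reps$tn + reps$fp + reps$fn == nrow(f)))
  expect_error(pa_cross_validate(f, "lr", folds = 100), "fold count")
})

test_that("fold assignment is stratified and exhaustive", {
  set.seed(3)
  y <- rep(c("real", "false"), c(40, 40))
  cls <- split(seq_along(y), y)
  fold <- integer(length(y))
  for (ix in cls) fold[ix] <- sample(rep_len(1:10, length(ix)))
  # the same construction pa_cross_validate uses: per class, folds balanced
  for (lbl in c("real", "false")) {
    tab <- table(fold[y == lbl])
    expect_true(max(tab) - min(tab) <= 1)
  }
  expect_equal(sort(unique(fold)), 1:10)
})

test_that("threshold sweep is monotone with sensible extremes", {
  set.seed(4)
  p <- c(runif(50, 0.4, 1), runif(50, 0, 0.6))
  y <- rep(c("real", "false"), each = 50)
  roc <- pa_roc(p, y)
  expect_equal(roc$sn[roc$threshold == 0], 100)
  expect_equal(roc$sp[nrow(roc)], 100)  # threshold 1 > max(p)
  expect_true(all(diff(roc$sn) <= 1e-9))
  expect_true(all(diff(roc$sp) >= -1e-9))
  expect_error(pa_roc(p, rep("real", 100)), "both classes")
  expect_error(pa_roc(p * 2, y), "\\[0,1\\]")
})

test_that("well-separated classes put the Youden threshold near 0.5", {
  f <- local({
    set.seed(5)
    x <- matrix(rnorm(2000 * 4), ncol = 4,
                dimnames = list(NULL, c("f_up3", "f_down3", "f_cs2",
                                        "f_nom")))
    x[1:1000, ] <- x[1:1000, ] + rep(c(1.5, 1, 0.5, 0.5), each = 1000)
    out <- tibble::as_tibble(as.data.frame(x))
    out$label <- rep(c("real", "false"), each = 1000)
    out
  })
  m <- pa_train(f, "lr")
  roc <- pa_roc(predict(m, f)$.prob, f$label)
  expect_gte(attr(roc, "youden_threshold"), 0.3)
  expect_lte(attr(roc, "youden_threshold"), 0.7)
})

test_that("reciprocal sensitivity is the pair mean and matches the table", {
  expect_equal(pa_reciprocal_sn(90, 87), 88.5)
  expect_equal(pa_reciprocal_sn(90, 80), 85.0)
  expect_equal(pa_reciprocal_sn(73.2, 73.2), 73.2)

  # all 21 species pairs: mean of the directed matrix equals the published
  # rSn column
  rsn <- pa_rsn_table()
  expect_equal(nrow(rsn), 21L)
  ref <- pa_benchmark_distances()
  key <- paste(pmin(ref$species1, ref$species2),
               pmax(ref$species1, ref$species2))
  m <- match(paste(pmin(rsn$species1, rsn$species2),
                   pmax(rsn$species1, rsn$species2)), key)
  expect_false(anyNA(m))
  expect_equal(rsn$rsn, ref$rsn[m])
})

test_that("distance-rSn correlations reproduce the published values", {
  ref <- pa_benchmark_distances()
  expect_equal(round(pa_distance_cor(ref, "gapdh"), 2), -0.87)
  expect_equal(round(pa_distance_cor(ref, "d18s"), 2), -0.50)
  expect_equal(round(pa_distance_cor(ref, "cpsf3"), 2), -0.77)

  toy <- tibble::tibble(d = 1:5, rsn = seq(90, 50, by = -10))
  expect_equal(pa_distance_cor(toy, "d"), -1)
  perm <- toy[c(3, 1, 5, 2, 4), ]
  expect_equal(pa_distance_cor(perm, "d"), -1)
  expect_error(pa_distance_cor(toy[1:2, ], "d"), "at least 3")
  flat <- tibble::tibble(d = rep(1, 5), rsn = seq(90, 50, by = -10))
  expect_error(pa_distance_cor(flat, "d"), "zero variance")
})

test_that("a model applied to its own training set matches training Sn", {
  d <- training_dataset(150, seed = 6)
  bundle <- pa_polya_model(d, "lr")
  real <- d[d$label == "real", ]
  attr(real, "region") <- pa_dataset_region(d)
  sn_direct <- 100 * mean(
    predict(bundle$classifier,
            bundle$features[bundle$features$label == "real", ])$.label ==
      "real"
  )
  expect_equal(pa_cross_species_sn(bundle, real), sn_direct)
})

test_that("random sequences yield cross-species Sn near the FP rate", {
  d <- training_dataset(300, seed = 7)
  bundle <- pa_polya_model(d, "lr")
  # negatives from the same chain = the model's own false class
  mk <- pa_fit_markov(d)
  rand <- pa_sample_negatives(mk, 400, length = 600, seed = 8)
  set.seed(9)
  rand$track <- lapply(seq_len(400), function(i) {
    pmin(pmax(0.6 + rnorm(600, 0, 0.05), 0), 1)
  })
  rand$label <- "real"  # treat as the 'real' set of a signal-less species
  attr(rand, "region") <- pa_dataset_region(d)
  class(rand) <- class(d)
  sn_rand <- pa_cross_species_sn(bundle, rand)
  fp_rate <- 100 - 100 * mean(
    predict(bundle$classifier,
            bundle$features[bundle$features$label == "false", ])$.label ==
      "false"
  )
  expect_lte(abs(sn_rand - fp_rate), 10)
})
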