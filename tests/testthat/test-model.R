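# independent LDA oracle: evaluate the two shared-covariance Gaussian
# densities directly and compare posteriors
oracle_lda_posterior <- function(x, mu1, mu0, sigma, p1, p0) {
  dens <- function(z, mu) {
    k <- length(mu)
    d <- z - mu
    exp(-0.5 * drop(t(d) %*% solve(sigma) %*% d)) /
      sqrt((2 * pi)^k * det(sigma))
  }
  apply(x, 1, function(z) {
    a <- p1 * dens(z, mu1); b <- p0 * dens(z, mu0)
    a / (a + b)
  })
}

as_feat <- function(v) {
  matrix(v, 1, dimnames = list(NULL, c("f_up3", "f_down3", "f_cs2",
                                       "f_nom")))
}

toy_features <- function(n, delta, seed, sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n * 4, 0, sd), ncol = 4,
              dimnames = list(NULL, c("f_up3", "f_down3", "f_cs2", "f_nom")))
  y <- rep(c("real", "false"), each = n)
  x[y == "real", ] <- x[y == "real", ] + rep(delta, each = n)
  out <- tibble::as_tibble(as.data.frame(x))
  out$label <- y
  out
}

test_that("feature assembly uses the fixed subregions in fixed order", {
  d <- training_dataset(40, seed = 1)
  real <- d[d$label == "real", ]; attr(real, "region") <- pa_dataset_region(d)
  false <- d[d$label == "false", ]
  attr(false, "region") <- pa_dataset_region(d)
  psm3 <- pa_psm(real, false, k = 3)
  psm2 <- pa_psm(real, false, k = 2)
  nom <- pa_nom(do.call(rbind, real$track), do.call(rbind, false$track))
  f <- pa_features(d, psm3, psm2, nom)
  expect_named(f, c("id", "label", "f_up3", "f_down3", "f_cs2", "f_nom"))
  # each column reproduces the underlying scoring call
  seqs <- pa_trim(d, pa_region(-100L, 100L))$sequence
  expect_equal(f$f_up3, pa_psm_score(psm3, seqs, pa_region(-100L, -1L)))
  expect_equal(f$f_down3, pa_psm_score(psm3, seqs, pa_region(1L, 50L)))
  expect_equal(f$f_cs2, pa_psm_score(psm2, seqs, pa_region(-10L, 10L)))
  expect_equal(f$f_nom, pa_nom_score(nom, do.call(rbind, d$track)))
  # planted signal shows in the upstream feature
  expect_gt(mean(f$f_up3[f$label == "real"]),
            mean(f$f_up3[f$label == "false"]))

  # all-zero matrices give the zero vector
  z3 <- psm3; z3$values[] <- 0
  z2 <- psm2; z2$values[] <- 0
  zn <- nom; zn$values[] <- 0
  fz <- pa_features(d[1:2, ] |> `attr<-`("region", pa_dataset_region(d)),
                    z3, z2, zn)
  expect_equal(unname(as.matrix(fz[, 3:6])), matrix(0, 2, 4))
})

test_that("standardizer gives pooled mean 0 / sd 1 and is train-only", {
  f <- toy_features(100, c(1, 0, 0, 0), seed = 2)
  std <- pa_fit_standardizer(f)
  z <- pa_standardize(std, f)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4), tolerance = 1e-9)

  # hand example: values {0, 2} -> mean 1, transformed to -/+ 1/sd
  m <- matrix(c(0, 2), ncol = 1, dimnames = list(NULL, "f_up3"))
  s2 <- pa_fit_standardizer(m)
  expect_equal(unname(s2$means), 1)
  expect_equal(unname(pa_standardize(s2, m)[, 1]), c(-1, 1) / sqrt(2))

  # a fitted model standardizes new data with training parameters
  model <- pa_train(f, "lr")
  test <- toy_features(10, c(5, 5, 5, 5), seed = 3)  # shifted test set
  p <- predict(model, test)
  expect_true(all(p$.prob >= 0 & p$.prob <= 1))
  cons <- matrix(1, 3, 4,
                 dimnames = list(NULL, c("f_up3", "f_down3", "f_cs2",
                                         "f_nom")))
  expect_error(pa_fit_standardizer(cons), "zero variance")
})

test_that("logistic training separates, is label-antisymmetric, converges", {
  f <- toy_features(150, c(10, 0, 0, 0), seed = 4)  # classes far apart
  m <- pa_train(f, "lr")
  acc <- mean(predict(m, f)$.label == f$label)
  expect_equal(acc, 1)

  # moderate overlap so the fit is interior
  f2 <- toy_features(300, c(1, 0.5, 0, 0), seed = 5)
  f2l <- f2; f2l$label <- ifelse(f2$label == "real", "false", "real")
  w1 <- pa_train(f2, "lr")$parameters$coefficients
  w2 <- pa_train(f2l, "lr")$parameters$coefficients
  expect_equal(unname(w1), unname(-w2), tolerance = 1e-4)
})

test_that("logistic fit approaches the Bayes-optimal linear boundary", {
  # two spherical Gaussians, equal priors: optimal w = mu1 - mu0,
  # b = -(|mu1|^2 - |mu0|^2)/2
  mu1 <- c(1, 0.5, -0.5, 0.25)
  n <- 10000
  f <- toy_features(n, mu1, seed = 6)
  m <- pa_train(f, "lr", standardize = FALSE)
  co <- m$parameters$coefficients
  w <- co[-1]; b <- co[1]
  # compare directions after normalizing both to |w| = 1
  w_opt <- mu1; b_opt <- -sum(mu1^2) / 2
  expect_equal(unname(w / sqrt(sum(w^2))), w_opt / sqrt(sum(w_opt^2)),
               tolerance = 0.05)
  expect_equal(unname(b / sqrt(sum(w^2))), b_opt / sqrt(sum(w_opt^2)),
               tolerance = 0.05)
})

test_that("LDA matches the brute-force Gaussian-density oracle", {
  f <- toy_features(25, c(1.5, -1, 0.5, 0), seed = 7)  # 50-point toy set
  m <- pa_train(f, "lda", standardize = FALSE)
  par <- m$parameters
  p_pkg <- predict(m, f)$.prob
  p_orc <- oracle_lda_posterior(polyasite:::feature_matrix(f),
                                par$mu_real, par$mu_false, par$cov_pooled,
                                par$prior_real, par$prior_false)
  expect_equal(p_pkg, unname(p_orc), tolerance = 1e-10)

  # same class assignments as MASS::lda on the same data
  ml <- MASS::lda(polyasite:::feature_matrix(f), grouping = f$label)
  cls <- as.character(predict(ml)$class)
  expect_equal(ifelse(p_pkg >= 0.5, "real", "false"), cls)

  # posterior at a class mean favours that class
  expect_gt(predict(m, as_feat(par$mu_real))$.prob, 0.5)
  expect_lt(predict(m, as_feat(par$mu_false))$.prob, 0.5)
})

test_that("symmetric classes put the LDA boundary at the midpoint", {
  set.seed(8)
  f <- toy_features(500, c(2, 0, 0, 0), seed = 8)
  m <- pa_train(f, "lda", standardize = FALSE)
  mid <- (m$parameters$mu_real + m$parameters$mu_false) / 2
  expect_equal(predict(m, as_feat(mid))$.prob, 0.5, tolerance = 1e-9)
})

test_that("prediction obeys the tie rule, monotonicity and batch identity", {
  f <- toy_features(100, c(2, 1, 0, 0), seed = 9)
  m <- pa_train(f, "lr")
  # tie at threshold is positive
  m2 <- m; m2$threshold <- 0.25
  probe <- f[3, ]
  p <- predict(m, probe)$.prob
  m3 <- m; m3$threshold <- p
  expect_equal(predict(m3, probe)$.label, "real")

  # monotone in a positively weighted feature
  w <- m$parameters$coefficients[-1]
  j <- which.max(w)
  x1 <- polyasite:::feature_matrix(f[1, ])
  x2 <- x1; x2[, j] <- x2[, j] + 10
  expect_gte(predict(m, x2)$.prob, predict(m, x1)$.prob)

  # batch equals record-wise
  batch <- predict(m, f)$.prob
  each <- vapply(seq_len(nrow(f)), function(i) predict(m, f[i, ])$.prob, 0)
  expect_equal(batch, each)

  expect_error(predict(m, f[, c(1, 2, 3)]), "feature columns")
  expect_error(pa_train(f[f$label == "real", ], "lr"), "both classes")
})

test_that("LR and LDA agree on well-separated data", {
  f <- toy_features(1000, c(2, 1, -1, 0.5), seed = 10)
  test <- toy_features(500, c(2, 1, -1, 0.5), seed = 11)
  lr <- predict(pa_train(f, "lr"), test)$.label
  lda <- predict(pa_train(f, "lda"), test)$.label
  expect_gte(mean(lr == lda), 0.9)
})

test_that("fitted objects serialize to JSON and back", {
  f <- toy_features(60, c(1, 0, 0, 0.5), seed = 12)
  for (method in c("lr", "lda")) {
    m <- pa_train(f, method)
    path <- tempfile(fileext = ".json")
    pa_write_json(m, path)
    m2 <- pa_read_model(path)
    expect_equal(predict(m2, f)$.prob, predict(m, f)$.prob,
                 tolerance = 1e-8)
  }
  d <- pa_simulate(pa_profile(), 20, 0, seed = 13)
  mk <- pa_fit_markov(d)
  path <- tempfile(fileext = ".json")
  pa_write_json(mk, path)
  mk2 <- pa_read_markov(path)
  expect_equal(mk2$transitions, mk$transitions, tolerance = 1e-12)
  expect_identical(pa_sample_negatives(mk2, 3, 50, seed = 1)$sequence,
                   pa_sample_negatives(mk, 3, 50, seed = 1)$sequence)
})
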