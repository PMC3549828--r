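#' Assemble the four-feature vector
#'
#' Every site is summarized by four scores: the upstream trimer PSM score
#' over `<-100,-1>` (`f_up3`), the downstream trimer PSM score over
#' `<+1,+50>` (`f_down3`), the cleavage-site dimer PSM score over
#' `<-10,+10>` (`f_cs2`), and the NOM occupancy score over `<-300,+300>`
#' (`f_nom`). The feature order is fixed and part of the API. Sequences are
#' scored over the PSM region (`<-100,+100>` by default), extracted from the
#' dataset's wider region if necessary; tracks must match the NOM region.
#'
#' @param data a [pa_dataset()] whose region contains the PSM region and,
#'   when `nom` is given, whose `track` column covers the NOM region.
#' @param psm3 trimer [pa_psm()].
#' @param psm2 dimer [pa_psm()].
#' @param nom optional [pa_nom()]; without it the `f_nom` column is omitted
#'   and the classifier runs on the three sequence features.
#' @return A tibble: `id`, `label`, `f_up3`, `f_down3`, `f_cs2`, `f_nom`.
#' @export
pa_features <- function(data, psm3, psm2, nom = NULL) {
  seqs <- pa_trim(data, psm3$region)$sequence
  f1 <- pa_psm_score(psm3, seqs, pa_region(-100L, -1L))
  f2 <- pa_psm_score(psm3, seqs, pa_region(1L, 50L))
  f3 <- pa_psm_score(psm2, pa_trim(data, psm2$region)$sequence,
                     pa_region(-10L, 10L))
  if (is.null(nom)) {
    return(tibble::tibble(id = data$id, label = data$label,
                          f_up3 = f1, f_down3 = f2, f_cs2 = f3))
  }
  f4 <- {
    if (!"track" %in% names(data))
      stop("dataset has no `track` column for the NOM feature",
           call. = FALSE)
    tr <- data
    if (pa_dataset_region(data)$length != nom$region$length)
      tr <- pa_trim(data, nom$region)
    pa_nom_score(nom, do.call(rbind, tr$track))
  }
  tibble::tibble(id = data$id, label = data$label,
                 f_up3 = f1, f_down3 = f2, f_cs2 = f3, f_nom = f4)
}

feature_cols <- c("f_up3", "f_down3", "f_cs2", "f_nom")

feature_matrix <- function(features) {
  nms <- if (is.matrix(features)) colnames(features) else names(features)
  cols <- intersect(feature_cols, nms)
  if (!length(cols)) stop("no feature columns found", call. = FALSE)
  if (is.matrix(features)) features[, cols, drop = FALSE]
  else as.matrix(features[cols])
}

#' Feature standardization
#'
#' Fits per-feature means and standard deviations over the pooled training
#' set (real and false together) and applies the z-transform. Test data must
#' be standardized with the training parameters, never its own statistics;
#' [pa_train()] enforces this by storing the standardizer inside the model.
#'
#' @param features a feature tibble or numeric matrix.
#' @return `pa_fit_standardizer()`: a `pa_standardizer` (means, sds);
#'   `pa_standardize()`: the transformed matrix.
#' @export
pa_fit_standardizer <- function(features) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  if (nrow(x) < 2L) stop("need at least 2 vectors", call. = FALSE)
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  zero <- sd_ <= 0 | !is.finite(sd_)
  if (any(zero))
    stop("zero variance in feature(s): ",
         paste(colnames(x)[zero], collapse = ", "), call. = FALSE)
  structure(list(means = mu, sds = sd_), class = "pa_standardizer")
}

#' @rdname pa_fit_standardizer
#' @param standardizer a fitted `pa_standardizer`.
#' @export
pa_standardize <- function(standardizer, features) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  scale(x, center = standardizer$means, scale = standardizer$sds)[, ,
                                                                  drop = FALSE]
}

#' Train a poly(A) site classifier
#'
#' Fits a logistic regression (`"lr"`, maximum likelihood via IRLS through
#' [stats::glm()], iteration-capped so perfectly separable data converges
#' with a warning) or a linear discriminant analysis (`"lda"`, class means
#' with pooled within-class covariance and class-frequency priors) on the
#' four standardized features. Both classifiers output a positive-class
#' probability; the decision threshold defaults to 0.5 and ties are called
#' positive.
#'
#' @param features a feature tibble from [pa_features()] (columns `label`
#'   plus the four features), or a matrix with `labels` given separately.
#' @param method `"lr"` or `"lda"`.
#' @param labels optional character/factor labels when `features` is a
#'   matrix.
#' @param threshold decision cutoff on the positive-class probability.
#' @param standardize fit a standardizer on this training set (default);
#'   set `FALSE` if features are already standardized.
#' @param ridge ridge added to a singular pooled covariance (LDA), as a
#'   fraction of its mean diagonal.
#' @return A `pa_model`.
#' @export
pa_train <- function(features, method = c("lr", "lda"), labels = NULL,
                     threshold = 0.5, standardize = TRUE, ridge = 1e-8) {
  method <- match.arg(method)
  x <- feature_matrix(features)
  y <- if (!is.null(labels)) as.character(labels) else features$label
  if (length(unique(y)) != 2L)
    stop("both classes must be present", call. = FALSE)
  if (!all(y %in% c("real", "false")))
    stop("labels must be \"real\"/\"false\"", call. = FALSE)
  std <- if (standardize) pa_fit_standardizer(x) else NULL
  xs <- if (standardize) pa_standardize(std, x) else x
  yb <- as.integer(y == "real")
  if (method == "lr") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, xs), yb,
                     family = stats::binomial(),
                     control = list(maxit = 100))
    )
    if (!fit$converged)
      warning("logistic fit did not converge within 100 IRLS iterations ",
              "(possible perfect separation)", call. = FALSE)
    params <- list(coefficients = fit$coefficients)
  } else {
    params <- fit_lda(xs, yb, ridge)
  }
  structure(list(method = method, standardizer = std, parameters = params,
                 threshold = threshold, features = colnames(x)),
            class = "pa_model")
}

fit_lda <- function(x, yb, ridge) {
  x1 <- x[yb == 1L, , drop = FALSE]
  x0 <- x[yb == 0L, , drop = FALSE]
  n1 <- nrow(x1); n0 <- nrow(x0)
  mu1 <- colMeans(x1); mu0 <- colMeans(x0)
  s1 <- stats::cov(x1); s0 <- stats::cov(x0)
  sp <- ((n1 - 1) * s1 + (n0 - 1) * s0) / (n1 + n0 - 2)
  inv <- tryCatch(solve(sp), error = function(e) NULL)
  if (is.null(inv)) {
    message("pooled covariance singular; adding ridge ", ridge)
    sp <- sp + diag(ridge * mean(diag(sp)), ncol(x))
    inv <- solve(sp)
  }
  list(mu_real = mu1, mu_false = mu0, cov_pooled = sp, cov_inv = inv,
       prior_real = n1 / (n1 + n0), prior_false = n0 / (n1 + n0))
}

#' @export
print.pa_model <- function(x, ...) {
  cat("<pa_model> ", toupper(x$method), " on ",
      paste(x$features, collapse = ", "),
      "; threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Predict poly(A) site probabilities and labels
#'
#' Applies the model's stored standardizer, then the fitted classifier.
#' Records with probability at or above the threshold are labelled
#' `"real"` (ties go to the positive class).
#'
#' @param object a [pa_train()] model.
#' @param newdata a feature tibble or matrix.
#' @param ... unused.
#' @return A tibble with `.prob` and `.label`.
#' @export
predict.pa_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  if (!identical(colnames(x), object$features))
    stop("feature columns must be exactly: ",
         paste(object$features, collapse = ", "), call. = FALSE)
  if (!is.null(object$standardizer))
    x <- pa_standardize(object$standardizer, x)
  p <- if (object$method == "lr") {
    eta <- drop(cbind(1, x) %*% object$parameters$coefficients)
    stats::plogis(eta)
  } else {
    lda_posterior(object$parameters, x)
  }
  tibble::tibble(.prob = p,
                 .label = ifelse(p >= object$threshold, "real", "false"))
}

lda_posterior <- function(par, x) {
  # shared-covariance Gaussian discriminant: posterior of class "real"
  d1 <- mahal_quad(x, par$mu_real, par$cov_inv)
  d0 <- mahal_quad(x, par$mu_false, par$cov_inv)
  a <- log(par$prior_real) - d1 / 2
  b <- log(par$prior_false) - d0 / 2
  1 / (1 + exp(b - a))
}

mahal_quad <- function(x, mu, inv) {
  d <- sweep(x, 2, mu)
  rowSums((d %*% inv) * d)
}
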