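#' Confusion-matrix performance metrics
#'
#' Sensitivity `Sn = Tp/(Tp+Fn) * 100`, specificity `Sp = Tn/(Tn+Fp) * 100`
#' (both percentages), and the Matthews correlation coefficient
#' `MCC = (Tp*Tn - Fp*Fn) / sqrt((Tp+Fp)(Tp+Fn)(Tn+Fp)(Tn+Fn))`, with the
#' convention MCC = 0 whenever a denominator factor is 0. The positive class
#' is `"real"`.
#'
#' @param predicted,truth equal-length label vectors (`"real"`/`"false"`),
#'   or `pa_confusion_counts(tp, tn, fp, fn)` for direct counts.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `sn`, `sp`, `mcc`.
#' @export
pa_confusion <- function(predicted, truth) {
  if (!length(predicted) || length(predicted) != length(truth))
    stop("predicted and truth must be nonempty and of equal length",
         call. = FALSE)
  pa_confusion_counts(
    tp = sum(predicted == "real" & truth == "real"),
    tn = sum(predicted == "false" & truth == "false"),
    fp = sum(predicted == "real" & truth == "false"),
    fn = sum(predicted == "false" & truth == "real")
  )
}

#' @rdname pa_confusion
#' @param tp,tn,fp,fn nonnegative counts.
#' @export
pa_confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sn = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    mcc = mcc
  )
}

#' Repeated stratified cross-validation
#'
#' Evaluates a classifier by `repetitions` independent rounds of stratified
#' `folds`-fold cross-validation (the default, 20 x 10-fold, performs 200
#' model fits). Folds are stratified by class; within each repetition every
#' record is tested exactly once by a model trained on the remaining folds.
#' The standardizer is refitted on each training split, so no test-set
#' statistics leak into training; set `paper_standardization = TRUE` to
#' standardize once over the whole dataset before splitting instead.
#' Metrics are computed per repetition from the pooled out-of-fold
#' predictions and averaged.
#'
#' @param features a feature tibble from [pa_features()].
#' @param method `"lr"` or `"lda"`.
#' @param repetitions,folds cross-validation design (defaults 20 and 10).
#' @param threshold decision cutoff passed to [pa_train()].
#' @param paper_standardization standardize on the full dataset once.
#' @param seed optional integer seed.
#' @return A one-row tibble of mean metrics (`sn`, `sp`, `mcc`) with their
#'   standard deviations (`sn_sd`, ...); per-repetition results in the
#'   `"repetitions"` attribute, total fit count in `"n_fits"`.
#' @export
pa_cross_validate <- function(features, method = c("lr", "lda"),
                              repetitions = 20L, folds = 10L,
                              threshold = 0.5,
                              paper_standardization = FALSE, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  y <- features$label
  cls <- split(seq_along(y), y)
  if (length(cls) != 2L) stop("both classes must be present", call. = FALSE)
  if (any(vapply(cls, length, 1L) < folds))
    stop("fold count exceeds the size of a class", call. = FALSE)
  feats <- features
  standardize <- TRUE
  if (paper_standardization) {
    std <- pa_fit_standardizer(feats)
    fm <- pa_standardize(std, feats)
    feats <- tibble::as_tibble(fm)
    feats$label <- y
    standardize <- FALSE
  }
  n_fits <- 0L
  reps <- purrr::map_dfr(seq_len(repetitions), function(rep_i) {
    fold <- integer(length(y))
    for (ix in cls) fold[ix] <- sample(rep_len(seq_len(folds), length(ix)))
    pred <- character(length(y))
    for (f in seq_len(folds)) {
      test <- fold == f
      m <- pa_train(feats[!test, , drop = FALSE], method,
                    threshold = threshold, standardize = standardize)
      n_fits <<- n_fits + 1L
      pred[test] <- predict(m, feats[test, , drop = FALSE])$.label
    }
    dplyr::mutate(pa_confusion(pred, y), repetition = rep_i)
  })
  out <- tibble::tibble(
    method = method, repetitions = repetitions, folds = folds,
    sn = mean(reps$sn), sn_sd = stats::sd(reps$sn),
    sp = mean(reps$sp), sp_sd = stats::sd(reps$sp),
    mcc = mean(reps$mcc), mcc_sd = stats::sd(reps$mcc)
  )
  attr(out, "repetitions") <- reps
  attr(out, "n_fits") <- n_fits
  out
}

#' Threshold sweep (ROC analysis)
#'
#' Computes sensitivity and specificity over a grid of decision thresholds
#' and reports the Youden-optimal threshold (max `Sn + Sp`). By
#' construction Sn is non-increasing and Sp non-decreasing in the
#' threshold.
#'
#' @param probabilities positive-class probabilities in `[0,1]`.
#' @param truth labels (`"real"`/`"false"`).
#' @param thresholds grid over `[0,1]` (default `seq(0, 1, 0.01)`).
#' @return A tibble (`threshold`, `sn`, `sp`, `youden`); the best threshold
#'   in attribute `"youden_threshold"`.
#' @export
pa_roc <- function(probabilities, truth, thresholds = seq(0, 1, by = 0.01)) {
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0,1]", call. = FALSE)
  if (length(unique(truth)) < 2L)
    stop("truth must contain both classes", call. = FALSE)
  pos <- truth == "real"
  out <- purrr::map_dfr(thresholds, function(t) {
    pred <- ifelse(probabilities >= t, "real", "false")
    m <- pa_confusion(pred, truth)
    tibble::tibble(threshold = t, sn = m$sn, sp = m$sp,
                   youden = m$sn + m$sp - 100)
  })
  attr(out, "youden_threshold") <- out$threshold[which.max(out$youden)]
  out
}

#' Cross-species sensitivity
#'
#' Applies a model trained on species A to the real site sequences of
#' species B and reports the fraction predicted positive (x 100). Feature
#' extraction for B uses A's matrices (PSMs and NOM) and A's standardizer —
#' the whole bundle travels with the model (see [pa_polya_model()]).
#'
#' @param bundle a [pa_polya_model()] of the source species.
#' @param data a [pa_dataset()] of the target species' real sites (tracks
#'   required when the bundle carries a NOM).
#' @return Sensitivity as a percentage.
#' @export
pa_cross_species_sn <- function(bundle, data) {
  stopifnot(inherits(bundle, "pa_polya_model"))
  f <- pa_features(data, bundle$psm3, bundle$psm2, bundle$nom)
  pred <- predict(bundle$classifier, f)
  100 * mean(pred$.label == "real")
}

#' Reciprocal sensitivity
#'
#' The symmetric cross-species agreement for a species pair: the arithmetic
#' mean of the two directed sensitivities (A's model on B's sites and
#' vice versa). Used as a proxy for the similarity of poly(A) site
#' architecture between species.
#'
#' @param sn_ab,sn_ba directed sensitivities in `[0,100]`.
#' @return `(sn_ab + sn_ba) / 2`.
#' @export
pa_reciprocal_sn <- function(sn_ab, sn_ba) {
  stopifnot(all(sn_ab >= 0 & sn_ab <= 100), all(sn_ba >= 0 & sn_ba <= 100))
  (sn_ab + sn_ba) / 2
}

#' Correlation between phylogenetic distance and reciprocal sensitivity
#'
#' Pearson correlation, over species pairs, of a marker-gene phylogenetic
#' distance against reciprocal sensitivity. A strongly negative value means
#' model transferability decays with evolutionary distance.
#'
#' @param table a data frame of species pairs with an `rsn` column.
#' @param marker name of the distance column (e.g. `"gapdh"`).
#' @return Pearson correlation coefficient.
#' @export
pa_distance_cor <- function(table, marker) {
  if (!marker %in% names(table))
    stop("no column ", sQuote(marker), " in table", call. = FALSE)
  d <- table[[marker]]; r <- table$rsn
  ok <- stats::complete.cases(d, r)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(d[ok]) == 0 || stats::sd(r[ok]) == 0)
    stop("zero variance in ", if (stats::sd(d[ok]) == 0) marker else "rsn",
         call. = FALSE)
  stats::cor(d[ok], r[ok])
}
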