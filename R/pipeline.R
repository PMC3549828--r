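#' Fit a complete poly(A) site model
#'
#' Convenience wrapper running the full training pipeline on a labelled
#' dataset: build the trimer and dimer PSMs over `<-100,+100>`, the NOM over
#' `<-300,+300>` (when tracks are present), assemble the four features, and
#' train the classifier. The returned bundle carries everything needed to
#' score new sequences — matrices, standardizer and classifier — so it can
#' be applied unchanged to another species' data ([pa_cross_species_sn()])
#' or slid along a chromosome ([pa_scan()]).
#'
#' @param data a [pa_dataset()] over a region containing `<-100,+100>`
#'   (and `<-300,+300>` when tracks are used) with both `"real"` and
#'   `"false"` records; give `track` as a list-column to enable the NOM
#'   feature.
#' @param method `"lr"` or `"lda"`.
#' @param alpha PSM/NOM pseudocount.
#' @param bins NOM probability bins.
#' @param threshold decision cutoff.
#' @param use_nom include the NOM feature (default: when tracks present).
#' @return A `pa_polya_model`: `psm3`, `psm2`, `nom` (or `NULL`),
#'   `classifier`, `features` (the training feature tibble).
#' @export
pa_polya_model <- function(data, method = c("lr", "lda"), alpha = 1,
                           bins = 20L, threshold = 0.5,
                           use_nom = "track" %in% names(data)) {
  method <- match.arg(method)
  real <- data[data$label == "real", ]
  false <- data[data$label == "false", ]
  attr(real, "region") <- attr(false, "region") <- pa_dataset_region(data)
  if (!nrow(real) || !nrow(false))
    stop("need both real and false records", call. = FALSE)
  psm_region <- pa_region(-100L, 100L)
  psm3 <- pa_psm(real, false, k = 3L, region = psm_region, alpha = alpha)
  psm2 <- pa_psm(real, false, k = 2L, region = psm_region, alpha = alpha)
  nom <- NULL
  if (use_nom) {
    nom_region <- pa_region(-300L, 300L)
    rt <- do.call(rbind, pa_trim(real, nom_region)$track)
    ft <- do.call(rbind, pa_trim(false, nom_region)$track)
    nom <- pa_nom(rt, ft, bins = bins, alpha = alpha, region = nom_region)
  }
  feats <- pa_features(data, psm3, psm2, nom)
  classifier <- pa_train(feats, method, threshold = threshold)
  structure(list(psm3 = psm3, psm2 = psm2, nom = nom,
                 classifier = classifier, features = feats,
                 method = method),
            class = "pa_polya_model")
}

#' @export
print.pa_polya_model <- function(x, ...) {
  cat("<pa_polya_model> ", toupper(x$method), ", ",
      sum(x$features$label == "real"), " real / ",
      sum(x$features$label == "false"), " false training sites",
      if (is.null(x$nom)) ", no NOM feature" else "", "\n", sep = "")
  invisible(x)
}

#' Sliding-window scan of a long sequence
#'
#' Slides a 600-nt window along a sequence, scoring each window as if its
#' centre were a cleavage point (window = `<-300,+300>`; PSM features from
#' the central `<-100,+100>`, NOM feature from the whole window). Candidate
#' sites are local probability maxima at or above the threshold, merged
#' within `merge_radius` nt (keeping the strongest). The reported `site` is
#' the sequence position playing the role of `-1`, i.e. the last
#' transcribed base before the putative cleavage point.
#'
#' @param bundle a [pa_polya_model()].
#' @param sequence a single DNA string, length >= 600.
#' @param track optional occupancy track of the same length; if absent and
#'   the bundle uses a NOM, the sequence-derived stand-in profile
#'   ([pa_predict_occupancy()]) is computed over the whole sequence.
#' @param step window step in nt (default 1).
#' @param threshold call threshold on the probability (default: the
#'   classifier's).
#' @param merge_radius merge calls closer than this many nt (default 25).
#' @return A tibble of windows (`start`, `site`, `prob`); called sites in
#'   the `"calls"` attribute (tibble `site`, `prob`).
#' @export
pa_scan <- function(bundle, sequence, track = NULL, step = 1L,
                    threshold = NULL, merge_radius = 25L) {
  stopifnot(inherits(bundle, "pa_polya_model"))
  sequence <- normalize_dna(sequence)
  stopifnot(length(sequence) == 1L)
  window <- 600L
  L <- nchar(sequence)
  if (L < window)
    stop("sequence (", L, " nt) shorter than the ", window, "-nt window",
         call. = FALSE)
  if (is.null(threshold)) threshold <- bundle$classifier$threshold
  use_nom <- !is.null(bundle$nom)
  if (use_nom && is.null(track)) track <- occupancy_profile(sequence)
  if (use_nom && length(track) != L)
    stop("track length must equal sequence length", call. = FALSE)
  starts <- seq.int(1L, L - window + 1L, by = step)
  codes <- encode_bases(sequence)
  idx3 <- kmer_indices(codes, 3L)[1, ]
  idx2 <- kmer_indices(codes, 2L)[1, ]
  wreg <- pa_region(-300L, 300L)
  psm_reg <- bundle$psm3$region
  # window-local kmer start offsets for each feature subregion
  off <- function(psm, win) {
    pa_to_index(psm$region$from, wreg) - 1L +
      subregion_start_indices(psm$region, win, psm$k)
  }
  f1 <- window_sums(bundle$psm3$values, idx3,
                    off(bundle$psm3, pa_region(-100L, -1L)),
                    subregion_start_indices(psm_reg, pa_region(-100L, -1L),
                                            3L), starts)
  f2 <- window_sums(bundle$psm3$values, idx3,
                    off(bundle$psm3, pa_region(1L, 50L)),
                    subregion_start_indices(psm_reg, pa_region(1L, 50L),
                                            3L), starts)
  f3 <- window_sums(bundle$psm2$values, idx2,
                    off(bundle$psm2, pa_region(-10L, 10L)),
                    subregion_start_indices(psm_reg, pa_region(-10L, 10L),
                                            2L), starts)
  f4 <- if (use_nom) {
    bi <- bin_index(pmin(pmax(track, 0), 1), bundle$nom$edges)
    window_sums(bundle$nom$values, bi, seq_len(window), seq_len(window),
                starts)
  } else numeric(length(starts))
  feats <- tibble::tibble(f_up3 = f1, f_down3 = f2, f_cs2 = f3, f_nom = f4)
  prob <- predict(bundle$classifier, feats)$.prob
  site <- starts + 299L  # window position -1 in sequence coordinates
  windows <- tibble::tibble(start = starts, site = site, prob = prob)
  attr(windows, "calls") <- call_sites(windows, threshold, merge_radius)
  windows
}

# sum V[code[s + w - 1], col] over window offsets; vectorized over starts
window_sums <- function(V, code, win_offsets, cols, starts) {
  nr <- nrow(V)
  acc <- numeric(length(starts))
  for (i in seq_along(win_offsets)) {
    cj <- code[starts + win_offsets[i] - 1L]
    ok <- !is.na(cj)
    if (all(ok)) {
      acc <- acc + V[cj + nr * (cols[i] - 1L)]
    } else {
      acc[ok] <- acc[ok] + V[cj[ok] + nr * (cols[i] - 1L)]
    }
  }
  acc
}

call_sites <- function(windows, threshold, merge_radius) {
  p <- windows$prob
  n <- length(p)
  if (!n) return(tibble::tibble(site = integer(), prob = double()))
  left <- c(-Inf, p[-n]); right <- c(p[-1], -Inf)
  cand <- which(p >= threshold & p >= left & p >= right)
  if (!length(cand)) return(tibble::tibble(site = integer(),
                                           prob = double()))
  ord <- cand[order(p[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) ||
        all(abs(windows$site[i] - windows$site[kept]) > merge_radius))
      kept <- c(kept, i)
  }
  kept <- sort(kept)
  tibble::tibble(site = windows$site[kept], prob = windows$prob[kept])
}
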