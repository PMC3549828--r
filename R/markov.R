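#' Fit a second-order Markov chain to real poly(A) sequences
#'
#' False (negative) site sequences are drawn from a homogeneous 2nd-order
#' Markov chain fitted to the real sequences, so that negatives preserve
#' local trinucleotide composition while carrying no positional signal. The
#' chain is fitted by pooling trinucleotide counts over all sequences and
#' positions of the fitting region (default `<-300,+300>`), with Laplace
#' smoothing: `P(z | xy) = (count(xyz)+alpha) / (count(xy.)+4*alpha)`. The
#' initial distribution over the 16 starting dinucleotides is smoothed the
#' same way.
#'
#' @param data a [pa_dataset()]; only rows with `label == "real"` are used.
#' @param alpha additive smoothing pseudocount (default 1; 0 gives the
#'   unsmoothed maximum-likelihood estimate).
#' @return A `pa_markov2` object: `initial` (16 probabilities), `transitions`
#'   (16 x 4 row-stochastic matrix), plus the raw counts and `alpha`.
#' @export
pa_fit_markov <- function(data, alpha = 1) {
  seqs <- data$sequence[data$label == "real"]
  if (!length(seqs)) stop("no real sequences to fit", call. = FALSE)
  codes <- encode_bases(seqs)
  di <- kmer_indices(codes, 2L)
  tri <- kmer_indices(codes, 3L)
  init_counts <- tabulate(di[, 1][!is.na(di[, 1])], nbins = 16L)
  tri_counts <- tabulate(tri[!is.na(tri)], nbins = 64L)
  # trinucleotide index = (dinucleotide context - 1) * 4 + next base
  trans_counts <- matrix(tri_counts, nrow = 16L, ncol = 4L, byrow = TRUE)
  dimnames(trans_counts) <- list(all_kmers(2L), BASES)
  transitions <- (trans_counts + alpha) /
    (rowSums(trans_counts) + 4 * alpha)
  initial <- (init_counts + alpha) / (sum(init_counts) + 16 * alpha)
  names(initial) <- all_kmers(2L)
  if (alpha == 0) {
    transitions[!is.finite(transitions)] <- 0
    if (!sum(init_counts)) stop("empty fit", call. = FALSE)
  }
  structure(
    list(initial = initial, transitions = transitions,
         initial_counts = stats::setNames(init_counts, all_kmers(2L)),
         transition_counts = trans_counts, alpha = alpha),
    class = "pa_markov2"
  )
}

#' @export
print.pa_markov2 <- function(x, ...) {
  cat("<pa_markov2> 2nd-order Markov chain, alpha =", x$alpha, "\n")
  cat("  pooled trinucleotide count:", sum(x$transition_counts), "\n")
  invisible(x)
}

#' Sample false poly(A) sequences from a fitted Markov chain
#'
#' Draws `n` sequences of the requested length from a [pa_fit_markov()]
#' model. The default length, 600 nt, matches the `<-300,+300>` negative
#' region so that every narrower analysis window can be cut from one
#' negative; the returned dataset is labelled `"false"`.
#'
#' @param model a `pa_markov2`.
#' @param n number of sequences.
#' @param length sequence length in nt (>= 3).
#' @param region [pa_region()] to attach (default `<-300,+300>` scaled to
#'   `length`; must satisfy `region$length == length`).
#' @param seed optional integer seed for reproducibility.
#' @return A [pa_dataset()] with `label = "false"`.
#' @export
pa_sample_negatives <- function(model, n, length = 600L, region = NULL,
                                seed = NULL) {
  stopifnot(inherits(model, "pa_markov2"), n >= 1L, length >= 3L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(region)) {
    half <- length %/% 2L
    region <- pa_region(-half, length - half)
  }
  stopifnot(region$length == length)
  out <- matrix(0L, nrow = n, ncol = length)
  di <- sample.int(16L, n, replace = TRUE, prob = model$initial)
  out[, 1] <- (di - 1L) %/% 4L + 1L
  out[, 2] <- (di - 1L) %% 4L + 1L
  cum <- t(apply(model$transitions, 1, cumsum))
  for (t in 3:length) {
    u <- stats::runif(n)
    nxt <- 1L + (u > cum[di, 1]) + (u > cum[di, 2]) + (u > cum[di, 3])
    out[, t] <- nxt
    di <- (out[, t - 1L] - 1L) * 4L + nxt
  }
  seqs <- apply(out, 1, function(r) paste(BASES[r], collapse = ""))
  pa_dataset(sprintf("neg_%05d", seq_len(n)), seqs, "false", region)
}
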