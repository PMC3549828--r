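#' Build a Position Score Matrix (PSM)
#'
#' A PSM is a `4^k x (l-k+1)` matrix of log2 ratios comparing, at every kmer
#' start position of the region, how often real versus false site sequences
#' carry each kmer. With the default frequency normalization and Laplace
#' pseudocount `alpha`, entry `(w, n)` is
#' `log2( (c_real(w,n)+alpha)/(R+alpha*4^k) / ((c_false(w,n)+alpha)/(F+alpha*4^k)) )`
#' where `R`, `F` are the real/false sequence counts — the real/false fold
#' difference made size-invariant and finite. With `normalize = FALSE` the
#' raw smoothed count ratio is used instead. `alpha = 0` is accepted only
#' when no entry would be infinite.
#'
#' @param real,false [pa_dataset()]s covering `region` (trimmed if wider).
#' @param k kmer size.
#' @param region scoring [pa_region()] (default `<-100,+100>`).
#' @param alpha pseudocount (default 1).
#' @param normalize use per-class frequencies rather than raw counts.
#' @return A `pa_psm`: `values` (`4^k x (l-k+1)`, rows = kmers lexicographic,
#'   columns labelled by signed kmer start positions), plus metadata.
#' @export
pa_psm <- function(real, false, k = 3L, region = pa_region(-100L, 100L),
                   alpha = 1, normalize = TRUE) {
  real <- trim_if_wider(real, region)
  false <- trim_if_wider(false, region)
  cr <- pkm_counts(real, k)
  cf <- pkm_counts(false, k)
  R <- nrow(real); F_ <- nrow(false)
  if (!R || !F_) stop("both a real and a false dataset are required",
                      call. = FALSE)
  nk <- 4^k
  if (normalize) {
    vals <- log2(((cr + alpha) / (R + alpha * nk)) /
                   ((cf + alpha) / (F_ + alpha * nk)))
  } else {
    vals <- log2((cr + alpha) / (cf + alpha))
  }
  if (any(!is.finite(vals)))
    stop("non-finite PSM entries; use a positive pseudocount", call. = FALSE)
  vals <- t(vals)  # kmers x positions
  structure(list(values = vals, k = k, region = region, alpha = alpha,
                 normalize = normalize, n_real = R, n_false = F_),
            class = "pa_psm")
}

trim_if_wider <- function(data, region) {
  r <- pa_dataset_region(data)
  if (identical(r$from, region$from) && identical(r$to, region$to)) return(data)
  pa_trim(data, region)
}

pkm_counts <- function(data, k) {
  m <- pa_kmer_matrix(data, k, label = NULL)$counts
  colnames(m) <- all_kmers(k)
  m
}

#' @export
print.pa_psm <- function(x, ...) {
  cat("<pa_psm> ", nrow(x$values), " ", x$k, "-mers x ", ncol(x$values),
      " positions over ", format(x$region), " (alpha=", x$alpha,
      ", ", if (x$normalize) "frequencies" else "counts", ")\n", sep = "")
  invisible(x)
}

# 1-based kmer-start index range whose kmers lie fully inside `window`
subregion_start_indices <- function(psm_region, window, k) {
  if (!pa_region_contains(psm_region, window))
    stop("subregion ", format(window), " not contained in ",
         format(psm_region), call. = FALSE)
  a <- pa_to_index(window$from, psm_region)
  b <- pa_to_index(window$to, psm_region)
  if (b - k + 1L < a)
    stop("subregion ", format(window), " too narrow for ", k, "-mers",
         call. = FALSE)
  a:(b - k + 1L)
}

#' Score sequences against a PSM
#'
#' The PSM score of a sequence over a subregion is the sum of matrix entries
#' `v(w, n)` for every kmer `w` starting at position `n` such that the kmer
#' lies entirely inside the subregion (both its start and end positions).
#' Kmers containing ambiguous bases contribute 0. Scores are in bits.
#'
#' @param psm a [pa_psm()].
#' @param sequences character vector of sequences of the PSM region length,
#'   or a [pa_dataset()] over that region.
#' @param window subregion [pa_region()] (default: the full PSM region).
#' @return Numeric vector of scores, one per sequence.
#' @export
pa_psm_score <- function(psm, sequences, window = NULL) {
  stopifnot(inherits(psm, "pa_psm"))
  if (inherits(sequences, "pa_dataset")) sequences <- sequences$sequence
  sequences <- normalize_dna(sequences)
  if (any(nchar(sequences) != psm$region$length))
    stop("sequence length must equal the PSM region length ",
         psm$region$length, call. = FALSE)
  if (is.null(window)) window <- psm$region
  starts <- subregion_start_indices(psm$region, window, psm$k)
  idx <- kmer_indices(encode_bases(sequences), psm$k)
  score <- numeric(length(sequences))
  nk <- nrow(psm$values)
  v <- psm$values
  for (j in starts) {
    ij <- idx[, j]
    ok <- !is.na(ij)
    score[ok] <- score[ok] + v[ij[ok] + nk * (j - 1L)]
  }
  score
}
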