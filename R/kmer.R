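# Shared kmer indexing utilities (internal).
#
# Sequences are encoded as integer base codes 1..4 (A,C,G,T lexicographic);
# ambiguous bases become NA and any kmer touching one is excluded from
# counting and contributes nothing to scores.

BASES <- c("A", "C", "G", "T")

# character vector of sequences (equal length) -> n x l integer matrix
encode_bases <- function(seqs) {
  l <- unique(nchar(seqs))
  stopifnot(length(l) == 1L)
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), BASES),
              nrow = length(seqs), ncol = l, byrow = TRUE)
  m
}

# n x l base-code matrix -> n x (l-k+1) kmer-index matrix (1..4^k, NA = ambiguous)
kmer_indices <- function(codes, k) {
  l <- ncol(codes)
  if (k > l) stop("k (", k, ") exceeds sequence length (", l, ")",
                  call. = FALSE)
  p <- l - k + 1L
  idx <- codes[, 1:p, drop = FALSE] - 1L
  if (k > 1L) for (j in 2:k) {
    idx <- idx * 4L + (codes[, j:(j + p - 1L), drop = FALSE] - 1L)
  }
  idx + 1L
}

# all kmers of size k in lexicographic (index) order
all_kmers <- function(k) {
  g <- expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE)[, k:1,
                                                                  drop = FALSE]
  do.call(paste0, g)
}

# column-wise kmer occurrence counts: (l-k+1) x 4^k
count_kmer_positions <- function(idx, k) {
  nk <- 4L^k
  t(apply(idx, 2, function(col) tabulate(col[!is.na(col)], nbins = nk)))
}
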