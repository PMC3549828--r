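# Shared fixture builders. All randomness is seeded at the call site.

# dataset from literal sequences, region inferred from length (<-n/2,+n/2>)
toy_dataset <- function(seqs, label = "real", region = NULL) {
  if (is.null(region)) {
    l <- nchar(seqs[1])
    region <- pa_region(-(l %/% 2), l - l %/% 2)
  }
  pa_dataset(paste0("s", seq_along(seqs)), seqs, label, region)
}

# flat-plus-noise occupancy tracks as a matrix
flat_tracks <- function(n, level = 0.6, sd = 0.05, len = 600, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rnorm(n * len, level, sd), nrow = n)
  pmin(pmax(m, 0), 1)
}

# dip-shaped tracks (gaussian dip centred between -1/+1)
dip_tracks <- function(n, depth = 0.3, width = 150, level = 0.6, sd = 0.05,
                       len = 600, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  region <- pa_region(-(len %/% 2), len - len %/% 2)
  pos <- pa_from_index(seq_len(len), region)
  sigma <- width / (2 * sqrt(2 * log(2)))
  dip <- depth * exp(-(pos^2) / (2 * sigma^2))
  m <- matrix(stats::rnorm(n * len, 0, sd), nrow = n, byrow = TRUE)
  m <- sweep(m, 2, level - dip, `+`)
  pmin(pmax(m, 0), 1)
}

# labelled training dataset: synthetic real sites + markov negatives with
# flat-noise tracks, ready for pa_polya_model()
training_dataset <- function(n_real, n_false = n_real,
                             profile = pa_profile(), seed = 1) {
  real <- pa_simulate(profile, n_real, 0, seed = seed)
  mk <- pa_fit_markov(real)
  neg <- pa_sample_negatives(mk, n_false, length = 600, seed = seed + 1)
  set.seed(seed + 2)
  neg$track <- lapply(seq_len(n_false), function(i) {
    pmin(pmax(profile$occ_baseline +
                stats::rnorm(600, 0, profile$occ_noise_sd), 0), 1)
  })
  pa_bind(real, neg)
}

# pooled trinucleotide counts over a character vector of sequences
trinucleotide_counts <- function(seqs) {
  k3 <- pa_kmer_matrix(toy_dataset(seqs, region = pa_region(
    -(nchar(seqs[1]) %/% 2), nchar(seqs[1]) - nchar(seqs[1]) %/% 2
  )), 3)
  colSums(k3$counts)
}
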