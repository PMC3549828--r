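#' Published multispecies benchmark tables
#'
#' Reference tables for seven eukaryotes (human, mouse, chicken,
#' C. elegans, O. sativa, Arabidopsis, S. lycopersicum) shipped as
#' plain-text fixtures and used in worked examples and consistency checks:
#'
#' * `pa_benchmark_distances()` — per species pair, phylogenetic distances
#'   from three marker genes (`d18s`, `gapdh`, `cpsf3`) together with the
#'   reciprocal sensitivity (`rsn`) of cross-species poly(A) model
#'   transfer.
#' * `pa_benchmark_sensitivity()` — the directed cross-species sensitivity
#'   matrix: row = species whose model is applied, column = species whose
#'   real sites are predicted (the diagonal is within-species sensitivity).
#' * `pa_benchmark_performance()` — within-species sensitivity, specificity
#'   (percent) and MCC for the LDA and LR classifiers.
#'
#' @return A tibble (`pa_benchmark_sensitivity()` returns the matrix as a
#'   tibble with a `model` column).
#' @name pa_benchmarks
NULL

read_benchmark <- function(file) {
  readr::read_tsv(system.file("extdata", file, package = "polyasite",
                              mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' @rdname pa_benchmarks
#' @export
pa_benchmark_distances <- function() read_benchmark("species_distances_rsn.tsv")

#' @rdname pa_benchmarks
#' @export
pa_benchmark_sensitivity <- function() {
  read_benchmark("cross_species_sensitivity.tsv")
}

#' @rdname pa_benchmarks
#' @export
pa_benchmark_performance <- function() read_benchmark("species_performance.tsv")

#' Recompute reciprocal sensitivities from the directed matrix
#'
#' Forms, for every unordered species pair, the mean of the two directed
#' cross-species sensitivities in [pa_benchmark_sensitivity()] (or any
#' matrix shaped like it).
#'
#' @param sensitivity a tibble with a `model` column and one numeric column
#'   per species (default: the shipped benchmark matrix).
#' @return A tibble: `species1`, `species2`, `sn_12` (model 1 on sites 2),
#'   `sn_21`, `rsn`.
#' @export
pa_rsn_table <- function(sensitivity = pa_benchmark_sensitivity()) {
  sp <- sensitivity$model
  m <- as.matrix(sensitivity[, -1])
  rownames(m) <- sp
  pairs <- utils::combn(sp, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tibble::tibble(species1 = a, species2 = b,
                   sn_12 = m[a, b], sn_21 = m[b, a],
                   rsn = pa_reciprocal_sn(m[a, b], m[b, a]))
  })
}
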