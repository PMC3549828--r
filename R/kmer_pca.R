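#' Position-by-kmer occurrence matrix
#'
#' Counts, for every kmer start position in the region, how many sequences
#' carry each of the `4^k` kmers there. Rows are positions (labelled by the
#' signed position of the kmer start), columns are kmers in lexicographic
#' order. Kmers containing ambiguous bases are excluded, so row sums may be
#' below the number of sequences.
#'
#' @param data a [pa_dataset()].
#' @param k kmer size (>= 1, <= region length).
#' @param label which records to count (default `"real"`; `NULL` for all).
#' @return A `pa_pkm`: the counts matrix plus `k` and `region`.
#' @export
pa_kmer_matrix <- function(data, k, label = "real") {
  region <- pa_dataset_region(data)
  if (k < 1L || k > region$length)
    stop("k must be in 1..", region$length, call. = FALSE)
  seqs <- if (is.null(label)) data$sequence
          else data$sequence[data$label == label]
  if (!length(seqs)) stop("no sequences selected", call. = FALSE)
  idx <- kmer_indices(encode_bases(seqs), k)
  counts <- count_kmer_positions(idx, k)
  rownames(counts) <- pa_from_index(seq_len(nrow(counts)), region)
  colnames(counts) <- all_kmers(k)
  structure(list(counts = counts, k = k, region = region,
                 n_sequences = length(seqs)),
            class = "pa_pkm")
}

#' @export
print.pa_pkm <- function(x, ...) {
  cat("<pa_pkm> ", nrow(x$counts), " positions x ", ncol(x$counts), " ",
      x$k, "-mers over ", format(x$region), ", ", x$n_sequences,
      " sequences\n", sep = "")
  invisible(x)
}

#' PCA position and oligo profiles
#'
#' Principal component analysis of the position-by-kmer matrix. Positions
#' whose kmer composition deviates from the bulk stand out as points far
#' from the origin in the first two components (the position profile), and
#' the kmers driving them appear as loading arrows in the same plane (the
#' oligo profile) — a biplot reading that localizes cis-elements without
#' presupposing their sequence. Columns are centred; unit-variance scaling
#' is off by default because all counts share one scale. Component signs are
#' normalized so the farthest-from-origin position has nonnegative
#' coordinates, making results deterministic across eigensolvers.
#'
#' @param pkm a [pa_kmer_matrix()].
#' @param scale. logical; also scale columns to unit variance.
#' @return A `pa_pca_profile` with tibbles `positions` (`position`, `pc1`,
#'   `pc2`, `distance`), `loadings` (`kmer`, `pc1`, `pc2`, `length`,
#'   `angle` in degrees), and `variance_explained` (length-2 fractions).
#' @export
pa_pca <- function(pkm, scale. = FALSE) {
  stopifnot(inherits(pkm, "pa_pkm"))
  x <- pkm$counts
  if (nrow(x) < 3L) stop("need at least 3 positions", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (sum(v > 0) < 2L)
    stop("degenerate input: fewer than 2 kmer columns with nonzero variance",
         call. = FALSE)
  if (scale.) x <- x[, v > 0, drop = FALSE]
  p <- stats::prcomp(x, center = TRUE, scale. = scale.)
  scores <- p$x[, 1:2, drop = FALSE]
  # biplot scaling: loadings stretched by component sd
  loads <- p$rotation[, 1:2, drop = FALSE] %*% diag(p$sdev[1:2])
  dist <- sqrt(rowSums(scores^2))
  ref <- which.max(dist)
  for (j in 1:2) if (scores[ref, j] < 0) {
    scores[, j] <- -scores[, j]
    loads[, j] <- -loads[, j]
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(
    list(
      positions = tibble::tibble(
        position = as.integer(rownames(pkm$counts)),
        pc1 = scores[, 1], pc2 = scores[, 2], distance = dist
      ),
      loadings = tibble::tibble(
        kmer = rownames(loads), pc1 = loads[, 1], pc2 = loads[, 2],
        length = sqrt(rowSums(loads^2)),
        angle = atan2(loads[, 2], loads[, 1]) * 180 / pi
      ),
      variance_explained = ve[1:2],
      k = pkm$k, region = pkm$region
    ),
    class = "pa_pca_profile"
  )
}

#' @export
print.pa_pca_profile <- function(x, ...) {
  cat("<pa_pca_profile> ", x$k, "-mer PCA over ", format(x$region),
      "; variance explained ",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " / "),
      "\n", sep = "")
  invisible(x)
}

#' Detect localization peaks in a PCA position profile
#'
#' Positions whose origin distance reaches `threshold` times the maximum are
#' kept and merged into contiguous groups (a gap of more than 2 positions
#' starts a new group). Each group reports its peak position and the kmers
#' whose loading direction lies within 45 degrees of the group's
#' distance-weighted mean score direction — the angular reading used to
#' assign oligos to regions such as DUR, PUR, CS and DR.
#'
#' @param profile a [pa_pca()] result.
#' @param threshold fraction of the maximum origin distance, in `(0, 1]`.
#' @param min_loading report only kmers whose loading length reaches this
#'   fraction of the maximum loading length (default 0.25).
#' @return A tibble with one row per group: `peak`, `from`, `to`,
#'   `distance`, `direction` (degrees) and `kmers` (comma-separated).
#' @export
pa_detect_peaks <- function(profile, threshold = 0.5, min_loading = 0.25) {
  stopifnot(inherits(profile, "pa_pca_profile"))
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]", call. = FALSE)
  pos <- profile$positions
  if (!nrow(pos)) stop("empty profile", call. = FALSE)
  dmax <- max(pos$distance)
  if (dmax == 0) return(empty_peaks())
  keep <- which(pos$distance >= threshold * dmax)
  if (!length(keep)) return(empty_peaks())
  grp <- cumsum(c(1L, diff(keep) > 3L))  # gap > 2 positions splits
  lds <- profile$loadings
  lds <- lds[lds$length >= min_loading * max(lds$length), , drop = FALSE]
  purrr::map_dfr(split(keep, grp), function(ix) {
    sub <- pos[ix, ]
    w <- sub$distance
    dir <- atan2(sum(w * sub$pc2), sum(w * sub$pc1)) * 180 / pi
    dang <- abs(((lds$angle - dir + 180) %% 360) - 180)
    tibble::tibble(
      peak = sub$position[which.max(sub$distance)],
      from = min(sub$position), to = max(sub$position),
      distance = max(sub$distance), direction = dir,
      kmers = paste(lds$kmer[dang <= 45], collapse = ",")
    )
  })
}

empty_peaks <- function() {
  tibble::tibble(peak = integer(), from = integer(), to = integer(),
                 distance = double(), direction = double(),
                 kmers = character())
}

#' Estimate the start of a localized cis-element
#'
#' Localizes one cis-element from a PCA position profile: within a search
#' window, takes the position of maximal origin distance and walks left to
#' the onset of its contiguous run of positions at or above half that
#' local maximum. Because kmers spanning an element smear its localization
#' signal downstream of the element start, the onset of the above-half-max
#' run — not the argmax — estimates where the element begins. The default
#' search window targets the upstream poly(A) signal (NUE), excluding the
#' cleavage-site element.
#'
#' @param profile a [pa_pca()] result.
#' @param search [pa_region()] to search (default `<-60,-6>`).
#' @return A one-row tibble: `onset`, `argmax`, `distance` (at the argmax).
#' @export
pa_signal_position <- function(profile, search = pa_region(-60L, -6L)) {
  stopifnot(inherits(profile, "pa_pca_profile"))
  pos <- profile$positions
  sel <- pos$position >= search$from & pos$position <= search$to
  if (!any(sel)) stop("search window outside the profile", call. = FALSE)
  sub <- pos[sel, ]
  i_max <- which.max(sub$distance)
  keep <- sub$distance >= sub$distance[i_max] / 2
  onset <- i_max
  while (onset > 1L && keep[onset - 1L]) onset <- onset - 1L
  tibble::tibble(onset = sub$position[onset],
                 argmax = sub$position[i_max],
                 distance = sub$distance[i_max])
}
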