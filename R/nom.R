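#' Sequence-derived nucleosome occupancy score (stand-in predictor)
#'
#' A deterministic per-position occupancy score in `[0,1]` computed from the
#' sequence alone: the logistic transform of the 147-nt running GC fraction
#' (the nucleosomal footprint length) minus a penalty for A/T homopolymer
#' runs, which are strong nucleosome-excluding elements. This is a simple
#' composition-based surrogate exposing the same interface as any external
#' occupancy predictor or experimental track supplied through
#' [pa_read_track()]; its contract is determinism, range `[0,1]`, and
#' monotone sensitivity to base composition — not biophysical accuracy.
#' Because the running window is unreliable near sequence ends, 200
#' positions on each side are discarded: a 1000-nt `<-500,+500>` window
#' yields the 600-nt `<-300,+300>` track used by the NOM.
#'
#' @param sequence a single DNA string covering at least `<-500,+500>`
#'   (1000 nt); longer inputs are centre-trimmed to 1000 nt first.
#' @param trim positions discarded at each end (default 200).
#' @return Numeric vector of length `length(sequence) - 2*trim` in `[0,1]`.
#' @export
pa_predict_occupancy <- function(sequence, trim = 200L) {
  sequence <- normalize_dna(sequence)
  stopifnot(length(sequence) == 1L)
  l <- nchar(sequence)
  if (l < 2L * trim + 1L)
    stop("sequence too short: need > ", 2L * trim, " nt", call. = FALSE)
  occ <- occupancy_profile(sequence)
  occ[(trim + 1L):(l - trim)]
}

# full-length raw occupancy profile (internal; also used by the scanner)
occupancy_profile <- function(sequence) {
  b <- strsplit(sequence, "", fixed = TRUE)[[1]]
  gc <- as.numeric(b %in% c("G", "C"))
  sm <- running_mean(gc, 147L)
  r <- rle(b)
  runlen <- rep(r$lengths, r$lengths)
  at_run <- rep(r$values %in% c("A", "T"), r$lengths)
  penalty <- ifelse(at_run & runlen >= 5, 0.05 * pmin(runlen, 10), 0)
  stats::plogis(6 * (sm - 0.5) - penalty)
}

# centred running mean with partial windows at the ends
running_mean <- function(x, w) {
  half <- w %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Read a site-anchored occupancy track from bedGraph or WIG
#'
#' Extracts per-position occupancy values around a cleavage site from a
#' genome-wide track (bedGraph or fixed-step WIG, read with
#' \pkg{rtracklayer}). Values are returned in site-anchored orientation: for
#' a `-` strand site the window is mirrored and reversed so that position
#' `-1` is always the last transcribed base. Values outside `[0,1]` are
#' clipped with a message; positions not covered by the track are an error
#' unless a `fill` value is given.
#'
#' @param path bedGraph/WIG file (format auto-detected by extension, or set
#'   `format`).
#' @param chrom,site,strand site location: chromosome, 1-based position of
#'   the last transcribed base, strand `"+"`/`"-"`.
#' @param region [pa_region()] of the form `<-N,+M>` (default `<-300,+300>`).
#' @param fill optional value for uncovered positions.
#' @param format passed to [rtracklayer::import()] when the extension is
#'   ambiguous.
#' @return Numeric vector of length `region$length` in `[0,1]`.
#' @export
pa_read_track <- function(path, chrom, site, strand = "+",
                          region = pa_region(-300L, 300L), fill = NULL,
                          format = NULL) {
  gr <- if (is.null(format)) rtracklayer::import(path)
        else rtracklayer::import(path, format = format)
  plus <- strand == "+"
  lo <- if (plus) site - region$upstream + 1L else site - region$downstream
  hi <- if (plus) site + region$downstream else site + region$upstream - 1L
  vals <- rep(NA_real_, region$length)
  sel <- gr[GenomicRanges::seqnames(gr) == chrom]
  st <- GenomicRanges::start(sel); en <- GenomicRanges::end(sel)
  sc <- sel$score
  for (i in seq_along(sel)) {
    a <- max(st[i], lo); b <- min(en[i], hi)
    if (a <= b) vals[(a - lo + 1L):(b - lo + 1L)] <- sc[i]
  }
  if (anyNA(vals)) {
    if (is.null(fill)) {
      gaps <- range(which(is.na(vals)))
      stop("track does not cover positions ", lo + gaps[1] - 1L, "..",
           lo + gaps[2] - 1L, " on ", chrom,
           " (supply `fill` to impute)", call. = FALSE)
    }
    vals[is.na(vals)] <- fill
  }
  if (any(vals < 0 | vals > 1)) {
    message("clipping ", sum(vals < 0 | vals > 1),
            " occupancy value(s) to [0,1]")
    vals <- pmin(pmax(vals, 0), 1)
  }
  if (!plus) vals <- rev(vals)
  vals
}

#' Build a Nucleosome Occupancy Matrix (NOM)
#'
#' The NOM carries the occupancy analogue of the PSM: per position, the log2
#' ratio of how often real versus false sites show an occupancy probability
#' in each bin. With `B` equal-width bins over `[0,1]` and pseudocount
#' `alpha`, entry `(b, n)` is
#' `log2( (c_real(b,n)+alpha)/(R+alpha*B) / ((c_false(b,n)+alpha)/(F+alpha*B)) )`.
#' The alternative `mode = "profile"` stores a single per-position log2
#' ratio of mean occupancies (scores are then inner products with the
#' track); the binned construction is the default because it makes scoring
#' a new track a straight lookup-and-sum, exactly parallel to the PSM.
#'
#' @param real_tracks,false_tracks lists (or row-matrices) of equal-length
#'   occupancy tracks, values in `[0,1]`; default length 600 (`<-300,+300>`).
#' @param bins number of probability bins `B` (default 20).
#' @param alpha pseudocount (default 1).
#' @param mode `"binned"` (default) or `"profile"`.
#' @param region [pa_region()] the tracks are anchored to.
#' @return A `pa_nom`.
#' @export
pa_nom <- function(real_tracks, false_tracks, bins = 20L, alpha = 1,
                   mode = c("binned", "profile"),
                   region = pa_region(-300L, 300L)) {
  mode <- match.arg(mode)
  rt <- as_track_matrix(real_tracks, region)
  ft <- as_track_matrix(false_tracks, region)
  R <- nrow(rt); F_ <- nrow(ft)
  if (!R || !F_) stop("both real and false tracks are required",
                      call. = FALSE)
  edges <- seq(0, 1, length.out = bins + 1L)
  if (mode == "binned") {
    cb_r <- bin_count_matrix(rt, edges, bins)
    cb_f <- bin_count_matrix(ft, edges, bins)
    vals <- log2(((cb_r + alpha) / (R + alpha * bins)) /
                   ((cb_f + alpha) / (F_ + alpha * bins)))
  } else {
    eps <- alpha / 100
    vals <- matrix(log2((colMeans(rt) + eps) / (colMeans(ft) + eps)),
                   nrow = 1L)
  }
  colnames(vals) <- pa_from_index(seq_len(region$length), region)
  structure(list(values = vals, bins = bins, edges = edges, alpha = alpha,
                 mode = mode, region = region, n_real = R, n_false = F_),
            class = "pa_nom")
}

as_track_matrix <- function(tracks, region) {
  m <- if (is.matrix(tracks)) tracks else do.call(rbind, as.list(tracks))
  if (is.null(m) || !nrow(m)) stop("empty track collection", call. = FALSE)
  if (ncol(m) != region$length)
    stop("tracks must have length ", region$length, call. = FALSE)
  if (any(m < 0 | m > 1)) stop("occupancy values must lie in [0,1]",
                               call. = FALSE)
  m
}

bin_index <- function(x, edges) {
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

bin_count_matrix <- function(m, edges, bins) {
  bi <- bin_index(m, edges)
  dim(bi) <- dim(m)
  apply(bi, 2, tabulate, nbins = bins)
}

#' @export
print.pa_nom <- function(x, ...) {
  cat("<pa_nom> ", x$mode, " NOM, ", nrow(x$values), " x ", ncol(x$values),
      " over ", format(x$region), " (alpha=", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Score occupancy tracks against a NOM
#'
#' The NOM score of a track is the sum over positions of the matrix entry
#' for the bin its occupancy probability falls in (binned mode), or the
#' inner product of the track with the per-position log-ratio profile
#' (profile mode). Scores are in bits.
#'
#' @param nom a [pa_nom()].
#' @param tracks a single numeric track, a list of tracks, or a row-matrix.
#' @return Numeric vector of scores.
#' @export
pa_nom_score <- function(nom, tracks) {
  stopifnot(inherits(nom, "pa_nom"))
  if (is.numeric(tracks) && is.null(dim(tracks)))
    tracks <- matrix(tracks, nrow = 1L)
  m <- as_track_matrix(tracks, nom$region)
  if (nom$mode == "profile") return(drop(m %*% nom$values[1, ]))
  bi <- bin_index(m, nom$edges)
  dim(bi) <- dim(m)
  B <- nrow(nom$values)
  v <- nom$values
  idx <- sweep(bi, 2, B * (seq_len(ncol(m)) - 1L), `+`)
  rowSums(matrix(v[idx], nrow = nrow(m)))
}
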