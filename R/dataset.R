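#' Cleavage-anchored sequence datasets
#'
#' A poly(A) dataset is a tibble with one row per site: columns `id`,
#' `sequence` (uppercase DNA over A/C/G/T/N, all the same length), `label`
#' (`"real"` or `"false"`), and optionally `track` (a list-column of
#' per-position nucleosome-occupancy probabilities). The shared
#' cleavage-anchored [pa_region()] is carried in the `"region"` attribute and
#' retrieved with `pa_dataset_region()`.
#'
#' @param id character vector of record ids.
#' @param sequence character vector of DNA sequences.
#' @param label `"real"` or `"false"`, recycled.
#' @param region the shared [pa_region()]; its length must equal every
#'   sequence length.
#' @param track optional list of numeric occupancy tracks (values in
#'   `[0,1]`), one per record.
#' @param max_ambiguous reject records whose fraction of non-ACGT bases
#'   exceeds this (quality floor; default 0.10).
#' @return A tibble of class `pa_dataset`.
#' @export
pa_dataset <- function(id, sequence, label, region, track = NULL,
                       max_ambiguous = 0.10) {
  sequence <- normalize_dna(sequence)
  label <- rep_len(as.character(label), length(sequence))
  if (!all(label %in% c("real", "false")))
    stop("labels must be \"real\" or \"false\"", call. = FALSE)
  lens <- nchar(sequence)
  bad <- lens != region$length
  if (any(bad))
    stop("sequence length != region length (", region$length, ") for: ",
         paste(utils::head(id[bad], 5L), collapse = ", "), call. = FALSE)
  amb <- ambiguous_fraction(sequence)
  if (any(amb > max_ambiguous))
    stop("records with >", round(100 * max_ambiguous), "% ambiguous bases ",
         "rejected: ", paste(utils::head(id[amb > max_ambiguous], 5L),
                             collapse = ", "), call. = FALSE)
  out <- tibble::tibble(id = as.character(id), sequence = sequence,
                        label = label)
  if (!is.null(track)) {
    stopifnot(length(track) == nrow(out))
    out$track <- track
  }
  attr(out, "region") <- region
  class(out) <- c("pa_dataset", class(out))
  out
}

#' @rdname pa_dataset
#' @param x a `pa_dataset` (or any object carrying a `"region"` attribute).
#' @export
pa_dataset_region <- function(x) {
  r <- attr(x, "region", exact = TRUE)
  if (is.null(r)) stop("object carries no region attribute", call. = FALSE)
  r
}

# uppercase, RNA U -> DNA T
normalize_dna <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(as.character(x))))
}

ambiguous_fraction <- function(seqs) {
  n_ok <- vapply(
    strsplit(seqs, "", fixed = TRUE),
    function(b) sum(b %in% c("A", "C", "G", "T")),
    integer(1)
  )
  1 - n_ok / nchar(seqs)
}

#' Read a cleavage-anchored FASTA file
#'
#' Each record must either carry its cleavage offset in the header as an
#' `offset=K` token (K = number of bases transcribed before the cleavage
#' point) or be pre-trimmed so that its length equals `region$length` (then
#' the offset is taken to be `region$upstream`). Sequences are uppercased and
#' RNA `U` is mapped to `T`; records too short for the requested region are
#' rejected by id.
#'
#' @param path FASTA file.
#' @param region target [pa_region()] of the form `<-N,+M>`.
#' @inheritParams pa_dataset
#' @return A [pa_dataset()] with `label = "real"`.
#' @export
pa_read_fasta <- function(path, region, label = "real",
                          max_ambiguous = 0.10) {
  ss <- Biostrings::readBStringSet(path)  # tolerate RNA/lowercase input
  headers <- names(ss)
  seqs <- as.character(ss)
  ids <- sub("\\s.*$", "", headers)
  off <- stringr::str_match(headers, "offset=(\\d+)")[, 2]
  offset <- suppressWarnings(as.integer(off))
  lens <- nchar(seqs)
  no_off <- is.na(offset)
  if (any(no_off & lens != region$length))
    stop("records without offset= token and not of region length ",
         region$length, ": ",
         paste(utils::head(ids[no_off & lens != region$length], 5L),
               collapse = ", "), call. = FALSE)
  offset[no_off] <- region$upstream
  lo <- offset - region$upstream + 1L
  hi <- offset + region$downstream
  bad <- lo < 1L | hi > lens
  if (any(bad))
    stop("records too short for region ", format(region), ": ",
         paste(utils::head(ids[bad], 5L), collapse = ", "), call. = FALSE)
  pa_dataset(ids, substr(seqs, lo, hi), label, region,
             max_ambiguous = max_ambiguous)
}

#' Extract cleavage-anchored windows from a genome
#'
#' Sites are supplied as single-base BED intervals (0-based half-open; the
#' strand field is required) marking the last transcribed base before the
#' cleavage point. For a `+` site at 1-based genomic position `s` and region
#' `<-N,+M>` the window is `[s-N+1, s+M]`; for a `-` site the mirrored window
#' `[s-M, s+N-1]` is taken and reverse-complemented, so position `-1` is
#' always the last transcribed base. Sites whose windows run off the contig
#' are skipped and counted in the `"n_skipped"` attribute.
#'
#' @param genome_path FASTA file of contigs, or a named character vector of
#'   sequences.
#' @param sites_path BED6 file of single-base sites (score ignored), or a
#'   data frame with columns chrom/start/end/name/score/strand.
#' @param region target [pa_region()] of the form `<-N,+M>`.
#' @inheritParams pa_dataset
#' @return A [pa_dataset()]; attribute `n_skipped` counts boundary skips.
#' @export
pa_extract_windows <- function(genome_path, sites_path, region,
                               label = "real", max_ambiguous = 0.10) {
  genome <- if (is.character(genome_path) && length(genome_path) == 1L &&
                file.exists(genome_path)) {
    ss <- Biostrings::readDNAStringSet(genome_path)
    names(ss) <- sub("\\s.*$", "", names(ss))
    ss
  } else {
    Biostrings::DNAStringSet(stats::setNames(normalize_dna(genome_path),
                                             names(genome_path)))
  }
  sites <- if (is.data.frame(sites_path)) {
    tibble::as_tibble(sites_path)
  } else {
    readr::read_tsv(sites_path,
                    col_names = c("chrom", "start", "end", "name", "score",
                                  "strand"),
                    col_types = "ciicdc", progress = FALSE)
  }
  if (!all(sites$strand %in% c("+", "-")))
    stop("BED strand field must be '+' or '-'", call. = FALSE)
  missing_chr <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosomes absent from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  s <- sites$start + 1L  # 1-based site base
  plus <- sites$strand == "+"
  lo <- ifelse(plus, s - region$upstream + 1L, s - region$downstream)
  hi <- ifelse(plus, s + region$downstream, s + region$upstream - 1L)
  clen <- Biostrings::width(genome)[match(sites$chrom, names(genome))]
  keep <- lo >= 1L & hi <= clen
  n_skipped <- sum(!keep)
  if (n_skipped)
    warning(n_skipped, " site(s) too close to contig ends were skipped",
            call. = FALSE)
  if (!any(keep)) stop("no usable sites", call. = FALSE)
  sub <- Biostrings::subseq(genome[sites$chrom[keep]], lo[keep], hi[keep])
  neg <- !plus[keep]
  if (any(neg)) sub[neg] <- Biostrings::reverseComplement(sub[neg])
  ids <- if ("name" %in% names(sites) && !all(is.na(sites$name)))
    as.character(sites$name[keep])
  else paste0(sites$chrom[keep], ":", s[keep], sites$strand[keep])
  out <- pa_dataset(ids, as.character(sub), label, region,
                    max_ambiguous = max_ambiguous)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Trim a dataset to a narrower cleavage-anchored region
#'
#' Cuts every sequence (and track, if present) of a `<-N,+M>` dataset down to
#' an inner region such as `<-100,+100>`.
#'
#' @param data a [pa_dataset()].
#' @param region inner [pa_region()]; must be contained in the dataset's.
#' @return A [pa_dataset()] over `region`.
#' @export
pa_trim <- function(data, region) {
  outer <- pa_dataset_region(data)
  if (!pa_region_contains(outer, region))
    stop("region ", format(region), " not contained in dataset region ",
         format(outer), call. = FALSE)
  lo <- pa_to_index(region$from, outer)
  hi <- pa_to_index(region$to, outer)
  tr <- if ("track" %in% names(data)) lapply(data$track, function(t) t[lo:hi])
  pa_dataset(data$id, substr(data$sequence, lo, hi), data$label, region,
             track = tr, max_ambiguous = 1)
}

#' Combine datasets sharing a region
#'
#' Row-binds datasets (e.g. real sites and Markov negatives) after checking
#' they share the same cleavage-anchored region, preserving the region
#' attribute that plain `rbind`/`bind_rows` would drop.
#'
#' @param ... [pa_dataset()]s over identical regions.
#' @return A [pa_dataset()].
#' @export
pa_bind <- function(...) {
  parts <- list(...)
  regions <- lapply(parts, pa_dataset_region)
  r1 <- regions[[1]]
  same <- vapply(regions, function(r) identical(format(r), format(r1)),
                 logical(1))
  if (!all(same)) stop("datasets cover different regions", call. = FALSE)
  out <- dplyr::bind_rows(lapply(parts, function(p) {
    class(p) <- setdiff(class(p), "pa_dataset")
    p
  }))
  attr(out, "region") <- r1
  class(out) <- c("pa_dataset", class(out))
  out
}
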