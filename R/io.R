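#' Write and read score matrices as TSV
#'
#' PSMs and NOMs are serialized as tab-separated tables: rows are kmers
#' (lexicographic) or probability bins, columns are signed positions, with
#' metadata carried in `#`-prefixed header lines so a written matrix can be
#' read back losslessly.
#'
#' @param x a [pa_psm()] or [pa_nom()].
#' @param path output (input) file.
#' @return `pa_write_matrix()` returns `path` invisibly; `pa_read_psm()` /
#'   `pa_read_nom()` the reconstructed object.
#' @export
pa_write_matrix <- function(x, path) {
  UseMethod("pa_write_matrix")
}

#' @export
pa_write_matrix.pa_psm <- function(x, path) {
  hdr <- c(
    sprintf("# type=psm k=%d region=%s alpha=%.10g normalize=%s", x$k,
            format(x$region), x$alpha, x$normalize),
    sprintf("# n_real=%d n_false=%d", x$n_real, x$n_false)
  )
  write_matrix_tsv(x$values, "kmer", hdr, path)
}

#' @export
pa_write_matrix.pa_nom <- function(x, path) {
  hdr <- c(
    sprintf("# type=nom bins=%d region=%s alpha=%.10g mode=%s", x$bins,
            format(x$region), x$alpha, x$mode),
    sprintf("# n_real=%d n_false=%d", x$n_real, x$n_false)
  )
  m <- x$values
  rownames(m) <- if (x$mode == "binned") {
    sprintf("[%.3f,%.3f%s", x$edges[-length(x$edges)], x$edges[-1],
            c(rep(")", x$bins - 1L), "]"))
  } else "log2_mean_ratio"
  write_matrix_tsv(m, "bin", hdr, path)
}

write_matrix_tsv <- function(m, rowlab, header, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c(rowlab, colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- unlist(stringr::str_match_all(paste(hdr, collapse = " "),
                                        "(\\S+)=(\\S+)"))
  meta <- stats::setNames(
    matrix(meta, ncol = 3)[, 3],
    matrix(meta, ncol = 3)[, 2]
  )
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            sep = "\t", header = TRUE, row.names = 1,
                            check.names = FALSE, comment.char = "")
  list(meta = as.list(meta), values = as.matrix(body))
}

#' @rdname pa_write_matrix
#' @export
pa_read_psm <- function(path) {
  p <- read_matrix_tsv(path)
  stopifnot(identical(p$meta$type, "psm"))
  structure(
    list(values = p$values, k = as.integer(p$meta$k),
         region = pa_region(p$meta$region),
         alpha = as.numeric(p$meta$alpha),
         normalize = as.logical(p$meta$normalize),
         n_real = as.integer(p$meta$n_real),
         n_false = as.integer(p$meta$n_false)),
    class = "pa_psm"
  )
}

#' @rdname pa_write_matrix
#' @export
pa_read_nom <- function(path) {
  p <- read_matrix_tsv(path)
  stopifnot(identical(p$meta$type, "nom"))
  bins <- as.integer(p$meta$bins)
  structure(
    list(values = unname(p$values), bins = bins,
         edges = seq(0, 1, length.out = bins + 1L),
         alpha = as.numeric(p$meta$alpha), mode = p$meta$mode,
         region = pa_region(p$meta$region),
         n_real = as.integer(p$meta$n_real),
         n_false = as.integer(p$meta$n_false)),
    class = "pa_nom"
  )
}

#' Serialize fitted objects to JSON
#'
#' Classifiers ([pa_train()]) and Markov chains ([pa_fit_markov()]) are
#' written as JSON (parameters, standardizer, threshold / counts and
#' pseudocount) and can be read back into equivalent objects.
#'
#' @param x a `pa_model` or `pa_markov2`.
#' @param path output (input) file.
#' @return `pa_write_json()` returns `path` invisibly; the readers return
#'   the reconstructed object.
#' @export
pa_write_json <- function(x, path) {
  obj <- if (inherits(x, "pa_model")) {
    list(type = "pa_model", method = x$method,
         standardizer = if (!is.null(x$standardizer))
           unclass(x$standardizer),
         parameters = x$parameters,
         threshold = x$threshold, features = x$features)
  } else if (inherits(x, "pa_markov2")) {
    list(type = "pa_markov2", alpha = x$alpha,
         initial_counts = as.list(x$initial_counts),
         transition_counts = x$transition_counts)
  } else stop("unsupported object", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname pa_write_json
#' @export
pa_read_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(o$type, "pa_model"))
  par <- lapply(o$parameters, function(p) {
    if (is.list(p)) unlist(p) else p
  })
  if (!is.null(par$cov_pooled)) {
    k <- length(o$features)
    par$cov_pooled <- json_matrix(o$parameters$cov_pooled, k)
    par$cov_inv <- json_matrix(o$parameters$cov_inv, k)
    for (nm in c("mu_real", "mu_false"))
      par[[nm]] <- stats::setNames(as.numeric(par[[nm]]), o$features)
  }
  std <- if (!is.null(o$standardizer)) {
    structure(list(means = unlist(o$standardizer$means),
                   sds = unlist(o$standardizer$sds)),
              class = "pa_standardizer")
  }
  structure(list(method = o$method, standardizer = std, parameters = par,
                 threshold = o$threshold, features = o$features),
            class = "pa_model")
}

json_matrix <- function(p, k) {
  if (is.matrix(p)) matrix(as.numeric(p), k, k)
  else matrix(unlist(p), k, k, byrow = TRUE)
}

#' @rdname pa_write_json
#' @export
pa_read_markov <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(o$type, "pa_markov2"))
  tc <- o$transition_counts
  tc <- if (is.matrix(tc)) matrix(as.numeric(tc), 16L, 4L)
        else matrix(unlist(tc), 16L, 4L, byrow = TRUE)
  dimnames(tc) <- list(all_kmers(2L), BASES)
  ic <- unlist(o$initial_counts)
  alpha <- o$alpha
  structure(
    list(initial = (ic + alpha) / (sum(ic) + 16 * alpha),
         transitions = (tc + alpha) / (rowSums(tc) + 4 * alpha),
         initial_counts = ic, transition_counts = tc, alpha = alpha),
    class = "pa_markov2"
  )
}
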