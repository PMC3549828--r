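#' Cleavage-site-anchored regions
#'
#' Positions around a poly(A) cleavage site are written in signed
#' coordinates: `-1` is the last transcribed base before the cleavage point,
#' `+1` the first base after it, and there is no position 0. A region is a
#' contiguous signed interval, conventionally printed `"<-N,+M>"`. The full
#' modelling windows used throughout the package are regions of the form
#' `<-N,+M>`; feature subregions such as `<-100,-1>` (upstream only) use the
#' same notation.
#'
#' @param from,to signed positions (integers, nonzero, `from <= to`), or a
#'   single string in region notation for `pa_region(text)`.
#' @return A `pa_region` object with fields `from`, `to`, `upstream` (number
#'   of positions before the cleavage point), `downstream`, and `length`.
#' @examples
#' pa_region("<-100,+100>")
#' pa_region(-10, 10)
#' @export
pa_region <- function(from, to = NULL) {
  if (is.character(from)) {
    stopifnot(is.null(to), length(from) == 1L)
    return(pa_parse_region(from))
  }
  from <- as.integer(from); to <- as.integer(to)
  if (length(from) != 1L || length(to) != 1L || is.na(from) || is.na(to))
    stop("`from` and `to` must be single integers", call. = FALSE)
  if (from == 0L || to == 0L)
    stop("there is no position 0 in cleavage-site coordinates", call. = FALSE)
  if (from > to) stop("`from` must not exceed `to`", call. = FALSE)
  up <- if (from < 0L) -from else 0L
  down <- if (to > 0L) to else 0L
  len <- if (from < 0L && to > 0L) up + down else to - from + 1L
  structure(
    list(from = from, to = to, upstream = up, downstream = down,
         length = len),
    class = "pa_region"
  )
}

#' Parse region notation
#'
#' Parses strings like `"<-100,+100>"` or `"<-100,-1>"` into a [pa_region()].
#' Position 0 is rejected: the convention has no zero.
#'
#' @param text a single string, `"<from,to>"` with explicit signs.
#' @return A `pa_region`.
#' @export
pa_parse_region <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(
    text,
    regexec("^<\\s*([+-]\\d+)\\s*,\\s*([+-]\\d+)\\s*>$", trimws(text))
  )[[1]]
  if (length(m) != 3L)
    stop("malformed region notation: ", sQuote(text),
         " (expected e.g. \"<-100,+100>\")", call. = FALSE)
  from <- as.integer(m[2]); to <- as.integer(m[3])
  if (from == 0L || to == 0L)
    stop("region ", sQuote(text), " references position 0, which does not ",
         "exist in cleavage-site coordinates", call. = FALSE)
  pa_region(from, to)
}

#' @export
format.pa_region <- function(x, ...) {
  sprintf("<%+d,%+d>", x$from, x$to)
}

#' @export
print.pa_region <- function(x, ...) {
  cat("<pa_region> ", format(x), "  (", x$length, " nt)\n", sep = "")
  invisible(x)
}

#' Convert signed positions to array indices and back
#'
#' `pa_to_index()` maps a signed cleavage-anchored position onto the 1-based
#' index of that base within a region's sequence; `pa_from_index()` is its
#' inverse. The maps are bijections over the region's valid positions.
#'
#' @param pos signed position(s); 0 is invalid.
#' @param index 1-based array index (or indices).
#' @param region a [pa_region()] (any signed interval).
#' @return Integer vector of indices (positions).
#' @examples
#' r <- pa_region("<-100,+100>")
#' pa_to_index(-100, r)  # 1
#' pa_to_index(-1, r)    # 100
#' pa_to_index(+1, r)    # 101
#' @export
pa_to_index <- function(pos, region) {
  pos <- as.integer(pos)
  if (any(pos == 0L, na.rm = TRUE))
    stop("position 0 does not exist", call. = FALSE)
  if (any(pos < region$from | pos > region$to, na.rm = TRUE))
    stop("position out of region ", format(region), call. = FALSE)
  # collapse the missing zero, then shift so region$from -> 1
  lin <- ifelse(pos > 0L, pos - 1L, pos)
  lin0 <- if (region$from > 0L) region$from - 1L else region$from
  as.integer(lin - lin0 + 1L)
}

#' @rdname pa_to_index
#' @export
pa_from_index <- function(index, region) {
  index <- as.integer(index)
  if (any(index < 1L | index > region$length, na.rm = TRUE))
    stop("index out of range 1..", region$length, call. = FALSE)
  lin0 <- if (region$from > 0L) region$from - 1L else region$from
  lin <- index - 1L + lin0
  as.integer(ifelse(lin >= 0L, lin + 1L, lin))
}

#' Is one region contained in another?
#' @param inner,outer [pa_region()] objects.
#' @return Logical scalar.
#' @export
pa_region_contains <- function(outer, inner) {
  inner$from >= outer$from && inner$to <= outer$to
}
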