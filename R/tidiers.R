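#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy score matrices into long tibbles
#'
#' @param x a `pa_psm`, `pa_nom`, `pa_markov2` or `pa_model`.
#' @param ... unused.
#' @return A tibble in long format (one row per matrix entry, transition,
#'   or model term).
#' @export
tidy.pa_psm <- function(x, ...) {
  tibble::tibble(
    kmer = rep(rownames(x$values), times = ncol(x$values)),
    position = rep(as.integer(colnames(x$values)),
                   each = nrow(x$values)),
    score = as.vector(x$values)
  )
}

#' @rdname tidy.pa_psm
#' @export
tidy.pa_nom <- function(x, ...) {
  b <- nrow(x$values)
  tibble::tibble(
    bin = rep(seq_len(b), times = ncol(x$values)),
    bin_lower = rep(x$edges[seq_len(b)], times = ncol(x$values)),
    position = rep(as.integer(colnames(x$values)), each = b),
    score = as.vector(x$values)
  )
}

#' @rdname tidy.pa_psm
#' @export
tidy.pa_markov2 <- function(x, ...) {
  tibble::tibble(
    context = rep(rownames(x$transitions), times = 4L),
    base = rep(colnames(x$transitions), each = 16L),
    probability = as.vector(x$transitions),
    count = as.vector(x$transition_counts)
  )
}

#' @rdname tidy.pa_psm
#' @export
tidy.pa_model <- function(x, ...) {
  if (x$method == "lr") {
    co <- x$parameters$coefficients
    return(tibble::tibble(term = names(co), estimate = unname(co)))
  }
  w <- drop(x$parameters$cov_inv %*%
              (x$parameters$mu_real - x$parameters$mu_false))
  tibble::tibble(term = x$features, estimate = w)
}

#' Model-level summaries
#'
#' `glance()` reports one row of model-level information: the method, the
#' decision threshold, feature count and (for LDA) the class priors.
#'
#' @param x a `pa_model`.
#' @param ... unused.
#' @return A one-row tibble.
#' @export
glance.pa_model <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_features = length(x$features),
    threshold = x$threshold,
    standardized = !is.null(x$standardizer),
    prior_real = if (x$method == "lda") x$parameters$prior_real else NA_real_
  )
}

#' @rdname tidy.pa_psm
#' @export
tidy.pa_pca_profile <- function(x, ...) x$positions
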