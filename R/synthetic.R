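#' Synthetic poly(A) site generation profile
#'
#' Describes the site anatomy the generator plants into background sequence:
#' an A-rich hexamer signal ~20 nt upstream of the cleavage point (start
#' position drawn from a rounded normal), a cleavage-site dinucleotide
#' straddling `-1`/`+1` (CA-dominant), an optional U/GU-rich downstream
#' element over `+5..+30` (enabled in the vertebrate-style default, absent
#' in a plant-style profile), and a nucleosome-occupancy dip centred on the
#' site. The hexamer weights default to the canonical mammalian usage
#' (AATAAA 0.66, ATTAAA 0.16); the remaining mass plants no signal,
#' emulating non-canonical sites. These are scenario defaults for testing
#' the model end to end, not claims of biological realism.
#'
#' @param hexamer_weights named weights of planted signal hexamers; any
#'   mass short of 1 plants no hexamer.
#' @param signal_pos_mean,signal_pos_sd normal law for the hexamer start
#'   position (signed coordinates; clamped so the hexamer stays upstream).
#' @param cs_weights named weights of the cleavage dinucleotide (first base
#'   at `-1`, second at `+1`); must sum to 1.
#' @param dse_enabled plant a U/GU-rich downstream element.
#' @param dse_u_fraction T fraction inside the DSE window; G gets half the
#'   remainder, A/C a quarter each.
#' @param dse_window signed positions of the DSE (default `+5..+30`).
#' @param background named base frequencies (A/C/G/T) or a `pa_markov2`
#'   model for the background sequence.
#' @param occ_baseline,dip_depth,dip_width occupancy baseline, dip depth
#'   and full width at half maximum (nt) of the Gaussian dip in real
#'   tracks; false tracks are flat at the baseline.
#' @param occ_noise_sd per-position Gaussian track noise, clipped to
#'   `[0,1]`.
#' @return A `pa_profile` list.
#' @export
pa_profile <- function(hexamer_weights = c(AATAAA = 0.66, ATTAAA = 0.16),
                       signal_pos_mean = -21, signal_pos_sd = 3,
                       cs_weights = c(CA = 0.6, TA = 0.15, GA = 0.15,
                                      AA = 0.10),
                       dse_enabled = TRUE, dse_u_fraction = 0.5,
                       dse_window = c(5L, 30L),
                       background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                       occ_baseline = 0.6, dip_depth = 0.3,
                       dip_width = 150, occ_noise_sd = 0.05) {
  if (sum(hexamer_weights) > 1 + 1e-9)
    stop("hexamer weights must sum to at most 1", call. = FALSE)
  if (abs(sum(cs_weights) - 1) > 1e-9)
    stop("cleavage dinucleotide weights must sum to 1", call. = FALSE)
  if (any(nchar(names(hexamer_weights)) != 6L))
    stop("signal hexamers must be 6 nt", call. = FALSE)
  if (any(nchar(names(cs_weights)) != 2L))
    stop("cleavage elements must be dinucleotides", call. = FALSE)
  if (!inherits(background, "pa_markov2")) {
    stopifnot(setequal(names(background), c("A", "C", "G", "T")))
    background <- background[c("A", "C", "G", "T")] / sum(background)
  }
  structure(
    list(hexamer_weights = hexamer_weights,
         signal_pos_mean = signal_pos_mean, signal_pos_sd = signal_pos_sd,
         cs_weights = cs_weights, dse_enabled = dse_enabled,
         dse_u_fraction = dse_u_fraction, dse_window = as.integer(dse_window),
         background = background, occ_baseline = occ_baseline,
         dip_depth = dip_depth, dip_width = dip_width,
         occ_noise_sd = occ_noise_sd),
    class = "pa_profile"
  )
}

#' @export
print.pa_profile <- function(x, ...) {
  cat("<pa_profile> signal ",
      paste0(names(x$hexamer_weights), ":", x$hexamer_weights,
             collapse = ", "),
      " @ N(", x$signal_pos_mean, ",", x$signal_pos_sd, "); DSE ",
      if (x$dse_enabled) "on" else "off", "; dip depth ", x$dip_depth,
      "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic cleavage-anchored dataset
#'
#' Real records are background sequence with the profile's signal hexamer,
#' cleavage dinucleotide and (optionally) downstream element planted, and an
#' occupancy track with a centred dip; false records are background-only
#' sequences with flat tracks. Fully reproducible under `seed`.
#'
#' @param profile a [pa_profile()].
#' @param n_real,n_false record counts.
#' @param region [pa_region()] of the form `<-N,+M>` (default
#'   `<-300,+300>`).
#' @param seed optional integer seed.
#' @return A [pa_dataset()] with a `track` list-column.
#' @export
pa_simulate <- function(profile, n_real, n_false,
                        region = pa_region(-300L, 300L), seed = NULL) {
  stopifnot(inherits(profile, "pa_profile"))
  if (!is.null(seed)) set.seed(seed)
  l <- region$length
  n <- n_real + n_false
  codes <- background_codes(profile$background, n, l)
  # --- plant elements into the real records -------------------------------
  if (n_real > 0) {
    hw <- profile$hexamer_weights
    pick <- sample.int(length(hw) + 1L, n_real, replace = TRUE,
                       prob = c(hw, max(0, 1 - sum(hw))))
    start <- round(stats::rnorm(n_real, profile$signal_pos_mean,
                                profile$signal_pos_sd))
    start <- pmin(pmax(start, region$from), -6L)  # keep hexamer upstream
    for (i in seq_len(n_real)) {
      if (pick[i] > length(hw)) next
      hex <- match(strsplit(names(hw)[pick[i]], "")[[1]], BASES)
      j <- pa_to_index(start[i], region)
      codes[i, j:(j + 5L)] <- hex
    }
    cs <- sample.int(length(profile$cs_weights), n_real, replace = TRUE,
                     prob = profile$cs_weights)
    cs_b <- vapply(strsplit(names(profile$cs_weights), ""), match,
                   integer(2), table = BASES)
    i_m1 <- pa_to_index(-1L, region)
    codes[seq_len(n_real), i_m1] <- cs_b[1, cs]
    codes[seq_len(n_real), i_m1 + 1L] <- cs_b[2, cs]
    if (profile$dse_enabled) {
      dw <- profile$dse_window
      jj <- pa_to_index(dw[1], region):pa_to_index(dw[2], region)
      u <- profile$dse_u_fraction
      pdse <- c((1 - u) / 4, (1 - u) / 4, (1 - u) / 2, u)  # A,C,G,T
      codes[seq_len(n_real), jj] <-
        sample.int(4L, n_real * length(jj), replace = TRUE, prob = pdse)
    }
  }
  seqs <- apply(codes, 1, function(r) paste(BASES[r], collapse = ""))
  # --- occupancy tracks ----------------------------------------------------
  pos <- pa_from_index(seq_len(l), region)
  sigma <- profile$dip_width / (2 * sqrt(2 * log(2)))
  dip <- profile$dip_depth * exp(-(pos^2) / (2 * sigma^2))
  mk_track <- function(base_curve) {
    pmin(pmax(base_curve + stats::rnorm(l, 0, profile$occ_noise_sd), 0), 1)
  }
  tracks <- c(
    lapply(seq_len(n_real), function(i) mk_track(profile$occ_baseline - dip)),
    lapply(seq_len(n_false), function(i) mk_track(profile$occ_baseline))
  )
  pa_dataset(
    c(sprintf("real_%05d", seq_len(n_real)),
      sprintf("false_%05d", seq_len(n_false))),
    seqs, rep(c("real", "false"), c(n_real, n_false)), region,
    track = tracks
  )
}

background_codes <- function(background, n, l) {
  if (inherits(background, "pa_markov2")) {
    d <- pa_sample_negatives(background, n, l)
    encode_bases(d$sequence)
  } else {
    matrix(sample.int(4L, n * l, replace = TRUE, prob = background),
           nrow = n, ncol = l)
  }
}

#' Generate long sequences with one planted site each, for scanning
#'
#' Builds `n` background sequences of the given length, plants one complete
#' synthetic site (per `profile`) at a cleavage point drawn uniformly from
#' the central portion, and returns matching full-length occupancy tracks
#' with the dip centred on the planted site.
#'
#' @param profile a [pa_profile()].
#' @param n number of sequences.
#' @param length sequence length (default 2000).
#' @param margin minimum distance of the planted cleavage point from either
#'   end (default 400, so every site is coverable by a 600-nt window).
#' @param seed optional integer seed.
#' @return A tibble: `id`, `site` (position of the `-1` base), `sequence`,
#'   `track` (list-column).
#' @export
pa_simulate_scan <- function(profile, n, length = 2000L, margin = 400L,
                             seed = NULL) {
  stopifnot(inherits(profile, "pa_profile"), length > 2L * margin)
  if (!is.null(seed)) set.seed(seed)
  site <- sample.int(length - 2L * margin, n, replace = TRUE) + margin
  region <- pa_region(-300L, 300L)
  planted <- pa_simulate(profile, n, 0L, region = region)
  codes <- background_codes(profile$background, n, length)
  pcodes <- encode_bases(planted$sequence)
  tracks <- vector("list", n)
  base <- profile$occ_baseline
  for (i in seq_len(n)) {
    lo <- site[i] - 300L + 1L
    codes[i, lo:(lo + 599L)] <- pcodes[i, ]
    tr <- pmin(pmax(base + stats::rnorm(length, 0, profile$occ_noise_sd),
                    0), 1)
    tr[lo:(lo + 599L)] <- planted$track[[i]]
    tracks[[i]] <- tr
  }
  tibble::tibble(
    id = sprintf("scan_%04d", seq_len(n)), site = site,
    sequence = apply(codes, 1, function(r) paste(BASES[r], collapse = "")),
    track = tracks
  )
}

#' Divergent generation profiles
#'
#' Produces profiles interpolated away from a base profile, emulating
#' species whose site anatomy has drifted: hexamer weights move toward an
#' alternate hexamer set, the signal position shifts upstream, and the
#' downstream element weakens, all proportionally to `divergence` in
#' `[0, 1]`.
#'
#' @param base a [pa_profile()].
#' @param divergence scalar or vector of divergences in `[0,1]`.
#' @param alt_hexamers named weights of the fully-diverged signal set.
#' @param pos_shift signal-position shift (nt) at divergence 1.
#' @return A list of `pa_profile`s, one per divergence value.
#' @export
pa_divergent_profiles <- function(base, divergence,
                                  alt_hexamers = c(AATGAA = 0.66,
                                                   TATAAA = 0.16),
                                  pos_shift = -10) {
  stopifnot(inherits(base, "pa_profile"),
            all(divergence >= 0 & divergence <= 1))
  lapply(divergence, function(d) {
    hex <- c(base$hexamer_weights * (1 - d), alt_hexamers * d)
    hex <- vapply(split(hex, factor(names(hex), unique(names(hex)))), sum,
                  numeric(1))
    p <- base
    p$hexamer_weights <- hex[hex > 0]
    p$signal_pos_mean <- base$signal_pos_mean + d * pos_shift
    p$dse_u_fraction <- base$dse_u_fraction * (1 - d)
    p
  })
}
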