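#' Library descriptor
#'
#' Describes one paired-read library: the insert-size model used everywhere
#' paired evidence is consulted (correctly-placed-pair windows, bifurcation
#' counts, CE statistic).
#'
#' @param library_id Short unique identifier for the library.
#' @param mean_insert Mean insert size `m` in bp (outer distance, first base
#'   of the leftmost read to last base of the rightmost read). Must be > 0.
#' @param sd_insert Insert-size standard deviation in bp, >= 0.
#' @param orientation `"fr"` (forward-reverse, typical paired-end) or `"rf"`
#'   (reverse-forward, typical mate-pair after circularization).
#' @return An object of class `library_descriptor`.
#' @export
library_descriptor <- function(library_id, mean_insert, sd_insert,
                               orientation = c("fr", "rf")) {
  orientation <- match.arg(orientation)
  stopifnot(is.character(library_id), length(library_id) == 1L,
            nzchar(library_id))
  if (!(is.numeric(mean_insert) && length(mean_insert) == 1L && mean_insert > 0))
    stop("mean_insert must be a single positive number")
  if (!(is.numeric(sd_insert) && length(sd_insert) == 1L && sd_insert >= 0))
    stop("sd_insert must be a single non-negative number")
  structure(list(library_id = library_id,
                 mean_insert = as.numeric(mean_insert),
                 sd_insert = as.numeric(sd_insert),
                 orientation = orientation),
            class = "library_descriptor")
}

#' @export
print.library_descriptor <- function(x, ...) {
  cat(sprintf("<library %s: insert %g +/- %g bp, %s>\n",
              x$library_id, x$mean_insert, x$sd_insert, toupper(x$orientation)))
  invisible(x)
}

#' Reconciliation configuration
#'
#' All tunable thresholds of the merger in one object. Defaults are the
#' bacteria-scale settings (`B_min = 10`, `T_c = 0.75`, `T_l = 200`); the
#' `"large"` profile raises `B_min` to 50 and `T_l` to 500 bp for
#' large-genome runs.
#'
#' @param B_min Minimum number of reads for a block to be kept at
#'   construction time.
#' @param T_c Coverage-ratio threshold in `[0, 1]`: a block is kept iff the
#'   larger of its two block/global coverage ratios reaches `T_c`.
#' @param T_l Frame-length threshold in bp for the length filter.
#' @param T_U,T_L Upper/lower bifurcation thresholds in `[0, 1]` applied to
#'   the normalized spanning-pair ratio `n / (n + u)`; requires `T_U > T_L`.
#' @param min_identity Minimum identity (fraction) a junction's semi-global
#'   alignment must reach before sequences are merged.
#' @param band_pad Extra half-width in bp added to the alignment band beyond
#'   the length difference of the two sequences.
#' @param min_inversion_evidence Minimum number of wrongly-oriented pairs on
#'   exactly one assembly required to call an inversion in a 2-node cycle.
#' @param flank_len Maximum flank length in bp over which junction identity
#'   is evaluated.
#' @param profile Optional profile name (`"bacteria"` or `"large"`) applied
#'   before explicit arguments.
#' @param seed Optional integer seed recorded in the config (the pipeline
#'   itself is deterministic; the seed drives fixture simulation).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(B_min = 10L, T_c = 0.75, T_l = 200L,
                         T_U = 0.9, T_L = 0.1,
                         min_identity = 0.95, band_pad = 64L,
                         min_inversion_evidence = 5L,
                         flank_len = 1000L,
                         profile = NULL, seed = NULL) {
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("bacteria", "large"))
    defs <- switch(profile,
                   bacteria = list(B_min = 10L, T_c = 0.75, T_l = 200L),
                   large = list(B_min = 50L, T_c = 0.75, T_l = 500L))
    call_args <- names(match.call())[-1L]
    for (nm in names(defs))
      if (!nm %in% call_args) assign(nm, defs[[nm]])
  }
  stopifnot(B_min >= 1, T_c >= 0, T_c <= 1, T_l >= 0,
            T_U >= 0, T_U <= 1, T_L >= 0, T_L <= 1,
            min_identity >= 0, min_identity <= 1,
            band_pad >= 0, min_inversion_evidence >= 1, flank_len >= 1)
  if (!(T_U > T_L)) stop("T_U must be strictly greater than T_L")
  structure(list(B_min = as.integer(B_min), T_c = T_c, T_l = as.integer(T_l),
                 T_U = T_U, T_L = T_L, min_identity = min_identity,
                 band_pad = as.integer(band_pad),
                 min_inversion_evidence = as.integer(min_inversion_evidence),
                 flank_len = as.integer(flank_len),
                 profile = if (is.null(profile)) NA_character_ else profile,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "recon_config")
}

#' @export
print.recon_config <- function(x, ...) {
  cat(sprintf(paste0("<recon_config: B_min=%d T_c=%g T_l=%d T_U=%g T_L=%g ",
                     "min_identity=%g band_pad=%d min_inv_ev=%d flank=%d>\n"),
              x$B_min, x$T_c, x$T_l, x$T_U, x$T_L, x$min_identity,
              x$band_pad, x$min_inversion_evidence, x$flank_len))
  invisible(x)
}
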