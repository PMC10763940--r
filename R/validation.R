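#' Spike-recovery metrics
#'
#' For a sample spiked with a known Cr(VI) amount, recovery is
#' `100 * measured / spiked` percent and the recovery error is
#' `RE = 100 - recovery` (an exact identity, preserved at full precision).
#'
#' @param spiked_ppb known added concentration(s), must be positive.
#' @param measured_ppb pipeline estimate(s), same length.
#' @return Data frame of class `recovery_record` with columns `spiked_ppb`,
#'   `measured_ppb`, `recovery_pct`, `re_pct`.
#' @examples
#' recovery(c(50, 500), c(50.528, 499.858))
#' @export
recovery <- function(spiked_ppb, measured_ppb) {
  if (length(spiked_ppb) != length(measured_ppb))
    stop("'spiked_ppb' and 'measured_ppb' must have equal length")
  if (any(!is.finite(spiked_ppb)) || any(spiked_ppb <= 0))
    stop("spiked concentrations must be positive")
  rec <- 100 * measured_ppb / spiked_ppb
  out <- data.frame(spiked_ppb = spiked_ppb, measured_ppb = measured_ppb,
                    recovery_pct = rec, re_pct = 100 - rec)
  class(out) <- c("recovery_record", "data.frame")
  out
}

#' @export
print.recovery_record <- function(x, ...) {
  shown <- x
  shown$recovery_pct <- round(shown$recovery_pct, 4)
  shown$re_pct <- round(shown$re_pct, 4)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Absolute relative deviation between two measurements
#'
#' `|test - reference| / reference`, the per-sample error fraction used in
#' paired method comparison (a value of 0.068 means 6.8% relative
#' deviation). Scale-invariant: multiplying both arguments by a positive
#' constant leaves it unchanged.
#'
#' @param reference_ppb reference-method value(s), must be positive.
#' @param test_ppb test-method value(s).
#' @return Numeric vector of error fractions.
#' @examples
#' error_fraction(187.412, 174.740)  # 0.068
#' @export
error_fraction <- function(reference_ppb, test_ppb) {
  if (any(!is.finite(reference_ppb)) || any(reference_ppb <= 0))
    stop("reference values must be positive")
  abs(test_ppb - reference_ppb) / reference_ppb
}

#' Paired comparison of two measurement methods
#'
#' Compares concentrations from a reference method (e.g. spectrophotometer)
#' and a test method (the plate imager) on the same samples. Pairs where
#' either method reports non-detectable (`NA`) are excluded. Reports the
#' per-pair error fraction, the Pearson correlation over all included pairs,
#' and -- because gross outliers can occur in field samples -- the
#' correlation over the pairs whose error fraction does not exceed
#' `outlier_tol`.
#'
#' @param reference_ppb,test_ppb paired concentration vectors (`NA` for
#'   non-detectable results).
#' @param sample_id optional identifiers.
#' @param outlier_tol error-fraction threshold above which a pair is flagged
#'   discordant (default 0.5).
#' @return Object of class `method_comparison`: data frame `pairs`
#'   (sample_id, reference_ppb, test_ppb, error_fraction, flagged) plus
#'   `pearson_r` (all included pairs), `pearson_r_concordant`, `n_used`,
#'   `n_excluded`.
#' @export
compare_methods <- function(reference_ppb, test_ppb, sample_id = NULL,
                            outlier_tol = 0.5) {
  if (length(reference_ppb) != length(test_ppb))
    stop("reference and test vectors must have equal length")
  if (is.null(sample_id)) sample_id <- seq_along(reference_ppb)
  sample_id <- as.character(sample_id)
  keep <- is.finite(reference_ppb) & is.finite(test_ppb)
  n_excluded <- sum(!keep)
  ref <- reference_ppb[keep]; tst <- test_ppb[keep]
  if (length(ref) < 3L) stop("need >= 3 paired non-N.D. samples")
  ef <- error_fraction(ref, tst)
  flagged <- ef > outlier_tol
  r_all <- stats::cor(ref, tst)
  r_conc <- if (sum(!flagged) >= 3L) stats::cor(ref[!flagged], tst[!flagged]) else NA_real_
  pairs <- data.frame(sample_id = sample_id[keep], reference_ppb = ref,
                      test_ppb = tst, error_fraction = ef, flagged = flagged,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, pearson_r = r_all,
                 pearson_r_concordant = r_conc,
                 n_used = length(ref), n_excluded = n_excluded,
                 outlier_tol = outlier_tol),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Method comparison over %d pairs (%d excluded as N.D.)\n",
              x$n_used, x$n_excluded))
  cat(sprintf("  Pearson r = %.5f (all pairs); %.5f over the %d pairs with error fraction <= %g\n",
              x$pearson_r,
              x$pearson_r_concordant, sum(!x$pairs$flagged), x$outlier_tol))
  if (any(x$pairs$flagged))
    cat("  discordant sample(s):",
        paste(x$pairs$sample_id[x$pairs$flagged], collapse = ", "), "\n")
  invisible(x)
}

#' Ion-selectivity report
#'
#' Quantifies cross-reactivity of the chromogenic reaction: for each
#' potentially interfering species the blank-subtracted signal is expressed
#' as a fraction of the blank-subtracted Cr(VI) signal. Species whose ratio
#' exceeds `interference_tol` are flagged as interfering.
#'
#' @param signal_by_species named numeric vector of responses, one per ion
#'   (e.g. `c("Cr3+" = ..., "Pb2+" = ...)`).
#' @param cr6_signal response with Cr(VI) present.
#' @param blank response of the blank reaction (no analyte); required.
#' @param interference_tol ratio above which a species is flagged
#'   (default 0.1).
#' @return Data frame of class `selectivity_report`: species, signal, ratio,
#'   flagged.
#' @export
selectivity_report <- function(signal_by_species, cr6_signal, blank,
                               interference_tol = 0.1) {
  if (missing(blank) || is.null(blank) || !is.finite(blank))
    stop("a finite blank signal is required for blank subtraction")
  if (!is.finite(cr6_signal)) stop("Cr(VI) signal must be present and finite")
  denom <- cr6_signal - blank
  if (denom == 0) stop("Cr(VI) signal equals the blank; no selectivity to report")
  if (is.null(names(signal_by_species)) || any(names(signal_by_species) == ""))
    stop("'signal_by_species' must be a fully named vector")
  ratio <- (signal_by_species - blank) / denom
  out <- data.frame(species = names(signal_by_species),
                    signal = as.numeric(signal_by_species),
                    ratio = as.numeric(ratio),
                    flagged = as.numeric(ratio) > interference_tol,
                    stringsAsFactors = FALSE)
  class(out) <- c("selectivity_report", "data.frame")
  out
}

#' @export
print.selectivity_report <- function(x, ...) {
  shown <- x
  shown$ratio <- round(shown$ratio, 4)
  print.data.frame(shown, row.names = FALSE)
  if (any(x$flagged))
    cat("Interfering species:", paste(x$species[x$flagged], collapse = ", "), "\n")
  else cat("No species exceeds the interference tolerance.\n")
  invisible(x)
}
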