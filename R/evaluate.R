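# Evaluation metrics: signed relative error, median absolute percent error
# (overall and per charge), and residual-descriptor correlations.

#' Signed relative CCS error in percent
#'
#' @param pred Predicted CCS (Angstrom^2).
#' @param obs Observed CCS (Angstrom^2), must be positive.
#' @return \code{100 * (pred - obs) / obs}.
#' @export
relative_error <- function(pred, obs) {
  if (any(obs <= 0)) stop_domain("observed CCS must be positive")
  100 * (pred - obs) / obs
}

#' Median absolute percent error
#'
#' The comparison metric used throughout: the median of the absolute signed
#' relative errors, robust to the mass-dependent spread of CCS values.
#'
#' @inheritParams relative_error
#' @return MAPE in percent.
#' @export
mape <- function(pred, obs) {
  if (length(pred) == 0L) stop_domain("empty input")
  if (length(pred) != length(obs)) stop_domain("pred and obs lengths differ")
  median(abs(relative_error(pred, obs)))
}

#' Per-charge median absolute percent error
#'
#' @inheritParams relative_error
#' @param charge Charge state per observation.
#' @return Named numeric vector, one MAPE per charge state.
#' @export
mape_per_charge <- function(pred, obs, charge) {
  if (length(pred) == 0L) stop_domain("empty input")
  err <- abs(relative_error(pred, obs))
  vapply(split(err, charge), median, numeric(1))
}

#' Correlate model residuals with additive scalar descriptors
#'
#' Pearson correlation between the sequence-wise predicted residual CCS
#' contribution and each of the nine length-normalized scalar descriptors.
#'
#' @param residuals Numeric vector of predicted residuals.
#' @param sequences Canonical compact sequences, same length.
#' @param table Descriptor table, default [descriptor_table()].
#' @return Named numeric vector of nine correlations; a zero-variance
#'   descriptor yields NA.
#' @export
correlate_residual_descriptors <- function(residuals, sequences,
                                           table = descriptor_table()) {
  if (length(residuals) < 3L) stop_domain("need at least 3 sequences")
  if (length(residuals) != length(sequences))
    stop_domain("residuals and sequences lengths differ")
  desc <- t(vapply(sequences, scalar_descriptors, numeric(length(table)),
                   table = table))
  apply(desc, 2L, function(col) {
    if (sd(col) == 0) return(NA_real_)
    cor(residuals, col)
  })
}

#' Evaluation report for a set of CCS predictions
#'
#' @inheritParams mape_per_charge
#' @param sequences Optional sequences; when given, residual-descriptor
#'   correlations are included (residual here = pred - obs).
#' @return List with overall MAPE, per-charge MAPE, the per-ion relative
#'   errors, and optionally the descriptor correlations.
#' @export
eval_report <- function(pred, obs, charge, sequences = NULL) {
  rep_ <- list(mape = mape(pred, obs),
               mape_per_charge = mape_per_charge(pred, obs, charge),
               relative_error = relative_error(pred, obs))
  if (!is.null(sequences))
    rep_$descriptor_correlation <-
      correlate_residual_descriptors(pred - obs, sequences)
  rep_
}
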