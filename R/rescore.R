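# CCS feature set for PSM rescoring and its injection into percolator PIN
# files.

#' CCS feature set for one PSM
#'
#' The five rescoring features: observed CCS, predicted CCS, the signed
#' error (observed - predicted), the absolute error, and the signed percent
#' error relative to the observed value.
#'
#' @param observed Observed CCS (Angstrom^2), positive.
#' @param predicted Predicted CCS (Angstrom^2).
#' @return Data frame with columns \code{ccs_observed}, \code{ccs_predicted},
#'   \code{ccs_error}, \code{ccs_abs_error}, \code{ccs_perc_error}.
#' @export
#' @examples
#' ccs_features(600, 570)
ccs_features <- function(observed, predicted) {
  if (any(observed <= 0)) stop_domain("observed CCS must be positive")
  err <- observed - predicted
  data.frame(ccs_observed = observed,
             ccs_predicted = predicted,
             ccs_error = err,
             ccs_abs_error = abs(err),
             ccs_perc_error = 100 * err / observed)
}

CCS_FEATURE_NAMES <- c("ccs_observed", "ccs_predicted", "ccs_error",
                       "ccs_abs_error", "ccs_perc_error")

pin_charge <- function(pin) {
  charge_cols <- grep("^Charge[0-9]+$", pin$header)
  if (length(charge_cols) == 0L)
    stop_format("PIN has no Charge<N> one-hot columns")
  charges <- as.integer(sub("^Charge", "", pin$header[charge_cols]))
  if (nrow(pin$rows) == 0L) return(integer(0))
  onehot <- pin$rows[, charge_cols, drop = FALSE] == "1"
  apply(onehot, 1L, function(r) {
    hit <- which(r)
    if (length(hit) == 1L) charges[hit] else NA_integer_
  })
}

#' Add CCS features to a percolator PIN table
#'
#' Joins each PSM to an observed/predicted CCS pair by (peptide, charge),
#' computes the five [ccs_features()] columns and inserts them immediately
#' before the peptide column. The PSM charge is taken from the
#' \code{Charge<N>} one-hot feature columns. Rows with charge above
#' \code{max_charge} are removed (the predictor is not trained for them), as
#' are rows without a matching prediction; both removals are counted
#' separately in the report. All other columns are untouched.
#'
#' @param pin A \code{pin_table} from [read_pin()].
#' @param ccs_table Data frame with columns \code{peptide} (matching the PIN
#'   peptide column), \code{charge}, \code{ccs_observed},
#'   \code{ccs_predicted}.
#' @param max_charge Highest charge state kept (default 4).
#' @return List with \code{pin} (augmented \code{pin_table}) and
#'   \code{report} (\code{charge_filtered}, \code{unmatched},
#'   \code{rows_out}).
#' @export
augment_pin <- function(pin, ccs_table, max_charge = 4L) {
  stopifnot(inherits(pin, "pin_table"))
  if (any(CCS_FEATURE_NAMES %in% pin$header))
    stop_format("PIN already contains CCS feature columns; refusing to augment twice")
  need <- c("peptide", "charge", "ccs_observed", "ccs_predicted")
  miss <- setdiff(need, names(ccs_table))
  if (length(miss))
    stop_format("ccs_table missing column(s): %s", paste(miss, collapse = ", "))

  pep_col <- which(tolower(pin$header) == "peptide")
  if (length(pep_col) != 1L)
    stop_format("PIN must have exactly one peptide column")

  charge <- pin_charge(pin)
  keep_charge <- !is.na(charge) & charge <= max_charge
  key_pin <- paste(pin$rows[, pep_col], charge, sep = "\r")
  key_tab <- paste(ccs_table$peptide, ccs_table$charge, sep = "\r")
  match_idx <- match(key_pin, key_tab)
  matched <- !is.na(match_idx)
  keep <- keep_charge & matched

  feats <- ccs_features(ccs_table$ccs_observed[match_idx[keep]],
                        ccs_table$ccs_predicted[match_idx[keep]])
  feat_str <- vapply(feats, function(col) sprintf("%.6f", col),
                     character(sum(keep)))
  if (sum(keep) == 1L) feat_str <- matrix(feat_str, nrow = 1L)

  rows <- pin$rows[keep, , drop = FALSE]
  new_rows <- cbind(rows[, seq_len(pep_col - 1L), drop = FALSE],
                    feat_str,
                    rows[, pep_col:ncol(rows), drop = FALSE])
  dimnames(new_rows) <- NULL
  new_header <- append(pin$header, CCS_FEATURE_NAMES, after = pep_col - 1L)
  dd <- pin$default_direction
  if (!is.null(dd))
    dd <- append(dd, rep("0", length(CCS_FEATURE_NAMES)), after = pep_col - 1L)

  out <- structure(list(header = new_header, rows = new_rows,
                        default_direction = dd),
                   class = "pin_table")
  list(pin = out,
       report = list(charge_filtered = sum(!keep_charge),
                     unmatched = sum(keep_charge & !matched),
                     rows_out = nrow(new_rows)))
}
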