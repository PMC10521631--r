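# Per-charge square-root baseline: CCS_init(mz, c) = w_c * sqrt(mz) + b_c.

#' Fit the per-charge square-root CCS baseline
#'
#' For each charge state up to \code{max_charge}, fits
#' \code{ccs ~ w * sqrt(mz) + b} by linear least squares. The model is
#' linear in its parameters, so the fit is deterministic. Charges above
#' \code{max_charge} are excluded; a modeled charge present with fewer than
#' two points is an error.
#'
#' @param ds An [ion_dataset()] with CCS values (typically deduplicated).
#' @param max_charge Highest modeled charge state (default 4).
#' @return Object of class \code{sqrt_fit}: per-charge \code{w}, \code{b},
#'   number of points \code{n} and residual \code{mae}.
#' @export
fit_sqrt <- function(ds, max_charge = 4L) {
  if (anyNA(ds$ccs)) stop_domain("all records must carry a CCS value")
  params <- list()
  for (c_ in seq_len(max_charge)) {
    idx <- which(ds$charge == c_)
    if (length(idx) == 0L) next
    if (length(idx) < 2L)
      stop_fit("charge %d has %d point(s); need at least 2", c_, length(idx))
    x <- sqrt(ds$mz[idx])
    fit <- stats::lm.fit(cbind(1, x), ds$ccs[idx])
    w <- unname(fit$coefficients[2L])
    b <- unname(fit$coefficients[1L])
    if (!is.finite(w) || w <= 0)
      warning(sprintf("non-positive slope w=%g for charge %d", w, c_),
              call. = FALSE)
    params[[as.character(c_)]] <- list(
      w = w, b = b, n = length(idx),
      mae = mean(abs(fit$residuals)))
  }
  if (length(params) == 0L) stop_fit("no charge state has data to fit")
  structure(list(params = params, max_charge = as.integer(max_charge)),
            class = "sqrt_fit")
}

#' @export
print.sqrt_fit <- function(x, ...) {
  cat("<sqrt_fit: CCS ~ w * sqrt(mz) + b per charge>\n")
  for (c_ in names(x$params)) {
    p <- x$params[[c_]]
    cat(sprintf("  charge %s: w = %8.4f  b = %9.4f  (n = %d, MAE = %.3f)\n",
                c_, p$w, p$b, p$n, p$mae))
  }
  invisible(x)
}

#' Baseline CCS prediction from m/z and charge
#'
#' @param mz m/z values (Th).
#' @param charge Charge states (recycled against \code{mz}).
#' @param params A \code{sqrt_fit} from [fit_sqrt()].
#' @return \code{w_c * sqrt(mz) + b_c} in Angstrom^2.
#' @export
#' @examples
#' \dontrun{predict_init(400, 2, params)}
predict_init <- function(mz, charge, params) {
  stopifnot(inherits(params, "sqrt_fit"))
  n <- max(length(mz), length(charge))
  mz <- rep_len(mz, n)
  charge <- rep_len(as.integer(charge), n)
  bad <- setdiff(unique(charge), as.integer(names(params$params)))
  if (length(bad))
    stop_domain("no fitted baseline for charge(s) %s",
                paste(sort(bad), collapse = ", "))
  w <- vapply(as.character(charge), function(k) params$params[[k]]$w, numeric(1))
  b <- vapply(as.character(charge), function(k) params$params[[k]]$b, numeric(1))
  unname(w * sqrt(mz) + b)
}

#' Serialize a square-root baseline fit to JSON
#' @param params A \code{sqrt_fit}.
#' @param path Output path.
#' @export
write_sqrt_fit <- function(params, path) {
  jsonlite::write_json(list(max_charge = params$max_charge,
                            params = params$params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a square-root baseline fit from JSON
#' @param path Path written by [write_sqrt_fit()].
#' @return A \code{sqrt_fit}.
#' @export
read_sqrt_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  structure(list(params = obj$params,
                 max_charge = as.integer(obj$max_charge)),
            class = "sqrt_fit")
}
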