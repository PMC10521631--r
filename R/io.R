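# Reading search-engine identification tables and percolator PIN files,
# and the canonical dataset CSV format.

CANONICAL_COLUMNS <- c("sequence", "charge", "mz", "inv_k0", "ccs",
                       "intensity", "occurrence", "source_id")

#' Construct an ion dataset
#'
#' The canonical in-memory container: a data frame of identified peptide ion
#' observations with dataset-level metadata attached (drift gas, temperature,
#' any alignment shift already applied).
#'
#' @param records Data frame with columns \code{sequence} (canonical compact
#'   modified sequence), \code{charge}, \code{mz}, and optionally
#'   \code{inv_k0}, \code{ccs}, \code{intensity}, \code{occurrence},
#'   \code{source_id}; deduplicated datasets additionally carry
#'   \code{modality} and \code{n_modes}.
#' @param source_id Label of the originating dataset.
#' @param gas Drift gas label (default nitrogen).
#' @param temperature Drift gas temperature in Kelvin.
#' @param shift_applied Additive CCS alignment shift already applied, in
#'   Angstrom^2.
#' @return Object of class \code{ion_dataset} (a data frame).
#' @export
ion_dataset <- function(records, source_id = "", gas = "N2",
                        temperature = 305, shift_applied = 0) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (nrow(records) == 0L) records <- empty_records()
  for (col in c("inv_k0", "ccs", "intensity"))
    if (is.null(records[[col]])) records[[col]] <- NA_real_
  if (is.null(records$occurrence)) records$occurrence <- 1L
  if (is.null(records$source_id)) records$source_id <- source_id
  if (nrow(records) > 0L) {
    if (is.null(records$sequence) || is.null(records$charge) ||
        is.null(records$mz))
      stop_format("records need sequence, charge and mz columns")
    records$charge <- as.integer(records$charge)
    records$occurrence <- as.integer(records$occurrence)
    if (any(records$charge < 1L)) stop_domain("charge must be >= 1")
    if (any(records$mz <= 0)) stop_domain("mz must be positive")
    if (any(!is.na(records$ccs) & records$ccs <= 0))
      stop_domain("ccs must be positive when present")
    if (any(records$occurrence < 1L)) stop_domain("occurrence must be >= 1")
  }
  ord <- intersect(c(CANONICAL_COLUMNS, "modality", "n_modes"), names(records))
  records <- records[, ord, drop = FALSE]
  structure(records,
            class = c("ion_dataset", "data.frame"),
            meta = list(source_id = source_id, gas = gas,
                        temperature = temperature,
                        shift_applied = shift_applied))
}

#' @export
print.ion_dataset <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<ion_dataset: %d records, source '%s', gas %s, %g K, shift %+g A^2>\n",
              nrow(x), m$source_id, m$gas, m$temperature, m$shift_applied))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more records\n", nrow(x) - 6L))
  invisible(x)
}

dataset_meta <- function(ds) attr(ds, "meta")

empty_records <- function() {
  data.frame(sequence = character(0), charge = integer(0), mz = numeric(0),
             inv_k0 = numeric(0), ccs = numeric(0), intensity = numeric(0),
             occurrence = integer(0), source_id = character(0),
             stringsAsFactors = FALSE)
}

num_or_na <- function(x) {
  x[!nzchar(trimws(ifelse(is.na(x), "", x)))] <- NA
  suppressWarnings(as.numeric(x))
}

# Default PEAKS column map; overridable because PEAKS exports vary.
PEAKS_DEFAULT_MAP <- c(sequence = "Peptide", charge = "Z", mz = "m/z",
                       ccs = "CCS", inv_k0 = "1/K0", intensity = "Intensity")

require_columns <- function(have, need, path) {
  missing <- setdiff(need, have)
  if (length(missing))
    stop_format("missing mandatory column(s) %s in %s",
                paste(sprintf('"%s"', missing), collapse = ", "), path)
}

#' Read a search-engine identification table
#'
#' Parses a MaxQuant evidence-style TSV, a PEAKS-style CSV, or the canonical
#' dataset CSV into an [ion_dataset()]. Sequences are converted to the
#' canonical form via [tokenize()]; rows whose sequence or charge cannot be
#' parsed (e.g. unknown modifications outside the closed vocabulary) are
#' skipped and counted in the read report.
#'
#' @param path Path to the file.
#' @param dialect One of \code{"canonical"}, \code{"maxquant"}, \code{"peaks"}.
#' @param column_map Named character vector overriding the PEAKS column map
#'   (names: sequence, charge, mz, ccs, inv_k0, intensity).
#' @param source_id Dataset label; defaults to the file name.
#' @return An [ion_dataset()]; attribute \code{read_report} holds
#'   \code{n_rows}, \code{n_kept} and \code{n_skipped}.
#' @export
read_search_results <- function(path,
                                dialect = c("canonical", "maxquant", "peaks"),
                                column_map = NULL,
                                source_id = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_io("file not found: %s", path)

  if (dialect == "canonical") {
    raw <- read.csv(path, colClasses = "character", check.names = FALSE)
    require_columns(names(raw), c("sequence", "charge", "mz"), path)
    cols <- list(sequence = raw$sequence, charge = raw$charge, mz = raw$mz,
                 inv_k0 = raw$inv_k0, ccs = raw$ccs,
                 intensity = raw$intensity, occurrence = raw$occurrence,
                 src = raw$source_id, modality = raw$modality,
                 n_modes = raw$n_modes)
    seq_dialect <- "canonical"
  } else if (dialect == "maxquant") {
    raw <- read.delim(path, check.names = FALSE, colClasses = "character",
                      sep = "\t")
    require_columns(names(raw), c("Modified sequence", "Charge", "m/z"), path)
    if (!any(c("CCS", "1/K0") %in% names(raw)))
      stop_format('missing mandatory column(s) "CCS" or "1/K0" in %s', path)
    cols <- list(sequence = raw[["Modified sequence"]], charge = raw$Charge,
                 mz = raw[["m/z"]], inv_k0 = raw[["1/K0"]], ccs = raw$CCS,
                 intensity = raw$Intensity, occurrence = NULL, src = NULL,
                 modality = NULL, n_modes = NULL)
    seq_dialect <- "maxquant"
  } else {
    map <- PEAKS_DEFAULT_MAP
    if (!is.null(column_map)) map[names(column_map)] <- column_map
    raw <- read.csv(path, check.names = FALSE, colClasses = "character")
    require_columns(names(raw), unname(map[c("sequence", "charge", "mz")]), path)
    if (!any(map[c("ccs", "inv_k0")] %in% names(raw)))
      stop_format('missing mandatory column(s) "%s" or "%s" in %s',
                  map[["ccs"]], map[["inv_k0"]], path)
    get <- function(key) if (map[[key]] %in% names(raw)) raw[[map[[key]]]] else NULL
    cols <- list(sequence = get("sequence"), charge = get("charge"),
                 mz = get("mz"), inv_k0 = get("inv_k0"), ccs = get("ccs"),
                 intensity = get("intensity"), occurrence = NULL, src = NULL,
                 modality = NULL, n_modes = NULL)
    seq_dialect <- "peaks"
  }

  n_rows <- length(cols$sequence)
  if (n_rows == 0L) {
    ds <- ion_dataset(empty_records(), source_id = source_id)
    attr(ds, "read_report") <- list(n_rows = 0L, n_kept = 0L, n_skipped = 0L)
    warning("empty identification table: ", path, call. = FALSE)
    return(ds)
  }

  seq_canon <- character(n_rows)
  keep <- logical(n_rows)
  charge <- suppressWarnings(as.integer(cols$charge))
  mz <- num_or_na(cols$mz)
  inv_k0 <- if (is.null(cols$inv_k0)) rep(NA_real_, n_rows) else num_or_na(cols$inv_k0)
  ccs <- if (is.null(cols$ccs)) rep(NA_real_, n_rows) else num_or_na(cols$ccs)
  for (i in seq_len(n_rows)) {
    tokens <- tryCatch(tokenize(cols$sequence[[i]], seq_dialect),
                       pepccs_tokenization_error = function(e) NULL)
    ok <- !is.null(tokens) && !is.na(charge[i]) && charge[i] >= 1L &&
      !is.na(mz[i]) && mz[i] > 0 && (!is.na(inv_k0[i]) || !is.na(ccs[i]))
    if (ok) {
      seq_canon[i] <- detokenize(tokens)
      keep[i] <- TRUE
    }
  }

  records <- data.frame(
    sequence = seq_canon[keep],
    charge = charge[keep],
    mz = mz[keep],
    inv_k0 = inv_k0[keep],
    ccs = ccs[keep],
    intensity = if (is.null(cols$intensity)) NA_real_ else num_or_na(cols$intensity)[keep],
    occurrence = if (is.null(cols$occurrence)) 1L else {
      occ <- suppressWarnings(as.integer(cols$occurrence))
      ifelse(is.na(occ), 1L, occ)[keep]
    },
    source_id = if (is.null(cols$src)) source_id else {
      src <- cols$src
      ifelse(is.na(src) | !nzchar(src), source_id, src)[keep]
    },
    stringsAsFactors = FALSE
  )
  if (!is.null(cols$modality)) {
    records$modality <- cols$modality[keep]
    records$n_modes <- suppressWarnings(as.integer(cols$n_modes))[keep]
  }
  ds <- ion_dataset(records, source_id = source_id)
  attr(ds, "read_report") <- list(n_rows = n_rows, n_kept = sum(keep),
                                  n_skipped = n_rows - sum(keep))
  ds
}

format_real <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))

#' Write an ion dataset as canonical CSV
#'
#' Column order is fixed (sequence, charge, mz, inv_k0, ccs, intensity,
#' occurrence, source_id, plus modality/n_modes for deduplicated data);
#' missing values are empty strings, reals carry six decimals so that
#' [read_search_results()] round-trips the dataset.
#'
#' @param ds An [ion_dataset()].
#' @param path Output file path.
#' @export
write_dataset <- function(ds, path) {
  has_modality <- "modality" %in% names(ds)
  header <- CANONICAL_COLUMNS
  if (has_modality) header <- c(header, "modality", "n_modes")
  lines <- paste(header, collapse = ",")
  if (nrow(ds) > 0L) {
    body <- paste(ds$sequence, ds$charge, format_real(ds$mz),
                  format_real(ds$inv_k0), format_real(ds$ccs),
                  format_real(ds$intensity), ds$occurrence, ds$source_id,
                  sep = ",")
    if (has_modality)
      body <- paste(body, ds$modality, ds$n_modes, sep = ",")
    lines <- c(lines, body)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write dataset to %s", path)
  invisible(path)
}

#' Read a percolator PIN file
#'
#' Tab-separated PSM feature table: a header line (id, label, scan number,
#' feature columns, peptide, proteins), an optional \code{DefaultDirection}
#' line, then one row per PSM. Parsing is line-based so untouched columns
#' survive a read/write round trip byte-identically.
#'
#' @param path Path to the PIN file.
#' @return Object of class \code{pin_table}: list with \code{header}
#'   (character vector), \code{rows} (character matrix) and
#'   \code{default_direction} (character vector or NULL).
#' @export
read_pin <- function(path) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop_format("empty PIN file: %s", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  ncol <- length(header)
  body_start <- 2L
  default_direction <- NULL
  if (length(lines) >= 2L &&
      grepl("^DefaultDirection\t", lines[2L])) {
    default_direction <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
    body_start <- 3L
  }
  rows <- matrix(character(0), nrow = 0L, ncol = ncol)
  if (length(lines) >= body_start) {
    parts <- strsplit(lines[body_start:length(lines)], "\t", fixed = TRUE)
    lens <- lengths(parts)
    if (any(lens != ncol)) {
      bad <- which(lens != ncol)[1L]
      stop_format("ragged PIN row at line %d: %d fields, expected %d",
                  body_start + bad - 1L, lens[bad], ncol)
    }
    rows <- do.call(rbind, parts)
  }
  label_col <- which(tolower(header) == "label")
  if (length(label_col) == 1L && nrow(rows) > 0L &&
      !all(rows[, label_col] %in% c("1", "+1", "-1")))
    stop_format("label column must be +1/-1 in %s", path)
  structure(list(header = header, rows = rows,
                 default_direction = default_direction),
            class = "pin_table")
}

#' @export
print.pin_table <- function(x, ...) {
  cat(sprintf("<pin_table: %d rows x %d columns>\n", nrow(x$rows),
              length(x$header)))
  cat("columns:", paste(x$header, collapse = ", "), "\n")
  invisible(x)
}

#' Write a percolator PIN file
#'
#' Inverse of [read_pin()]; \code{write_pin(read_pin(f), g)} reproduces
#' \code{f} byte-identically.
#'
#' @param pin A \code{pin_table}.
#' @param path Output file path.
#' @export
write_pin <- function(pin, path) {
  lines <- paste(pin$header, collapse = "\t")
  if (!is.null(pin$default_direction))
    lines <- c(lines, paste(pin$default_direction, collapse = "\t"))
  if (nrow(pin$rows) > 0L)
    lines <- c(lines, apply(pin$rows, 1L, paste, collapse = "\t"))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write PIN to %s", path)
  invisible(path)
}
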