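# Mobility-to-CCS conversion, deduplication of (sequence, charge) features
# with multimodality detection, and linear CCS alignment between datasets.

# Physical constants (SI / CODATA 2018).
ELEMENTARY_CHARGE <- 1.602176634e-19   # C
BOLTZMANN         <- 1.380649e-23      # J/K
LOSCHMIDT         <- 2.6867811e25      # m^-3, gas number density at STP
ATOMIC_MASS_KG    <- 1.66053906660e-27 # kg per Da

#' Mason-Schamp conversion constants
#'
#' Drift gas mass, temperature and the fixed physical constants entering the
#' reduced-mobility to CCS conversion. Defaults follow the timsTOF
#' convention: nitrogen drift gas (28.013 Da) at 305 K.
#'
#' @param gas_mass Drift gas molecular mass in Da.
#' @param temperature Drift gas temperature in Kelvin.
#' @param gas Gas label, metadata only.
#' @return Object of class \code{mobility_constants}.
#' @export
mobility_constants <- function(gas_mass = 28.013, temperature = 305,
                               gas = "N2") {
  if (gas_mass <= 0 || temperature <= 0)
    stop_domain("gas_mass and temperature must be positive")
  structure(list(gas_mass = gas_mass, temperature = temperature, gas = gas),
            class = "mobility_constants")
}

mason_schamp_factor <- function(charge, ion_mass, consts) {
  mu <- ion_mass * consts$gas_mass / (ion_mass + consts$gas_mass) *
    ATOMIC_MASS_KG
  # (3/16) z e / N0 * sqrt(2 pi / (mu kB T)); inv_k0 in Vs/cm^2 -> x1e4 in SI;
  # m^2 -> Angstrom^2 is x1e20.
  (3 / 16) * charge * ELEMENTARY_CHARGE / LOSCHMIDT *
    sqrt(2 * pi / (mu * BOLTZMANN * consts$temperature)) * 1e4 * 1e20
}

#' Convert inverse reduced mobility to collisional cross-section
#'
#' Mason-Schamp relation: CCS is proportional to charge times 1/K0, scaled
#' by the inverse square root of the reduced mass of the ion/drift-gas pair
#' and the gas temperature.
#'
#' @param inv_k0 Inverse reduced mobility, Vs/cm^2.
#' @param charge Integer charge state.
#' @param ion_mass Ion (neutral peptide + protons) mass in Da.
#' @param consts A [mobility_constants()] object.
#' @return CCS in Angstrom^2.
#' @seealso [ccs_to_k0()] for the inverse.
#' @export
#' @examples
#' k0_to_ccs(1.1, charge = 2, ion_mass = 1500)
k0_to_ccs <- function(inv_k0, charge, ion_mass, consts = mobility_constants()) {
  if (any(inv_k0 <= 0) || any(charge < 1) || any(ion_mass <= 0))
    stop_domain("inv_k0, charge and ion_mass must be positive")
  mason_schamp_factor(charge, ion_mass, consts) * inv_k0
}

#' Convert collisional cross-section to inverse reduced mobility
#'
#' @inheritParams k0_to_ccs
#' @param ccs CCS in Angstrom^2.
#' @return Inverse reduced mobility in Vs/cm^2.
#' @export
ccs_to_k0 <- function(ccs, charge, ion_mass, consts = mobility_constants()) {
  if (any(ccs <= 0) || any(charge < 1) || any(ion_mass <= 0))
    stop_domain("ccs, charge and ion_mass must be positive")
  ccs / mason_schamp_factor(charge, ion_mass, consts)
}

#' Aggregate the CCS observations of one (sequence, charge) feature
#'
#' Implements the two-sigma fusion rule. Exact-CCS duplicates are merged
#' first (occurrences summed). The main feature is the instance with the
#' highest occurrence (ties broken toward the lower CCS). sigma is the
#' occurrence-weighted population standard deviation of all CCS instances in
#' the group; instances within two sigma of the main feature are fused into
#' it by occurrence-weighted mean, the remainder are secondary conformers:
#' they are dropped from the returned value but counted in \code{n_modes}
#' and \code{dropped_occurrence}.
#'
#' @param ccs Numeric vector of observed CCS values (Angstrom^2).
#' @param occurrence Integer vector of occurrence counts, recycled to
#'   \code{length(ccs)}.
#' @return List with \code{ccs} (fused main-feature value),
#'   \code{occurrence} (fused count), \code{modality}
#'   (\code{"unimodal"}/\code{"multimodal"}), \code{n_modes} and
#'   \code{dropped_occurrence}.
#' @export
#' @examples
#' aggregate_group(c(500, 501, 530), c(4, 4, 2))
aggregate_group <- function(ccs, occurrence = rep(1L, length(ccs))) {
  if (length(ccs) == 0L) stop_domain("empty group")
  occurrence <- rep_len(as.numeric(occurrence), length(ccs))
  if (any(ccs <= 0) || any(occurrence < 1))
    stop_domain("ccs must be positive and occurrences >= 1")

  # merge identical CCS instances
  agg <- rowsum(occurrence, group = ccs)
  vals <- as.numeric(rownames(agg))
  occ <- as.numeric(agg[, 1L])

  main <- which(occ == max(occ))
  main <- main[which.min(vals[main])]   # tie -> lower CCS

  total <- sum(occ)
  mu <- sum(occ * vals) / total
  sigma <- sqrt(sum(occ * (vals - mu)^2) / total)

  fuse <- abs(vals - vals[main]) <= 2 * sigma
  fused_ccs <- sum(occ[fuse] * vals[fuse]) / sum(occ[fuse])
  n_modes <- 1L + sum(!fuse)
  list(ccs = fused_ccs,
       occurrence = as.integer(sum(occ[fuse])),
       modality = if (n_modes >= 2L) "multimodal" else "unimodal",
       n_modes = n_modes,
       dropped_occurrence = as.integer(sum(occ[!fuse])))
}

#' Deduplicate a dataset into aggregated (sequence, charge) features
#'
#' Applies [aggregate_group()] per (sequence, charge) group. Only the main
#' conformer of multimodal features is kept; the occurrence mass of dropped
#' secondary modes is reported so that fused plus dropped occurrences equal
#' the input total.
#'
#' @param ds An [ion_dataset()] whose records all carry a CCS value.
#' @return An [ion_dataset()] of aggregated features (one row per
#'   (sequence, charge), extra columns \code{modality}, \code{n_modes});
#'   attribute \code{dedup_report} holds group counts, the multimodal
#'   fraction and the occurrence bookkeeping.
#' @export
deduplicate <- function(ds) {
  if (nrow(ds) == 0L) {
    out <- ds
    attr(out, "dedup_report") <- list(n_groups = 0L, multimodal_fraction = NA_real_,
                                      input_occurrence = 0L,
                                      fused_occurrence = 0L,
                                      dropped_occurrence = 0L)
    return(out)
  }
  if (anyNA(ds$ccs)) stop_domain("all records must carry a CCS value")
  key <- paste(ds$sequence, ds$charge, sep = "\r")
  groups <- split(seq_len(nrow(ds)), key)
  rows <- lapply(groups, function(idx) {
    g <- aggregate_group(ds$ccs[idx], ds$occurrence[idx])
    data.frame(sequence = ds$sequence[idx[1L]],
               charge = ds$charge[idx[1L]],
               mz = sum(ds$mz[idx] * ds$occurrence[idx]) / sum(ds$occurrence[idx]),
               inv_k0 = NA_real_,
               ccs = g$ccs,
               intensity = NA_real_,
               occurrence = g$occurrence,
               source_id = ds$source_id[idx[1L]],
               modality = g$modality,
               n_modes = g$n_modes,
               dropped = g$dropped_occurrence,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  dropped <- sum(res$dropped)
  res$dropped <- NULL
  meta <- dataset_meta(ds)
  out <- ion_dataset(res, source_id = meta$source_id, gas = meta$gas,
                     temperature = meta$temperature,
                     shift_applied = meta$shift_applied)
  attr(out, "dedup_report") <- list(
    n_groups = nrow(res),
    multimodal_fraction = mean(res$modality == "multimodal"),
    input_occurrence = sum(ds$occurrence),
    fused_occurrence = sum(res$occurrence),
    dropped_occurrence = as.integer(dropped))
  out
}

#' Align a dataset to a reference by a linear CCS shift
#'
#' Matches (sequence, charge) pairs present in both datasets and computes
#' the mean difference of reference minus target CCS (per-pair mean CCS if a
#' pair has several records). The shift is added to every target CCS so the
#' matched-pair means agree.
#'
#' @param target Dataset to be shifted.
#' @param reference Reference dataset.
#' @param weighted If TRUE, the per-pair differences are weighted by the
#'   target occurrence counts.
#' @return List with \code{shift} (reference_id, target_id, shift,
#'   n_matched) and \code{dataset}, the shifted target.
#' @export
align_datasets <- function(target, reference, weighted = FALSE) {
  key_t <- paste(target$sequence, target$charge, sep = "\r")
  key_r <- paste(reference$sequence, reference$charge, sep = "\r")
  common <- intersect(unique(key_t), unique(key_r))
  if (length(common) == 0L)
    stop_alignment("no (sequence, charge) pairs shared between datasets")
  mean_by <- function(x, k, keys) {
    s <- rowsum(x, k)[keys, 1L]
    n <- rowsum(rep(1, length(k)), k)[keys, 1L]
    s / n
  }
  t_mean <- mean_by(target$ccs, key_t, common)
  r_mean <- mean_by(reference$ccs, key_r, common)
  w <- if (weighted) rowsum(as.numeric(target$occurrence), key_t)[common, 1L]
       else rep(1, length(common))
  shift <- sum(w * (r_mean - t_mean)) / sum(w)

  shifted <- target
  shifted$ccs <- shifted$ccs + shift
  meta <- dataset_meta(target)
  attr(shifted, "meta")$shift_applied <- meta$shift_applied + shift
  list(shift = list(reference_id = dataset_meta(reference)$source_id,
                    target_id = meta$source_id,
                    shift = shift,
                    n_matched = length(common)),
       dataset = shifted)
}

#' Write an alignment report as JSON
#'
#' @param shift The \code{shift} element returned by [align_datasets()].
#' @param path Output path.
#' @export
write_alignment_report <- function(shift, path) {
  jsonlite::write_json(shift, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
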