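# Seedable synthetic ion generator: CCS follows a per-charge square-root
# law in m/z plus an additive token-effect residual and Gaussian noise,
# with optional injected bimodal (multi-conformer) features.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default additive residual effects per sequence token
#'
#' Residue effects are proportional to Kyte-Doolittle hydropathy (scaled by
#' 1.5 Angstrom^2 per unit), so hydrophobic residues extend and hydrophilic
#' residues compact the ion relative to the square-root baseline.
#' Phosphorylated tokens sit 35 Angstrom^2 below their base residue: large
#' enough that the CCS decrease outweighs the baseline increase caused by
#' the +80 Da mass shift, reproducing the compaction direction seen in
#' measured phosphopeptides. Oxidation, cysteinylation and N-terminal
#' acetylation carry smaller offsets.
#'
#' @return Named numeric vector of per-token residual effects (Angstrom^2).
#' @export
default_token_effects <- function() {
  kd <- descriptor_table()$hydropathy
  eff <- 1.5 * kd[AMINO_ACIDS]
  names(eff) <- AMINO_ACIDS
  eff["S-ph"] <- eff[["S"]] - 35
  eff["T-ph"] <- eff[["T"]] - 35
  eff["Y-ph"] <- eff[["Y"]] - 35
  eff["M-ox"] <- eff[["M"]] - 4
  eff["C-cam"] <- eff[["C"]] + 1
  eff["C-cys"] <- eff[["C"]] - 2
  eff["<START-ac>"] <- -5
  eff
}

#' Ground-truth parameters for the synthetic ion generator
#'
#' @param w,b Per-charge slope (Angstrom^2 / sqrt(Th)) and intercept
#'   (Angstrom^2) of the square-root CCS law, indexed by charge 1..4.
#' @param effects Named per-token residual effects (see
#'   [default_token_effects()]); NULL for a purely square-root law.
#' @param noise_sd Gaussian CCS noise, Angstrom^2.
#' @param length_range Peptide length range (residues), inclusive.
#' @param charge_probs Sampling probabilities for charges 1..4.
#' @param phospho_prob Probability that a peptide with an S/T/Y site carries
#'   one phosphorylation.
#' @param acetyl_prob Probability of N-terminal acetylation.
#' @param ox_prob Per-methionine oxidation probability.
#' @param cam_prob,cys_prob Per-cysteine carbamidomethylation /
#'   cysteinylation probabilities.
#' @param seed Integer seed; the same truth generates the same data.
#' @return Object of class \code{synthetic_truth}.
#' @export
synthetic_truth <- function(w = c(15, 18, 21, 24),
                            b = c(120, 60, 40, 30),
                            effects = default_token_effects(),
                            noise_sd = 2,
                            length_range = c(7L, 16L),
                            charge_probs = c(0.10, 0.55, 0.28, 0.07),
                            phospho_prob = 0.2,
                            acetyl_prob = 0.05,
                            ox_prob = 0.2,
                            cam_prob = 0.9,
                            cys_prob = 0.02,
                            seed = 1L) {
  stopifnot(length(w) == 4L, length(b) == 4L, noise_sd >= 0,
            length(charge_probs) == 4L, all(charge_probs >= 0))
  structure(list(w = w, b = b, effects = effects, noise_sd = noise_sd,
                 length_range = as.integer(length_range),
                 charge_probs = charge_probs / sum(charge_probs),
                 phospho_prob = phospho_prob, acetyl_prob = acetyl_prob,
                 ox_prob = ox_prob, cam_prob = cam_prob, cys_prob = cys_prob,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

sample_tokens <- function(truth) {
  len <- sample(truth$length_range[1L]:truth$length_range[2L], 1L)
  res <- sample(AMINO_ACIDS, len, replace = TRUE)
  for (i in seq_along(res)) {
    if (res[i] == "C") {
      u <- runif(1)
      if (u < truth$cam_prob) res[i] <- "C-cam"
      else if (u < truth$cam_prob + truth$cys_prob) res[i] <- "C-cys"
    } else if (res[i] == "M" && runif(1) < truth$ox_prob) {
      res[i] <- "M-ox"
    }
  }
  if (runif(1) < truth$phospho_prob) {
    sites <- which(res %in% c("S", "T", "Y"))
    if (length(sites)) {
      k <- if (length(sites) == 1L) sites else sample(sites, 1L)
      res[k] <- paste0(res[k], "-ph")
    }
  }
  start <- if (runif(1) < truth$acetyl_prob) START_AC_TOKEN else START_TOKEN
  c(start, res, END_TOKEN)
}

token_effect_sum <- function(tokens, effects) {
  if (is.null(effects)) return(0)
  keys <- c(residue_tokens(tokens),
            if (tokens[1L] == START_AC_TOKEN) START_AC_TOKEN)
  vals <- effects[keys]
  sum(vals[!is.na(vals)])
}

#' Generate a synthetic ion dataset with known structure
#'
#' Draws peptide sequences (with PTMs from the closed vocabulary), charges
#' and occurrence counts; computes m/z from the monoisotopic mass; and sets
#' \code{ccs = w_c sqrt(mz) + b_c + sum(token effects) + N(0, noise_sd)}.
#' Occurrences are drawn as 2 + Poisson(2), emulating features seen across
#' replicate runs. The per-ion ground-truth decomposition is returned next
#' to the dataset.
#'
#' @param truth A [synthetic_truth()].
#' @param n Number of ions.
#' @return List with \code{dataset} (an [ion_dataset()]) and \code{truth}
#'   (data frame with per-ion baseline, residual effect and noise).
#' @export
generate_ions <- function(truth, n) {
  stopifnot(inherits(truth, "synthetic_truth"), n >= 1L)
  with_seed(truth$seed, {
    charge <- sample(1:4, n, replace = TRUE, prob = truth$charge_probs)
    seqs <- character(n)
    mz <- numeric(n)
    effect <- numeric(n)
    for (i in seq_len(n)) {
      tokens <- sample_tokens(truth)
      seqs[i] <- detokenize(tokens)
      mz[i] <- peptide_mz(monoisotopic_mass(tokens), charge[i])
      effect[i] <- token_effect_sum(tokens, truth$effects)
    }
    baseline <- truth$w[charge] * sqrt(mz) + truth$b[charge]
    noise <- rnorm(n, 0, truth$noise_sd)
    ccs <- baseline + effect + noise
    occurrence <- 2L + rpois(n, 2)
    ds <- ion_dataset(
      data.frame(sequence = seqs, charge = charge, mz = mz,
                 inv_k0 = NA_real_, ccs = ccs, intensity = NA_real_,
                 occurrence = occurrence, source_id = "synthetic",
                 stringsAsFactors = FALSE),
      source_id = "synthetic")
    list(dataset = ds,
         truth = data.frame(sequence = seqs, charge = charge, mz = mz,
                            baseline = baseline, residual = effect,
                            noise = noise, ccs = ccs,
                            stringsAsFactors = FALSE))
  })
}

#' Inject bimodal (multi-conformer) features into a dataset
#'
#' A random subset of (sequence, charge) keys gains a second conformer at
#' \code{ccs + separation} whose occurrence is a fraction of (and strictly
#' below) the main mode's. The selected keys are returned as ground truth
#' so mode-recovery can be scored.
#'
#' @param ds An [ion_dataset()].
#' @param fraction Fraction of keys to make bimodal.
#' @param separation Mode separation in Angstrom^2 (> 0).
#' @param seed Integer seed.
#' @param occ_ratio Secondary/main occurrence ratio (default 0.3).
#' @return List with \code{dataset} and \code{injected} (data frame of
#'   sequence, charge).
#' @export
inject_multimodality <- function(ds, fraction, separation, seed = 1L,
                                 occ_ratio = 0.3) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction > 0 && separation <= 0) stop_domain("separation must be > 0")
  if (fraction == 0)
    return(list(dataset = ds,
                injected = data.frame(sequence = character(0),
                                      charge = integer(0))))
  with_seed(seed, {
    eligible <- which(ds$occurrence >= 2L)
    n_pick <- round(fraction * nrow(ds))
    pick <- sort(sample(eligible, min(n_pick, length(eligible))))
    extra <- as.data.frame(ds[pick, , drop = FALSE])
    extra$ccs <- extra$ccs + separation
    extra$occurrence <- pmax(1L, pmin(extra$occurrence - 1L,
                                      as.integer(round(occ_ratio * extra$occurrence))))
    meta <- dataset_meta(ds)
    out <- ion_dataset(rbind(as.data.frame(ds), extra),
                       source_id = meta$source_id, gas = meta$gas,
                       temperature = meta$temperature,
                       shift_applied = meta$shift_applied)
    list(dataset = out,
         injected = data.frame(sequence = ds$sequence[pick],
                               charge = ds$charge[pick],
                               stringsAsFactors = FALSE))
  })
}

render_maxquant <- function(compact) {
  tokens <- tokenize(compact)
  inner <- residue_tokens(tokens)
  body <- vapply(inner, function(tk) {
    mod <- mod_of_token(tk)
    if (nzchar(mod)) paste0(base_residue(tk), "(", mod, ")") else tk
  }, character(1))
  prefix <- if (tokens[1L] == START_AC_TOKEN) "(ac)" else ""
  paste0("_", prefix, paste(body, collapse = ""), "_")
}

render_peaks <- function(compact) {
  tokens <- tokenize(compact)
  inner <- residue_tokens(tokens)
  body <- vapply(inner, function(tk) {
    mod <- mod_of_token(tk)
    if (nzchar(mod))
      paste0(base_residue(tk), sprintf("(%+.2f)", MOD_DELTA[[mod]]))
    else tk
  }, character(1))
  if (tokens[1L] == START_AC_TOKEN)
    body[1L] <- paste0(body[1L], sprintf("(%+.2f)", MOD_DELTA[["ac"]]))
  paste(body, collapse = "")
}

#' Write a dataset as a search-engine style identification table
#'
#' Emits either a MaxQuant evidence-style TSV (underscore-flanked modified
#' sequences, short modification codes) or a PEAKS-style CSV (bracketed
#' mass deltas), suitable for [read_search_results()].
#'
#' @param ds An [ion_dataset()].
#' @param path Output path.
#' @param dialect \code{"maxquant"} or \code{"peaks"}.
#' @export
emit_search_table <- function(ds, path, dialect = c("maxquant", "peaks")) {
  dialect <- match.arg(dialect)
  if (dialect == "maxquant") {
    header <- paste(c("Modified sequence", "Charge", "m/z", "CCS", "1/K0",
                      "Intensity"), collapse = "\t")
    body <- if (nrow(ds) == 0L) character(0) else
      paste(vapply(ds$sequence, render_maxquant, character(1)),
            ds$charge, format_real(ds$mz), format_real(ds$ccs),
            format_real(ds$inv_k0), format_real(ds$intensity), sep = "\t")
  } else {
    header <- paste(c("Peptide", "Z", "m/z", "CCS", "1/K0", "Intensity"),
                    collapse = ",")
    body <- if (nrow(ds) == 0L) character(0) else
      paste(vapply(ds$sequence, render_peaks, character(1)),
            ds$charge, format_real(ds$mz), format_real(ds$ccs),
            format_real(ds$inv_k0), format_real(ds$intensity), sep = ",")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
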