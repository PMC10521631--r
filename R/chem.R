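# Peptide chemistry: tokenization of modified sequences, monoisotopic
# masses, m/z, and additive per-residue scalar descriptors.

AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Residue monoisotopic masses (Da), standard IUPAC values.
AA_MONO <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04049, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)

WATER_MONO  <- 18.010565
PROTON_MASS <- 1.007276

# Modification mass deltas (Da).
MOD_DELTA <- c(
  ph  = 79.96633,   # phosphorylation (STY)
  ac  = 42.01057,   # N-terminal acetylation
  cam = 57.02146,   # carbamidomethylation (C)
  ox  = 15.99491,   # oxidation (M)
  cys = 119.00410   # cysteinylation (C)
)

# Which residues each modification may sit on.
MOD_RESIDUES <- list(ph = c("S", "T", "Y"), ox = "M", cam = "C", cys = "C")

PAD_TOKEN      <- "<PAD>"
START_TOKEN    <- "<START>"
START_AC_TOKEN <- "<START-ac>"
END_TOKEN      <- "<END>"

#' Token vocabulary for peptide sequence models
#'
#' The closed vocabulary used by the tokenizer and the GRU residual model:
#' a padding token, the 20 canonical amino acids, the modified residues
#' C-cam, C-cys, M-ox, S-ph, T-ph, Y-ph, and the terminal tokens
#' \code{<START>}, \code{<START-ac>} (N-terminally acetylated peptide) and
#' \code{<END>}. The padding token has index 0.
#'
#' @return An object of class \code{token_vocab}: a list with elements
#'   \code{tokens} (character vector) and \code{index} (named integer vector
#'   mapping token to 0-based index).
#' @export
#' @examples
#' v <- token_vocab()
#' length(v$tokens)
token_vocab <- function() {
  tokens <- c(PAD_TOKEN, AMINO_ACIDS,
              "C-cam", "C-cys", "M-ox", "S-ph", "T-ph", "Y-ph",
              START_TOKEN, START_AC_TOKEN, END_TOKEN)
  stopifnot(!anyDuplicated(tokens), length(tokens) <= 64)
  structure(
    list(tokens = tokens,
         index = setNames(seq_along(tokens) - 1L, tokens)),
    class = "token_vocab"
  )
}

#' @export
print.token_vocab <- function(x, ...) {
  cat(sprintf("<token_vocab: %d tokens>\n", length(x$tokens)))
  cat(paste(x$tokens, collapse = " "), "\n")
  invisible(x)
}

residue_tokens <- function(tokens) {
  tokens[!tokens %in% c(PAD_TOKEN, START_TOKEN, START_AC_TOKEN, END_TOKEN)]
}

base_residue <- function(token) substr(token, 1L, 1L)

mod_of_token <- function(token) {
  ifelse(grepl("-", token, fixed = TRUE), sub("^[A-Z]-", "", token), "")
}

# --- dialect parsers ---------------------------------------------------------

# Canonical compact form: optional "(ac)" prefix, residues with optional
# "(ph)"/"(ox)"/"(cam)"/"(cys)" suffixes, e.g. "(ac)M(ox)AAS(ph)K".
parse_compact <- function(raw) {
  tokens <- character(0)
  i <- 1L
  n <- nchar(raw)
  start <- START_TOKEN
  if (startsWith(raw, "(ac)")) {
    start <- START_AC_TOKEN
    i <- 5L
  }
  while (i <= n) {
    ch <- substr(raw, i, i)
    if (!ch %in% AMINO_ACIDS)
      stop_token("unknown residue '%s' at position %d in \"%s\"", ch, i, raw)
    i <- i + 1L
    if (i <= n && substr(raw, i, i) == "(") {
      close <- regexpr(")", substr(raw, i, n), fixed = TRUE)
      if (close < 0L)
        stop_token("unbalanced '(' at position %d in \"%s\"", i, raw)
      mod <- substr(raw, i + 1L, i + close - 2L)
      i <- i + close
      tokens <- c(tokens, mod_token(ch, mod, raw))
    } else {
      tokens <- c(tokens, ch)
    }
  }
  if (length(tokens) == 0L) stop_token("no residues in \"%s\"", raw)
  c(start, tokens, END_TOKEN)
}

# Map a modification spec (short code or long MaxQuant-style name) on a
# residue to a vocabulary token.
mod_token <- function(residue, mod, raw) {
  key <- normalize_mod(mod)
  if (is.na(key))
    stop_token("unknown modification \"(%s)\" in \"%s\"", mod, raw)
  if (key == "ac")
    stop_token("acetylation must be N-terminal in \"%s\"", raw)
  allowed <- MOD_RESIDUES[[key]]
  if (!residue %in% allowed)
    stop_token("modification \"%s\" not allowed on residue '%s' in \"%s\"",
               key, residue, raw)
  paste0(residue, "-", key)
}

normalize_mod <- function(mod) {
  m <- tolower(trimws(mod))
  if (m %in% c("ac") || startsWith(m, "acetyl")) return("ac")
  if (m %in% c("ox") || startsWith(m, "oxidation")) return("ox")
  if (m %in% c("ph") || startsWith(m, "phospho")) return("ph")
  if (m %in% c("ca", "cam") || startsWith(m, "carbamidomethyl")) return("cam")
  if (m %in% c("cys") || startsWith(m, "cysteinyl")) return("cys")
  NA_character_
}

# MaxQuant "Modified sequence": underscores flank the sequence, modifications
# in (possibly nested) parentheses, N-terminal mods before the first residue.
parse_maxquant <- function(raw) {
  s <- gsub("^_|_$", "", raw)
  i <- 1L
  n <- nchar(s)
  start <- START_TOKEN
  tokens <- character(0)
  grab_paren <- function(from) {
    depth <- 0L
    for (j in from:n) {
      cj <- substr(s, j, j)
      if (cj == "(") depth <- depth + 1L
      if (cj == ")") {
        depth <- depth - 1L
        if (depth == 0L) return(j)
      }
    }
    stop_token("unbalanced '(' at position %d in \"%s\"", from, raw)
  }
  if (substr(s, 1L, 1L) == "(") {
    end <- grab_paren(1L)
    mod <- substr(s, 2L, end - 1L)
    key <- normalize_mod(mod)
    if (is.na(key) || key != "ac")
      stop_token("unknown N-terminal modification \"(%s)\" in \"%s\"", mod, raw)
    start <- START_AC_TOKEN
    i <- end + 1L
  }
  while (i <= n) {
    ch <- substr(s, i, i)
    if (!ch %in% AMINO_ACIDS)
      stop_token("unknown residue '%s' at position %d in \"%s\"", ch, i, raw)
    i <- i + 1L
    if (i <= n && substr(s, i, i) == "(") {
      end <- grab_paren(i)
      mod <- substr(s, i + 1L, end - 1L)
      i <- end + 1L
      tokens <- c(tokens, mod_token(ch, mod, raw))
    } else {
      tokens <- c(tokens, ch)
    }
  }
  if (length(tokens) == 0L) stop_token("no residues in \"%s\"", raw)
  c(start, tokens, END_TOKEN)
}

# PEAKS-style: bracketed mass deltas after residues, e.g. "AAS(+79.97)K".
# Deltas are matched to known modifications within 0.02 Da.
parse_peaks <- function(raw) {
  i <- 1L
  n <- nchar(raw)
  start <- START_TOKEN
  tokens <- character(0)
  first <- TRUE
  while (i <= n) {
    ch <- substr(raw, i, i)
    if (!ch %in% AMINO_ACIDS)
      stop_token("unknown residue '%s' at position %d in \"%s\"", ch, i, raw)
    i <- i + 1L
    toks_here <- ch
    while (i <= n && substr(raw, i, i) == "(") {
      close <- regexpr(")", substr(raw, i, n), fixed = TRUE)
      if (close < 0L)
        stop_token("unbalanced '(' at position %d in \"%s\"", i, raw)
      spec <- substr(raw, i + 1L, i + close - 2L)
      i <- i + close
      delta <- suppressWarnings(as.numeric(spec))
      if (is.na(delta))
        stop_token("unparseable mass delta \"(%s)\" in \"%s\"", spec, raw)
      d <- abs(MOD_DELTA - delta)
      key <- names(MOD_DELTA)[which.min(d)]
      if (min(d) > 0.02)
        stop_token("no known modification within 0.02 Da of %+.5f in \"%s\"",
                   delta, raw)
      if (key == "ac") {
        if (!first)
          stop_token("acetylation delta on interior residue in \"%s\"", raw)
        start <- START_AC_TOKEN
      } else {
        toks_here <- mod_token(ch, key, raw)
      }
    }
    tokens <- c(tokens, toks_here)
    first <- FALSE
  }
  if (length(tokens) == 0L) stop_token("no residues in \"%s\"", raw)
  c(start, tokens, END_TOKEN)
}

#' Tokenize a modified peptide sequence
#'
#' Converts a peptide sequence in a source dialect into the canonical token
#' vector: a start token (\code{<START>} or \code{<START-ac>} for
#' N-terminally acetylated peptides), one token per residue (modified
#' residues as e.g. \code{S-ph}), and \code{<END>}.
#'
#' @param raw Character scalar, the sequence in the source dialect.
#' @param dialect One of \code{"canonical"} (compact form such as
#'   \code{"(ac)M(ox)AAK"}), \code{"maxquant"} (underscore-flanked MaxQuant
#'   modified sequence), or \code{"peaks"} (bracketed mass deltas such as
#'   \code{"AAS(+79.97)K"}).
#' @return Character vector of tokens, all members of [token_vocab()].
#' @seealso [detokenize()], [token_vocab()]
#' @export
#' @examples
#' tokenize("PEPS(ph)IDE")
#' tokenize("_(ac)M(ox)AAK_", dialect = "maxquant")
tokenize <- function(raw, dialect = c("canonical", "maxquant", "peaks")) {
  dialect <- match.arg(dialect)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw))
    stop_token("sequence must be a non-empty character scalar")
  switch(dialect,
         canonical = parse_compact(raw),
         maxquant = parse_maxquant(raw),
         peaks = parse_peaks(raw))
}

#' Convert a token vector back to the canonical compact sequence
#'
#' Inverse of [tokenize()] for the canonical dialect:
#' \code{detokenize(tokenize(x)) == x} for any canonical compact string.
#'
#' @param tokens Character vector of tokens as produced by [tokenize()].
#' @return Character scalar in canonical compact form.
#' @export
#' @examples
#' detokenize(c("<START-ac>", "M-ox", "A", "K", "<END>"))
detokenize <- function(tokens) {
  if (length(tokens) < 3L)
    stop_token("token vector must contain start, residues and end")
  if (!tokens[1L] %in% c(START_TOKEN, START_AC_TOKEN))
    stop_token("token vector must begin with a start token")
  if (tokens[length(tokens)] != END_TOKEN)
    stop_token("token vector must end with <END>")
  inner <- tokens[-c(1L, length(tokens))]
  vocab <- token_vocab()
  bad <- setdiff(inner, vocab$tokens)
  if (length(bad))
    stop_token("unknown token(s): %s", paste(bad, collapse = ", "))
  body <- vapply(inner, function(tk) {
    mod <- mod_of_token(tk)
    if (nzchar(mod)) paste0(base_residue(tk), "(", mod, ")") else tk
  }, character(1))
  prefix <- if (tokens[1L] == START_AC_TOKEN) "(ac)" else ""
  paste0(prefix, paste(body, collapse = ""))
}

as_token_vector <- function(x, dialect = "canonical") {
  if (length(x) == 1L && !x %in% token_vocab()$tokens) tokenize(x, dialect)
  else x
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water, plus modification mass
#' deltas (phospho +79.96633, acetyl +42.01057, carbamidomethyl +57.02146,
#' oxidation +15.99491, cysteinylation +119.00410 Da).
#'
#' @param x Either a token vector from [tokenize()] or a canonical compact
#'   sequence string.
#' @return Monoisotopic mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("G")       # glycine peptide, 75.03203 Da
#' monoisotopic_mass("PEPTIDE")
monoisotopic_mass <- function(x) {
  tokens <- as_token_vector(x)
  res <- residue_tokens(tokens)
  mass <- WATER_MONO + sum(AA_MONO[vapply(res, base_residue, character(1))])
  mods <- mod_of_token(res)
  mods <- mods[nzchar(mods)]
  if (length(mods)) mass <- mass + sum(MOD_DELTA[mods])
  if (tokens[1L] == START_AC_TOKEN) mass <- mass + MOD_DELTA[["ac"]]
  unname(mass)
}

#' Mass-to-charge ratio of a peptide ion
#'
#' @param mass Monoisotopic mass in Da.
#' @param charge Positive integer charge state (number of protons).
#' @return m/z in Thomson: \code{(mass + charge * 1.007276) / charge}.
#' @export
#' @examples
#' peptide_mz(1000, 2)
peptide_mz <- function(mass, charge) {
  if (any(charge < 1L))
    stop_domain("charge must be >= 1, got %s", paste(charge, collapse = ", "))
  (mass + charge * PROTON_MASS) / charge
}

descriptor_cache <- new.env(parent = emptyenv())

#' Per-amino-acid scalar descriptor tables
#'
#' Nine published per-amino-acid scales: volume, polarity, hydropathy
#' (Kyte-Doolittle), hydrophilicity (Hopp-Woods), solvent-exposed area,
#' accessible surface area, accessible surface area in folded proteins,
#' local flexibility and side-chain pK. Values are pinned constants shipped
#' with the package (inst/extdata/aa_descriptors.csv).
#'
#' @return Named list of nine named numeric vectors (one value per amino acid).
#' @export
descriptor_table <- function() {
  if (!is.null(descriptor_cache$table)) return(descriptor_cache$table)
  path <- system.file("extdata", "aa_descriptors.csv", package = "pepccs",
                      mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  tab <- lapply(split(raw, raw$scale), function(d) setNames(d$value, d$amino_acid))
  for (nm in names(tab)) {
    missing <- setdiff(AMINO_ACIDS, names(tab[[nm]]))
    if (length(missing))
      stop_format("descriptor scale '%s' missing amino acids: %s",
                  nm, paste(missing, collapse = ", "))
  }
  descriptor_cache$table <- tab
  tab
}

#' Length-normalized additive scalar descriptors of a peptide
#'
#' For each of the nine scales, sums the per-amino-acid contributions over
#' the residues of the sequence and divides by sequence length. Modified
#' residues contribute the value of their base amino acid; terminal tokens
#' are excluded from the length.
#'
#' @param x Token vector or canonical compact sequence string.
#' @param table Descriptor table, default [descriptor_table()].
#' @return Named numeric vector of length 9.
#' @export
#' @examples
#' \dontrun{scalar_descriptors("PEPTIDE")}
scalar_descriptors <- function(x, table = descriptor_table()) {
  res <- residue_tokens(as_token_vector(x))
  if (length(res) == 0L) stop_domain("sequence has no residues")
  base <- vapply(res, base_residue, character(1))
  vapply(table, function(scale) sum(scale[base]) / length(base), numeric(1))
}
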