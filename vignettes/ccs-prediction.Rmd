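---
title: "Predicting peptide collisional cross-sections: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting peptide collisional cross-sections: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Trapped ion mobility spectrometry (TIMS) coupled to mass spectrometry
separates peptide ions by their mobility through a neutral drift gas. The
measured inverse reduced mobility 1/K0 maps, through the Mason–Schamp
relation, to the collisional cross-section (CCS, in Å²): the effective
area an ion presents to gas collisions, a reproducible property of its
gas-phase conformation. A sequence-based CCS predictor is useful twice
over: to design acquisition schemes, and to supply additional evidence
when rescoring peptide-spectrum matches (PSMs), because a candidate whose
predicted CCS disagrees badly with the measured one is likely wrong.

`pepccs` implements the full path from search-engine identification tables
to trained predictor and rescoring features, with a seedable synthetic
generator standing in for instrument data so every stage is testable.

## The two-stage model

CCS is dominated by ion mass and charge. The predictor therefore splits
into a physics-flavored projection and a learned residual:

$$\mathrm{CCS}_{\mathrm{init}}(m/z, c) = w_c \sqrt{m/z} + b_c$$

$$\mathrm{CCS}_{\mathrm{final}}(m/z, c, s) =
  \mathrm{CCS}_{\mathrm{init}}(m/z, c) + M(s, c, \theta)$$

The per-charge coefficients $(w_c, b_c)$, $c \in \{1,\dots,4\}$, are fit a
priori by linear least squares on the transformed regressor $\sqrt{m/z}$
(the model is linear in its parameters, so the fit is closed-form and
deterministic; `fit_sqrt()`). They are then frozen: the network
$M(s, c, \theta)$ only learns the sequence-specific deviation. This
residual formulation starts training close to the answer, stabilizes
optimization, and makes the learned contribution directly inspectable —
`predict()` returns baseline, residual and sum separately.

The residual network (`build_ccs_model()`) is a token embedding (128
dimensions) feeding two bidirectional GRU layers (128 units per
direction), whose final states are concatenated with a one-hot charge
indicator and passed through dense layers of 128 and 64 units (dropout 0.2
between them) to a scalar. Charges above 4 are outside the modeled range
and are rejected. With the packaged 30-token vocabulary this totals
540,161 trainable weights; each GRU direction contributes
$3(nu + u^2 + 2u)$ weights for input width $n$ and $u$ units (dual-bias
parameterisation), an accounting the test suite checks against the
reported count. The recurrent core is implemented in C++ (RcppArmadillo):
forward pass, backpropagation through time, and Adam are written out
explicitly, which keeps training single-threaded and bit-reproducible for
a given seed. Sequences are processed at their native length, so
predictions are trivially independent of any padding convention. The final
output layer is zero-initialised: an untrained model predicts exactly the
baseline.

Training (`train_ccs_model()`) minimizes the mean absolute error (MAE) of
the residual — identical to the MAE of the final CCS since the baseline is
frozen — with Adam at an initial learning rate of $10^{-3}$. After each
epoch the validation MAE is computed; after three epochs without
improvement the learning rate drops by a factor of ten, and after three
further stale epochs training stops, returning the best-validation
weights. One reading decision: an improvement after the reduction resets
the patience counter but not the schedule phase, so a second three-epoch
plateau always stops training rather than reducing again.

## Preprocessing

**Mobility conversion.** `k0_to_ccs()` applies the Mason–Schamp relation
with explicit physical constants: CCS is proportional to $z \cdot (1/K_0)$
and to $(\mu k_B T)^{-1/2}$ with $\mu$ the reduced mass of the ion /
drift-gas pair. Defaults are nitrogen (28.013 Da) at 305 K, the usual
timsTOF operating point; both are overridable via `mobility_constants()`.
The inverse `ccs_to_k0()` round-trips to better than $10^{-9}$ relative.

**Deduplication and multimodality.** Identified features are (sequence,
charge, CCS) instances with occurrence counts. Some peptides adopt more
than one gas-phase conformation, so a (sequence, charge) group may be
genuinely bimodal; a single fused value would then sit between the modes
and poison training. `aggregate_group()` implements a two-sigma rule: the
instance with the highest occurrence is the main feature (ties break
toward the lower CCS, for determinism), σ is the occurrence-weighted
population standard deviation of all CCS instances in the group, instances
within 2σ of the main feature are fused into it by occurrence-weighted
mean, and anything outside is a secondary conformer — dropped from the
output but counted (`n_modes`, dropped occurrence mass), so occurrence
totals are conserved and the multimodal fraction is reported. Two readings
were open: σ is computed once on the full group (not after excluding
candidates), and exact-CCS duplicates are merged before the rule applies.
A brute-force oracle that expands every instance into its occurrence
copies and applies the rule literally agrees with the implementation on
1,000 random groups in the test suite.

**Alignment.** Instruments and labs differ by a small systematic CCS
offset. `align_datasets()` estimates a single additive shift as the mean
over matched (sequence, charge) pairs of the reference-minus-target CCS
difference, applies it, and reports the pair count. The mean is unweighted
by default (an occurrence-weighted variant sits behind a flag, since it is
not obvious which the convention should be); nonlinear or per-charge
alignment is deliberately out of scope.

## Tokenization and the closed vocabulary

Modified sequences arrive in different dialects: MaxQuant-style
(`_(ac)M(ox)AAK_`, short codes or long names, nested parentheses) and
PEAKS-style bracketed mass deltas (`AAS(+79.97)K`, matched to known
modifications within 0.02 Da). Both map onto one canonical token set: the
20 amino acids, S/T/Y-phospho, C-carbamidomethyl, C-cysteinyl,
M-oxidation, the terminals `<START>` / `<START-ac>` / `<END>`, and a
padding token — 30 tokens in total. The vocabulary is closed because the
embedding table must be stable across training and inference; rows whose
sequence uses anything outside it are skipped and counted at read time
rather than guessed at. N-terminal acetylation is encoded in the start
token rather than on a residue, which keeps residue tokens position-free.

## Scalar descriptors

For interpretation, nine published per-amino-acid scales (volume,
polarity, hydropathy, hydrophilicity, solvent-exposed area, accessible
surface area, accessible surface area folded, local flexibility, side-
chain pK) ship as pinned constants. `scalar_descriptors()` sums each scale
over the residues and divides by sequence length; modified residues
contribute their base amino acid's value, since the scales cover only the
canonical residues. `correlate_residual_descriptors()` then gives the
Pearson correlation of the learned residual against each scale — the
standard way to ask *what* the network learned.

## Rescoring features

For PSM rescoring, `ccs_features()` computes five values per PSM: observed
CCS, predicted CCS, the signed error (observed − predicted), its absolute
value, and the signed percent error relative to the observed value.
`augment_pin()` inserts them into a percolator PIN file immediately before
the peptide column, reading the PSM charge from the `Charge<N>` one-hot
columns. Rows with charge above 4 are removed — the predictor is not
trained for them; removal, rather than zero-filling, is the stricter
reading — and counted, as are rows without a matching prediction. PIN
parsing is line-based so untouched columns survive byte-identically, and a
PIN that already carries the feature columns is refused rather than
augmented twice.

## The synthetic generator

`generate_ions()` draws peptides (length 7–16, uniform residues, PTMs from
the vocabulary: 90% of cysteines carbamidomethylated, 2% cysteinylated,
20% of methionines oxidised, 20% of peptides carrying one phospho site
when S/T/Y is present, 5% N-terminally acetylated), charges with
probabilities (0.10, 0.55, 0.28, 0.07) for 1–4, m/z from the monoisotopic
mass, and sets

$$\mathrm{CCS} = w_c \sqrt{m/z} + b_c + \textstyle\sum_{t \in s}
\mathrm{effect}(t) + \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2).$$

Defaults, chosen once as plausible for tryptic timsTOF data: per-charge
truth $w = (15, 18, 21, 24)$, $b = (120, 60, 40, 30)$; noise σ = 2 Å²
(post-aggregation reproducibility of TIMS CCS is below one percent);
occurrence counts 2 + Poisson(2), emulating features seen across replicate
runs. Residue effects are 1.5× Kyte–Doolittle hydropathy; phospho tokens
sit 35 Å² below their base residue, so the CCS decrease outweighs the
baseline increase caused by the +80 Da mass shift — reproducing the
compaction direction observed for measured phosphopeptides.
`inject_multimodality()` adds a second conformer at a fixed separation to
a random subset of keys, with strictly smaller occurrence, and returns the
selection as ground truth.

The generator makes recovery checks meaningful: the additive effects are
learnable by the GRU and analyzable by the descriptors, baseline
parameters are exactly recoverable, and injected bimodality is detectable
by the two-sigma rule. What it does **not** emulate: realistic intensity
or retention-time structure, homology between sequences, charge-dependent
residual interactions, heteroscedastic noise, or calibration drift within
a run. Passing tests therefore demonstrate that the machinery is correct
and that the model class can recover structure of this additive form —
not that any particular accuracy will be achieved on instrument data.

## Problem sizes and numerical choices

The test suite and the acceptance script use desk-scale sizes chosen to
exercise each property well inside a routine CI budget: 5,000 training
ions with a 1,250-ion validation split and a reduced architecture
(embedding 32, GRU 32/32) for the training checks — about 50k weights and
under a minute of single-core training — 1,000 random groups for the
aggregation oracle, 4,000 ions with 5% injected bimodality for mode
recovery, and the full 128-unit architecture only where parameter
accounting itself is under test. Further numerical choices: means and
standard deviations in the aggregation rule are occurrence-weighted
population statistics; the two-sigma boundary is inclusive; MAPE uses the
median (mean of the central pair for even counts); zero-variance
descriptors yield `NA` correlations rather than an error; canonical CSV
reals carry six decimals, which bounds round-trip error at 5e-7.

## Limitations

The predictor is bounded by its closed vocabulary (new modifications
require a vocabulary release and retraining), models charges 1–4 only,
drops secondary conformers rather than predicting them, and learns a
single additive shift per dataset during alignment. The shipped code
trains from scratch; no pretrained weights are included.
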