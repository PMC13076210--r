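---
title: "Methods: fragment-ion calculus, intensity modelling and rescoring in multifrag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-ion calculus, intensity modelling and rescoring in multifrag}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

multifrag implements a complete desk-scale pipeline for tandem-MS data
acquired with collision- (HCD), electron- (ECD, EID, ETciD) and
photon-based (UVPD) peptide fragmentation: theoretical fragment-ion
mass calculus, spectrum annotation, training-dataset construction, a
recurrent intensity-prediction model conditioned on the fragmentation
method, and target–decoy rescoring statistics. This vignette is the
package's own account of the underlying models, the parameters that
matter, and the choices made where the design was genuinely open.

## Fragment-ion calculus

Peptide and fragment masses are monoisotopic throughout; there is no
average-mass mode. A peptide's neutral mass is the sum of its residue
masses plus one water. Ten backbone ion series are supported. The five
N-terminal series are defined relative to the b series (neutral mass =
prefix residue sum): a = b − CO, a+1 = a + H, c = b + NH₃, c−1 = c − H.
The five C-terminal series are defined relative to the y series
(suffix residues + H₂O): x = y + CO − H₂, x+1 = x + H, z = y − NH₃ + H,
z+1 = z + H. The "+1"/"−1" variants are radical species differing by
one hydrogen atom; a+1 in particular is a radical a ion carrying an
additional hydrogen, a signature of electron- and photon-based
gas-phase chemistry rather than a ¹³C isotope artefact.

The z and z+1 offsets follow the radical "z-dot" convention that
dominates the ECD literature. Because hydrogen accounting for the
radical series varies between communities, both offsets are plain
arguments of `ion_series_table()` — they are conventions exposed as
configuration, not fixed facts.

Two invariants anchor the whole module and are enforced by tests: for
every cleavage site, the neutral b and y fragments sum exactly to the
peptide's neutral mass (≤ 1 nDa drift), and every series offset
identity above holds for random peptides of every length.

## Spectrum annotation

Annotation matches observed peaks against the theoretical ions of the
assigned peptide (fragment lengths 1–29, fragment charges 1–3, the
method's ion-series set) within a relative tolerance of 10 ppm, with
the ppm sign convention (observed − theoretical)/theoretical × 10⁶.
Three steps run in a fixed order for determinism:

1. peaks inside a 2.4 Da full-width window centred on the precursor
   m/z are excluded;
2. peaks matching any of the first four precursor isotope positions —
   at the precursor charge and at charge + 1 — are flagged and
   excluded, so isotopologues of the intact ion cannot be mistaken for
   fragments;
3. remaining peaks are matched to theoretical ions, and many-to-many
   candidates are resolved greedily by ascending |ppm|, with ties
   broken by a fixed series priority (y, b, c, z, a, x, z+1, a+1,
   c−1, x+1), then lower fragment charge, then lower ordinal.

Each theoretical ion annotates at most one peak and vice versa. When
several peaks fall within tolerance of one ion the nearest-ppm peak
wins by default; a config switch (`peak_rule = "intense"`) selects the
most intense peak instead. The near-coincidence of a+1 ions with the
¹³C peak of the corresponding a ion (Δ ≈ 0.0045 Da) is resolved by the
same nearest-ppm rule — fragment isotope envelopes are not modelled,
which is a documented approximation of this implementation.

Per-method default series sets are ECD {c−1, c, z, z+1, y, b},
HCD {a, a+1, b, y}, ETciD {b, c, y, z, z+1} and all ten series for EID
and UVPD; all are overridable through `annotation_params()`.

The module's correctness contract is oracle equivalence: a quadratic
brute-force matcher implementing the same rules, written independently
in the test suite, must produce byte-identical assignments on
simulated spectra with noise.

## Training datasets

Annotated PSMs become model-ready records in five steps, each with a
deliberately boring, testable contract:

- **Cleaning** removes decoys and PSMs with no assignments.
- **Deduplication** keeps one record per (modified sequence, charge,
  method), the instance with the highest search-engine hyperscore;
  ties break lexicographically by (raw file, scan) for determinism.
- **Ion dictionary**: the model's unstructured output space is the
  list of ion labels occurring ≥ 100 times in the corpus ("100 or
  more" is inclusive), in canonical (series priority, ordinal, charge)
  order. At the full scale of the original study this dictionary has
  815 entries; at desk scale it is rebuilt from whatever corpus is at
  hand.
- **Vectorization**: each record's target vector has one entry per
  dictionary ion. Ions that cannot occur — ordinal at or beyond the
  peptide length, or fragment charge above the precursor charge — are
  set to −1 and masked out of training. All other unannotated ions are
  0, and non-negative entries are max-scaled by the most intense ion
  so targets lie in {−1} ∪ [0, 1]. The masked count has a closed form
  in (length, charge, dictionary), which the tests check record by
  record. An all-zero spectrum stays all zero: max-scaling is applied
  exactly to the non-negative entries, and the degenerate case is left
  untouched rather than renormalised.
- **Splitting**: records are shuffled under a seed and split
  0.8/0.1/0.1 into train/validation/test; validation and test sizes
  are floor allocations with the remainder going to train, so 1,000
  records give exactly 800/100/100. The split is record-level to
  mirror the upstream study design; peptide-grouped splitting can be
  emulated by deduplicating before splitting, since after
  deduplication each (sequence, charge, method) key occurs once.
  Datasets are written as Parquet (train sharded into 8–12
  similar-size files for parallel loading) with columns sufficient to
  map any example back to its raw spectrum, plus a JSON sidecar
  carrying the dictionary and split provenance.

## The intensity model

The model maps (peptide, precursor charge, fragmentation method) to an
intensity vector over the ion dictionary. Architecture:

- residue tokens (20 amino acids plus `C(cam)` and `M(ox)` tokens and
  padding) are embedded and encoded by a bidirectional GRU; the
  per-position latent size is twice the encoder hidden size;
- charge (one-hot over 1–6, clamped above with a warning) and method
  (one-hot over the five techniques) are concatenated and linearly
  projected to the per-position latent size — 256 units at full scale,
  where the encoder contributes 128 units per direction. Collision
  energy is deliberately not an input;
- the metadata vector is combined with every sequence position by
  elementwise multiplication (the projection size equality is forced
  by this fusion), preserving the full 30-position sequence dimension;
- a bidirectional GRU decoder, a linear map to the dictionary, a
  LeakyReLU (negative slope 0.01) and mean pooling over the 30
  positions produce the final vector.

The loss is the masked spectral distance: drop the −1 entries,
L2-normalise both sub-vectors, and take (2/π)·arccos of their dot
product. The cosine is clamped to [0, 1] before the arccosine so the
loss is bounded in [0, 1] even though LeakyReLU predictions can be
negative; in the clamped region the loss saturates at 1 with zero
gradient. Masked entries contribute neither loss nor gradient — a
property verified by finite differences, as are all hand-derived GRU
backward passes (the network is implemented as explicit matrix
forward/backward code with Adam and linear learning-rate warmup;
training is bit-reproducible given the seed).

Tunable parameters and defaults: 30 epochs, Adam at learning rate
1 × 10⁻⁴ with 20,000 warmup steps at full scale. These optimizer
settings are tuned to the full-size model and millions of records; for
the desk-scale "tiny" preset (embedding 8, recurrent 16) the package's
study conditions use learning rate 5 × 10⁻³, warmup of roughly 1.5
epochs of steps, and batch 64 (16 when overfitting very small sets),
chosen once as sensible small-scale equivalents and not revisited.

Evaluation is the per-spectrum Pearson correlation between predicted
and target intensities computed over non-masked entries only (zeros
included); spectra with fewer than two non-masked entries or
degenerate variance are flagged NA and excluded from medians, never
silently scored 0. Computing the correlation over non-masked entries
(rather than the whole dictionary) is a documented choice: masked
entries are undefined by construction, and including them would reward
the model for predicting zeros at impossible ions.

## Rescoring statistics

Per PSM the feature table contains: spectral angle similarity (1 −
masked spectral distance between target and prediction), per-spectrum
Pearson, the ratio of observed to theoretically possible fragments,
the ratio of observed-and-predicted to predicted fragments (an ion
counts as predicted when its predicted intensity exceeds a floor,
default 0), the matched-ion count, and the fraction of total spectrum
intensity explained. Methods with large series sets (EID, UVPD)
necessarily produce small observed/theoretical ratios — the very
motivation for prediction-aware features.

Target–decoy q-values use the conservative competition estimate
FDR(t) = (#decoys ≥ t + 1)/(#targets ≥ t); a PSM's q-value is the
minimum estimate over all accepting thresholds, which makes q-values
non-increasing in score, and tied scores share a q-value. The +1
numerator is the standard conservative correction. The recovered
true-positive fraction at threshold t is (targets − decoys accepted at
q ≤ t)/(total targets − total decoys), clipped to [0, 1].

Full SVM-based rescoring is out of scope; the package's "rescored"
score is a logistic-regression combination of the feature table fit on
a held-out calibration split (default half, seeded). This preserves
the qualitative contract — a feature-aware score separates targets
from decoys at least as well as the base score — without
re-implementing an iterative SVM. Identification efficiency is
reported as 100 × confident PSMs / acquired MS2 scans.

## The synthetic-data generator

The simulator exists so every module is testable without instrument
data; it emulates the statistical structure of multi-method DDA
corpora, not the physics of dissociation. Random proteins (length
120–400, residue frequencies loosely matching natural abundance) are
digested in silico (trypsin, LysC, LysN, GluC, chymotrypsin with their
textbook cleavage rules), and peptides of 7–30 residues are drawn with
charges 2–4 (probabilities 0.5/0.35/0.15). Every cysteine carries the
fixed carbamidomethyl modification; methionines oxidise with
probability 0.1.

Fragmentation is modelled as deterministic sequence chemistry plus
measurement noise, because that determinism — the same precursor
fragments the same way on every scan — is the very property that
makes fragment-intensity prediction possible. Each backbone site
carries a cleavage propensity, a fixed log-normal function of its
flanking residue pair (two arbitrary fixed residue tables; simulator
constants, not measured values). A theoretical ion is detected when
its site's propensity exceeds a per-(series, fragment charge)
threshold calibrated so the marginal detection rate over random
sequences is detect_prob · w_s / max(w) times a charge fraction
(1/0.30/0.08), where w are the method profile's series propensity
weights. Consequently the expected count proportion per series equals
its weight — count-based annotation proportions recover the profile,
and intensity ratios such as [a+1]/[a] recover propensity ratios —
while the realised fragment set of any one peptide is a deterministic,
learnable function of its sequence. Detected amplitudes are
series-independent: a positional shape peaking mid-peptide, times a
fragment-charge share (0.70/0.25/0.05), times a log-normal
peptide-pattern draw (σ = 0.3) seeded by (peptide, charge, method) so
replicates share patterns, times per-scan replicate jitter (σ = 0.1).
Default weights qualitatively mirror the observed per-method ion-type
proportions (ECD dominated by c/z, HCD by y/b, EID/UVPD spread over
all ten series with y/b dominant); they are simulator knobs, not
measured constants. ECD's charge dependence is modelled by attenuating
fragment intensities of 2+ precursors (factor 0.35) relative to the
noise floor. Spectra also contain the precursor isotope peaks and 30
uniform-m/z noise peaks with exponential amplitudes; the base peak is
scaled to 1.

Each spectrum is paired with a target PSM and a decoy PSM whose
peptide is the reversed sequence with the C-terminal residue kept in
place (preserving the tryptic anchor). The synthetic hyperscore is 30
× (matched fraction of theoretical ions) plus Gaussian noise (σ = 1.5),
floored at 0 — a monotone surrogate labelled synthetic, with no claim
of search-engine equivalence.

What passing tests on this generator do **not** show about real data:
chimeric spectra, fragment isotope envelopes, neutral losses, internal
ions, mass-accuracy drift, retention-time structure and
intensity-dependent detector noise are all absent. Results on the
simulator validate the machinery (masses, matching, masking, loss,
FDR accounting) and the model's ability to learn method conditioning —
not absolute prediction accuracy on instrument data.

## Numerical choices and degenerate inputs

- Ties in clash resolution, deduplication and q-values are broken by
  fixed deterministic orders, documented above.
- The loss gradient guards the arccos singularity by capping the
  cosine at 1 − 10⁻⁷; rows with zero-norm targets or predictions
  contribute loss 0 and zero gradient and are logged as degenerate.
- Undefined ratios (no a-ion intensity for [a+1]/[a], no predicted
  ions above the floor) are flagged NA, never reported as 0.
- Weight initialisation is uniform Glorot-style; all randomness
  (initialisation, shuffling, splits, simulation) flows from explicit
  integer seeds, and identical seeds give bit-identical results on one
  device.
- Empty inputs are valid where a vacuous answer exists (empty peak
  list, empty dictionary corpus) and errors where it does not (empty
  theoretical set, no target PSMs).

## Desk-scale study conditions

The test suite and the acceptance script exercise the pipeline at
sizes chosen to be statistically meaningful on one CPU: a five-method
corpus of 2,000 spectra (400 per method, 40 proteins, seed-fixed) with
4,000 target+decoy PSMs, a dictionary built at the standard ≥ 100
occurrence threshold (~330 ions at this scale), the tiny model preset
trained for 30 epochs, a 50-spectrum overfitting check, and
property-based suites (mass conservation over 1,000 random peptides,
annotation oracle equivalence over 200 spectra, brute-force q-value
sweeps over random ≤ 50-PSM instances). Known limitation: at this
scale per-method Pearson medians are not comparable to full-scale
training on millions of PSMs; the package asserts behavioural
properties (capacity, method conditioning, feature-aware rescoring
gains) rather than absolute headline numbers.
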