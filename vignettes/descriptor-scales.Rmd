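---
title: "Amino-acid descriptor scales: encoding, derivation and comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amino-acid descriptor scales: encoding, derivation and comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protscales)
```

## The problem

Proteochemometric (PCM) and quantitative sequence–activity (QSAM) models
regress bioactivity on joint ligand and protein features. On the protein
side the dominant representation is a *descriptor scale*: each of the 20
standard amino acids is assigned a short numeric vector, and a sequence is
encoded as the position-major concatenation of its residues' vectors. A
dozen such scales are in wide use, constructed from very different raw
material — physicochemical property panels, topological indices of large
non-natural amino-acid collections, molecular-surface electrostatics,
factor analyses, substitution matrices. Two questions follow for anyone
building PCM models: *how do I encode with these scales reproducibly*, and
*which scales actually carry different information*? This package answers
both, and additionally re-implements the pipeline by which a PCA scale can
be derived from raw per-amino-acid property matrices.

## The bundled scales

`list_descriptor_sets()` names 13 sets. Their values are bundled as
versioned TSV files under `inst/extdata/descriptors/` (plain text, `#`
metadata headers, Unicode-minus tolerated) and validated on load: 20 rows
in the fixed canonical order `r paste(aa_alphabet(), collapse = " ")`, no
missing values, cumulative variance metadata non-decreasing. The ProtFP
family is stored once at 8 components; the 3- and 5-component variants are
its leading columns, registered with their own metadata, which makes the
identity `truncate_table(ProtFP_PCA8, k)` = `ProtFP_PCAk` structural
rather than coincidental. The same holds for the two Z-scales depths.

Two bundling notes. First, contemporary summaries of the T-/ST-scales
disagree on which has 5 and which 8 components; we follow the original
publications (T = 5, ST = 8) and record the discrepancy in the tables'
`notes` metadata. Second, ProtFP's published cumulative-variance row reads
0.85 at five components while the per-component row sums to 0.81 there
(rounding in the source); we store both as published and use the
per-component row arithmetically only at k = 3, where the two agree (0.75).

The `Zscales_Binned` set discretizes the five Z-scales into labelled
classes (one active class per scale, giving a 0/1 fingerprint per amino
acid). The published class boundaries are not available to us; the shipped
`zscales_bins.tsv` is this package's own design — four classes per scale
with hand-chosen breakpoints on the Sandberg values, fixed once against
three constraints: tryptophan's and glycine's published class assignments,
and pairwise distinctness of all 20 bit patterns. Users with the original
boundaries can supply their own bin file and rebuild the table with
`new_binned_descriptor_table()`.

The `ProtFP_Feature` variant maps each amino acid to a single hashed
integer. The hash function itself is not re-implemented; the integers are
authoritative lookup constants, usable for encoding but excluded from any
distance computation (all hash distances would be maximal and meaningless).

## Encoding

`encode_sequence()` is a pure lookup: encoding a concatenation equals
concatenating the encodings. Policies are explicit because silent
corruption of a PCM design matrix is worse than failure:

* `unknown_policy` (B, J, O, U, X, Z, and `-` when encoding a single
  sequence): `"error"` by default, `"skip"` (shrinks the vector) and
  `"zero"` opt-in. `*` is always an error.
* In `encode_collection()`, alignment gaps get their own `gap_policy`;
  `"zero"` writes a zero block and keeps the alignment column, the common
  choice when encoding aligned binding-site residues. Equal effective
  lengths are enforced, with offending ids named.

Labels are `p<position>_<component>` with 1-based positions, the residue
numbering convention of the field.

## Deriving a PCA scale from property matrices

`derive_protfp()` composes three steps:

1. **Unit-interval scaling** — each index is mapped linearly to [0, 1]
   (`(x − min)/(max − min)`). Constant indices are dropped with a warning.
2. **Recursive elimination of co-varying indices** — the published
   procedure states the goal (remove the most co-varying indices, keep a
   largely independent panel) but not the criterion. Ours: score each index
   by its maximum absolute Pearson correlation against the remaining
   indices, remove the global maximizer, repeat until `target_n` remain;
   ties break lexicographically on the index id so the run is
   deterministic. Indices with missing values among the 20 amino acids are
   excluded first — correlations over partial profiles are not comparable.
   The removal order is returned for audit.
3. **PCA** — amino acids as observations (20 × n), indices as variables,
   mean-centered and variance-scaled. Note this *double* scaling (unit
   interval, then standardization inside the PCA) is deliberate: both steps
   are part of the published recipe. The orientation — which axis is
   "observations" — is implied rather than stated in the source; scores
   must be per amino acid, which forces the choice made here.

Sign indeterminacy is resolved by making the largest-magnitude loading of
each component positive, so derived tables are reproducible bit-for-bit.
`n_components` defaults to 8, mirroring the published choice of forcing a
minimum of eight components for head-to-head comparison with other scales.
The exact published 58-index AAindex selection is *not* reproduced —
it requires a supplementary table and an unstated elimination criterion —
so correctness of the pipeline is established by parameter recovery on
synthetic data instead (below).

`parse_aaindex1()` reads the AAindex1 flat format (two data lines of ten
values under the `I` header, A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V column
order, `NA` for missing).

## Comparing descriptor sets

The comparison methodology, per pair of numeric sets:

1. Each set's 20 × 20 Euclidean amino-acid distance matrix (all 400 cells:
   diagonal and both symmetric copies — the counting convention kept
   throughout) is scaled linearly to [0, 1]. Since the diagonal fixes the
   minimum at 0, scaling is division by the per-set maximum.
2. The 400 per-cell absolute differences between two sets' scaled matrices
   are summarized by mean and standard deviation (population formula,
   n = 400, configurable). Differences enter in absolute value: over
   symmetric matrices a signed mean would cancel toward zero and could not
   serve as a distance.
3. The means form the symmetric inter-descriptor matrix (zero diagonal),
   which is submitted to PCA — mean-centered, variables not standardized
   (the matrix is already on a single scale; standardization is exposed as
   an option, as is classical MDS). Whether the original analysis
   standardized here is not stated; the unstandardized default is recorded
   so results are interpretable either way.

Scaled distance matrices are invariant to rotation, reflection, uniform
scaling and component permutation of a descriptor table — Euclidean
distances are orthogonally invariant and max-scaling absorbs the scalar —
and the test suite asserts this on random tables against brute-force
oracles. Binned tables participate with bits as 0/1 coordinates; the
feature variant is auto-excluded.

`run_full_analysis()` performs the whole chain on the 12 bundled numeric
sets. With `truncate_to = 2` it runs the *limited* variant: every numeric
set cut to its first two components. Truncation makes the three ProtFP PCA
depths identical, likewise the two Z-scales depths; value-identical tables
are collapsed to one entry (labelled by their common prefix), and the
binned set — having no ordered components to truncate — is dropped,
leaving 8 sets. In our runs the first two components of the
descriptor-space PCA carry 83.7% (full) and 67.9% (limited) of the
variance, and the limited map shows T- and ST-scales mutually closer than
either is to MS-WHIM. The original report of this methodology prints 70%
for the full analysis; the bulk of that difference traces to the binned
set's geometry (excluding it our full figure is 72.0%), i.e. to the
bin-boundary design discussed above rather than to the procedure.

The heat-map-level observation that ProtFP (PCA3) spreads amino acids more
widely than Z-scales (3) does *not* survive per-set max-scaling in our
implementation (mean scaled distances 0.439 vs 0.489): glycine is an
extreme outlier in ProtFP space, inflates the scaling maximum, and
compresses every other ProtFP distance. Standardizing components before
the distance step restores that ordering but degrades the limited-analysis
variance figure, so we keep the stated procedure and note the discrepancy
rather than hide it.

## Synthetic data: what it does and does not show

`generate_fixture_property_matrix(n_indices, n_latent_factors, noise_sd,
seed)` emulates a property database's essential structure: each index is a
random linear combination of a few latent amino-acid profiles plus
Gaussian noise. Defaults used in tests — 60 indices, 3 factors, noise SD
0.1 against unit-scale signal — approximate a curated property panel
(order 10¹–10² indices, a handful of dominant physicochemical axes, small
measurement noise). The generator records the realized share of per-index
variance attributable to the factor subspace; after per-index
standardization every index contributes equally, so that share is what a
k-component PCA should capture, and the recovery test requires agreement
within two percentage points. What this establishes is that the pipeline's
composition (scaling → elimination → PCA) is variance-faithful and
deterministic. What it does not establish: fidelity to any *particular*
published index selection, nor behavior under the heavy-tailed,
block-correlated structure of real property databases — real AAindex data
also carries missing values and near-duplicate index families, which the
pipeline handles (exclusion and elimination respectively) but the
generator does not emulate.

## Numerical and design choices

* Bundled values are stored exactly as printed in their sources (two
  decimals for ProtFP) in double precision; the feature integers are exact
  in doubles.
* Distance-matrix scaling: per set, over its own 400 entries.
* PCA sign convention: largest-|loading| positive, everywhere.
* Elimination tie-break: lexicographic on index id.
* Degenerate inputs fail loudly: zero-variance variables under scaling are
  named; empty sequences, unknown identifiers, mismatched alignment
  lengths raise classed errors (`ps_error_*`) that the CLI maps to exit
  status 1 (data) or 2 (usage).
* Problem sizes in the test suite (60–100 synthetic indices, 20
  observations, 12 descriptor sets) are the method's natural scale — the
  full comparison is a 66-pair loop over 400-cell matrices and completes
  in well under a second.

## Known limitations

* Third-party scale values are transcribed constants; they are validated
  structurally (shape, finiteness, ordering) but we cannot re-derive them
  from their original property matrices (explicitly out of scope).
* The binned Z-scales classification is a reconstruction constrained by
  two published worked examples and uniqueness, not the original table.
* The inter-descriptor "distance" (mean |difference|) is not guaranteed to
  satisfy the triangle inequality; we assert symmetry and non-negativity
  only, and the PCA treats it as a feature matrix, not a metric.
* The hash behind the feature variant is treated as opaque; a pluggable
  hook would be needed to extend it beyond the 20 bundled integers.
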