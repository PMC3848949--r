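# protscales

Amino-acid descriptor scales for proteochemometric (PCM) and peptide QSAR
modeling.

Protein–ligand interaction models need the protein side expressed as
numbers. The standard device is an *amino-acid descriptor set*: a fixed
mapping from each of the 20 standard amino acids to a short numeric vector
(for the Z-scales, for example, lipophilicity, bulk and polarity
components), so a peptide or binding-site sequence of length *L* becomes an
*L·k* feature vector. Many such sets exist — derived by PCA of
physicochemical properties, of topological descriptors, of surface
electrostatics, by factor analysis, or from substitution matrices — and they
do **not** perceive amino-acid similarity the same way. `protscales` is for
modelers who need to (a) encode sequences with any of the major published
sets, (b) derive fresh PCA-based sets from raw property matrices, and
(c) quantify which published sets behave alike and which are complementary,
so that a PCM project can sample descriptor sets that actually differ.

## What is inside

* **Registry** — 13 bundled, validated descriptor sets:
  Z-scales (3, 5, and a binned 0/1 variant), VHSE, T-scales, ST-scales,
  MS-WHIM, FASGAI, BLOSUM-derived indices, and the ProtFP family
  (PCA scores over curated AAindex properties at 3/5/8 components, plus a
  hashed single-integer feature variant).
* **Encoding** — `encode_sequence()` / `encode_collection()` turn
  single-letter sequences (or aligned sets, FASTA in) into position-major
  feature tibbles with explicit policies for non-standard residues and
  alignment gaps.
* **Derivation** — `parse_aaindex1()`, `scale_unit_interval()`,
  `eliminate_covarying()`, `pca_scores()` and the composed
  `derive_protfp()` re-create the ProtFP construction pipeline on any
  property matrix: scale each index to [0, 1], recursively drop the most
  co-varying indices, then PCA (centered and scaled) with amino acids as
  observations.
* **Comparison** — for each numeric set, the 20×20 Euclidean amino-acid
  distance matrix scaled to [0, 1]; for each pair of sets, the mean and SD
  of the 400 per-cell absolute distance differences; the resulting
  inter-descriptor distance matrix; and its PCA, mapping descriptor sets
  into a plane (`run_full_analysis()`).

The core statistic is the **inter-descriptor distance**

> d(A, B) = mean over all 400 amino-acid pairs (i, j) of
> | D̂A(i, j) − D̂B(i, j) |,

where D̂ is a set's Euclidean amino-acid distance matrix scaled by its own
maximum. Small d means two sets judge amino-acid similarity alike.

## Worked example

```r
library(protscales)

list_descriptor_sets()
#>  [1] "BLOSUM"  "FASGAI"  "MSWHIM"  "ProtFP_PCA3" "ProtFP_PCA5" "ProtFP_PCA8"
#>  [7] "ProtFP_Feature" "STscales" "Tscales" "VHSE" "Zscales_3" "Zscales_5"
#> [13] "Zscales_Binned"

encode_sequence("GA", get_table("ProtFP_PCA3"))$values
#> p1_PC1 p1_PC2 p1_PC3 p2_PC1 p2_PC2 p2_PC3
#>  -5.70  -8.72   4.18  -0.10  -4.94  -2.13
```

The two triplets are exactly the glycine and alanine rows of the bundled
ProtFP table: position 1 contributes glycine's three principal-component
scores, position 2 alanine's.

```r
cmp <- run_full_analysis()          # 12 numeric sets; hash variant excluded
glance(cmp)
#> # A tibble: 1 × 4
#>   n_sets n_pairs_per_set cum_var_pc2 truncate_to
#>    <int>           <int>       <dbl>       <int>
#> 1     12             400       0.837          NA

lim <- run_full_analysis(truncate_to = 2)
names(lim$tables)
#> [1] "BLOSUM" "FASGAI" "MSWHIM" "ProtFP_PCA" "STscales" "Tscales" "VHSE" "Zscales"
round(100 * sum(lim$pca$variance_fractions[1:2]), 1)
#> [1] 67.9
```

`cum_var_pc2` is the share of variance the first two components of the
descriptor-space PCA capture: 0.837 across the 12 full sets, 67.9% in the
limited analysis where every set is cut to its first two components (the
ProtFP PCA variants and the two Z-scales versions then coincide and are
collapsed, leaving 8 sets). `autoplot(cmp)` draws the descriptor map;
topology-derived T- and ST-scales sit together in it, away from MS-WHIM.

A derivation run on synthetic data:

```r
pm  <- generate_fixture_property_matrix(60, 3, noise_sd = 0.1, seed = 1)
fit <- derive_protfp(pm, target_n = 60, n_components = 3)
cumsum(fit$pca$variance_fractions)[3]
#> [1] 0.9864712
```

Three components recover 98.6% of the variance — matching the planted
three-factor structure's realized share (the generator bookkeeps it) to
well under a percentage point.

A command-line front end (`list`, `encode`, `compare`, `derive`,
`fixtures`) ships as `inst/scripts/protscales`; `protscales::cli_main()` is
the same interface in-process.

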