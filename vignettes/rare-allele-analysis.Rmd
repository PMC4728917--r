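---
title: "Rare-allele haplotypes, polarized mutation rates and the unfolded SFS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-allele haplotypes, polarized mutation rates and the unfolded SFS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rarehap)
```

# The model

`rarehap` analyses per-locus multiple alignments of *n* accessions of one
species (typically *n* ≈ 96, loci ≈ 500 bp) paired with one aligned
outgroup sequence.  Three ideas carry the whole package.

**1. A distinct haplotype is perfect co-segregation.**  A set of
accessions forms a distinct haplotype when at least `min_fixed` biallelic
columns split the panel *identically*: every called member carries one
allele, every called non-member the other.  This is deliberately exact
(perfect linkage), not a clustering with mismatch tolerance: the
fixed/non-fixed dichotomy that drives all downstream rate comparisons
(gSNP versus nfSNP) would blur under tolerant grouping.  Discovery is
implemented by grouping qualifying columns by their minor-allele carrier
set (`carrier_partitions()`), so it is O(sites), and a brute-force subset
search over all accession subsets serves as its oracle in the tests for
small panels.

**2. The outgroup orients every mutation.**  For a biallelic site split
between a focal allele class and the rest, the outgroup base decides which
side mutated: it matches the other allele → the focal side carries a new,
*derived* mutation; it matches the focal allele → the mutation happened on
the other (major) lineage and is counted *ancient*; a third state, gap or
missing base excludes the site (no parsimony guessing).  The relative rate
derived/ancient is the focal allele's relative evolutionary speed, and the
same orientation applied to every polymorphic site yields the unfolded
SFS.

**3. Frequency classes carve the taxonomy.**  Distinct haplotypes with
frequency `< 0.10` are rare (type II), `0.10 ≤ f < 0.50` intermediate, the
complement is the major allele.  Supporting columns are gSNPs; other
polymorphic sites are nfSNPs at haplotype-bearing loci and dSNPs at
single-haplotype loci; nfSNPs and dSNPs below 10% frequency are the type I
rare substitutions.  All cutoffs are strict (`<`), and frequencies are
computed over called accessions.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_fixed` | 5 | substitutions | ~1% fixed divergence on a ~500 bp locus; small enough to find real blocks, large enough that neutral coalescent noise rarely produces a *rare-frequency* block (measured below 5%, see the acceptance suite) |
| `rare_cutoff` | 0.10 | frequency | 9 or fewer accessions of 96 |
| `intermediate_cutoff` | 0.50 | frequency | majority rule for the major allele |
| `min_accessions`, `min_length` | 60, 400 | count, bp | locus-quality screen |
| `min_outgroup_identity` | 0.85 | fraction | drops misaligned/paralogous outgroup pairings; identity exactly at the threshold is kept |
| `min_side_coverage` | 0.8 | fraction | a "fixed" column must have ≥80% of each side called, so modest missing data cannot fake or break co-segregation |
| SFS bins | 10 | half-open `[0,0.1) … [0.9,1)` | sites at derived frequency exactly 1 are fixed differences, outside the SFS; fixation is reached by quadratic extrapolation to frequency 1 instead |

# Conventions and numerical choices

* **Coordinates** are 0-based half-open internally and in machine-readable
  outputs; positions in prose and locus naming are 1-based.
* **Gaps** (`-`) are missing data for substitution-level analysis; maximal
  gap runs are promoted to indel events by `detect_indels()`, merged when
  their spans are identical across accessions, excluded when spans overlap
  without matching (unequal indel sizes between haplotypes), and polarized
  by the outgroup's gap structure over the exact span.
* **Ambiguity codes** other than `N` are mapped to `N` with a warning —
  a conservative choice; they are rare in consensus-called panels.
* **Outgroup identity** is computed against the alignment's
  majority-consensus sequence over columns where both are called.  Using
  the consensus rather than a privileged reference accession keeps the
  filter deterministic and accession-agnostic.
* **Overlap resolution.**  Two qualifying carrier sets that overlap
  without nesting cannot both be haplotypes under perfect co-segregation;
  the one with more supporting sites wins (ties: smaller member set, then
  lexicographic).  Nested qualifying sets are both kept — that is the
  complex-locus pattern — and each accession is assigned to the smallest
  qualifying set containing it, so the final groups partition the panel.
  A candidate covering ≥50% of the panel names the wrong side and is
  flipped to its complement.  These tie-breaks are this package's
  convention; the underlying biology does not dictate one.
* **Rounding.**  Ratios are reported half-up to 2 decimals, percentages to
  1, Ts/Tv to 3 (`round_half_up()`), while TSV outputs carry full
  precision.  A ratio with zero ancient mutations is `NA`, not an error.
* **Tajima's D** uses complete-case columns only (no gaps, no `N`
  anywhere), the standard constants, and returns `NA` for S = 0 or n < 4.
  The tests pin it to an independently written naive implementation at
  1e-9 on random small alignments.
* **Relative-rate decay over frequency** (`rate_by_frequency()`) bins
  polarized sites by their *focal-allele* (minor or haplotype-group)
  frequency.  Binning by derived-allele frequency instead would place all
  derived-class sites in low bins and all ancient-class sites in high bins
  by construction, making every per-bin ratio 0, ∞ or undefined; the
  focal-frequency convention yields the informative decay — under
  neutrality the odds that the minor allele is the new mutation scale as
  (n−i)/i.
* **The random-occurrence χ²** pools cells with expected count < 5 into
  the adjacent lower-count cell (df = pooled cells − 1).  The significance
  checks on rate differences are 2×2 χ² without continuity correction;
  the Dxy class comparison is a one-sided permutation test on per-locus
  values — both are conventions for tests whose family, but not
  construction, is standard.
* **Quadratic extrapolation** is an OLS degree-2 fit of binned counts with
  `y_at_1 = c0 + c1 + c2`; on noiseless quadratics the coefficients are
  recovered to < 1e-9.

# What the generator emulates — and what it does not

`simulate_neutral_locus()` draws a Kingman genealogy on `n_accessions`
leaves, places mutations as a Poisson process at rate θ/2 per site per
unit coalescent time under infinite sites (distinct columns), and derives
the outgroup from the sample's ancestral sequence at `outgroup_divergence`
per site (default 0.05).  θ per site defaults to 0.0044, which *is* the
expected pairwise diversity of the neutral background (0.44%).
`simulate_structured_locus()` layers implanted haplotypes on top: each
implant gives a chosen carrier set `n_fixed ≥ 5` private fixed
substitutions at columns untouched by background mutation, each site
derived on the implant lineage with probability `p_derived_rare` (default
0.587, the observed derived share among rare-versus-major fixed sites) or
ancient otherwise; optional fixed indels (70% derived in the implant
group) can elevate the flank substitution rate on the indel-carrying
lineage by `indel_flank_multiplier` within `indel_flank_bp` (default
1 kb), emulating indel-associated local mutagenesis.  Dataset-level
defaults place rare implants at 23.4% of loci with the count of distinct
rare types following the empirical 179:26:10:4:1 distribution, and
intermediates at 22.4%.  One root seed plus the locus index determines
every locus independently of `n_loci`, so outputs are byte-stable.

Limitations worth knowing when reading test results:

* **No recombination within loci.**  Deep neutral clades therefore carry
  their basal-branch mutations as perfectly linked blocks, and roughly a
  fifth of purely neutral loci at these settings contain *some* distinct
  (mostly intermediate-frequency) haplotype.  The meaningful null for a
  *rare allele* call — a sub-10% carrier set with ≥5 fixed substitutions —
  sits just below 5% (`null_haplotype_rate()`, default `klass =
  "rare_typeII"`), and that is the calibration the acceptance suite
  checks.  It is a boundary-grazing property: Monte-Carlo estimates at
  1000 replicates fluctuate on either side of 0.05 across streams.
* **Dataset diversity exceeds the background.**  Implanted fixed sites add
  pairwise diversity on top of the 0.44% neutral background, so the
  simulated dataset's total diversity is higher (~0.7%); real panels'
  printed diversity already includes their haplotype structure.  The
  calibration target applies to the neutral background, which the
  acceptance script reports separately.
* **Truth ledgers record implants, not emergent structure**, so
  locus-type "agreement" with the ledger is bounded by the neutral
  distinct-haplotype rate; recovery tests assert the implant-recall
  direction (every implanted haplotype found; k = 4 implants never
  reported at `min_fixed = 5`).
* No selection, no demography, no sequencing error, and the outgroup is a
  star divergence from the sample ancestor rather than a coalescent of its
  own.  `outgroup_error_rate` exists purely to exercise "excluded"
  polarization paths.

# Worked dataset run

```{r, eval = FALSE}
cfg <- sim_config(n_loci = 300)
dir <- tempfile()
simulate_dataset(cfg, dir, seed = 1)
res <- run_pipeline(file.path(dir, "manifest.tsv"), out_dir = "report")
res$summary          # per-category mutation table with relative rates
res$random_occurrence
autoplot(res$sfs)    # unfolded SFS vs (1/i)/sum(1/j)
```

Problem sizes used throughout the tests and the acceptance script — 200 to
1000 simulated loci per Monte-Carlo property, a 300-locus end-to-end run,
a 1214-locus filtering panel — are chosen so each property's sampling
error is small relative to the effect it checks.

# Known discrepancies in the published worked examples

Two printed numbers this package's arithmetic cannot reproduce from their
own operands, and therefore reports as computed: a gSNP-category ratio
printed as 1.25 where the printed counts give 2722/2218 = 1.23, and a
random-occurrence χ² printed as 3.23 that standard pooling of the printed
observed/expected cells does not yield (the package computes its own χ²,
8.11 on those counts, with the pooling stated above).  A published
frequency-excess "0.194/0.019 − 1 = 9.09" likewise evaluates to 9.21.  In
each case the computed value is authoritative here.
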