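# rarehap

Rare-allele haplotype discovery and evolutionary-rate analysis for
per-locus multiple alignments of many accessions of one species, with an
aligned outgroup.

## The problem

Resequencing panels of selfing plants such as *Arabidopsis thaliana*
routinely show loci where a small block of accessions differs from the rest
by a run of perfectly co-segregating substitutions — a *distinct
haplotype*.  When such a block is carried by fewer than 10% of accessions
it is a **rare allele** (a type II rare variant); low-frequency SNPs
scattered across accessions are type I rare substitutions.  Whether these
rare alleles are ancient relics, products of selective sweeps or population
structure, or newly minted mutation clusters is decided by quantitative
signatures: how fast the rare lineage accumulated new (derived) mutations
relative to the major allele, how the unfolded site-frequency spectrum
departs from neutrality, and how far the rare pattern extends into flanking
sequence.

`rarehap` implements that analysis end to end:

* **Haplotype discovery.**  A distinct haplotype is a set of accessions
  separated from the rest by at least *k* fixed substitutions (default
  *k* = 5, about 1% fixed divergence on a ~500 bp locus).  Groups are
  labelled *rare* (frequency < 0.10), *intermediate* (0.10–0.50) or
  *major*; loci become gSNP loci (haplotype-bearing), dSNP loci (dispersed
  SNPs only) or complex (two or more distinct non-major haplotypes).
* **SNP taxonomy.**  Fixed substitutions supporting a haplotype are
  **gSNPs**; other polymorphic sites are **nfSNPs** at haplotype-bearing
  loci and **dSNPs** at single-haplotype loci (together **rSNPs**).
* **Polarization.**  With an aligned outgroup each biallelic site is
  oriented: outgroup = major allele ⇒ the focal (rare/minor) allele carries
  a new, *derived* mutation; outgroup = focal allele ⇒ the mutation is
  *ancient* (it happened on the major lineage); any other outgroup state
  excludes the site.  The **relative rate** derived/ancient measures how
  much faster the focal allele evolved (1 = equal rates).  Indel events are
  polarized the same way.
* **Statistics.**  A random-occurrence model for the number of rare-allele
  types per locus, E[Fᵢ] = F₁ⁱ, with a χ² fit; per-accession occurrence
  against a binomial expectation; Tajima's D per locus; the unfolded SFS
  with its constant-size neutral expectation (1/i)/Σ 1/j and per-bin
  frequency excess; quadratic extrapolation of binned SNP counts to
  frequency 1 (the fixation end); between-species divergence Dxy;
  synonymous/nonsynonymous and codon-position effects; Ts/Tv ratios; and
  the bp extent of a rare pattern into flanking sequence.
* **Synthetic data.**  A seeded Kingman-coalescent generator (infinite
  sites, ~0.44% background diversity, 5% outgroup divergence) with
  implanted rare/intermediate haplotypes, fixed indels and optional
  indel-flank mutation-rate elevation, emitting FASTA + manifest plus a
  complete ground-truth ledger for recovery testing.

## Worked example

Simulate one 96-accession locus with an implanted 5-accession rare
haplotype (7 fixed substitutions), then analyse it:

```r
library(rarehap)

cfg <- sim_config()
sim <- simulate_structured_locus(cfg, seed = 42, rare_spec = list(c(5, 7)))

haps <- identify_haplotypes(sim$locus, min_fixed = 5)
haps[, c("klass", "n_members", "freq", "n_supporting")]
#>   klass       n_members   freq n_supporting
#> 1 rare_typeII         5 0.0521            7
#> 2 major              91 0.948             0

snps <- classify_snps(sim$locus, haps)
dplyr::count(snps, category, polarization)
#>   category polarization         n
#> 1 gSNP     ancient              3
#> 2 gSNP     derived_in_focus     4
#> 3 nfSNP    ancient              3
#> 4 nfSNP    derived_in_focus     9
#> 5 nfSNP    excluded             1

tajima_d(sim$locus)
#>   locus_id     n     S    pi      D
#> 1 sim         96    20  2.58 -0.980
```

The implanted group is recovered exactly (5 of 96 accessions, 7 supporting
gSNPs).  Of the polarizable gSNPs, 4 are derived in the rare allele and 3
ancient — `relative_rate(4, 3)` = 1.33, i.e. on this locus the rare lineage
accumulated new mutations ~1.3× faster than the major allele.  Tajima's D
is negative (−0.98), the expected signature of an excess of rare variants,
and `dxy()` shows the rare block slightly more diverged from the outgroup
(0.0608) than the major allele (0.0598).

For a whole dataset, `simulate_dataset()` writes a manifest plus per-locus
FASTA and `run_pipeline(manifest, out_dir)` produces the full set of report
tables (`loci.tsv`, `haplotypes.tsv`, `snps.tsv`, `summary.tsv`, `sfs.tsv`,
`fits.tsv`, `dxy.tsv`, `occurrence.tsv`, `indels.tsv`, `run.json`);
`audit_report(out_dir)` re-derives the summary from the per-row tables.
`autoplot()` methods draw the SFS, rate-decay, quadratic-fit and
occurrence figures; `tidy()`/`glance()` tidy the fitted objects.

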