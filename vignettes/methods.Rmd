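---
title: "Methods: shared neoantigen panel construction and cohort validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shared neoantigen panel construction and cohort validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models, thresholds and design
decisions behind `otsneo`, in the order the pipeline runs them.

## Recurrent-mutation catalog

Somatic variants enter as MAF-style rows. The filter cascade runs in a
fixed order: (1) drop variants with VAF below `min_vaf` (default 0.02; a
standard floor against sequencing noise in fresh-frozen material — rows
without a VAF pass through unharmed); (2) keep only genes with a
cancer-hallmark annotation from a user-supplied gene table (the package
deliberately takes this list as *data*, not as built-in knowledge: which
"functional relevance" filter to apply upstream of recurrence is a
curation decision, so it is externalized to a `gene, role, hallmark`
table); (3) keep nonsynonymous consequences only; (4) aggregate by
`gene_proteinChange` over *distinct* patients, so multi-sample patients
count once; (5) keep mutations in at least `min_recurrence = 2` patients.

Two conventions matter downstream. Frequencies always use the full cohort
size as denominator, not just mutation-bearing patients, because coverage
curves and panel frequencies are statements about the whole population.
And frameshift variants are collapsed into truncation groups keyed by gene
and position (`G659fs`, `G659Vfs*41` and the shorthand `G659X` are one
mutation identity): distinct downstream frameshift alleles at the same
position produce overlapping novel peptide sets and are clinically
interchangeable at panel-design granularity.

## Co-mutation screen

For each unordered pair of catalog mutations the cohort is
cross-classified into a 2×2 table (cells sum to the cohort size,
including patients with no retained variant). The two-sided p-value uses
the minimum-likelihood rule — the sum of hypergeometric probabilities at
or below that of the observed table — which is the dominant convention for
Fisher's exact test; a relative tolerance of 1e-7 absorbs floating-point
ties, and the implementation is verified against exact integer-arithmetic
enumeration for every table with total at most 40. The odds ratio is the
unconditional cross-product `ad/bc`, reported as exactly `Inf` or `0` for
degenerate tables rather than continuity-corrected, so that extreme
co-occurrence structure stays visible; only the plotting export caps
infinite log-ORs (at the largest finite |log OR| + 1). Multiplicity is
handled by Benjamini–Hochberg across all tested pairs jointly, with
significance at FDR < 0.05. Mutation-level pairs are the default key;
gene-level screening is available because truncation groups make the two
non-equivalent.

## HLA population coverage

Country-level allele frequencies are aggregated per population group by
sample-size-weighted means, with a country that does not report an allele
contributing zero at its full weight — this treats absence from a large
typing study as evidence of rarity rather than missingness, which is the
conservative choice for coverage claims. Alleles are truncated to
two-field resolution before aggregation because class I binding
prediction operates at that resolution.

Coverage of an allele set is reported under two models, and every report
names the model used:

* **allelic**: the summed selected-allele frequency across loci, capped at
  1 — the expected fraction of the population allele pool captured;
* **genotypic** (default): `1 − Π_l (1 − S_l)²` with `S_l` the selected
  mass at locus `l` — the Hardy–Weinberg probability that a diploid
  individual carries at least one selected allele, assuming independent
  loci.

The genotypic model is the default because panel coverage is a statement
about individuals, not allele pools. Linkage disequilibrium between HLA
loci is deliberately ignored (a known limitation; real A–B–C haplotype
structure makes true genotypic coverage slightly lower than the
independence closed form). Allele-set selection is greedy by descending
frequency with lexicographic tie-breaks, which makes selection
deterministic and reproducible; greedy selection is not guaranteed optimal
under the genotypic model but is within noise of random equal-size subsets
in property tests and mirrors how such sets are assembled in practice.

## Epitope enumeration

Mutations are applied at the protein level: substitution for missense,
truncation before the stop for nonsense, prefix-plus-novel-tail for
frameshift (the novel tail must be supplied — by the caller for real data,
by the simulator here — because CDS-level translation is out of scope).
Every window of lengths 8–11 that lies fully inside the mutant protein and
overlaps an altered position is emitted, clipped at the termini; the
number of windows of length `k` overlapping position `p` in a protein of
length `L` is `min(p, L−k+1) − max(1, p−k+1) + 1`, and the test suite
checks emitted windows against a brute-force string scan for all `L ≤ 50`.
Nonsense mutations create no novel residues and therefore no class I
neo-peptides; they stay in the catalog flagged peptide-less. For the
25-mer stimulation peptides the altered residue is centred (offset 13),
shifted minimally at termini — placement is not dictated by any standard,
so it is a documented, configurable choice.

## Binder classification and the synthetic predictor

Percentile-rank thresholds are strict: rank < 0.5 is a strong binder,
rank < 2 a (weak) binder, and boundary values are non-binders, following
the usual reading of "below". Affinities in nM, when present, are carried
through but never used for classification.

`synthetic_predict()` exists so that every downstream stage is testable
without an external predictor: the rank is a pure 31-bit multiplicative
hash of (peptide, allele, seed) mapped uniformly onto (0, 100], with
planted (mutation, allele) pairs mapped into (0, 0.5). It is
position-agnostic and motif-free *by design* — realism is explicitly not a
goal; determinism and uniformity are, and both are property-tested. The
simulator's `simulate_binding()` additionally re-hashes unplanted pairs
that land below the binder threshold (salted re-draws) so planted truth is
exactly recoverable; with separation disabled, unplanted pairs become
binders at the expected ~2% background rate.

## Panel assembly and neoantigen frequency

A catalog mutation enters the panel when it has at least one binder among
every requested population's alleles (`any_binder`); `extended` mode also
admits mutations with frequency ≥ 1% and at least one strong binder,
trading a stricter binding bar for recurrence. Both rules are exposed
because the binder criterion for published panels is ambiguous between
the 2% and 0.5% thresholds. Per (mutation, allele), the best (minimum)
rank across peptide windows is used, so an allele counts once per
mutation. The population neoantigen frequency is the mean of
`mutation frequency × allele frequency` over the mutation's binding
alleles restricted to rank < 2% — linear in mutation frequency and bounded
by `mutation frequency × max allele frequency`, both checked as
properties.

## Cohort validation

Patient-level coverage requires a matched mutation–HLA pair; mutation
presence alone never counts. Genotypes are treated as presence sets (a
homozygous locus contributes one distinct allele), and matching uses weak
or strong binders by default, mirroring the 2% prediction filter. MSI
status is called from the five mononucleotide markers BAT-25, BAT-26,
MONO-27, NR-21, NR-24 (≥ 2 unstable → MSI-H) and its association with
panel carriage uses the same exact test as the co-mutation screen;
degenerate margins raise an error rather than a meaningless p-value.
Spearman correlations use mid-ranks with the large-sample t
approximation, flagged approximate below n = 10. ELISpot fold changes add
a pseudocount of 1 only when the wild-type well is zero, and a positive
call additionally requires 10 mutant spots — the floor guards against
2-versus-1-spot artifacts; both are configurable.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a colorectal
tumor cohort: a default variant-level spectrum with a few drivers at
6–3.5% (KRAS G12D, BRAF V600E, KRAS G13D, KRAS G12V), hotspot
TP53/PIK3CA/APC variants, frameshift truncation groups and a long tail
down to recurrence-level frequencies; one planted co-occurring pair (BRAF
V600E with RNF43 G659X, odds ratio 18.7) drawn from the exact 2×2 joint
distribution with the requested odds ratio (Plackett construction, which
preserves both marginals); MSI-H prevalence 15% with marker calls
consistent with the classification rule; VAFs uniform on [0.05, 0.6];
diploid genotypes drawn i.i.d. per locus from the frequency table with
residual mass assigned to a placeholder allele. Defaults of 308 discovery
and 67 validation patients set the cohort scale. Loci are simulated
independently, deliberately matching the coverage model's assumption so
that closed-form versus Monte-Carlo comparisons are exact tests of the
implementation rather than of the biology.

ELISpot counts use a negative-binomial model with `size = 100` (mild
overdispersion, as for spot counts pooled over replicate wells). This
dispersion is calibrated to the generator's design targets: a true 3-fold
effect at a baseline of 20 spots is called reactive in over 90% of draws,
and non-reactive pairs in under 10%.

What the generator does **not** emulate: mutational signatures, binding
motifs and anchor-residue effects, HLA linkage disequilibrium, transcript
expression, or antigen processing. Passing tests therefore demonstrate
correctness of the computational chain — filters, exact tests, coverage
algebra, recovery of planted structure — not predictive validity on real
tumors.

## Numerical and testing choices

Problem sizes in the test suite are chosen to make oracle comparisons
exhaustive where feasible: all 2×2 tables with total ≤ 40 against exact
rational enumeration (within 1e-12); all proteins up to length 50 for
window completeness; 1 000 random vectors for the BH step-up against its
quadratic definition; 10⁵ Monte-Carlo genotypes per coverage check (three
binomial standard errors); 500 null replicates for type-I control of the
screen and 100 planted replicates for power; 2 000-patient cohorts for
frequency recovery within exact binomial 99% intervals. End-to-end
determinism is asserted byte-for-byte over two seeded runs; the JSON run
report carries md5 checksums and no timestamps.

## Known limitations

* The hallmark gene filter is only as good as the supplied annotation
  table; no gene list ships with the package.
* Greedy allele-set selection can miss the optimal genotypic-coverage set
  for a given size.
* Frameshift peptide enumeration depends on a caller-supplied novel tail;
  no transcript-level translation is attempted.
* Population coverage assumes Hardy–Weinberg proportions and independent
  loci; both are approximations for real HLA data.
* The shipped allele-frequency table is a synthetic stand-in shaped like
  curated population-database exports and should be replaced by real
  tables for any substantive analysis.
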