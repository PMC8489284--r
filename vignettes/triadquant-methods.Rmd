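---
title: "Homoeolog-aware proteomics and promoter haplotype analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homoeolog-aware proteomics and promoter haplotype analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadquant)
```

# Scope

Allohexaploid bread wheat carries three related subgenomes (A, B and D),
so most genes exist as a homoeolog triplet. When root proteins are
quantified under phosphate (Pi) starvation, two questions arise that
ordinary differential-abundance workflows do not answer: *which
homoeolog* produced each responsive protein, and whether expression
across a triplet is balanced. `triadquant` implements that
subgenome-resolved workflow — exact-identity peptide matching against an
A/B/D-partitioned protein database, homoeolog assignment, responsive-
protein calling from isobaric reporter intensities, and a balance test —
together with a promoter population-genetics arm (SNP calling,
nucleotide diversity, haplotype grouping, trait association, CAPS marker
design) and a synthetic-data generator that makes every stage testable
without external datasets.

# The proteomics arm

## Peptide-to-proteome matching

The identification criterion is 100% identity of the full-length
peptide, which for a peptide query is exactly substring matching:
`map_peptide()` reports every locus whose protein contains the peptide
verbatim. This removes any aligner dependency while reproducing the
intended criterion. Isoleucine and leucine are kept distinct by default
because the genomic database distinguishes them; since isobaric mass
spectrometry cannot, `index_proteome(collapse_il = TRUE)` offers the
I=L convention. Match specificity is classified as

* `locus_unique` — one locus contains the peptide;
* `family_shared` — several loci, all in one homoeolog family;
* `cross_family` — loci from two or more families;
* `unmatched`.

Adding sequences to the database can only move a peptide toward the more
shared classes, never back — a property the test suite checks against a
brute-force substring scan.

## Homoeolog assignment

A reported protein is assigned to specific homoeologs only on
`locus_unique` evidence: the assigned loci are the union of loci hit by
its unique peptides, required to lie in a single family (a cross-family
conflict excludes the protein with a warning). Proteins supported only
by family-shared peptides are reported `unassigned` — peptides that
cannot distinguish homoeologs cannot justify a subgenome-specific call,
even though the family itself may be known. This strict unique-peptide
rule is a design choice: an identification pipeline could instead trust
the search database identifier, but that would assign proteins on
evidence the peptides themselves do not carry.

The expression category is the set of assigned subgenomes (`A`, `B`,
`D`, `A+B`, `A+D`, `B+D`, `A+B+D`), and the bias flag separates three
situations: `single_bias` (one homoeolog expressed although the family
has others — homoeolog expression bias), `singleton` (the family has a
single gene, so no bias is possible), and `multi` (two or three
homoeologs expressed). Summary percentages use half-up rounding to one
decimal, the convention of the published tables (738/1015 → 72.7%,
62/1015 → 6.1%).

The chromosome distribution counts one per assigned locus, so an `A+D`
protein contributes to both its chromosomes. This is one plausible
reading of a locus-level summary over multi-homoeolog proteins; a
protein-level count would differ for those entries.

## Quantification and responsive-protein calling

Protein abundance per channel is the sum of reporter areas over the
protein's unique peptides. The per-protein NP/CK fold change is

$$ R = \frac{1}{r}\sum_{i=1}^{r} \frac{\mathrm{NP}_i}{\overline{\mathrm{CK}}} $$

the mean over treatment replicates of each NP channel against the
control-channel mean. No single definition of the per-protein ratio is
canonical for reporter data; this one is robust to single-channel noise
and reproduces planted fold changes exactly in the noise-free limit,
which the tests exploit.

Calling uses inclusive fold-change thresholds, up at ≥ 1.20 and down at
≤ 0.83 (≈ 1/1.20), with all six channels required to be positive
(`require_all_replicates`, mirroring detection in all three replicates
of both conditions). A two-sided pooled Student's *t*-test on log
abundances is always computed; by default it does not gate the call,
because the responsive set is defined by fold thresholds alone, but
`p_filter_enabled = TRUE` adds the `p < alpha` condition for
volcano-style filtering. Whether a significance gate was part of the
original 323-protein filter is not stated in the source material; both
behaviours are therefore supported, with the text's reading as default.

Channel normalisation (`total_sum` or `median`) removes per-channel
loading differences. Ratios and classes are invariant under global
rescaling of all channels, which the suite asserts.

## Homoeolog balance

For proteins expressed from 2–3 homoeologs, `test_balance()` runs a
one-way ANOVA across loci on log abundances (treatment channels by
default) and declares the family unbalanced at p < 0.05. The test was
not named in the source; one-way ANOVA handles two and three loci
uniformly and reduces exactly to the squared pooled *t*-test for two
groups, which the tests verify numerically. Families lacking unique-
peptide quantification for some contributing locus are reported
untestable rather than guessed. Whether raw or normalised areas feed the
test is unspecified upstream; the package applies it to whatever
`protein_quant` table it is given, normalised by default in
`run_demo()`.

# The statistics layer

`student_t()` and `one_way_anova()` wrap the base R implementations
(pooled-variance Student by default; Welch available). Degenerate
inputs follow fixed conventions: identical constant samples give t = 0,
p = 1; constant samples with unequal means give p = 0 (infinitely
significant on zero variance); all-identical ANOVA input gives F = 0,
p = 1.

`duncan_mrt()` implements Duncan's multiple range test because no
installed package provides it. Critical values are computed from the
studentized range distribution at Duncan's protection level
$1-(1-\alpha)^{p-1}$ for a stretch of $p$ ordered means (so any error
degrees of freedom work, with no lookup tables), with the harmonic mean
of group sizes in unbalanced designs, and the standard
stepwise rule that a stretch contained in a retained non-significant
stretch is not subdivided. Letters follow maximal non-significant
stretches; groups sharing no letter always span a significant Duncan
range (a property the tests enforce), while overlap chains are allowed
as usual.

# The population-genetics arm

## Coordinates and missing data

Promoter positions are ATG-relative: +1 is the A of ATG, upstream
positions are strictly negative, and there is no position 0. The
default gap/N policy is complete deletion — columns containing any gap
or N are excluded from both SNP calling and diversity — because it
gives a deterministic effective length; pairwise deletion is available.

## Nucleotide diversity

`nucleotide_diversity()` computes the Nei–Li average pairwise
difference,

$$ \pi = \frac{\sum_{i<j} d_{ij}}{\binom{n}{2}\, L_\mathrm{eff}} $$

with $d_{ij}$ the number of differing used columns. For a panel of
observed sequences this equals the frequency-weighted estimator on
haplotype data, stated here to avoid ambiguity. The implementation is
the definition itself; tests check it against an independently coded
brute-force oracle and against `ape::dist.dna` pairwise distances.

## Haplotypes, association, CAPS design

Sequences identical across variant sites share a haplotype; labels are
frequency-ordered (`Hap1` most frequent, ties by first occurrence), and
each pattern's SNP count against `Hap1` is reported — the reference-
haplotype convention of the published panel. Sequences with N at a
variant site are rescued only when compatible with exactly one observed
pattern, otherwise labelled ambiguous.

`haplotype_association()` is one-way ANOVA plus Duncan letters over
per-line trait values, the design used for four cultivars per haplotype;
haplotypes with fewer than two lines are excluded with a warning.

CAPS design scans amplicon alleles for restriction sites under IUPAC
expansion (degenerate codes expand to base sets; N in the *sequence*
never matches; overlapping sites all count; non-palindromic recognitions
are scanned on both strands). Sites present in exactly one allele become
candidate markers, each carrying both predicted digest patterns, sorted
by the smallest band-size difference between alleles as a gel-
resolvability proxy. Fragment sizes use top-strand cut positions only:
overhang geometry moves band edges by at most a few bases and never
changes the cut/uncut readout.

# The synthetic-data generator

The generator produces data with the statistical structure the analyses
assume, at the study's design points:

* **Proteome** — homoeolog triplet families (singletons at a configurable
  fraction, subgenome drawn uniformly), i.i.d. amino-acid substitutions
  between homoeologs at a tunable per-site divergence, family *i* on
  homoeologous group `(i-1) %% 7 + 1`. Defaults: divergence 0.05
  (enough for unique peptides to exist at typical protein lengths),
  singleton fraction 0.06 (matching the observed 6.1% singleton share),
  protein lengths 200–600 aa.
* **Reporter intensities** — 3 control + 3 treatment channels; locus
  baselines and peptide response weights log-normal; planted NP/CK fold
  changes; multiplicative log-normal channel noise parameterised by a
  coefficient of variation (default 0.1, a typical reporter-level
  spread). The noise is median-unbiased, so planted ratios are
  recovered exactly at cv = 0 — the anchor for the caller's calibration
  tests. Homoeolog expression bias is planted by restricting
  `expressed_loci`.
* **Promoter panel** — 62 sequences spanning −1513..+1, nine SNP
  positions (including −799 and −796) forming four haplotypes that
  differ from Hap1 by 6, 2 and 1 SNPs. Per-haplotype counts 30/14/10/8
  are a choice: the source reports which haplotypes exist but not their
  frequencies among the 62 cultivars, so a realistic skewed spectrum
  with the reference haplotype most frequent was fixed once.
* **CAPS amplicon** — a 703-bp allele pair in which the two diagnostic
  C/G SNPs sit inside (C alleles) or break (G alleles) a single Fnu4HI
  `GCNGC` site at offset 455, so digestion yields 457 + 246 bp versus
  one intact 703-bp band; stray sites are scrubbed deterministically.

Every generator is a pure function of its specification including the
seed (byte-identical reruns), checked by the suite.

What the generator does **not** emulate: spectrum-level effects
(missing peptides, interference, ratio compression), peptide
detectability models, within-subgenome paralogy beyond the permissive
loader mode, indels or recombination in the promoter panel, and
sequencing error. Passing tests therefore demonstrate correctness of
the analysis logic under the stated statistical assumptions, not
robustness to every artefact of real MS or Sanger data.

# Numerical and design choices

* Digestion defaults (tryptic, peptide length 6–50, no missed
  cleavages in simulation) are search-engine conventions, configurable
  everywhere they appear; the source does not report its settings.
* Percentages are rounded half away from zero to one decimal, matching
  the published style (base `round()` would give 72.7 but 0.2 for
  0.25).
* `translate_orf()` enforces a complete ORF (ATG start, length
  divisible by 3, exactly one terminal stop) and returns length/3 − 1
  residues; the minimal ORF `ATGTAA` yields `"M"`.
* Haplotype label ties break by first occurrence in the input, making
  labels deterministic under permutation up to that stated rule.
* p = 0 volcano coordinates are clipped to the smallest positive
  double before the log.

# Problem sizes used by the checks

The simulation-based checks run at 70 triplet families (≈ 210 loci,
comfortably above the 200-protein design point of the calibration
properties), 1000 simulated families for the balance-test false-positive
rate, and 2000 replicates for the null-uniformity KS check — sizes at
which the Monte-Carlo error of each property is far below its asserted
margin while the whole suite stays fast.

# Known limitations

* Protein inference is deliberately minimal (no parsimony grouping, no
  FDR): the assignment rules above are the entire model.
* The balance test assumes log-normal within-locus replicate noise;
  heavy-tailed reporter artefacts would inflate its false-positive
  rate.
* π on the synthetic panel reflects the chosen haplotype frequencies;
  it is the estimator, not the published panel, that is validated.
* The CAPS module predicts band patterns, not primer behaviour; primer
  design is out of scope.
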