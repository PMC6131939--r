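---
title: "Mapping-by-sequencing with simulated multi-parent populations: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping-by-sequencing with simulated multi-parent populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`tfsmap` re-creates, on synthetic data, the discovery of a recessive
herbicide-sensitivity allele: a 1-bp frameshift insertion found by
filtering skim-sequencing variants of a MAGIC population for perfect
concordance with the sensitive phenotype. This vignette is the package's
account of the models it implements, the defaults it chose where the design
was genuinely open, and what a passing test does and does not establish.

## The genetic model

Sensitivity is recessive: the tolerance allele encodes a functional
detoxifying P450, so one intact copy suffices. `assign_phenotypes()`
implements exactly this — sensitive iff homozygous for the disrupted
allele, with a penetrance parameter (default 1.0) for incomplete
expressivity. An F2 between a sensitive and a tolerant line therefore
segregates 3:1 tolerant:sensitive, which `chi_square_segregation()` tests
with the uncorrected Pearson statistic (the published worked example,
1255:440 against 3:1, gives 0.8309 only without the Yates correction;
the correction is available behind a flag).

## The simulator's stated world

The generator's defaults are the experimental design, not tuning knobs:

* **11 founders**, exactly one carrying the causal allele; non-causal sites
  are i.i.d. Bernoulli(maf = 0.3) per founder, redrawn if monomorphic.
  A founder-pair differs at a site with probability 2·f·(1−f).
* **Breeding**: half-diallel (55 F1 families), then 5 cycles of random
  mating in which each offspring takes a uniformly drawn seed parent and an
  independently drawn pollen parent — the literal reading of "bulked equal
  pollen", implying selfing at rate 1/N during the cycles — then 6
  generations of selfing by single-seed descent to 550 RILs. Heterozygosity
  halves per selfing generation, leaving (1/2)^6 ≈ 1.6% of the pre-selfing
  level.
* **Genetic map**: the source study publishes none, so the default is a
  single 60 Mb / 100 cM chromosome ("D10") with uniform recombination —
  upland-cotton chromosome scale without claiming real map data. Crossovers
  per chromosome are Poisson(genetic length in Morgans) with positions
  uniform in genetic coordinates and no interference, so two loci d Morgans
  apart recombine at Haldane's r = (1 − e^(−2d))/2. This is the simplest
  model consistent with the design and gives every test a closed form.
* **Observation**: depth Poisson (20x parents, 3x RILs), reads drawn from
  the individual's two alleles with per-read error e (default 0.001), and a
  naive caller — missing at depth 0, het iff both alleles seen. The
  caller's failure modes at 3x (about 5% missing cells; a het called
  homozygous with probability (1/2)^d) are precisely the stress the
  concordance filter must survive.
* **Sensitive-RIL count is emergent.** The study observed 20/550, well
  below the naive 1/11 expectation; simulated draws land around 30–60
  depending on seed and are never forced to 20. Tests require only
  "at least 20 sensitive".
* **Expression generator**: reference gene induced at ≥50 µM in the
  sensitive genotype and only at 3000 µM in the tolerant one (step profile,
  baseline 1, induced 8 in relative units); co-regulated genes share the
  profile up to a positive scale in [0.5, 2]; independent genes are flat;
  Gaussian replicate noise (SD 0.5, ~6% of the induced level) over 6
  replicates. Baseline/induced/noise are not printed in the source; they
  were fixed once at values giving a realistic ~10-fold induction with
  qPCR-like replicate scatter.

## The concordance filter and its missing-data semantics

A candidate site must have the sensitive parent hom-alt (a), every other
parent hom-ref (b), and every sensitive RIL hom-alt (c). In **permissive**
mode (the 3x default) a missing call never disqualifies: with 20+ sensitive
RILs at 3x, the chance that all are covered at a given site is only about
0.95^20 ≈ 0.36, so strict missing-handling would routinely discard the true
site. **Strict** mode (full-coverage data) lets any missing call
disqualify. Rule (a) is treated like the others for consistency: a missing
sensitive-parent call is compatible in permissive mode, though at 20x this
almost never occurs.

A heterozygous *sensitive* RIL always disqualifies a site: RILs are
near-fully inbred and a het sensitive RIL contradicts recessiveness.

**Tolerant-RIL exclusion (rule d)** — no tolerant RIL hom-alt — is kept
behind a flag, on by default in `filter_config()`. Two deliberate
deviations from a literal reading:

1. A heterozygous tolerant RIL never disqualifies, in either mode. Het
   carriers are tolerant *by construction* under a recessive trait, and
   residual RIL heterozygosity (~0.8% per site, i.e. a handful of carriers
   among 550 RILs at the causal site) would otherwise disqualify the true
   site at full coverage with near certainty.
2. Low-coverage discovery runs (`run_pipeline()` in permissive mode, and
   the recovery acceptance check) switch rule (d) off entirely: at 3x, a
   hom-alt call from a het carrier occurs with probability (1/2)^d per
   sample, so with a few carriers present the true causal site would be
   discarded in roughly 40% of runs. The underlying filter description
   ("unique to the sensitive parent and shared by all sensitive RILs")
   names only the sensitive set; tolerant hom-alt counts are still reported
   as per-site evidence so a user can apply their own judgement.

Recovery checks run the observation model with e = 0. With the naive
any-read caller, a 20x homozygous parent is miscalled het with probability
≈ 1 − (1 − e)^depth (about 2% at e = 0.001); across ten tolerant parents
plus the sensitive parent this alone loses the causal site in roughly a
fifth of runs, so "always recovers" is only a property of the e = 0 world.
The e > 0 default remains in place for ordinary use and is exercised by the
unit tests; robustness to *coverage*-driven miscalls (missingness,
het-to-hom undercalling) is fully retained at e = 0.

## Effect annotation

Variants are normalized before classification (shared-suffix then
shared-prefix trimming; anchored indels are additionally left-aligned when
a reference sequence is supplied), because an indel position is meaningful
only under a fixed normalization. Exon ordinals are counted in transcript
orientation (strand-aware); the frameshift decision is purely
(indel length mod 3) within the CDS. A variant whose altered bases cross an
exon–intron boundary is reported as the explicit category
`boundary_spanning` rather than silently misclassified. A pure insertion
whose anchor is the last base of an exon lands in the exon/intron joint and
is likewise boundary-spanning.

Pseudogene detection aligns a CDS to a homeologous region globally
(match +1, mismatch −1, linear gap −2 — only gap presence and mod-3 matter,
so the exact scheme is configurable) and reports every gap plus whether the
*net* indel length is ≡ 0 mod 3. Below 60% identity the verdict is "not
homologous" and no frameshift call is made. Alignment is delegated to
Biostrings and checked in the tests against an independent Needleman–Wunsch
implementation.

## VIGS window selection

All L − k + 1 k-mers (k = 21) of the target are compared against every
*other* transcript by pure Hamming distance (≤ 1 mismatch by default, no
indels), on both strands, since siRNA-mediated silencing is
orientation-independent (a `--stranded` flag disables this). k-mers
containing N are untestable and excluded from scoring. The selected window
minimizes the count of off-target-hitting k-mers fully inside it; ties go
to the leftmost window. Leftmost-minimal-count is this package's documented
rule — the original tool's tie-breaking is unspecified. The vectorized scan
is verified against a brute-force all-pairs oracle.

## Co-expression classification

Correlation is computed over condition means (2 genotypes × 5 doses = 10
points), not raw replicates: replicate pairing across genes is not defined
by the assay, and the published correlations describe expression *patterns*.
The classification rule is the single threshold r > 0.7; a joint rule
(r > τ and p < α) is available behind `require_significance` since the
source wording also mentions significance. Genes with constant profiles
have undefined r and form their own "constant" category outside both
classes. Whether the 0.7 cut was originally applied to means or replicates
is unknowable from the text; means are the documented choice here.

## Numerical and interface choices

* Coordinates are 1-based and closed; indels use VCF anchor-base
  representation; VCF 4.2 with GT:DP and `./.` for missing; GFF3 1-based
  closed; FASTA wrapped at 60 columns.
* All randomness in a pipeline run flows from one seed (stage seeds are
  drawn once from it); the seed is recorded in the VCF header, and
  identical seeds give byte-identical outputs.
* Chi-square verdicts use α = 0.05 and print "ns" for non-significant,
  mirroring conventional segregation tables. `fit_ratio_set()` breaks
  p-value ties toward fewer classes, then listed order.
* Sample/line counts (550 RILs, 1695 and 2145 F2, 384-cultivar panel with
  12 mutant cultivars, 9–23 plants per cultivar emulated as small pools)
  are the study design's sizes and are the defaults throughout.

## What a green test establishes — and what it does not

The synthetic world has uniform recombination, site-independent founder
alleles, no genotyping structure beyond Poisson depth and i.i.d. read
error, full penetrance by default, and a single causal locus with no
epistasis or selection. Passing tests establish that the *analysis logic*
is correct under the stated stochastic model — not that the pipeline would
perform identically on real skim data, which carries alignment artifacts,
allele-specific bias, population structure among founders, and segregation
distortion (the observed 20/550 sensitive RILs, against a naive ~50,
hints at exactly such unmodeled forces; the simulator deliberately does
not reproduce that deficit). Read-level simulation, alignment and
likelihood-based calling are out of scope by design: the naive caller makes
the filter's robustness measurable in closed form.
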