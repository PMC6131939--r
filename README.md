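# tfsmap

Mapping-by-sequencing of a recessive herbicide-sensitivity locus in
multi-parent cotton populations — as a fully simulated, tested pipeline.

## The problem

Most upland-cotton cultivars tolerate the sulfonylurea herbicide
trifloxysulfuron sodium (TFS); a few are killed by it. Tolerance behaves as
a single dominant locus, so sensitivity is recessive: only plants homozygous
for the disrupted allele die. The causal lesion is a 1-bp adenine insertion
in the third exon of a cytochrome P450 gene on chromosome D10 — a
frameshift that knocks out the detoxifying enzyme. Discovering such a
variant from skim sequencing of a MAGIC (multi-parent advanced generation
inter-cross) population is a filtering problem: find the polymorphism that
is unique to the one sensitive founder and shared by every sensitive
recombinant inbred line (RIL).

No sequencing data from the original study is deposited, so `tfsmap` ships
a first-class simulator of the whole experimental design and validates the
analysis against it:

* **popgen simulation** — 11 inbred founders with one planted causal
  insertion; a half-diallel (55 F1 families), 5 cycles of random mating by
  bulked pollen, 6 generations of selfing by single-seed descent to 550
  RILs; a biparental F2 of 2145; crossovers are Poisson with no
  interference (Haldane model).
* **genotype observation** — per-site read depth `d ~ Poisson(λ)` (20x
  parents, 3x RILs), per-read allele error `e`; missing at `d = 0`, het iff
  both alleles seen (a deliberately naive caller).
* **concordance filter** — a site is a candidate iff the sensitive parent
  is hom-alt, every other parent hom-ref, and every sensitive RIL hom-alt;
  permissive mode lets missing calls through (essential at 3x, where ~5% of
  calls are missing).
* **effect annotation** — exon/intron placement, strand-aware exon
  ordinals, CDS offset/codon, frameshift iff indel length mod 3 ≠ 0; plus
  homeolog pseudogene detection by global alignment.
* **segregation statistics** — Pearson chi-square against Mendelian ratios
  (`X² = Σ (O−E)²/E`, df = classes − 1).
* **VIGS design** — all `L − k + 1` 21-mers of a target CDS scanned against
  a transcriptome within Hamming distance 1 (both strands); the 350-bp
  window with fewest off-target k-mers is selected.
* **co-expression** — Pearson correlation of condition-mean dose-response
  profiles (2 genotypes × doses 0/12.5/50/100/3000 µM, 6 replicates)
  against a reference gene; co-induced iff `r > 0.7`.

## Worked example

```r
library(tfsmap)
rep <- run_pipeline(run_config(seed = 42, out_dir = "tfsmap_demo"))
```

```
[simulate] founders: 11 founders x 1000 sites
[simulate] MAGIC: 550 RILs (5 cycles, 6 selfing generations)
[simulate] 54 of 550 RILs sensitive
[observe] parents at 20x, RILs at 3x, error 0.001
[filter] concordance filter, permissive mode
[filter] 1 candidate(s); causal site retained
[annotate] causal variant: exonic_frameshift, exon 3
[simulate] F2: n = 2145
[segtest] F2 1627:518 vs 3:1 -> X2 = 0.828 (ns)
[concordance] 0 discordant of 2145 F2
```

```r
print(as.data.frame(rep$candidates))
#>   chrom      pos ref alt n_sens_hom_alt n_sens_missing n_other_parent_missing n_tol_hom_alt
#> 1   D10 28455988   A  AA             52              2                      0             1
```

Reading the output: out of 1000 simulated variant sites, the filter kept
exactly one — the planted `A → AA` insertion at D10:28,455,988. 52 of the
54 sensitive RILs were observed hom-alt there and 2 had no coverage
(permissive mode tolerates that); the single tolerant hom-alt call is a het
carrier miscalled at 3x, which is why tolerant-RIL exclusion is off by
default at low coverage. The variant annotates as a frameshift in exon 3,
the F2 segregates 1627:518 tolerant:sensitive (`X² = 0.83`, not significant
against 3:1 — the same statistic as the published count 1255:440), and the
marker is perfectly concordant with the phenotype in all 2145 F2.

The classic two-count test on its own:

```r
chi_square_segregation(c(1255, 440), c(3, 1))
#> X-squared = 0.8309, df = 1, p = 0.362 (ns) vs ratio 3:1
```

A command-line interface mirrors the stages
(`simulate`, `filter`, `annotate`, `segtest`, `vigs`, `coexpress`, `run`):

```sh
Rscript inst/cli/tfsmap.R segtest --observed 1255,440 --ratio 3,1
Rscript inst/cli/tfsmap.R vigs --target Gene1 --db transcripts.fasta --window 350
```

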