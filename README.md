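# gibeltx

Comparative transcriptome toolkit for a sexually reproducing diploid and a
unisexual (gynogenetic) triploid fish population — the diploid crucian carp /
triploid gibel carp system of the *Carassius auratus* complex.

Unisexual vertebrates usually arise by hybridisation, which elevates
heterozygosity; a triploid gynogen is expected to show *tri-allelic* variation
(genotype ABC) wherever hybrid heterozygosity was retained. This package
implements, as tested reusable functions, the comparative analyses that
characterise such a pair of populations from their transcript catalogs:

* **Transcript catalog** — longest-ORF protein-coding classification (intact
  ORF of at least 50 amino acids, the 150-nt rule) and collapse of putative
  splice variants sharing 100% identity over at least 100 bp.
* **Ortholog divergence dating** — reciprocal-best-hit orthologs (local
  alignment, mutual best hits aligned over ≥ 300 bp), codon alignments by
  protein back-threading, the Nei–Gojobori (1986) counting estimator
  (synonymous sites per codon, pathway-averaged differences, Jukes–Cantor
  correction `Ks = -3/4 ln(1 - 4/3 pS)`), Ks histograms in 0.002-wide bins,
  and molecular-clock dating `T = Ks_peak / r` with
  `r = 3.51e-9` synonymous substitutions per site per year.
* **Allele multiplicity** — polymorphic-site calling from read pileups at
  minimum coverage 5 with allele-support filters, classifying sites as mono-,
  di-, tri-allelic or higher; per-transcript diversity summaries.
* **Microsatellites** — perfect tandem repeats of unit 2–6 above repeat-count
  thresholds 8/5/5/5/5 with > 50 bp flanks on both sides; per-individual
  genotyping into homozygous / di-allelic / tri-allelic classes.
* **Expression statistics** — hypergeometric category over-representation,
  exact-test differential expression with Benjamini–Hochberg control (FDR
  0.001, minimum fold change 4), expression-pattern grouping, and relative
  qPCR quantification by the comparative Cq method (2^−ΔΔCq).
* **Synthetic data** — generators for every pipeline input with known ground
  truth: ortholog pairs evolved to a target Ks, triploid/diploid pileups from
  planted genotypes (AAA, AAB, ABC), transcripts with planted
  microsatellites, and count tables with planted fold changes.

## Worked example

Simulate a diverged ortholog pair with known truth, align it, estimate its
divergence, and date a Ks peak:

```r
library(gibeltx)

pair <- evolve_ortholog_pair(n_codons = 300, target_ks = 0.02,
                             omega = 0.1, seed = 42)
aln <- build_codon_alignment(pair$seq_a, pair$seq_b, "gibel_tx1", "crucian_tx1")
ng86_stats(aln)
#> NG86: S=232.92 N=667.08 Sd=3.00 Nd=3.00 pS=0.01288 pN=0.00450
#>       Ks=0.01299 Ka=0.00451 (300 codons)
pair$true_syn; pair$true_nonsyn
#> 3 synonymous and 3 nonsynonymous events were actually planted

date_divergence(0.008, 3.51e-9, mode_interval = c(0.006, 0.01))
#> divergence dating: peak Ks 0.008 / rate 3.51e-09 per year
#>   T = 2279202 years (2.2 million years)
#>   mode interval: 1.7 - 2.8 million years
```

The estimator recovers the planted synonymous divergence (3 planted events,
`Sd = 3.00`), and a Ks peak of 0.008 dates the hybridisation to 2.2 million
years ago (range 1.7–2.8 My from the histogram mode interval 0.006–0.01),
times reported in millions of years truncated to one decimal.

Allele-dosage classification from a simulated triploid pileup:

```r
gt <- random_genotypes(200, ploidy = 3, seed = 1)
sim <- simulate_pileup(gt, coverage = 60, error_rate = 0.005, seed = 2)
sites <- call_sites(sim$pileup, min_coverage = 5)
table(sites$class)
#>  di-allelic monomorphic tri-allelic
#>          60          73          67
```

## Command line

Every stage is also a CLI subcommand (`catalog`, `orthoks`, `date`,
`variants`, `ssr`, `enrich`, `deg`, `ddcq`, `simulate`), run through the thin
launcher in `inst/scripts/gibeltx`:

```sh
Rscript inst/scripts/gibeltx date --peak-ks 0.008 --rate 3.51e-9 --lo 0.006 --hi 0.01
Rscript inst/scripts/gibeltx simulate orthologs --n 100 --codons 500 --ks 0.008 --seed 1 --out sim
```

All outputs are TSV with a commented header recording the tool version and
parameters; all stochastic stages take explicit seeds.

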