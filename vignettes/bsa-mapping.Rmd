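---
title: "Mapping a recessive locus by bulk-segregant SNP-index analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a recessive locus by bulk-segregant SNP-index analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsamapr)
```

## The problem and the model

A recessive mutant (here the motivating case is an EMS-induced
yellow-virescent-leaf mutant of *Brassica napus*) is crossed to its
wild-type progenitor; the F1 is selfed. If the trait is controlled by a
single recessive nuclear gene, the F2 segregates 3 wild-type : 1 mutant,
and a backcross of the F1 to the mutant parent segregates 1:1. Both
expectations are tested with a df = 1 chi-square with Yates' continuity
correction,

$$\chi^2 = \sum_{i \in \{a,b\}} \frac{(\max(|O_i - E_i| - 0.5,\, 0))^2}{E_i},$$

the form customarily used for two-class segregation tables ("fits" when
$\chi^2 < 3.84$). An uncorrected mode (`correct = FALSE`) is provided; the
corrected statistic is never larger than the uncorrected one.

For mapping, two phenotype-extreme pools of F2 plants are whole-genome
sequenced: the mutant-like **Y pool** and the wild-type-like **G pool**.
At every site where the parents are opposite homozygotes, each pool's
**SNP-index** is the fraction of its reads carrying the mutant-parent
allele, and $\Delta = \mathrm{index}_Y - \mathrm{index}_G$. Selection acts
only at the causal locus: there the Y pool is fixed for the mutant allele
($\mathrm{index}_Y = 1$) while the G pool's genotypes are 1 AA : 2 Aa, so
$E[\mathrm{index}_G] = 1/3$ and $E[\Delta] = 2/3$. At unlinked loci both
pools sample the same 1:2:1 population and $E[\Delta] = 0$; between these
extremes $\Delta$ decays with the recombination fraction to the causal
locus. The scan therefore looks for a genomic interval where the windowed
mean $\Delta$ is too large to be sampling noise.

## Pipeline stages and tunable parameters

1. **Polarisation** (`polarize()`). Only sites where both parents are
   homozygous for different alleles are informative. "Homozygous" is
   operationalised as a minor-allele read fraction ≤ 0.1 (`hom_threshold`);
   there is no universal numeric convention, and at 20–30× parental depth a
   0.1 cut-off tolerates about two stray reads while rejecting
   heterozygous-looking sites. Alleles are re-oriented so *alt* is always
   the mutant-parent allele, making the Y-pool index directly interpretable
   as the mutant-allele frequency. Indel alleles are carried through
   identically to SNPs (`snps_only = TRUE` restricts to SNPs).

2. **Site filters** (`filter_sites()`). Sites with an index below 0.3 in
   *both* pools (`low_index`) are removed as uninformative background, and
   sites below 7 reads (`min_depth`) as too noisy. The depth rule is
   applied per pool — each pool must reach 7 reads — because an index
   estimated from fewer than 7 reads is meaningless in *either* pool;
   `depth_semantics = "summed"` switches to combined-depth semantics for
   users who read the rule the other way.

3. **Windows** (`sliding_windows()`). 1-Mb windows advanced in 10-kb steps
   (the field-standard defaults), anchored at position 1 on every
   chromosome. Window means are unweighted across member sites — the
   statistic is "the average of the SNP-indices", not a depth-weighted
   pooled estimate — so a handful of deep sites cannot dominate a window.
   Sites with zero depth in a pool have an undefined index and are excluded
   from window membership rather than imputed. Trailing windows truncated
   by the chromosome end keep their true shorter span and carry a
   `partial` flag.

4. **Significance** (`null_band()`, `call_candidate_regions()`). The
   motivating study reported its candidate interval without a printed
   threshold, so the package supplies the mechanism that is standard for
   this statistic: an empirical null band. For each tabulated depth, pool
   allele frequencies at an unlinked locus are resampled (each of
   $2 \times \mathrm{bulk\ size}$ allele copies an independent Bernoulli(½)
   draw for an F2), read counts are Binomial(depth, f), and the band is the
   two-sided empirical 95% (default; 99% also tabulated) quantile interval
   of $\Delta$. Windows whose mean $\Delta$ exceeds the upper bound at the
   window's mean pool depth are significant; overlapping or book-ended
   significant windows merge into maximal candidate regions. Comparing a
   window *mean* against a per-site band is conservative for false
   positives, which is the right direction for a region-calling screen.

5. **Fine mapping** (`map_interval()`). In a panel of mutant-phenotype
   (hence homozygous-mutant) individuals, any marker genotype that is not
   homozygous-mutant records a recombination between marker and locus.
   Both heterozygous and homozygous-wild-type calls count as recombinants;
   missing genotypes are ignored. The locus is confined between the
   innermost markers on each side of the zero-recombinant core that still
   show recombinants; a side with no recombinant marker is flagged as an
   open flank rather than silently clamped.

6. **Variant characterisation** (`annotate_snp_effect()`, `caps_scan()`).
   Effects are computed on CDS coordinates with the standard genetic code
   (genomic positions project through the exon structure;
   intronic/UTR positions classify as `non-coding` rather than erroring).
   For a nonsense change at codon $c$ of an $L$-residue protein the
   truncation length is defined as $L - (c - 1)$: the stop codon itself and
   everything downstream. CAPS detection finds all occurrences of the
   recognition sequence (IUPAC codes honoured, overlapping occurrences
   counted, the reverse-complement orientation scanned automatically when
   the recognition is not palindromic) in the reference and substituted
   amplicons and classifies the variant by the occurrences overlapping it.

## What the generator simulates — and what it does not

`simulate_bsa_experiment()` produces data with exactly the statistical
structure the analysis assumes:

* **Meiosis**: crossovers per chromosome are Poisson with mean equal to the
  map length in Morgans, positions uniform, no interference (Haldane's
  model). No genetic map accompanies the motivating study, so a uniform
  2.5 cM/Mb is used — the ballpark of published *B. napus* maps
  (~2000–2500 cM over ~850 Mb).
* **Phenotype**: single recessive locus, complete penetrance; a
  `misclass_rate` parameter exists but defaults to 0, since visually scored
  leaf-colour classes in the emulated design were clean.
* **Bulks**: `bulk_size` individuals (default 30 per pool) drawn uniformly
  at random from each phenotype class. How the original experimenters chose
  among eligible plants is not recorded; uniform sampling is the neutral
  choice and does not affect the pool allele-frequency distribution under
  complete penetrance.
* **Sequencing**: per-site pool depth Poisson with mean 25 (between the
  ~27× and ~30× pool depths of the emulated experiment), and alt reads
  Binomial(depth, $f(1-\varepsilon) + (1-f)\varepsilon$) with
  $\varepsilon = 0.001$ — an Illumina-scale per-read error.
* **Scale**: the default fixture genome is 3 chromosomes × 10 Mb with one
  SNP per 10 kb (~3,000 sites), a deliberate desk-scale reduction of a
  19-chromosome, ~180,000-SNP experiment; the default population is an F2
  of 927 with the causal locus at A03:2,500,000.

It does **not** simulate reads (depths are drawn directly — no alignment
or mapping-bias artefacts), library or GC biases, paralogous mis-mapping,
structural variation, or more than one causal locus. Passing tests
therefore demonstrate that the *statistics and algorithms* behave correctly
on data satisfying the model's assumptions, not that any particular real
dataset satisfies them.

A consequence of the scale reduction worth knowing: at 2.5 cM/Mb a 10-Mb
chromosome is only ~25 cM, so linkage to a central causal locus is strong
everywhere on that chromosome and the called candidate region typically
spans most of it. That is the correct behaviour at these parameters — the
interval *contains* the locus — and region *width* is governed by genome
scale and recombination, which is why recovery (containment) rather than
interval width is the property checked.

## Numerical and design choices

* All randomness flows from one integer master seed through
  `split_seed()`, which derives independent sub-seeds per stage; the same
  seed reproduces a byte-identical variant table.
* Coordinates are 1-based inclusive (VCF convention) internally; window
  ends are half-open; BED export converts to 0-based half-open.
* Zero-depth sites yield `NA` indices and are excluded, never imputed.
* The chi-square p-value is the df = 1 upper tail; the 3.84 verdict
  threshold is `qchisq(0.95, 1)`.
* Ties in the fine-mapping panel: if *no* marker co-segregates perfectly,
  the markers with the fewest recombinants act as the core.
* Problem sizes in the shipped checks: 100 seeded replicates of the full
  default experiment for region recovery, 100 seeded 21-marker panels of
  400 F2 plants for fine-mapping containment, 10,000-simulation null
  bands, and 1,000-case oracle comparisons for windows, effect annotation
  and restriction-site scanning.

## A complete run

```{r, eval = FALSE}
ex <- simulate_bsa_experiment(design = cross_design("F2", 500), seed = 42)
band <- null_band(30, 30, seed = 42)
scan <- bsa_scan(ex$variants, band = band,
                 chrom_lengths = c(A01 = 1e7, A02 = 1e7, A03 = 1e7))
scan$regions
plot_snp_index(scan$windows, band = band, regions = scan$regions)

# segregation of the phenotype classes
tidy(chi_square_segregation(719, 208, ratio = c(3, 1)))

# fine mapping on the mutant plants
mk <- genotype_markers(ex$population,
                       tibble::tibble(chrom = "A03",
                                      pos = seq(15e5, 35e5, by = 1e5)))
map_interval(mk)
```

## Known limitations

* One biallelic causal locus, fully penetrant; no quantitative or
  multi-locus architectures.
* Multi-allelic VCF records are skipped (with a logged count), not
  decomposed.
* The null band conditions on depth but assumes free segregation in the
  bulks; segregation distortion would shift it.
* No alternative smoothing (loess/tricube) or test statistics
  (G-statistic, Fisher exact); the SNP-index with an empirical band is the
  single supported method.
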