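# bsamapr

Map a single recessive mutation from pooled whole-genome sequencing of a
segregating plant population — and test every step of that pipeline against
simulated data with known truth.

`bsamapr` is an R implementation of the bulked-segregant-analysis (BSA-seq)
workflow used to clone recessive mutants in crops such as *Brassica napus*:
two parents (a wild-type line and an EMS-derived mutant) are crossed, the F2
segregates 3:1, and two phenotype-extreme pools of 30 plants each (the
wild-type-like "G" pool and the mutant-like "Y" pool) are whole-genome
sequenced. For every parent-polymorphic SNP the package computes the
**SNP-index** of each pool — the fraction of reads carrying the
mutant-parent allele,

```
SNP-index = alt reads / (ref reads + alt reads)
```

and the **ΔSNP-index = index(Y) − index(G)**. At loci unlinked to the
causal gene E[Δ] = 0; at the causal locus of a recessive trait the Y pool is
fixed (index 1) while the G pool segregates 1 AA : 2 Aa (expected index
1/3), so E[Δ] = 2/3. Sites are filtered by the standard rules (drop sites
with index < 0.3 in *both* pools or depth < 7), averaged in 1-Mb windows
advanced by 10-kb steps, and windows exceeding a simulation-based null band
are merged into candidate regions. Around the core statistic the package
provides:

* a **synthetic-data generator** (Haldane crossover model, recessive
  phenotype assignment, phenotype-selected bulks, binomial read sampling)
  emitting VCF + truth files, so the whole pipeline is testable end to end;
* **Mendelian segregation χ² tests** (Yates-corrected, df = 1) for 3:1 / 1:1
  phenotype ratios, with broom-style `tidy()`/`glance()`;
* **fine mapping**: recombinant-driven interval narrowing between flanking
  markers in a homozygous-mutant panel;
* **variant characterisation**: codon-level effect annotation (synonymous /
  missense / nonsense with truncation length) and **CAPS marker** detection
  (restriction-site gain/loss, e.g. Bln I `CCTAGG`, IUPAC-aware).

## Worked example

```r
library(bsamapr)

# a synthetic F2 bulk-segregant experiment: 3 x 10 Mb genome, recessive
# locus at A03:2,500,000, bulks of 30, ~25x pooled depth
ex <- simulate_bsa_experiment(design = cross_design("F2", 500), seed = 42)
band <- null_band(30, 30, seed = 42)
scan <- bsa_scan(ex$variants, band = band,
                 chrom_lengths = c(A01 = 1e7, A02 = 1e7, A03 = 1e7))
scan$regions
#> # A tibble: 1 × 5
#>   chrom start      end peak_delta n_windows
#>   <chr> <int>    <int>      <dbl>     <int>
#> 1 A03       1 10000001      0.667      1000
```

The scan calls a single candidate region, on the chromosome carrying the
simulated locus; its peak window's mean ΔSNP-index (0.667) sits at the
theoretical 2/3 for a recessive F2 design. (On this desk-scale genome a
10-Mb chromosome is only ~25 cM, so the significant region spans most of
the chromosome; `plot_snp_index(scan$windows, band, scan$regions)` draws
the three tracks.)

```r
chi_square_segregation(719, 208, ratio = c(3, 1), cross = "ZS9 x yvl F2")
#> Segregation test (ZS9 x yvl F2): 719 : 208 vs 3:1 -> chi2 = 3.11 (df 1), P = 0.078 [fits]
```

A 719 : 208 F2 phenotype ratio is consistent with 3:1 — a single recessive
nuclear gene.

```r
gmod <- gene_model("BnaA03g04440D-like", "+",
                   tibble::tibble(start = 1, end = 4143),
                   cds = paste(c("ATG", rep("GCT", 1369), "CAA",
                                 rep("GCT", 10)), collapse = ""))
annotate_snp_effect(gmod, codon_index = 1371, offset = 1,
                    ref_base = "C", alt_base = "T")
#> # A tibble: 1 × 8
#>   gene_id  codon_index ref_codon alt_codon ref_residue alt_residue class    residues_lost
#>   <chr>          <int> <chr>     <chr>     <chr>       <chr>       <chr>            <int>
#> 1 BnaA03g…        1371 CAA       TAA       Q           *           nonsense            11

caps_scan("GAGGACCCAGGTTTGA", 8, "C", "T")
#> <caps_result> BlnI (CCTAGG, palindromic): gain  [ref sites: 0, alt sites: 1]
```

On a synthetic 1381-codon gene, a C→T transition at codon 1371 creates a
premature stop truncating the last 11 residues, and the same class of
substitution converts `CCCAGG` into a Bln I site (`CCTAGG`) — a CAPS marker
genotypable by restriction digestion.

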