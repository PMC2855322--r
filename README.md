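# nucorg

Quantitative analysis of nuclear organization in budding yeast: where a
gene sits relative to the nuclear envelope, where chromatin factors bind
along chromosomes, and how their loss changes the transcriptome. The
package is aimed at groups running lacO/GFP locus-tracking assays,
tiling-array ChIP experiments, or small replicate expression studies who
need the corresponding statistics as tested, scriptable building blocks
rather than spreadsheet arithmetic.

It implements three analysis stages plus seeded simulators, so every stage
runs end to end without any external data:

1. **Three-zone position assay.** A spot's position is the
   spot-to-envelope distance divided by the nuclear diameter, measured in
   the focal plane where the GFP signal is brightest. The unit-diameter
   cross-section is split into three concentric zones of equal area with
   boundaries

   b₁ = (1 − √(2/3))/2 ≈ 0.0918  and  b₂ = (1 − √(1/3))/2 ≈ 0.2113,

   so uniform (random) positioning predicts 33% per zone. Observed counts
   (n₁, n₂, n₃) are tested against the uniform null with Pearson's χ² on 2
   df (for which p = exp(−χ²/2)); two conditions are compared by a 2×3 χ²
   test of homogeneity. Colocalization with clustered nuclear pores is an
   exact two-sided binomial test of k overlapping cells out of n against
   the random expectation p₀ = 0.09.

2. **Tiling ChIP binding calls.** Each array locus (300 bp or 100 bp)
   carries 11 probe log2 IP/input ratios. Binding is called with an exact
   one-sided Wilcoxon signed-rank test against zero — the null obtained by
   full enumeration of all 2ⁿ sign assignments — and a locus is positive
   when the upper-tail p < 0.025. On top of the calls: maximal runs of ≥ 2
   contiguous positive loci (clusters), the top-10 peaks with signal log
   ratio > 0.8, per-chromosome coincidence tables between two factors,
   positive-locus counts in terminal 10-kb subtelomere zones, paired-signal
   rank correlations, and promoter/ORF context classification from GFF3
   annotations.

3. **Differential expression.** Per-gene two-sample t-tests on replicate
   log2 intensities (mutant vs wild type, ≥ 3 replicates each), significance
   at raw p < 0.05, "changed" at ≥ 1.25-fold (|log2 ratio| ≥ log2 1.25,
   inclusive), up/down set classification, integer-rounded Venn overlaps,
   ranked top tables with the parenthesis convention for non-significant
   partner ratios, and gene-class (e.g. ribosomal protein) effect summaries.

## Worked example

```r
library(nucorg)

# --- zone assay on simulated spots (peripheral enrichment planted) -------
spots  <- simulate_spots(spot_sim_config(n_cells = 200,
                                         zone_probs = c(0.49, 0.30, 0.21),
                                         seed = 42))
counts <- tabulate_zones(spots, group_by = "stage")
counts
#>   group z1 z2 z3   n
#> 1    G1 44 44 23 111
#> 2     S 45 25 19  89
zone_test_random(counts[1, ])
#> Zone chi-squared test (observed vs uniform random)
#>   zone%: 39.6 / 39.6 / 20.7
#>   chi2 = 7.946, df = 2, p = 0.01882

coloc_test(72, 322)   # clustered-pore overlap, random expectation 9%
#> Colocalization: 72/322 cells = 22.4% (random expectation 9%), exact binomial p = 5.51e-13

# --- binding calls on a simulated 413-locus chromosome arm ---------------
sim   <- simulate_tiling(tiling_sim_config(
           data.frame(chrom = "chr6R", length = 124000), seed = 42))
trk_a <- call_track(sim$probes_a, factor_label = "Arp6")
trk_b <- call_track(sim$probes_b, factor_label = "Swr1")
coincidence_table(trk_a, trk_b)
#> Factor coincidence by chromosome (counts, % in parentheses)
#>  chrom detectable a_positive  a_and_b
#>  chr6R        413  110 (27%) 82 (75%)
#>  Total        413  110 (27%) 82 (75%)
```

The zone table says that in G1 cells 39.6% of spots sit in the outermost
zone versus the 33% random line, a departure from uniformity at p ≈ 0.019;
the colocalization line says 22.4% complete overlap where 9% is expected
by chance. The coincidence table reads: of 413 detectable loci, 110 (27%)
were called positive for factor A, and 82 of those 110 (75%) were also
positive for factor B.

The full demo pipeline (all three stages, outputs as TSV/BED/JSON with a
config hash stamped in each header) is one call:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "demo_out"))
```

or from a shell, `Rscript inst/scripts/nucorg.R run --seed 1 --out-dir demo_out`.

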