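# duplexmask

Weak/strong base-pair mask analysis of peptide–dsDNA binding specificity.

## The problem

Short regulatory tripeptides such as **EDR** (Glu-Asp-Arg) and **KED**
(Lys-Glu-Asp) bind in the minor groove of B-form DNA, where an A:T pair is
nearly indistinguishable from T:A and G:C from C:G. The working hypothesis
is that such peptides recognise the sequence of *base-pair classes* rather
than either strand's base sequence: weak pairs (A:T/T:A, IUPAC `W`) versus
strong pairs (G:C/C:G, IUPAC `S`). The W/S string of a duplex is its
**mask**.

`duplexmask` implements the full downstream analysis for this hypothesis,
for anyone with per-duplex affinity scores (docking output or otherwise):

- **Duplex space.** A strand and its reverse complement are the same
  molecule, so the unique double-stranded k-mer space has
  `(4^k + 4^(k/2))/2` members for even k — **2080** hexanucleotide
  duplexes, enumerated by `enumerate_duplexes(6)` under a lexicographic
  canonical representative.
- **Mask aggregation.** `summarize_by_mask()` clusters a score table by
  mask (count, mean, SD, best score, best sequence per cluster);
  `best_complex()` and `compare_peptides()` extract each peptide's
  strongest complex and the cross-peptide contrast. Two independent
  uniform masks of length k coincide with probability `(1/2)^k`
  (`coincidence_probability(6)` = 0.015625 ≈ 0.0156), which is what makes
  a *shared* best mask between two peptides informative.
- **Promoter scanning.** `scan_promoters()` counts exact words and
  degenerate W/S masks in gene promoters across the four
  strand/orientation variants (original, complement, reverse, reverse
  complement), with overlapping matches and per-variant reporting.
- **Synthetic data with ground truth.** A calibrated linear score
  simulator (`simulate_scores()`: intercept + GC slope + optional mask
  offsets + Gaussian noise) stands in for the docking engine, and
  `generate_promoter()` builds promoters with *verified* planted motif
  counts. Packaged, checksummed transcriptions of published per-mask
  docking summaries for EDR and KED (48 mask clusters each) and of a
  promoter-occurrence reference are available via `load_fixtures()`.

## Worked example

```r
library(duplexmask)

# the unique hexanucleotide duplex space
nrow(enumerate_duplexes(6))
#> [1] 2080

# the published screen, aggregated: best complexes and the EDR advantage
fx <- load_fixtures()
compare_peptides(fx$table1_edr, fx$table1_ked)
#> Peptide comparison: EDR vs KED
#>   shared masks: 48
#>   best complexes: GAGTGG (-44.71, mask SWSWSS) vs CAGAGG (-26.56, mask SWSWSS)
#>   best masks identical: TRUE
#>   mean difference (a - b): median -21.70 over shared masks

coincidence_probability(6, rounded = TRUE)
#> [1] 0.0156

# simulate a complete EDR-like score table and recover its GC trend
tab <- simulate_scores(edr_score_params(seed = 1), enumerate_duplexes(6), "EDR")
fit <- fit_gc_slope(tab)
c(slope = fit$estimate, se = fit$se)
#>       slope          se
#> -0.95644920  0.04611716

# a synthetic promoter carrying GAGTGG exactly 3 times, then scanned
gp <- generate_promoter(600, plants = list(plant_spec("GAGTGG", 3)),
                        seed = 11, gene = "GAP43")
scan_promoters(list(needle("GAGTGG"), needle("SWSWSS", "mask")), gp$record)
#>   needle_label  gene original complement reverse reverse_complement total
#> 1       GAGTGG GAP43        3          0       0                  0     3
#> 2       SWSWSS GAP43       10         10      12                 12    44
```

Reading the output: both peptides' best complexes carry the same mask
`SWSWSS` (a 1-in-64 coincidence if masks were random), EDR binds more
strongly than KED in every shared mask cluster, the recovered GC slope
matches the calibration (−0.925) within its standard error, and the
scanner returns the planted exact count while the degenerate mask —
matching 1 window in 64 by chance — accumulates background hits on all
four variants.

`run_all(run_config(out_dir = "results/run1", seed = 1))` executes the
whole pipeline (enumerate → score → summarize → compare → scan) into one
directory; a command-line front end with the same stages ships at
`system.file("scripts", "duplexmask.R", package = "duplexmask")`.

See `vignettes/mask-specificity.Rmd` for the model, conventions and
limitations in full.

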