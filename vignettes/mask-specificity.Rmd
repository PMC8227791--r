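---
title: "Weak/strong mask analysis of peptide-dsDNA binding specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak/strong mask analysis of peptide-dsDNA binding specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexmask)
```

## The question the package addresses

Short regulatory tripeptides such as EDR (Glu-Asp-Arg) and KED
(Lys-Glu-Asp) bind in the minor groove of B-form double-stranded DNA. In
the minor groove the hydrogen-bonding faces of an A:T pair and a T:A pair
are nearly indistinguishable, as are G:C and C:G. A natural hypothesis is
therefore that such peptides do not read a *strand sequence* at all but a
sequence of *base-pair classes*: weak pairs (A:T or T:A, two hydrogen
bonds, IUPAC code `W`) versus strong pairs (G:C or C:G, three hydrogen
bonds, IUPAC code `S`). We call the W/S string of a duplex its **mask**.

`duplexmask` provides the complete downstream analysis for testing this
hypothesis against per-duplex affinity scores (e.g. from docking):

1. enumerate the space of unique double-stranded k-mers,
2. attach one affinity score per duplex (loaded, or simulated from a
   calibrated generative stand-in),
3. cluster scores by mask and summarize each cluster,
4. compare two peptides' mask preferences and quantify how unlikely a
   chance coincidence of their best masks would be, and
5. scan gene promoter sequences for the best-binding words and masks
   across the four strand/orientation variants.

The docking computation itself is out of scope: affinity scores are an
*input*. Everything else runs end to end with no external data.

## The duplex space

A DNA duplex of length k is written two ways: a strand and its reverse
complement. We choose as canonical representative the lexicographically
smaller of the two under `A < C < G < T` — the convention of standard
k-mer tooling, deterministic and total. Reverse-complement palindromes
(strands equal to their own reverse complement, possible only for even k)
have a single written form, so the number of distinct duplexes is

$$N(k) = \begin{cases} (4^k + 4^{k/2})/2 & k \text{ even}\\ 4^k/2 & k \text{ odd,}\end{cases}$$

which gives `r duplex_space_size(6)` unique hexanucleotide duplexes
(including `r as.integer(4^3)` palindromes). `enumerate_duplexes()`
materialises all `4^k` strands and collapses them through
`canonicalize()`; the test suite checks the result against a brute-force
oracle built on an independent reverse-complement implementation, for set
equality and not just cardinality.

Scores always attach to the *duplex* (canonical identity), never to the
written strand. Ingesting a table that lists both `GAGTGG` and `CCACTC`
is a hard error: they are the same molecule.

When short duplexes are modelled inside a longer B-form helix they are
conventionally embedded between A/T-only flanks (a hexamer between four
A/T pairs on each side gives a 14-mer). "A/T base pair" does not fix
which base sits on the written strand, so `embed_in_flanks()` defaults to
the alternating written pattern `ATAT` and accepts any A/T-only override
(`AAAA`, `TTAA`, ...). This is an explicit convention, not a claim about
how any particular study built its constructs.

## The synthetic score model

Real docking scores for all 2080 hexamer duplexes come from commercial
engines and long compute runs; to keep every downstream stage testable
with known ground truth, `simulate_scores()` provides a declared
generative stand-in:

$$\mathrm{score}_i = \beta_0 + \beta_{GC}\,g_i + m(\mathrm{mask}_i) + \varepsilon_i,
\qquad \varepsilon_i \sim \mathcal{N}(0, \sigma^2),$$

where $g_i$ is the G+C count of duplex $i$, $m(\cdot)$ is an optional
per-mask offset (default zero), and lower scores mean stronger predicted
binding. The model encodes the robust qualitative feature of the real
screens — GC-richer duplexes bind these tripeptides more strongly — and
nothing else.

The shipped calibrations are anchored to the two extreme mask clusters of
the packaged reference summaries (see below):

* **EDR-like** (`edr_score_params()`): $\beta_0 = -31.76$ (the all-weak
  `WWWWWW` cluster mean), $\beta_{GC} = (-37.31 + 31.76)/6 = -0.925$ per
  G/C base (the all-strong/all-weak contrast spread over six positions),
  $\sigma = 2.5$, the magnitude of the printed per-cluster standard
  deviations (≈ 1.9–3.5).
* **KED-like** (`ked_score_params()`): the same two-anchor construction
  applied to the KED column, $\beta_0 = -12.50$,
  $\beta_{GC} = -0.28/6 \approx -0.047$ (the KED GC trend is an order of
  magnitude weaker than EDR's), $\sigma = 3.4$ (midrange of the KED
  cluster SDs).

Noise is Gaussian and homoscedastic — the simplest model consistent with
the printed dispersions; nothing downstream depends on that choice.
`fit_gc_slope()` (ordinary least squares of score on G+C count) closes
the loop: with $\sigma = 0$ it recovers $\beta_{GC}$ exactly, and across
20 seeds at n = 2080 the estimates scatter around the true slope with
the analytic OLS standard error (≈ 0.045). Simulation uses a private,
seeded RNG stream and never perturbs the caller's random state.

## Mask aggregation

`summarize_by_mask()` groups a score table by mask and reports, per
cluster: member count, mean, standard deviation, best (minimum) score and
the written strand achieving it. Numerical conventions, chosen once:

* **Keying.** A length-6 duplex's canonical strand realises all 64 W/S
  masks across the duplex space, but externally produced tables key
  clusters by whatever strand the scoring engine reported, which need not
  be canonical. Both policies are exposed: `keying = "canonical"`
  (deterministic; the default for simulated tables) and
  `keying = "as_written"` (reproduces the layout of external tables,
  which is also why the packaged reference summaries have 48 mask rows
  per peptide rather than 64 — the mask inventory there reflects the
  strands the engine happened to report).
* **Standard deviation** is the sample definition (n − 1); singleton
  clusters report 0. The alternative (population, n) is indistinguishable
  without the per-sequence scores, which are not published for the
  reference screens.
* **Ties** at the best score are broken by the lexicographically smallest
  sequence and reported via `message()`, so results are deterministic and
  the tie is visible.
* **Sorting** is by cluster mean ascending, ties by mask, so the
  strongest-binding cluster is always the first row and output files are
  byte-stable.
* Conservation is asserted on every run: cluster sizes must sum to the
  input record count.

`compare_peptides()` reports, for two peptides, the per-mask difference
of cluster means and whether the two global best complexes share a mask.
The probability that two independent uniform masks of length k coincide
is $(1/2)^k$ — `coincidence_probability(6)` = 0.015625, reported to four
decimals as 0.0156 — which is what makes a shared best mask for two
different peptides noteworthy rather than expected.

## Packaged reference tables

`load_fixtures()` returns hand-transcribed summaries of a published
docking screen of the EDR and KED tripeptides against all 2080 hexamer
duplexes (48 mask clusters per peptide: mean and SD of the score, best
score, best sequence), together with a reference table of promoter
occurrence counts for an Alzheimer's-disease gene panel (CASP3, TP53,
SOD2, GPX1, PPARA, PPARG, NES, GAP43, SUMO1, APOE, IGF1). These
transcriptions are *data*, shipped with md5 checksums verified on load;
the package never recomputes them (the docking engine and the promoter
database version behind them are not available). On these tables the
package's aggregation reproduces the published headline result: best EDR
complex `GAGTGG` at −44.71 and best KED complex `CAGAGG` at −26.56, both
with mask `SWSWSS`, with EDR stronger than KED in every one of the 48
shared mask clusters.

One transcription note: a sign was restored on one occurrence-table mean
(−37.89) whose printed source dropped it; the value matches the
corresponding per-mask summary row.

## Promoter scanning

`scan_promoters()` counts needles — exact words, or degenerate W/S masks
where `W` matches A/T and `S` matches C/G — in every promoter. For each
promoter the four variants are compiled (`compile_variants()`): the
written strand, its complement, its reverse and its reverse complement.
Only the original and reverse complement are genuine 5'→3' reading
frames; the other two are nevertheless compiled because the four-variant
convention is how such searches have been described, and
`scan_policy(variants = "biological")` restricts to the two real frames
when that is wanted. Note that for a reverse-complement palindrome the
four variants collapse to two (complement and reverse coincide exactly
when a strand equals its own reverse complement), so the default totals
count each *distinct* variant string once (`dedup = TRUE`).

The counting convention (not fixed by any external standard): matches may
**overlap**, totals are sums over deduplicated variants, and the
per-variant breakdown is always emitted so any other convention can be
read off the report. Windows overlapping an `N` never match. Counting is
a vectorised positionwise set-membership sweep; the tests pin it to a
naive character-by-character sliding window and, independently, to
IUPAC-aware `Biostrings` matching.

On an i.i.d. uniform background each window matches a fixed hexamer mask
with probability $(1/2)^6$, so a strand of length L carries
$(L-5)/64$ expected mask hits — the same arithmetic as the coincidence
probability. The acceptance tests verify the scanner reproduces this
rate over 200 simulated 600-bp promoters.

## Synthetic promoters with planted ground truth

`generate_promoter()` draws an i.i.d. background at a chosen GC fraction
(default 0.5 — typical of GC-enriched human promoter windows, and the
composition under which W and S are equiprobable), writes each requested
plant at non-overlapping positions (on any of the four variants, via the
inverse transform), then **verifies with the occurrence counter that the
total count of each planted needle over the deduplicated variants equals
exactly the planted count**, redrawing the background up to 100 times
otherwise. Rejection sampling is simpler than constructive avoidance and
adequate at promoter scale for hexamer needles (a specific hexamer
appears by chance ≈ 0.6 times per 600-bp promoter across variants, so
most draws verify). For much shorter words, exact-count verification
becomes infeasible — by design: the generator refuses rather than emit a
promoter whose ground truth it cannot certify.

What the generator emulates: length, GC composition and known motif
counts. What it does not emulate: CpG islands, repeats, TATA/Inr
elements, positional bias of real promoters. Passing tests therefore
demonstrate the *counting machinery* is exact, not that any particular
biological promoter carries a given motif count.

`make_demo_bundle()` ties everything together: simulated EDR-like and
KED-like score tables over all 2080 duplexes, their summaries, 11
synthetic promoters named after the gene panel with planted counts 0–3,
the scan report and a JSON manifest — self-checked against the manifest
before returning, and byte-identical across runs with the same seed.

## Orchestration and determinism

`run_config()` + `run_all()` execute enumerate → score → summarize →
compare → scan and write every stage output, the serialized config and a
run log into one directory. Primary outputs are byte-identical for a
fixed config and seed; only the log carries timestamps. A thin command
line front end over the same functions ships at
`system.file("scripts", "duplexmask.R", package = "duplexmask")`.

Problem sizes used throughout the tests and the acceptance script — the
full 2080-duplex space, 20-seed parameter recovery, 11 promoters of
600 bp, 200 background simulations, 100-case scanner/oracle sweeps — are
the scales at which the analysis is actually run; all complete in
seconds.

## Known limitations

* The synthetic score model is linear in GC with optional mask offsets;
  it is a stand-in for testing the pipeline, not a physical model of
  minor-groove recognition.
* The packaged occurrence reference depends on an unspecified promoter
  database version and window; it is shipped for orientation, not
  asserted as reproducible, and whether such counts reflect
  exact-sequence or degenerate-mask matching is ambiguous — both needle
  kinds are provided.
* Canonical-strand masks and written-strand masks differ; users ingesting
  external tables should choose `keying` consciously (the default for
  files is the table's own written strands only if requested —
  simulated-table summaries default to canonical keying).
* Enumeration materialises `4^k` strands and is capped at k = 10 by
  default; the analysis itself targets k ≈ 6.

```{r session, eval = FALSE}
sessionInfo()
```
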