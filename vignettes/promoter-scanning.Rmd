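---
title: "Scoring promoters for transcription factor binding: the model behind promscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring promoters for transcription factor binding: the model behind promscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promscan)
```

## The problem

A transcription factor such as Pea3/ETV4 recognises short, degenerate DNA
motifs — for ETS-family factors, a GGAA/T core flanked by weakly preferred
bases. Candidate target genes are screened *in silico* by scanning each
gene's promoter (a window anchored at the transcription start site, TSS)
for subsequences that resemble the factor's position weight matrix (PWM),
and the survivors are verified at the bench by qPCR, expression profiling
and chromatin immunoprecipitation. promscan implements that whole loop as
composable, testable functions: promoter extraction, PWM scanning with a
dissimilarity-rate score, threshold classification and list overlaps, and
the downstream quantification formulas.

## The matching score and dissimilarity rate

A PWM over positions $i = 1..L$ stores base frequencies $f_i(b)$,
$b \in \{A,C,G,T\}$. For a window $w$ the raw score is the sum of the
matched frequencies, $S(w) = \sum_i f_i(w_i)$, which promscan min–max
normalises:

$$\mathrm{match}(w) = \frac{S(w) - S_{\min}}{S_{\max} - S_{\min}}, \qquad
\mathrm{dissimilarity}(w) = 100\,(1 - \mathrm{match}(w))\,\%$$

where $S_{\max}$ and $S_{\min}$ sum the per-position maxima and minima.
This pins the two anchors that make the percent scale interpretable: the
consensus k-mer (per-position argmax, alphabetical tie-break for
determinism) scores exactly 0% dissimilarity, and the worst possible
window exactly 100%. Screening tools that report a "dissimilarity rate"
do not publish a common formula; we chose min–max normalisation of the
frequency sum because it is the simplest score that honours the
0%-at-consensus anchor and makes a "minimum matching score of 80%"
well-defined (it is the complement of a 20% dissimilarity threshold).
Published per-gene scores from such tools should therefore be treated as
anchors for table layout and thresholds, not as values this score must
reproduce. An information-weighted variant (each position weighted by its
information content, as in MatInspector-style scoring) is available via
`information_weighted = TRUE` but is not the default: nothing in the
workflow we emulate indicates weighting.

A fully uniform matrix has $S_{\max} = S_{\min}$; every window is then
defined to match at 1 (no window is more consensus-like than any other).
Windows containing non-ACGT symbols are skipped and tallied, never
scored — imputing a score for an ambiguous base would manufacture
evidence.

```{r score-example}
m <- default_demo_pwm()
pwm_consensus(m)
dissimilarity(m, "ACGGAA")   # the consensus: 0 percent
dissimilarity(m, "ACGGTA")   # one mismatch at a conserved position
```

## Scanning, strands, thresholds

`scan_sequence()` scores every length-$L$ window; by default both strands
are scanned, with a minus-strand hit reported at its forward-strand
offset and its k-mer read 5'→3' on the minus strand. Double-stranded DNA
carries an ETS site equally well in either orientation, so both strands
is the scientifically neutral default; `strands = "plus"` reproduces a
forward-only screen. Threshold comparisons are **strict** (`< 5%`),
matching the usual phrasing "dissimilarity rate of less than 5%"; the
conventional settings are 5% for curated candidate lists and 10% for
genome-wide scans, exposed in the CLI as `--mode curated|genome` and
never chosen silently. A gene with several promoters is a candidate if
*any* promoter passes; the per-promoter table is always emitted so a
stricter aggregation can be recomputed.

## Promoter windows and coordinates

Internally everything is 0-based half-open; BED6 is read natively and
GFF3 (1-based inclusive) converted on read. A window of $U$ upstream and
$D$ downstream bases around a TSS at genomic index $t$ covers
$[t-U, t+D)$ on the plus strand and the mirrored interval
$[t-D+1, t+U+1)$, reverse-complemented, on the minus strand, so the
output always reads in transcript orientation with the TSS base at
offset $U$. There is no "position 0" in the promoter convention: the
classical $-700..+300$ window is exactly $700 + 300 = 1000$ bases.
Windows that run off a contig edge are clipped and flagged rather than
rejected, so genome-scale extraction never aborts on a boundary gene.

## Verification mathematics

**Relative quantity.** qPCR expression changes use the
efficiency-corrected delta-Ct ratio
$RQ = E_t^{\Delta Ct_t} / E_r^{\Delta Ct_r}$ with
$\Delta Ct = Ct_\mathrm{control} - Ct_\mathrm{treated}$ and per-cycle
efficiencies $E \in (1, 2]$; $RQ > 1$ means higher expression in treated
cells. Replicate RQs are log2-transformed and tested against mean 0 with
a two-tailed one-sample t-test ($\alpha = 0.05$). Zero-variance replicate
sets (possible with 3 replicates) are flagged `degenerate_variance`
instead of aborting, reporting p = 0 or 1 by the direction of the mean.

**ChIP percent input.** With an input aliquot fraction $f$ (dilution
factor $DF = 1/f$), the input Ct is first adjusted by
$Ct^{*} = Ct_\mathrm{input} - \log_2 DF$ and enrichment is
$2^{-(Ct_\mathrm{IP} - Ct^{*})} \times 100\%$. The adjustment is the
standard reading of "input × DF" on the Ct scale — multiplying a cycle
threshold itself by a dilution factor is dimensionally incoherent, and
only the log2 adjustment yields percentages bounded by 100 for typical
data (equal raw Cts give exactly $f \times 100$).

**FDR and fold bins.** Expression tables gate significance at
Benjamini–Hochberg adjusted p ≤ 0.05 (`bh_fdr()` wraps the standard
step-up). Significant genes are binned by linear fold magnitude with
closed-left bins: $[2, 5)$ and $[5, \infty)$ — prose like "between 2- and
5-fold" does not fix edge membership, so we fixed it once; the binning is
done on the log2 scale so the 2- and 5-fold edges are exact in floating
point.

## The synthetic generators: what they emulate, what they do not

Every stage is testable offline through seeded generators
(`random_sequence()`, `plant_motif()`, `simulate_promoters()`,
`simulate_ct_table()`, `simulate_chip_table()`,
`simulate_expression()`), all driven by R's Mersenne Twister and
bit-reproducible under a fixed seed.

* Promoters are i.i.d. base draws with a composition knob; planted sites
  *overwrite* bases so truth coordinates stay valid. The benchmark
  configuration used in the test suite — 200 promoters × 1000 bp with 60
  planted consensus sites, scanned at the 5% threshold — is the package's
  reduced-scale stand-in for a genome-wide screen: large enough that the
  background hit rate is measurable against the exhaustive per-window
  expectation, small enough to run in seconds. Real promoters are not
  i.i.d. (isochores, CpG islands, repeats), so a passing benchmark
  demonstrates correctness of the scanner and calibration of its false
  positive behaviour under the stated null, not performance on real
  genomes.
* Ct tables are built by inverting the RQ formula (reference delta-Ct
  zero, target Ct shifted by $\log_E RQ$) and adding Gaussian per-Ct
  noise; sd 0.1 cycles reflects a well-run SYBR assay. With 50
  replicates the mean recovered RQ sits within 5% of truth; wet-lab
  designs with 3 replicates carry proportionally more spread.
* Expression tables allocate class counts deterministically
  (largest-remainder), draw fold changes uniformly inside each class's
  bin, and emit adjusted p-values on the correct side of the 0.05 gate,
  so noiseless classification recovers the truth labels exactly. The
  joint distribution of raw and adjusted p is not modelled — only the
  gate matters downstream.

## Sequence logos

`logo_columns()` computes, per alignment column, the information content
$IC = 2 + \sum_b f_b \log_2 f_b$ bits and letter heights $f_b \times IC$
— the numbers a logo plot draws, where total column height is the degree
of conservation (2 bits at a point mass, 0 at uniform). The small-sample
correction $e(n) = 3/(2 n \ln 2)$ is available but off by default; logo
renderings differ in whether they apply it, and the uncorrected heights
are the ones that satisfy the exact identities used in testing. Output
is a tibble/TSV; graphics go through `plot_logo()`.

## Numerical and design notes

* Consensus ties break alphabetically (A < C < G < T): determinism over
  biology, since a tied column carries no preference anyway.
* Count matrices convert to frequencies with a default pseudocount of
  0.2 per base (0.8 per position), a common choice for public count
  matrices; matrices supplied as frequencies are used as-is. The
  pseudocount is recorded on the converted object.
* The bundled curated target tables keep their original European number
  formatting (decimal commas, `N/A`); `read_target_table()` parses both
  comma and dot decimals, and missing scores always *fail* a threshold
  filter rather than being imputed.
* Scan thresholds, window geometry and strand handling are all explicit
  arguments with the conventional defaults; the CLI refuses to accept
  both `--max-dissimilarity` and `--min-matching` at once rather than
  guessing which scale was intended.

## Known limitations

* The dissimilarity score is a per-window frequency-sum statistic; it is
  not a thermodynamic binding model and ignores inter-position
  dependence.
* Gene-level aggregation is ANY-pass over promoters; a
  worst-case/best-case sensitivity analysis must be assembled from the
  per-promoter summaries.
* The background model for the false-positive calibration is i.i.d.
  sequence; empirical promoter backgrounds will show different (usually
  higher) hit rates at a given threshold.
* Retrieval of genomes, annotations or matrices from web services is out
  of scope: all inputs are local files.
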