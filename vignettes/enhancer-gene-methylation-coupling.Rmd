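---
title: "Screening for phenotype-specific enhancer–gene methylation couplings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for phenotype-specific enhancer–gene methylation couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcouple)
```

## The problem and the model

Colorectal cancers with the CpG island methylator phenotype (CIMP) carry
elevated DNA methylation at cancer-specific loci relative to non-CIMP
tumours. If an enhancer regulates a gene, their methylation states should be
coordinately controlled, so an enhancer–target pair that helps define a
phenotype should show (i) a methylation difference between phenotypes at
both loci and (ii) strong sample-by-sample co-variation of methylation
between the two loci. `methcouple` operationalises that idea as a staged
screen over bisulfite CpG counts.

The data model is simple: per sample and CpG, a methylated count $m$ out of
total coverage $t$, giving a beta-value $\beta = m/t$; a region's
methylation in a sample is the **unweighted mean** of the beta-values of the
CpGs inside it (1-based inclusive bounds, so CpGs exactly at the region
edges count). The unweighted mean — rather than a coverage-weighted pool —
is a deliberate contract: the region value names the per-CpG methylation
levels, not the read pool, and it keeps region values comparable between
samples with different coverage profiles. Whether to combine calls from
opposite strands is left to the caller: the readers keep `+` and `−` calls
as separate observations, since no merging rule is part of the contract.

## Stage 1: windowed DMR detection

Chromosomes are tiled into non-overlapping 1000-bp windows
$[kw+1, (k+1)w]$. For each window, counts are pooled per sample and a
binomial GLM with logit link regresses the methylated proportion on the
group indicator, one observation per sample weighted by its total coverage.
The test statistic is the likelihood-ratio chi-square (1 df) against the
intercept-only model; with one pooled observation per group it coincides
with the classical two-proportion G-statistic, which the test suite uses as
an independent oracle. The likelihood-ratio form was chosen over Wald for
stability at extreme proportions (all-methylated or all-unmethylated
windows give a clean p = 1 instead of a diverging standard error).

The effect size is reported on the pooled scale,
$100\,(\sum m / \sum t\,|_{g_1} - \sum m / \sum t\,|_{g_2})$ percentage
points. A window passes when $|\text{difference}| > 50$ and $q < 0.01$.
Windows with zero coverage in either group are *skipped and counted*, never
assigned p = 1: an untestable window is missing evidence, not evidence of
no difference.

**Q-values.** The default method rescales Benjamini–Hochberg q-values by an
estimate of the null proportion $\pi_0$, in the spirit of sliding-linear-model
q-values: $\hat\pi_0(\lambda) = \#\{p > \lambda\} / (n(1-\lambda))$ on the
grid $\lambda = 0.1, \ldots, 0.9$, taking the value at the flattest segment
of the curve (smallest absolute finite-difference slope), clamped to
$(0, 1]$; with fewer than 20 p-values the estimate falls back to 1. The
exact spline machinery of the original sliding linear model is not
reproduced — the $\pi_0$-weighted BH shares its structure and is fully
documented here; plain BH is available via `qmethod = "bh"`.

**Calibration.** The aggregated-count GLM treats per-sample pooled counts
as binomial. When the data are beta-binomial with precision $\phi$ (the
generator's default regime), the per-sample pooled proportion has variance
inflated by roughly $1 + \bar c/(\phi + 1)$ for mean coverage $\bar c$ — at
the defaults ($\bar c = 30$, $\phi = 50$) a factor near 1.6, which pushes
the raw type-I error of the window test at $\alpha = 0.05$ above $2\alpha$.
This is a property of aggregation-based window tests generally, not of this
implementation, and it is immaterial to the DMR call itself because the
50-percentage-point effect filter — not the p-value — is binding under
overdispersed nulls (the null-cohort pass rate in the acceptance suite is
0 at the published thresholds). The suite therefore asserts the
$[\alpha/2, 2\alpha]$ calibration band under a binomial-regime null, which
checks the test's own correctness, and treats the overdispersion inflation
as documented model misfit.

## Stages 2–4: containment, DME selection, correlation screen

Passing DMRs nominate catalog enhancers by **complete containment** (the
window lies entirely inside the enhancer; `--overlap-mode any` exists as an
escape hatch but is off by default). One DMR may nominate several
overlapping enhancers; all pairs are reported.

Candidate enhancers — usually much longer than 1000 bp — are then measured
over their full span, and a two-tailed two-sample t-test on per-sample
enhancer methylation selects **differentially methylated enhancers** at raw
p < 0.05. Welch's variant is the default (robust to the unequal 6-vs-5
group sizes); Student's pooled-variance variant is available since the
screen this mirrors did not record which was used. No multiple-testing
correction is applied at this stage — a faithful reproduction of the
original small-candidate-set screen, not a statistical endorsement; the
selection rate under a null cohort is checked to sit near the nominal
$\alpha$. When both groups are exactly constant, equal means give p = 1 by
convention and unequal means p = 0.

Each selected DME is paired with every **intrachromosomal** passing DMR,
excluding DMRs contained in that DME (which would correlate with it
trivially through shared CpGs). Pearson $r$ is computed across
pairwise-complete samples ($n \ge 3$, both variances nonzero; degenerate
pairs are skipped and counted), with the two-tailed p from
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df. BH adjustment is applied **per
enhancer** across its candidate pairs — each enhancer's screen is reported
separately, so its candidate family is the natural FDR unit; a pooled
family is available via `fdr_family = "pooled"`. A pair passes at
$|r| \ge 0.85$ and $q \le 0.05$; the published band "−0.85 ≥ r ≥ 0.85" is
read as the magnitude threshold, being unsatisfiable as written. Strength
labels follow the reporting scale: $|r| \ge 0.5$ "good to excellent", else
"moderate to nil".

## Stage 5: annotation conventions

Partner regions are classified with priority **promoter > gene body >
intergenic**. The promoter is the 1500 bp immediately upstream of the TSS
in gene orientation ($[\mathrm{TSS}-1500, \mathrm{TSS}-1]$ on `+`,
mirrored on `−`, clipped at position 1). Gene-body hits report exon/intron
sub-features numbered in *transcription order* (exon 1 nearest the TSS),
which is what reproduces labels like "intron 3, exon 4, intron 4" for a
minus-strand gene. Intergenic regions report the nearest gene by boundary
gap with an orientation-aware upstream/downstream call; nearest-gene ties
break to the smaller accession string for determinism.

TSS distances are exposed under an explicit **anchor** parameter
(`region_start`, `region_end`, `nearest_edge`) because published
distance-to-TSS columns mix conventions across rows — one row anchored at
an enhancer's start, another at an end, another at the DMR rather than the
enhancer. Rather than guess a single rule, the pipeline defaults to
`nearest_edge` and always reports all three values.

## Stage 6: capture-seq validation

An independent capture cohort measures enrichment, not base-level
methylation, so region methylation is quantified as
$\mathrm{rpkm} = c \,/\, \big((L/1000)(N/10^6)\big)$ with $c$ the reads
overlapping the region by ≥ 1 bp (configurable), $L$ the region length and
$N$ the sample's total mapped reads (its full read-file line count). Reads
are used unextended; no fragment-length smoothing is applied. Nominated
pairs are re-tested with the same Pearson code path, with no magnitude
threshold: validation reports $r$, $p$ and the strength label and lets the
reader judge.

## The synthetic-data generator

`sim_config()` fixes the emulated study conditions: 6 vs 5 samples, one
2-Mb chromosome with 20,000 CpGs, negative-binomial coverage (mean 30,
size 8, floored at one read), beta-binomial methylation with precision 50,
50 planted grid-aligned 1000-bp DMR windows with true group means 0.2 vs
0.8 (difference exactly 0.6), 20 enhancers of 1–4 kb of which 3 carry group
effects (hypermethylated in group 1, each containing one planted DMR), and
10 coupled pairs distributed round-robin over the differential enhancers
with signs drawn at random.

Coupling is latent-factor based: each differential-enhancer family $f$ has
per-sample factors $u_{fs} \sim N(0,1)$; the enhancer's per-sample mean is
its group base plus $a\,u_{fs}$ and a coupled partner's is its group base
plus $\mathrm{sign} \cdot b\,u_{fs}$, clamped to $[0.02, 0.98]$ so Pearson
correlations stay defined. One factor per enhancer family (rather than a
single global factor) keeps unrelated couplings statistically distinct.
Uncoupled planted elements instead receive independent per-sample noise
(sd 0.08), the generator's stand-in for biological within-group
variability. The defaults $a = b = 0.08$ and sd 0.08 were fixed from a
design analysis before any end-to-end run: a planted partner's pooled
difference is $0.6 + b(\bar u_{g_1} - \bar u_{g_2})$ with sd
$\approx 0.6 b$ plus measurement noise, so slopes near 0.08 keep planted
windows comfortably above the 50-point filter (per-window recovery
probability ≈ 0.98) while the coupling correlation is near 1 regardless,
being dominated by the shared group effect.

Background CpGs follow a bimodal landscape — low (0.1) inside simulated
CpG-dense segments, high (0.8) elsewhere — identical in both groups, so
background windows are null by construction. Elements are placed in
disjoint blocks of the window grid; placement that cannot satisfy the
non-overlap requirement is a configuration error, not a silent retry.

The capture generator draws fresh phenotype labels and latent factors for
its (default 24) samples, computes each truth region's per-sample
methylation by the same rules, and places Poisson numbers of fixed-length
36-bp reads in each region with rate proportional to methylation × length
against a *fixed* normaliser (so expected counts are exactly linear in
intensity), plus uniform background reads rejected out of the truth
regions. Library sizes are the realised read counts.

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: read sequences and mappability, bisulfite
conversion error, PCR duplicates, copy-number aberrations, chromosome-scale
methylation domains, and realistic locus-to-locus correlation structure.
Its purpose is parameter recovery: every downstream stage can be checked
against planted truth.

## What recovery does and does not mean here

Under the default conditions the pipeline recovers ≥ 90 % of planted DMR
windows, selects exactly the 3 differential enhancers, recovers the planted
coupled pairs with the correct sign, and reproduces every recovered pair's
sign in the capture cohort — the acceptance suite computes all of these.

One property deliberately *fails* and is reported honestly: the screen's
precision against the planted couplings. With a single chromosome and a
common two-group effect of 0.6 on every planted element, any two elements
that both pass the 50-point filter share most of their variance through the
group indicator alone: the expected cross-element correlation is
$\mathrm{var}_g / \sqrt{(\mathrm{var}_g + \tau_1^2)(\mathrm{var}_g +
\tau_2^2)}$ with $\mathrm{var}_g = 0.6^2 \cdot \frac{6}{11}\cdot\frac{5}{11}
\approx 0.089$, which at any within-group sd $\tau$ compatible with ≥ 90 %
DMR recovery ($\tau \lesssim 0.13$) stays near 0.85 — so uncoupled
DME–DMR pairs pass the $|r|$ screen in large numbers and precision stays
low (the acceptance script reports it, at well under 90 %). Suppressing
those false pairs would require $\tau > 0.35$, which
destroys DMR recovery; no setting satisfies both. In this regime the
correlation screen is a *phenotype-coherence* filter, not a pure
coupling-detector; distinguishing genuine couplings from group-driven
co-variation would need within-group contrasts (e.g. partial correlation on
the group indicator) or multi-chromosome designs, both outside the present
scope. The acceptance suite keeps the ≥ 90 % precision check in place and
red, as the honest statement of this limit.

## Numerical choices and degenerate inputs

* Coordinates are uniformly 1-based inclusive internally; BED's 0-based
  half-open convention is converted only at I/O. Sorting is total and
  stable: chromosome lexicographic, then start, then end.
* Coverage filtering (`min_coverage`, default 10) happens at read time;
  region values require `min_cpgs` (default 3) contributing CpGs, else the
  value is missing — missing is a value, not an error.
* `p = 1` contracts: window test on identical pooled proportions; t-test on
  two constant equal groups. `p = 0`: $|r| = 1$; constant unequal groups.
* Group semantics: "group1" is the first factor level (or first label in
  order of appearance), fixing the sign of every reported difference;
  swapping levels negates effect signs and preserves p-values, a property
  the suite asserts.
* Determinism: a seed plus a configuration fully determines every output;
  pipeline reruns are byte-identical, and the run report carries an MD5
  hash of the canonical (key-sorted) configuration.
* Problem sizes in the test and acceptance suites are the generator
  defaults (2,000 windows, 11 + 24 samples, 100-fixture oracle sweeps,
  1,000-region null calibrations) — large enough for the stated bands,
  small enough to run routinely.

## Known limitations

The window test ignores overdispersion by design (see Stage 1); the DME
stage applies no multiple-testing correction, mirroring the procedure it
reproduces; the screen cannot separate coupling from shared group structure
within one chromosome (above); annotation is single-isoform with no
UTR/CDS resolution; and the capture stage models enrichment only — no
CpG-density normalisation or absolute calibration is attempted.
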