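---
title: "Modeling functional nucleosome states: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling functional nucleosome states: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucstates)
```

## The model

`nucstates` classifies positioned nucleosomes into chromatin states using a
discrete, univariate, first-order hidden Markov model.  The observation for
each nucleosome is the *combination* of histone marks overlapping it,
encoded as a bitmask: with $n$ declared marks the alphabet has $2^n$ symbols
and symbol $x$ carries mark $i$ iff bit $2^i$ is set.  With the default
seven marks (H3K4me3, H3K4me1, H3K27ac, H3K79me2, H3K36me3, H3K9me3,
H3K27me3 on bits 0–6) a nucleosome overlapped by H3K4me3 and H3K79me2 is
symbol $1 + 8 = 9$ of 128.  Enumerating combinations rather than using a
multivariate emission makes "does mark $m$ occur in state $s$" a pure
marginalization:

$$\Pr{}_{id}(s) = \sum_{x\,:\,x \,\&\, 2^{id} > 0} B_{s,x},$$

which `mark_state_matrix()` computes by a bit scan over the alphabet.

Observation sequences are *directional*: one sequence per gene, running 5′
to 3′ over a window from `upstream_bp` (default 100 kb) before the unique
5′ TSS through `downstream_bp` (default 10 kb) past the TTS, with
minus-strand genes reversed.  A nucleosome falling in two gene windows
contributes to both sequences; training treats sequences as independent, so
this duplication only reweights shared flanks slightly.

### Training, selection, pruning

Training is two rounds of Baum–Welch (scaled forward–backward, compiled):

1. **Selection round.** For each candidate state count (default 15–25, or
   any range) and each of `replicates` (default 5) Dirichlet-random seeded
   initializations, run up to 300 iterations and score
   $\mathrm{BIC} = k\ln n - 2\log L$ with
   $k = (S-1) + S(S-1) + S(V-1)$.  The minimum-BIC fit wins; ties prefer
   fewer states, then the earlier replicate.
2. **Pruning.** States Viterbi-assigned fewer than 0.5% of nucleosomes are
   removed; for every surviving row of the transition matrix (and the
   initial distribution) the mass that pointed at removed states is
   redistributed *evenly* over the survivors, keeping rows stochastic.
3. **Retraining.** Up to 200 further iterations from the pruned model.

Numerical choices: log-likelihood convergence tolerance `1e-4`
(non-decreasing trace is asserted in tests to `1e-6` slack); an emission
floor of `1e-10` is renormalized in after every M-step because most of a
128-symbol alphabet is unseen in any finite data set and exact zeros would
lock states out irreversibly.  Viterbi decoding runs in log space with ties
broken toward the lower state index, which makes decoded output
deterministic.

Occupancy for pruning is computed from Viterbi paths (the posterior-sum
alternative is a one-line change; Viterbi was chosen because the same
decoded paths drive every downstream module, keeping one notion of
state membership).

## Nucleosome organization

**Arrays.** A nucleosome array is a maximal run of same-state nucleosomes
with adjacent dyad gaps under 350 bp.  Per state we report the mean member
count ("Ave No."), and each array contributes its member coverage to a 1 kb
window anchored at the array start (strand-aware).

**Phasing.** The averaged array signal (native 10 bp/point, i.e. sample
rate 100 per kb) is linearly interpolated to 1 bp/point (rate 1000) —
linear because it is shape-preserving and cannot ring — and passed through
Welch's periodogram-averaging estimator: Hann-windowed frames of
`frame_len = 512` samples advanced by half a frame, periodogram
$|\mathrm{FFT}|^2/M$ per frame, averaged.  The reported quantity is
1000 × the maximum spectral density in the 4–10 Hz band, which at rate 1000
corresponds to periods of 250 down to 100 bp via $\mathrm{period} =
f_s/f$.  The frame length and hop are configurable; 512/256 gives ~2 Hz
resolution on a 1 kb window while still averaging two frames.

**Spacing.** Local maxima of the array signal: a sample strictly above both
neighbors, or the middle of a flat plateau (lower-middle for even
plateaus).  Spacing is the mean of consecutive inter-maximum distances; by
default the first four intervals in the 1 kb window are used.  Two
robustness knobs, both off by default so the bare rule is exactly the
published one, exist for noisy signals: a centered moving-average smoother
and a minimum peak prominence.  The noisy-recovery tests use a 31 bp
smoother (~period/6) chosen a priori: the mean of consecutive intervals
telescopes to (last − first)/(k−1), so after mild smoothing the residual
peak-location jitter contributes well under the 2 bp tolerance.

A per-nucleosome spacing filter mirrors the published tolerance band: the
$k$-th nucleosome of an array (interval $= k-1$) must have its observed gap
within $\mathrm{spacing} \pm \mathrm{interval}\,(5 + \mathrm{rank}\cdot
\mathrm{coef})$, where rank is the state's descending phasing rank and coef
defaults to 1 bp; the first nucleosome's degenerate band always retains it.

**Positioning.** Two inter-correlated scores:

- read-based reference: $\mathrm{rNP} =
  \mathrm{norm}(\mathrm{enrich}) / (\mathrm{norm}(\mathrm{fwhm}) +
  \mathrm{norm}(\mathrm{std}))$, with enrichment = reads within ±73 bp of
  the dyad, std = read-center offset dispersion, and fwhm = width at half
  maximum of the 10 bp-smoothed read-center histogram restricted to the
  nucleosome span.  The width is measured as the *count* of positions at or
  above half maximum: on dispersed, nearly flat pileups a contiguous scan
  latches onto a single noise bump and collapses, inverting the feature.
- call-based: $\mathrm{NP} = (\mathrm{height} +
  \log_2(\mathrm{pval}_{peak}\,\mathrm{pval}_{valley} + 1) +
  \mathrm{area}) / (3\,\mathrm{width})$ over the caller's attributes, after
  replacing the last array member's valley significance with the population
  median (it is systematically inflated at array ends regardless of shape).

"norm" is interquartile normalization $(x - Q_1)/(Q_3 - Q_1)$ — invariant
under positive affine transforms of the population.  Because this centering
puts a quarter of any population at or below zero *by construction*,
denominators (and the $\log_2$ argument) are floored at **0.1**, not at an
epsilon: an epsilon floor turns the best-positioned quartile into
meaningless $10^6$-scale sentinels and destroys the NP–rNP correlation the
score exists to preserve.  One tenth of the IQR unit keeps scores bounded
while leaving every worked example (all of which sit above the floor)
unchanged.  Per-state positioning is the mean NP after dropping scores
outside the state's 0.05/0.95 quantiles.

## Region annotation

Decoded nucleosomes are profiled against a gene-centric scheme: Distal
(−100 kb..−10 kb), Proximal (−10 kb..−1 kb), Promoter (−1 kb..TSS), gene
body as percent of gene length (100 bins), and Downstream (TTS..+10 kb),
all in gene orientation.  The Distal/Proximal boundary is not published;
−10 kb is the package default and configurable.  A state's dominant region
maximizes the enrichment ratio (state fraction in region over mean
fraction across states); the frequency profiles themselves are also
emitted so either view can be inspected.  States whose mark-state row has
no mark at or above the (arbitrary, configurable, default 0.5) threshold
are reported `unlabeled` rather than given a functional name.

## Splicing potentiality

Skipped-exon events arrive as a summary table with isoform-exclusive read
counts $X$ and $Y$ and the inclusion-level confidence-interval width.
Reliability uses two rules: $X + Y \ge N$ with $Y \ge 1$ (N defaults to the
upper quartile of the $X+Y$ distribution when not supplied — the published
derivation is unstated), and CI-width **greater than** the median CI-width.
The second rule is implemented exactly as printed even though its direction
is counter-intuitive (a wider interval means a *less* certain estimate); an
`invert_rule2` flag provides the opposite reading.

Per state, the splicing-potentiality score multiplies three components
min-max scaled to [0, 1] across the compared states: the discrete Fréchet
distance between the state's mean positional signals in reliable vs
unreliable events (dynamic program over monotone couplings, compiled, and
cross-checked against exhaustive coupling enumeration in tests), the
absolute difference of median NP scores between the groups, and the
normalized share of the state's nucleosomes found in reliable events.  The
printed form of the combining equation has unbalanced parentheses; the
product-of-three-normalized-terms reading is used.  SE affinity is
observed/predicted event counts under a random-association null.

## The synthetic world

The generator emits every input the pipeline reads, from a known ground
truth, so each claim is testable offline:

- genes: non-overlapping, unique TSS, both strands, desk-scale sizes
  (5–20 kb genes, 4.5–9 kb intergenic gaps — wide enough that the default
  2 kb/1 kb placement windows of adjacent genes cannot interleave, which
  the exact symbol round-trip property requires);
- nucleosomes: dyads spaced $N(185, 15)$ bp truncated at the 147 bp core,
  states from the truth Markov chain, symbols from its emission rows,
  decoded into mark peaks that fully cover their nucleosome;
- truth models: sticky transitions (0.7 self) and emissions with 0.7 mass
  on one anchor combination per state.  This mirrors real mark-state
  matrices, which are near 0/1 per mark; an earlier, flatter calibration
  (0.55/0.6) produced truth states that Bayesian model selection *should
  not* separate at 10k nucleosomes, contradicting the recovery contract
  the generator must satisfy;
- array signals: Gaussian peaks (sd 30 bp) at one period apart with
  geometric amplitude decay and optional white noise;
- read pileups: read-center dispersion 10 bp ("well") or 40 bp ("fuzzy"),
  or any numeric dispersion for a continuum; call attributes are derived
  from a heavily smoothed (30 bp) version of the same pileup, emulating
  the Gaussian/LoG smoothing real callers apply before measuring shape;
  read depth is Poisson by default (constant depth makes the synthetic
  "area" attribute degenerate under IQR normalization) with an
  equal-count switch for the pairwise ranking contract;
- SE tables: reliable events planted above the support cutoff with wide
  CIs, unreliable events failing the support rule.

What a green test does **not** establish: the generator has no sequence
preference, no MNase bias, no inter-array coupling, no chromatin-domain
structure, and its mark peaks are exactly nucleosome-aligned — so passing
tests certify the algorithmic contracts, not genome-scale biological
performance.  Published genome-wide figures (tens of millions of
nucleosomes, the 13-state model and its summary table) require the
original sequencing data and are deliberately out of scope.

## Known limitations

- The number of candidate states must still be supplied as a range; BIC
  selects within it but cannot argue for states outside it.
- Mark assignment uses a single overlap fraction (default 0.5 of the
  nucleosome span) — the published rule says only "degree of overlapping",
  so the threshold is exposed rather than hidden.
- With the Hann window, a constant signal leaks ~1e-4 of its power into
  the 4–10 Hz band through sidelobes; band quantities should be compared
  between states, not read as absolute zeros.
- Fréchet comparison pairs curves by x-index with signal value as y; it is
  sensitive to the common binning chosen for the two groups.
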