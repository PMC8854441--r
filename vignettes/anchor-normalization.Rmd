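---
title: "Generalized-anchor batch normalization for mass cytometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized-anchor batch normalization for mass cytometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytanchor)
```

## The problem

Mass cytometry quantifies dozens of metal-isotope-tagged antibodies per cell,
but signal intensities drift with instrument tuning, antibody lots and
staining batches. Pooling samples across barcode plates — let alone across
studies — therefore confounds biology with batch. The gold standard, bead
normalization, needs bead events recorded with every sample; public
repository data often lack them, and identical technical replicates across
batches (as required by replicate-based correctors) are rarer still.

cytanchor removes batch effects using *generalized anchors*: references that
are not identical across batches but are expected to vary little. Two kinds
are supported:

* **healthy control samples**, one per batch — aliquots of healthy bone
  marrow or PBMC included on each barcode plate;
* **stable channels** — the shared markers with the least biological and
  technical variability across the samples being integrated.

## The model

Let $T_j \in \mathbb{R}^{c_j \times m}$ be the cells-by-markers matrix of a
sample in batch $j$ (arcsinh scale), and let the batch's anchor have
per-channel mean $\mathrm{MSI}^{(c)}_j$ and standard deviation
$\mathrm{SD}^{(c)}_j$ (population convention, denominator $c$). The
*universal reference* pools the single-cell data of all anchors by row-wise
concatenation; its $\mathrm{MSI}^{(u)}$ and $\mathrm{SD}^{(u)}$ are the
column means and standard deviations of the pooled matrix. Pooling at the
cell level means anchors with more cells weigh more; this differs from
averaging per-anchor means when cell counts are unequal, and the package
deliberately uses the cell-weighted form (the audit records which anchor was
used, so the alternative is easy to audit).

Five per-channel affine corrections fit the anchor to the reference; the
identical transform is then applied to every sample of the batch:

* **MSFT** (meanshift): $T - (\mathrm{MSI}^{(c)} - \mathrm{MSI}^{(u)})$;
* **MSFTB** (meanshift bulk): subtract the single scalar
  $\overline{\mathrm{MSI}^{(c)}} - \overline{\mathrm{MSI}^{(u)}}$ (bar =
  mean over channels);
* **VAR**: meanshift followed by per-channel scaling by
  $\mathrm{SD}^{(u)}/\mathrm{SD}^{(c)}$;
* **Z**: $(T - \mathrm{MSI}^{(c)})\cdot
  \mathrm{SD}^{(u)}/\mathrm{SD}^{(c)} + \mathrm{MSI}^{(u)}$;
* **BL** (bead-like): multiply all channels by the through-origin
  least-squares slope $\beta = \sum_i u_i h_i / \sum_i h_i^2$ of the
  reference means $u$ on the anchor means $h$, mimicking the single gain
  factor of bead standardization.

**Sign convention.** The corrections are oriented so that the anchor lands
*on* the reference: after MSFT or Z the anchor's per-channel means equal
$\mathrm{MSI}^{(u)}$; after Z or VAR its per-channel standard deviations
equal $\mathrm{SD}^{(u)}$; after MSFTB the bulk means agree; after BL a
refitted slope equals 1. These identities are enforced by the test suite and
are the defining contract of the implementation — a formulation that *added*
the anchor-minus-reference difference would move data away from the goal
distribution and violate all of them.

A key assumption is that anchors differ between batches mostly through the
batch effect itself: anchors must vary less between batches than the target
samples do, or the estimated correction absorbs biology. VAR and Z further
assume the anchors share their variance structure; they are most appropriate
when anchors are true aliquots of the same material.

## Stable channels

When no healthy control is available, stable channels substitute. For each
sample $s$, PCA is run on the column-centered (never unit-scaled — the score
must reflect absolute variability) matrix $T^{(s)}$, giving loadings
$P^{(s)} \in \mathbb{R}^{m\times k}$ and component standard deviations
$\mathrm{SD}^{(s)}_i$. The non-redundancy score of marker $j$ is

$$\mathrm{NRS}_j \;=\; \frac{1}{R}\sum_{s=1}^{R}\sum_{i=1}^{k}
\big(\mathrm{SD}^{(s)}_i\big)^2\,\bigl|P^{(s)}_{[j,i]}\bigr|,$$

with $k = 3$ components by default. Absolute loadings are used because
principal-component signs are arbitrary; without them the score would change
under sign flips of the PCs (the tests verify this invariance explicitly).
Internally the PCA uses the sample-variance convention of `prcomp`
(denominator $n-1$); at cytometry cell counts the distinction from the
population convention is negligible, but the tests' oracle fixes this choice.
Selection takes either the $n$ lowest-NRS channels (default $n = 3$) or all
channels strictly below a cutoff. The universal stable reference is the
per-stable-channel mean over the concatenation of *all* samples, and each
sample is shifted by one scalar — its stable-channel bulk mean minus the
reference's — applied to every channel. A single scalar can remove uniform
offsets exactly but, by construction, not channel-specific ones.

## Panel homogenization

Channel labels are matched against a user-supplied template
(metal, antigen, regex pattern, standardized name) case-insensitively,
first match wins in template order — so more specific patterns (CD45 before
CD4) must precede their prefixes; precedence is under template-author
control and deterministic. The consensus panel is the intersection of
matched standardized names over all files; non-consensus channels are
dropped from the data but always logged in the homogenization report. Two
raw channels in one file matching the same standardized name is an error
(ambiguity is surfaced, not resolved silently). Values are only selected
and renamed, never altered, which makes the operation idempotent.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `cofactor` | 5 | arcsinh divisor; the CyTOF standard |
| positivity threshold | 10 counts | gate boundary, `asinh(10/5)` ≈ 1.44 in transformed space |
| `mode` | — | one of MSFT, MSFTB, VAR, Z, BL |
| `condition_priority` | `"basal"` | anchor selection prefers unstimulated healthy samples; ties broken by filename |
| `k` | 3 | PCs entering the NRS |
| `n` / `cutoff` | 3 / — | stable-channel selection (cutoff is strict `<`) |
| network `threshold` | 0.9 | cosine-similarity edge rule, inclusive (≥) |
| distance `subsample` | 2000 cells/batch | pair-distance summaries, seeded |

Normalization operates on arcsinh-transformed data by default; raw counts
can be transformed on the way in (`--data-scale raw` in the CLI). Anchors
with a zero-variance channel are a hard error under VAR and Z rather than a
silent skip: a degenerate anchor is a data problem the user must see.

## The synthetic study conditions

The generator emulates the structure the method targets: `n_batches = 3`
barcode plates of `samples_per_batch = 4` samples (one healthy anchor each),
2000 cells and 20 channels per sample, three Gaussian subpopulations in
arcsinh space with channel means uniform in [0.5, 4.5] and within-population
sd 0.3 — typical ranges for cofactor-5 CyTOF data — and per-batch affine
batch effects $x \mapsto \gamma_b x + \delta_b$ with
$\delta_b \sim N(0, 0.5^2)$ per channel and $\gamma_b = 1$ by default.
Anchors are drawn from a shared healthy mixture *before* the batch
transform, so the batch effect is the only systematic cross-batch difference
between them. Batch effects are applied in arcsinh space as affine maps
because the five normalizers are themselves per-channel affine: exact
recovery is then a meaningful oracle, not an approximation. Injected
"stable" channels (common mean across populations, sd 0.01) provide ground
truth for NRS ranking.

What the simulation does *not* model: spillover between metal channels, bead
and doublet events, acquisition-time drift within a run, zero-inflation of
raw counts, and non-affine batch distortions. Passing tests therefore
demonstrate that the estimators recover the transformations inside their
model class at realistic noise levels — not that real batch effects are
affine. On real data the residual after correction is an empirical question;
the evaluation module (RMSD/R² against a trusted reference, similarity
networks, distance ratios, ARI) exists to measure exactly that.

## Numerical choices and degenerate inputs

* Variances are population-style (denominator $n$) in channel statistics,
  matching the universal-reference definition; PCA inside the NRS uses
  `prcomp`'s $n-1$.
* The BL slope is fit through the origin; with anchor equal to reference the
  slope is exactly 1 and every mode reduces to the identity (tested to
  1e-12).
* Audits store the exact per-channel `shift`/`scale`/`offset` triple, and
  replaying an audit reproduces the output bit for bit.
* Ties: anchor selection breaks condition ties lexicographically by
  filename; stable-channel selection breaks NRS ties by channel name; gate
  assignment is first-match in gate order. All deterministic.
* FCS files are written as FCS 3.1 with 64-bit float data so that
  write/read round trips are lossless even for transformed values; the
  reader accepts FCS 3.0/3.1 float, double and uniform-width integer data
  and takes channel labels from `$PnS`, falling back to `$PnN`.
* Problem sizes in the test suite (e.g. 50-trial sweeps over 1000×15
  matrices, 20 replicate stable-channel recoveries at 500 cells) were chosen
  as the smallest sizes at which sampling error is clearly separated from
  the effects being tested.

## Known limitations

* BL models a single multiplicative gain per batch; channel-specific gains
  are outside its class (and MSFTB removes only uniform offsets — the test
  suite asserts this negative control rather than hiding it).
* Bulk (sample-level) corrections cannot fix population-specific batch
  effects; cluster-resolved correction is deliberately out of scope.
* Homogenization needs a curated template; it does not infer synonyms by
  edit distance, and non-overlapping markers are dropped, not imputed.
* The healthy-anchor strategy assumes the anchors are comparable material;
  an anchor whose biology differs across batches biases every sample of its
  batch.
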