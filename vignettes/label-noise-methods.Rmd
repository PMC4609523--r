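---
title: "Interobserver variability and label noise in CTC image classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interobserver variability and label noise in CTC image classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ctcnoise)
```

## The problem

Automated enumeration of circulating tumor cells (CTCs) from fluorescence
microscopy rests on manually annotated reference data, and manual
annotation of faint, ambiguous image cutouts is far from perfect: panels
of observers disagree on a substantial fraction of data points. This
package implements, end to end, an analysis of what that disagreement
does to classifier training and evaluation: interobserver agreement
statistics, a binomial consensus construction, hue/saturation feature
extraction from three-channel cutouts, random-forest and SVM training
under controlled amounts of annotation noise, and a synthetic-data
module that stands in for the original (non-deposited) microscopy data.

The annotation task it models: each square cutout is centered on a
nucleus-positive object, and an observer calls it a CTC when the blue
nuclear stain is intact and the green EpCAM/cytokeratin stain is
structured, and never when red CD45 counterstain (a leukocyte marker) is
present.

## Agreement statistics

For binary label vectors $A, B \in \{0,1\}^N$ of two observers, the
pairwise agreement is

$$P_{Agr}(A,B) = 1 - \frac{1}{N}\sum_{i=1}^{N} |A_i - B_i|,$$

one minus the normalized Hamming distance. Per-observer summaries
average this over the $M-1$ partners and track the signed mean
difference in CTC counts,
$\Delta CTC(A) = \frac{1}{M-1}\sum_{B\neq A}(N_{CTC}(A)-N_{CTC}(B))$;
conservative observers (who resolve uncertainty to "no CTC") sit at
negative $\Delta CTC$ and low agreement, which is exactly how they are
identified in a panel. `delta_ctc` is signed, and its sum over
observers is exactly zero — a useful invariant for testing.

If every observer matched a cutout's latent label independently with the
same probability $p$, two observers would agree with probability
$p^2$ (keeping the concordant-positive term of the Bernoulli model), so
$p=\sqrt{P(A=B)}$ and all $M$ observers should be unanimous on about
$N p^M$ cutouts. Real panels are far more unanimous than this predicts
(the observed mean agreement implies one $p$, the observed unanimity a
larger one; a one-sample t-test of the $M(M-1)/2$ pairwise agreements
against the unanimity-implied value rejects equality decisively), which
shows that disagreement concentrates on a hard minority of cutouts
rather than spreading uniformly. That empirical fact motivates both the
consensus construction and the shape of the synthetic difficulty
distribution below.

## Consensus limit and partition

Under a fair-coin null, the number of observers $X$ (out of $M$) voting
"CTC" is $Binomial(M, 1/2)$. The consensus limit $c$ is the smallest
vote count whose one-sided tail $P(X \ge c)$ falls below $\alpha=0.05$;
a cutout with at least $c$ concordant votes in either direction is a
consensus point. The one-sided reading is used because it uniquely
reproduces both published anchors ($c=9$ for 11 observers, $c=5$ for 5);
the two-sided version would give $c=10$ for 11 observers. For $M \le 4$
no $c \le M$ satisfies the condition and `consensus_limit()` returns a
sentinel (`NA`). Ties (possible only for even $M$) are never consensus
because $c > M/2$ always.

The partition splits data points into the total-consensus stratum
(unanimous; treated as ground truth, GT), the consensus stratum
($\ge c$ concordant votes, carrying the majority label), and the
non-unanimous remainder (probGT). probGT points only admit
*probabilistic annotation*: each point gets the label of a uniformly
drawn observer, so label 1 appears with the point's vote fraction $q_i$,
two independent annotations differ at a point with probability
$2q_i(1-q_i)$, and the expected number of label changes over a set is
the sum of those terms.

## Preprocessing

Cutouts arrive at 1.0, 0.5 or 0.25 µm²/pixel (10x/20x/40x objectives).
The pipeline, in order: centered crop to a fixed 2500 µm² region (side
$\mathrm{round}(\sqrt{2500/\text{pixel area}})$: 50, 71 or 100 px);
isotropic Gaussian smoothing with $\sigma = 1$ pixel at the original
resolution (smoothing precedes downsampling, matching the stated
processing order); bilinear downsampling to 50 × 50; HSV conversion with
the V (intensity) channel dropped; row-major vectorization of the H and
S planes into a 5000-entry feature vector, hue block first.

Numerical conventions: hue is kept as a plain real in $[0,1)$ with no
circular encoding — the wraparound of reds (H near 0 vs near 1) is a
known artifact of this representation; achromatic pixels get H = 0;
the Gaussian kernel is sampled on a $(2\lceil 3\sigma\rceil+1)^2$
support and normalized, with replicated image borders; $\sigma = 0$ is
the identity; upsampling is refused rather than interpolated. Because
H and S are invariant to a global rescaling of the RGB channels, the
entire pipeline is invariant to overall image brightness — the stated
reason for dropping V ("not decisive"), and a property the test suite
checks exactly.

## Classifiers

Two fixed contracts, with the fitting routine treated as a pluggable
standard implementation (the experimental design, not the fitter, is
the point): a Breiman random forest with 500 trees,
$\lfloor\sqrt{p}\rfloor$ candidate features per split and unlimited
depth (fitted with `ranger`, single-threaded, seeded — the seed is also
passed at prediction time so that 250/250 tree-vote ties resolve
reproducibly); and a soft-margin SVM with RBF kernel
$k(x,y)=\exp(-\gamma\|x-y\|^2)$, $C = 2$, $\gamma = 0.005$ (fitted with
`kernlab`, unscaled, since features already live in $[0,1]$). The
$\gamma$ convention matters for transferring $C$ and $\gamma$ between
implementations and is documented here once: `kernlab`'s `sigma` *is*
this $\gamma$. No probability calibration or threshold tuning; hard
labels only. Performance is reported as accuracy, precision and recall
from pooled confusion counts; precision (recall) is flagged `NA` when no
positives are predicted (present).

## Experimental protocols

Three protocols, all with randomized balanced folds (sizes differ by at
most one) and audited train/test disjointness:

* **Cross-observer whole-set evaluation.** For each observer's
  annotation: five folds; in each of five rotations one fold is tested,
  the cyclically next fold is excluded entirely, and training uses the
  remaining three — so every point is classified exactly once per
  sweep. Confusion counts are pooled per observer; means and SDs are
  then taken across observers. (Pooling before averaging is a
  documented choice; the across-observer SD is unaffected at first
  order.)
* **GT/probGT noise grid.** GT is split into three folds, probGT into
  two, giving five folds of comparable size. Training uses two folds —
  both GT, one GT plus one probGT, or both probGT — and testing always
  uses a GT fold not used in training, rotated over all three GT folds.
  probGT training labels are freshly sampled probabilistic annotations
  in every repetition (the package defaults to 10 repetitions for the
  fixed-label pure-GT condition and 50 for the resampling conditions);
  the deterministic fold schedule (`(t mod 3)+1` for the GT training
  fold, `((t+r) mod 2)+1` for the probGT fold) exercises both probGT
  folds. If a panel is entirely unanimous there is no uncertain stratum
  and every condition collapses to pure-GT training.
* **Consensus evaluation.** Four-fold cross-validation on the consensus
  set against consensus labels, plus each observer's raw annotation
  scored against the same reference — with the standing caveat that the
  observers voted in the consensus and the classifiers did not.

Seeds follow a documented schedule: one master seed expands into fold
seeds, per-repetition annotation seeds and per-fit forest seeds through
a deterministic counter hash, so any cell of the grid can be re-run in
isolation and whole runs are bit-reproducible.

## The synthetic-data generator

No image or annotation data are deposited with the study this package
models, so the generator is a first-class module: it must produce
cutouts and observer panels with the statistical structure the analysis
assumes, at the study's scale (617 cutouts, 11 observers).

**Scenes.** Each scene has a latent truth (CTC or not; prevalence 0.5,
matching the observed mean of ~300 CTC calls in 617 cutouts), a
difficulty $d \in [0,1]$, and two further latent quantities drawn per
scene: a perceptual *lean* (below) and an *appearance evidence*
$e = (1-d)\,t + d\,j$ with truth-coupled jitter
$j \sim Beta(1+t, 2-t)$. The rendered image follows $e$: a central
Gaussian-profile nucleus (blue); a green blob whose intensity and
punctate texture both scale with $e$ (at $e=0$ only a faint diffuse
haze remains); for red-positive non-CTC scenes a red CD45 blob
attenuated as the scene becomes CTC-like. Scenes vary per draw in
nucleus size, blob placement, texture grain, flanking debris count,
background level and noise amplitude — cutouts pooled from dozens of
source images are heterogeneous, and that heterogeneity is what makes
the fixed-$\gamma$ RBF kernel operate in a local regime. Channels
receive spectral bleed-through (filter crosstalk varying with staining
and exposure), a dark background offset with a faint green
autofluorescence tint, and uniform sensor noise. Finally the whole
frame fades with difficulty ($\times(1-0.55d)$): faintness is an
intensity effect, and since hue and saturation are invariant to a
global brightness factor, the classifier features deliberately cannot
see how faint a scene is — mirroring the design decision to drop V.

**Observers.** At difficulty $d$ an observer is unsure with probability
$d^{s}$ (slope $s$, default 1). When sure, the truth is reported
(sensitivity defaults to 1, so difficulty-0 scenes are always labelled
correctly). When unsure, a neutral observer votes "CTC" with the
scene's shared lean — all observers look at the same stimulus, so
unsure votes are correlated through the scene, with
$\text{lean} \sim Beta(0.5+0.5t,\; 0.5+0.5(1-t))$ weakly informative of
the truth — while a conservative observer always votes "no CTC". Two
conservative profiles among nine neutral ones reproduce the observed
panel structure: lowest CTC counts, lowest mean agreement, isolated in
the agreement-versus-count plane. Independent coin-flip guessing cannot
produce that isolation (neutral guessers then disagree with each other
as much as with the conservatives), which is why the shared lean is
part of the model. Keeping the lean, the appearance jitter and the
truth mutually distinct is equally deliberate: what a scene shows and
what the panel reads into it both track the truth, but not through the
same noise — otherwise probabilistic annotations would be learnably
consistent with the images and annotation noise would cost classifiers
nothing.

**Difficulty distribution and calibration.** Difficulty is a
two-component mixture: a clear component $Beta(1,24)$ and an ambiguous
component $Beta(4,3)$, because the agreement analysis above shows
disagreement is not uniform across cutouts. The ambiguous mass is the
main calibration knob: `calibrate_difficulty()` brackets it on a coarse
grid, bisects on mean pairwise agreement (monotone in the mass), and
selects over a small grid of uncertainty slopes the family member whose
consensus fraction comes closest to target, averaging a few hundred
simulated panels of annotation-only draws (images are not needed for
agreement statistics, which keeps calibration to seconds). Targets of
0.85 mean agreement and 0.81 consensus fraction land at an ambiguous
mass near 0.48 with slope 1. Unreachable targets (e.g. agreement 0.5
with an all-conservative panel) raise a `calibration_failure` condition
carrying the best parameters found.

**What the generator does and does not emulate.** Aggregate agreement
statistics, the consensus/probGT proportions, the expected label
instability (≈80 changes between probabilistic annotations at study
scale), the conservative-observer clustering, and class geometry loose
enough that a fixed-hyperparameter SVM degrades under training-label
noise while the random forest largely shrugs it off — these are
controlled. Optical physics, realistic morphology, focus artifacts and
the full vote-count distribution are not. Passing tests therefore show
that the *analysis machinery* behaves as published under the assumed
statistical structure; they are not evidence about any particular real
data set.

## Problem sizes and run times

The test suite exercises the full study scale where it matters: the
label-noise acceptance checks run one calibrated panel of 617 cutouts
and 11 observers with 10 repetitions per grid condition (a few minutes
on one core); unit tests use panels of 30–1000 annotation-only draws
and small image fixtures. The analysis scripts under `analysis/` run
the same pipeline with the paper-scale repetition counts (50 for
probGT-containing conditions), which takes tens of minutes; their
outputs under `results/` are regenerated, not shipped.

## Known limitations

* The stylized image model has a single object archetype per class;
  real cutouts contain clusters, debris and staining artifacts the
  generator does not attempt.
* Hue's circular topology is ignored (as in the original feature
  design); red-dominated content near H = 1 is a known discontinuity.
* The observer model couples all error to a scalar difficulty; real
  observers plausibly disagree for qualitatively different reasons
  (color vision, display, fatigue) that a single lean cannot express.
* Calibration matches aggregate targets (mean agreement, consensus
  fraction), not the full distribution of per-cutout vote counts.
* With eleven observers the conservative/neutral distinction is
  identifiable; the package makes no claim about detecting bias in
  small panels.
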