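---
title: "Weak supervision for anatomically-resolved PET/CT abnormality detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak supervision for anatomically-resolved PET/CT abnormality detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(anatomaly)
```

This vignette is the package's account of its own science: the model and
its assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, the numerical choices, and the places where the
design was genuinely open and a decision had to be made. No empirical claim
is made here that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. The labelling model

### Ontology and propagation

Anatomical regions form a directed acyclic graph: edges run from regions to
sub-regions ("lungs" → "left lung"), and a region may have several parents
(mediastinal lymph nodes descend from both the thoracic lymph nodes and the
mediastinum). Each exam's report is reduced to a *region probability map*:
for region $t$, collect the probabilities $p_1,\dots,p_{n_t}$ of every
mention of $t$ **or any of its descendants**, and combine them assuming
independence as the probability that at least one mention is abnormal:

$$\bar y_t = 1 - \prod_{i=1}^{n_t} (1 - p_i).$$

Two modelling commitments deserve flagging:

* **"Children" means all descendants.** Upward propagation could plausibly
  collect only direct children. We propagate through the full transitive
  closure: a left-lung mention should raise the chest probability even
  though the chest is two levels up, which is what "propagating
  probabilities up the DAG" has to mean for a multi-level ontology to be
  useful. The unit tests pin this by comparing against a brute-force
  reachability oracle on random DAGs.
* **Silence means normal.** Regions with no contributing mention get
  $\bar y_t = 0$. This mirrors the hand-labelling convention for this kind
  of data: a region not mentioned in findings/impression is labelled
  normal. It is an assumption, not a fact — a radiologist may omit a true
  finding — and it is exactly the kind of label noise weak supervision is
  designed to absorb.

The independence assumption in the noisy-OR is knowingly wrong (two
sentences about the same lesion are correlated); its virtue is monotonicity
(more abnormal-sounding mentions never lower a probability) and the
guarantee $\bar y_t \ge \max_i p_i$.

### Tokenization

The token classifier operates on wordpieces so rare compound terms
("subcarinal") decompose into frequent fragments ("sub" + "carinal"). The
vocabulary is built greedily: starting from single characters, repeatedly
merge the adjacent-piece pair whose merge most reduces the total token
count of the training corpus (equivalently, the most frequent adjacent
pair, counted without overlap), with ties broken lexicographically on the
merged string. The published approach states only "greedy … minimize the
number of tokens"; iterative pair-merging is the canonical instantiation,
and the tie-break makes builds reproducible. `target_size` defaults to
3000 at full scale; synthetic-corpus tests use ~120. Callers must exclude
evaluation text from the vocabulary corpus — that exclusion is part of the
contract, not something the function can enforce.

Tokenization is greedy longest-match-first within whitespace-delimited
words, lowercased with character offsets preserved, no continuation
markers; any character outside the vocabulary becomes `[UNK]` (one marker
per character), so tokenization never fails.

### The token classifier

Training sentences carry labels $y_i \in \{0, 1, -\}$: tokens inside an
abnormal mention are 1, inside a neutral/negative mention 0, and `-`
(coded `NA`) elsewhere. The loss is cross-entropy masked to labelled
tokens and scaled by $1/n$ per sentence, so predictions on `-` tokens are
provably irrelevant — the acceptance suite perturbs them and asserts the
loss is bit-identical.

The sequence encoder is a *contract*: any function mapping $n$ token ids
to $n$ hidden vectors works, so a pre-trained transformer slots in
unchanged. The shipped implementation is deliberately small — each token is
represented by the concatenated embeddings of a ±2 window plus the mean
embedding of the whole sentence, through one ReLU layer. The sentence-mean
term is what carries negation cues ("no", "physiologic") to every token in
the sentence; without it, a ±2 window cannot see a sentence-initial
negation from a sentence-final mention. The known cost: if one sentence
contains two mentions with *different* states, the sentence-level context
cannot distinguish them. The synthetic generator emits one mention per
sentence — typical of the terse, region-by-region style of PET/CT findings
— so this limitation is real but unexercised; a transformer encoder would
lift it.

Mention probability is the arithmetic mean of token probabilities over the
wordpiece tokens intersecting the mention span (wordpiece tokens, not
words, where a mention word splits).

Training follows the published schedule shape: Adam, learning-rate halving
on a fixed epoch period, sentences sampled with replacement each epoch,
model selection by best validation AUROC. Two profiles ship:
`report_train_config("published")` keeps the published constants (lr $10^{-4}$,
halving every 20 epochs, batch 16, 100 mentions/epoch, 85 epochs);
`"desk"` keeps the shape but raises the learning rate to 0.01 and uses
200 samples/epoch for 40 epochs, which brings the small CPU encoder to
ceiling on templated data in seconds. The published constants are tuned to
a large transformer on a real corpus; running them verbatim on a 5-digit
parameter model would be slow for no scientific reason.

### The rule-based baseline

The comparison labeler assigns 1 to every region mentioned in a sentence
containing no negative-finding keyword (and to all its ontology ancestors),
else 0. Only three keywords are quoted in the source material
("physiologic", "without", "unremarkable"); the shipped default extends
them with the obvious negation/stability cues ("no", "not", "negative",
"resolved", "stable"). The list is a parameter precisely because it is the
baseline's weakness: neutral phrasing without a keyword ("mild uptake …
likely reflects benign activity") defeats it, which is the behaviour the
labeler-comparison test exercises.

## 2. The scan model

### Encoder contract

The encoder maps $X \in \mathbb{R}^{2\times H\times W\times l}$ (channel 1
PET, channel 2 CT, both resampled to a common in-plane grid by bilinear
interpolation) to an encoding $A$ with $d$ channels on a grid reduced by a
declared spatial factor and a declared temporal factor with ceiling
division. The full-size configuration declares $d = 1024$, 32× spatial
(224 → 7) and 6× temporal, hence $1024 \times 7 \times 7 \times \lceil l/6
\rceil$ — 33 temporal positions at $l = 198$. This shape is asserted, not
derived from a particular CNN: a standard inflated-inception encoder
reduces time by a power of two, and the modification that yields exactly
6× is not recoverable from the published description, so the package
specifies the contract and lets any encoder honour it.

The shipped encoder is not a deep CNN (no GPU framework is assumed):
block-average pooling to the declared grid, three appended normalized
coordinate channels, then a pointwise two-layer ReLU network to $d$
channels. The coordinate channels are load-bearing: attention heads must
distinguish *where* uptake is elevated, a deep CNN gets position implicitly
from its receptive-field geometry, and a pointwise map does not — so
position is supplied explicitly. All rectifiers honour the
guided-backpropagation contract, and the analytic gradients are verified
against numerical differentiation in the unit tests.

### Attention and heads

Per region $t$: scores $s_{ijk} = \mathbf{w}^\top \mathbf{a}_{ijk}$, a
single softmax jointly over all voxels giving $\alpha \ge 0$,
$\sum\alpha = 1$, pooled vector $\mathbf{a} = \sum \alpha_{ijk}
\mathbf{a}_{ijk}$, and a linear-sigmoid readout. $\alpha$ is returned for
interpretation. The multi-task loss is the mean over heads of soft-target
binary cross-entropy against $\bar y_t$ — the weak labels enter *as
probabilities*, not binarized, because the training objective substitutes
the propagated probability directly. Predictions are clamped to
$[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-7}$, before the
logarithm.

### Training schedules

`scan_train_config("published")` carries the published constants: Adam at
$10^{-4}$ halved every 16 epochs, batch size 2, 2000 exams sampled with
replacement per epoch, 15 multi-task epochs, 5 fine-tuning epochs with
best-validation-epoch selection, crop/brightness augmentation on.
`"desk"` (the default, used by tests and acceptance) keeps 15 epochs and
the halving period but uses 500 samples/epoch, batch 8, lr 0.02,
augmentation off. The desk numbers were chosen so that the tiny encoder
actually reaches its asymptote within the 15-epoch budget on the reference
200-exam cohort; with substantially fewer optimization steps per epoch it
plateaus short of convergence. Augmentation is off at desk scale because
the synthetic volumes carry no pose variability for it to regularize
against; the operation itself is tested separately.

Augmentation semantics: one random crop location per sequence covering
200/224 of each in-plane axis, bilinear resize back, then a single
brightness factor for the whole sequence. The jitter magnitude is
$\gamma \sim \mathrm{Uniform}(0, 0.25)$; whether the published "factor
$\gamma$" brightens or darkens is unstated, so the package multiplies by
$1 \pm \gamma$ with a random sign, documented and configurable. Fine-tuning
re-initializes the task head (the third open reading — reusing multi-task
head weights — is not implemented; a fresh head makes the
pre-training-vs-scratch comparison clean).

## 3. Interpretation

Guided backpropagation is defined as a backward-pass contract — negative
gradients are zeroed at every rectifier — so any encoder honouring it is
visualizable. The saliency post-processing follows the published recipe
exactly: absolute value, maximum over the two input channels, subtract the
minimum, divide by the maximum (an all-constant gradient is defined as an
all-zero map), then in 3D mode zero everything below a threshold
$\beta_t$. The published thresholds were chosen manually and never
reported; the package defaults $\beta_t$ to the 95th percentile of the
normalized map, which reproduces the intended "keep the top sliver"
behaviour without per-region hand-tuning. 2D mode performs no clipping.
Attention maps are projected to the scan grid by nearest-neighbour
upsampling with max-normalized opacity.

## 4. Evaluation statistics

* AUROC uses the rank statistic with midranks (ties count ½), pinned to a
  concordant-pair-counting oracle in tests.
* Worklist sensitivity sorts by descending score with stable tie-breaking
  (input order) and reads the top $\lceil fN \rceil$; the tie rule only
  matters for degenerate score ties and is documented rather than clever.
* Bootstrap CIs are percentile intervals of the resampled mean, default
  10,000 resamples — the published text says only "bootstrapping" over the
  five per-seed scores; 10,000 makes Monte-Carlo error negligible at the
  3-decimal level, verified against exact enumeration of all $5^5$
  resamples.
* Paired permutation tests flip the signs of paired differences;
  $p = (1 + \#\text{extreme})/(1 + n_{\text{iter}})$ with
  $n_{\text{iter}} = 10{,}000$ by default, one- or two-sided, with exact
  enumeration available for $n \le 20$ pairs. Pairing granularity is the
  caller's: the tests pair per unit supplied (e.g. region × seed), since
  the published analyses imply but never state the granularity.
* Mortality labels: death within $x$ days of the scan, **inclusive**
  boundary ("within $x$ days" read as $\le x$); patients without a
  recorded death date are assumed alive and labelled 0. A death date
  before the scan date is flagged with a warning.
* Median-of-seeds ensembling uses `stats::median` (even counts: mean of
  the central two).

## 5. The synthetic world

The generator exists so that every stage has checkable ground truth, and
its defaults were fixed once, before any acceptance measurement:

* **Volumes** 64×64×16, two channels. PET background is
  $\mathcal{N}(0, 1)$; each abnormal leaf region receives one Gaussian blob
  of amplitude 4 (4 background SDs — conspicuous, as real FDG-avid lesions
  are against quiet background) centred randomly inside its mask. CT is a
  fixed body-ellipse texture. Masks are axis-aligned boxes in a body-like
  arrangement (lungs upper left/right, liver mid-right, spleen mid-left,
  inguinal nodes low midline), specified as volume fractions so they scale
  with resolution.
* **Reports** are templated: abnormal leaves always yield an abnormal
  sentence; normal leaves yield, with probability 0.3 (a realistic rate of
  incidental neutral commentary), a neutral/negative sentence. Two of the
  five normal templates are *hard negatives* — neutral phrasing with no
  negation keyword — so roughly 12% of normal region-sentences defeat the
  rule-based labeler. This one dial creates the measurable gap between the
  trained labeler and the baseline and injects honest label noise into the
  end-to-end recovery test.
* **Mortality** is optionally linked through a logistic hazard on the
  number of abnormal regions.

What a green test establishes: the implementation is internally coherent —
propagation matches brute force, gradients are exact, the pipeline
recovers labels it planted, attention concentrates where the signal was
placed. What it does **not** establish: performance on real PET/CT.
Real reports have free prose, hedging, coreference and negation scope that
templates do not; real lesions are not Gaussian boxes; real PET has
physiological uptake (brain, bladder, myocardium) that mimics disease.
Numbers from this package on synthetic data say the machinery works, not
that the clinical results transfer.

## 6. Known limitations

* The shipped encoders are CPU-scale stand-ins behind the published
  contracts; reproducing clinical-cohort AUROCs would require the original
  private data and GPU-scale encoders, both out of scope.
* One-mention-per-sentence is assumed by the shipped sequence encoder's
  sentence-mean context (see §1).
* The rule baseline's keyword list is a minimal reconstruction; the
  original's full list was not published.
* `build_ontology_candidates` mines frequent k-grams; deciding which are
  anatomical remains human curation, as it was in the source workflow.
* The 94-region fixture ontology is synthetic (same shape, invented
  content); real deployments supply their own config.
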