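# anatomaly

Weakly supervised, anatomically-resolved abnormality detection for
whole-body FDG-PET/CT — in R.

## The problem

A whole-body FDG-PET/CT exam pairs a metabolic volume (PET) with an
anatomical one (CT), and the radiologist's free-text report records which
anatomical regions show abnormal tracer uptake. Training a scan classifier
that predicts, *per region of an anatomical ontology*, whether uptake is
abnormal would normally require painstaking expert annotation of thousands
of 3D exams. `anatomaly` implements the alternative: mine the labels the
radiologists already wrote.

The pipeline has three stages:

1. **Weak labels from reports.** Tagging functions locate every mention of
   an ontology region in the findings/impression sections. A token
   classifier (a sequence encoder `G` mapping wordpieces `x_1..x_n` to
   hidden vectors `z_1..z_n`, with a per-token head
   `P(x_i abnormal) = σ(wᵀz_i + b)`) scores whether each mention sits in an
   abnormal context; a mention's probability is the mean over its tokens.
   Mention probabilities are reconciled up the region DAG by noisy-OR:

   ```
   ȳ_t = P(t abnormal) = 1 − ∏ᵢ (1 − pᵢ)   over mentions of t and its descendants
   ```

   A rule-based baseline labeler (mention + no negation keyword ⇒ abnormal)
   is included for comparison.

2. **Multi-task scan model.** A shared 3D encoder `F` turns the 2-channel
   volume `X ∈ ℝ^(2×224×224×l)` into an encoding
   `A ∈ ℝ^(d×7×7×⌈l/6⌉)` of voxel vectors `a_ijk`. Each region gets a task
   head with soft spatial attention — scores `s_ijk = wᵀa_ijk`, weights
   `α = softmax(s)`, pooled vector `a = Σ α_ijk a_ijk` — and a linear
   sigmoid classifier. Training minimizes the mean soft-target
   cross-entropy between `ȳ_t` (used as-is, not binarized) and the head
   outputs, then fine-tunes single tasks from the multi-task checkpoint.

3. **Interpretation and evaluation.** Guided-backpropagation saliency maps
   (negative gradients zeroed at rectifiers, then abs → channel-max →
   min-max normalization → optional clipping at β), attention-map
   projection onto the scan grid, AUROC/F1/sensitivity/specificity,
   worklist-triage sensitivity curves, percentile-bootstrap CIs over
   training seeds, sign-flip paired permutation tests with Bonferroni
   correction, and median-of-seeds ensembling.

Everything is exercisable offline: the `synthetic_data` module generates
paired reports and volumes with token-level and voxel-level ground truth
(templated sentences with planted mention spans; Gaussian uptake blobs
inside per-region masks exactly when the region is abnormal).

## Worked example

```r
library(anatomaly)

ont <- demo_ontology()
report <- parse_report(paste(
  "CLINICAL HISTORY: Lymphoma, restaging.",
  "FINDINGS: Abnormal FDG uptake in the left lung.",
  "Physiologic uptake in the liver.",
  "IMPRESSION: Suspicious left pulmonary focus."))
tag_report(report, ont)
#>   region_id    section sentence_index start end      text probability
#> 1 left_lung   findings              2    27  36 left lung          NA
#> 2     liver   findings              3    26  31     liver          NA
#> 3     lungs impression              4    16  25 pulmonary          NA

round(generate_weak_labels(report, ont, labeler = "rule"), 2)
#>            chest                lungs            left_lung
#>                1                    1                    1
#>       right_lung              abdomen                liver
#>                0                    0                    0
#>           spleen inguinal_lymph_nodes
#>                0                    0
```

The abnormal left-lung mention propagates to `lungs` and `chest`; the
liver mention is suppressed by the "physiologic" cue. On a synthetic
cohort, the weak labels are strong enough to train the scan model to
recover the planted ground truth:

```r
co   <- generate_cohort(ont, n_exams = 200, seed = 1)
weak <- weak_label_table(lapply(co, `[[`, "report"), ont, labeler = "rule")
sel  <- select_task_regions(weak)   # prevalence >= 10% -> "main" tasks

fit <- train_multitask(
  multitask_model(scan_encoder(seed = 1), sel$main, seed = 1),
  lapply(co[1:160], `[[`, "volume"), weak[1:160, ],
  scan_train_config(), seed = 1)

preds <- predict_scan(fit, lapply(co[161:200], `[[`, "volume"))
truth <- oracle_labels(co)[161:200, ]
round(sapply(sel$main, function(r) binary_metrics(preds[, r], truth[, r])$auroc), 3)
#>              abdomen                chest                lungs
#>                1.000                1.000                1.000
#>               spleen                liver            left_lung
#>                1.000                1.000                0.997
#>           right_lung inguinal_lymph_nodes
#>                1.000                1.000

worklist_sensitivity(preds[, "liver"], truth[, "liver"], f = 0.75)
#> [1] 1
```

Held-out AUROC is ≈ 1 per region because the synthetic blobs are planted
well above the noise floor — the generator's job is to make every stage of
the pipeline verifiable, not to be hard. Sorting the synthetic worklist by
the liver head's probability captures every abnormal liver within the
first three quarters of the list; an unsorted worklist would capture 75%
in expectation.

For saliency and attention maps:

```r
sal <- compute_saliency(fit, co[[161]]$volume, "liver", mode = "2d-unclipped")
att <- attend(fit$heads[["liver"]], encode_scan(fit, co[[161]]$volume))
overlay <- project_attention(att$alpha, dim(sal$values))
```

## Command line

A single dispatcher covers the scriptable surface:

```sh
Rscript -e 'anatomaly::anatomaly_cli()' ontology-validate inst/extdata/ontology_synthetic_94.json
Rscript -e 'anatomaly::anatomaly_cli()' tag --reports r.jsonl --ontology o.json --out mentions.jsonl
Rscript -e 'anatomaly::anatomaly_cli()' label-reports --reports r.jsonl --ontology o.json --out weak.csv
Rscript -e 'anatomaly::anatomaly_cli()' simulate --n 50 --out simdir --seed 3
```

## Scope notes

The shipped 94-region ontology (`inst/extdata/ontology_synthetic_94.json`)
is a synthetic stand-in with the shape of a production whole-body ontology;
region lists are institution-specific. Transformer pre-training, DICOM
ingestion, survival modelling (Cox/Harrell) and the hand-labelling GUI are
out of scope. See `vignettes/weak-supervision-petct.Rmd` for the modelling
assumptions, parameter choices, and the limits of what the synthetic tests
establish.
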