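#' Demo ontology (8 regions)
#'
#' A small two-level DAG used throughout the examples and tests:
#' chest -> lungs -> \{left lung, right lung\}, abdomen -> \{liver, spleen\},
#' and pelvis with its inguinal lymph nodes. The five leaves carry spatial
#' masks in the synthetic volumes (see [region_mask_layout()]).
#'
#' @return a `region_ontology` with 8 regions.
#' @export
demo_ontology <- function() {
  region_ontology(
    regions = list(
      list(id = "chest"),
      list(id = "lungs", patterns = c("lungs", "pulmonary")),
      list(id = "left_lung", patterns = "left lung"),
      list(id = "right_lung", patterns = "right lung"),
      list(id = "abdomen"),
      list(id = "liver", patterns = c("liver", "hepatic")),
      list(id = "spleen", patterns = c("spleen", "splenic")),
      list(id = "inguinal_lymph_nodes",
           patterns = c("inguinal lymph nodes", "inguinal lymphadenopathy"))),
    edges = list(
      c("chest", "lungs"), c("lungs", "left_lung"), c("lungs", "right_lung"),
      c("abdomen", "liver"), c("abdomen", "spleen")))
}

#' Synthetic 94-region ontology
#'
#' A stand-in with the same shape as a production whole-body PET/CT region
#' ontology: 94 regions spanning coarse compartments (chest, abdomen,
#' pelvis, head/neck, skeleton), laterality splits, and a multi-parent
#' lymph-node hierarchy (e.g. mediastinal lymph nodes descend from both the
#' thoracic lymph nodes and the mediastinum). The exact region list of any
#' particular clinical deployment is institution-specific; this fixture is
#' synthetic and exists so ontology-scale behavior is testable. Also shipped
#' serialized as `inst/extdata/ontology_synthetic_94.json`.
#'
#' @return a `region_ontology` with exactly 94 regions.
#' @export
synthetic_ontology_94 <- function() {
  spec <- list(
    # id = parents (character(0) for roots)
    head_neck = character(), brain = "head_neck", cerebral_cortex = "brain",
    cerebellum = "brain", neck = "head_neck", thyroid = "neck",
    larynx = "neck", nasopharynx = "head_neck", oropharynx = "head_neck",
    tonsils = "oropharynx", salivary_glands = "head_neck",
    parotid_gland = "salivary_glands", left_parotid_gland = "parotid_gland",
    right_parotid_gland = "parotid_gland",
    chest = character(), lungs = "chest", left_lung = "lungs",
    right_lung = "lungs", upper_lobe_left_lung = "left_lung",
    lower_lobe_left_lung = "left_lung", upper_lobe_right_lung = "right_lung",
    middle_lobe_right_lung = "right_lung",
    lower_lobe_right_lung = "right_lung", pleura = "chest",
    mediastinum = "chest", heart = "chest", esophagus = "chest",
    chest_wall = "chest", breast = "chest", left_breast = "breast",
    right_breast = "breast",
    abdomen = character(), liver = "abdomen", left_hepatic_lobe = "liver",
    right_hepatic_lobe = "liver", gallbladder = "abdomen",
    spleen = "abdomen", pancreas = "abdomen", stomach = "abdomen",
    bowel = "abdomen", small_bowel = "bowel", colon = "bowel",
    rectum = "colon", kidneys = "abdomen", left_kidney = "kidneys",
    right_kidney = "kidneys", adrenal_glands = "abdomen",
    left_adrenal_gland = "adrenal_glands",
    right_adrenal_gland = "adrenal_glands",
    pelvis = character(), bladder = "pelvis", uterus = "pelvis",
    ovaries = "pelvis", prostate = "pelvis",
    skeleton = character(), spine = "skeleton", cervical_spine = "spine",
    thoracic_spine = "spine", lumbar_spine = "spine", sacrum = "spine",
    pelvic_skeleton = "skeleton", hips = "pelvic_skeleton",
    ribs = "skeleton", sternum = "skeleton", skull = "skeleton",
    femur = "skeleton", left_femur = "femur", right_femur = "femur",
    humerus = "skeleton", shoulder = "skeleton", bone_marrow = "skeleton",
    lymph_nodes = character(),
    cervical_lymph_nodes = c("lymph_nodes", "neck"),
    supraclavicular_lymph_nodes = c("lymph_nodes", "neck"),
    thoracic_lymph_nodes = c("lymph_nodes", "chest"),
    mediastinal_lymph_nodes = c("thoracic_lymph_nodes", "mediastinum"),
    hilar_lymph_nodes = "thoracic_lymph_nodes",
    subcarinal_lymph_nodes = "mediastinal_lymph_nodes",
    paratracheal_lymph_nodes = "mediastinal_lymph_nodes",
    axillary_lymph_nodes = c("lymph_nodes", "chest"),
    left_axillary_lymph_nodes = "axillary_lymph_nodes",
    right_axillary_lymph_nodes = "axillary_lymph_nodes",
    abdominal_lymph_nodes = c("lymph_nodes", "abdomen"),
    retroperitoneal_lymph_nodes = "abdominal_lymph_nodes",
    celiac_lymph_nodes = "abdominal_lymph_nodes",
    mesenteric_lymph_nodes = "abdominal_lymph_nodes",
    periportal_lymph_nodes = "abdominal_lymph_nodes",
    pelvic_lymph_nodes = c("lymph_nodes", "pelvis"),
    iliac_lymph_nodes = "pelvic_lymph_nodes",
    inguinal_lymph_nodes = "pelvic_lymph_nodes",
    left_inguinal_lymph_nodes = "inguinal_lymph_nodes",
    right_inguinal_lymph_nodes = "inguinal_lymph_nodes",
    muscles = character(), skin = character())
  regions <- lapply(names(spec), function(id) list(id = id))
  edges <- list()
  for (id in names(spec)) {
    for (p in spec[[id]]) edges[[length(edges) + 1L]] <- c(p, id)
  }
  region_ontology(regions, edges)
}

# Sentence templates. {region} is substituted by the display name.
.templates_abnormal <- c(
  "Abnormal FDG uptake in the {region}.",
  "There is intense radiotracer uptake in the {region}.",
  "Focal hypermetabolic activity in the {region} suspicious for malignancy.")
# negative/neutral templates that *contain* a negative-finding keyword
.templates_negative <- c(
  "No abnormal FDG uptake in the {region}.",
  "The {region} is unremarkable.",
  "Physiologic uptake in the {region}.")
# hard negatives: neutral phrasing with no negative keyword, which the
# rule-based baseline mislabels as abnormal while a trained model can use
# the context words to label correctly
.templates_hard_negative <- c(
  "Mild uptake in the {region} likely reflects benign activity.",
  "Tracer distribution in the {region} consistent with prior treatment.")

#' Region mask layout for synthetic volumes
#'
#' Deterministic, resolution-independent ground-truth masks: each leaf
#' region of the demo ontology occupies a fixed axis-aligned box in a
#' body-like arrangement (lungs upper left/right, liver mid-right, spleen
#' mid-left, inguinal nodes low midline), expressed as fractions of the
#' volume shape. Internal regions take the union of their descendants'
#' masks.
#'
#' @param ontology a `region_ontology` (leaves needing masks must be among
#'   the demo-ontology leaves).
#' @param shape integer vector `c(H, W, l)`.
#' @return named list of boolean `H x W x l` arrays, one per region.
#' @export
region_mask_layout <- function(ontology, shape = c(64L, 64L, 16L)) {
  boxes <- list(  # fractions: x0,x1 (H axis), y0,y1 (W axis), z0,z1 (slices)
    left_lung  = c(0.15, 0.42, 0.25, 0.70, 0.05, 0.35),
    right_lung = c(0.58, 0.85, 0.25, 0.70, 0.05, 0.35),
    liver      = c(0.50, 0.85, 0.30, 0.75, 0.40, 0.60),
    spleen     = c(0.15, 0.35, 0.35, 0.65, 0.40, 0.55),
    inguinal_lymph_nodes = c(0.30, 0.70, 0.30, 0.70, 0.78, 0.95))
  leaf_ids <- intersect(names(boxes), names(ontology$regions))
  masks <- list()
  for (id in leaf_ids) {
    b <- boxes[[id]]
    m <- array(FALSE, dim = shape)
    xr <- max(1L, ceiling(b[1] * shape[1])):ceiling(b[2] * shape[1])
    yr <- max(1L, ceiling(b[3] * shape[2])):ceiling(b[4] * shape[2])
    zr <- max(1L, ceiling(b[5] * shape[3])):ceiling(b[6] * shape[3])
    m[xr, yr, zr] <- TRUE
    masks[[id]] <- m
  }
  # internal regions: union over masked descendants
  for (id in names(ontology$regions)) {
    if (id %in% names(masks)) next
    dd <- intersect(descendants(ontology, id), leaf_ids)
    if (!length(dd)) next
    m <- array(FALSE, dim = shape)
    for (d in dd) m <- m | masks[[d]]
    masks[[id]] <- m
  }
  masks
}

# deterministic CT "anatomy": a soft body ellipse with a vertical gradient
.ct_texture <- function(shape) {
  x <- (seq_len(shape[1]) - 0.5) / shape[1] - 0.5
  y <- (seq_len(shape[2]) - 0.5) / shape[2] - 0.5
  body <- outer(x, y, function(a, b) as.numeric((a / 0.45)^2 + (b / 0.4)^2 < 1))
  z <- (seq_len(shape[3]) - 0.5) / shape[3]
  ct <- array(0, dim = shape)
  for (s in seq_len(shape[3])) ct[, , s] <- body * (0.5 + 0.5 * z[s])
  ct
}

# one smooth uptake blob inside a mask, on the volume grid
.add_blob <- function(vol, mask, intensity) {
  idx <- which(mask, arr.ind = TRUE)
  c0 <- idx[sample.int(nrow(idx), 1L), ]
  sig <- pmax(apply(idx, 2L, function(v) diff(range(v))) / 4, 1)
  dd <- dim(vol)
  dx <- ((seq_len(dd[1]) - c0[1]) / sig[1])^2
  dy <- ((seq_len(dd[2]) - c0[2]) / sig[2])^2
  dz <- ((seq_len(dd[3]) - c0[3]) / sig[3])^2
  blob <- exp(-0.5 * (outer(outer(dx, dy, `+`), dz, `+`)))
  vol + intensity * blob * mask
}

#' Generate a synthetic PET/CT cohort with ground truth
#'
#' Emulates the paired structure of a whole-body PET/CT data set: for each
#' exam, leaf-region abnormality states are drawn independently from the
#' stated prevalences; the report's findings section gets one abnormal
#' sentence per abnormal leaf (and, with probability `neutral_sentence_rate`,
#' a neutral/negative sentence per normal leaf); the PET channel of the
#' volume receives a Gaussian uptake blob inside the region mask for exactly
#' the abnormal leaves, on top of N(0, `noise_sd`) background noise, while
#' the CT channel carries a fixed anatomical texture. Mention spans and
#' per-mention states are recorded so token-level training data can be
#' derived, and masks ship with each exam for localization checks. All
#' randomness derives from `seed`; regenerating with the same seed is
#' bitwise identical.
#'
#' Three of five normal-leaf sentence templates contain an explicit
#' negative-finding keyword; the other two are "hard negatives" (neutral
#' phrasing with no keyword) that the rule-based baseline systematically
#' mislabels — the lever behind the labeler-comparison experiments.
#'
#' @param ontology a `region_ontology`; defaults to [demo_ontology()].
#' @param n_exams number of exams.
#' @param prevalences named vector of leaf prevalences in \[0, 1\] (regions
#'   with masks); unnamed scalar applies to all masked leaves.
#' @param volume_shape integer `c(H, W, l)` (default 64 x 64 x 16).
#' @param blob_intensity PET blob amplitude over background (default 4).
#' @param noise_sd PET background noise standard deviation (default 1).
#' @param neutral_sentence_rate probability a normal leaf yields a
#'   neutral/negative sentence (default 0.3).
#' @param mortality_link optional `list(intercept, slope, horizon_days)`:
#'   death occurs with probability
#'   `plogis(intercept + slope * n_abnormal_regions)` within
#'   `horizon_days` of the scan.
#' @param seed integer seed.
#' @return list of class `synthetic_cohort`; each element is a
#'   `synthetic_exam`: list with `exam_id`, `region_states` (named 0/1 over
#'   all regions, OR-propagated), `report` (a `report_document`),
#'   `sentence_truth` (data.frame: sentence_index, region_id, start, end,
#'   state), `volume` (`scan_volume`), `region_masks`, `scan_date`,
#'   `date_of_death` (NA if censored).
#' @export
generate_cohort <- function(ontology = demo_ontology(), n_exams = 100L,
                            prevalences = 0.3,
                            volume_shape = c(64L, 64L, 16L),
                            blob_intensity = 4, noise_sd = 1,
                            neutral_sentence_rate = 0.3,
                            mortality_link = NULL, seed = 1L) {
  set.seed(seed)
  masks <- region_mask_layout(ontology, volume_shape)
  leaf_ids <- names(masks)[vapply(names(masks), function(id)
    length(ontology$children[[id]]) == 0L, NA)]
  if (!length(leaf_ids)) stop("no masked leaf regions in this ontology")
  if (is.null(names(prevalences))) {
    prevalences <- stats::setNames(rep(prevalences[1L], length(leaf_ids)),
                                   leaf_ids)
  }
  if (any(prevalences < 0 | prevalences > 1)) {
    stop("prevalences must lie in [0, 1]")
  }
  ct <- .ct_texture(volume_shape)
  all_ids <- names(ontology$regions)
  exams <- vector("list", n_exams)
  for (i in seq_len(n_exams)) {
    states <- stats::setNames(integer(length(leaf_ids)), leaf_ids)
    for (id in leaf_ids) {
      states[[id]] <- stats::rbinom(1L, 1L, prevalences[[id]])
    }
    # OR-propagate leaf states to every region
    full_states <- stats::setNames(integer(length(all_ids)), all_ids)
    for (id in all_ids) {
      scope <- intersect(c(id, descendants(ontology, id)), leaf_ids)
      full_states[[id]] <- as.integer(length(scope) > 0L &&
                                        any(states[scope] == 1L))
    }

    # report text + recorded mention ground truth
    finding_rows <- list()
    for (id in leaf_ids) {
      disp <- ontology$regions[[id]]$display_name
      if (states[[id]] == 1L) {
        tpl <- sample(.templates_abnormal, 1L)
      } else if (stats::runif(1L) < neutral_sentence_rate) {
        tpl <- sample(c(.templates_negative, .templates_hard_negative), 1L)
      } else {
        next
      }
      sent <- sub("{region}", disp, tpl, fixed = TRUE)
      start <- regexpr(disp, sent, fixed = TRUE)[[1L]] - 1L
      finding_rows[[length(finding_rows) + 1L]] <- list(
        sentence = sent, region_id = id, start = start,
        end = start + nchar(disp), state = states[[id]])
    }
    findings <- vapply(finding_rows, `[[`, "", "sentence")
    raw <- paste0(
      "CLINICAL HISTORY: Restaging examination. ",
      "PROCEDURE: Whole-body FDG-PET/CT from skull base to thigh. ",
      "FINDINGS: ",
      if (length(findings)) paste(findings, collapse = " ") else "",
      " IMPRESSION: ",
      if (any(states == 1L)) "Findings as above." else
        "No evidence of abnormal FDG uptake.")
    report <- parse_report(raw, exam_id = sprintf("exam_%04d", i))
    truth <- if (length(finding_rows)) {
      data.frame(
        sentence_index = vapply(finding_rows, function(r)
          which(report$sentences$sentence == r$sentence)[1L], 0L),
        region_id = vapply(finding_rows, `[[`, "", "region_id"),
        start = vapply(finding_rows, `[[`, 0L, "start"),
        end = vapply(finding_rows, `[[`, 0L, "end"),
        state = vapply(finding_rows, `[[`, 0L, "state"))
    } else {
      data.frame(sentence_index = integer(), region_id = character(),
                 start = integer(), end = integer(), state = integer())
    }

    # volume: PET noise + blobs in abnormal leaf masks; fixed CT texture
    pet <- array(stats::rnorm(prod(volume_shape), 0, noise_sd),
                 dim = volume_shape)
    for (id in leaf_ids) {
      if (states[[id]] == 1L && blob_intensity != 0) {
        pet <- .add_blob(pet, masks[[id]], blob_intensity)
      }
    }
    vol <- array(0, dim = c(2L, volume_shape))
    vol[1L, , , ] <- pet
    vol[2L, , , ] <- ct

    scan_date <- as.Date("2008-01-01") + (i %% 365L)
    dod <- as.Date(NA)
    if (!is.null(mortality_link)) {
      p_death <- stats::plogis(mortality_link$intercept +
                                 mortality_link$slope * sum(states))
      if (stats::runif(1L) < p_death) {
        dod <- scan_date + sample.int(mortality_link$horizon_days, 1L)
      }
    }
    exams[[i]] <- structure(
      list(exam_id = report$exam_id, region_states = full_states,
           report = report, sentence_truth = truth,
           volume = scan_volume(vol), region_masks = masks,
           scan_date = scan_date, date_of_death = dod),
      class = "synthetic_exam")
  }
  structure(exams, class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d exams, %d regions\n",
              length(x), length(x[[1L]]$region_states)))
  invisible(x)
}

#' Ground-truth region labels for a synthetic cohort
#'
#' The generator's leaf states propagated up the ontology by logical OR —
#' the p -> 1 limit of the noisy-OR propagation rule.
#'
#' @param cohort a `synthetic_cohort`.
#' @return integer matrix exams x regions of 0/1 states.
#' @export
oracle_labels <- function(cohort) {
  t(vapply(cohort, function(ex) ex$region_states,
           cohort[[1L]]$region_states))
}

#' Labeled token sentences for report-model training
#'
#' Flattens a cohort's recorded sentence-level ground truth into the
#' `(ids, labels)` format consumed by [train_report_model()]: each mention
#' sentence is wordpiece-tokenized and its mention span labeled with the
#' generator's true state.
#'
#' @param cohort a `synthetic_cohort`.
#' @param vocab a `wordpiece_vocab`.
#' @return list of `list(ids, labels, sentence)` entries.
#' @export
cohort_labeled_sentences <- function(cohort, vocab) {
  out <- list()
  for (ex in cohort) {
    tr <- ex$sentence_truth
    for (ri in seq_len(nrow(tr))) {
      sent <- ex$report$sentences$sentence[tr$sentence_index[ri]]
      tokseq <- wp_tokenize(sent, vocab)
      ids <- match(tokseq$tokens, vocab$pieces)
      ids[is.na(ids)] <- match(vocab$unk, vocab$pieces)
      labels <- label_tokens(tokseq,
                             data.frame(start = tr$start[ri], end = tr$end[ri]),
                             tr$state[ri])
      out[[length(out) + 1L]] <- list(ids = ids, labels = labels,
                                      sentence = sent)
    }
  }
  out
}
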