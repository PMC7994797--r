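#' Generate weak labels for one report
#'
#' The full report-to-label path: tag region mentions in the findings and
#' impression sections, score each mention (with the trained report model or
#' the rule-based baseline), and propagate the mention probabilities up the
#' ontology into one probability of abnormality per region. Regions never
#' mentioned get 0, mirroring the hand-labeling rule that silence about a
#' region means no abnormal uptake.
#'
#' @param report a `report_document` (or raw report text, which is parsed).
#' @param ontology a `region_ontology`.
#' @param labeler either the string `"rule"` (rule-based baseline), or a list
#'   with elements `model` (a `report_model`) and `vocab` (its
#'   `wordpiece_vocab`).
#' @param negative_keywords passed to [rule_based_label()] when
#'   `labeler = "rule"`.
#' @return named numeric vector over all ontology regions (the region
#'   probability map for this exam).
#' @export
generate_weak_labels <- function(report, ontology, labeler = "rule",
                                 negative_keywords = NULL) {
  if (is.character(report) && !inherits(report, "report_document")) {
    report <- parse_report(report)
  }
  mentions <- tag_report(report, ontology)
  if (!nrow(mentions)) return(propagate(ontology, NULL))
  scored <- .score_mentions(report, mentions, ontology, labeler,
                            negative_keywords)
  propagate(ontology, scored)
}

.score_mentions <- function(report, mentions, ontology, labeler,
                            negative_keywords = NULL) {
  out <- list()
  for (si in unique(mentions$sentence_index)) {
    sent <- report$sentences$sentence[si]
    sub <- mentions[mentions$sentence_index == si, , drop = FALSE]
    if (identical(labeler, "rule")) {
      args <- list(sentence = sent, mentions = sub, ontology = ontology)
      if (!is.null(negative_keywords)) args$negative_keywords <- negative_keywords
      lab <- do.call(rule_based_label, args)
      sub <- data.frame(region_id = lab$region_id,
                        probability = as.numeric(lab$state))
    } else {
      sub <- predict_mention_probability(sent, sub, labeler$model,
                                         labeler$vocab)
    }
    out[[length(out) + 1L]] <- sub[, c("region_id", "probability")]
  }
  do.call(rbind, out)
}

#' Weak-label table for a set of reports
#'
#' @param reports list of `report_document`s (or raw texts).
#' @param ontology a `region_ontology`.
#' @inheritParams generate_weak_labels
#' @return numeric matrix, one row per exam (named by exam id where
#'   available), one column per ontology region.
#' @export
weak_label_table <- function(reports, ontology, labeler = "rule",
                             negative_keywords = NULL) {
  rows <- lapply(reports, generate_weak_labels, ontology = ontology,
                 labeler = labeler, negative_keywords = negative_keywords)
  tab <- do.call(rbind, rows)
  ids <- vapply(reports, function(r)
    if (inherits(r, "report_document")) as.character(r$exam_id) else
      NA_character_, "")
  if (!anyNA(ids)) rownames(tab) <- ids
  tab
}

#' Select task regions by weak-label prevalence
#'
#' Region prevalence is the fraction of exams whose propagated weak label,
#' binarized at `binarize_at`, is positive. "Main" task regions have at least
#' one positive for every nine negatives (prevalence >= 10% by default);
#' "rare" regions have positive prevalence below 3%. The two sets are
#' disjoint by construction, each ordered by decreasing prevalence.
#'
#' @param labels a numeric matrix of weak labels (exams x regions, e.g. from
#'   [weak_label_table()]) or a list of region probability maps.
#' @param threshold_main inclusive main-task prevalence threshold (0.10).
#' @param threshold_rare exclusive rare-task prevalence ceiling (0.03).
#' @param binarize_at probability cutoff for calling a weak label positive.
#' @return list with character vectors `main` and `rare` and the named
#'   `prevalence` vector.
#' @export
select_task_regions <- function(labels, threshold_main = 0.10,
                                threshold_rare = 0.03, binarize_at = 0.5) {
  if (is.list(labels) && !is.data.frame(labels)) {
    labels <- do.call(rbind, labels)
  }
  stopifnot(nrow(labels) > 0L)
  prev <- colMeans(labels >= binarize_at)
  ord <- order(-prev, colnames(labels))
  prev <- prev[ord]
  list(main = names(prev)[prev >= threshold_main],
       rare = names(prev)[prev > 0 & prev < threshold_rare],
       prevalence = prev)
}

#' Binary mortality label for an exam
#'
#' 1 when a recorded date of death falls within `x` days of the scan
#' (inclusive boundary: death exactly `x` days after the scan counts).
#' Patients without a recorded date of death are assumed alive (censored)
#' and labeled 0. A death date before the scan date is flagged with a
#' warning and labeled 1.
#'
#' @param date_of_death a `Date` or `NA` when no death is recorded.
#' @param scan_date a `Date`.
#' @param x horizon in days (the published thresholds are 45, 90, 180, 365).
#' @return integer 0 or 1.
#' @export
derive_mortality_label <- function(date_of_death, scan_date, x = 180L) {
  stopifnot(inherits(scan_date, "Date"))
  if (is.null(date_of_death) || is.na(date_of_death)) return(0L)
  stopifnot(inherits(date_of_death, "Date"))
  delta <- as.numeric(date_of_death - scan_date)
  if (delta < 0) {
    warning("date of death precedes scan date by ", -delta, " days")
    return(1L)
  }
  as.integer(delta <= x)
}
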