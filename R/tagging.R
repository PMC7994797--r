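#' Parse a free-text radiology report into sections and sentences
#'
#' Whole-body PET/CT reports conventionally contain four sections: clinical
#' history, procedure, findings and impression. Section headers are matched
#' case-insensitively (an optional trailing colon is consumed); any text
#' before the first recognized header is assigned to `clinical_history`.
#' Missing sections yield empty strings, so all four keys always exist.
#'
#' Sentences are segmented on a period or semicolon followed by whitespace.
#' Decimal numbers and measurement strings ("13 x 12 mm", "SUV 6.5") survive
#' because their periods are not followed by whitespace.
#'
#' @param raw_text report text.
#' @param exam_id optional exam identifier carried through the pipeline.
#' @return an object of class `report_document`: list with `exam_id`,
#'   `sections` (named list of 4 strings) and `sentences` (data.frame with
#'   columns `section`, `sentence`; `sentence_index` is the row number).
#' @export
parse_report <- function(raw_text, exam_id = NA_character_) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L, nzchar(raw_text))
  section_names <- c("clinical_history", "procedure", "findings", "impression")
  headers <- c("clinical history", "procedure", "findings", "impression")
  txt <- raw_text

  # the *first* occurrence of each header delimits its section, so that a
  # later mention of e.g. "findings" in running text does not re-open it
  hits <- data.frame(section = character(), start = integer(), end = integer())
  for (i in seq_along(headers)) {
    m <- regexpr(paste0("(?i)\\b", gsub(" ", "\\\\s+", headers[i]), "\\b:?"),
                 txt, perl = TRUE)
    if (m[1L] != -1L) {
      hits <- rbind(hits, data.frame(
        section = section_names[i], start = as.integer(m),
        end = as.integer(m) + attr(m, "match.length") - 1L))
    }
  }
  sections <- stats::setNames(as.list(rep("", 4L)), section_names)
  if (nrow(hits) == 0L) {
    sections$clinical_history <- trimws(txt)
  } else {
    hits <- hits[order(hits$start), , drop = FALSE]
    if (hits$start[1L] > 1L) {
      pre <- trimws(substr(txt, 1L, hits$start[1L] - 1L))
      if (nzchar(pre)) sections$clinical_history <- pre
    }
    for (i in seq_len(nrow(hits))) {
      to <- if (i < nrow(hits)) hits$start[i + 1L] - 1L else nchar(txt)
      body <- trimws(substr(txt, hits$end[i] + 1L, to))
      sections[[hits$section[i]]] <-
        trimws(paste(sections[[hits$section[i]]], body))
    }
  }

  sent_list <- lapply(section_names, function(sec) {
    s <- split_sentences(sections[[sec]])
    if (length(s)) data.frame(section = sec, sentence = s) else NULL
  })
  sentences <- do.call(rbind, sent_list)
  if (is.null(sentences)) {
    sentences <- data.frame(section = character(), sentence = character())
  }
  rownames(sentences) <- NULL
  structure(list(exam_id = exam_id, sections = sections, sentences = sentences),
            class = "report_document")
}

#' Split a text block into sentences
#'
#' Rule-based segmentation: split after `.` or `;` followed by whitespace.
#' @param text a string (may be empty).
#' @return character vector of trimmed sentences (empty if no content).
#' @export
split_sentences <- function(text) {
  if (is.null(text) || !nzchar(trimws(text))) return(character())
  txt <- gsub("\\s+", " ", trimws(text))
  parts <- strsplit(txt, "(?<=[.;])\\s+", perl = TRUE)[[1L]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' @export
print.report_document <- function(x, ...) {
  cat(sprintf("<report_document> exam %s, %d sentences (%s)\n",
              x$exam_id, nrow(x$sentences),
              paste(sprintf("%s: %d", names(x$sections),
                            vapply(x$sections, nchar, 0L)), collapse = ", ")))
  invisible(x)
}

#' Tag anatomical-region mentions in a report
#'
#' Runs every region's tagging patterns over each sentence of the findings
#' and impression sections only (mentions elsewhere carry no finding
#' semantics). Matching is case-insensitive; within a region, longer pattern
#' matches win and overlapping matches of the same region are suppressed.
#' Patterns for *different* regions may overlap and all fire. A plain-word
#' pattern is wrapped in word boundaries automatically.
#'
#' @param report a `report_document`.
#' @param ontology a `region_ontology`.
#' @return a data.frame of mentions, ordered by (sentence_index, start,
#'   region_id), with columns `region_id`, `section`, `sentence_index`
#'   (1-based row in `report$sentences`), `start`, `end` (half-open 0-based
#'   character offsets into the sentence), `text` and `probability` (NA until
#'   a labeler scores the mention).
#' @export
tag_report <- function(report, ontology) {
  stopifnot(inherits(report, "report_document"),
            inherits(ontology, "region_ontology"))
  rows <- list()
  for (si in seq_len(nrow(report$sentences))) {
    sec <- report$sentences$section[si]
    if (!sec %in% c("findings", "impression")) next
    sent <- report$sentences$sentence[si]
    for (rid in names(ontology$regions)) {
      spans <- .match_region(sent, ontology$regions[[rid]]$patterns)
      if (nrow(spans)) {
        rows[[length(rows) + 1L]] <- data.frame(
          region_id = rid, section = sec, sentence_index = si,
          start = spans$start, end = spans$end,
          text = substr(sent, spans$start + 1L, spans$end),
          probability = NA_real_)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region_id = character(), section = character(),
               sentence_index = integer(), start = integer(), end = integer(),
               text = character(), probability = numeric())
  out <- out[order(out$sentence_index, out$start, out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All non-overlapping matches of a region's patterns in one sentence.
# Longest-match-first: collect every pattern's matches, sort by length
# descending then offset, then drop overlaps. Offsets are 0-based half-open.
.match_region <- function(sentence, patterns) {
  all_m <- list()
  for (p in patterns) {
    rx <- if (grepl("[\\^$|()\\[\\]{}*+?.]", p, perl = TRUE)) p else
      paste0("\\b", p, "\\b")
    m <- gregexpr(rx, sentence, perl = TRUE, ignore.case = TRUE)[[1L]]
    if (m[1L] == -1L) next
    len <- attr(m, "match.length")
    all_m[[length(all_m) + 1L]] <-
      data.frame(start = as.integer(m) - 1L, end = as.integer(m) - 1L + len)
  }
  if (!length(all_m)) return(data.frame(start = integer(), end = integer()))
  cand <- do.call(rbind, all_m)
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  keep <- logical(nrow(cand))
  taken <- rep(FALSE, nchar(sentence))
  for (i in seq_len(nrow(cand))) {
    idx <- (cand$start[i] + 1L):cand$end[i]
    if (!any(taken[idx])) {
      keep[i] <- TRUE
      taken[idx] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}
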