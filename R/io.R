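# JSON-lines / CSV plumbing shared by the CLI and tests.

#' Read reports from a JSON-lines file
#'
#' Each line is an object `{"exam_id": ..., "text": ...}` (raw report text)
#' or a pre-sectioned `{"exam_id": ..., "sections": {...}}`.
#'
#' @param path JSON-lines file.
#' @return list of `report_document`s.
#' @export
read_reports_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    if (!is.null(obj$text)) {
      parse_report(obj$text, exam_id = obj$exam_id %||% NA_character_)
    } else {
      txt <- paste(
        "CLINICAL HISTORY:", obj$sections$clinical_history %||% "",
        "PROCEDURE:", obj$sections$procedure %||% "",
        "FINDINGS:", obj$sections$findings %||% "",
        "IMPRESSION:", obj$sections$impression %||% "")
      parse_report(txt, exam_id = obj$exam_id %||% NA_character_)
    }
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a weak-label table as CSV
#' @param labels exams x regions numeric matrix (see [weak_label_table()]).
#' @param path output CSV path.
#' @export
write_label_table <- function(labels, path) {
  df <- data.frame(exam_id = rownames(labels) %||% seq_len(nrow(labels)),
                   labels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Command-line interface
#'
#' One dispatcher for the package's command-line surface, suitable for
#' `Rscript -e 'anatomaly::anatomaly_cli()' <command> ...` or the shipped
#' `inst/exec/anatomaly` wrapper. Commands:
#' \describe{
#'   \item{`ontology-validate <file>`}{load and validate an ontology config.}
#'   \item{`ontology-candidates <reports.jsonl> [--min-count n]`}{k-gram
#'     candidate mining over report texts.}
#'   \item{`tag --reports <jsonl> --ontology <json> --out <jsonl>`}{emit all
#'     tagged mentions.}
#'   \item{`label-reports --reports <jsonl> --ontology <json> --out <csv>`}{
#'     rule-based weak-label table.}
#'   \item{`evaluate --pred <csv> --labels <csv> --out <csv>`}{per-region
#'     AUROC/F1/sensitivity/specificity.}
#'   \item{`simulate --n <int> --out <dir> [--seed s]`}{write a synthetic
#'     cohort (reports as JSON-lines, ground truth as CSV, volumes as RDS).}
#' }
#' @param args character vector (defaults to `commandArgs(trailingOnly=TRUE)`).
#' @return exit status, invisibly.
#' @export
anatomaly_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: anatomaly <ontology-validate|ontology-candidates|tag|",
        "label-reports|evaluate|simulate> [options]\n", sep = "")
    return(invisible(1L))
  }
  cmd <- args[[1L]]
  opts <- .cli_opts(args[-1L])
  switch(cmd,
    "ontology-validate" = {
      ont <- load_ontology(opts$positional[[1L]])
      cat(sprintf("ok: %d regions, %d edges, acyclic\n",
                  length(ont$regions), nrow(ont$edges)))
    },
    "ontology-candidates" = {
      reports <- read_reports_jsonl(opts$positional[[1L]])
      corpus <- vapply(reports, function(r)
        paste(unlist(r$sections), collapse = " "), "")
      cand <- build_ontology_candidates(
        corpus, min_count = as.integer(opts[["min-count"]] %||% 35L))
      utils::write.csv(cand, opts$out %||% stdout(), row.names = FALSE)
    },
    "tag" = {
      ont <- load_ontology(opts$ontology)
      reports <- read_reports_jsonl(opts$reports)
      con <- file(opts$out, "w"); on.exit(close(con))
      for (r in reports) {
        m <- tag_report(r, ont)
        m$exam_id <- r$exam_id
        writeLines(jsonlite::toJSON(m, dataframe = "rows"), con)
      }
    },
    "label-reports" = {
      ont <- load_ontology(opts$ontology)
      reports <- read_reports_jsonl(opts$reports)
      labels <- weak_label_table(reports, ont, labeler = "rule")
      write_label_table(labels, opts$out)
    },
    "evaluate" = {
      pred <- utils::read.csv(opts$pred, check.names = FALSE)
      lab <- utils::read.csv(opts$labels, check.names = FALSE)
      regions <- setdiff(intersect(names(pred), names(lab)), "exam_id")
      rows <- lapply(regions, function(r) {
        y <- as.integer(lab[[r]] >= 0.5)
        if (length(unique(y)) < 2L) return(NULL)
        m <- binary_metrics(pred[[r]], y)
        data.frame(region = r, auroc = m$auroc, f1 = m$f1,
                   sensitivity = m$sensitivity, specificity = m$specificity,
                   ppv = m$ppv)
      })
      out <- do.call(rbind, rows)
      utils::write.csv(out, opts$out %||% stdout(), row.names = FALSE)
    },
    "simulate" = {
      seed <- as.integer(opts$seed %||% 1L)
      n <- as.integer(opts$n %||% 20L)
      cohort <- generate_cohort(n_exams = n, seed = seed)
      dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
      con <- file(file.path(opts$out, "reports.jsonl"), "w")
      for (ex in cohort) {
        writeLines(jsonlite::toJSON(
          list(exam_id = ex$exam_id,
               sections = ex$report$sections), auto_unbox = TRUE), con)
      }
      close(con)
      write_label_table(oracle_labels(cohort),
                        file.path(opts$out, "ground_truth.csv"))
      saveRDS(lapply(cohort, `[[`, "volume"),
              file.path(opts$out, "volumes.rds"))
      cat(sprintf("wrote %d exams to %s\n", n, opts$out))
    },
    stop("unknown command: ", cmd))
  invisible(0L)
}

.cli_opts <- function(args) {
  opts <- list(positional = list())
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      opts[[substring(a, 3L)]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      opts$positional[[length(opts$positional) + 1L]] <- a
      i <- i + 1L
    }
  }
  opts
}
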