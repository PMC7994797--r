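#' Anatomical-region ontology
#'
#' The ontology is a directed acyclic graph (DAG) of anatomical regions.
#' Nodes are regions (e.g. "lungs", "left_lung"); a directed edge connects a
#' region to each of its sub-regions. Regions carry case-insensitive matching
#' patterns (synonyms or regular expressions) used by the tagging functions,
#' and the DAG is the substrate over which mention probabilities are
#' propagated upward (see [propagate()]).
#'
#' @param regions a list of region descriptors, each a list with elements
#'   `id` (unique string), optional `display_name` and `patterns`
#'   (character vector of case-insensitive regexes; defaults to the id with
#'   underscores replaced by spaces).
#' @param edges a list of `c(parent_id, child_id)` character pairs (or a
#'   two-column character matrix).
#' @return an object of class `region_ontology` with elements `regions`
#'   (named list), `children` and `parents` (named lists of character
#'   vectors), and `edges` (two-column character matrix).
#' @examples
#' ont <- region_ontology(
#'   regions = list(list(id = "chest"), list(id = "lungs"),
#'                  list(id = "left_lung", patterns = "left lung")),
#'   edges = list(c("chest", "lungs"), c("lungs", "left_lung")))
#' descendants(ont, "chest")
#' @export
region_ontology <- function(regions, edges = list()) {
  if (length(regions) == 0L) stop("ontology needs at least one region")
  regions <- lapply(regions, function(r) {
    if (is.null(r$id) || !nzchar(r$id)) stop("every region needs a non-empty id")
    if (is.null(r$display_name)) r$display_name <- gsub("_", " ", r$id)
    if (is.null(r$patterns) || length(r$patterns) == 0L) {
      r$patterns <- gsub("_", " ", r$id)
    }
    r$patterns <- as.character(r$patterns)
    # patterns must compile
    for (p in r$patterns) {
      ok <- tryCatch({ grepl(p, "", perl = TRUE); TRUE },
                     error = function(e) FALSE)
      if (!ok) stop(sprintf("pattern '%s' of region '%s' does not compile", p, r$id))
    }
    r[c("id", "display_name", "patterns")]
  })
  ids <- vapply(regions, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate region id: ", ids[duplicated(ids)][1L])
  }
  names(regions) <- ids

  if (is.matrix(edges)) edges <- asplit(edges, 1L)
  edges <- lapply(edges, as.character)
  if (length(edges)) {
    bad <- vapply(edges, function(e) length(e) != 2L, NA)
    if (any(bad)) stop("edges must be (parent, child) pairs")
    emat <- do.call(rbind, edges)
  } else {
    emat <- matrix(character(), ncol = 2L)
  }
  colnames(emat) <- c("parent", "child")
  unknown <- setdiff(c(emat), ids)
  if (length(unknown)) {
    stop("edge references unknown region(s): ", paste(unknown, collapse = ", "))
  }
  children <- lapply(ids, function(i) unique(emat[emat[, 1L] == i, 2L]))
  parents  <- lapply(ids, function(i) unique(emat[emat[, 2L] == i, 1L]))
  names(children) <- names(parents) <- ids

  ont <- structure(
    list(regions = regions, children = children, parents = parents,
         edges = emat),
    class = "region_ontology")
  .check_acyclic(ont)
  ont
}

# Kahn's algorithm; on failure report one edge that sits on a cycle.
.check_acyclic <- function(ont) {
  ids <- names(ont$regions)
  indeg <- vapply(ont$parents, length, 0L)
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in ont$children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    cyc <- ids[indeg > 0L]
    e <- ont$edges[ont$edges[, 1L] %in% cyc & ont$edges[, 2L] %in% cyc, ,
                   drop = FALSE]
    stop(sprintf("ontology contains a cycle (e.g. edge %s -> %s)",
                 e[1L, 1L], e[1L, 2L]))
  }
  invisible(ont)
}

#' @export
print.region_ontology <- function(x, ...) {
  cat(sprintf("<region_ontology> %d regions, %d edges, %d roots\n",
              length(x$regions), nrow(x$edges),
              sum(vapply(x$parents, length, 0L) == 0L)))
  invisible(x)
}

#' Load an ontology from a JSON config file
#'
#' The config has the shape
#' `{"regions": [{"id": ..., "display_name": ..., "patterns": [...]}, ...],
#'   "edges": [["parent","child"], ...]}`.
#' Validation (unique ids, compiling patterns, known edge endpoints,
#' acyclicity) is performed by [region_ontology()]; a cycle aborts with a
#' message naming an offending edge.
#'
#' @param path path to a JSON ontology config.
#' @return a `region_ontology`.
#' @seealso [write_ontology()], [synthetic_ontology_94()]
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(cfg$regions)) stop("ontology config has no 'regions' field")
  edges <- lapply(cfg$edges, function(e) unlist(e, use.names = FALSE))
  region_ontology(cfg$regions, edges)
}

#' Write an ontology to a JSON config file
#' @param ontology a `region_ontology`.
#' @param path output path.
#' @export
write_ontology <- function(ontology, path) {
  stopifnot(inherits(ontology, "region_ontology"))
  cfg <- list(
    regions = lapply(unname(ontology$regions), function(r)
      list(id = r$id, display_name = r$display_name,
           patterns = as.list(r$patterns))),
    edges = lapply(asplit(ontology$edges, 1L), as.list))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' All descendants of a region
#'
#' Transitive closure of the child relation, excluding the region itself.
#'
#' @param ontology a `region_ontology`.
#' @param id a region id.
#' @return character vector of descendant ids (sorted, possibly empty).
#' @export
descendants <- function(ontology, id) {
  .assert_region(ontology, id)
  out <- character()
  frontier <- ontology$children[[id]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(
      unique(unlist(ontology$children[frontier], use.names = FALSE)), out)
  }
  sort(out)
}

#' All ancestors of a region
#'
#' Transitive closure of the parent relation, excluding the region itself.
#' @inheritParams descendants
#' @return character vector of ancestor ids (sorted, possibly empty).
#' @export
ancestors <- function(ontology, id) {
  .assert_region(ontology, id)
  out <- character()
  frontier <- ontology$parents[[id]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(
      unique(unlist(ontology$parents[frontier], use.names = FALSE)), out)
  }
  sort(out)
}

.assert_region <- function(ontology, id) {
  stopifnot(inherits(ontology, "region_ontology"))
  if (!id %in% names(ontology$regions)) stop("unknown region id: ", id)
  invisible(id)
}

#' Propagate mention probabilities up the ontology
#'
#' For each region t, collects the probabilities p_1..p_n of every mention of
#' t or of any of its descendants, and computes the probability that at least
#' one of those mentions is abnormal under independence:
#' \deqn{\bar y_t = 1 - \prod_i (1 - p_i).}
#' Regions with no contributing mentions get 0 (the empty product is 1).
#'
#' @param ontology a `region_ontology`.
#' @param mention_probs a data.frame with columns `region_id` and
#'   `probability`, or a list of `list(region_id=, probability=)` pairs, or an
#'   empty object. Several mentions of the same region are allowed.
#' @return a named numeric vector over all ontology regions, values in
#'   \[0, 1\] (a "region probability map").
#' @examples
#' ont <- region_ontology(
#'   list(list(id = "chest"), list(id = "lungs"), list(id = "left_lung"),
#'        list(id = "liver")),
#'   list(c("chest", "lungs"), c("lungs", "left_lung")))
#' propagate(ont, data.frame(region_id = c("left_lung", "lungs", "liver"),
#'                           probability = c(0.9, 0.2, 0.4)))
#' @export
propagate <- function(ontology, mention_probs) {
  stopifnot(inherits(ontology, "region_ontology"))
  ids <- names(ontology$regions)
  out <- stats::setNames(numeric(length(ids)), ids)
  mp <- .as_mention_probs(mention_probs)
  if (nrow(mp) == 0L) return(out)
  unknown <- setdiff(mp$region_id, ids)
  if (length(unknown)) stop("unknown region id: ", unknown[[1L]])
  if (any(!is.finite(mp$probability) | mp$probability < 0 | mp$probability > 1)) {
    stop("mention probabilities must lie in [0, 1]")
  }
  for (t in ids) {
    scope <- c(t, descendants(ontology, t))
    p <- mp$probability[mp$region_id %in% scope]
    out[[t]] <- 1 - prod(1 - p)
  }
  out
}

.as_mention_probs <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0L) || length(x) == 0L) {
    return(data.frame(region_id = character(), probability = numeric()))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("region_id", "probability") %in% names(x)))
    return(x[c("region_id", "probability")])
  }
  data.frame(
    region_id = vapply(x, function(m) as.character(m$region_id), ""),
    probability = vapply(x, function(m) as.numeric(m$probability), 0))
}

#' Mine ontology candidate k-grams from a report corpus
#'
#' Counts all 1-, 2- and 3-grams over lowercased, punctuation-stripped,
#' whitespace-split tokens and keeps those occurring at least `min_count`
#' times. This reproduces the corpus-driven construction rule for the region
#' ontology (a k-gram naming an anatomical region enters the ontology when it
#' appears at least 35 times); deciding *which* frequent k-grams are
#' anatomical remains a curation step outside the package.
#'
#' @param corpus character vector of report texts.
#' @param k_max maximum k-gram length (default 3).
#' @param min_count inclusive frequency threshold (default 35).
#' @return data.frame with columns `ngram` and `count`, sorted by count
#'   descending then lexicographically.
#' @export
build_ontology_candidates <- function(corpus, k_max = 3L, min_count = 35L) {
  stopifnot(length(corpus) > 0L)
  grams <- unlist(lapply(corpus, function(txt) {
    toks <- .candidate_tokens(txt)
    n <- length(toks)
    if (n == 0L) return(character())
    unlist(lapply(seq_len(min(k_max, n)), function(k) {
      if (n < k) return(character())
      starts <- seq_len(n - k + 1L)
      vapply(starts, function(s) paste(toks[s:(s + k - 1L)], collapse = " "), "")
    }))
  }), use.names = FALSE)
  if (!length(grams)) {
    return(data.frame(ngram = character(), count = integer()))
  }
  tab <- table(grams)
  tab <- tab[tab >= min_count]
  out <- data.frame(ngram = names(tab), count = as.integer(tab))
  out <- out[order(-out$count, out$ngram), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.candidate_tokens <- function(txt) {
  txt <- tolower(txt)
  txt <- gsub("[^a-z0-9 ]", " ", txt)
  toks <- strsplit(trimws(gsub("\\s+", " ", txt)), " ", fixed = TRUE)[[1L]]
  toks[nzchar(toks)]
}
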