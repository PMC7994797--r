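# Shared fixtures and independent oracle implementations. Oracles are kept
# deliberately naive (fixpoint iteration, sliding windows, exhaustive
# enumeration) and never call the code paths they check.

chain_ontology <- function() {
  region_ontology(
    regions = list(list(id = "chest"), list(id = "lungs"),
                   list(id = "left_lung", patterns = "left lung"),
                   list(id = "liver")),
    edges = list(c("chest", "lungs"), c("lungs", "left_lung")))
}

# reachability by repeated edge expansion to fixpoint
oracle_descendants <- function(edges, id) {
  out <- character()
  repeat {
    nxt <- unique(c(out, edges[edges[, 1L] %in% c(id, out), 2L]))
    if (setequal(nxt, out)) break
    out <- nxt
  }
  sort(setdiff(out, id))
}

# brute-force noisy-OR: per node, gather mentions on any node that can reach
# it (path enumeration via the oracle reachability)
oracle_propagate <- function(ids, edges, mention_df) {
  out <- stats::setNames(numeric(length(ids)), ids)
  for (t in ids) {
    scope <- c(t, oracle_descendants(edges, t))
    p <- mention_df$probability[mention_df$region_id %in% scope]
    out[[t]] <- 1 - prod(1 - p)
  }
  out
}

# random DAG over n nodes: edges only from lower to higher topological index
random_dag <- function(n, p_edge = 0.25) {
  ids <- sprintf("r%02d", seq_len(n))
  edges <- matrix(character(), ncol = 2L)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1L) < p_edge) {
        edges <- rbind(edges, c(ids[i], ids[j]))
      }
    }
  }
  list(ids = ids, edges = edges,
       ontology = region_ontology(lapply(ids, function(i) list(id = i)),
                                  asplit(edges, 1L)))
}

# naive sliding-window k-gram tally
oracle_kgram_counts <- function(corpus, k_max = 3L) {
  counts <- new.env(parent = emptyenv())
  for (txt in corpus) {
    txt <- tolower(txt)
    txt <- gsub("[^a-z0-9 ]", " ", txt)
    toks <- strsplit(trimws(gsub("\\s+", " ", txt)), " ")[[1L]]
    toks <- toks[nzchar(toks)]
    for (k in seq_len(k_max)) {
      if (length(toks) < k) next
      for (s in seq_len(length(toks) - k + 1L)) {
        g <- paste(toks[s:(s + k - 1L)], collapse = " ")
        counts[[g]] <- (if (is.null(counts[[g]])) 0L else counts[[g]]) + 1L
      }
    }
  }
  keys <- ls(counts)
  stats::setNames(vapply(keys, function(k) counts[[k]], 0L), keys)
}

# AUROC as concordant-pair fraction (ties count 1/2)
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  num <- 0
  for (p in pos) for (q in neg) {
    num <- num + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  num / (length(pos) * length(neg))
}

tiny_volume <- function(h = 16L, w = 16L, l = 4L, seed = 1L) {
  set.seed(seed)
  scan_volume(array(stats::rnorm(2 * h * w * l), dim = c(2L, h, w, l)))
}
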