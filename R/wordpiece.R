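#' Wordpiece vocabulary and tokenizer
#'
#' Subword units let the report model handle rare, domain-specific words:
#' frequent words ("lymph", "uptake") stay intact while rare compounds
#' ("subcarinal") split into frequent fragments ("sub" + "carinal").
#'
#' The vocabulary is built greedily by iterative pair merging: starting from
#' all single characters seen in the corpus (plus the unknown marker), each
#' step merges the adjacent-piece pair that maximally reduces the total token
#' count over the corpus, i.e. the most frequent adjacent pair; ties break
#' lexicographically on the merged string. Merging stops when `target_size`
#' pieces exist or no pair occurs more than once. Callers must exclude
#' evaluation/test texts from `corpus` so that test-set tokenization reflects
#' generalization, not leakage.
#'
#' Text is normalized to lowercase; words are whitespace-delimited and pieces
#' never cross word boundaries. No continuation markers are used: a token
#' sequence plus its character spans reconstructs the normalized sentence.
#'
#' @param corpus character vector of training texts.
#' @param target_size total number of pieces (single characters + merges +
#'   unknown marker). The published full-scale configuration uses 3000.
#' @param base an existing `wordpiece_vocab` whose pieces are kept and
#'   extended (optional).
#' @return an object of class `wordpiece_vocab`: list with `pieces`
#'   (character vector, unknown marker first, then single characters, then
#'   merged pieces in merge order) and `unk` (the unknown marker `"[UNK]"`).
#' @examples
#' v <- build_wordpiece_vocab(rep("sub carinal subcarinal", 10), target_size = 20)
#' wp_tokenize("subcarinal", v)$tokens
#' @export
build_wordpiece_vocab <- function(corpus, target_size = 3000L, base = NULL) {
  stopifnot(length(corpus) > 0L)
  words <- .word_counts(corpus)
  chars <- sort(unique(unlist(strsplit(names(words), ""), use.names = FALSE)))
  base_pieces <- unique(c("[UNK]", chars,
                          if (!is.null(base)) base$pieces))
  if (target_size < length(base_pieces)) {
    stop(sprintf("target_size %d < %d pieces needed for base coverage",
                 target_size, length(base_pieces)))
  }
  pieces <- base_pieces
  # each word is a sequence of pieces, initially characters (or base pieces)
  segs <- lapply(names(words), function(w) .greedy_segment(w, pieces))
  cnt <- unname(words)

  sep <- rawToChar(as.raw(1L))  # internal pair-key separator; never occurs in text
  while (length(pieces) < target_size) {
    pair_tab <- .pair_counts(segs, cnt, sep)
    if (!length(pair_tab) || max(pair_tab) < 2L) break
    best <- max(pair_tab)
    cand <- names(pair_tab)[pair_tab == best]
    cand <- cand[order(gsub(sep, "", cand, fixed = TRUE), cand)]
    parts <- strsplit(cand[[1L]], sep, fixed = TRUE)[[1L]]
    pieces <- c(pieces, paste0(parts[1L], parts[2L]))
    segs <- lapply(segs, .apply_merge, a = parts[1L], b = parts[2L])
  }
  structure(list(pieces = pieces, unk = "[UNK]"), class = "wordpiece_vocab")
}

.word_counts <- function(corpus) {
  w <- unlist(strsplit(tolower(corpus), "\\s+"), use.names = FALSE)
  w <- w[nzchar(w)]
  table(w)
}

# Non-overlapping counts of adjacent piece pairs, weighted by word
# frequency. A pair's count equals the token-count reduction its merge would
# achieve, so taking the argmax is the greedy token-minimizing step.
.pair_counts <- function(segs, cnt, sep) {
  env <- new.env(parent = emptyenv())
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    if (length(s) < 2L) next
    keys <- unique(paste(s[-length(s)], s[-1L], sep = sep))
    for (k in keys) {
      ab <- strsplit(k, sep, fixed = TRUE)[[1L]]
      n <- .count_pair(s, ab[1L], ab[2L]) * cnt[[i]]
      env[[k]] <- (if (is.null(env[[k]])) 0L else env[[k]]) + n
    }
  }
  keys <- ls(env)
  stats::setNames(vapply(keys, function(k) env[[k]], 0L), keys)
}

# non-overlapping occurrences of (a, b) as adjacent pieces in s
.count_pair <- function(s, a, b) {
  n <- 0L
  i <- 1L
  while (i < length(s)) {
    if (s[i] == a && s[i + 1L] == b) { n <- n + 1L; i <- i + 2L }
    else i <- i + 1L
  }
  n
}

.apply_merge <- function(s, a, b) {
  if (length(s) < 2L) return(s)
  i <- 1L
  out <- character()
  while (i <= length(s)) {
    if (i < length(s) && s[i] == a && s[i + 1L] == b) {
      out <- c(out, paste0(a, b))
      i <- i + 2L
    } else {
      out <- c(out, s[i])
      i <- i + 1L
    }
  }
  out
}

# greedy longest-prefix-first segmentation of a single word
.greedy_segment <- function(word, pieces) {
  n <- nchar(word)
  out <- character()
  i <- 1L
  piece_set <- new.env(parent = emptyenv())
  for (p in pieces) assign(p, TRUE, envir = piece_set)
  while (i <= n) {
    hit <- NULL
    for (len in seq(min(n - i + 1L, 24L), 1L)) {
      cand <- substr(word, i, i + len - 1L)
      if (!is.null(piece_set[[cand]])) { hit <- cand; break }
    }
    if (is.null(hit)) { out <- c(out, "[UNK]"); i <- i + 1L }
    else { out <- c(out, hit); i <- i + nchar(hit) }
  }
  out
}

#' @export
print.wordpiece_vocab <- function(x, ...) {
  cat(sprintf("<wordpiece_vocab> %d pieces (unk = %s)\n",
              length(x$pieces), x$unk))
  invisible(x)
}

#' Tokenize a sentence into wordpieces
#'
#' Deterministic greedy longest-match-first decomposition: the sentence is
#' lowercased (offsets preserved), split into whitespace-delimited words, and
#' each word is consumed left to right by the longest vocabulary piece
#' matching at the cursor. Characters not in the vocabulary become the
#' unknown marker (one per character). Every character is consumed.
#'
#' @param sentence a string.
#' @param vocab a `wordpiece_vocab`.
#' @return an object of class `token_sequence`: list with `tokens` (character
#'   vector) and `char_spans` (integer matrix, columns `start`,`end`;
#'   half-open 0-based offsets into the lowercased sentence).
#' @export
wp_tokenize <- function(sentence, vocab) {
  stopifnot(inherits(vocab, "wordpiece_vocab"))
  s <- tolower(sentence)
  tokens <- character()
  starts <- integer(); ends <- integer()
  if (nzchar(s)) {
    m <- gregexpr("\\S+", s, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      w_start <- as.integer(m)
      w_len <- attr(m, "match.length")
      for (wi in seq_along(w_start)) {
        word <- substr(s, w_start[wi], w_start[wi] + w_len[wi] - 1L)
        seg <- .greedy_segment(word, vocab$pieces)
        pos <- w_start[wi] - 1L  # 0-based
        for (p in seg) {
          w <- if (p == vocab$unk) 1L else nchar(p)
          tokens <- c(tokens, p)
          starts <- c(starts, pos)
          ends <- c(ends, pos + w)
          pos <- pos + w
        }
      }
    }
  }
  structure(list(tokens = tokens,
                 char_spans = cbind(start = starts, end = ends),
                 text = s),
            class = "token_sequence")
}

#' Reconstruct the normalized sentence from a token sequence
#' @param tokseq a `token_sequence`.
#' @return the lowercased source sentence with original spacing.
#' @export
wp_detokenize <- function(tokseq) {
  stopifnot(inherits(tokseq, "token_sequence"))
  if (!length(tokseq$tokens)) return("")
  n <- max(tokseq$char_spans[, "end"])
  chars <- rep(" ", n)
  for (i in seq_along(tokseq$tokens)) {
    sp <- tokseq$char_spans[i, ]
    piece <- tokseq$tokens[i]
    if (piece == "[UNK]") piece <- substr(tokseq$text, sp[1L] + 1L, sp[2L])
    chars[(sp[1L] + 1L):sp[2L]] <- strsplit(piece, "")[[1L]]
  }
  trimws(paste(chars, collapse = ""))
}
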