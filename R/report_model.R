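#' Sequence encoder for the report model
#'
#' The report model maps a wordpiece token sequence (x_1..x_n) to an
#' equal-length sequence of hidden vectors (z_1..z_n); a per-token sigmoid
#' head on top of z_i gives the probability that token x_i occurs in the
#' context of an abnormal finding. Any function with this signature can act
#' as the encoder (a pre-trained transformer would slot in unchanged); the
#' implementation shipped here is a lightweight contextual encoder trainable
#' on a CPU in seconds: each token is represented by the concatenation of the
#' embeddings in a +/-`window` neighborhood together with the mean embedding
#' of the whole sentence (which carries sentence-level negation cues like
#' "no" or "physiologic" to every token), followed by one ReLU layer.
#'
#' @param vocab_size number of wordpieces the embedding table covers.
#' @param embed_dim embedding dimension (default 16).
#' @param hidden hidden size d_h of the z vectors (default 32).
#' @param window half-width of the local context window (default 2).
#' @param seed integer seed for parameter initialization.
#' @return an object of class `seq_encoder` (fields: `params` with `E`, `W1`,
#'   `b1`; `embed_dim`, `hidden`, `window`, `vocab_size`).
#' @export
sequence_encoder <- function(vocab_size, embed_dim = 16L, hidden = 32L,
                             window = 2L, seed = 1L) {
  set.seed(seed)
  k <- 2L * window + 2L  # window blocks + sentence-mean block
  feat <- k * embed_dim
  params <- list(
    E  = matrix(stats::rnorm(vocab_size * embed_dim, sd = 0.1),
                vocab_size, embed_dim),
    W1 = matrix(stats::rnorm(feat * hidden, sd = sqrt(2 / feat)), feat, hidden),
    b1 = numeric(hidden))
  structure(list(params = params, vocab_size = vocab_size,
                 embed_dim = embed_dim, hidden = hidden, window = window),
            class = "seq_encoder")
}

#' Token classification head
#'
#' A single fully-connected layer with sigmoid activation on each hidden
#' vector: `P(x_i abnormal | x_1..x_n) = sigmoid(w' z_i + b)`.
#'
#' @param hidden hidden size d_h matching the encoder.
#' @param seed integer seed.
#' @return list with weight vector `w` and scalar bias `b`.
#' @export
token_head <- function(hidden, seed = 1L) {
  set.seed(seed + 7L)
  list(w = stats::rnorm(hidden, sd = 0.1), b = 0)
}

# Forward pass; returns hidden matrix Z (n x hidden) and, if `cache`, the
# feature matrix needed for backprop.
.encode_forward <- function(encoder, ids, cache = FALSE) {
  p <- encoder$params
  n <- length(ids)
  e <- encoder$embed_dim
  w <- encoder$window
  X <- p$E[ids, , drop = FALSE]
  blocks <- vector("list", 2L * w + 2L)
  bi <- 0L
  for (o in (-w):w) {
    bi <- bi + 1L
    B <- matrix(0, n, e)
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    B[ok, ] <- X[src[ok], , drop = FALSE]
    blocks[[bi]] <- B
  }
  blocks[[bi + 1L]] <- matrix(colMeans(X), n, e, byrow = TRUE)
  Fmat <- do.call(cbind, blocks)
  Zpre <- sweep(Fmat %*% p$W1, 2L, p$b1, `+`)
  Z <- pmax(Zpre, 0)
  if (cache) list(Z = Z, Fmat = Fmat, X = X) else list(Z = Z)
}

#' Encode a token sequence into hidden vectors
#' @param encoder a `seq_encoder`.
#' @param ids integer vector of 1-based token ids (indices into the
#'   vocabulary piece list).
#' @return numeric matrix, one row of size d_h per token.
#' @export
encode_tokens <- function(encoder, ids) {
  stopifnot(inherits(encoder, "seq_encoder"), length(ids) >= 1L)
  .encode_forward(encoder, ids)$Z
}

#' Per-token abnormality probabilities
#' @inheritParams encode_tokens
#' @param head a [token_head()].
#' @return numeric vector of probabilities in (0, 1), one per token.
#' @export
predict_token_probs <- function(encoder, head, ids) {
  Z <- encode_tokens(encoder, ids)
  as.numeric(.sigmoid(Z %*% head$w + head$b))
}

#' Masked token-level cross-entropy loss
#'
#' The training objective for one sentence: cross-entropy summed over tokens
#' that belong to a mention, scaled by 1/n for sentence length n; tokens with
#' label `NA` ("not part of any mention") are masked out and contribute
#' nothing, so perturbing predictions on them leaves the loss unchanged.
#'
#' @param probs numeric vector of per-token probabilities.
#' @param labels integer vector of the same length over \{0, 1, NA\}.
#' @return scalar loss.
#' @export
masked_token_loss <- function(probs, labels) {
  stopifnot(length(probs) == length(labels))
  n <- length(labels)
  keep <- !is.na(labels)
  if (!any(keep)) return(0)
  p <- .clamp01(probs[keep])
  y <- labels[keep]
  sum(-(y * log(p) + (1 - y) * log(1 - p))) / n
}

#' Map mention character spans to token labels
#'
#' Tokens whose character span intersects a mention span receive that
#' mention's state (0 = neutral/negative, 1 = abnormal); all other tokens get
#' `NA`, the "not part of any mention" marker. Word-level spans map onto
#' wordpiece spans by character-offset intersection.
#'
#' @param tokseq a `token_sequence` from [wp_tokenize()].
#' @param mentions data.frame with columns `start`, `end` (half-open 0-based
#'   character offsets into the sentence).
#' @param states integer vector in \{0, 1\}, one per mention row.
#' @return integer vector over \{0, 1, NA\}, one entry per token.
#' @export
label_tokens <- function(tokseq, mentions, states) {
  stopifnot(inherits(tokseq, "token_sequence"),
            nrow(mentions) == length(states), all(states %in% c(0L, 1L)))
  labels <- rep(NA_integer_, length(tokseq$tokens))
  if (!nrow(mentions)) return(labels)
  for (mi in seq_len(nrow(mentions))) {
    hit <- .tokens_in_span(tokseq, mentions$start[mi], mentions$end[mi])
    clash <- !is.na(labels[hit]) & labels[hit] != states[mi]
    if (any(clash)) {
      stop("overlapping mentions with conflicting states at token ",
           which(hit)[clash][1L])
    }
    labels[hit] <- states[mi]
  }
  labels
}

.tokens_in_span <- function(tokseq, start, end) {
  ts <- tokseq$char_spans[, "start"]
  te <- tokseq$char_spans[, "end"]
  ts < end & te > start
}

#' Report-model training configuration
#'
#' `profile = "published"` reproduces the published training schedule: Adam with initial
#' learning rate 1e-4 annealed by half every 20 epochs, batch size 16, 100
#' mention sentences sampled with replacement per epoch, 85 epochs, early
#' stopping on validation AUROC. `profile = "desk"` keeps the same shape but
#' is sized for the shipped CPU encoder (larger learning rate, 40 epochs),
#' which reaches ceiling on templated synthetic reports in seconds.
#'
#' @param profile `"desk"` or `"published"`.
#' @param ... overrides for individual fields.
#' @return list of training hyperparameters.
#' @export
report_train_config <- function(profile = c("desk", "published"), ...) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    desk  = list(epochs = 40L, samples_per_epoch = 200L, batch_size = 16L,
                 lr = 0.01, anneal_every = 20L, anneal_factor = 0.5),
    published = list(epochs = 85L, samples_per_epoch = 100L, batch_size = 16L,
                 lr = 1e-4, anneal_every = 20L, anneal_factor = 0.5))
  utils::modifyList(cfg, list(...))
}

#' Train the report model
#'
#' Minimizes the masked token cross-entropy over labeled sentences using
#' Adam with the step-annealing schedule from the config, sampling sentences
#' with replacement each epoch, and returns the parameters from the epoch
#' with the best validation token AUROC (early stopping by model selection).
#'
#' @param train,val lists of labeled sentences; each element is a list with
#'   `ids` (integer token ids) and `labels` (over \{0, 1, NA\}; see
#'   [label_tokens()]). Every training sentence must contain at least one
#'   labeled token, and both classes must be present overall.
#' @param vocab_size vocabulary size for the embedding table.
#' @param config a [report_train_config()].
#' @param encoder optionally a pre-built `seq_encoder` (fresh one otherwise).
#' @param seed integer seed controlling initialization and sampling.
#' @return list of class `report_model`: `encoder`, `head`, `vocab_size`,
#'   `history` (data.frame epoch/loss/val_auroc/lr), `best_epoch`.
#' @export
train_report_model <- function(train, val, vocab_size,
                               config = report_train_config(),
                               encoder = NULL, seed = 1L) {
  if (!length(train)) stop("empty training set")
  if (!length(val)) stop("empty validation set")
  lab <- unlist(lapply(train, `[[`, "labels"))
  if (!any(!is.na(lab))) stop("no labeled tokens in the training set")
  bad <- vapply(train, function(s) all(is.na(s$labels)), NA)
  if (any(bad)) stop("every training sentence needs at least one labeled token")
  if (length(unique(lab[!is.na(lab)])) < 2L) {
    stop("degenerate labels: only one class present among labeled tokens")
  }

  set.seed(seed)
  if (is.null(encoder)) encoder <- sequence_encoder(vocab_size, seed = seed)
  head <- token_head(encoder$hidden, seed = seed)
  params <- c(encoder$params, list(hw = head$w, hb = head$b))
  state <- adam_init(params)

  best <- list(auroc = -Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     val_auroc = numeric(), lr = numeric())
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    idx <- sample.int(length(train), config$samples_per_epoch, replace = TRUE)
    losses <- numeric()
    for (bstart in seq(1L, length(idx), by = config$batch_size)) {
      batch <- idx[bstart:min(bstart + config$batch_size - 1L, length(idx))]
      acc <- list()
      bl <- 0
      for (si in batch) {
        gs <- .report_grad(encoder, params, train[[si]])
        bl <- bl + gs$loss
        for (nm in names(gs$grads)) acc <- .acc(acc, nm, gs$grads[[nm]])
      }
      acc <- lapply(acc, `/`, length(batch))
      upd <- adam_step(params, acc, state, lr)
      params <- upd$params; state <- upd$state
      losses <- c(losses, bl / length(batch))
    }
    encoder$params <- params[c("E", "W1", "b1")]
    head$w <- params$hw; head$b <- params$hb
    va <- .token_auroc(encoder, head, val)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = mean(losses),
                                   val_auroc = va, lr = lr))
    if (!is.na(va) && va > best$auroc) {
      best <- list(auroc = va, params = params, epoch = epoch)
    }
  }
  encoder$params <- best$params[c("E", "W1", "b1")]
  head$w <- best$params$hw; head$b <- best$params$hb
  structure(list(encoder = encoder, head = head, vocab_size = vocab_size,
                 history = hist, best_epoch = best$epoch),
            class = "report_model")
}

#' @export
print.report_model <- function(x, ...) {
  cat(sprintf(
    "<report_model> d_h = %d, best epoch %d (val AUROC %.3f of %d epochs)\n",
    x$encoder$hidden, x$best_epoch,
    x$history$val_auroc[x$best_epoch], nrow(x$history)))
  invisible(x)
}

# loss + analytic gradients for one labeled sentence
.report_grad <- function(encoder, params, sent) {
  ids <- sent$ids; labels <- sent$labels
  n <- length(ids)
  e <- encoder$embed_dim
  w <- encoder$window
  enc <- list(params = params[c("E", "W1", "b1")],
              embed_dim = e, hidden = encoder$hidden, window = w,
              vocab_size = encoder$vocab_size)
  class(enc) <- "seq_encoder"
  fwd <- .encode_forward(enc, ids, cache = TRUE)
  Z <- fwd$Z
  p <- .clamp01(as.numeric(.sigmoid(Z %*% params$hw + params$hb)))
  loss <- masked_token_loss(p, labels)

  mask <- as.numeric(!is.na(labels))
  y <- ifelse(is.na(labels), 0, labels)
  g <- (p - y) * mask / n            # d loss / d logit
  dhw <- as.numeric(crossprod(Z, g))
  dhb <- sum(g)
  dZ <- outer(g, params$hw)
  dA1 <- dZ * (Z > 0)
  dW1 <- crossprod(fwd$Fmat, dA1)
  db1 <- colSums(dA1)
  dF <- dA1 %*% t(params$W1)

  dE <- matrix(0, nrow(params$E), e)
  bi <- 0L
  for (o in (-w):w) {
    bi <- bi + 1L
    blk <- dF[, ((bi - 1L) * e + 1L):(bi * e), drop = FALSE]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    if (any(ok)) {
      contrib <- rowsum(blk[ok, , drop = FALSE], group = ids[src[ok]])
      ridx <- as.integer(rownames(contrib))
      dE[ridx, ] <- dE[ridx, , drop = FALSE] + contrib
    }
  }
  cblk <- dF[, (bi * e + 1L):((bi + 1L) * e), drop = FALSE]
  dmean <- colSums(cblk) / n
  contrib <- rowsum(matrix(dmean, n, e, byrow = TRUE), group = ids)
  ridx <- as.integer(rownames(contrib))
  dE[ridx, ] <- dE[ridx, , drop = FALSE] + contrib

  list(loss = loss,
       grads = list(E = dE, W1 = dW1, b1 = db1, hw = dhw, hb = dhb))
}

.token_auroc <- function(encoder, head, val) {
  scores <- numeric(); labels <- integer()
  for (s in val) {
    keep <- !is.na(s$labels)
    if (!any(keep)) next
    p <- predict_token_probs(encoder, head, s$ids)
    scores <- c(scores, p[keep])
    labels <- c(labels, s$labels[keep])
  }
  if (length(unique(labels)) < 2L) return(NA_real_)
  binary_metrics(scores, labels)$auroc
}

#' Score mentions with a trained report model
#'
#' Runs the token classifier over the sentence and reduces token
#' probabilities to one probability per mention by taking the arithmetic
#' mean over the wordpiece tokens inside the mention span.
#'
#' @param sentence sentence text.
#' @param mentions data.frame with `start`, `end` columns (0-based half-open
#'   character spans), e.g. rows of [tag_report()] output.
#' @param model a `report_model` (or a list with `encoder` and `head`).
#' @param vocab the `wordpiece_vocab` the model was trained with.
#' @return `mentions` with the `probability` column filled.
#' @export
predict_mention_probability <- function(sentence, mentions, model, vocab) {
  tokseq <- wp_tokenize(sentence, vocab)
  if (!length(tokseq$tokens)) stop("sentence yields no tokens")
  ids <- match(tokseq$tokens, vocab$pieces)
  ids[is.na(ids)] <- match(vocab$unk, vocab$pieces)
  p <- predict_token_probs(model$encoder, model$head, ids)
  probs <- numeric(nrow(mentions))
  for (mi in seq_len(nrow(mentions))) {
    hit <- .tokens_in_span(tokseq, mentions$start[mi], mentions$end[mi])
    if (!any(hit)) {
      stop(sprintf("mention span [%d, %d) maps to zero tokens",
                   mentions$start[mi], mentions$end[mi]))
    }
    probs[mi] <- mean(p[hit])
  }
  mentions$probability <- probs
  mentions
}

#' Rule-based baseline labeler
#'
#' The regular-expression baseline: if a sentence contains no negative-
#' finding keyword, every region mentioned in it — and all ancestors of those
#' regions in the ontology — is labeled abnormal (1); if any keyword is
#' present, every mentioned region is labeled 0. Keywords are matched as
#' whole words, case-insensitively.
#'
#' @param sentence sentence text.
#' @param mentions data.frame with a `region_id` column (rows of
#'   [tag_report()] output for this sentence).
#' @param ontology a `region_ontology` (for ancestor assignment).
#' @param negative_keywords character vector of keywords; the default covers
#'   the conventional negation/neutrality cues in PET/CT reports.
#' @return data.frame with columns `region_id`, `state` (0/1).
#' @export
rule_based_label <- function(sentence, mentions, ontology,
                             negative_keywords = c(
                               "physiologic", "without", "unremarkable",
                               "no", "not", "negative", "resolved", "stable")) {
  rx <- paste0("\\b(", paste(negative_keywords, collapse = "|"), ")\\b")
  neg <- grepl(rx, sentence, ignore.case = TRUE, perl = TRUE)
  rids <- unique(mentions$region_id)
  if (!length(rids)) return(data.frame(region_id = character(), state = integer()))
  if (neg) {
    out <- data.frame(region_id = rids, state = 0L)
  } else {
    all_ids <- unique(c(rids, unlist(lapply(rids, ancestors, ontology = ontology),
                                     use.names = FALSE)))
    out <- data.frame(region_id = all_ids, state = 1L)
  }
  rownames(out) <- NULL
  out
}
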