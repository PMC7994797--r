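# shared fixture: a small synthetic sentence corpus + vocab, built once
rm_fixture <- local({
  co <- generate_cohort(n_exams = 120L, seed = 7L)
  corpus <- vapply(co, function(ex)
    paste(unlist(ex$report$sections), collapse = " "), "")
  vocab <- build_wordpiece_vocab(corpus, target_size = 120L)
  sents <- cohort_labeled_sentences(co, vocab)
  set.seed(42)
  idx <- sample(length(sents))
  n_tr <- round(0.8 * length(sents))
  list(vocab = vocab, train = sents[idx[seq_len(n_tr)]],
       val = sents[idx[(n_tr + 1L):length(sents)]])
})

test_that("label_tokens reproduces the {0,1,-} span scheme", {
  v <- rm_fixture$vocab
  sent <- "Abnormal FDG uptake in the left lung"
  ts <- wp_tokenize(sent, v)
  start <- regexpr("left lung", sent, fixed = TRUE)[[1L]] - 1L
  labels <- label_tokens(ts, data.frame(start = start, end = start + 9L), 1L)
  # exactly the tokens covering "left lung" are labeled 1, the rest "-"
  covered <- ts$char_spans[, "start"] < start + 9L &
    ts$char_spans[, "end"] > start
  expect_identical(!is.na(labels), covered)
  expect_true(all(labels[covered] == 1L))
  # word-level view: with whole words in vocab this is [- - - - - 1 1]
  if (all(c("left", "lung") %in% v$pieces)) {
    expect_identical(labels[ts$tokens %in% c("left", "lung")], c(1L, 1L))
  }

  # no mentions -> all "-"
  expect_true(all(is.na(label_tokens(ts, data.frame(start = integer(),
                                                    end = integer()),
                                     integer()))))
  # two disjoint mentions with different states
  s2 <- "left lung and liver"
  ts2 <- wp_tokenize(s2, v)
  lab2 <- label_tokens(ts2, data.frame(start = c(0L, 14L), end = c(9L, 19L)),
                       c(1L, 0L))
  expect_identical(lab2[ts2$char_spans[, "start"] < 9L],
                   rep(1L, sum(ts2$char_spans[, "start"] < 9L)))
  expect_true(all(lab2[ts2$char_spans[, "start"] >= 14L] == 0L))
  expect_true(all(is.na(lab2[ts2$char_spans[, "start"] >= 9L &
                               ts2$char_spans[, "start"] < 14L])))
  # conflicting overlap errors
  expect_error(
    label_tokens(ts2, data.frame(start = c(0L, 5L), end = c(9L, 9L)),
                 c(1L, 0L)),
    "conflicting")
})

test_that("masked loss ignores '-' tokens exactly", {
  probs <- c(0.9, 0.1, 0.5, 0.8)
  labels <- c(1L, NA, NA, 0L)
  base <- masked_token_loss(probs, labels)
  # perturb the masked positions arbitrarily: loss unchanged to machine eps
  probs2 <- probs
  probs2[c(2L, 3L)] <- c(0.999, 0.001)
  expect_identical(masked_token_loss(probs2, labels), base)
  # hand-computed value: (1/4) * (-log(.9) - log(1 - .8))
  expect_equal(base, (-log(0.9) - log(0.2)) / 4)
  expect_identical(masked_token_loss(probs, rep(NA_integer_, 4L)), 0)
})

test_that("encoder and head honor the sequence contract", {
  enc <- sequence_encoder(50L, embed_dim = 8L, hidden = 12L, seed = 2L)
  head <- token_head(12L, seed = 2L)
  ids <- c(3L, 17L, 9L, 44L)
  Z <- encode_tokens(enc, ids)
  expect_equal(dim(Z), c(4L, 12L))
  expect_identical(Z, encode_tokens(enc, ids))  # deterministic
  p <- predict_token_probs(enc, head, ids)
  expect_length(p, 4L)
  expect_true(all(p > 0 & p < 1))
  expect_equal(p, as.numeric(1 / (1 + exp(-(Z %*% head$w + head$b)))))
})

test_that("degenerate label sets are rejected", {
  s1 <- list(ids = 1:3, labels = c(1L, NA, NA))
  s0 <- list(ids = 1:3, labels = c(NA, NA, NA))
  expect_error(train_report_model(list(s1, s0), list(s1), 10L),
               "at least one labeled token")
  expect_error(train_report_model(list(s1), list(s1), 10L), "one class")
  expect_error(train_report_model(list(), list(s1), 10L), "empty")
})

test_that("training separates synthetic abnormal/neutral contexts", {
  cfg <- report_train_config()
  fit <- train_report_model(rm_fixture$train, rm_fixture$val,
                            vocab_size = length(rm_fixture$vocab$pieces),
                            config = cfg, seed = 0L)
  expect_s3_class(fit, "report_model")
  best <- max(fit$history$val_auroc, na.rm = TRUE)
  expect_gt(best, 0.95)
  expect_lte(fit$best_epoch, cfg$epochs)
  # optimization made progress
  expect_gt(fit$history$loss[1L],
            fit$history$loss[which.max(fit$history$val_auroc)])
  # schedule: lr annealed by half every 20 epochs
  expect_equal(fit$history$lr[1L], cfg$lr)
  expect_equal(lr_at_epoch(cfg, 20L), cfg$lr / 2)
  expect_equal(lr_at_epoch(scan_train_config(), 16L),
               scan_train_config()$lr / 2)
})

test_that("mention probability is the mean over mention tokens", {
  v <- rm_fixture$vocab
  fit <- train_report_model(rm_fixture$train[1:30], rm_fixture$val[1:10],
                            vocab_size = length(v$pieces),
                            config = report_train_config(epochs = 2L,
                                                         samples_per_epoch = 20L),
                            seed = 1L)
  sent <- "Abnormal FDG uptake in the left lung."
  ts <- wp_tokenize(sent, v)
  ids <- match(ts$tokens, v$pieces)
  ids[is.na(ids)] <- match(v$unk, v$pieces)
  p_tok <- predict_token_probs(fit$encoder, fit$head, ids)
  start <- regexpr("left lung", sent, fixed = TRUE)[[1L]] - 1L
  m <- data.frame(start = start, end = start + 9L)
  scored <- predict_mention_probability(sent, m, fit, v)
  covered <- ts$char_spans[, "start"] < start + 9L &
    ts$char_spans[, "end"] > start
  expect_equal(scored$probability, mean(p_tok[covered]))
  # single-token mention equals that token's probability
  one <- data.frame(start = ts$char_spans[1L, "start"],
                    end = ts$char_spans[1L, "end"])
  expect_equal(predict_mention_probability(sent, one, fit, v)$probability,
               p_tok[1L])
  # span outside any token errors
  expect_error(
    predict_mention_probability(sent, data.frame(start = 500L, end = 510L),
                                fit, v),
    "zero tokens")
})

test_that("training is reproducible for a fixed seed", {
  cfg <- report_train_config(epochs = 3L, samples_per_epoch = 40L)
  f1 <- train_report_model(rm_fixture$train[1:40], rm_fixture$val[1:10],
                           length(rm_fixture$vocab$pieces), cfg, seed = 5L)
  f2 <- train_report_model(rm_fixture$train[1:40], rm_fixture$val[1:10],
                           length(rm_fixture$vocab$pieces), cfg, seed = 5L)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$encoder$params, f2$encoder$params)
})

test_that("rule-based baseline follows the negative-keyword rule", {
  ont <- chain_ontology()
  doc <- parse_report("FINDINGS: Abnormal FDG uptake in the left lung.")
  m <- tag_report(doc, ont)
  lab <- rule_based_label(doc$sentences$sentence[m$sentence_index[1L]], m, ont)
  # mentioned region and all ancestors get 1
  expect_setequal(lab$region_id[lab$state == 1L],
                  c("left_lung", "lungs", "chest"))

  # the canonical neutral sentence: "physiologic" suppresses the label
  ont2 <- region_ontology(list(list(id = "cerebral_cortex",
                                    patterns = "cerebral cortex")), list())
  doc2 <- parse_report(
    "FINDINGS: intense physiologic uptake in the cerebral cortex.")
  m2 <- tag_report(doc2, ont2)
  lab2 <- rule_based_label(doc2$sentences$sentence[m2$sentence_index[1L]],
                           m2, ont2)
  expect_equal(lab2$state, 0L)

  # explicit negation
  ont3 <- region_ontology(list(list(id = "cervical_lymph_nodes",
                                    patterns = "cervical.*lymphadenopathy")),
                          list())
  doc3 <- parse_report(paste(
    "FINDINGS: no pathologically enlarged or hypermetabolic cervical",
    "or supraclavicular lymphadenopathy on the current study."))
  m3 <- tag_report(doc3, ont3)
  expect_equal(nrow(m3), 1L)
  lab3 <- rule_based_label(doc3$sentences$sentence[m3$sentence_index[1L]],
                           m3, ont3)
  expect_equal(lab3$state, 0L)
})

test_that("the trained labeler beats the rule baseline on hard negatives", {
  ont <- demo_ontology()
  fit <- train_report_model(rm_fixture$train, rm_fixture$val,
                            vocab_size = length(rm_fixture$vocab$pieces),
                            seed = 0L)
  co2 <- generate_cohort(ont, n_exams = 50L, seed = 99L)
  truth <- integer(); p_model <- numeric(); p_rule <- integer()
  for (ex in co2) {
    mens <- tag_report(ex$report, ont)
    if (!nrow(mens)) next
    st <- ex$sentence_truth
    for (si in unique(mens$sentence_index)) {
      sent <- ex$report$sentences$sentence[si]
      sub <- mens[mens$sentence_index == si, , drop = FALSE]
      scored <- predict_mention_probability(sent, sub, fit, rm_fixture$vocab)
      rl <- rule_based_label(sent, sub, ont)
      for (k in seq_len(nrow(sub))) {
        tstate <- st$state[st$sentence_index == si &
                             st$region_id == sub$region_id[k]]
        if (!length(tstate)) next
        truth <- c(truth, tstate[1L])
        p_model <- c(p_model, scored$probability[k])
        p_rule <- c(p_rule,
                    as.integer(sub$region_id[k] %in%
                                 rl$region_id[rl$state == 1L]))
      }
    }
  }
  f1_model <- binary_metrics(p_model, truth)$f1
  f1_rule <- binary_metrics(as.numeric(p_rule), truth)$f1
  expect_gt(f1_model, f1_rule)
})
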