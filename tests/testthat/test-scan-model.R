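test_that("bilinear resize preserves constants and matches closed form", {
  m <- matrix(5, 4L, 4L)
  expect_equal(resize_bilinear(m, 8L, 8L), matrix(5, 8L, 8L))

  # 4x4 checkerboard to 8x8: hand-computed half-pixel-center weights.
  cb <- outer(1:4, 1:4, function(i, j) as.numeric((i + j) %% 2L == 0L))
  got <- resize_bilinear(cb, 8L, 8L)
  # oracle: independent scalar loop over output pixels
  want <- matrix(0, 8L, 8L)
  for (i in 1:8) for (j in 1:8) {
    sy <- min(max((i - 0.5) * 4 / 8 - 0.5, 0), 3)
    sx <- min(max((j - 0.5) * 4 / 8 - 0.5, 0), 3)
    y0 <- floor(sy); x0 <- floor(sx)
    fy <- sy - y0; fx <- sx - x0
    y1 <- min(y0 + 1, 3); x1 <- min(x0 + 1, 3)
    want[i, j] <- (1 - fy) * (1 - fx) * cb[y0 + 1, x0 + 1] +
      (1 - fy) * fx * cb[y0 + 1, x1 + 1] +
      fy * (1 - fx) * cb[y1 + 1, x0 + 1] +
      fy * fx * cb[y1 + 1, x1 + 1]
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("preprocess_scan resamples both channels to a common grid", {
  pet <- array(1, dim = c(16L, 16L, 3L))
  ct <- array(2, dim = c(64L, 64L, 3L))
  sv <- preprocess_scan(pet, ct, size = 32L)
  expect_s3_class(sv, "scan_volume")
  expect_equal(dim(sv$data), c(2L, 32L, 32L, 3L))
  expect_true(all(sv$data[1L, , , ] == 1))
  expect_true(all(sv$data[2L, , , ] == 2))
  expect_error(preprocess_scan(pet, ct[, , 1:2], size = 32L), "mismatch")
})

test_that("augment is seeded, shape-preserving, and identity at gamma 0", {
  sv <- tiny_volume(32L, 32L, 4L, seed = 3L)
  a1 <- augment(sv, seed = 11L)
  a2 <- augment(sv, seed = 11L)
  expect_identical(a1$data, a2$data)
  expect_equal(dim(a1$data), dim(sv$data))
  # gamma_max = 0 forces the identity brightness; full-frame crop leaves the
  # slice untouched up to the resize, which is exact for crop_frac = 1
  a3 <- augment(sv, crop_frac = 1, gamma_max = 0, seed = 1L)
  expect_equal(a3$data, sv$data, tolerance = 1e-12)
})

test_that("brightness jitter magnitude follows Uniform(0, 0.25)", {
  set.seed(99)
  draws <- replicate(10000L, {
    g <- stats::runif(1L, 0, 0.25)
    sample(c(-1, 1), 1L)  # consume the sign draw as augment does
    g
  })
  se <- sqrt(0.25^2 / 12 / 10000L)
  expect_lt(abs(mean(draws) - 0.125), 3 * se)
  # and the factors realized by augment stay within [0.75, 1.25]
  sv <- tiny_volume(8L, 8L, 2L, seed = 1L)
  sv$data[] <- 1
  for (s in 1:20) {
    f <- augment(sv, crop_frac = 1, seed = s)$data[1L, 1L, 1L, 1L]
    expect_true(f >= 0.75 && f <= 1.25)
  }
})

test_that("encoder output shape follows the declared reduction contract", {
  fe <- full_scan_encoder()
  expect_equal(encoding_shape(fe, 224L, 224L, 198L), c(1024L, 7L, 7L, 33L))
  expect_equal(encoding_shape(fe, 224L, 224L, 30L)[4L], 5L)  # ceil(30/6)
  tiny <- scan_encoder(d = 32L, spatial_reduction = 8L,
                       temporal_reduction = 2L)
  expect_equal(encoding_shape(tiny, 64L, 64L, 8L), c(32L, 8L, 8L, 4L))
  # realized shapes match the declaration across slice counts
  for (l in c(2L, 5L, 8L)) {
    sv <- tiny_volume(16L, 16L, l, seed = l)
    enc <- scan_encoder(d = 8L, hidden = 6L, spatial_reduction = 4L,
                        temporal_reduction = 2L, seed = 1L)
    e <- encode_scan(enc, sv)
    expect_equal(dim(e$data), encoding_shape(enc, 16L, 16L, l))
  }
  expect_error(encode_scan(scan_encoder(temporal_reduction = 4L),
                           tiny_volume(16L, 16L, 3L)),
               "below the encoder minimum")
})

test_that("attention satisfies the softmax-pooling contract", {
  set.seed(8)
  A <- matrix(rnorm(20L * 6L), 20L, 6L)
  # zero attention vector -> uniform weights, pooled = voxel mean
  h0 <- list(w = numeric(6L), u = rnorm(6L), b = 0)
  att <- attend(h0, A)
  expect_equal(att$alpha, rep(1 / 20, 20L))
  expect_equal(att$pooled, colMeans(A))
  # saturation: one dominating score
  A2 <- A; A2[7L, ] <- A2[7L, ] + 100
  h1 <- list(w = rep(1, 6L), u = rnorm(6L), b = 0)
  att2 <- attend(h1, A2)
  expect_gt(max(att2$alpha), 0.99)
  expect_equal(which.max(att2$alpha), 7L)
  expect_equal(att2$pooled, A2[7L, ], tolerance = 1e-2)
  # toy 4-voxel case against hand arithmetic
  A3 <- matrix(c(1, 0, 0, 1, 1, 1, 2, 0), 4L, 2L, byrow = TRUE)
  h3 <- list(w = c(1, -1), u = c(1, 1), b = 0)
  s <- as.numeric(A3 %*% h3$w)
  al <- exp(s) / sum(exp(s))
  att3 <- attend(h3, A3)
  expect_equal(att3$alpha, al, tolerance = 1e-6)
  expect_equal(att3$pooled, as.numeric(t(A3) %*% al), tolerance = 1e-6)
  # normalization holds on random inputs and real encodings
  expect_true(all(att3$alpha >= 0))
  expect_equal(sum(att3$alpha), 1)
  expect_error(attend(list(w = numeric(5L)), A), "does not match")
})

test_that("predict_region is a sigmoid-linear readout", {
  h <- list(w = numeric(2L), u = numeric(2L), b = 0)
  expect_equal(predict_region(h, c(1, 1)), 0.5)
  h$b <- 50
  expect_equal(predict_region(h, c(1, 1)), 1, tolerance = 1e-8)
  h2 <- list(u = c(0.3, -0.2), b = 0.1)
  a <- c(1.5, 2.0)
  expect_equal(predict_region(h2, a),
               1 / (1 + exp(-(0.3 * 1.5 - 0.2 * 2.0 + 0.1))))
})

test_that("multitask loss is the mean soft-target cross-entropy", {
  expect_equal(multitask_loss(0.5, 0.5), log(2))
  expect_lt(multitask_loss(1, 1 - 1e-9), 1e-6)
  # two-task hand computation
  want <- mean(c(-(0.9 * log(0.7) + 0.1 * log(0.3)),
                 -(0.2 * log(0.4) + 0.8 * log(0.6))))
  expect_equal(multitask_loss(c(0.9, 0.2), c(0.7, 0.4)), want)
  # extreme predictions are clamped, not infinite
  expect_true(is.finite(multitask_loss(c(1, 0), c(0, 1))))
  # batch mean over matrix rows
  tg <- rbind(c(0.9, 0.2), c(0.9, 0.2))
  pr <- rbind(c(0.7, 0.4), c(0.7, 0.4))
  expect_equal(multitask_loss(tg, pr), want)
})

test_that("analytic gradients agree with numerical differentiation", {
  set.seed(12)
  enc <- scan_encoder(d = 5L, hidden = 4L, spatial_reduction = 4L,
                      temporal_reduction = 2L, seed = 2L)
  sv <- tiny_volume(8L, 8L, 4L, seed = 2L)
  V <- anatomaly:::.pool_volume(sv, enc)$V
  model <- multitask_model(enc, c("a", "b"), seed = 3L)
  params <- anatomaly:::.flatten_model(model)
  ybar <- c(a = 0.8, b = 0.1)
  gs <- anatomaly:::.scan_grad(params, c("a", "b"), V, ybar)
  eps <- 1e-6
  for (nm in names(params)) {
    for (j in seq_len(min(length(params[[nm]]), 5L))) {
      p1 <- params; p1[[nm]][j] <- p1[[nm]][j] + eps
      p2 <- params; p2[[nm]][j] <- p2[[nm]][j] - eps
      num <- (anatomaly:::.scan_grad(p1, c("a", "b"), V, ybar)$loss -
                anatomaly:::.scan_grad(p2, c("a", "b"), V, ybar)$loss) /
        (2 * eps)
      expect_equal(gs$grads[[nm]][j], num, tolerance = 1e-5)
    }
  }
})

test_that("with a frozen encoder, heads are gradient-isolated", {
  enc <- scan_encoder(d = 6L, hidden = 4L, spatial_reduction = 4L,
                      temporal_reduction = 2L, seed = 5L)
  sv <- tiny_volume(8L, 8L, 4L, seed = 5L)
  V <- anatomaly:::.pool_volume(sv, enc)$V
  model <- multitask_model(enc, c("a", "b"), seed = 1L)
  params <- anatomaly:::.flatten_model(model)
  # loss restricted to head "a": gradient on head "b" parameters is absent
  gs <- anatomaly:::.scan_grad(params, "a", V, c(a = 1), encoder_grad = FALSE)
  expect_null(gs$grads[["w.b"]])
  expect_null(gs$grads[["u.b"]])
  expect_setequal(names(gs$grads), c("w.a", "u.a", "b.a"))
})

test_that("a short multitask run is reproducible and learns", {
  ont <- demo_ontology()
  co <- generate_cohort(ont, n_exams = 40L, volume_shape = c(32L, 32L, 8L),
                        seed = 17L)
  vols <- lapply(co, `[[`, "volume")
  labs <- oracle_labels(co) * 1.0
  enc <- scan_encoder(spatial_reduction = 4L, seed = 1L)
  cfg <- scan_train_config(epochs = 4L, samples_per_epoch = 120L)
  m1 <- train_multitask(multitask_model(enc, colnames(labs), seed = 1L),
                        vols, labs, cfg, seed = 1L)
  m2 <- train_multitask(multitask_model(enc, colnames(labs), seed = 1L),
                        vols, labs, cfg, seed = 1L)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$encoder$params, m2$encoder$params)
  expect_lt(m1$history$loss[4L], m1$history$loss[1L])
  expect_error(train_multitask(multitask_model(enc, "nope", seed = 1L),
                               vols, labs, cfg),
               "missing model region")
  expect_error(train_multitask(multitask_model(enc, "liver"), list(),
                               labs, cfg),
               "empty dataset")
})

test_that("fine-tuning selects the best validation epoch and reuses heads", {
  ont <- demo_ontology()
  co <- generate_cohort(ont, n_exams = 60L, volume_shape = c(32L, 32L, 8L),
                        seed = 23L,
                        mortality_link = list(intercept = -2, slope = 1.5,
                                              horizon_days = 180L))
  vols <- lapply(co, `[[`, "volume")
  labs <- oracle_labels(co) * 1.0
  tr <- 1:40; ev <- 41:60
  enc <- scan_encoder(spatial_reduction = 4L, seed = 1L)
  cfg <- scan_train_config(epochs = 3L, samples_per_epoch = 100L,
                           finetune_epochs = 5L)
  base <- train_multitask(multitask_model(enc, colnames(labs), seed = 1L),
                          vols[tr], labs[tr, ], cfg, seed = 1L)
  ft <- finetune_single_task(base, "liver", vols[tr], labs[tr, "liver"],
                             cfg, vols[ev], labs[ev, "liver"], seed = 2L)
  expect_identical(ft$regions, "liver")
  expect_equal(nrow(ft$history), 5L)
  expect_identical(ft$best_epoch, which.max(ft$history$val_auroc))
  # mortality labels plug in with no architecture change
  mort <- vapply(co, function(ex)
    derive_mortality_label(ex$date_of_death, ex$scan_date, 180L), 0L)
  ft2 <- finetune_single_task(base, "mortality_180d", vols[tr], mort[tr],
                              cfg, vols[ev], mort[ev], seed = 2L)
  expect_identical(ft2$regions, "mortality_180d")
  expect_true(all(predict_scan(ft2, vols[ev]) >= 0 &
                    predict_scan(ft2, vols[ev]) <= 1))
})

test_that("multi-task pre-training transfers to a rare sub-region task", {
  # left lung is planted rare (6% prevalence) and excluded from the
  # multi-task region set; its parents (lungs, chest) are trained, so the
  # pre-trained encoder has seen the relevant anatomy. A short fine-tune at
  # a reduced learning rate probes representation quality: from the
  # multi-task checkpoint it must match or beat the same budget from a
  # random encoder, for every fine-tuning seed tried.
  ont <- demo_ontology()
  prev <- c(left_lung = 0.06, right_lung = 0.35, liver = 0.35, spleen = 0.35,
            inguinal_lymph_nodes = 0.3)
  co <- generate_cohort(ont, n_exams = 260L, prevalences = prev,
                        volume_shape = c(32L, 32L, 8L), seed = 29L)
  vols <- lapply(co, `[[`, "volume")
  labs <- oracle_labels(co) * 1.0
  tr <- 1:140; ev <- 141:260
  cfg <- scan_train_config(epochs = 6L, samples_per_epoch = 200L)
  main <- setdiff(colnames(labs), "left_lung")
  pre <- train_multitask(
    multitask_model(scan_encoder(spatial_reduction = 4L, seed = 1L),
                    main, seed = 1L),
    vols[tr], labs[tr, ], cfg, seed = 1L)
  scratch <- multitask_model(scan_encoder(spatial_reduction = 4L, seed = 1L),
                             main, seed = 1L)
  cfg_ft <- scan_train_config(finetune_epochs = 3L, samples_per_epoch = 100L,
                              lr = 0.004)
  auroc_of <- function(m) {
    p <- predict_scan(m, vols[ev])[, 1L]
    binary_metrics(p, labs[ev, "left_lung"])$auroc
  }
  for (s in c(3L, 4L)) {
    ft_pre <- finetune_single_task(pre, "left_lung", vols[tr],
                                   labs[tr, "left_lung"], cfg_ft,
                                   vols[ev], labs[ev, "left_lung"], seed = s)
    ft_scr <- finetune_single_task(scratch, "left_lung", vols[tr],
                                   labs[tr, "left_lung"], cfg_ft,
                                   vols[ev], labs[ev, "left_lung"], seed = s)
    expect_gte(auroc_of(ft_pre), auroc_of(ft_scr))
  }
})
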