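test_that("the tanh-softmax head has the promised structure and bounds", {
  h <- build_head(4, 3)
  F <- matrix(rnorm(8), 2, 4)
  P <- beetlesieve:::head_forward(h, F)$P
  expect_equal(P, matrix(1 / 3, 2, 3))          # zero weights -> uniform

  expect_equal(build_head(75264, 12)$n_params, 75264L * 12L + 12L)

  # pre-softmax values live in [-1, 1], so probabilities are bounded away
  # from 0 and 1 for arbitrary weights and inputs
  set.seed(4)
  for (n in c(2L, 5L, 12L)) {
    h2 <- build_head(6, n)
    h2$W <- matrix(rnorm(6 * n, 0, 10), 6, n)   # deliberately huge weights
    h2$b <- rnorm(n, 0, 5)
    P2 <- beetlesieve:::head_forward(h2, matrix(rnorm(30, 0, 3), 5, 6))$P
    lo <- exp(-1) / (exp(-1) + (n - 1) * exp(1))
    expect_true(all(P2 > lo - 1e-12))
    expect_true(all(P2 < 1 - (n - 1) * lo + 1e-12))
    expect_equal(rowSums(P2), rep(1, 5))
  }
})

test_that("label-smoothing cross-entropy matches closed forms", {
  for (n in c(2L, 12L)) {
    expect_equal(label_smoothing_loss(rep(1 / n, n), 1L, eps = 0.1), log(n))
    expect_equal(label_smoothing_loss(rep(1 / n, n), 1L, eps = 0.3), log(n))
  }
  onehot <- c(1, 0, 0)
  expect_equal(label_smoothing_loss(onehot, 1L, eps = 0), 0)
  p <- c(0.7, 0.2, 0.1)
  hand <- -((0.9 + 0.1 / 3) * log(0.7) + (0.1 / 3) * log(0.2) + (0.1 / 3) * log(0.1))
  expect_equal(label_smoothing_loss(p, 1L, eps = 0.1), hand, tolerance = 1e-12)
  # clamp keeps the loss finite when a positive-target class has probability 0
  expect_lt(label_smoothing_loss(c(0, 1), 1L, eps = 0.1), Inf)
})

test_that("augment is a deterministic passthrough at probability zero", {
  cfg <- train_config(image_size = 24L, augment_prob = 0)
  img <- matrix(runif(24 * 24), 24, 24)
  expect_identical(augment(img, 1L, cfg), img)

  cfg8 <- train_config(image_size = 24L)
  a1 <- augment(img, 9L, cfg8)
  a2 <- augment(img, 9L, cfg8)
  expect_identical(a1, a2)                      # same seed, same output
  expect_false(identical(augment(img, 10L, cfg8), a1))
  expect_equal(dim(a1), c(24L, 24L))

  # brightness is an additive shift with clipping
  shifted <- beetlesieve:::adjust_brightness(img, 0.15)
  expect_equal(shifted, pmin(pmax(img + 0.15, 0), 1))
  expect_equal(beetlesieve:::adjust_contrast(img, 1.2),
               pmin(pmax(0.5 + (img - 0.5) * 1.2, 0), 1))
})

test_that("warm-up freezes the backbone bit-exactly and training is deterministic", {
  dat <- make_crop_dataset(n_classes = 3L, batches_per_class = 1L,
                           replicates = 1L, seed = 15L)
  cfg <- train_config(image_size = 32L, seed = 2L, warmup_epochs = 1L,
                      epochs = 0L, n_filters = 8L)
  m_warm <- suppressWarnings(train_classifier(dat$crops, dat$labels, cfg))
  # reconstruct the initial backbone deterministically: same rng draws
  rng <- beetlesieve:::make_rng(cfg$seed)
  bb0 <- beetlesieve:::new_tiny_cnn(cfg, rng)
  bb0 <- beetlesieve:::calibrate_tiny_cnn(bb0, dat$crops)
  expect_identical(m_warm$backbone$K, bb0$K)
  expect_identical(m_warm$backbone$bK, bb0$bK)

  cfg_full <- train_config(image_size = 32L, seed = 2L, epochs = 2L,
                           n_filters = 8L)
  m1 <- suppressWarnings(train_classifier(dat$crops, dat$labels, cfg_full))
  m2 <- suppressWarnings(train_classifier(dat$crops, dat$labels, cfg_full))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$head$W, m2$head$W)
  expect_false(identical(m1$backbone$K, bb0$K))  # full epochs do update it
})

test_that("training separates the synthetic classes and predicts proper vectors", {
  dat <- make_crop_dataset(n_classes = 3L, batches_per_class = 3L,
                           replicates = 3L, seed = 33L,
                           spec = synthetic_spec(n_classes = 3L))
  man <- data.frame(label = dat$labels, group_id = dat$groups)
  folds <- kfold_group_split(man, k = 2L, seed = 8L)
  tr <- which(man$group_id %in% folds$fold_1)
  va <- which(man$group_id %in% folds$fold_2)
  cfg <- train_config(image_size = 32L, seed = 5L)
  model <- train_classifier(dat$crops[tr], dat$labels[tr], cfg,
                            val_images = dat$crops[va],
                            val_labels = dat$labels[va])
  # training loss decreases over epochs, allowing one non-monotone step
  dl <- diff(model$history$train_loss)
  expect_lte(sum(dl > 0), 1L)

  P <- predict(model, dat$crops[va])
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  expect_true(all(P > 0 & P < 1))
  pred <- model$class_names[max.col(P, ties.method = "first")]
  expect_gte(macro_f1(dat$labels[va], pred), 0.95)

  # confusion matrix is diagonal-dominant per row
  cm <- table(factor(dat$labels[va], levels = model$class_names),
              factor(pred, levels = model$class_names))
  for (i in seq_len(nrow(cm))) {
    expect_true(all(cm[i, i] > cm[i, -i]))
  }

  # duplicated crop gives the identical vector
  P2 <- predict(model, list(dat$crops[[va[1]]], dat$crops[[va[1]]]))
  expect_identical(P2[1, ], P2[2, ])

  # a class exemplar is recognized with p > 0.5
  expect_gt(P[1, dat$labels[va[1]]], 0.5)
})

test_that("training requires at least two classes and warns without validation", {
  dat <- make_crop_dataset(n_classes = 2L, batches_per_class = 1L,
                           replicates = 1L, seed = 3L,
                           spec = synthetic_spec(n_classes = 2L))
  cfg <- train_config(image_size = 32L, seed = 1L, epochs = 1L, n_filters = 4L)
  expect_error(train_classifier(dat$crops, rep("only", length(dat$crops)), cfg),
               ">= 2 classes")
  expect_warning(train_classifier(dat$crops, dat$labels, cfg),
                 "no validation")
})
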