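test_that("generate_composite honors counts, roles and placement contracts", {
  spec <- synthetic_spec()
  gen <- generate_composite(spec, class_idx = 2L, rng = 44L)
  tt <- table(gen$truth$role)
  expect_equal(as.integer(tt["beetle"]), spec$n_beetles)
  expect_equal(as.integer(tt["edge"]), spec$n_edge_objects)
  expect_equal(as.integer(tt["debris"]), spec$n_debris)

  sz <- spec$image_size
  b <- gen$truth[gen$truth$role == "beetle", ]
  expect_true(all(b$bbox_r0 > 0 & b$bbox_c0 > 0 & b$bbox_r1 < sz & b$bbox_c1 < sz))
  # beetle boxes pairwise disjoint
  for (i in seq_len(nrow(b))) for (j in seq_len(nrow(b))) {
    if (i < j) {
      expect_equal(bbox_iou(as.numeric(b[i, 3:6]), as.numeric(b[j, 3:6])), 0)
    }
  }
  # edge objects do touch the border
  e <- gen$truth[gen$truth$role == "edge", ]
  expect_true(all(e$bbox_r0 == 0 | e$bbox_c0 == 0 | e$bbox_r1 == sz | e$bbox_c1 == sz))
  # debris well below a tenth of the smallest beetle
  expect_true(all(gen$truth$area[gen$truth$role == "debris"] <
                    0.1 * min(b$area)))

  empty <- generate_composite(synthetic_spec(n_beetles = 0L, n_edge_objects = 0L,
                                             n_debris = 0L), 1L, rng = 2L)
  expect_equal(nrow(empty$truth), 0L)
  expect_equal(dim(empty$image), c(320L, 320L, 3L))
})

test_that("rendered blob areas track the class mean area", {
  spec <- synthetic_spec(n_beetles = 1L, n_edge_objects = 0L, n_debris = 0L)
  rng_seed <- 500L
  for (ci in c(1L, 4L)) {
    areas <- vapply(seq_len(100), function(k) {
      g <- generate_composite(spec, ci, rng = rng_seed + k)
      g$truth$area[1]
    }, numeric(1))
    expect_lt(abs(mean(areas) - spec$mean_area[ci]) / spec$mean_area[ci], 0.2)
    expect_gt(mean(abs(areas / spec$mean_area[ci] - 1) <= 0.3), 0.95)
  }
})

test_that("generate_dataset builds batches of shared objects and group ids", {
  spec <- synthetic_spec(n_classes = 3L, n_beetles = 4L)
  ds <- generate_dataset(spec, batches_per_class = 2L,
                         replicates_per_batch = 10L, seed = 77L)
  expect_equal(nrow(ds$manifest), 3L * 2L * 10L)
  expect_equal(length(unique(ds$manifest$group_id)), 6L)
  # replicates of a batch share label and group and re-place the same objects
  for (g in unique(ds$manifest$group_id)) {
    rows <- which(ds$manifest$group_id == g)
    expect_length(unique(ds$manifest$label[rows]), 1L)
    areas <- lapply(rows, function(i)
      sort(ds$truths[[i]]$area[ds$truths[[i]]$role == "beetle"]))
    # same physical objects: per-replicate rendered areas nearly identical
    ref <- areas[[1]]
    for (a in areas[-1]) expect_equal(a, ref, tolerance = 0.1)
  }
  # determinism: the same seed reproduces the pixels exactly
  ds2 <- generate_dataset(spec, batches_per_class = 2L,
                          replicates_per_batch = 10L, seed = 77L)
  expect_identical(ds$composites[[5]]$pixels, ds2$composites[[5]]$pixels)
})

test_that("probability-vector generator matches its Dirichlet contracts", {
  conf <- generate_probability_vectors(10000, 12L, "confident", seed = 9L)
  expect_true(all(abs(rowSums(conf$P) - 1) < 1e-9))
  expect_gte(mean(apply(conf$P, 1L, max)), 0.8)

  ood <- generate_probability_vectors(10000, 12L, "ood", seed = 10L)
  # symmetric Dirichlet(5): each coordinate mean 1/12, sd of the mean known
  mc_se <- sqrt(1 / 12 * 11 / 12 / (12 * 5 + 1)) / sqrt(10000)
  expect_true(all(abs(colMeans(ood$P) - 1 / 12) < 3 * mc_se + 1e-3))
  expect_true(all(is.na(ood$true_class)))
})

test_that("the separable regime supports a near-perfect simple linear classifier", {
  spec <- synthetic_spec()
  ds <- generate_dataset(spec, batches_per_class = 2L,
                         replicates_per_batch = 2L, seed = 13L)
  rows <- list()
  for (i in seq_along(ds$truths)) {
    tb <- ds$truths[[i]][ds$truths[[i]]$role == "beetle", ]
    g <- to_grayscale(ds$composites[[i]]$pixels)
    for (j in seq_len(nrow(tb))) {
      rows[[length(rows) + 1L]] <- data.frame(
        area = tb$area[j],
        intensity = mean(g[(tb$bbox_r0[j] + 1):tb$bbox_r1[j],
                           (tb$bbox_c0[j] + 1):tb$bbox_c1[j]]),
        y = ds$manifest$label[i])
    }
  }
  feats <- do.call(rbind, rows)
  feats$y <- factor(feats$y)
  # linear discriminant analysis on the two raw features
  fit <- MASS::lda(y ~ area + intensity, data = feats)
  pred <- predict(fit)$class
  expect_gte(mean(pred == feats$y), 0.99)
})

test_that("generated files round-trip through the manifest and image readers", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_classes = 2L, n_beetles = 3L, n_edge_objects = 1L,
                         n_debris = 1L, image_size = 160L)
  ds <- generate_dataset(spec, batches_per_class = 1L,
                         replicates_per_batch = 2L, seed = 3L, dir = dir)
  m <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(m), 4L)
  expect_true(all(file.exists(file.path(dir, m$composite_path))))
  img <- read_pnm(file.path(dir, m$composite_path[1]))
  expect_equal(dim(img), c(160L, 160L, 3L))
  # 8-bit quantization round trip
  expect_lt(max(abs(img - ds$composites[[1]]$pixels)), 1 / 255 + 1e-9)
})
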