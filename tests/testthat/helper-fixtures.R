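# Shared fixtures: everything is generated in code at test time.

# segment a generated dataset into in-memory crops with labels and groups
make_crop_dataset <- function(n_classes = 4L, batches_per_class = 2L,
                              replicates = 2L, seed = 21L, spec = NULL) {
  if (is.null(spec)) spec <- synthetic_spec(n_classes = n_classes)
  ds <- generate_dataset(spec, batches_per_class = batches_per_class,
                         replicates_per_batch = replicates, seed = seed)
  crops <- list(); labels <- character(0); groups <- character(0)
  for (i in seq_along(ds$composites)) {
    res <- disaggregate(ds$composites[[i]])
    for (cr in res$crops) {
      crops[[length(crops) + 1L]] <- cr$pixels
      labels <- c(labels, ds$manifest$label[i])
      groups <- c(groups, ds$manifest$group_id[i])
    }
  }
  list(crops = crops, labels = labels, groups = groups, dataset = ds)
}

# 0-based half-open bbox intersection-over-union
bbox_iou <- function(a, b) {
  ri <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ci <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ri * ci
  inter / ((a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

macro_f1 <- function(truth, pred, classes = sort(unique(truth))) {
  mean(vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1)))
}

# independent stack-based flood fill (8-connectivity) used as the labeling
# oracle; intentionally different from the package's frontier implementation
oracle_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    if (!mask[r, cc] || lab[r, cc] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, cc))
    lab[r, cc] <- nxt
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; c2 <- p[2] + dc
        if (rr >= 1 && rr <= h && c2 >= 1 && c2 <= w &&
            mask[rr, c2] && lab[rr, c2] == 0L) {
          lab[rr, c2] <- nxt
          stack[[length(stack) + 1L]] <- c(rr, c2)
        }
      }
    }
  }
  lab
}

# naive double-loop unknown-probability oracle
oracle_pu <- function(P, t) {
  d <- P ^ (1 - abs(P - t))
  n <- length(d)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(d[i] - d[j])
  1 - s / (2 * (n - 1) * sum(d))
}

# uniform draw from the probability simplex
random_simplex <- function(n_vec, n_classes) {
  g <- matrix(stats::rexp(n_vec * n_classes), n_vec, n_classes)
  g / rowSums(g)
}
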