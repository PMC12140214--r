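# Leakage-free data splitting. The unit of assignment is the group (one
# physical batch of specimens = one dish = all its agitation replicates), so
# that no individual can appear on both sides of a split. The test draw is
# stratified by class with largest-remainder rounding; the remaining groups
# are dealt into k cross-validation folds, balanced per class.

# unique (group_id, label) pairs of a manifest, with consistency check
group_table <- function(manifest) {
  if (is.null(manifest) || nrow(manifest) == 0L)
    stop("empty manifest", call. = FALSE)
  stopifnot(all(c("group_id", "label") %in% names(manifest)))
  gt <- unique(manifest[, c("group_id", "label")])
  if (anyDuplicated(gt$group_id))
    stop("a group_id maps to more than one label; groups must be single-class",
         call. = FALSE)
  gt
}

# largest-remainder allocation of per-class test counts: floor the exact
# quotas, then hand the remaining seats to the classes with the largest
# fractional remainders (ties broken by class order for determinism).
largest_remainder_counts <- function(class_sizes, frac) {
  exact <- class_sizes * frac
  base <- floor(exact)
  rem <- exact - base
  total <- round(sum(exact))
  extra <- total - sum(base)
  if (extra > 0) {
    give <- order(rem, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Stratified, grouped train/test split
#'
#' Assigns whole groups to the test set, per class, with the number of test
#' groups per class given by largest-remainder rounding of
#' `test_frac * (groups in class)` and a minimum of 1 where the class has at
#' least two groups. A class with a single group keeps it in train (with a
#' warning): in the closed-set setting the test set must not contain a class
#' absent from training. Selection within a class is uniform given the seed.
#'
#' @param manifest data.frame with at least `group_id` and `label` columns.
#' @param test_frac fraction of groups to hold out, strictly in (0, 1);
#'   the protocol default is 0.2.
#' @param seed integer seed.
#' @return List with character vectors `train_groups` and `test_groups`.
#' @export
stratified_group_test_split <- function(manifest, test_frac = 0.2, seed = 1L) {
  if (!is.numeric(test_frac) || test_frac <= 0 || test_frac >= 1)
    stop("test_frac must lie strictly in (0, 1)", call. = FALSE)
  gt <- group_table(manifest)
  classes <- sort(unique(gt$label))
  sizes <- vapply(classes, function(cl) sum(gt$label == cl), integer(1))
  counts <- largest_remainder_counts(sizes, test_frac)
  # minimum 1 test group where feasible; singleton-group classes stay in train
  counts <- ifelse(sizes >= 2L, pmax(counts, 1L), 0L)
  if (any(sizes == 1L))
    warning("class(es) with a single group kept entirely in train: ",
            paste(classes[sizes == 1L], collapse = ", "), call. = FALSE)
  counts <- pmin(counts, sizes - 1L)   # never empty a class's train side
  counts <- pmax(counts, 0L)
  test_groups <- character(0)
  rng <- make_rng(seed)
  for (i in seq_along(classes)) {
    g <- sort(gt$group_id[gt$label == classes[i]])
    if (counts[i] > 0L)
      test_groups <- c(test_groups, rng_sample(rng, g, counts[i]))
  }
  list(train_groups = sort(setdiff(gt$group_id, test_groups)),
       test_groups = sort(test_groups))
}

#' Grouped, class-balanced k-fold split
#'
#' Partitions groups into k folds so that within every class the per-fold
#' group counts differ by at most one, and no group appears in two folds.
#'
#' @param manifest data.frame with `group_id` and `label`, already restricted
#'   to the training groups.
#' @param k number of folds (>= 2); the protocol default is 5.
#' @param seed integer seed.
#' @return List of k character vectors of group ids, named `fold_1..fold_k`.
#' @export
kfold_group_split <- function(manifest, k = 5L, seed = 1L) {
  if (!is.numeric(k) || k < 2L) stop("k must be >= 2", call. = FALSE)
  gt <- group_table(manifest)
  if (k > nrow(gt))
    stop("k (", k, ") exceeds the number of groups (", nrow(gt), ")", call. = FALSE)
  folds <- replicate(k, character(0), simplify = FALSE)
  names(folds) <- paste0("fold_", seq_len(k))
  rng <- make_rng(seed)
  offset <- 0L
  for (cl in sort(unique(gt$label))) {
    g <- sort(gt$group_id[gt$label == cl])
    g <- rng_sample(rng, g, length(g))
    # deal round-robin, rotating the starting fold across classes so that
    # small classes do not all pile into fold 1
    pos <- ((seq_along(g) - 1L + offset) %% k) + 1L
    for (i in seq_along(g)) folds[[pos[i]]] <- c(folds[[pos[i]]], g[i])
    offset <- (offset + length(g)) %% k
  }
  lapply(folds, sort)
}

#' Attach split assignments to a manifest
#'
#' Writes a `split` column: `"test"` for test groups, `"fold_<j>"` for each
#' cross-validation fold.
#'
#' @param manifest data.frame with `group_id` and `label`.
#' @param test_frac,k,seed see [stratified_group_test_split()] and
#'   [kfold_group_split()].
#' @return The manifest with a `split` column added.
#' @export
assign_splits <- function(manifest, test_frac = 0.2, k = 5L, seed = 1L) {
  tt <- stratified_group_test_split(manifest, test_frac, seed)
  train_manifest <- manifest[manifest$group_id %in% tt$train_groups, , drop = FALSE]
  folds <- kfold_group_split(train_manifest, k, seed)
  split <- rep(NA_character_, nrow(manifest))
  split[manifest$group_id %in% tt$test_groups] <- "test"
  for (j in seq_along(folds))
    split[manifest$group_id %in% folds[[j]]] <- names(folds)[j]
  manifest$split <- split
  manifest
}
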