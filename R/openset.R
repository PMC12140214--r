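# Unknown-class (out-of-class) probability scoring. A closed-set classifier
# over n known classes outputs a probability vector P; a dispersion statistic
# on a threshold-anchored transform d of P estimates the probability that the
# input belongs to none of the trained classes. Near 0 when one class
# dominates, near 1 when the probabilities are all similar.

check_probability_vector <- function(P, tol = 1e-6) {
  if (!is.numeric(P) || length(P) < 2L)
    stop("P must be a numeric probability vector of length >= 2", call. = FALSE)
  if (any(P < -tol) || any(P > 1 + tol))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(P) - 1) > tol)
    stop("probabilities must sum to 1 (tolerance 1e-6)", call. = FALSE)
  pmin(pmax(P, 0), 1)
}

check_threshold <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t <= 0 || t >= 1)
    stop("threshold t must lie strictly in (0, 1)", call. = FALSE)
  t
}

#' Threshold-anchored probability transform
#'
#' Raises each probability to the power of the complement of its absolute
#' distance to the decision threshold: `d_i = P_i ^ (1 - |P_i - t|)`. The
#' exponent lies in (0, 1], so `d_i` is well defined (with `0^positive = 0`)
#' and in `[0, 1]`. Probabilities close to the threshold are accentuated.
#'
#' @param P probability vector (length n >= 2, sums to 1).
#' @param t decision-boundary threshold, strictly in (0, 1).
#' @return Numeric vector `d` of length n.
#' @export
transform_probabilities <- function(P, t) {
  P <- check_probability_vector(P)
  t <- check_threshold(t)
  P ^ (1 - abs(P - t))
}

# mean-absolute-difference (Gini-type) dispersion ratio of a nonnegative
# vector d: sum_ij |d_i - d_j| / (2 (n-1) sum_j d_j), over ordered pairs.
# Computed via the sorted-order identity sum_ij |d_i - d_j| =
# 2 * sum_k (2k - n - 1) d_(k). Always in [0, 1].
gini_dispersion <- function(d) {
  n <- length(d)
  ds <- sort(d)
  pair_sum <- 2 * sum((2 * seq_len(n) - n - 1) * ds)
  pair_sum / (2 * (n - 1) * sum(d))
}

#' Unknown-class probability of a prediction
#'
#' `Pu = 1 - sum_ij |d_i - d_j| / (2 (n - 1) sum_j d_j)` with
#' `d = transform_probabilities(P, t)` and the double sum over all ordered
#' pairs. `Pu` is 0 exactly when `d` is one-hot (one certain class) and 1
#' exactly when all `d_i` are equal (no class stands out), and lies in
#' `[0, 1]` always by the standard mean-absolute-difference bound.
#'
#' @inheritParams transform_probabilities
#' @return Scalar `Pu` in `[0, 1]`.
#' @seealso [unknown_probability_matrix()] for a vectorized batch version.
#' @export
unknown_probability <- function(P, t) {
  d <- transform_probabilities(P, t)
  1 - gini_dispersion(d)
}

#' Unknown-class probabilities for a matrix of predictions
#'
#' Row-wise vectorized version of [unknown_probability()].
#'
#' @param P_mat numeric matrix, one probability vector per row.
#' @param t threshold in (0, 1).
#' @return Numeric vector of `Pu`, one per row.
#' @export
unknown_probability_matrix <- function(P_mat, t) {
  t <- check_threshold(t)
  P_mat <- as.matrix(P_mat)
  n <- ncol(P_mat)
  if (n < 2L) stop("need >= 2 classes", call. = FALSE)
  d <- P_mat ^ (1 - abs(P_mat - t))
  ds <- t(apply(d, 1L, sort))
  wts <- 2 * seq_len(n) - n - 1
  pair_sum <- 2 * as.vector(ds %*% wts)
  1 - pair_sum / (2 * (n - 1) * rowSums(d))
}

#' Open-set classification of one probability vector
#'
#' Two scoring methods share one interface. `method = "max_prob"` is the
#' conventional decision boundary: the input is "unknown" iff `max(P) < t`,
#' otherwise the argmax class (ties to the lowest index). `method = "formula"`
#' thresholds the unknown-class probability: "unknown" iff `Pu >= t_open`
#' (by default `t_open = t`). Both methods report `Pu` alongside the class
#' probabilities, and an `unknown_score` oriented so that higher means more
#' unknown (`Pu` for the formula, `1 - max(P)` for the baseline), which lets
#' ROC code treat the two identically.
#'
#' @param P probability vector.
#' @param config list with `t` (threshold in (0,1)), `method` ("formula" or
#'   "max_prob"), and optionally `t_open` (defaults to `t`); see
#'   [openset_config()].
#' @param class_names optional character vector of class names (defaults to
#'   `names(P)` or `class_1..n`).
#' @return An `openset_result`: list with `d`, `Pu`, `unknown_score`,
#'   `decision`, `argmax_class`, `method`, `t`.
#' @export
classify_openset <- function(P, config, class_names = NULL) {
  P <- check_probability_vector(P)
  t <- check_threshold(config$t)
  method <- match.arg(config$method, c("formula", "max_prob"))
  t_open <- if (!is.null(config$t_open)) check_threshold(config$t_open) else t
  n <- length(P)
  if (is.null(class_names)) class_names <- names(P)
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(n))
  d <- P ^ (1 - abs(P - t))
  Pu <- 1 - gini_dispersion(d)
  amax <- which.max(P)                       # first max: lowest-index tie-break
  argmax_class <- class_names[amax]
  score <- if (method == "formula") Pu else 1 - max(P)
  decision <- if (method == "formula") {
    if (Pu >= t_open) "unknown" else argmax_class
  } else {
    if (max(P) < t) "unknown" else argmax_class
  }
  structure(list(d = d, Pu = Pu, unknown_score = score, decision = decision,
                 argmax_class = argmax_class, method = method, t = t),
            class = "openset_result")
}

#' Open-set scoring configuration
#'
#' @param t decision-boundary threshold in (0, 1); the operational default in
#'   the deployed tool is 0.8.
#' @param method `"formula"` (unknown-class probability) or `"max_prob"`
#'   (conventional max-probability decision boundary).
#' @param t_open optional separate threshold applied to `Pu` by the formula
#'   method; defaults to `t`.
#' @return A list usable as the `config` of [classify_openset()].
#' @export
openset_config <- function(t = 0.8, method = c("formula", "max_prob"),
                           t_open = NULL) {
  check_threshold(t)
  if (!is.null(t_open)) check_threshold(t_open)
  list(t = t, method = match.arg(method), t_open = t_open)
}

#' @export
print.openset_result <- function(x, ...) {
  cat(sprintf("<openset_result method=%s decision=%s Pu=%.4f score=%.4f>\n",
              x$method, x$decision, x$Pu, x$unknown_score))
  invisible(x)
}
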