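# Disaggregation of composite photographs: dark specimens on a near-white
# background are isolated by grayscale conversion, Otsu binarization, border
# clearing, 8-connected component labeling, a two-means size filter, and crop
# extraction from the original color image. Bounding boxes are 0-based,
# half-open: (r0, c0, r1, c1) with r0 <= r < r1, c0 <= c < c1.

#' Convert a color image to grayscale
#'
#' Luminance-weighted channel combination with the ITU-R BT.601 weights
#' (0.299, 0.587, 0.114), the de-facto standard for this conversion.
#'
#' @param image H x W x 3 numeric array.
#' @return H x W numeric matrix.
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("to_grayscale() expects a 3-channel H x W x 3 array", call. = FALSE)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

#' Otsu threshold of a grayscale image
#'
#' Builds a 256-bin histogram over `[0, 1]` and returns the intensity cut
#' maximizing the between-class variance. Ties are broken toward the lower
#' threshold. The returned scalar `t` is chosen so that `gray < t` reproduces
#' the optimal histogram split exactly.
#'
#' @param gray numeric matrix with values in `[0, 1]` and at least two distinct
#'   intensity values.
#' @return Scalar threshold in (0, 1].
#' @export
otsu_threshold <- function(gray) {
  v <- as.vector(gray)
  if (anyNA(v)) stop("image contains NA", call. = FALSE)
  bins <- pmin(pmax(floor(v * 255), 0), 255)
  counts <- tabulate(bins + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L)
    stop("degenerate image: Otsu thresholding needs >= 2 distinct intensity levels",
         call. = FALSE)
  n <- length(v)
  lev <- 0:255
  counts <- as.numeric(counts)            # avoid 32-bit overflow in w0 * w1
  w0 <- cumsum(counts)                    # class 0 = bins <= k
  s0 <- cumsum(counts * lev)
  stot <- s0[256]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (stot - s0) / w1, 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2      # between-class variance (x n^2)
  sigma_b[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(sigma_b) - 1L            # which.max picks the first maximum
  (k + 1) / 255
}

#' Binarize a grayscale image
#'
#' Foreground (the specimens, photographed dark on a light background) is the
#' set of pixels strictly below the threshold.
#'
#' @param gray numeric matrix.
#' @param threshold scalar intensity cut, e.g. from [otsu_threshold()].
#' @return A `binary_mask`: list with logical matrix `pixels` (TRUE =
#'   foreground) and `threshold_used`.
#' @export
binarize <- function(gray, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  structure(list(pixels = gray < threshold, threshold_used = threshold),
            class = "binary_mask")
}

# ---- connected components (8-neighborhood) ----------------------------------

# label foreground pixels of a logical matrix with 8-connectivity.
# Returns an integer matrix: 0 = background, components numbered 1..n in
# raster-scan order (row-major, matching image reading order) of their first
# pixel. Frontier-based flood fill, vectorized per layer.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  # raster order = by row then column; column-major linear indices sorted
  # accordingly
  fg <- which(mask)
  if (length(fg) == 0L) return(lab)
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  ord <- order(rows, cols)
  fg_raster <- fg[ord]
  # 8-neighbor linear offsets (column-major): guard rows/cols at edges
  visited <- matrix(FALSE, h, w)
  nextlab <- 0L
  for (seed in fg_raster) {
    if (visited[seed]) next
    nextlab <- nextlab + 1L
    frontier <- seed
    visited[seed] <- TRUE
    lab[seed] <- nextlab
    while (length(frontier) > 0L) {
      fr <- ((frontier - 1L) %% h) + 1L
      fc <- ((frontier - 1L) %/% h) + 1L
      nr <- c(fr - 1L, fr - 1L, fr - 1L, fr, fr, fr + 1L, fr + 1L, fr + 1L)
      nc <- c(fc - 1L, fc, fc + 1L, fc - 1L, fc + 1L, fc - 1L, fc, fc + 1L)
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nidx <- (nc[ok] - 1L) * h + nr[ok]
      nidx <- unique(nidx[mask[nidx] & !visited[nidx]])
      visited[nidx] <- TRUE
      lab[nidx] <- nextlab
      frontier <- nidx
    }
  }
  lab
}

#' Remove foreground components touching the image border
#'
#' Any 8-connected foreground component with at least one pixel on the first or
#' last row or column is removed entirely; interior components are untouched.
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @return A `binary_mask` of the same size.
#' @export
clear_border_objects <- function(mask) {
  thr <- NA_real_
  if (inherits(mask, "binary_mask")) { thr <- mask$threshold_used; mask <- mask$pixels }
  lab <- label_components(mask)
  h <- nrow(lab); w <- ncol(lab)
  border_labels <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  border_labels <- border_labels[border_labels != 0L]
  out <- mask
  if (length(border_labels) > 0L) out[lab %in% border_labels] <- FALSE
  structure(list(pixels = out, threshold_used = thr), class = "binary_mask")
}

#' Label foreground objects and compute their bounding boxes
#'
#' One detected object per 8-connected foreground component, with exact pixel
#' area and tight 0-based half-open bounding box. Object ids follow the
#' raster-scan order of each component's first pixel.
#'
#' @param mask a `binary_mask` (or logical matrix).
#' @return data.frame with columns `object_id`, `area`, `bbox_r0`, `bbox_c0`,
#'   `bbox_r1`, `bbox_c1`, `kept` (initialized TRUE), `reject_reason`
#'   (initialized "none").
#' @export
label_objects <- function(mask) {
  if (inherits(mask, "binary_mask")) mask <- mask$pixels
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) {
    return(data.frame(object_id = integer(0), area = integer(0),
                      bbox_r0 = integer(0), bbox_c0 = integer(0),
                      bbox_r1 = integer(0), bbox_c1 = integer(0),
                      kept = logical(0), reject_reason = character(0),
                      stringsAsFactors = FALSE))
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  r <- ((idx - 1L) %% nrow(lab)) + 1L
  cc <- ((idx - 1L) %/% nrow(lab)) + 1L
  data.frame(
    object_id = seq_len(n),
    area = as.integer(tabulate(l, nbins = n)),
    bbox_r0 = as.integer(tapply(r, l, min) - 1L),
    bbox_c0 = as.integer(tapply(cc, l, min) - 1L),
    bbox_r1 = as.integer(tapply(r, l, max)),
    bbox_c1 = as.integer(tapply(cc, l, max)),
    kept = TRUE,
    reject_reason = "none",
    stringsAsFactors = FALSE
  )
}

# exact 1-D two-means: the global minimum-SSE two-partition of a set of
# values is a threshold partition of the sorted values, found by scanning all
# n-1 split points. Returns a logical vector, TRUE = member of the
# larger-mean cluster.
two_means_large_cluster <- function(x) {
  n <- length(x)
  if (n < 2L || length(unique(x)) == 1L) return(rep(TRUE, n))
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs); css <- cumsum(xs^2)
  sse <- vapply(seq_len(n - 1L), function(m) {
    s1 <- cs[m]; q1 <- css[m]
    s2 <- cs[n] - s1; q2 <- css[n] - q1
    (q1 - s1^2 / m) + (q2 - s2^2 / (n - m))
  }, 0)
  m <- which.min(sse)                      # first minimum: deterministic
  large <- logical(n)
  large[o[(m + 1L):n]] <- TRUE             # upper cluster has the larger mean
  large
}

#' Size-filter detected objects with a two-cluster split on area
#'
#' Clusters object areas into two groups (exact 1-D minimum-SSE two-partition,
#' the converged two-means solution) and keeps the cluster with the larger mean
#' area: specimens are the large objects, debris the small ones. Degenerate
#' inputs (fewer than two objects, or all areas equal) keep everything.
#'
#' @param objects data.frame from [label_objects()].
#' @return The same data.frame with `kept` and `reject_reason` updated
#'   (`"small_cluster"` for the rejected small-area cluster).
#' @export
filter_by_size <- function(objects) {
  if (nrow(objects) == 0L) return(objects)
  keep <- two_means_large_cluster(objects$area)
  objects$kept <- keep
  objects$reject_reason[!keep] <- "small_cluster"
  objects
}

# robust aspect-ratio outlier flag: |aspect - median| > 3.5 * MAD (with a
# floor on the MAD so near-constant aspect sets don't flag everything)
aspect_outlier_flags <- function(heights, widths) {
  asp <- pmax(heights, widths) / pmin(heights, widths)
  if (length(asp) < 3L) return(rep(FALSE, length(asp)))
  med <- stats::median(asp)
  mad <- stats::median(abs(asp - med))
  abs(asp - med) > 3.5 * max(mad, 0.05)
}

bboxes_overlap <- function(b1, b2) {
  b1[1] < b2[3] && b2[1] < b1[3] && b1[2] < b2[4] && b2[2] < b1[4]
}

#' Extract single-specimen crops from the original color composite
#'
#' Copies the color pixels of each kept object's (half-open) bounding box,
#' optionally expanded by a margin and clipped to the image. Crops are flagged
#' for human review when their box overlaps another kept box
#' (`touching_another_box`) or their aspect ratio is a robust outlier
#' (`aspect_outlier`); flagged crops stand in for the manual removal of
#' multi-specimen or partial crops in the original workflow.
#'
#' @param composite a [composite_image()].
#' @param objects data.frame from [filter_by_size()].
#' @param margin non-negative integer margin added on all sides (default 0).
#' @return List of `beetle_crop` objects: `pixels`, `bbox` (the expanded box
#'   actually cropped), `source_bbox` (the tight detection box), `flags`,
#'   `parent_composite`.
#' @export
extract_crops <- function(composite, objects, margin = 0L) {
  stopifnot(inherits(composite, "composite_image"), margin >= 0L)
  img <- composite$pixels
  h <- dim(img)[1]; w <- dim(img)[2]
  kept <- objects[objects$kept, , drop = FALSE]
  if (nrow(kept) == 0L) {
    warning("no objects kept; returning zero crops", call. = FALSE)
    return(list())
  }
  if (any(kept$bbox_r0 < 0L | kept$bbox_c0 < 0L | kept$bbox_r1 > h | kept$bbox_c1 > w |
          kept$bbox_r0 >= kept$bbox_r1 | kept$bbox_c0 >= kept$bbox_c1))
    stop("internal consistency error: bounding box out of image bounds", call. = FALSE)
  boxes <- lapply(seq_len(nrow(kept)), function(i) {
    c(max(kept$bbox_r0[i] - margin, 0L), max(kept$bbox_c0[i] - margin, 0L),
      min(kept$bbox_r1[i] + margin, h), min(kept$bbox_c1[i] + margin, w))
  })
  touch <- vapply(seq_along(boxes), function(i) {
    any(vapply(seq_along(boxes)[-i], function(j) bboxes_overlap(boxes[[i]], boxes[[j]]),
               logical(1)))
  }, logical(1))
  asp_out <- aspect_outlier_flags(kept$bbox_r1 - kept$bbox_r0,
                                  kept$bbox_c1 - kept$bbox_c0)
  lapply(seq_len(nrow(kept)), function(i) {
    b <- boxes[[i]]
    flags <- character(0)
    if (touch[i]) flags <- c(flags, "touching_another_box")
    if (asp_out[i]) flags <- c(flags, "aspect_outlier")
    structure(list(
      pixels = img[(b[1] + 1L):b[3], (b[2] + 1L):b[4], , drop = FALSE],
      bbox = b,
      source_bbox = c(kept$bbox_r0[i], kept$bbox_c0[i], kept$bbox_r1[i], kept$bbox_c1[i]),
      object_id = kept$object_id[i],
      area = kept$area[i],
      flags = flags,
      parent_composite = composite$source_path
    ), class = "beetle_crop")
  })
}

# Otsu effectiveness ratio: between-class variance at the threshold over the
# total bin variance. Near 1 for high-contrast object/background images;
# about 0.75 or below for unimodal (object-free) intensity distributions.
otsu_effectiveness <- function(gray, threshold) {
  bins <- pmin(pmax(floor(as.vector(gray) * 255), 0), 255)
  lo <- bins[gray < threshold]; hi <- bins[gray >= threshold]
  if (length(lo) == 0L || length(hi) == 0L) return(0)
  w0 <- length(lo) / length(bins)
  sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  tot <- stats::var(bins) * (length(bins) - 1) / length(bins)
  if (tot <= 0) return(0)
  sb / tot
}

#' Disaggregate a composite photograph into single-specimen crops
#'
#' Runs the full procedure: grayscale conversion, Otsu binarization (specimens
#' dark, background light), removal of border-touching objects, 8-connected
#' labeling, two-means size filtering, and crop extraction from the color
#' original. A degenerate (constant) image yields zero crops with the reason
#' recorded in the report rather than an error.
#'
#' @param composite a [composite_image()].
#' @param margin crop margin in pixels (default 0).
#' @param min_effectiveness images whose Otsu split explains less than this
#'   fraction of the intensity variance are treated as object-free (a unimodal
#'   histogram — e.g. pure background noise — scores about 0.75 or less,
#'   while dark specimens on the light background score near 1).
#' @return List with `crops` (list of `beetle_crop`) and `report` (stage
#'   counts: `n_objects_total`, `n_edge_removed`, `n_size_rejected`, `n_kept`,
#'   `threshold`, `degenerate`).
#' @export
disaggregate <- function(composite, margin = 0L, min_effectiveness = 0.8) {
  gray <- to_grayscale(composite$pixels)
  thr <- tryCatch(otsu_threshold(gray), error = function(e) NULL)
  if (!is.null(thr) && otsu_effectiveness(gray, thr) < min_effectiveness)
    thr <- NULL
  if (is.null(thr)) {
    return(list(crops = list(),
                report = list(n_objects_total = 0L, n_edge_removed = 0L,
                              n_size_rejected = 0L, n_kept = 0L,
                              threshold = NA_real_, degenerate = TRUE)))
  }
  mask <- binarize(gray, thr)
  objs_all <- label_objects(mask)
  cleared <- clear_border_objects(mask)
  objs <- label_objects(cleared)
  n_edge <- nrow(objs_all) - nrow(objs)
  objs <- filter_by_size(objs)
  n_rej <- sum(!objs$kept)
  crops <- if (any(objs$kept)) extract_crops(composite, objs, margin = margin) else {
    if (nrow(objs) == 0L) list() else suppressWarnings(extract_crops(composite, objs, margin))
  }
  list(crops = crops,
       report = list(n_objects_total = nrow(objs_all), n_edge_removed = n_edge,
                     n_size_rejected = n_rej, n_kept = sum(objs$kept),
                     threshold = thr, degenerate = FALSE))
}
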