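# Synthetic composite-image generator. Emulates what the disaggregation
# algorithm actually sees in the laboratory photographs: dark, compact,
# textured objects of one class per dish on a near-white background, some
# objects touching the image edge, and small debris specks — plus Dirichlet
# probability-vector generators exercising the open-set scoring in
# "confident known" and "ambiguous/unknown" regimes. Not photorealistic by
# design: ellipses with a sinusoidal texture are enough to drive the
# thresholding, labeling and size-filter logic.

#' Default synthetic world specification
#'
#' Each class carries a morphological signature: mean pixel area, elongation
#' (aspect ratio), base body intensity, and texture wavelength. Signatures are
#' laid out so that (i) classes are linearly separable on simple crop features
#' (areas and intensities pairwise >= 5 generator standard deviations apart,
#' the "separable" regime), and (ii) any left-out class shares its intensity
#' band with one remaining class and its texture band with another, so
#' excluded-class crops are genuinely ambiguous for a leave-one-class-out
#' evaluation rather than trivially separable.
#'
#' @param n_classes number of classes (2..8; default 4).
#' @param image_size composite image side in pixels (square; default 256).
#' @param n_beetles interior specimens per composite (default 8).
#' @param n_edge_objects specimens touching the border (default 2).
#' @param n_debris small specks (default 3), each far below 10% of the
#'   smallest specimen area.
#' @param background_intensity near-white background level (default 0.95).
#' @param noise_sd pixelwise Gaussian noise sd (default 0.01).
#' @return A `synthetic_spec` list with per-class parameter vectors
#'   `mean_area`, `aspect`, `intensity`, `texture_wavelength`, plus
#'   `texture_amplitude`, `intensity_sd`, `radius_jitter`, `debris_area_range`
#'   and the arguments above.
#' @export
synthetic_spec <- function(n_classes = 4L, image_size = 320L, n_beetles = 8L,
                           n_edge_objects = 2L, n_debris = 3L,
                           background_intensity = 0.95, noise_sd = 0.01) {
  stopifnot(n_classes >= 2L, n_classes <= 8L, image_size >= 96L,
            n_beetles >= 0L, n_edge_objects >= 0L, n_debris >= 0L)
  i <- seq_len(n_classes)
  # Class signatures are concentric dark marking patterns (central disc, mid
  # annulus, rim, and their unions) on a common body intensity. Any left-out
  # pattern is a sub- or super-position of patterns still in the training set,
  # so an excluded class projects between known classes instead of
  # extrapolating beyond them — the synthetic analogue of evaluating open-set
  # scoring on congeners "closely related" to the training genera. Sizes
  # follow a geometric ladder and are the trait a simple (area, intensity)
  # classifier can use.
  patterns <- list(c("disc"), c("mid"), c("rim"), c("disc", "rim"),
                   c("mid", "rim"), c("disc", "mid"), character(0),
                   c("disc", "mid", "rim"))
  spec <- list(
    n_classes = as.integer(n_classes),
    image_size = as.integer(image_size),
    n_beetles = as.integer(n_beetles),
    n_edge_objects = as.integer(n_edge_objects),
    n_debris = as.integer(n_debris),
    background_intensity = background_intensity,
    noise_sd = noise_sd,
    class_names = paste0("genus_", LETTERS[i]),
    mean_area = round(300 * 1.9^(i - 1L)^0.92), # >= 5 sigma apart pairwise
    aspect = 1.5 + 0.25 * ((i - 1L) %% 2L),     # mild elongation variety
    intensity = rep(0.40, n_classes),           # common body intensity
    marking_pattern = patterns[i],
    marking_delta = -0.28,                      # markings darker than body
    marking_annuli = list(disc = c(0, 0.45), mid = c(0.55, 0.80),
                          rim = c(0.88, 1.0)),
    texture_wavelength = rep(8, n_classes),
    texture_amplitude = 0.08,
    intensity_sd = 0.02,                        # per-object intensity jitter
    radius_jitter = 0.04,                       # relative axis-length jitter
    debris_area_range = c(6, 18),
    debris_intensity = 0.35,
    tint_strength = 0.06                        # per-class color tint
  )
  class(spec) <- "synthetic_spec"
  spec
}

# rasterize one rotated textured ellipse onto a grayscale canvas.
# Returns the modified canvas plus the tight bbox (0-based half-open) and area.
# annuli: list of c(rho0, rho1) ranges of the normalized elliptical radius
# carrying the dark class marking
render_ellipse <- function(canvas, center, axes, phi, base_int, tex_amp,
                           tex_lambda, tex_phase, annuli = list(),
                           marking_delta = 0) {
  h <- nrow(canvas); w <- ncol(canvas)
  half <- ceiling(max(axes)) + 2L
  r_lo <- max(1L, floor(center[1]) - half); r_hi <- min(h, ceiling(center[1]) + half)
  c_lo <- max(1L, floor(center[2]) - half); c_hi <- min(w, ceiling(center[2]) + half)
  if (r_lo > r_hi || c_lo > c_hi)
    return(list(canvas = canvas, bbox = NULL, area = 0L))
  rr <- rep(r_lo:r_hi, times = c_hi - c_lo + 1L)
  cc <- rep(c_lo:c_hi, each = r_hi - r_lo + 1L)
  dr <- rr - center[1]; dc <- cc - center[2]
  u <- dr * cos(phi) + dc * sin(phi)
  v <- -dr * sin(phi) + dc * cos(phi)
  inside <- (u / axes[1])^2 + (v / axes[2])^2 <= 1
  if (!any(inside))
    return(list(canvas = canvas, bbox = NULL, area = 0L))
  ri <- rr[inside]; ci <- cc[inside]
  tex <- tex_amp * sin(2 * pi * u[inside] / tex_lambda + tex_phase)
  val <- base_int + tex
  if (length(annuli) > 0L && marking_delta != 0) {
    rho <- sqrt((u[inside] / axes[1])^2 + (v[inside] / axes[2])^2)
    marked <- Reduce(`|`, lapply(annuli, function(a) rho >= a[1] & rho <= a[2]))
    val[marked] <- val[marked] + marking_delta
  }
  canvas[cbind(ri, ci)] <- pmin(pmax(val, 0.02), 0.88)
  list(canvas = canvas,
       bbox = c(min(ri) - 1L, min(ci) - 1L, max(ri), max(ci)),
       area = sum(inside))
}

bbox_clear <- function(b1, b2, gap = 3L) {
  # TRUE when the two (half-open) boxes are separated by at least `gap` pixels
  b1[3] + gap <= b2[1] || b2[3] + gap <= b1[1] ||
    b1[4] + gap <= b2[2] || b2[4] + gap <= b1[2]
}

# draw per-object morphology for `n` specimens of one class
draw_object_params <- function(spec, class_idx, n, rng) {
  area <- spec$mean_area[class_idx] *
    (1 + rng_norm(rng, n, 0, spec$radius_jitter))^2
  aspect <- spec$aspect[class_idx] * (1 + rng_norm(rng, n, 0, 0.05))
  b <- sqrt(area / (pi * aspect))
  data.frame(
    a = aspect * b, b = b,
    intensity = pmax(spec$intensity[class_idx] +
                       rng_norm(rng, n, 0, spec$intensity_sd), 0.02),
    lambda = rep(spec$texture_wavelength[class_idx], n),
    phase = rng_unif(rng, n, 0, 2 * pi)
  )
}

place_objects <- function(spec, params, rng, existing_boxes, edge = FALSE,
                          max_tries = 400L) {
  # returns list(centers, phis) such that rendered ellipses stay clear of
  # existing boxes; edge objects must intersect the border instead
  sz <- spec$image_size
  out <- vector("list", nrow(params))
  boxes <- existing_boxes
  for (i in seq_len(nrow(params))) {
    half <- ceiling(max(params$a[i], params$b[i])) + 2L
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      phi <- rng_unif(rng, 1, 0, pi)
      # orientation-aware footprint: tight support extents of the rotated
      # ellipse along rows and columns
      a_i <- params$a[i]; b_i <- params$b[i]
      ext_r <- ceiling(sqrt((a_i * cos(phi))^2 + (b_i * sin(phi))^2)) + 2L
      ext_c <- ceiling(sqrt((a_i * sin(phi))^2 + (b_i * cos(phi))^2)) + 2L
      if (edge) {
        # place the center close enough to a randomly chosen border that the
        # ellipse is guaranteed to cross it: the support of a rotated ellipse
        # along the border normal is sqrt((a cos phi)^2 + (b sin phi)^2)
        # (rows) or sqrt((a sin phi)^2 + (b cos phi)^2) (cols)
        side <- rng_int(rng, 1, 4)
        ext <- if (side <= 2L) ext_r else ext_c
        off <- rng_unif(rng, 1, -0.3, 0.3) * ext
        pos <- rng_unif(rng, 1, half + 2, sz - half - 2)
        center <- switch(side, c(1 + off, pos), c(sz - off, pos),
                         c(pos, 1 + off), c(pos, sz - off))
      } else {
        center <- c(rng_unif(rng, 1, ext_r + 3, sz - ext_r - 3),
                    rng_unif(rng, 1, ext_c + 3, sz - ext_c - 3))
      }
      cand <- c(floor(center[1] - ext_r), floor(center[2] - ext_c),
                ceiling(center[1] + ext_r), ceiling(center[2] + ext_c))
      ok <- all(vapply(boxes, function(b) bbox_clear(cand, b), logical(1)))
      if (ok) {
        boxes <- c(boxes, list(cand))
        out[[i]] <- list(center = center, phi = phi)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place all objects without overlap; ",
           "reduce n_beetles or enlarge image_size", call. = FALSE)
  }
  list(placements = out, boxes = boxes)
}

#' Generate one synthetic composite image with ground truth
#'
#' Renders `n_beetles` interior non-overlapping textured ellipses of a single
#' class, `n_edge_objects` ellipses intersecting the border, and `n_debris`
#' small specks on a noisy near-white background, and records each object's
#' true bounding box and role.
#'
#' @param spec a [synthetic_spec()].
#' @param class_idx class index (1-based) of this composite's single class.
#' @param rng an rng handle from the internal `make_rng()`, or an integer seed.
#' @param params optional pre-drawn per-object morphology (used by
#'   [generate_dataset()] to re-place the same objects across replicates).
#' @return List with `image` (H x W x 3 array), `truth` (data.frame: `role`,
#'   `class`, `bbox_r0..c1` 0-based half-open, `area`), and `params`.
#' @export
generate_composite <- function(spec, class_idx = 1L, rng = 1L, params = NULL) {
  if (is.numeric(rng)) rng <- make_rng(rng)
  stopifnot(class_idx >= 1L, class_idx <= spec$n_classes)
  sz <- spec$image_size
  canvas <- matrix(spec$background_intensity, sz, sz)
  if (is.null(params)) {
    params <- list(
      beetle = draw_object_params(spec, class_idx, spec$n_beetles, rng),
      edge = draw_object_params(spec, class_idx, spec$n_edge_objects, rng),
      debris = data.frame(
        area = rng_unif(rng, spec$n_debris, spec$debris_area_range[1],
                        spec$debris_area_range[2]),
        intensity = spec$debris_intensity +
          rng_norm(rng, spec$n_debris, 0, 0.03)
      )
    )
  }
  truth <- list()
  boxes <- list()
  # interior specimens, largest first so tight canvases still pack
  if (nrow(params$beetle) > 0L) {
    params$beetle <- params$beetle[order(-(params$beetle$a * params$beetle$b)), ,
                                   drop = FALSE]
    pl <- place_objects(spec, params$beetle, rng, boxes, edge = FALSE)
    boxes <- pl$boxes
    for (i in seq_len(nrow(params$beetle))) {
      p <- params$beetle[i, ]
      res <- render_ellipse(canvas, pl$placements[[i]]$center, c(p$a, p$b),
                            pl$placements[[i]]$phi, p$intensity,
                            spec$texture_amplitude, p$lambda, p$phase,
                            annuli = spec$marking_annuli[spec$marking_pattern[[class_idx]]],
                            marking_delta = spec$marking_delta)
      canvas <- res$canvas
      truth[[length(truth) + 1L]] <- data.frame(
        role = "beetle", class = spec$class_names[class_idx],
        bbox_r0 = res$bbox[1], bbox_c0 = res$bbox[2],
        bbox_r1 = res$bbox[3], bbox_c1 = res$bbox[4], area = res$area)
    }
  }
  # border-touching specimens
  if (nrow(params$edge) > 0L) {
    pl <- place_objects(spec, params$edge, rng, boxes, edge = TRUE)
    boxes <- pl$boxes
    for (i in seq_len(nrow(params$edge))) {
      p <- params$edge[i, ]
      res <- render_ellipse(canvas, pl$placements[[i]]$center, c(p$a, p$b),
                            pl$placements[[i]]$phi, p$intensity,
                            spec$texture_amplitude, p$lambda, p$phase,
                            annuli = spec$marking_annuli[spec$marking_pattern[[class_idx]]],
                            marking_delta = spec$marking_delta)
      canvas <- res$canvas
      if (!is.null(res$bbox))
        truth[[length(truth) + 1L]] <- data.frame(
          role = "edge", class = spec$class_names[class_idx],
          bbox_r0 = res$bbox[1], bbox_c0 = res$bbox[2],
          bbox_r1 = res$bbox[3], bbox_c1 = res$bbox[4], area = res$area)
    }
  }
  # debris specks: small circles
  if (nrow(params$debris) > 0L) {
    for (i in seq_len(nrow(params$debris))) {
      rad <- sqrt(params$debris$area[i] / pi)
      dd <- data.frame(a = rad, b = rad)
      pl <- place_objects(spec, dd, rng, boxes, edge = FALSE)
      boxes <- pl$boxes
      res <- render_ellipse(canvas, pl$placements[[1]]$center, c(rad, rad),
                            0, params$debris$intensity[i], 0, 1, 0)
      canvas <- res$canvas
      if (!is.null(res$bbox))
        truth[[length(truth) + 1L]] <- data.frame(
          role = "debris", class = spec$class_names[class_idx],
          bbox_r0 = res$bbox[1], bbox_c0 = res$bbox[2],
          bbox_r1 = res$bbox[3], bbox_c1 = res$bbox[4], area = res$area)
    }
  }
  canvas <- canvas + matrix(rng_norm(rng, sz * sz, 0, spec$noise_sd), sz, sz)
  canvas <- pmin(pmax(canvas, 0), 1)
  # slight class-specific tint so the color -> grayscale path is exercised
  tint <- spec$tint_strength * (class_idx / spec$n_classes - 0.5)
  img <- gray_to_rgb(canvas)
  img[, , 1] <- pmin(pmax(img[, , 1] * (1 + tint), 0), 1)
  img[, , 3] <- pmin(pmax(img[, , 3] * (1 - tint), 0), 1)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(role = character(0), class = character(0),
               bbox_r0 = integer(0), bbox_c0 = integer(0),
               bbox_r1 = integer(0), bbox_c1 = integer(0), area = integer(0))
  list(image = img, truth = truth, params = params)
}

#' Generate a full synthetic dataset of composites
#'
#' Batches emulate physical dishes: each batch holds specimens of one class
#' and is "photographed" `replicates_per_batch` times, re-placing the same
#' objects (same sizes, intensities, textures) at fresh positions and
#' orientations, as dish agitation would. All replicates of a batch share a
#' `group_id`.
#'
#' @param spec a [synthetic_spec()].
#' @param batches_per_class number of batches (dishes) per class.
#' @param replicates_per_batch photographs per batch (protocol default 10).
#' @param seed integer seed.
#' @param dir optional directory; when given, images are written as ASCII PPM
#'   and a `manifest.csv` is written alongside.
#' @return List with `manifest` (data.frame: `composite_path`, `label`,
#'   `group_id`, `replicate`), `composites` (list of [composite_image()]),
#'   and `truths` (list of truth data.frames).
#' @export
generate_dataset <- function(spec, batches_per_class = 2L,
                             replicates_per_batch = 10L, seed = 1L,
                             dir = NULL) {
  rng <- make_rng(seed)
  manifest <- list(); composites <- list(); truths <- list()
  idx <- 0L
  for (ci in seq_len(spec$n_classes)) {
    for (b in seq_len(batches_per_class)) {
      group <- sprintf("%s_b%02d", spec$class_names[ci], b)
      base <- generate_composite(spec, ci, rng)   # draws the batch's objects
      params <- base$params
      for (r in seq_len(replicates_per_batch)) {
        comp <- if (r == 1L) base else generate_composite(spec, ci, rng, params)
        idx <- idx + 1L
        fname <- sprintf("%s_r%02d.ppm", group, r)
        # the manifest keeps paths relative to its own directory, so a rerun
        # into a different directory is byte-identical
        ci_obj <- composite_image(comp$image, spec$class_names[ci], group, fname)
        composites[[idx]] <- ci_obj
        truths[[idx]] <- comp$truth
        manifest[[idx]] <- data.frame(
          composite_path = fname, label = spec$class_names[ci],
          group_id = group, replicate = r, stringsAsFactors = FALSE)
        if (!is.null(dir)) write_pnm(comp$image, file.path(dir, fname))
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  if (!is.null(dir))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, composites = composites, truths = truths)
}

#' Generate probability vectors with controlled confidence structure
#'
#' Dirichlet draws on the n-simplex. Regime `"confident"` concentrates mass on
#' one class (alpha = 50 on the true class, 0.5 elsewhere), emulating a
#' well-trained closed-set prediction; `"ambiguous"` and `"ood"` draw from the
#' symmetric Dirichlet(5), emulating the flat vectors an out-of-distribution
#' input tends to produce.
#'
#' @param n number of vectors.
#' @param n_classes vector length (>= 2).
#' @param regime `"confident"`, `"ambiguous"` or `"ood"`.
#' @param seed integer seed (or an rng handle).
#' @param true_class optional fixed index for the confident class; default
#'   cycles over classes.
#' @return List with `P` (n x n_classes matrix, rows on the simplex), `regime`,
#'   and `true_class` (NA for the symmetric regimes).
#' @export
generate_probability_vectors <- function(n, n_classes,
                                         regime = c("confident", "ambiguous", "ood"),
                                         seed = 1L, true_class = NULL) {
  regime <- match.arg(regime)
  stopifnot(n >= 1L, n_classes >= 2L)
  rng <- if (is.numeric(seed)) make_rng(seed) else seed
  if (regime == "confident") {
    tc <- if (is.null(true_class)) ((seq_len(n) - 1L) %% n_classes) + 1L
          else rep(as.integer(true_class), n)
    alpha <- matrix(0.5, n, n_classes)
    alpha[cbind(seq_len(n), tc)] <- 50
  } else {
    tc <- rep(NA_integer_, n)
    alpha <- matrix(5, n, n_classes)
  }
  g <- matrix(rng_gamma(rng, n * n_classes, shape = as.vector(alpha)),
              n, n_classes)
  P <- g / rowSums(g)
  list(P = P, regime = regime, true_class = tc)
}
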