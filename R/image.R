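# Low-level image utilities shared by the segmentation, augmentation and
# synthetic-data modules. Images are plain numeric arrays: H x W (grayscale)
# or H x W x 3 (color), intensities in [0, 1]. Row 1 is the top of the image;
# all bounding boxes in the package are 0-based and half-open.

#' Construct a composite-image record
#'
#' A composite image is one photograph containing many specimens of a single
#' class, together with its label and the batch ("group") identifier shared by
#' all agitation replicates of the same physical dish.
#'
#' @param pixels H x W x 3 numeric array with values in `[0, 1]` (8-bit input
#'   is rescaled on load by [read_pnm()]).
#' @param label class name (character scalar).
#' @param group_id batch identifier shared by replicate photographs; non-empty.
#' @param source_path optional file the image came from.
#' @return An object of class `composite_image`.
#' @export
composite_image <- function(pixels, label, group_id, source_path = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("composite image pixels must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("composite image must have positive dimensions", call. = FALSE)
  if (!is.character(label) || length(label) != 1L)
    stop("label must be a character scalar", call. = FALSE)
  if (!is.character(group_id) || length(group_id) != 1L || !nzchar(group_id))
    stop("group_id must be a non-empty character scalar", call. = FALSE)
  structure(
    list(pixels = pixels, label = label, group_id = group_id,
         source_path = source_path),
    class = "composite_image"
  )
}

#' @export
print.composite_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<composite_image %dx%d label=%s group=%s>\n",
              d[1], d[2], x$label, x$group_id))
  invisible(x)
}

# ---- plain-text PNM (ASCII PGM/PPM) I/O -------------------------------------
# The deployment format of the original pipeline was PNG; this environment has
# no binary image codec available, so the package reads and writes the ASCII
# PNM formats (P2 grayscale, P3 color), which round-trip 8-bit data exactly.

#' Write an image as ASCII PNM (P2/P3)
#'
#' @param img H x W or H x W x 3 numeric array in `[0, 1]`.
#' @param path output file; conventionally `.pgm` (gray) or `.ppm` (color).
#' @param maxval integer maximum sample value (default 255).
#' @return `path`, invisibly.
#' @export
write_pnm <- function(img, path, maxval = 255L) {
  stopifnot(is.numeric(img), maxval >= 1L)
  q <- function(v) as.integer(round(pmin(pmax(v, 0), 1) * maxval))
  if (length(dim(img)) == 3L) {
    h <- dim(img)[1]; w <- dim(img)[2]
    # interleave r,g,b per pixel in row-major raster order
    vals <- rbind(q(t(img[, , 1])), q(t(img[, , 2])), q(t(img[, , 3])))
    header <- c("P3", paste(w, h), as.character(maxval))
  } else {
    img <- as.matrix(img)
    h <- nrow(img); w <- ncol(img)
    vals <- q(t(img))
    header <- c("P2", paste(w, h), as.character(maxval))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  # chunk samples into lines to keep them comfortably under the 70-char limit
  v <- as.vector(vals)
  per_line <- 12L
  idx <- ceiling(seq_along(v) / per_line)
  writeLines(vapply(split(v, idx), paste, "", collapse = " "), con)
  invisible(path)
}

#' Read an ASCII PNM image (P2/P3)
#'
#' @param path file to read.
#' @return Numeric array in `[0, 1]`: H x W for P2, H x W x 3 for P3.
#' @export
read_pnm <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- sub("#.*$", "", raw)
  tok <- unlist(strsplit(paste(raw, collapse = " "), "[[:space:]]+"))
  tok <- tok[nzchar(tok)]
  magic <- tok[1]
  if (!magic %in% c("P2", "P3"))
    stop("unsupported PNM magic '", magic, "' (only ASCII P2/P3)", call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.numeric(tok[4])
  v <- as.numeric(tok[-(1:4)]) / maxval
  if (magic == "P2") {
    if (length(v) != h * w) stop("corrupt PGM: wrong sample count", call. = FALSE)
    t(matrix(v, nrow = w, ncol = h))
  } else {
    if (length(v) != 3L * h * w) stop("corrupt PPM: wrong sample count", call. = FALSE)
    m <- matrix(v, nrow = 3L)
    arr <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3) arr[, , ch] <- t(matrix(m[ch, ], nrow = w, ncol = h))
    arr
  }
}

# ---- resampling -------------------------------------------------------------

# sample a grayscale matrix at fractional (row, col) coordinates with bilinear
# interpolation; coordinates outside the image take `fill`.
bilinear_sample <- function(img, r, c, fill = 1) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  gv <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out <- rep(fill, length(ri))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    out
  }
  v00 <- gv(r0, c0); v01 <- gv(r0, c0 + 1)
  v10 <- gv(r0 + 1, c0); v11 <- gv(r0 + 1, c0 + 1)
  (1 - fr) * ((1 - fc) * v00 + fc * v01) + fr * ((1 - fc) * v10 + fc * v11)
}

#' Resize an image with bilinear interpolation
#'
#' Direct resize ("squash"): the aspect ratio is not preserved. Used to bring
#' crops to the classifier's input size.
#'
#' @param img H x W or H x W x 3 numeric array.
#' @param out_h,out_w target dimensions.
#' @return Resized array of the same number of channels.
#' @export
resize_image <- function(img, out_h, out_w) {
  nd <- length(dim(img))
  if (nd == 3L) {
    out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- resize_image(img[, , ch], out_h, out_w)
    return(out)
  }
  img <- as.matrix(img)
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  # align pixel centers of source and target grids
  rr <- if (out_h == 1L) (h + 1) / 2 else (seq_len(out_h) - 0.5) * h / out_h + 0.5
  cc <- if (out_w == 1L) (w + 1) / 2 else (seq_len(out_w) - 0.5) * w / out_w + 0.5
  rr <- pmin(pmax(rr, 1), h); cc <- pmin(pmax(cc, 1), w)
  grid_r <- rep(rr, times = out_w)
  grid_c <- rep(cc, each = out_h)
  matrix(bilinear_sample(img, grid_r, grid_c), nrow = out_h, ncol = out_w)
}

# apply the inverse of an affine map (2x2 matrix A and offset b, acting on
# centered (row, col) coordinates) to every output pixel and sample the input.
affine_warp <- function(img, A, b = c(0, 0), fill = 1) {
  nd <- length(dim(img))
  if (nd == 3L) {
    out <- array(0, dim = dim(img))
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- affine_warp(img[, , ch], A, b, fill)
    return(out)
  }
  img <- as.matrix(img)
  h <- nrow(img); w <- ncol(img)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  gr <- rep(seq_len(h), times = w) - cr
  gc <- rep(seq_len(w), each = h) - cc
  Ainv <- solve(A)
  src <- Ainv %*% rbind(gr - b[1], gc - b[2])
  vals <- bilinear_sample(img, src[1, ] + cr, src[2, ] + cc, fill = fill)
  matrix(vals, nrow = h, ncol = w)
}

# separable gaussian blur with edge replication; sigma in pixels, sigma <= 0
# is a no-op.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  nd <- length(dim(img))
  if (nd == 3L) {
    out <- array(0, dim = dim(img))
    for (ch in seq_len(dim(img)[3]))
      out[, , ch] <- gaussian_blur(img[, , ch], sigma)
    return(out)
  }
  img <- as.matrix(img)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad:rad)^2) / (2 * sigma^2))
  k <- k / sum(k)
  conv1 <- function(m, kern) {
    # convolve along rows (dimension 1) with replicated edges
    n <- nrow(m); rad <- (length(kern) - 1L) / 2L
    idx <- pmin(pmax(outer(seq_len(n), (-rad):rad, `+`), 1L), n)
    out <- matrix(0, nrow = n, ncol = ncol(m))
    for (j in seq_along(kern)) out <- out + kern[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img, k)), k))
}

# replicate a grayscale matrix into a 3-channel array
gray_to_rgb <- function(gray) {
  array(rep(as.matrix(gray), 3L), dim = c(nrow(gray), ncol(gray), 3L))
}
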