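#' RGB image container
#'
#' Wraps an `H x W x 3` integer array with channel values in `[0, 255]`.
#' This is the raw input of the pipeline, before grayscale conversion.
#'
#' @param pixels numeric or integer `H x W x 3` array, channels in `[0, 255]`.
#' @return an object of class `rgb_image` (the validated integer array).
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_data("rgb_image: expected an H x W x 3 array, got dims [%s]",
              paste(dim(pixels), collapse = " x "))
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop_data("rgb_image: empty image (H and W must be >= 1)")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_data("rgb_image: channel values must be in [0, 255] with no NA")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "rgb_image")
}

#' Grayscale image container
#'
#' @param pixels numeric or integer `H x W` matrix with values in `[0, 255]`
#'   (0 = black, 255 = white).
#' @return an object of class `gray_image`.
#' @export
gray_image <- function(pixels) {
  if (!is.matrix(pixels))
    stop_data("gray_image: expected an H x W matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop_data("gray_image: empty image (H and W must be >= 1)")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop_data("gray_image: values must be in [0, 255] with no NA")
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "gray_image")
}

#' Convert an RGB image to grayscale
#'
#' Uses ITU-R BT.601 luma weights by default: each output pixel is
#' `round(0.299 R + 0.587 G + 0.114 B)` with half-up rounding, clamped to
#' `[0, 255]`. The weights are an argument so they stay swappable in one
#' place.
#'
#' @param img an [rgb_image()].
#' @param weights length-3 non-negative weights for (R, G, B).
#' @return a [gray_image()] with the same dimensions.
#' @export
rgb_to_gray <- function(img, weights = c(0.299, 0.587, 0.114)) {
  img <- as_rgb_image(img)
  if (length(weights) != 3L || any(weights < 0))
    stop_usage("rgb_to_gray: weights must be 3 non-negative numbers")
  y <- weights[1] * img[, , 1] + weights[2] * img[, , 2] + weights[3] * img[, , 3]
  y <- round_half_up(y)
  y[y < 0] <- 0L
  y[y > 255] <- 255L
  gray_image(matrix(y, nrow = dim(img)[1]))
}

#' Gray-level histogram
#'
#' @param img a [gray_image()].
#' @return class `gray_histogram`: an integer vector of 256 counts indexed by
#'   gray level 0..255, with attribute `total` (the pixel count).
#' @export
gray_histogram <- function(img) {
  img <- as_gray_image(img)
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  structure(counts, total = length(img), class = "gray_histogram")
}

as_histogram <- function(x) {
  if (inherits(x, "gray_histogram")) return(x)
  if (inherits(x, "gray_image") || is.matrix(x)) return(gray_histogram(x))
  if (is.numeric(x) && length(x) == 256L && all(x >= 0) && !anyNA(x)) {
    counts <- as.integer(x)
    return(structure(counts, total = sum(counts), class = "gray_histogram"))
  }
  stop_data("expected a gray_histogram, gray_image, or 256 counts")
}

as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) x else gray_image(x)
}

as_rgb_image <- function(x) {
  if (inherits(x, "rgb_image")) x else rgb_image(x)
}

#' Otsu's maximum-interclass-variance threshold
#'
#' Selects the threshold `K` in `[0, 255]` maximizing the interclass variance
#' `g(K) = omega0 * omega1 * (mu0 - mu1)^2`, where class 0 is the set of
#' pixels with gray level `<= K` and class 1 the set with gray level `> K`;
#' `omega0`, `omega1` are the two class fractions and `mu0`, `mu1` the class
#' mean gray levels. Every candidate threshold is scanned; ties are broken
#' toward the smallest `K`, so the result is deterministic.
#'
#' An image with a single distinct gray level has no two-class split: the
#' result then carries `g = 0`, `K` equal to that level, and
#' `degenerate = TRUE` rather than an error, so batch pipelines continue.
#'
#' @param hist a `gray_histogram`, or anything [gray_histogram()] accepts.
#' @return class `otsu_result`: list with `threshold`, `omega0`, `omega1`,
#'   `mu0`, `mu1`, `g`, `degenerate`.
#' @export
otsu_threshold <- function(hist) {
  hist <- as_histogram(hist)
  counts <- as.numeric(hist)
  total <- sum(counts)
  if (total <= 0) stop_data("otsu_threshold: empty histogram")
  levels <- 0:255

  nonzero <- which(counts > 0)
  if (length(nonzero) == 1L) {
    lev <- nonzero - 1L
    return(structure(list(threshold = as.integer(lev),
                          omega0 = 1, omega1 = 0,
                          mu0 = as.numeric(lev), mu1 = NA_real_,
                          g = 0, degenerate = TRUE),
                     class = "otsu_result"))
  }

  # cumulative class-0 mass and first moment for K = 0..255
  w0 <- cumsum(counts) / total
  m0 <- cumsum(counts * levels) / total
  mu <- m0[256]
  w1 <- 1 - w0
  # guard empty classes; g is 0 there by convention (omega product vanishes)
  mu0 <- ifelse(w0 > 0, m0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (mu - m0) / w1, 0)
  g <- w0 * w1 * (mu0 - mu1)^2
  g[w0 == 0 | w1 == 0] <- 0

  k <- which.max(g) - 1L   # which.max returns the first (smallest K) maximum
  structure(list(threshold = as.integer(k),
                 omega0 = w0[k + 1L], omega1 = w1[k + 1L],
                 mu0 = mu0[k + 1L], mu1 = mu1[k + 1L],
                 g = g[k + 1L], degenerate = FALSE),
            class = "otsu_result")
}

#' Binarize a grayscale image
#'
#' Pixels whose gray value strictly exceeds `K` become white (255); all
#' others, including pixels exactly at `K`, become black (0).
#'
#' @param img a [gray_image()].
#' @param K integer threshold in `[0, 255]`.
#' @return class `binary_mask`: an integer matrix over `{0, 255}` with
#'   attribute `threshold_used`.
#' @export
binarize <- function(img, K) {
  img <- as_gray_image(img)
  if (length(K) != 1L || is.na(K) || K < 0 || K > 255)
    stop_range("binarize: threshold K must be a single value in [0, 255], got %s",
               format(K))
  m <- matrix(ifelse(unclass(img) > K, 255L, 0L), nrow = nrow(img))
  structure(m, threshold_used = as.integer(K), class = "binary_mask")
}

as_binary_mask <- function(x) {
  if (inherits(x, "binary_mask")) return(x)
  if (is.matrix(x) && all(x %in% c(0, 255))) {
    m <- x; storage.mode(m) <- "integer"
    return(structure(m, threshold_used = NA_integer_, class = "binary_mask"))
  }
  stop_data("expected a binary_mask (values restricted to {0, 255})")
}

#' White-area fraction of a binary mask
#'
#' @param mask a `binary_mask`.
#' @return class `area_ratio`: list with exact integer `white_pixels`,
#'   `total_pixels`, and their quotient `ratio` in `[0, 1]`.
#' @export
white_ratio <- function(mask) {
  mask <- as_binary_mask(mask)
  white <- sum(unclass(mask) == 255L)
  total <- length(mask)
  structure(list(white_pixels = as.integer(white),
                 total_pixels = as.integer(total),
                 ratio = white / total),
            class = "area_ratio")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("Otsu threshold K = %d (g = %.4f%s)\n", x$threshold, x$g,
              if (x$degenerate) ", degenerate single-level image" else ""))
  cat(sprintf("  class<=K: omega0 = %.4f, mu0 = %.2f\n", x$omega0, x$mu0))
  cat(sprintf("  class> K: omega1 = %.4f, mu1 = %.2f\n", x$omega1, x$mu1))
  invisible(x)
}

#' @export
print.area_ratio <- function(x, ...) {
  cat(sprintf("white/total = %d/%d = %.6f\n",
              x$white_pixels, x$total_pixels, x$ratio))
  invisible(x)
}
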