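# Shared test fixtures and independent oracles.

# Independent brute-force Otsu oracle: plain double loop over all 256
# candidate thresholds, class statistics recomputed from raw counts each
# time. Deliberately shares no code with otsu_threshold().
brute_otsu <- function(counts) {
  total <- sum(counts)
  levels <- 0:255
  best_g <- -1
  best_k <- NA_integer_
  for (K in 0:255) {
    in0 <- levels <= K
    n0 <- sum(counts[in0]); n1 <- total - n0
    if (n0 == 0 || n1 == 0) {
      g <- 0
    } else {
      mu0 <- sum(levels[in0] * counts[in0]) / n0
      mu1 <- sum(levels[!in0] * counts[!in0]) / n1
      g <- (n0 / total) * (n1 / total) * (mu0 - mu1)^2
    }
    if (g > best_g) { best_g <- g; best_k <- K }
  }
  list(threshold = best_k, g = best_g)
}

random_gray <- function(h, w, levels = 0:255) {
  gray_image(matrix(sample(levels, h * w, replace = TRUE), h, w))
}

table1_path <- function() {
  system.file("extdata", "table1_calibration.csv", package = "fluoarea")
}

table2_df <- function() {
  read.csv(system.file("extdata", "table2_distance_sensitivity.csv",
                       package = "fluoarea"))
}

table1_set <- function() fit_calibration_set(load_calibration_table(table1_path()))

# curves built from the published (printed-precision) coefficients
printed_curves <- function() {
  calibration_set(list(
    distance_curve(50, -18.7376, 0.0285, 0.9951, 8),
    distance_curve(75, 18.6109, 0.0725, 0.9981, 8),
    distance_curve(100, -18.1121, 0.136, 0.9953, 8)))
}

# a centered square of the given physical area
square_scene <- function(area_mm2, distance_cm, noise = list(),
                         focal_constant = 200, width = 480L, height = 360L,
                         seed = 1L) {
  side <- sqrt(area_mm2)
  scene_spec(list(shape_rectangle(side, side)), distance_cm,
             focal_constant = focal_constant, width = width, height = height,
             noise = noise, seed = seed)
}

# run a rendered scene through the measurement pipeline (gray -> Otsu ->
# binarize) and return the white-pixel count
measure_pixels <- function(scene) {
  gray <- rgb_to_gray(scene$image)
  K <- otsu_threshold(gray_histogram(gray))$threshold
  white_ratio(binarize(gray, K))$white_pixels
}

# calibrate synthetic curves at the given distances over the given areas
synthetic_calibration <- function(distances, areas, noise = list(),
                                  focal_constant = 200, width = 480L,
                                  height = 360L, seed = 1L) {
  curves <- lapply(distances, function(d) {
    pts <- data.frame(
      area = areas,
      pixels = vapply(seq_along(areas), function(i) {
        sc <- render_scene(square_scene(areas[i], d, noise = noise,
                                        focal_constant = focal_constant,
                                        width = width, height = height,
                                        seed = seed + i + round(100 * d)))
        measure_pixels(sc)
      }, numeric(1)))
    fit_distance_curve(pts, d)
  })
  calibration_set(curves, total_pixels = as.integer(width) * as.integer(height))
}
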