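#' Single-reference lambda calibration
#'
#' Under orthogonal photography at distance `d` much larger than the focal
#' length, the imaged fraction of the frame is proportional to the physical
#' area, and the unknown reciprocal focal length can be folded into one
#' camera constant:
#'
#'   area = d * lambda * (white/total ratio)
#'
#' `lambda_calibration()` builds the object from a known constant (e.g. a
#' previously published value); [fit_lambda()] estimates it from a reference
#' object of known area photographed at a known distance.
#'
#' @param lam calibration constant, mm^2 per (cm * ratio).
#' @param ref_area,ref_distance,ref_ratio the reference measurement the
#'   constant was derived from, if known.
#' @return class `lambda_calibration`.
#' @export
lambda_calibration <- function(lam, ref_area = NA_real_, ref_distance = NA_real_,
                               ref_ratio = NA_real_) {
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam <= 0)
    stop_data("lambda_calibration: lambda must be a single positive number")
  structure(list(lam = as.numeric(lam), ref_area = ref_area,
                 ref_distance = ref_distance, ref_ratio = ref_ratio),
            class = "lambda_calibration")
}

#' Fit the lambda constant from a reference object
#'
#' `lambda = ref_area / (d * ref_ratio)`: e.g. a coin of radius 11 mm
#' (area `pi * 11^2` = 380.13 mm^2) photographed at 33.4 cm whose binarized
#' image has white fraction 0.002605.
#'
#' @param ref_area known physical area of the reference object, mm^2.
#' @param d camera-to-surface distance, cm.
#' @param ref_ratio white/total pixel fraction of the reference's binarized
#'   image.
#' @return a [lambda_calibration()].
#' @export
fit_lambda <- function(ref_area, d, ref_ratio) {
  for (nm in c("ref_area", "d", "ref_ratio")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
      stop_data("fit_lambda: %s must be a single positive number", nm)
  }
  lambda_calibration(ref_area / (d * ref_ratio),
                     ref_area = ref_area, ref_distance = d, ref_ratio = ref_ratio)
}

new_measurement <- function(distance, ratio, estimated_area, method,
                            pixels = NA_integer_, warnings = character()) {
  structure(list(distance = distance, ratio = ratio,
                 estimated_area = estimated_area, method = method,
                 pixels = pixels, warnings = warnings),
            class = "fluoarea_measurement")
}

#' Physical area from a lambda calibration
#'
#' @param cal a [lambda_calibration()].
#' @param d photography distance, cm.
#' @param ratio white/total pixel fraction in `[0, 1]`.
#' @return class `fluoarea_measurement` with `estimated_area = lam * d * ratio`
#'   (mm^2) and `method = "lambda"`.
#' @export
area_from_lambda <- function(cal, d, ratio) {
  if (!inherits(cal, "lambda_calibration"))
    stop_usage("area_from_lambda: cal must be a lambda_calibration")
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0)
    stop_data("area_from_lambda: distance must be a single positive number")
  if (inherits(ratio, "area_ratio")) ratio <- ratio$ratio
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) ||
      ratio < 0 || ratio > 1)
    stop_data("area_from_lambda: ratio must be in [0, 1]")
  new_measurement(distance = d, ratio = ratio,
                  estimated_area = cal$lam * d * ratio, method = "lambda")
}

#' Construct a distance curve from known coefficients
#'
#' For curves taken from an external source (e.g. a published fit) rather
#' than fitted from points; [fit_distance_curve()] is the fitting path.
#'
#' @param distance photography distance, cm.
#' @param a0 intercept, mm^2.
#' @param a1 slope, mm^2 per pixel.
#' @param r2 coefficient of determination in `[0, 1]`.
#' @param n number of points behind the fit (>= 2).
#' @return class `distance_curve`.
#' @export
distance_curve <- function(distance, a0, a1, r2 = NA_real_, n = 2L) {
  if (distance <= 0) stop_data("distance_curve: distance must be positive")
  if (!is.na(r2) && (r2 < 0 || r2 > 1)) stop_data("distance_curve: r2 must be in [0, 1]")
  if (n < 2L) stop_data("distance_curve: n must be >= 2")
  structure(list(distance = as.numeric(distance), a0 = as.numeric(a0),
                 a1 = as.numeric(a1), r2 = as.numeric(r2), n = as.integer(n)),
            class = "distance_curve")
}

#' Fit a per-distance calibration curve by ordinary least squares
#'
#' Regresses physical area (response, mm^2) on white-pixel count
#' (predictor): `f(x) = a0 + a1 * x`, reporting the coefficient of
#' determination r^2 = 1 - SS_resid / SS_tot. This orientation reproduces
#' the published coefficients; the inverse orientation does not.
#'
#' @param points data.frame with columns `area` (mm^2) and `pixels` (white
#'   pixel counts), one row per calibration target.
#' @param distance the photography distance these points share, cm.
#' @return class `distance_curve`: list with `distance`, `a0`, `a1`, `r2`, `n`.
#' @export
fit_distance_curve <- function(points, distance) {
  if (!is.data.frame(points) || !all(c("area", "pixels") %in% names(points)))
    stop_data("fit_distance_curve: points must have columns 'area' and 'pixels'")
  if (nrow(points) < 2L)
    stop_data("fit_distance_curve: need >= 2 points at distance %s, got %d",
              format(distance), nrow(points))
  if (length(unique(points$pixels)) < 2L)
    stop_data("fit_distance_curve: zero pixel variance at distance %s",
              format(distance))
  if (any(points$area <= 0) || any(points$pixels <= 0))
    stop_data("fit_distance_curve: areas and pixel counts must be positive")
  fit <- stats::lm(area ~ pixels, data = points)
  ss_resid <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((points$area - mean(points$area))^2)
  r2 <- if (ss_tot > 0) 1 - ss_resid / ss_tot else 1
  structure(list(distance = as.numeric(distance),
                 a0 = unname(stats::coef(fit)[1]),
                 a1 = unname(stats::coef(fit)[2]),
                 r2 = r2,
                 n = nrow(points)),
            class = "distance_curve")
}

#' Predict physical area from a white-pixel count
#'
#' @param curve a [fit_distance_curve()] result.
#' @param pixels non-negative white-pixel count.
#' @return predicted area `a0 + a1 * pixels` in mm^2. A negative prediction
#'   (pixel counts below the intercept crossing) is returned as-is with a
#'   warning of class `fluoarea_negative_area`.
#' @export
predict_area <- function(curve, pixels) {
  if (!inherits(curve, "distance_curve"))
    stop_usage("predict_area: curve must be a distance_curve")
  if (any(pixels < 0)) stop_data("predict_area: pixels must be >= 0")
  a <- curve$a0 + curve$a1 * pixels
  if (any(a < 0))
    warning(warningCondition(
      sprintf("predicted area below zero at %.0f px on the %g cm curve (small regions fall below the intercept)",
              pixels[which(a < 0)[1]], curve$distance),
      class = "fluoarea_negative_area"))
  a
}

#' Bundle distance curves into a calibration set
#'
#' @param curves list of [fit_distance_curve()] results; distances must be
#'   unique. Stored sorted by ascending distance.
#' @param total_pixels image pixel count (H*W) the pixel counts were measured
#'   against, if known; lets ratio-based reports be converted back to counts.
#' @return class `calibration_set`.
#' @export
calibration_set <- function(curves, total_pixels = NA_integer_) {
  if (length(curves) < 1L || !all(vapply(curves, inherits, TRUE, "distance_curve")))
    stop_data("calibration_set: need >= 1 distance_curve")
  d <- vapply(curves, `[[`, numeric(1), "distance")
  if (anyDuplicated(d))
    stop_data("calibration_set: duplicate calibration distance %g", d[duplicated(d)][1])
  structure(list(curves = curves[order(d)],
                 total_pixels = total_pixels),
            class = "calibration_set")
}

distances_of <- function(cal) vapply(cal$curves, `[[`, numeric(1), "distance")

#' Interpolated area at an arbitrary distance
#'
#' For `d` between two calibrated distances `d_lo <= d <= d_hi`, blends the
#' two curves' predictions linearly:
#' `f_lo(pixels) + (d - d_lo) / (d_hi - d_lo) * (f_hi(pixels) - f_lo(pixels))`.
#' At a calibrated distance the corresponding curve's prediction is returned
#' exactly. Distances outside the calibrated range raise a range error
#' unless `allow_extrapolation = TRUE`, in which case the nearest bracketing
#' pair is extended.
#'
#' @param cal a [calibration_set()].
#' @param d photography distance, cm.
#' @param pixels white-pixel count.
#' @param allow_extrapolation extend beyond the calibrated distance range
#'   (default FALSE: the method is only validated inside it).
#' @return class `fluoarea_measurement` with `method = "interpolated"` (or
#'   `"curve"` when the set holds a single curve at exactly `d`).
#' @export
interpolate_area <- function(cal, d, pixels, allow_extrapolation = FALSE) {
  if (!inherits(cal, "calibration_set"))
    stop_usage("interpolate_area: cal must be a calibration_set")
  if (!is.numeric(d) || length(d) != 1L || is.na(d) || d <= 0)
    stop_data("interpolate_area: distance must be a single positive number")
  ds <- distances_of(cal)

  exact <- which(ds == d)
  if (length(exact) == 1L) {
    est <- predict_area(cal$curves[[exact]], pixels)
    method <- if (length(ds) == 1L) "curve" else "interpolated"
    return(new_measurement(d, NA_real_, est, method, pixels = pixels))
  }
  if (d < min(ds) || d > max(ds)) {
    if (!allow_extrapolation)
      stop_range("interpolate_area: distance %g cm outside calibrated range [%g, %g] cm",
                 d, min(ds), max(ds))
    if (length(ds) == 1L)
      stop_range("interpolate_area: cannot extrapolate from a single curve")
    idx <- if (d < min(ds)) c(1L, 2L) else c(length(ds) - 1L, length(ds))
  } else {
    lo <- max(which(ds <= d))
    idx <- c(lo, lo + 1L)
  }
  c_lo <- cal$curves[[idx[1]]]; c_hi <- cal$curves[[idx[2]]]
  t <- (d - c_lo$distance) / (c_hi$distance - c_lo$distance)
  f_lo <- predict_area(c_lo, pixels)
  f_hi <- predict_area(c_hi, pixels)
  new_measurement(d, NA_real_, f_lo + t * (f_hi - f_lo), "interpolated",
                  pixels = pixels)
}

#' Read a calibration table CSV
#'
#' Expects a header `distance_cm, area_mm2, pixels`. Thousands separators in
#' numeric fields (as printed in source tables, e.g. "10,547") are stripped.
#' Rows are validated (positive values) and grouped by distance.
#'
#' @param path CSV path.
#' @return list of groups sorted by ascending distance, each
#'   `list(distance = cm, points = data.frame(area, pixels))`.
#' @export
load_calibration_table <- function(path) {
  if (!file.exists(path)) stop_data("load_calibration_table: no such file: %s", path)
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", strip.white = TRUE),
    error = function(e) stop_data("load_calibration_table: cannot parse %s: %s",
                                  path, conditionMessage(e)))
  need <- c("distance_cm", "area_mm2", "pixels")
  if (!all(need %in% names(df)))
    stop_data("load_calibration_table: %s must have header %s",
              path, paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop_data("load_calibration_table: %s has no data rows", path)
  num <- function(col, row) {
    v <- suppressWarnings(as.numeric(gsub(",", "", df[[col]][row], fixed = TRUE)))
    if (is.na(v)) stop_data("load_calibration_table: row %d: bad %s value '%s'",
                            row, col, df[[col]][row])
    if (v <= 0) stop_data("load_calibration_table: row %d: nonpositive %s (%g)",
                          row, col, v)
    v
  }
  parsed <- data.frame(
    distance = vapply(seq_len(nrow(df)), function(i) num("distance_cm", i), 0),
    area     = vapply(seq_len(nrow(df)), function(i) num("area_mm2", i), 0),
    pixels   = vapply(seq_len(nrow(df)), function(i) num("pixels", i), 0))
  groups <- split(parsed[c("area", "pixels")], parsed$distance)
  ds <- as.numeric(names(groups))
  ord <- order(ds)
  lapply(ord, function(i) list(distance = ds[i],
                               points = `rownames<-`(groups[[i]], NULL)))
}

#' Fit a calibration set from a grouped table
#'
#' Duplicate distance blocks are merged before fitting (grouping in
#' [load_calibration_table()] already merges them; this also accepts a raw
#' list with repeats).
#'
#' @param table result of [load_calibration_table()], or any list of
#'   `list(distance, points)` groups.
#' @param total_pixels optional image pixel count the counts refer to.
#' @return a [calibration_set()].
#' @export
fit_calibration_set <- function(table, total_pixels = NA_integer_) {
  if (length(table) == 0L) stop_data("fit_calibration_set: empty table")
  ds <- vapply(table, `[[`, numeric(1), "distance")
  merged <- lapply(unique(ds), function(d) {
    pts <- do.call(rbind, lapply(table[ds == d], `[[`, "points"))
    list(distance = d, points = pts)
  })
  curves <- lapply(merged, function(g) fit_distance_curve(g$points, g$distance))
  calibration_set(curves, total_pixels = total_pixels)
}

#' Persist / restore a calibration set as JSON
#'
#' Layout: `{"total_pixels": n, "curves": [{"distance_cm", "a0", "a1", "r2",
#' "n"}, ...]}`.
#'
#' @param cal a [calibration_set()].
#' @param path JSON path.
#' @return `write_calibration`: the path, invisibly. `read_calibration`: a
#'   [calibration_set()].
#' @export
write_calibration <- function(cal, path) {
  if (!inherits(cal, "calibration_set"))
    stop_usage("write_calibration: cal must be a calibration_set")
  obj <- list(
    total_pixels = cal$total_pixels,
    curves = lapply(cal$curves, function(cv)
      list(distance_cm = cv$distance, a0 = cv$a0, a1 = cv$a1,
           r2 = cv$r2, n = cv$n)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_data("read_calibration: no such file: %s", path)
  obj <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop_data("read_calibration: bad JSON in %s: %s",
                                                path, conditionMessage(e)))
  if (is.null(obj$curves))
    stop_data("read_calibration: %s has no 'curves' entry", path)
  curves <- lapply(obj$curves, function(cv)
    distance_curve(as.numeric(cv$distance_cm), as.numeric(cv$a0),
                   as.numeric(cv$a1), as.numeric(cv$r2 %||% NA),
                   as.integer(cv$n %||% 2L)))
  tp <- if (is.null(obj$total_pixels)) NA_integer_ else as.integer(obj$total_pixels)
  calibration_set(curves, total_pixels = tp)
}

#' @export
print.distance_curve <- function(x, ...) {
  cat(sprintf("distance curve @ %g cm: f(x) = %.4f + %.4g x (r2 = %.4f, n = %d)\n",
              x$distance, x$a0, x$a1, x$r2, x$n))
  invisible(x)
}

#' @export
print.calibration_set <- function(x, ...) {
  cat(sprintf("calibration set: %d curve(s), distances %s cm\n",
              length(x$curves), paste(distances_of(x), collapse = ", ")))
  for (cv in x$curves) print(cv)
  invisible(x)
}

#' @export
print.fluoarea_measurement <- function(x, ...) {
  cat(sprintf("estimated area: %.2f mm^2 (%s method, d = %g cm)\n",
              x$estimated_area, x$method, x$distance))
  invisible(x)
}
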