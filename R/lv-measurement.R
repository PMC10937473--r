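#' Derive the three LV linear dimensions from four keypoints
#'
#' Caliper-style measurements: IVS = |SEPT_ANT - SEPT_POST|,
#' LVD = |SEPT_POST - FW_ANT|, FW = |FW_ANT - FW_POST|, as full
#' Euclidean distances between consecutive keypoints. Centimetre
#' values apply the per-axis spacing to the coordinate deltas before
#' the norm, so anisotropic calibration is handled exactly; pixel
#' values are Euclidean in raw pixel coordinates. Geometric sanity
#' checks ([check_geometry()]) flag out-of-order or markedly
#' non-collinear point sets rather than silently projecting them.
#'
#' @param points Named list over [KEYPOINT_NAMES]: `c(x, y)` or `NULL`
#'   for a missing point.
#' @param spacing `c(sx_cm, sy_cm)` cm per pixel along x and y.
#' @param collinearity_tol_deg Tolerance for the collinearity flag.
#' @param order_check Run the monotone-order check.
#' @return A one-row tibble (class `measurement_triplet`): `ivs_cm`,
#'   `lvd_cm`, `fw_cm`, `ivs_px`, `lvd_px`, `fw_px`, `valid`, `flags`
#'   (comma-separated string, empty when valid).
#' @export
derive_measurements <- function(points, spacing,
                                collinearity_tol_deg = 15,
                                order_check = TRUE) {
  stopifnot(all(spacing > 0))
  present <- !vapply(points[KEYPOINT_NAMES], is.null, logical(1))
  flags <- character(0)
  vals_cm <- rep(NA_real_, 3)
  vals_px <- rep(NA_real_, 3)
  pair_idx <- list(c(1, 2), c(2, 3), c(3, 4))
  for (s in 1:3) {
    i <- pair_idx[[s]][1]; j <- pair_idx[[s]][2]
    if (present[i] && present[j]) {
      a <- points[[KEYPOINT_NAMES[i]]]; b <- points[[KEYPOINT_NAMES[j]]]
      d <- c(b[1] - a[1], b[2] - a[2])
      vals_px[s] <- sqrt(sum(d^2))
      vals_cm[s] <- sqrt((d[1] * spacing[1])^2 + (d[2] * spacing[2])^2)
    }
  }
  if (!all(present)) {
    flags <- c(flags, "MISSING_POINT")
  } else {
    flags <- c(flags, check_geometry(points, collinearity_tol_deg, order_check))
  }
  out <- tibble::tibble(
    ivs_cm = vals_cm[1], lvd_cm = vals_cm[2], fw_cm = vals_cm[3],
    ivs_px = vals_px[1], lvd_px = vals_px[2], fw_px = vals_px[3],
    valid = length(flags) == 0,
    flags = paste(flags, collapse = ","))
  class(out) <- c("measurement_triplet", class(out))
  out
}

#' Geometric sanity checks on a four-keypoint set
#'
#' Fits the total-least-squares line through the 4 points and flags
#' `OUT_OF_ORDER` when the projections onto it are not monotone in
#' anatomical order, and `NON_COLLINEAR` when the maximum
#' perpendicular deviation exceeds `tan(collinearity_tol_deg)` times
#' the projected span -- the "diagonal path across the ventricle"
#' failure mode.
#'
#' @param points Named list with all 4 keypoints present.
#' @param collinearity_tol_deg Angular tolerance in degrees.
#' @param order_check Whether to run the monotonicity check.
#' @return Character vector of flags (possibly empty).
#' @export
check_geometry <- function(points, collinearity_tol_deg = 15,
                           order_check = TRUE) {
  p <- do.call(rbind, points[KEYPOINT_NAMES])
  stopifnot(nrow(p) == 4)
  centred <- sweep(p, 2, colMeans(p))
  sv <- svd(centred)
  dir <- sv$v[, 1]
  proj <- centred %*% dir
  perp <- centred %*% sv$v[, 2]
  flags <- character(0)
  if (order_check) {
    d <- diff(proj[, 1])
    if (!(all(d > 0) || all(d < 0))) flags <- c(flags, "OUT_OF_ORDER")
  }
  span <- max(proj) - min(proj)
  if (span > 0 &&
      max(abs(perp)) > tan(collinearity_tol_deg * pi / 180) * span) {
    flags <- c(flags, "NON_COLLINEAR")
  }
  flags
}

#' Tabulate measurements for every annotation of a dataset
#'
#' Applies [derive_measurements()] to each annotation row and returns
#' the long measurement table used by the consensus validation
#' framework: one row per (frame, site, rater, repeat) with a finite
#' value. Sites rendered undefined by missing points are dropped;
#' geometry flags are carried along but do not exclude rows.
#'
#' @param dataset An [echo_dataset()].
#' @param annotations Annotation tibble to tabulate; defaults to the
#'   dataset's own annotations. Pass e.g. `rbind(panel, predictions)`
#'   to combine simulated raters with model output.
#' @return Tibble: `frame_id`, `phase`, `site`, `rater_id`,
#'   `repeat_index`, `value_cm`, `valid`, `flags`.
#' @export
tabulate_measurements <- function(dataset, annotations = NULL) {
  ann <- annotations %||% dataset$annotations
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    fr <- dataset$frames[dataset$frames$frame_id == ann$frame_id[i], ]
    mt <- derive_measurements(annotation_points(ann[i, ]),
                              c(fr$spacing_x_cm, fr$spacing_y_cm))
    tibble::tibble(frame_id = fr$frame_id, phase = fr$phase,
                   site = SITE_NAMES,
                   rater_id = ann$rater_id[i],
                   repeat_index = ann$repeat_index[i],
                   value_cm = c(mt$ivs_cm, mt$lvd_cm, mt$fw_cm),
                   valid = mt$valid, flags = mt$flags)
  })
  out <- dplyr::bind_rows(rows)
  out[!is.na(out$value_cm), ]
}
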