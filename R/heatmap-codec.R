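# Gaussian heatmap encoding/decoding. Targets are rendered directly at
# working resolution (never resized), so peaks are not attenuated by
# interpolation; each plane is normalized to peak 1, which keeps the
# decoded confidence interpretable as a match quality in [0, 1].

render_gaussian_plane <- function(p, size, sigma_px) {
  h <- size[1]; w <- size[2]
  gx <- exp(-((0:(w - 1)) - p[1])^2 / (2 * sigma_px^2))
  gy <- exp(-((0:(h - 1)) - p[2])^2 / (2 * sigma_px^2))
  plane <- outer(gy, gx)
  m <- max(plane)
  if (m > 0) plane / m else plane
}

#' Encode one annotation as a Gaussian heatmap stack
#'
#' Produces 5 channels at working resolution: one isotropic Gaussian
#' per keypoint (`exp(-||q - p||^2 / (2 sigma^2))`, normalized to peak
#' 1 at the keypoint) plus the pseudo-line channel of
#' [render_pseudo_line()]. A missing keypoint yields an all-zero
#' channel with loss mask 0, so it contributes nothing to a masked
#' loss; the pseudo-line channel is masked out when fewer than 2
#' points are present.
#'
#' @param annotation One-row annotation tibble (native coordinates).
#' @param frame Matching one-row frame tibble (for the native size).
#' @param working_size Working grid `c(H, W)`, default `c(320, 320)`.
#' @param sigma_px Gaussian SD in working pixels, default 15.
#' @return A `heatmap_stack`: list with `channels` (`[H, W, 5]` array,
#'   channel order [KEYPOINT_NAMES] then `"PSEUDO_LINE"`), `mask`
#'   (0/1 weight per channel), `sigma_px` and `scale_to_native`
#'   (`c(sx, sy)` mapping working to native pixels).
#' @export
encode_keypoints <- function(annotation, frame,
                             working_size = c(320, 320), sigma_px = 15) {
  stopifnot(all(working_size > 0), sigma_px > 0)
  sx <- frame$width_px / working_size[2]
  sy <- frame$height_px / working_size[1]
  pts <- annotation_points(annotation)
  work_pts <- lapply(pts, function(p) {
    if (is.null(p)) NULL else c(p[[1]] / sx, p[[2]] / sy)
  })
  channels <- array(0, dim = c(working_size[1], working_size[2], 5))
  mask <- numeric(5)
  for (i in seq_along(KEYPOINT_NAMES)) {
    p <- work_pts[[KEYPOINT_NAMES[i]]]
    if (!is.null(p)) {
      channels[, , i] <- render_gaussian_plane(p, working_size, sigma_px)
      mask[i] <- 1
    }
  }
  line <- render_pseudo_line(work_pts, working_size, sigma_px)
  channels[, , 5] <- line$plane
  mask[5] <- line$mask
  structure(list(channels = channels, mask = mask, sigma_px = sigma_px,
                 scale_to_native = c(sx, sy)),
            class = "heatmap_stack")
}

#' Render the pseudo-line collinearity channel
#'
#' A Gaussian ridge over the polyline joining the present keypoints in
#' anatomical order (`SEPT_ANT -> SEPT_POST -> FW_ANT -> FW_POST`):
#' plane value at pixel `q` is `exp(-d(q)^2 / (2 sigma^2))` with `d`
#' the Euclidean distance to the polyline, so the plane is exactly 1 on
#' the line. This auxiliary target rewards geometrically consistent
#' (near-collinear) keypoint predictions.
#'
#' @param points Named list over [KEYPOINT_NAMES] of working-space
#'   `c(x, y)` coordinates or `NULL`.
#' @param working_size Grid `c(H, W)`.
#' @param sigma_px Gaussian SD in working pixels.
#' @return List with `plane` (`[H, W]` matrix) and `mask` (1, or 0
#'   with an all-zero plane when fewer than 2 points are present).
#' @export
render_pseudo_line <- function(points, working_size, sigma_px) {
  present <- points[!vapply(points, is.null, logical(1))]
  if (length(present) < 2) {
    return(list(plane = matrix(0, working_size[1], working_size[2]),
                mask = 0))
  }
  h <- working_size[1]; w <- working_size[2]
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  d2 <- rep(Inf, h * w)
  for (i in seq_len(length(present) - 1)) {
    a <- present[[i]]; b <- present[[i + 1]]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      seg_d2 <- (gx - a[1])^2 + (gy - a[2])^2
    } else {
      t <- ((gx - a[1]) * ab[1] + (gy - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      seg_d2 <- (gx - (a[1] + t * ab[1]))^2 + (gy - (a[2] + t * ab[2]))^2
    }
    d2 <- pmin(d2, seg_d2)
  }
  list(plane = matrix(exp(-d2 / (2 * sigma_px^2)), h, w), mask = 1)
}

#' Decode a predicted heatmap plane to sub-pixel coordinates
#'
#' Locates the global maximum (ties broken toward the smallest
#' row-major index) and, when `refine = TRUE`, refines it as the
#' intensity-weighted centroid of the baseline-subtracted 7x7 window
#' around the peak (the window minimum is subtracted before weighting;
#' the window is clipped at borders). Returns `NULL` when the peak is
#' below `confidence_floor`.
#'
#' @param plane `[H, W]` numeric matrix.
#' @param confidence_floor Minimum peak value to accept (default 0.1).
#' @param refine Apply sub-pixel refinement (default `TRUE`).
#' @return Named numeric `c(x, y, confidence)` in 0-based plane
#'   coordinates, or `NULL`.
#' @export
decode_heatmap <- function(plane, confidence_floor = 0.1, refine = TRUE) {
  if (length(plane) == 0) stop("empty heatmap plane")
  if (any(!is.finite(plane))) stop("non-finite values in heatmap plane")
  peak <- max(plane)
  if (peak < confidence_floor) return(NULL)
  h <- nrow(plane); w <- ncol(plane)
  hits <- which(plane == peak)
  rows <- ((hits - 1) %% h)       # 0-based
  cols <- ((hits - 1) %/% h)
  best <- which.min(rows * w + cols)  # smallest row-major index
  py <- rows[best]; px <- cols[best]
  x <- px; y <- py
  if (refine) {
    r0 <- max(py - 3, 0); r1 <- min(py + 3, h - 1)
    c0 <- max(px - 3, 0); c1 <- min(px + 3, w - 1)
    win <- plane[(r0:r1) + 1, (c0:c1) + 1, drop = FALSE]
    wgt <- win - min(win)
    s <- sum(wgt)
    if (s > 0) {
      xs <- c0:c1; ys <- r0:r1
      x <- sum(colSums(wgt) * xs) / s
      y <- sum(rowSums(wgt) * ys) / s
    }
  }
  c(x = x, y = y, confidence = peak)
}

#' Map working-grid coordinates back to native pixels
#'
#' The exact inverse of the resize used for inference:
#' `x_native = x_working * sx`, `y_native = y_working * sy`.
#'
#' @param coords `c(x, y)` or an `n x 2` matrix of working coordinates.
#' @param scale_to_native `c(sx, sy)` (native size / working size).
#' @return Coordinates in native pixels, same shape as `coords`.
#' @export
coords_working_to_native <- function(coords, scale_to_native) {
  stopifnot(all(scale_to_native > 0))
  if (is.matrix(coords)) {
    cbind(coords[, 1] * scale_to_native[1], coords[, 2] * scale_to_native[2])
  } else {
    c(coords[1] * scale_to_native[1], coords[2] * scale_to_native[2])
  }
}
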