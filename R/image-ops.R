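# Bilinear sampling utilities shared by the resize step, the affine
# augmentation and the phantom writer. All coordinate maps use the
# package convention: 0-based, pixel-center origin at top-left.

# sample a 2-D matrix at fractional 0-based (x, y); outside -> 0
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  get <- function(xi, yi) {
    ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
    v <- numeric(length(xi))
    v[ok] <- img[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  get(x0, y0) * (1 - fx) * (1 - fy) +
    get(x0 + 1, y0) * fx * (1 - fy) +
    get(x0, y0 + 1) * (1 - fx) * fy +
    get(x0 + 1, y0 + 1) * fx * fy
}

apply_channels <- function(img, f) {
  if (length(dim(img)) == 2 || is.null(dim(img))) return(f(as.matrix(img)))
  out <- array(0, dim = dim(img))
  for (c in seq_len(dim(img)[3])) out[, , c] <- f(img[, , c])
  out
}

#' Resize an image by bilinear interpolation
#'
#' Coordinate contract: destination pixel `(x, y)` samples the source
#' at `(x * w_src / w_dst, y * h_src / h_dst)` (0-based indices), the
#' exact inverse of [coords_working_to_native()], so that decoded
#' keypoints map back to native coordinates without residual shift.
#'
#' @param img `[H, W]` or `[H, W, C]` numeric array.
#' @param size Destination `c(H, W)`.
#' @return Resized array of the same channel count.
#' @export
resize_bilinear <- function(img, size) {
  h_dst <- size[1]; w_dst <- size[2]
  h_src <- dim(img)[1]; w_src <- dim(img)[2]
  gx <- rep((0:(w_dst - 1)) * (w_src / w_dst), each = h_dst)
  gy <- rep((0:(h_dst - 1)) * (h_src / h_dst), times = w_dst)
  apply_channels(img, function(m) {
    matrix(bilinear_sample(m, gx, gy), nrow = h_dst, ncol = w_dst)
  })
}

# 3x3 affine matrices mapping 0-based (x, y, 1) column vectors
affine_identity <- function() diag(3)

affine_about_center <- function(size, rotate_rad = 0, scale = 1,
                                translate = c(0, 0)) {
  cx <- (size[2] - 1) / 2; cy <- (size[1] - 1) / 2
  t_in <- matrix(c(1, 0, 0, 0, 1, 0, -cx, -cy, 1), 3, 3)
  rs <- matrix(c(cos(rotate_rad) * scale, sin(rotate_rad) * scale, 0,
                 -sin(rotate_rad) * scale, cos(rotate_rad) * scale, 0,
                 0, 0, 1), 3, 3)
  t_out <- matrix(c(1, 0, 0, 0, 1, 0,
                    cx + translate[1], cy + translate[2], 1), 3, 3)
  t_out %*% rs %*% t_in
}

#' Warp an image by an affine map
#'
#' `m` maps source coordinates to destination coordinates (both
#' 0-based, `(x, y)`); the warp inverse-maps each destination pixel and
#' samples the source bilinearly, with zero padding outside.
#'
#' @param img `[H, W]` or `[H, W, C]` numeric array.
#' @param m 3x3 affine matrix acting on `(x, y, 1)` column vectors.
#' @return Warped array, same dimensions as `img`.
#' @export
warp_affine <- function(img, m) {
  h <- dim(img)[1]; w <- dim(img)[2]
  minv <- solve(m)
  gx <- rep(0:(w - 1), each = h)
  gy <- rep(0:(h - 1), times = w)
  sx <- minv[1, 1] * gx + minv[1, 2] * gy + minv[1, 3]
  sy <- minv[2, 1] * gx + minv[2, 2] * gy + minv[2, 3]
  apply_channels(img, function(mm) {
    matrix(bilinear_sample(mm, sx, sy), nrow = h, ncol = w)
  })
}

# transform 0-based (x, y) points (n x 2 matrix) by a 3x3 affine
affine_transform_points <- function(pts, m) {
  pts <- rbind(t(pts), 1)
  out <- m %*% pts
  t(out[1:2, , drop = FALSE])
}

#' Write a grayscale or RGB image to PNG
#'
#' @param img `[H, W]` or `[H, W, 3]` numeric array in `[0, 1]`.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_frame_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
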