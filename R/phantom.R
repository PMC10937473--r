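#' Specify a synthetic long-axis phantom frame
#'
#' The phantom emulates the appearance of a long-axis echocardiographic
#' frame as seen by the measurement pipeline: two bright near-parallel
#' wall bands (septum and free wall), perpendicular to a measurement
#' axis that runs down the middle of a fan-shaped scan sector, over a
#' darker blood pool, with multiplicative speckle and a gamma curve.
#' The four ground-truth keypoints are the intersections of the axis
#' with the band edges, so consecutive truth points are exactly
#' `ivs_cm`, `lvd_cm`, `fw_cm` apart (converted to pixels).
#'
#' @param size_px Image side length in pixels (square frames).
#' @param axis_origin `c(x, y)` of the first keypoint (SEPT_ANT) in
#'   0-based pixels; `NULL` centres the measured span in the image.
#' @param axis_angle Direction of the measurement axis in radians
#'   (`pi/2` points straight down the image).
#' @param ivs_cm,lvd_cm,fw_cm Septal thickness, internal diameter and
#'   free-wall thickness in cm.
#' @param spacing_cm_per_px Isotropic calibration, cm per pixel.
#' @param wall_brightness,chamber_brightness Band and blood-pool
#'   intensities in `[0, 1]`; walls must be brighter than the chamber.
#' @param speckle_strength Multiplicative speckle amplitude (0 = none).
#' @param gamma Display gamma applied as `img^gamma`.
#' @param sector_half_angle Half-angle of the scan sector (radians).
#' @param apex_offset_px Distance from SEPT_ANT back along the axis to
#'   the sector apex.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size_px = 320, axis_origin = NULL,
                         axis_angle = pi / 2,
                         ivs_cm = 0.8, lvd_cm = 2.5, fw_cm = 0.7,
                         spacing_cm_per_px = 0.02,
                         wall_brightness = 0.85, chamber_brightness = 0.15,
                         speckle_strength = 0.15, gamma = 1,
                         sector_half_angle = 0.6,
                         apex_offset_px = 0.12 * size_px) {
  stopifnot(ivs_cm > 0, lvd_cm > 0, fw_cm > 0, spacing_cm_per_px > 0,
            wall_brightness > chamber_brightness,
            wall_brightness <= 1, chamber_brightness >= 0,
            speckle_strength >= 0, gamma > 0)
  span_px <- (ivs_cm + lvd_cm + fw_cm) / spacing_cm_per_px
  u <- c(cos(axis_angle), sin(axis_angle))
  if (is.null(axis_origin)) {
    centre <- c((size_px - 1) / 2, (size_px - 1) / 2)
    axis_origin <- centre - u * span_px / 2
  }
  spec <- list(size_px = as.integer(size_px), axis_origin = axis_origin,
               axis_angle = axis_angle, ivs_cm = ivs_cm, lvd_cm = lvd_cm,
               fw_cm = fw_cm, spacing_cm_per_px = spacing_cm_per_px,
               wall_brightness = wall_brightness,
               chamber_brightness = chamber_brightness,
               speckle_strength = speckle_strength, gamma = gamma,
               sector_half_angle = sector_half_angle,
               apex_offset_px = apex_offset_px)
  pts <- phantom_truth_points(spec)
  if (any(pts < 0) || any(pts > size_px - 1)) {
    stop("phantom geometry does not fit the image: keypoints at ",
         paste(round(as.vector(t(pts)), 1), collapse = ", "),
         " for size ", size_px)
  }
  structure(spec, class = "phantom_spec")
}

# 4 x 2 matrix of 0-based (x, y) truth keypoints along the axis
phantom_truth_points <- function(spec) {
  u <- c(cos(spec$axis_angle), sin(spec$axis_angle))
  t_cm <- cumsum(c(0, spec$ivs_cm, spec$lvd_cm, spec$fw_cm))
  t_px <- t_cm / spec$spacing_cm_per_px
  pts <- cbind(spec$axis_origin[1] + u[1] * t_px,
               spec$axis_origin[2] + u[2] * t_px)
  rownames(pts) <- KEYPOINT_NAMES
  colnames(pts) <- c("x", "y")
  pts
}

#' Render one phantom frame
#'
#' Deterministic for a given seed (the seed drives only the speckle).
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the speckle field.
#' @param study_id,frame_id,phase Metadata for the [frame_record()].
#' @return List with `frame` (one-row frame tibble), `image`
#'   (`[H, W]` matrix in `[0, 1]`) and `truth` (one-row annotation,
#'   `rater_id = "TRUTH"`).
#' @export
generate_phantom <- function(spec, seed = 1L, study_id = "PH-S1",
                             frame_id = "PH-F1", phase = "UNKNOWN") {
  n <- spec$size_px
  u <- c(cos(spec$axis_angle), sin(spec$axis_angle))
  gx <- matrix(rep(0:(n - 1), each = n), n, n)   # x = column index
  gy <- matrix(rep(0:(n - 1), times = n), n, n)  # y = row index
  dx <- gx - spec$axis_origin[1]
  dy <- gy - spec$axis_origin[2]
  t_axis <- dx * u[1] + dy * u[2]
  t_px <- cumsum(c(0, spec$ivs_cm, spec$lvd_cm, spec$fw_cm)) /
    spec$spacing_cm_per_px
  img <- matrix(spec$chamber_brightness, n, n)
  wall <- (t_axis >= t_px[1] & t_axis <= t_px[2]) |
    (t_axis >= t_px[3] & t_axis <= t_px[4])
  img[wall] <- spec$wall_brightness
  # fan-shaped sector, apex behind SEPT_ANT on the axis
  apex <- spec$axis_origin - u * spec$apex_offset_px
  ax <- gx - apex[1]; ay <- gy - apex[2]
  r <- sqrt(ax^2 + ay^2)
  radius <- spec$apex_offset_px + t_px[4] * 1.15
  cosang <- (ax * u[1] + ay * u[2]) / pmax(r, 1e-9)
  img[!(cosang >= cos(spec$sector_half_angle) & r <= radius)] <- 0
  if (spec$speckle_strength > 0) {
    rayleigh <- local_seed(seed, sqrt(-2 * log(runif(n * n))))
    noise <- 1 + spec$speckle_strength * (rayleigh - sqrt(pi / 2))
    img <- img * matrix(noise, n, n)
  }
  img <- pmin(pmax(img, 0), 1)^spec$gamma
  pts <- phantom_truth_points(spec)
  truth <- annotation_record(frame_id, "TRUTH", 1L,
                             lapply(seq_len(4), function(i) pts[i, ]) |>
                               stats::setNames(KEYPOINT_NAMES))
  frame <- frame_record(study_id, frame_id, NA_character_, n, n,
                        spec$spacing_cm_per_px, spec$spacing_cm_per_px,
                        phase)
  list(frame = frame, image = img, truth = truth)
}

#' Default phantom parameter ranges for cohort generation
#'
#' Calibration is fixed so the frame spans 6.4 cm (0.02 cm/px at 320
#' px, 0.05 cm/px at 128 px); dimension ranges cover typical canine
#' long-axis values; the measurement axis stays near the sector
#' midline so the measurement site is recoverable from visible
#' structure.
#'
#' @param size_px Frame side length in pixels.
#' @return Named list of `c(lo, hi)` ranges plus the fixed spacing.
#' @export
phantom_ranges <- function(size_px = 320) {
  list(
    size_px = size_px,
    spacing_cm_per_px = 6.4 / size_px,
    ivs_cm = c(0.5, 1.0),
    lvd_cm = c(1.8, 3.0),
    fw_cm = c(0.5, 1.0),
    axis_angle = pi / 2 + c(-0.08, 0.08),
    wall_brightness = c(0.75, 0.9),
    chamber_brightness = c(0.1, 0.2),
    speckle_strength = c(0.1, 0.2),
    gamma = c(0.9, 1.1)
  )
}

#' Generate a cohort of phantom frames with ground-truth annotations
#'
#' Parameters are drawn independently and uniformly from `ranges` for
#' each frame; every frame receives a `"TRUTH"` annotation. Frames are
#' grouped into synthetic studies of `length(phases)` frames each with
#' the phases cycling (default ED, ES — the structure of a validation
#' set where each study contributes one end-diastolic and one
#' end-systolic frame). All randomness derives from `seed` through
#' per-frame substreams, so cohorts are reproducible regardless of
#' generation order.
#'
#' @param n Number of frames (>= 1).
#' @param ranges Parameter ranges, see [phantom_ranges()].
#' @param seed Integer seed.
#' @param phases Phase labels cycled across frames within a study.
#' @return An [echo_dataset()] with in-memory images.
#' @export
generate_cohort <- function(n, ranges = phantom_ranges(), seed = 1L,
                            phases = c("ED", "ES")) {
  if (n < 1) stop("n must be >= 1")
  draw <- function(rng, s) {
    if (length(rng) == 1) return(rng)
    local_seed(s, runif(1, rng[1], rng[2]))
  }
  frames <- list(); anns <- list(); imgs <- list()
  for (i in seq_len(n)) {
    ph <- phases[((i - 1) %% length(phases)) + 1]
    sid <- sprintf("PH-S%04d", ceiling(i / length(phases)))
    fid <- sprintf("PH-F%05d", i)
    spec <- phantom_spec(
      size_px = ranges$size_px,
      axis_angle = draw(ranges$axis_angle, derive_seed(seed, "ang", i)),
      ivs_cm = draw(ranges$ivs_cm, derive_seed(seed, "ivs", i)),
      lvd_cm = draw(ranges$lvd_cm, derive_seed(seed, "lvd", i)),
      fw_cm = draw(ranges$fw_cm, derive_seed(seed, "fw", i)),
      spacing_cm_per_px = ranges$spacing_cm_per_px,
      wall_brightness = draw(ranges$wall_brightness, derive_seed(seed, "wb", i)),
      chamber_brightness = draw(ranges$chamber_brightness, derive_seed(seed, "cb", i)),
      speckle_strength = draw(ranges$speckle_strength, derive_seed(seed, "sp", i)),
      gamma = draw(ranges$gamma, derive_seed(seed, "gm", i)))
    ph_out <- generate_phantom(spec, seed = derive_seed(seed, "img", i),
                               study_id = sid, frame_id = fid, phase = ph)
    frames[[i]] <- ph_out$frame
    anns[[i]] <- ph_out$truth
    imgs[[fid]] <- ph_out$image
  }
  echo_dataset(dplyr::bind_rows(frames), dplyr::bind_rows(anns), imgs)
}

#' Specify a stochastic multi-rater labeling model
#'
#' Emulates a reader panel in which raters agree on wall depth but
#' differ on where along the wall to measure: each placed point is
#' displaced by independent transverse noise (along the measurement
#' axis, i.e. across the walls — this perturbs thickness) and
#' longitudinal noise (along the walls, perturbing the measurement
#' site), and each rater carries a fixed longitudinal bias (a
#' systematically more apical or basal choice of site) constant across
#' repeats and frames.
#'
#' @param n_raters,n_repeats Panel size and blinded repeats per rater
#'   (defaults 13 x 2, i.e. 26 labels per frame).
#' @param sigma_transverse_px SD of noise along the axis (px).
#' @param sigma_longitudinal_px SD of noise across the axis (px).
#' @param rater_longitudinal_bias_sd_px SD of the per-rater fixed
#'   longitudinal bias (px).
#' @param miss_probability Probability that a rater cannot place a
#'   given point (the point is recorded as missing).
#' @return A `rater_model` list.
#' @export
rater_model <- function(n_raters = 13L, n_repeats = 2L,
                        sigma_transverse_px = 2,
                        sigma_longitudinal_px = 8,
                        rater_longitudinal_bias_sd_px = 4,
                        miss_probability = 0) {
  stopifnot(n_raters >= 1, n_repeats >= 1,
            sigma_transverse_px >= 0, sigma_longitudinal_px >= 0,
            rater_longitudinal_bias_sd_px >= 0,
            miss_probability >= 0, miss_probability < 1)
  structure(list(n_raters = as.integer(n_raters),
                 n_repeats = as.integer(n_repeats),
                 sigma_transverse_px = sigma_transverse_px,
                 sigma_longitudinal_px = sigma_longitudinal_px,
                 rater_longitudinal_bias_sd_px = rater_longitudinal_bias_sd_px,
                 miss_probability = miss_probability),
            class = "rater_model")
}

#' Simulate a rater panel labeling one frame
#'
#' Rater biases are derived from `seed` and the rater index only, so
#' calling this per frame with the same base seed keeps each simulated
#' rater's bias fixed across frames, as a real systematic reader
#' tendency would be.
#'
#' @param truth One-row annotation with all 4 points present.
#' @param frame The matching one-row frame tibble.
#' @param model A [rater_model()].
#' @param seed Integer base seed.
#' @return Tibble of `n_raters * n_repeats` annotation rows with
#'   `rater_id` `"E01"`, `"E02"`, ... and `repeat_index` 1..n_repeats.
#' @export
simulate_raters <- function(truth, frame, model, seed = 1L) {
  pts <- annotation_points(truth)
  if (any(vapply(pts, is.null, logical(1)))) {
    stop("truth annotation must have all 4 keypoints")
  }
  p <- do.call(rbind, pts)
  u <- p[4, ] - p[1, ]; u <- u / sqrt(sum(u^2))  # along the axis
  v <- c(-u[2], u[1])                            # along the walls
  out <- vector("list", model$n_raters * model$n_repeats)
  idx <- 1
  for (r in seq_len(model$n_raters)) {
    bias <- local_seed(derive_seed(seed, "bias", r),
                       rnorm(1, 0, model$rater_longitudinal_bias_sd_px))
    for (k in seq_len(model$n_repeats)) {
      noise <- local_seed(derive_seed(seed, frame$frame_id, r, k), {
        list(t = rnorm(4, 0, model$sigma_transverse_px),
             l = rnorm(4, bias, model$sigma_longitudinal_px),
             miss = runif(4) < model$miss_probability)
      })
      newpts <- lapply(1:4, function(i) {
        if (noise$miss[i]) return(NULL)
        q <- p[i, ] + u * noise$t[i] + v * noise$l[i]
        c(min(max(q[1], 0), frame$width_px - 1e-6),
          min(max(q[2], 0), frame$height_px - 1e-6))
      })
      names(newpts) <- KEYPOINT_NAMES
      out[[idx]] <- annotation_record(frame$frame_id, sprintf("E%02d", r),
                                      k, newpts)
      idx <- idx + 1
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate a rater panel over every frame of a dataset
#'
#' Applies [simulate_raters()] to each frame's `"TRUTH"` annotation
#' with a shared base seed (so per-rater biases persist across
#' frames).
#'
#' @param dataset An [echo_dataset()] whose frames carry `"TRUTH"`
#'   annotations.
#' @param model A [rater_model()].
#' @param seed Integer base seed.
#' @return Tibble of simulated annotation rows for all frames.
#' @export
simulate_rater_panel <- function(dataset, model, seed = 1L) {
  truth <- dataset$annotations[dataset$annotations$rater_id == "TRUTH", ]
  if (nrow(truth) == 0) stop("dataset has no TRUTH annotations")
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    fr <- dataset$frames[dataset$frames$frame_id == truth$frame_id[i], ]
    simulate_raters(truth[i, ], fr, model, seed)
  })
  dplyr::bind_rows(rows)
}
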