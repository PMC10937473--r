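#' Construct a frame record
#'
#' One echocardiographic frame with its calibration metadata. Pixel
#' spacing is carried per axis (cm per pixel at native resolution) so
#' that anisotropic calibration -- and the anisotropic effective spacing
#' created by resizing non-square frames to a square working grid --
#' is representable.
#'
#' @param study_id,frame_id Identifiers; `frame_id` must be unique
#'   within a dataset.
#' @param image_path Path to the PNG/TIFF image (may be `NA` when the
#'   pixel data are held in memory, as for generated phantoms).
#' @param height_px,width_px Native image dimensions (positive integers).
#' @param spacing_x_cm,spacing_y_cm Centimetres per pixel along x
#'   (columns) and y (rows); must be positive.
#' @param phase Cardiac phase: `"ED"`, `"ES"` or `"UNKNOWN"`.
#' @return A one-row tibble.
#' @export
frame_record <- function(study_id, frame_id, image_path = NA_character_,
                         height_px, width_px,
                         spacing_x_cm, spacing_y_cm,
                         phase = "UNKNOWN") {
  stopifnot(height_px > 0, width_px > 0,
            spacing_x_cm > 0, spacing_y_cm > 0)
  phase <- match.arg(phase, c("ED", "ES", "UNKNOWN"))
  tibble::tibble(
    study_id = as.character(study_id),
    frame_id = as.character(frame_id),
    image_path = as.character(image_path),
    height_px = as.integer(height_px),
    width_px = as.integer(width_px),
    spacing_x_cm = as.numeric(spacing_x_cm),
    spacing_y_cm = as.numeric(spacing_y_cm),
    phase = phase
  )
}

ann_coord_cols <- function() {
  as.vector(t(outer(tolower(KEYPOINT_NAMES), c("x", "y"),
                    function(a, b) paste(a, b, sep = "_"))))
}

#' Construct an annotation record
#'
#' One rater's four (possibly missing) keypoints on one frame. Missing
#' points are represented by `NULL` entries in `points` and stored as
#' `NA` coordinates.
#'
#' @param frame_id Frame identifier.
#' @param rater_id Rater identifier (e.g. an expert code, `"TRUTH"` for
#'   phantom ground truth, `"AI"` for network predictions).
#' @param repeat_index Positive integer; blinded repeats by the same
#'   rater get successive indices.
#' @param points Named list over [KEYPOINT_NAMES]; each element a
#'   numeric `c(x, y)` in native 0-based pixel coordinates, or `NULL`.
#' @return A one-row tibble with coordinate columns
#'   `sept_ant_x, sept_ant_y, ..., fw_post_y`.
#' @export
annotation_record <- function(frame_id, rater_id, repeat_index = 1L,
                              points = list()) {
  stopifnot(repeat_index >= 1)
  row <- tibble::tibble(
    frame_id = as.character(frame_id),
    rater_id = as.character(rater_id),
    repeat_index = as.integer(repeat_index)
  )
  for (kp in KEYPOINT_NAMES) {
    p <- points[[kp]]
    row[[paste0(tolower(kp), "_x")]] <- if (is.null(p)) NA_real_ else as.numeric(p[[1]])
    row[[paste0(tolower(kp), "_y")]] <- if (is.null(p)) NA_real_ else as.numeric(p[[2]])
  }
  row
}

#' Extract the keypoints of one annotation row as a named list
#'
#' @param ann A one-row annotation tibble (see [annotation_record()]).
#' @return Named list over [KEYPOINT_NAMES]: numeric `c(x, y)` or
#'   `NULL` for missing points.
#' @export
annotation_points <- function(ann) {
  stopifnot(nrow(ann) == 1)
  pts <- stats::setNames(vector("list", 4), KEYPOINT_NAMES)
  for (kp in KEYPOINT_NAMES) {
    x <- ann[[paste0(tolower(kp), "_x")]]
    y <- ann[[paste0(tolower(kp), "_y")]]
    if (!is.na(x) && !is.na(y)) pts[[kp]] <- c(x = unname(x), y = unname(y))
  }
  pts
}

#' Bundle frames and annotations into a dataset
#'
#' Validates referential integrity (every annotation resolves to
#' exactly one frame, frame ids unique) and coordinate bounds
#' (present points lie within `[0, width) x [0, height)`).
#'
#' @param frames Tibble of frame records ([frame_record()] rows).
#' @param annotations Tibble of annotation records (may be empty).
#' @param images Optional named list `frame_id -> image array` holding
#'   pixel data in memory (`[H, W]` or `[H, W, 3]` arrays in `[0, 1]`).
#' @return An object of class `echo_dataset`.
#' @export
echo_dataset <- function(frames, annotations = NULL, images = NULL) {
  if (is.null(annotations) || nrow(annotations) == 0) {
    annotations <- annotation_record("x", "x")[0, ]
  }
  if (anyDuplicated(frames$frame_id)) {
    stop("duplicate frame_id in frames: ",
         paste(unique(frames$frame_id[duplicated(frames$frame_id)]),
               collapse = ", "))
  }
  dangling <- setdiff(annotations$frame_id, frames$frame_id)
  if (length(dangling) > 0) {
    stop("annotations reference unknown frame_id(s): ",
         paste(unique(dangling), collapse = ", "))
  }
  if (nrow(annotations) > 0) {
    fm <- frames[match(annotations$frame_id, frames$frame_id), ]
    for (kp in tolower(KEYPOINT_NAMES)) {
      x <- annotations[[paste0(kp, "_x")]]
      y <- annotations[[paste0(kp, "_y")]]
      ok <- is.na(x) | (x >= 0 & x < fm$width_px & y >= 0 & y < fm$height_px)
      if (!all(ok)) {
        stop("keypoint ", toupper(kp), " out of frame bounds for frame(s): ",
             paste(unique(annotations$frame_id[!ok]), collapse = ", "))
      }
    }
  }
  structure(list(frames = frames, annotations = annotations,
                 images = images),
            class = "echo_dataset")
}

#' @export
print.echo_dataset <- function(x, ...) {
  cat("<echo_dataset> ", nrow(x$frames), " frames (",
      length(unique(x$frames$study_id)), " studies), ",
      nrow(x$annotations), " annotations, ",
      if (is.null(x$images)) "images on disk" else
        paste0(length(x$images), " images in memory"),
      "\n", sep = "")
  invisible(x)
}

#' Fetch the pixel data of one frame
#'
#' Uses the in-memory image if the dataset carries one, otherwise reads
#' `image_path` (PNG or TIFF). Images are returned as numeric arrays in
#' `[0, 1]`, `[H, W]` (grayscale) or `[H, W, 3]`.
#'
#' @param dataset An [echo_dataset()].
#' @param frame_id Frame identifier.
#' @return Numeric array.
#' @export
dataset_image <- function(dataset, frame_id) {
  if (!is.null(dataset$images) && frame_id %in% names(dataset$images)) {
    return(dataset$images[[frame_id]])
  }
  fr <- dataset$frames[dataset$frames$frame_id == frame_id, ]
  if (nrow(fr) != 1) stop("unknown frame_id: ", frame_id)
  read_frame_image(fr$image_path)
}

#' Read a PNG or TIFF image as a numeric array in [0, 1]
#'
#' @param path Image path; format chosen by extension.
#' @return `[H, W]` or `[H, W, 3]` numeric array (an alpha channel, if
#'   present, is dropped).
#' @export
read_frame_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path))
  if (length(dim(img)) == 3 && dim(img)[3] %in% c(2, 4)) {
    img <- img[, , seq_len(dim(img)[3] - 1), drop = FALSE]
  }
  if (length(dim(img)) == 3 && dim(img)[3] == 1) dim(img) <- dim(img)[1:2]
  img
}

json_points <- function(ann) {
  pts <- annotation_points(ann)
  lapply(pts, function(p) if (is.null(p)) NULL else unname(as.numeric(p)))
}

#' Write a dataset to a JSON-lines annotation file
#'
#' One JSON object per annotation, carrying the frame metadata inline;
#' frames without annotations are written as frame-only lines (null
#' `rater_id`) so that write-then-read is the identity. Missing points
#' are explicit nulls; coordinates are written as decimal text at full
#' double precision.
#'
#' @param dataset An [echo_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_annotations()]
#' @export
write_annotations <- function(dataset, path) {
  lines <- character(0)
  ann <- dataset$annotations
  for (i in seq_len(nrow(dataset$frames))) {
    fr <- dataset$frames[i, ]
    rows <- ann[ann$frame_id == fr$frame_id, ]
    base <- list(
      study_id = fr$study_id, frame_id = fr$frame_id,
      image_path = fr$image_path,
      height_px = fr$height_px, width_px = fr$width_px,
      spacing_x_cm = fr$spacing_x_cm, spacing_y_cm = fr$spacing_y_cm,
      phase = fr$phase)
    if (nrow(rows) == 0) {
      obj <- c(base, list(rater_id = NULL, repeat_index = NULL, points = NULL))
      lines <- c(lines, jsonlite::toJSON(obj, auto_unbox = TRUE,
                                         digits = NA, null = "null"))
    } else {
      for (j in seq_len(nrow(rows))) {
        obj <- c(base, list(rater_id = rows$rater_id[j],
                            repeat_index = rows$repeat_index[j],
                            points = json_points(rows[j, ])))
        lines <- c(lines, jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = NA, null = "null"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines annotation file
#'
#' Inverse of [write_annotations()]. Malformed lines and lines missing
#' required fields raise an error naming the offending line number.
#'
#' @param path Path to a JSON-lines file.
#' @return An [echo_dataset()].
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  frame_rows <- list()
  ann_rows <- list()
  req <- c("study_id", "frame_id", "height_px", "width_px",
           "spacing_x_cm", "spacing_y_cm", "phase")
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      stop("line ", i, ": malformed JSON (", conditionMessage(e), ")")
                    })
    miss <- setdiff(req, names(obj))
    if (length(miss) > 0) {
      stop("line ", i, ": missing required field(s): ",
           paste(miss, collapse = ", "))
    }
    fr <- frame_record(obj$study_id, obj$frame_id,
                       if (is.null(obj$image_path)) NA_character_ else obj$image_path,
                       obj$height_px, obj$width_px,
                       obj$spacing_x_cm, obj$spacing_y_cm, obj$phase)
    prev <- frame_rows[[fr$frame_id]]
    if (is.null(prev)) {
      frame_rows[[fr$frame_id]] <- fr
    } else if (!identical(as.list(prev), as.list(fr))) {
      stop("line ", i, ": frame metadata for '", fr$frame_id,
           "' conflicts with an earlier line")
    }
    has_ann <- !is.null(obj$rater_id) || !is.null(obj$points)
    if (has_ann) {
      if (is.null(obj$rater_id)) stop("line ", i, ": missing required field(s): rater_id")
      if (is.null(obj$repeat_index)) stop("line ", i, ": missing required field(s): repeat_index")
      pts <- lapply(stats::setNames(KEYPOINT_NAMES, KEYPOINT_NAMES), function(kp) {
        p <- obj$points[[kp]]
        if (is.null(p)) NULL else c(as.numeric(p[[1]]), as.numeric(p[[2]]))
      })
      ann_rows[[length(ann_rows) + 1]] <-
        annotation_record(obj$frame_id, obj$rater_id, obj$repeat_index, pts)
    }
  }
  frames <- dplyr::bind_rows(frame_rows)
  annotations <- if (length(ann_rows) > 0) dplyr::bind_rows(ann_rows) else NULL
  echo_dataset(frames, annotations)
}

#' Split a dataset into training and testing partitions
#'
#' Default granularity is the study: all frames of one study land on
#' the same side, preventing leakage of near-duplicate frames from one
#' scan across the split. A frame-level mode is available for datasets
#' where each frame is independent.
#'
#' @param dataset An [echo_dataset()].
#' @param train_fraction Fraction of units (studies or frames) assigned
#'   to training; strictly between 0 and 1. The training side receives
#'   `floor(train_fraction * n_units)` units (at least 1, at most
#'   `n_units - 1`).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param level `"study"` (default) or `"frame"`.
#' @return List with elements `train` and `test`, both [echo_dataset()]s.
#' @export
split_dataset <- function(dataset, train_fraction = 0.8, seed = 1L,
                          level = c("study", "frame")) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  level <- match.arg(level)
  units <- if (level == "study") {
    unique(dataset$frames$study_id)
  } else {
    dataset$frames$frame_id
  }
  if (length(units) < 2) {
    stop("need at least 2 ", level, "s to split, got ", length(units))
  }
  n_train <- max(1L, min(length(units) - 1L,
                         floor(train_fraction * length(units))))
  shuffled <- local_seed(seed, sample(units))
  train_units <- shuffled[seq_len(n_train)]
  in_train <- if (level == "study") {
    dataset$frames$study_id %in% train_units
  } else {
    dataset$frames$frame_id %in% train_units
  }
  subset_ds <- function(keep) {
    fr <- dataset$frames[keep, ]
    ann <- dataset$annotations[dataset$annotations$frame_id %in% fr$frame_id, ]
    imgs <- if (!is.null(dataset$images)) {
      dataset$images[intersect(names(dataset$images), fr$frame_id)]
    }
    echo_dataset(fr, ann, imgs)
  }
  list(train = subset_ds(in_train), test = subset_ds(!in_train))
}
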