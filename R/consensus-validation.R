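# Multi-reader consensus validation: per-frame consensus of a reader
# panel, deviation spectra, dispersion comparison (Levene) and bias
# testing (paired t) for any candidate measurer.

#' Consensus of repeated measurements
#'
#' The per-frame reference standard: the arithmetic mean of all expert
#' labels (repeats by the same expert count as independent labels).
#'
#' @param values Numeric vector, length >= 2, all finite.
#' @return Scalar mean.
#' @export
consensus <- function(values) {
  if (length(values) < 2) stop("consensus needs at least 2 values")
  if (any(!is.finite(values))) stop("non-finite value in consensus input")
  mean(values)
}

#' Signed deviations from a consensus value
#'
#' @param values Numeric vector.
#' @param consensus Scalar reference value.
#' @return `values - consensus`, order preserved; sums to zero when
#'   `consensus` is the mean of `values`.
#' @export
deviations <- function(values, consensus) {
  if (!is.finite(consensus)) stop("consensus must be finite")
  values - consensus
}

#' Root-mean-square dispersion of deviations
#'
#' `sqrt(mean(devs^2))` -- the population form; identical to the
#' population SD when the pooled deviations are mean-zero by
#' construction (deviations from a per-frame mean always are).
#'
#' @param devs Numeric vector, length >= 1.
#' @return Scalar RMS.
#' @export
rms_dispersion <- function(devs) {
  if (length(devs) < 1) stop("rms_dispersion needs at least 1 value")
  sqrt(mean(devs^2))
}

#' Levene / Brown-Forsythe test of equal dispersion in two groups
#'
#' Computes `W = [(N - k)/(k - 1)] * sum(n_i (Zbar_i - Zbar)^2) /
#' sum((Z_ij - Zbar_i)^2)` with `Z_ij = |Y_ij - center_i|`, k = 2, and
#' the p-value from the upper tail of F(k - 1, N - k). Median
#' centering (the Brown-Forsythe variant, the default of the common
#' statistical routines) is the default; mean centering gives the
#' classic test.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param center `"median"` or `"mean"`.
#' @return List `(W, p, center, n)` with `n = c(length(group_a),
#'   length(group_b))`.
#' @export
levene_dispersion_test <- function(group_a, group_b,
                                   center = c("median", "mean")) {
  center <- match.arg(center)
  groups <- list(group_a, group_b)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 values")
  }
  cfun <- if (center == "median") stats::median else mean
  z <- lapply(groups, function(g) abs(g - cfun(g)))
  n_i <- vapply(z, length, integer(1))
  n <- sum(n_i)
  k <- 2
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / n
  between <- sum(n_i * (zbar_i - zbar)^2)
  within <- sum(vapply(seq_len(k), function(i) sum((z[[i]] - zbar_i[i])^2),
                       numeric(1)))
  if (within <= 0) {
    stop("DEGENERATE_DISPERSION: no within-group spread of |centered| scores")
  }
  w <- ((n - k) / (k - 1)) * between / within
  p <- stats::pf(w, k - 1, n - k, lower.tail = FALSE)
  list(W = w, p = p, center = center, n = n_i)
}

#' Paired-t test of mean bias against the consensus
#'
#' Mean of the paired differences and the two-sided paired-t p-value
#' with n - 1 degrees of freedom. Zero-variance differences make the
#' t statistic undefined; these are reported via the `degenerate`
#' flag (with `p = NA`), not as a number.
#'
#' @param candidate,consensus Equal-length numeric vectors (>= 2),
#'   paired by frame.
#' @return List `(mean_bias, t, df, p, degenerate)`.
#' @export
bias_test <- function(candidate, consensus) {
  if (length(candidate) != length(consensus)) stop("length mismatch")
  if (length(candidate) < 2) stop("bias_test needs at least 2 pairs")
  d <- candidate - consensus
  if (stats::sd(d) <= 1e-10 * max(abs(d), 1)) {
    if (all(abs(d) < 1e-12)) {
      # identical vectors: no bias, maximally non-significant
      return(list(mean_bias = 0, t = 0, df = length(d) - 1, p = 1,
                  degenerate = FALSE))
    }
    return(list(mean_bias = mean(d), t = NA_real_, df = length(d) - 1,
                p = NA_real_, degenerate = TRUE))
  }
  tt <- stats::t.test(candidate, consensus, paired = TRUE)
  list(mean_bias = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
}

#' Build the full consensus-validation summary
#'
#' For every (phase, site): the per-frame consensus is the mean of the
#' expert labels (all raters except the candidate); expert deviations
#' are pooled across frames; the candidate contributes one deviation
#' per frame. Dispersion of the candidate deviations versus the pooled
#' expert deviations is compared with [levene_dispersion_test()], and
#' the candidate's mean bias against the per-frame consensus with
#' [bias_test()]. Frames lacking a candidate value are excluded from
#' the candidate columns and listed in the `excluded` report, never
#' silently dropped.
#'
#' @param table Measurement table (see [tabulate_measurements()]):
#'   columns `frame_id`, `phase`, `site`, `rater_id`, `repeat_index`,
#'   `value_cm`. Every frame x site needs >= 2 expert labels; the
#'   candidate at most one value per frame x site.
#' @param candidate_id Rater id of the candidate measurer (default
#'   `"AI"`); any rater can be audited against the remaining panel.
#' @param levene_center Centering for the dispersion test.
#' @return List with `summary` (one row per phase x site:
#'   expert/candidate deviation mean, SD, median, `levene_W`,
#'   `levene_p`, `bias_cm`, `bias_p`, `n_frames`, `n_expert_labels`,
#'   `n_candidate`, test metadata), `records` (per-frame consensus and
#'   deviations) and `excluded` (frame x site combinations without a
#'   candidate value).
#' @export
build_summary <- function(table, candidate_id = "AI",
                          levene_center = c("median", "mean")) {
  levene_center <- match.arg(levene_center)
  stopifnot(all(c("frame_id", "phase", "site", "rater_id", "repeat_index",
                  "value_cm") %in% names(table)))
  dup <- table |>
    dplyr::count(.data$frame_id, .data$site, .data$rater_id,
                 .data$repeat_index) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate (frame, site, rater, repeat) rows in measurement table")
  }
  experts <- table[table$rater_id != candidate_id, ]
  cand <- table[table$rater_id == candidate_id, ]
  if (any(duplicated(cand[c("frame_id", "site")]))) {
    stop("candidate has more than one value per frame x site")
  }
  counts <- experts |>
    dplyr::count(.data$frame_id, .data$site)
  if (nrow(experts) == 0 || any(counts$n < 2)) {
    stop("every frame x site needs at least 2 expert labels")
  }

  per_frame <- experts |>
    dplyr::group_by(.data$phase, .data$site, .data$frame_id) |>
    dplyr::summarise(consensus_cm = consensus(.data$value_cm),
                     n_labels = dplyr::n(), .groups = "drop")
  records <- experts |>
    dplyr::inner_join(per_frame, by = c("phase", "site", "frame_id")) |>
    dplyr::mutate(deviation_cm = .data$value_cm - .data$consensus_cm,
                  role = "expert")
  cand_records <- cand |>
    dplyr::inner_join(per_frame, by = c("phase", "site", "frame_id")) |>
    dplyr::mutate(deviation_cm = .data$value_cm - .data$consensus_cm,
                  role = "candidate")
  excluded <- dplyr::anti_join(per_frame, cand,
                               by = c("frame_id", "site")) |>
    dplyr::select("phase", "site", "frame_id")

  cells <- unique(per_frame[c("phase", "site")])
  cells <- cells[order(match(cells$phase, c("ED", "ES", "UNKNOWN")),
                       match(cells$site, SITE_NAMES)), ]
  summary_rows <- lapply(seq_len(nrow(cells)), function(i) {
    ph <- cells$phase[i]; st <- cells$site[i]
    ed <- records$deviation_cm[records$phase == ph & records$site == st]
    cd <- cand_records$deviation_cm[cand_records$phase == ph &
                                      cand_records$site == st]
    cc <- cand_records$consensus_cm[cand_records$phase == ph &
                                      cand_records$site == st]
    cv <- cand_records$value_cm[cand_records$phase == ph &
                                  cand_records$site == st]
    lev <- if (length(cd) >= 2) {
      tryCatch(levene_dispersion_test(ed, cd, levene_center),
               error = function(e) list(W = NA_real_, p = NA_real_))
    } else {
      list(W = NA_real_, p = NA_real_)
    }
    bia <- if (length(cd) >= 2) {
      bias_test(cv, cc)
    } else {
      list(mean_bias = NA_real_, p = NA_real_, degenerate = FALSE)
    }
    tibble::tibble(
      phase = ph, site = st,
      expert_dev_mean = mean(ed),
      expert_dev_sd = rms_dispersion(ed),
      expert_dev_median = stats::median(ed),
      cand_dev_mean = if (length(cd)) mean(cd) else NA_real_,
      cand_dev_sd = if (length(cd)) rms_dispersion(cd) else NA_real_,
      cand_dev_median = if (length(cd)) stats::median(cd) else NA_real_,
      levene_W = lev$W, levene_p = lev$p,
      bias_cm = bia$mean_bias, bias_p = bia$p,
      bias_degenerate = isTRUE(bia$degenerate),
      n_frames = sum(per_frame$phase == ph & per_frame$site == st),
      n_expert_labels = length(ed),
      n_candidate = length(cd),
      levene_center = levene_center,
      candidate_id = candidate_id)
  })
  list(summary = dplyr::bind_rows(summary_rows),
       records = dplyr::bind_rows(records, cand_records),
       excluded = excluded)
}
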