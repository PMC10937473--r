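# Fixture builders shared across test files. Everything is generated
# in code; no binary fixtures.

square_frame <- function(frame_id = "F1", study_id = "S1", size = 320,
                         spacing = 0.02, phase = "UNKNOWN") {
  frame_record(study_id, frame_id, NA_character_, size, size,
               spacing, spacing, phase)
}

four_points <- function(x = c(100, 110, 190, 200), y = rep(100, 4)) {
  stats::setNames(lapply(1:4, function(i) c(x[i], y[i])), KEYPOINT_NAMES)
}

tiny_dataset <- function(n_studies = 5, frames_per_study = 2, size = 64) {
  frames <- list(); anns <- list()
  k <- 0
  for (s in seq_len(n_studies)) {
    for (f in seq_len(frames_per_study)) {
      k <- k + 1
      fid <- sprintf("F%03d", k)
      frames[[k]] <- square_frame(fid, sprintf("S%02d", s), size, 0.05)
      anns[[k]] <- annotation_record(fid, "R1", 1L,
                                     four_points(x = c(10, 15, 40, 45) + f,
                                                 y = rep(20 + (s %% 40), 4)))
    }
  }
  echo_dataset(dplyr::bind_rows(frames), dplyr::bind_rows(anns))
}

# small trained model cached across tests within one run
cached_tiny_model <- local({
  env <- new.env()
  function() {
    if (is.null(env$model)) {
      train_ds <- generate_cohort(60, phantom_ranges(64), seed = 11)
      sp <- split_dataset(train_ds, 0.8, seed = 1)
      net <- net_config(depth = 2, base_channels = 8,
                        working_size = c(64, 64))
      cfg <- train_config(epochs = 8, batch_size = 2, seed = 1,
                          optimizer = "adam",
                          augment = augment_config(enabled = FALSE))
      env$model <- train_keypoint_net(sp$train, sp$test, net, cfg)
      env$val <- generate_cohort(12, phantom_ranges(64), seed = 12)
    }
    list(model = env$model, val = env$val)
  }
})
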