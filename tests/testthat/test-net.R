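make_stack <- function(channels, mask) {
  structure(list(channels = channels, mask = mask, sigma_px = 6,
                 scale_to_native = c(1, 1)), class = "heatmap_stack")
}

test_that("masked MSE averages only over unmasked channels", {
  h <- 16
  tgt <- make_stack(array(0, dim = c(h, h, 5)), mask = c(1, 0, 0, 0, 0))
  pred <- array(0, dim = c(h, h, 5))
  expect_equal(masked_mse(pred, tgt), 0)

  pred[, , 1] <- 0.1
  expect_equal(masked_mse(pred, tgt), 0.01)

  # a large difference on a masked channel contributes exactly nothing
  pred[, , 2] <- 5
  expect_equal(masked_mse(pred, tgt), 0.01)

  all_masked <- make_stack(array(1, dim = c(h, h, 5)), mask = rep(0, 5))
  expect_equal(masked_mse(pred, all_masked), 0)

  expect_error(masked_mse(array(0, c(8, 8, 5)), tgt), "shape mismatch")
})

test_that("pseudo-line loss weight scales only channel 5", {
  h <- 8
  tgt <- make_stack(array(0, dim = c(h, h, 5)), mask = c(1, 1, 1, 1, 1))
  pred <- array(0, dim = c(h, h, 5))
  pred[, , 5] <- 0.2
  expect_equal(masked_mse(pred, tgt, pseudo_line_loss_weight = 1), 0.04 / 5)
  expect_equal(masked_mse(pred, tgt, pseudo_line_loss_weight = 3), 0.12 / 5)
  expect_equal(masked_mse(pred, tgt, pseudo_line_loss_weight = 0), 0)
})

test_that("analytic gradients match finite differences on a tiny net", {
  net <- net_config(depth = 1, base_channels = 2, working_size = c(8, 8))
  model <- init_keypoint_net(net, seed = 3)
  model$params$head$W <- matrix(rnorm(2 * 5, 0, 0.5), 2, 5)
  x <- withr::with_seed(5, array(runif(8 * 8 * 3), c(8, 8, 3)))
  tgt <- make_stack(withr::with_seed(6, array(runif(8 * 8 * 5), c(8, 8, 5))),
                    mask = c(1, 1, 0, 1, 1))
  fw <- echolv:::unet_forward(model$params, net, x)
  grads <- echolv:::unet_backward(model$params, net, fw$cache,
                                  echolv:::masked_mse_grad(fw$out, tgt))
  loss_at <- function(params) {
    masked_mse(echolv:::unet_forward(params, net, x, keep_cache = FALSE)$out,
               tgt)
  }
  eps <- 1e-6
  for (key in c("enc1_c1", "enc1_c2", "bot_c1", "dec1_c2", "head")) {
    idx <- withr::with_seed(7, sample(length(model$params[[key]]$W), 3))
    for (ii in c(idx, 1)) {
      plus <- model$params; plus[[key]]$W[ii] <- plus[[key]]$W[ii] + eps
      minus <- model$params; minus[[key]]$W[ii] <- minus[[key]]$W[ii] - eps
      num <- (loss_at(plus) - loss_at(minus)) / (2 * eps)
      expect_equal(grads[[key]]$W[ii], num, tolerance = 1e-4)
    }
    bplus <- model$params; bplus[[key]]$b[1] <- bplus[[key]]$b[1] + eps
    bminus <- model$params; bminus[[key]]$b[1] <- bminus[[key]]$b[1] - eps
    num <- (loss_at(bplus) - loss_at(bminus)) / (2 * eps)
    expect_equal(grads[[key]]$b[1], num, tolerance = 1e-4)
  }
})

test_that("plateau schedule reduces the LR exactly when patience is exhausted", {
  st <- echolv:::plateau_init(0.001, 5, 20)
  losses <- rep(1, 21)  # constant test loss for 21 epochs
  reductions <- 0
  for (l in losses) {
    st <- echolv:::plateau_step(st, l)
    reductions <- reductions + st$reduced
  }
  expect_equal(reductions, 1)
  expect_equal(st$lr, 0.001 / 5)

  # hand-simulated trace: improve, stall 19, improve, stall 20, stall 20
  st <- echolv:::plateau_init(0.001, 5, 20)
  trace <- c(1, 0.9, rep(0.9, 19), 0.8, rep(0.8, 20), rep(0.8, 20))
  lrs <- numeric(0)
  for (l in trace) {
    st <- echolv:::plateau_step(st, l)
    lrs <- c(lrs, st$lr)
  }
  expect_equal(sum(diff(lrs) != 0), 2)
  expect_equal(st$lr, 0.001 / 25)
})

test_that("identity augmentation ranges leave image and targets unchanged", {
  ds <- generate_cohort(1, phantom_ranges(64), seed = 2)
  fr <- ds$frames[1, ]
  img <- echolv:::prep_net_input(ds$images[[fr$frame_id]], c(64, 64))
  st <- encode_keypoints(ds$annotations[1, ], fr, c(64, 64), 3)
  cfg <- train_config(augment = augment_config(rotate_deg = 0,
                                               translate_frac = 0,
                                               scale = c(1, 1),
                                               gamma = c(1, 1)))
  out <- augment_pair(img, st, cfg, seed = 9)
  expect_identical(out$image, img)
  expect_identical(out$stack$channels, st$channels)
})

test_that("a pure translation moves decoded keypoints by the same amount", {
  fr <- square_frame("F1", size = 128, spacing = 0.05)
  ann <- annotation_record("F1", "r", 1,
                           four_points(x = c(40, 44, 80, 85),
                                       y = c(30, 42, 78, 90)))
  st <- encode_keypoints(ann, fr, c(128, 128), 6)
  m <- echolv:::affine_about_center(c(128, 128), 0, 1, c(5, 0))
  st$channels <- warp_affine(st$channels, m)
  for (i in 1:4) {
    dec <- decode_heatmap(st$channels[, , i])
    orig <- annotation_points(ann)[[KEYPOINT_NAMES[i]]]
    expect_lt(abs(dec["x"] - (orig[1] + 5)), 0.5)
    expect_lt(abs(dec["y"] - orig[2]), 0.5)
  }
})

test_that("gamma augmentation applies the power law to the image only", {
  img <- matrix(0.5, 32, 32)
  st <- make_stack(array(0.5, dim = c(32, 32, 5)), mask = rep(1, 5))
  cfg <- train_config(augment = augment_config(rotate_deg = 0,
                                               translate_frac = 0,
                                               scale = c(1, 1),
                                               gamma = c(2, 2)))
  out <- augment_pair(img, st, cfg, seed = 1)
  expect_equal(unique(as.vector(out$image)), 0.25)
  expect_identical(out$stack$channels, st$channels)
})

test_that("TAdam reduces to an EMA-consistent update and both optimizers step", {
  for (kind in c("adam", "tadam")) {
    p <- list(layer = list(W = matrix(1, 2, 2), b = c(0.5), k = 3L))
    opt <- echolv:::opt_init(p, kind)
    g <- list(layer = list(W = matrix(0.1, 2, 2), b = c(0.1)))
    st <- echolv:::opt_step(opt, p, g, lr = 0.01)
    expect_true(all(st$params$layer$W < 1))     # moved against the gradient
    expect_true(is.finite(st$params$layer$b))
  }
  # with a constant gradient the TAdam first moment approaches the
  # gradient value, as Adam's EMA does
  m <- 0; v <- 0; wt <- 0.9 / 0.1
  for (t in 1:200) {
    up <- echolv:::opt_update_tensor("tadam", 0, 0.3, m, v, wt, t, 0,
                                     0.9, 0.999, 1e-8)
    m <- up$m; v <- up$v; wt <- up$Wt
  }
  expect_equal(m, 0.3, tolerance = 1e-3)
})

test_that("short training beats the all-zero baseline and is seed-reproducible", {
  train_ds <- generate_cohort(16, phantom_ranges(64), seed = 21)
  sp <- split_dataset(train_ds, 0.75, seed = 1)
  net <- net_config(depth = 2, base_channels = 4, working_size = c(64, 64))
  cfg <- train_config(epochs = 3, batch_size = 2, seed = 5,
                      optimizer = "adam",
                      augment = augment_config(enabled = FALSE))
  model <- train_keypoint_net(sp$train, sp$test, net, cfg)
  # all-zero-prediction baseline on the same test targets
  samples <- echolv:::prepare_samples(sp$test, net, model$sigma_px)
  zero <- array(0, dim = c(64, 64, 5))
  baseline <- mean(vapply(samples, function(s) masked_mse(zero, s$stack),
                          numeric(1)))
  expect_lt(tail(model$history$test_loss, 1), baseline)
  expect_equal(nrow(model$history), 3)

  model2 <- train_keypoint_net(sp$train, sp$test, net, cfg)
  expect_identical(model$history, model2$history)
})

test_that("an untrained network reports every keypoint as missing", {
  net <- net_config(depth = 2, base_channels = 4, working_size = c(64, 64))
  model <- init_keypoint_net(net, seed = 1)
  model$cfg <- list(confidence_floor = 0.1)
  fr <- square_frame("F1", size = 64, spacing = 0.05)
  pred <- predict_keypoints(model, matrix(0, 64, 64), fr)
  expect_true(all(is.na(pred$x)))
  expect_equal(nrow(pred), 4)
})

test_that("a lightly trained model localizes phantom keypoints within bounds", {
  tm <- cached_tiny_model()
  ev <- evaluate_keypoint_model(tm$model, tm$val)
  expect_true(all(is.finite(ev$keypoints$err_px)))
  expect_lt(mean(ev$keypoints$err_px), 5)
  # predictions stay inside the native frame
  preds <- predict_dataset(tm$model, tm$val)
  expect_true(all(preds$sept_ant_x >= 0 & preds$sept_ant_x < 64, na.rm = TRUE))
})

test_that("translating the input moves a trained model's keypoints with it", {
  tm <- cached_tiny_model()
  fr <- tm$val$frames[1, ]
  img <- tm$val$images[[fr$frame_id]]
  base <- predict_keypoints(tm$model, img, fr)
  shifted <- matrix(0, 64, 64)
  shifted[, 9:64] <- img[, 1:56]  # shift 8 px rightward
  moved <- predict_keypoints(tm$model, shifted, fr)
  ok <- !is.na(base$x) & !is.na(moved$x) & base$x + 8 < 60
  expect_gt(sum(ok), 0)
  expect_lt(max(abs(moved$x[ok] - (base$x[ok] + 8))), 2)
  expect_lt(max(abs(moved$y[ok] - base$y[ok])), 2)
})
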