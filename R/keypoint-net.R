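#' Configure the U-Net backbone
#'
#' An encoder-decoder with `depth` resolution levels, two 3x3
#' convolution + ReLU blocks per level, 2x2 max-pooling on the way
#' down, nearest-neighbour upsampling with skip concatenation on the
#' way up, and a linear 1x1 head emitting one heatmap channel per
#' keypoint plus the pseudo-line channel.
#'
#' @param depth Number of down/upsampling levels (>= 1).
#' @param base_channels Channel count at the top level; doubles per
#'   level.
#' @param in_channels Input channels (3; grayscale inputs are
#'   replicated).
#' @param out_channels Output channels (5: 4 keypoints + pseudo-line).
#' @param working_size Working grid `c(H, W)`; must be divisible by
#'   `2^depth`.
#' @return A `net_config` list.
#' @export
net_config <- function(depth = 2L, base_channels = 8L, in_channels = 3L,
                       out_channels = 5L, working_size = c(320L, 320L)) {
  stopifnot(depth >= 1, base_channels >= 1,
            all(working_size %% 2^depth == 0))
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 working_size = as.integer(working_size)),
            class = "net_config")
}

#' Configure augmentation ranges
#'
#' One affine transform (rotation, isotropic scale, translation about
#' the image centre) is sampled per training example per epoch and
#' applied identically to the image and every heatmap channel; a gamma
#' change is applied to the image only. Degenerate ranges give the
#' identity.
#'
#' @param rotate_deg Max |rotation| in degrees.
#' @param translate_frac Max |translation| as a fraction of the image
#'   side, per axis.
#' @param scale `c(lo, hi)` isotropic scale range.
#' @param gamma `c(lo, hi)` image gamma range.
#' @param enabled Master switch.
#' @return An `augment_config` list.
#' @export
augment_config <- function(rotate_deg = 10, translate_frac = 0.05,
                           scale = c(0.9, 1.1), gamma = c(0.7, 1.4),
                           enabled = TRUE) {
  structure(list(rotate_deg = rotate_deg, translate_frac = translate_frac,
                 scale = scale, gamma = gamma, enabled = enabled),
            class = "augment_config")
}

#' Configure training
#'
#' Defaults follow the reference protocol: 200 epochs, initial
#' learning rate 0.001, LR divided by 5 whenever the test loss fails
#' to improve for 20 consecutive epochs, TAdam optimizer, MSE loss
#' with per-channel 0/1 masking of unlabeled keypoints, heatmap SD of
#' 15 px at a 320x320 working grid (scaled proportionally for other
#' working sizes).
#'
#' @param epochs,lr_init,plateau_factor,plateau_patience,batch_size
#'   Training loop parameters; `plateau_factor` is a divisor (> 1).
#' @param seed Integer seed controlling initialization, shuffling and
#'   augmentation.
#' @param optimizer `"tadam"` or `"adam"`.
#' @param augment An [augment_config()].
#' @param pseudo_line_loss_weight Weight of the pseudo-line channel in
#'   the loss (>= 0).
#' @param sigma_px Heatmap Gaussian SD in working pixels; `NULL` means
#'   `15 * min(working_size) / 320`.
#' @param confidence_floor Decoder acceptance threshold at inference.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, lr_init = 1e-3,
                         plateau_factor = 5, plateau_patience = 20L,
                         batch_size = 8L, seed = 1L,
                         optimizer = c("tadam", "adam"),
                         augment = augment_config(),
                         pseudo_line_loss_weight = 1,
                         sigma_px = NULL, confidence_floor = 0.1) {
  stopifnot(lr_init > 0, plateau_factor > 1, epochs >= 1, batch_size >= 1,
            pseudo_line_loss_weight >= 0)
  structure(list(epochs = as.integer(epochs), lr_init = lr_init,
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 optimizer = match.arg(optimizer),
                 augment = augment,
                 pseudo_line_loss_weight = pseudo_line_loss_weight,
                 sigma_px = sigma_px,
                 confidence_floor = confidence_floor),
            class = "train_config")
}

resolve_sigma <- function(cfg, net) {
  if (!is.null(cfg$sigma_px)) cfg$sigma_px else 15 * min(net$working_size) / 320
}

# conv layer keys in forward execution order
unet_layer_keys <- function(depth) {
  keys <- character(0)
  for (i in seq_len(depth)) keys <- c(keys, sprintf("enc%d_c1", i), sprintf("enc%d_c2", i))
  keys <- c(keys, "bot_c1", "bot_c2")
  for (i in rev(seq_len(depth))) keys <- c(keys, sprintf("dec%d_c1", i), sprintf("dec%d_c2", i))
  c(keys, "head")
}

unet_layer_shapes <- function(net) {
  b <- net$base_channels; d <- net$depth
  shapes <- list()
  cin <- net$in_channels
  for (i in seq_len(d)) {
    co <- b * 2^(i - 1)
    shapes[[sprintf("enc%d_c1", i)]] <- list(cin = cin, cout = co, k = 3L)
    shapes[[sprintf("enc%d_c2", i)]] <- list(cin = co, cout = co, k = 3L)
    cin <- co
  }
  shapes[["bot_c1"]] <- list(cin = b * 2^(d - 1), cout = b * 2^d, k = 3L)
  shapes[["bot_c2"]] <- list(cin = b * 2^d, cout = b * 2^d, k = 3L)
  for (i in rev(seq_len(d))) {
    shapes[[sprintf("dec%d_c1", i)]] <- list(cin = b * 2^i, cout = b * 2^(i - 1), k = 3L)
    shapes[[sprintf("dec%d_c2", i)]] <- list(cin = b * 2^i, cout = b * 2^(i - 1), k = 3L)
  }
  shapes[["head"]] <- list(cin = b, cout = net$out_channels, k = 1L)
  shapes
}

#' Initialize a keypoint network
#'
#' He-normal initialization for all hidden convolutions; the 1x1 head
#' starts at zero so an untrained network emits flat zero heatmaps
#' (every decode falls below the confidence floor).
#'
#' @param net A [net_config()].
#' @param seed Integer seed.
#' @return A `keypoint_model` list with `params` and `net`.
#' @export
init_keypoint_net <- function(net = net_config(), seed = 1L) {
  shapes <- unet_layer_shapes(net)
  params <- local_seed(seed, {
    lapply(shapes, function(s) {
      fan_in <- s$k^2 * s$cin
      w <- if (identical(s$k, 1L) && s$cout == net$out_channels) {
        matrix(0, fan_in, s$cout)
      } else {
        matrix(rnorm(fan_in * s$cout, 0, sqrt(2 / fan_in)), fan_in, s$cout)
      }
      list(W = w, b = numeric(s$cout), k = s$k)
    })
  })
  structure(list(params = params, net = net), class = "keypoint_model")
}

relu <- function(x) { x[x < 0] <- 0; x }

# forward pass; returns list(out, cache) -- cache holds conv inputs,
# ReLU masks, pooling indices and concat split points for backward
unet_forward <- function(params, net, x, keep_cache = TRUE) {
  d <- net$depth
  cache <- list(conv_x = list(), relu_post = list(), pool = list(),
                split = list())
  conv_relu <- function(key, cur) {
    if (keep_cache) cache$conv_x[[key]] <<- cur
    y <- relu(.conv2d_fw(cur, params[[key]]$W, params[[key]]$b, params[[key]]$k))
    if (keep_cache) cache$relu_post[[key]] <<- y > 0
    y
  }
  cur <- x
  skips <- vector("list", d)
  for (i in seq_len(d)) {
    cur <- conv_relu(sprintf("enc%d_c1", i), cur)
    cur <- conv_relu(sprintf("enc%d_c2", i), cur)
    skips[[i]] <- cur
    pl <- .maxpool2_fw(cur)
    if (keep_cache) cache$pool[[i]] <- list(idx = pl$idx, h = dim(cur)[1], w = dim(cur)[2])
    cur <- pl$y
  }
  cur <- conv_relu("bot_c1", cur)
  cur <- conv_relu("bot_c2", cur)
  for (i in rev(seq_len(d))) {
    cur <- .upsample2_fw(cur)
    cur <- conv_relu(sprintf("dec%d_c1", i), cur)
    n1 <- dim(cur)[3]
    cache$split[[i]] <- n1
    cur <- array(c(cur, skips[[i]]),
                 dim = c(dim(cur)[1], dim(cur)[2], n1 + dim(skips[[i]])[3]))
    cur <- conv_relu(sprintf("dec%d_c2", i), cur)
  }
  if (keep_cache) cache$conv_x[["head"]] <- cur
  out <- .conv2d_fw(cur, params[["head"]]$W, params[["head"]]$b,
                    params[["head"]]$k)
  list(out = out, cache = cache)
}

# backward pass: dout is dLoss/dout; returns per-layer gradients
unet_backward <- function(params, net, cache, dout) {
  d <- net$depth
  grads <- list()
  conv_relu_bw <- function(key, dy) {
    dy <- dy * cache$relu_post[[key]]
    bw <- .conv2d_bw(cache$conv_x[[key]], params[[key]]$W, dy, params[[key]]$k)
    grads[[key]] <<- list(W = bw$dW, b = as.numeric(bw$db))
    bw$dx
  }
  bw <- .conv2d_bw(cache$conv_x[["head"]], params[["head"]]$W, dout,
                   params[["head"]]$k)
  grads[["head"]] <- list(W = bw$dW, b = as.numeric(bw$db))
  dcur <- bw$dx
  dskip <- vector("list", d)
  for (i in seq_len(d)) {  # reverse of decoder execution order
    dcur <- conv_relu_bw(sprintf("dec%d_c2", i), dcur)
    n1 <- cache$split[[i]]
    n <- dim(dcur)[3]
    dskip[[i]] <- dcur[, , (n1 + 1):n, drop = FALSE]
    dcur <- dcur[, , 1:n1, drop = FALSE]
    dcur <- conv_relu_bw(sprintf("dec%d_c1", i), dcur)
    dcur <- .upsample2_bw(dcur)
  }
  dcur <- conv_relu_bw("bot_c2", dcur)
  dcur <- conv_relu_bw("bot_c1", dcur)
  for (i in rev(seq_len(d))) {
    p <- cache$pool[[i]]
    dcur <- .maxpool2_bw(p$idx, dcur, p$h, p$w) + dskip[[i]]
    dcur <- conv_relu_bw(sprintf("enc%d_c2", i), dcur)
    dcur <- conv_relu_bw(sprintf("enc%d_c1", i), dcur)
  }
  grads
}

stack_channels <- function(x) if (inherits(x, "heatmap_stack")) x$channels else x
stack_mask <- function(x, n) if (inherits(x, "heatmap_stack")) x$mask else rep(1, n)

# per-channel loss weights: 0/1 target mask times the pseudo-line weight
mse_channel_weights <- function(target, n_channels, pseudo_line_loss_weight) {
  mask <- stack_mask(target, n_channels)
  w <- mask
  if (n_channels >= 5) w[5] <- w[5] * pseudo_line_loss_weight
  list(mask = mask, w = w)
}

#' Masked mean-squared-error heatmap loss
#'
#' Mean over unmasked channel-pixels of the squared difference; the
#' pseudo-line channel's term is multiplied by
#' `pseudo_line_loss_weight`. Channels whose target mask is 0 (missing
#' keypoints, degenerate pseudo-line) contribute exactly nothing;
#' if every channel is masked the loss is 0.
#'
#' @param pred Predicted `[H, W, C]` array or `heatmap_stack`.
#' @param target Target `heatmap_stack` (or array, treated as fully
#'   unmasked).
#' @param pseudo_line_loss_weight Weight for channel 5 (default 1).
#' @return Scalar loss.
#' @export
masked_mse <- function(pred, target, pseudo_line_loss_weight = 1) {
  p <- stack_channels(pred); t <- stack_channels(target)
  if (!identical(dim(p), dim(t))) stop("prediction/target shape mismatch")
  nc <- dim(p)[3]
  cw <- mse_channel_weights(target, nc, pseudo_line_loss_weight)
  if (sum(cw$mask) == 0) return(0)
  total <- 0
  for (c in seq_len(nc)) {
    if (cw$mask[c] > 0) total <- total + cw$w[c] * mean((p[, , c] - t[, , c])^2)
  }
  total / sum(cw$mask)
}

# gradient of masked_mse with respect to pred
masked_mse_grad <- function(pred, target, pseudo_line_loss_weight = 1) {
  p <- stack_channels(pred); t <- stack_channels(target)
  nc <- dim(p)[3]
  cw <- mse_channel_weights(target, nc, pseudo_line_loss_weight)
  g <- array(0, dim = dim(p))
  n_unmasked <- sum(cw$mask)
  if (n_unmasked == 0) return(g)
  npx <- prod(dim(p)[1:2])
  for (c in seq_len(nc)) {
    if (cw$mask[c] > 0) {
      g[, , c] <- 2 * cw$w[c] * (p[, , c] - t[, , c]) / (npx * n_unmasked)
    }
  }
  g
}

#' Jointly augment an image and its heatmap stack
#'
#' Samples one affine transform from the ranges in `cfg$augment` and
#' applies it identically to the image and all heatmap channels
#' (masks are untouched); a gamma change is applied to the image only.
#' Deterministic for a given seed; degenerate ranges return the input
#' unchanged.
#'
#' @param image `[H, W]` or `[H, W, C]` array at working resolution.
#' @param stack A `heatmap_stack` at the same resolution.
#' @param cfg A [train_config()] (its `augment` field is used).
#' @param seed Integer seed.
#' @return List `(image, stack)`.
#' @export
augment_pair <- function(image, stack, cfg, seed = 1L) {
  a <- if (inherits(cfg, "augment_config")) cfg else cfg$augment
  draws <- local_seed(seed, list(
    rot = runif(1, -a$rotate_deg, a$rotate_deg) * pi / 180,
    tx = runif(1, -a$translate_frac, a$translate_frac) * dim(image)[2],
    ty = runif(1, -a$translate_frac, a$translate_frac) * dim(image)[1],
    sc = runif(1, a$scale[1], a$scale[2]),
    gm = runif(1, a$gamma[1], a$gamma[2])))
  m <- affine_about_center(dim(image)[1:2], draws$rot, draws$sc,
                           c(draws$tx, draws$ty))
  identity_map <- draws$rot == 0 && draws$sc == 1 &&
    draws$tx == 0 && draws$ty == 0
  img <- if (identity_map) image else warp_affine(image, m)
  if (draws$gm != 1) img <- pmin(pmax(img, 0), 1)^draws$gm
  if (!identity_map) stack$channels <- warp_affine(stack$channels, m)
  list(image = img, stack = stack)
}

# learning-rate plateau state machine: divide lr by `factor` whenever
# the monitored loss has not improved for `patience` consecutive epochs
plateau_init <- function(lr_init, factor, patience) {
  list(lr = lr_init, factor = factor, patience = patience,
       best = Inf, wait = 0L, reduced = FALSE)
}

plateau_step <- function(state, loss) {
  state$reduced <- FALSE
  if (loss < state$best) {
    state$best <- loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- state$lr / state$factor
      state$wait <- 0L
      state$reduced <- TRUE
    }
  }
  state
}

opt_init <- function(params, optimizer) {
  state <- lapply(params, function(p) {
    list(mW = array(0, dim(p$W)), vW = array(0, dim(p$W)),
         mb = numeric(length(p$b)), vb = numeric(length(p$b)),
         WtW = 0.9 / 0.1, Wtb = 0.9 / 0.1)
  })
  list(kind = optimizer, t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
       state = state)
}

# one Adam/TAdam update on a single tensor; returns list(theta, m, v, Wt)
opt_update_tensor <- function(kind, theta, g, m, v, Wt, t, lr,
                              beta1, beta2, eps) {
  if (kind == "tadam") {
    # robust Student-t estimate of the first moment: small weights for
    # gradients far (in v-metric) from the running mean
    dim_n <- length(g)
    nu <- dim_n
    wt <- (nu + dim_n) / (nu + sum((g - m)^2 / (v + eps)))
    m <- m + (wt / (Wt + wt)) * (g - m)
    Wt <- ((2 * beta1 - 1) / beta1) * Wt + wt
  } else {
    m <- beta1 * m + (1 - beta1) * g
  }
  v <- beta2 * v + (1 - beta2) * g^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  theta <- theta - lr * mhat / (sqrt(vhat) + eps)
  list(theta = theta, m = m, v = v, Wt = Wt)
}

opt_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  for (key in names(params)) {
    s <- opt$state[[key]]
    up <- opt_update_tensor(opt$kind, params[[key]]$W, grads[[key]]$W,
                            s$mW, s$vW, s$WtW, opt$t, lr,
                            opt$beta1, opt$beta2, opt$eps)
    params[[key]]$W <- up$theta; s$mW <- up$m; s$vW <- up$v; s$WtW <- up$Wt
    up <- opt_update_tensor(opt$kind, params[[key]]$b, grads[[key]]$b,
                            s$mb, s$vb, s$Wtb, opt$t, lr,
                            opt$beta1, opt$beta2, opt$eps)
    params[[key]]$b <- up$theta; s$mb <- up$m; s$vb <- up$v; s$Wtb <- up$Wt
    opt$state[[key]] <- s
  }
  list(opt = opt, params = params)
}

# image -> [H, W, 3] working-resolution array
prep_net_input <- function(img, working_size) {
  if (length(dim(img)) == 2 || is.null(dim(img))) {
    img <- array(rep(as.matrix(img), 3), dim = c(dim(img)[1], dim(img)[2], 3))
  }
  if (!identical(dim(img)[1:2], as.integer(working_size))) {
    img <- resize_bilinear(img, working_size)
  }
  img
}

# pick one training annotation per frame: TRUTH preferred, else the
# first rater encountered
training_annotations <- function(dataset) {
  ann <- dataset$annotations
  ann <- ann[order(ann$frame_id, ann$rater_id != "TRUTH", ann$rater_id,
                   ann$repeat_index), ]
  ann[!duplicated(ann$frame_id), ]
}

prepare_samples <- function(dataset, net, sigma_px) {
  ann <- training_annotations(dataset)
  lapply(seq_len(nrow(ann)), function(i) {
    fid <- ann$frame_id[i]
    fr <- dataset$frames[dataset$frames$frame_id == fid, ]
    list(
      frame_id = fid,
      image = prep_net_input(dataset_image(dataset, fid), net$working_size),
      stack = encode_keypoints(ann[i, ], fr, net$working_size, sigma_px))
  })
}

dataset_loss <- function(params, net, samples, plw) {
  losses <- vapply(samples, function(s) {
    fw <- unet_forward(params, net, s$image, keep_cache = FALSE)
    masked_mse(fw$out, s$stack, plw)
  }, numeric(1))
  mean(losses)
}

#' Train a keypoint network
#'
#' Mini-batch gradient training with masked MSE on the heatmap stacks,
#' per-epoch test-set monitoring, plateau-driven learning-rate
#' reduction and best-test-loss checkpointing. Fully seeded: the same
#' configuration and datasets reproduce the same loss history.
#'
#' @param train_set,test_set Non-empty, disjoint [echo_dataset()]s.
#' @param net A [net_config()].
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `keypoint_model` with elements `params` (best-test-loss
#'   checkpoint), `final_params`, `net`, `cfg`, `sigma_px`, `optimizer`
#'   and `history` (tibble: epoch, train_loss, test_loss, lr).
#' @export
train_keypoint_net <- function(train_set, test_set, net = net_config(),
                               cfg = train_config(), verbose = FALSE) {
  if (nrow(train_set$frames) == 0 || nrow(test_set$frames) == 0) {
    stop("train and test sets must be non-empty")
  }
  if (length(intersect(train_set$frames$frame_id,
                       test_set$frames$frame_id)) > 0) {
    stop("train and test sets overlap")
  }
  sigma_px <- resolve_sigma(cfg, net)
  plw <- cfg$pseudo_line_loss_weight
  train_samples <- prepare_samples(train_set, net, sigma_px)
  test_samples <- prepare_samples(test_set, net, sigma_px)
  model <- init_keypoint_net(net, seed = cfg$seed)
  params <- model$params
  opt <- opt_init(params, cfg$optimizer)
  sched <- plateau_init(cfg$lr_init, cfg$plateau_factor, cfg$plateau_patience)
  best_params <- params
  best_test <- Inf
  history <- vector("list", cfg$epochs)
  n <- length(train_samples)
  for (epoch in seq_len(cfg$epochs)) {
    order <- local_seed(derive_seed(cfg$seed, "shuffle", epoch), sample(n))
    batch_starts <- seq(1, n, by = cfg$batch_size)
    epoch_loss <- 0
    for (bs in batch_starts) {
      ids <- order[bs:min(bs + cfg$batch_size - 1, n)]
      acc <- NULL
      for (i in ids) {
        s <- train_samples[[i]]
        img <- s$image; stk <- s$stack
        if (cfg$augment$enabled) {
          aug <- augment_pair(img, stk, cfg,
                              derive_seed(cfg$seed, "aug", epoch, i))
          img <- aug$image; stk <- aug$stack
        }
        fw <- unet_forward(params, net, img)
        loss <- masked_mse(fw$out, stk, plw)
        if (!is.finite(loss)) {
          stop("non-finite training loss at epoch ", epoch,
               ", frame ", s$frame_id)
        }
        epoch_loss <- epoch_loss + loss
        g <- unet_backward(params, net, fw$cache,
                           masked_mse_grad(fw$out, stk, plw))
        if (is.null(acc)) {
          acc <- g
        } else {
          for (key in names(acc)) {
            acc[[key]]$W <- acc[[key]]$W + g[[key]]$W
            acc[[key]]$b <- acc[[key]]$b + g[[key]]$b
          }
        }
      }
      for (key in names(acc)) {
        acc[[key]]$W <- acc[[key]]$W / length(ids)
        acc[[key]]$b <- acc[[key]]$b / length(ids)
      }
      st <- opt_step(opt, params, acc, sched$lr)
      opt <- st$opt; params <- st$params
    }
    train_loss <- epoch_loss / n
    test_loss <- dataset_loss(params, net, test_samples, plw)
    if (!is.finite(test_loss)) stop("non-finite test loss at epoch ", epoch)
    if (test_loss < best_test) {
      best_test <- test_loss
      best_params <- params
    }
    lr_used <- sched$lr
    sched <- plateau_step(sched, test_loss)
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_loss = train_loss,
                                       test_loss = test_loss, lr = lr_used)
    if (verbose) {
      message(sprintf("epoch %3d  train %.3e  test %.3e  lr %.2e",
                      epoch, train_loss, test_loss, lr_used))
    }
  }
  structure(list(params = best_params, final_params = params, net = net,
                 cfg = cfg, sigma_px = sigma_px,
                 optimizer = cfg$optimizer,
                 history = dplyr::bind_rows(history)),
            class = "keypoint_model")
}

#' Predict keypoints on one frame
#'
#' Resizes the image to the working grid (bilinear), runs the forward
#' pass, decodes each keypoint channel to sub-pixel working
#' coordinates and maps them back to native pixels. Keypoints whose
#' peak is below the confidence floor are reported as missing (`NA`
#' coordinates).
#'
#' @param model A trained `keypoint_model`.
#' @param image `[H, W]` or `[H, W, 3]` numeric array in `[0, 1]`.
#' @param frame One-row frame tibble (for the native size).
#' @param confidence_floor Override of the model's decoder threshold.
#' @return Tibble: `keypoint`, `x`, `y` (native 0-based px),
#'   `confidence`.
#' @export
predict_keypoints <- function(model, image, frame,
                              confidence_floor = NULL) {
  floor <- if (!is.null(confidence_floor)) confidence_floor else
    model$cfg$confidence_floor %||% 0.1
  ws <- model$net$working_size
  x <- prep_net_input(image, ws)
  out <- unet_forward(model$params, model$net, x, keep_cache = FALSE)$out
  scale <- c(frame$width_px / ws[2], frame$height_px / ws[1])
  rows <- lapply(seq_along(KEYPOINT_NAMES), function(i) {
    dec <- decode_heatmap(out[, , i], confidence_floor = floor)
    if (is.null(dec)) {
      tibble::tibble(keypoint = KEYPOINT_NAMES[i], x = NA_real_,
                     y = NA_real_, confidence = max(out[, , i]))
    } else {
      nat <- coords_working_to_native(dec[c("x", "y")], scale)
      nat <- pmin(pmax(nat, 0), c(frame$width_px, frame$height_px) - 1e-9)
      tibble::tibble(keypoint = KEYPOINT_NAMES[i], x = nat[1], y = nat[2],
                     confidence = unname(dec["confidence"]))
    }
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict keypoints for every frame of a dataset
#'
#' @param model A trained `keypoint_model`.
#' @param dataset An [echo_dataset()].
#' @param rater_id Rater identity recorded on the predictions
#'   (default `"AI"`).
#' @return Tibble of annotation rows (one per frame).
#' @export
predict_dataset <- function(model, dataset, rater_id = "AI") {
  rows <- lapply(seq_len(nrow(dataset$frames)), function(i) {
    fr <- dataset$frames[i, ]
    pred <- predict_keypoints(model, dataset_image(dataset, fr$frame_id), fr)
    pts <- stats::setNames(lapply(seq_len(4), function(j) {
      if (is.na(pred$x[j])) NULL else c(pred$x[j], pred$y[j])
    }), KEYPOINT_NAMES)
    annotation_record(fr$frame_id, rater_id, 1L, pts)
  })
  dplyr::bind_rows(rows)
}

#' Evaluate a model against ground-truth annotations
#'
#' Compares predictions with each frame's `"TRUTH"` annotation:
#' per-keypoint Euclidean error in native pixels, and per-site
#' absolute relative error of the derived measurements.
#'
#' @param model A trained `keypoint_model`.
#' @param dataset An [echo_dataset()] carrying `"TRUTH"` annotations.
#' @return List with tibbles `keypoints` (frame_id, keypoint, err_px,
#'   confidence) and `measurements` (frame_id, site, truth_cm,
#'   pred_cm, abs_rel_err).
#' @export
evaluate_keypoint_model <- function(model, dataset) {
  truth <- dataset$annotations[dataset$annotations$rater_id == "TRUTH", ]
  kp_rows <- list(); m_rows <- list()
  for (i in seq_len(nrow(truth))) {
    fid <- truth$frame_id[i]
    fr <- dataset$frames[dataset$frames$frame_id == fid, ]
    pred <- predict_keypoints(model, dataset_image(dataset, fid), fr)
    tp <- annotation_points(truth[i, ])
    err <- vapply(seq_len(4), function(j) {
      p <- tp[[KEYPOINT_NAMES[j]]]
      if (is.null(p) || is.na(pred$x[j])) return(NA_real_)
      sqrt((pred$x[j] - p[1])^2 + (pred$y[j] - p[2])^2)
    }, numeric(1))
    kp_rows[[i]] <- tibble::tibble(frame_id = fid,
                                   keypoint = KEYPOINT_NAMES,
                                   err_px = err,
                                   confidence = pred$confidence)
    spacing <- c(fr$spacing_x_cm, fr$spacing_y_cm)
    mt_true <- derive_measurements(tp, spacing)
    pred_pts <- stats::setNames(lapply(seq_len(4), function(j) {
      if (is.na(pred$x[j])) NULL else c(pred$x[j], pred$y[j])
    }), KEYPOINT_NAMES)
    mt_pred <- derive_measurements(pred_pts, spacing)
    tr <- c(mt_true$ivs_cm, mt_true$lvd_cm, mt_true$fw_cm)
    pr <- c(mt_pred$ivs_cm, mt_pred$lvd_cm, mt_pred$fw_cm)
    m_rows[[i]] <- tibble::tibble(frame_id = fid, site = SITE_NAMES,
                                  truth_cm = tr, pred_cm = pr,
                                  abs_rel_err = abs(pr - tr) / tr)
  }
  list(keypoints = dplyr::bind_rows(kp_rows),
       measurements = dplyr::bind_rows(m_rows))
}
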