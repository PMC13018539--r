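#' Delineation network configuration
#'
#' The delineator is an encoder–decoder with skip connections mapping a
#' single-channel square slice to 8 output planes: for each joint, the two
#' unit-vector-field components (linear outputs, renormalised at use time)
#' and the source/sink heatmaps (logistic-squashed to `[0, 1]`). The
#' `"landmarks"` mode instead builds the 21-heatmap-per-joint baseline
#' network (42 planes) against which field walking is benchmarked.
#'
#' @param input_size Square input size in pixels. The full profile is 224
#'   (annotated scans are bicubically resampled there); the desk profile of
#'   64 exercises the identical code path at workstation scale.
#' @param depth Number of 2x2 poolings; `input_size` must be divisible by
#'   `2^depth`.
#' @param width Channel count of the first encoder stage (doubles per stage).
#' @param mode `"uvf"` for the 8-plane field/heatmap regressor, `"landmarks"`
#'   for the 21-heatmap baseline.
#' @param n_landmarks Landmarks per joint in `"landmarks"` mode.
#' @param lr,beta1,beta2 Adam hyperparameters; `lr` is the peak rate.
#' @param lr_schedule `"constant"`, or `"cosine"` for linear warmup over the
#'   first tenth of training followed by cosine decay — with short training
#'   runs the schedule matters as much as the peak rate.
#' @param alpha Heatmap loss weight: per-pixel weight is
#'   `1 + alpha * target`, counteracting background dominance.
#' @param heat_weight Multiplier on the heatmap loss component, balancing
#'   endpoint localisation against field regression in the shared encoder.
#' @param sigma_frac Proportionality constant tying the endpoint-heatmap
#'   sigma to the inter-contour region (see [heatmap_sigma()]).
#' @param on_contour_radius Width of the tangential band used when building
#'   training targets (see [build_target_uvf()]); a wider band gives the
#'   regressor a thicker smooth tangential channel to learn.
#' @param centripetal Lane-keeping blend of the training-target band (see
#'   [build_target_uvf()]); keeps a walker riding the widened band drawn to
#'   the contour centreline.
#' @param coord_channels Append normalised x/y coordinate maps to the input
#'   (3 input channels). Locating endpoints and separating the left from the
#'   right joint needs absolute position; a compact network's receptive
#'   field cannot always supply it from padding cues alone.
#' @param seed Seed for parameter initialisation and training order.
#' @export
delineator_config <- function(input_size = 64L, depth = 3L, width = 8L,
                              mode = c("uvf", "landmarks"), n_landmarks = 21L,
                              lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                              lr_schedule = c("constant", "cosine"),
                              alpha = 10, heat_weight = 1,
                              sigma_frac = 0.05, on_contour_radius = 0.75,
                              centripetal = 0, coord_channels = TRUE,
                              seed = 1L) {
  mode <- match.arg(mode)
  lr_schedule <- match.arg(lr_schedule)
  if (input_size %% 2^depth != 0L) {
    abort("`input_size` must be divisible by 2^depth")
  }
  out_planes <- if (mode == "uvf") 8L else 2L * n_landmarks
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 width = as.integer(width), mode = mode,
                 n_landmarks = as.integer(n_landmarks),
                 out_planes = out_planes, lr = lr,
                 lr_schedule = lr_schedule, beta1 = beta1,
                 beta2 = beta2, alpha = alpha, heat_weight = heat_weight,
                 sigma_frac = sigma_frac,
                 on_contour_radius = on_contour_radius,
                 centripetal = centripetal,
                 coord_channels = isTRUE(coord_channels),
                 seed = as.integer(seed)),
            class = "sij_delineator_config")
}

#' Augmentation specification
#'
#' Geometric transforms are applied to the image and the landmarks through
#' one shared affine; training targets are then regenerated from the
#' transformed landmarks, never warped directly. A left/right flip mirrors x
#' and swaps the joint sides (and with them the left/right target channel
#' groups). Photometric transforms touch only the image.
#'
#' @param translate Translation range as a fraction of image size (+/-).
#' @param scale Scale range (+/-), e.g. 0.2 for scales in `[0.8, 1.2]`.
#' @param rotate Rotation range in degrees (+/-).
#' @param lr_flip Allow left/right flips (applied with probability 1/2).
#' @param noise_sigma Additive Gaussian noise sd (intensity units).
#' @param blur_sigma Gaussian blur sd in pixels (applied with prob. 1/2).
#' @export
augment_spec <- function(translate = 0.2, scale = 0.2, rotate = 15,
                         lr_flip = TRUE, noise_sigma = 0.02,
                         blur_sigma = 0.5) {
  structure(list(translate = translate, scale = scale, rotate = rotate,
                 lr_flip = lr_flip, noise_sigma = noise_sigma,
                 blur_sigma = blur_sigma),
            class = "sij_augment_spec")
}

#' A single annotated training slice
#'
#' @param image `H x W` intensity matrix.
#' @param left,right `sij_polyline` annotations (may be absent).
#' @param spacing In-plane pixel spacing in mm/px.
#' @export
slice_sample <- function(image, left = absent_polyline("left"),
                         right = absent_polyline("right"), spacing = 1) {
  structure(list(image = image, left = left, right = right,
                 spacing = spacing), class = "sij_slice")
}

#' Resample a slice to the square model input
#'
#' Non-square slices are zero-padded on the right/bottom to a square (so the
#' aspect ratio of the content is unchanged), then bicubically resampled to
#' `size x size`. The returned object records the transform so predictions
#' can be mapped back to native pixels; [map_to_preprocessed()] and
#' [map_to_native()] move polylines between the two coordinate frames.
#'
#' @param image `H x W` matrix.
#' @param spacing Native in-plane spacing (mm/px), carried through.
#' @param size Model input size.
#' @return List with `image` (`size x size`), `scale`, `pad_to`,
#'   `native_shape`, `spacing`.
#' @export
preprocess_slice <- function(image, spacing = 1, size = 224L) {
  h <- nrow(image); w <- ncol(image)
  if (is.null(h) || h < 2L || w < 2L) abort("degenerate image")
  s <- max(h, w)
  if (h != s || w != s) {
    padded <- matrix(0, s, s)
    padded[seq_len(h), seq_len(w)] <- image
  } else {
    padded <- image
  }
  list(image = resize_bicubic(padded, size, size), scale = size / s,
       pad_to = s, native_shape = c(h, w), spacing = spacing, size = size)
}

#' @rdname preprocess_slice
#' @param poly A `sij_polyline` in native coordinates.
#' @param prep Result of `preprocess_slice()`.
#' @export
map_to_preprocessed <- function(poly, prep) {
  s <- prep$scale
  transform_polyline(poly, diag(c(s, s)), off = c(0.5 * s - 0.5, 0.5 * s - 0.5))
}

#' @rdname preprocess_slice
#' @export
map_to_native <- function(poly, prep) {
  s <- 1 / prep$scale
  transform_polyline(poly, diag(c(s, s)), off = c(0.5 * s - 0.5, 0.5 * s - 0.5))
}

#' Augment a training slice
#'
#' Draws one random geometric + photometric augmentation from `spec` (using
#' the current RNG state) and applies it. Landmarks that leave the frame
#' mark their side absent.
#'
#' @param sample A [slice_sample()].
#' @param spec An [augment_spec()].
#' @return The augmented `sij_slice`.
#' @export
augment_slice <- function(sample, spec) {
  img <- sample$image
  h <- nrow(img); w <- ncol(img)
  ctr <- c((w - 1) / 2, (h - 1) / 2)
  ang <- runif(1, -spec$rotate, spec$rotate) * pi / 180
  sc <- 1 + runif(1, -spec$scale, spec$scale)
  tx <- runif(1, -spec$translate, spec$translate) * w
  ty <- runif(1, -spec$translate, spec$translate) * h
  flip <- spec$lr_flip && runif(1) < 0.5
  rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  m <- sc * rot
  if (flip) m <- m %*% diag(c(-1, 1))
  # p' = m (p - ctr) + ctr + t
  off <- ctr + c(tx, ty) - m %*% ctr
  new_img <- affine_sample(img, m, off)
  left <- transform_polyline(sample$left, m, off, shape = c(h, w))
  right <- transform_polyline(sample$right, m, off, shape = c(h, w))
  if (flip) {
    tmp <- left
    left <- right; right <- tmp
    left$side <- "left"; right$side <- "right"
  }
  if (spec$blur_sigma > 0 && runif(1) < 0.5) {
    new_img <- gaussian_blur(new_img, spec$blur_sigma)
  }
  if (spec$noise_sigma > 0) {
    new_img <- new_img + matrix(rnorm(h * w, sd = spec$noise_sigma), h, w)
  }
  slice_sample(new_img, left, right, sample$spacing)
}

#' Delineation training loss
#'
#' Mean squared error on the 4 unit-vector-field planes plus per-pixel
#' weighted squared error on the 4 heatmap planes, with weight
#' `1 + alpha * target`; the two components are returned separately and sum
#' exactly to the total.
#'
#' @param pred `H x W x 8` array of activated predictions (heatmap planes in
#'   `[0, 1]`), or a `sij_targets`.
#' @param target A `sij_targets` (or 8-plane array).
#' @param alpha Heatmap weight strength; `alpha = 0` reduces the heatmap
#'   term to plain MSE.
#' @return List with `total`, `field`, `heatmap`.
#' @export
delineation_loss <- function(pred, target, alpha = 10) {
  if (inherits(pred, "sij_targets")) pred <- targets_to_planes(pred)
  if (inherits(target, "sij_targets")) target <- targets_to_planes(target)
  if (!all(dim(pred) == dim(target))) abort("shape mismatch")
  if (anyNA(pred) || anyNA(target)) abort("NaN in loss inputs")
  fi <- c(1L, 2L, 5L, 6L); hi <- c(3L, 4L, 7L, 8L)
  field <- mean((pred[, , fi] - target[, , fi])^2)
  th <- target[, , hi]
  heat <- mean((1 + alpha * th) * (pred[, , hi] - th)^2)
  list(total = field + heat, field = field, heatmap = heat)
}

#' Build an untrained delineator
#'
#' Parameter initialisation is seeded from the config, so two builds with
#' the same config are identical.
#' @param config A [delineator_config()].
#' @export
build_delineator <- function(config) {
  set.seed(config$seed)
  in_ch <- if (config$coord_channels) 3L else 1L
  params <- unet_init(in_ch, config$out_planes, config$depth, config$width)
  structure(list(params = params, config = config,
                 history = tibble(step = integer(), loss = numeric(),
                                  val_loss = numeric())),
            class = "sij_delineator")
}

#' @export
print.sij_delineator <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sij_delineator %s %dx%d depth=%d width=%d planes=%d steps=%d>\n",
              cfg$mode, cfg$input_size, cfg$input_size, cfg$depth, cfg$width,
              cfg$out_planes, nrow(x$history)))
  invisible(x)
}

# raw network output -> activated planes (heatmap planes squashed)
delineator_activate <- function(raw, config) {
  if (config$mode == "uvf") {
    hi <- c(3L, 4L, 7L, 8L)
    raw[, , hi] <- sigmoid(raw[, , hi])
  } else {
    raw <- sigmoid(raw)
  }
  raw
}

#' Predict activated output planes for one preprocessed slice
#' @param model A `sij_delineator`.
#' @param image `input_size x input_size` matrix (intensity-normalised).
#' @export
delineator_predict <- function(model, image) {
  cfg <- model$config
  raw <- unet_forward(model$params, delineator_input(image, cfg), cfg$depth)$out
  delineator_activate(raw, cfg)
}

# stack the image with normalised coordinate maps when configured
delineator_input <- function(image, config) {
  h <- nrow(image); w <- ncol(image)
  if (!config$coord_channels) return(array(image, c(h, w, 1L)))
  x <- array(0, c(h, w, 3L))
  x[, , 1] <- image
  x[, , 2] <- matrix(rep(seq(0, 1, length.out = w), each = h), h, w)
  x[, , 3] <- matrix(rep(seq(0, 1, length.out = h), times = w), h, w)
  x
}

# per-sample loss gradient wrt raw output planes (uvf mode)
uvf_loss_grad <- function(raw, tplanes, alpha, heat_weight = 1) {
  n <- length(tplanes[, , 1]) * 4
  fi <- c(1L, 2L, 5L, 6L); hi <- c(3L, 4L, 7L, 8L)
  d <- array(0, dim(raw))
  d[, , fi] <- 2 * (raw[, , fi] - tplanes[, , fi]) / n
  ph <- sigmoid(raw[, , hi])
  th <- tplanes[, , hi]
  d[, , hi] <- heat_weight * 2 * (1 + alpha * th) * (ph - th) / n * ph * (1 - ph)
  d
}

heatmap_loss_grad <- function(raw, tplanes, alpha) {
  n <- length(tplanes)
  ph <- sigmoid(raw)
  2 * (1 + alpha * tplanes) * (ph - tplanes) / n * ph * (1 - ph)
}

# 8-plane (uvf) or 42-plane (landmarks) target construction for a slice
slice_targets <- function(sample, config) {
  shape <- dim(sample$image)
  if (config$mode == "uvf") {
    lp <- sample$left$present && n_vertices(sample$left) >= 2L
    rp <- sample$right$present && n_vertices(sample$right) >= 2L
    sigma <- if (lp || rp) {
      heatmap_sigma(sample$left, sample$right, frac = config$sigma_frac)
    } else NULL
    targets_to_planes(contour_targets(sample$left, sample$right, shape,
                                      sigma = sigma,
                                      on_contour_radius = config$on_contour_radius,
                                      centripetal = config$centripetal))
  } else {
    landmark_target_planes(sample$left, sample$right, shape,
                           n = config$n_landmarks)
  }
}

#' Landmark heatmap targets for the baseline network
#'
#' Each joint contributes `n` Gaussian heatmaps, one per landmark; sparse
#' annotations are up-sampled to `n` points by linear interpolation along
#' the contour's arclength (endpoints preserved). Absent joints contribute
#' zero planes. Plane order: left landmarks 1..n, then right.
#'
#' @param left,right `sij_polyline`s.
#' @param shape `c(height, width)`.
#' @param n Landmarks per joint.
#' @param sigma Heatmap scale; defaults to 2 px (landmark-sized peaks).
#' @export
landmark_target_planes <- function(left, right, shape, n = 21L, sigma = 2) {
  planes <- array(0, c(shape[[1]], shape[[2]], 2L * n))
  fill <- function(poly, offset) {
    if (!poly$present || n_vertices(poly) < 2L) return()
    rs <- resample_polyline(poly, n)
    for (k in seq_len(n)) {
      planes[, , offset + k] <<-
        gaussian_heatmap(c(rs$x[k], rs$y[k]), shape, sigma)
    }
  }
  fill(left, 0L); fill(right, n)
  planes
}

#' Decode baseline landmark predictions into polylines
#'
#' Per plane, the landmark estimate is the heatmap argmax; the `n` estimates
#' of each side, in plane order, form the predicted contour. A side whose
#' mean peak value is below `presence_threshold` is absent. Consecutive
#' duplicate argmaxes are collapsed.
#'
#' @param planes `H x W x 2n` activated baseline output.
#' @param n Landmarks per side.
#' @param presence_threshold Minimum mean per-plane peak value.
#' @export
baseline_landmarks <- function(planes, n = 21L, presence_threshold = 0.3) {
  decode <- function(offset, side) {
    peaks <- vapply(seq_len(n), function(k) {
      hm <- planes[, , offset + k]
      c(heatmap_argmax(hm), max(hm))
    }, numeric(3))
    if (mean(peaks[3, ]) < presence_threshold) return(absent_polyline(side))
    x <- peaks[1, ]; y <- peaks[2, ]
    keep <- c(TRUE, x[-1] != x[-n] | y[-1] != y[-n])
    if (sum(keep) < 2L) return(absent_polyline(side))
    polyline(x[keep], y[keep], side)
  }
  list(left = decode(0L, "left"), right = decode(n, "right"))
}

#' Train a delineator
#'
#' Adam with the configured learning rate and betas; minibatches are drawn
#' and augmented per step, and targets are regenerated from the augmented
#' landmarks. Slices with absent joints stay in the training set so the
#' network learns to suppress endpoint heatmaps (and hence detections) where
#' a joint is out of frame. With a validation set, training stops early when
#' the validation loss has not improved for `patience` evaluations.
#'
#' @param samples List of [slice_sample()]s (images `input_size` square).
#' @param config A [delineator_config()].
#' @param augment An [augment_spec()], or `NULL` to disable augmentation.
#' @param steps Optimisation steps.
#' @param batch_size Minibatch size.
#' @param val_samples Optional validation slices.
#' @param val_every Steps between validation evaluations.
#' @param patience Early-stopping patience in evaluations.
#' @return A trained `sij_delineator` with a `history` tibble.
#' @export
train_delineator <- function(samples, config, augment = augment_spec(),
                             steps = 300L, batch_size = 8L,
                             val_samples = NULL, val_every = 25L,
                             patience = Inf) {
  if (length(samples) == 0L) abort("empty training set")
  model <- build_delineator(config)
  p <- model$params
  state <- adam_init(p)
  hist <- vector("list", steps)
  best_val <- Inf; since_best <- 0L
  # without augmentation the targets and inputs are fixed: cache them
  target_cache <- vector("list", length(samples))
  input_cache <- vector("list", length(samples))
  for (step in seq_len(steps)) {
    idx <- sample.int(length(samples), batch_size, replace = TRUE)
    grads <- zero_grads(p)
    loss_acc <- 0
    for (i in idx) {
      s <- samples[[i]]
      if (!is.null(augment)) {
        s <- augment_slice(s, augment)
        tpl <- slice_targets(s, config)
        x <- delineator_input(normalise_intensity(s$image), config)
      } else {
        if (is.null(target_cache[[i]])) {
          target_cache[[i]] <- slice_targets(s, config)
          input_cache[[i]] <- delineator_input(normalise_intensity(s$image),
                                               config)
        }
        tpl <- target_cache[[i]]
        x <- input_cache[[i]]
      }
      fw <- unet_forward(p, x, config$depth)
      act <- delineator_activate(fw$out, config)
      if (config$mode == "uvf") {
        l <- delineation_loss(act, tpl, config$alpha)
        loss_acc <- loss_acc + l$field + config$heat_weight * l$heatmap
        dout <- uvf_loss_grad(fw$out, tpl, config$alpha, config$heat_weight)
      } else {
        loss_acc <- loss_acc +
          mean((1 + config$alpha * tpl) * (act - tpl)^2)
        dout <- heatmap_loss_grad(fw$out, tpl, config$alpha)
      }
      grads <- acc_grads(grads, unet_backward(p, fw$cache, dout, config$depth),
                         scale = 1 / batch_size)
    }
    lr_t <- scheduled_lr(config, step, steps)
    upd <- adam_step(p, grads, state, lr = lr_t, beta1 = config$beta1,
                     beta2 = config$beta2)
    p <- upd$params; state <- upd$state
    vl <- NA_real_
    if (!is.null(val_samples) && step %% val_every == 0L) {
      vl <- mean(vapply(val_samples, function(s) {
        tpl <- slice_targets(s, config)
        x <- delineator_input(normalise_intensity(s$image), config)
        act <- delineator_activate(unet_forward(p, x, config$depth)$out, config)
        if (config$mode == "uvf") {
          lv <- delineation_loss(act, tpl, config$alpha)
          lv$field + config$heat_weight * lv$heatmap
        } else {
          mean((1 + config$alpha * tpl) * (act - tpl)^2)
        }
      }, numeric(1)))
      if (vl < best_val) { best_val <- vl; since_best <- 0L }
      else since_best <- since_best + 1L
    }
    hist[[step]] <- tibble(step = step, loss = loss_acc / batch_size,
                           val_loss = vl)
    if (since_best >= patience) break
  }
  model$params <- p
  model$history <- dplyr::bind_rows(hist)
  model
}

#' Delineate every slice of a volume
#'
#' Each slice is preprocessed to the model input size, pushed through the
#' network, and the two joints are extracted: in `"uvf"` mode by walking the
#' normalised field from source to sink, in `"landmarks"` mode by decoding
#' per-plane argmaxes. Predicted contours are mapped back to native pixel
#' coordinates.
#'
#' @param model A trained `sij_delineator`.
#' @param volume `H x W x n_slices` array (or `H x W` matrix for one slice).
#' @param walk A [walk_params()] (uvf mode).
#' @param spacing In-plane spacing (mm/px), carried to the output.
#' @return A tibble with columns `slice`, `side`, `present`, `contour`
#'   (list-column of `sij_polyline` in native coordinates).
#' @export
delineate_volume <- function(model, volume, walk = walk_params(), spacing = 1) {
  if (length(dim(volume)) == 2L) volume <- array(volume, c(dim(volume), 1L))
  cfg <- model$config
  n <- dim(volume)[3]
  rows <- vector("list", 2L * n)
  for (s in seq_len(n)) {
    prep <- preprocess_slice(normalise_intensity(volume[, , s]),
                             spacing = spacing, size = cfg$input_size)
    planes <- delineator_predict(model, prep$image)
    if (cfg$mode == "uvf") {
      tg <- planes_to_targets(planes)
      polys <- walk_targets(tg, walk)
    } else {
      polys <- baseline_landmarks(planes, cfg$n_landmarks,
                                  presence_threshold = walk$presence_threshold)
    }
    for (side in c("left", "right")) {
      poly <- polys[[side]]
      native <- if (poly$present) map_to_native(poly, prep) else poly
      rows[[(s - 1L) * 2L + (side == "right") + 1L]] <-
        tibble(slice = s, side = side, present = native$present,
               contour = list(native))
    }
  }
  dplyr::bind_rows(rows)
}


# learning rate at a given step under the configured schedule
scheduled_lr <- function(config, step, steps) {
  if (identical(config$lr_schedule, "cosine")) {
    warm <- max(1L, floor(steps / 10))
    if (step <= warm) return(config$lr * step / warm)
    frac <- (step - warm) / max(1L, steps - warm)
    return(config$lr * (0.5 * (1 + cos(pi * frac))))
  }
  config$lr
}
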