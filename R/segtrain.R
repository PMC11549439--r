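#' Training plan for a segmentation network
#'
#' Training proceeds in stages of decreasing learning rate; at the end of
#' each stage the weights with the best validation Dice seed the next
#' stage. Defaults follow the staged schedule used for the five
#' full-resolution structures; the olfactory-bulb variant is two stages of
#' 200 epochs at 1e-4 and 1e-5.
#'
#' @param stages list of `c(learning_rate, epochs)` pairs with strictly
#'   decreasing learning rates.
#' @param batch_size tiles per optimisation step.
#' @param steps_per_epoch optimisation steps per epoch.
#' @param augment_amplitude half-width of the uniform per-channel intensity
#'   offset applied to each training tile.
#' @param seed seed governing crop sampling, augmentation and dropout.
#' @export
train_plan <- function(stages = list(c(1e-4, 35), c(5e-5, 35), c(1e-5, 35)),
                       batch_size = 32L, steps_per_epoch = 8L,
                       augment_amplitude = 0.01, seed = 1L) {
  lrs <- vapply(stages, `[`, numeric(1), 1)
  eps <- vapply(stages, `[`, numeric(1), 2)
  if (length(stages) > 1 && any(diff(lrs) >= 0))
    stop_olf("learning rates must be strictly decreasing across stages")
  if (length(stages) > 0 && any(eps <= 0)) stop_olf("epochs must be positive")
  structure(list(stages = stages, batch_size = as.integer(batch_size),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 augment_amplitude = augment_amplitude, seed = as.integer(seed)),
            class = "train_plan")
}

#' Per-channel intensity augmentation
#'
#' Draws one offset per channel from `U(-amplitude, +amplitude)`, adds it
#' uniformly to that channel and clips to `[0, 1]` — forcing the network to
#' rely on relative rather than absolute channel intensity.
#'
#' @param tile `H x W x C` array in `[0, 1]`.
#' @param amplitude non-negative half-width of the offset distribution.
#' @param seed optional seed; if `NULL` the current RNG stream is used.
#' @export
augment_intensity <- function(tile, amplitude = 0.01, seed = NULL) {
  if (amplitude < 0) stop_olf("amplitude must be non-negative")
  if (amplitude == 0) return(tile)
  draw <- function() {
    off <- runif(dim(tile)[3], -amplitude, amplitude)
    for (ch in seq_len(dim(tile)[3]))
      tile[, , ch] <- pmin(pmax(tile[, , ch] + off[ch], 0), 1)
    tile
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Tile a section, predict, and assemble the probability map
#'
#' Covers the section with overlapping tiles stepped by
#' `tile_size - 2 * margin`; only each tile's centre region is kept in the
#' assembled map (edge tiles keep their outer border), the overlap being
#' split at its midpoint, so every pixel is predicted exactly once.
#' Sections smaller than a tile are zero-padded and cropped back.
#'
#' @param channels named list of channel matrices (one section).
#' @param predict_tile function mapping an `H x W x C` array to a matrix of
#'   foreground probabilities.
#' @param tile_size tile side in px.
#' @param margin centre-crop margin in px; must be `< tile_size / 2`.
#' @return Matrix of foreground probabilities for the whole section.
#' @export
tile_and_assemble <- function(channels, predict_tile, tile_size = 512L,
                              margin = 64L) {
  if (margin >= tile_size / 2) stop_olf("margin must be < tile_size / 2")
  H <- nrow(channels[[1]]); W <- ncol(channels[[1]])
  x <- array(unlist(channels, use.names = FALSE),
             dim = c(H, W, length(channels)))
  Hp <- max(H, tile_size); Wp <- max(W, tile_size)
  if (Hp > H || Wp > W) {
    xp <- array(0, dim = c(Hp, Wp, dim(x)[3]))
    xp[seq_len(H), seq_len(W), ] <- x
    x <- xp
  }
  starts <- function(L) {
    if (L == tile_size) return(1L)
    s <- seq(1L, L - tile_size + 1L, by = tile_size - 2L * margin)
    unique(c(s, L - tile_size + 1L))
  }
  sr <- starts(Hp); sc <- starts(Wp)
  cuts <- function(s, L) {
    # responsibility boundaries: midpoint of the overlap of adjacent tiles
    n <- length(s)
    lo <- c(1L, vapply(seq_len(n - 1), function(t)
      as.integer(floor((s[t] + tile_size - 1L + s[t + 1]) / 2)) + 1L,
      integer(1)))
    hi <- c(lo[-1] - 1L, L)
    cbind(lo, hi)
  }
  rr <- cuts(sr, Hp); rc <- cuts(sc, Wp)
  out <- matrix(NA_real_, Hp, Wp)
  for (ti in seq_along(sr)) {
    for (tj in seq_along(sc)) {
      tile <- x[sr[ti] + 0:(tile_size - 1), sc[tj] + 0:(tile_size - 1), ,
                drop = FALSE]
      pred <- predict_tile(tile)
      keep_r <- rr[ti, 1]:rr[ti, 2]; keep_c <- rc[tj, 1]:rc[tj, 2]
      out[keep_r, keep_c] <- pred[keep_r - sr[ti] + 1L, keep_c - sc[tj] + 1L]
    }
  }
  out[seq_len(H), seq_len(W)]
}

down2 <- function(img) pyr_down(img)

downsample_channels <- function(channels, factor) {
  while (factor > 1) {
    channels <- lapply(channels, down2)
    factor <- factor / 2
  }
  channels
}

downsample_mask <- function(mask, factor) {
  while (factor > 1) { mask <- (pyr_down(mask) >= 0.5) * 1; factor <- factor / 2 }
  mask
}

#' Predict the foreground probability map of a section
#'
#' Runs the model over the section with [tile_and_assemble()]; inputs are
#' downsampled first when the model was trained at reduced resolution, and
#' the probability map is upsampled back.
#'
#' @param model a `unet_model`.
#' @param channels named list of four channel matrices.
#' @param margin assembly margin, px.
#' @export
predict_section <- function(model, channels, margin = NULL) {
  f <- model$config$downsample_factor
  if (f > 1) channels <- downsample_channels(channels, f)
  ts <- min(model$config$tile_size,
            2^floor(log2(min(nrow(channels[[1]]), ncol(channels[[1]])))))
  ts <- max(ts, 8L)
  if (is.null(margin)) margin <- max(1L, ts %/% 8L)
  pt <- function(tile) unet_forward(model, list(tile))$probs[[1]][, , 2]
  pm <- tile_and_assemble(channels, pt, tile_size = ts, margin = margin)
  if (f > 1)
    pm <- matrix(EBImage::resize(pm, w = nrow(pm) * f, h = ncol(pm) * f),
                 nrow(pm) * f, ncol(pm) * f)
  pm
}

#' Segmentation metrics
#'
#' Dice, precision and recall of a predicted binary mask against the truth;
#' binary cross-entropy is added when a probability map is supplied. With
#' no predicted and no true positives the metrics equal 1 (perfect
#' agreement on absence).
#'
#' @param pred_mask,truth_mask binary matrices of equal shape.
#' @param prob_map optional probability map for the cross-entropy.
#' @return List with `dsc`, `precision`, `recall` and optionally `bce`.
#' @export
seg_metrics <- function(pred_mask, truth_mask, prob_map = NULL) {
  assert_same_shape(pred_mask, truth_mask, "masks")
  assert_binary(pred_mask, "pred_mask"); assert_binary(truth_mask, "truth_mask")
  tp <- sum(pred_mask * truth_mask)
  fp <- sum(pred_mask * (1 - truth_mask))
  fn <- sum((1 - pred_mask) * truth_mask)
  precision <- if (tp + fp == 0) as.numeric(fn == 0) else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  out <- list(dsc = dice(pred_mask, truth_mask), precision = precision,
              recall = recall)
  if (!is.null(prob_map)) {
    p <- pmin(pmax(prob_map, 1e-7), 1 - 1e-7)
    out$bce <- -mean(truth_mask * log(p) + (1 - truth_mask) * log(1 - p))
  }
  out
}

#' Dice-optimal binarisation threshold
#'
#' Scans a grid of candidate cut-offs and returns the one maximising the
#' Dice coefficient of `prob >= t` against the truth; ties resolve to the
#' smallest threshold.
#'
#' @param prob_map probability map, or list of maps (pooled).
#' @param truth_mask truth mask, or list matching `prob_map`.
#' @param grid candidate thresholds in `(0, 1)`; default 0.01 ... 0.99.
#' @return List with `threshold` and `dsc` at that threshold.
#' @export
select_threshold <- function(prob_map, truth_mask,
                             grid = seq(0.01, 0.99, by = 0.01)) {
  p <- unlist(if (is.list(prob_map)) prob_map else list(prob_map))
  y <- unlist(if (is.list(truth_mask)) truth_mask else list(truth_mask))
  if (sum(y) == 0)
    stop_olf("empty truth mask: threshold selection is undefined")
  if (any(grid <= 0 | grid >= 1)) stop_olf("grid values must lie in (0, 1)")
  sy <- sum(y)
  dscs <- vapply(grid, function(t) {
    pred <- p >= t
    s <- sum(pred) + sy
    if (s == 0) 1 else 2 * sum(y[pred]) / s
  }, numeric(1))
  list(threshold = grid[which.max(dscs)], dsc = max(dscs))
}

section_tensor <- function(s, factor = 1L) {
  ch <- if (factor > 1) downsample_channels(s$channels, factor) else s$channels
  array(unlist(ch, use.names = FALSE),
        dim = c(nrow(ch[[1]]), ncol(ch[[1]]), length(ch)))
}

#' Train a segmentation model
#'
#' Runs the staged training schedule on randomly cropped, intensity-
#' augmented tiles. At each epoch end the model is evaluated on the
#' validation sections (Dice at threshold 0.5 and binary cross-entropy);
#' the best validation weights of one stage initialise the next. For the
#' olfactory bulb (`downsample_factor = 4`) all inputs are downsampled
#' before training. After the final stage the Dice-optimal threshold is
#' selected on the validation set and stored with the model. Runs are
#' deterministic under a fixed plan seed (single-threaded).
#'
#' @param model an untrained or pre-trained `unet_model`.
#' @param training_sections,validation_sections lists of `section_record`s
#'   with ground-truth masks.
#' @param structure name of the target structure mask.
#' @param plan a [train_plan()].
#' @return The trained `unet_model` with `threshold` set and a `history`
#'   data frame (stage, epoch, validation Dice and cross-entropy).
#' @export
train_unet <- function(model, training_sections, validation_sections,
                       structure, plan = train_plan()) {
  stopifnot(inherits(model, "unet_model"), inherits(plan, "train_plan"))
  if (length(training_sections) < 1 || length(validation_sections) < 1)
    stop_olf("need at least one training and one validation section")
  f <- model$config$downsample_factor
  xs <- lapply(training_sections, section_tensor, factor = f)
  ys <- lapply(training_sections, function(s)
    downsample_mask(s$masks[[structure]], f))
  if (sum(vapply(ys, sum, numeric(1))) == 0)
    stop_olf("structure '%s' is empty in every training mask", structure)
  vx <- lapply(validation_sections, function(s)
    if (f > 1) downsample_channels(s$channels, f) else s$channels)
  vy <- lapply(validation_sections, function(s)
    downsample_mask(s$masks[[structure]], f))
  ts <- min(model$config$tile_size,
            2^floor(log2(min(vapply(ys, nrow, integer(1)),
                             vapply(ys, ncol, integer(1))))))
  ts <- max(8L, ts)

  validate <- function(m) {
    pt <- function(tile) unet_forward(m, list(tile))$probs[[1]][, , 2]
    res <- mapply(function(ch, y) {
      pm <- tile_and_assemble(ch, pt, tile_size = ts,
                              margin = max(1L, ts %/% 8L))
      mt <- seg_metrics((pm >= 0.5) * 1, y, prob_map = pm)
      c(mt$dsc, mt$bce)
    }, vx, vy)
    c(dsc = mean(res[1, ]), bce = mean(res[2, ]))
  }

  history <- data.frame()
  if (length(plan$stages) == 0) {
    model$history <- history
    return(model)
  }
  crop <- function(img, r0, c0) img[r0 + 0:(ts - 1), c0 + 0:(ts - 1)]
  with_seed(plan$seed, {
    state <- adam_init(model)
    t_global <- 0
    for (st in seq_along(plan$stages)) {
      lr <- plan$stages[[st]][1]; n_epochs <- plan$stages[[st]][2]
      best <- list(dsc = -Inf, layers = NULL)
      for (ep in seq_len(n_epochs)) {
        for (step in seq_len(plan$steps_per_epoch)) {
          bx <- vector("list", plan$batch_size)
          by <- vector("list", plan$batch_size)
          for (b in seq_len(plan$batch_size)) {
            si <- sample.int(length(xs), 1)
            H <- dim(xs[[si]])[1]; W <- dim(xs[[si]])[2]
            r0 <- sample.int(max(1L, H - ts + 1L), 1)
            c0 <- sample.int(max(1L, W - ts + 1L), 1)
            tl <- xs[[si]][r0 + 0:(ts - 1), c0 + 0:(ts - 1), , drop = FALSE]
            bx[[b]] <- augment_intensity(tl, plan$augment_amplitude)
            by[[b]] <- crop(ys[[si]], r0, c0)
          }
          fwd <- unet_forward(model, bx, training = TRUE)
          for (nm in names(fwd$bn_updates))
            model$layers[[nm]] <- fwd$bn_updates[[nm]]
          grads <- unet_backward(model, fwd, by)
          t_global <- t_global + 1
          upd <- adam_step(model, grads, state, lr, t_global)
          model <- upd$model; state <- upd$state
        }
        val <- validate(model)
        history <- rbind(history, data.frame(
          stage = st, epoch = ep, lr = lr, val_dsc = val["dsc"],
          val_bce = val["bce"], row.names = NULL))
        if (val["dsc"] > best$dsc)
          best <- list(dsc = val["dsc"], layers = model$layers)
      }
      if (!is.null(best$layers)) model$layers <- best$layers
    }
    pt <- function(tile) unet_forward(model, list(tile))$probs[[1]][, , 2]
    pms <- lapply(vx, function(ch)
      tile_and_assemble(ch, pt, tile_size = ts, margin = max(1L, ts %/% 8L)))
    if (sum(vapply(vy, sum, numeric(1))) > 0) {
      thr <- select_threshold(pms, vy)
      model$threshold <- thr$threshold
    }
    model$history <- history
    model
  })
}

#' Bootstrap hook: extend the ground truth and retrain
#'
#' Manual correction of poorly segmented sections is a human act; this hook
#' only automates the retraining once corrected sections are supplied.
#'
#' @inheritParams train_unet
#' @param new_sections corrected `section_record`s appended to the training
#'   set.
#' @export
add_sections_and_retrain <- function(model, training_sections, new_sections,
                                     validation_sections, structure,
                                     plan = train_plan()) {
  train_unet(model, c(training_sections, new_sections), validation_sections,
             structure, plan)
}

#' Save / load a segmentation model checkpoint
#'
#' The checkpoint is a single JSON file holding the configuration, the
#' threshold, the training history and every parameter tensor with its
#' dimensions.
#'
#' @param model a `unet_model`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  ser <- list(config = unclass(model$config), threshold = model$threshold,
              history = model$history,
              layers = lapply(model$layers, function(ly) {
                out <- list(type = ly$type)
                for (nm in setdiff(names(ly), "type"))
                  out[[nm]] <- list(dim = dim(ly[[nm]]) %||% length(ly[[nm]]),
                                    data = as.numeric(ly[[nm]]))
                out
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(unet_config, as.list(ser$config))
  layers <- lapply(ser$layers, function(ly) {
    out <- list(type = ly$type)
    for (nm in setdiff(names(ly), "type")) {
      v <- as.numeric(ly[[nm]]$data)
      d <- as.integer(ly[[nm]]$dim)
      out[[nm]] <- if (length(d) > 1) array(v, dim = d) else v
    }
    out
  })
  structure(list(config = cfg, layers = layers,
                 threshold = ser$threshold %||% NA_real_,
                 history = ser$history), class = "unet_model")
}
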