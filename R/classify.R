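# The trainable stage: intensity scaling to [0, 1], padding/resizing to the
# backbone's input shape, seven-transform augmentation (rotation, width
# shift, height shift, shear, zoom, horizontal flip, vertical flip), a
# convolutional feature extractor (trainable or frozen) with a small dense
# softmax head, Adam training and prediction.

backbone_side <- function(backbone) {
  switch(backbone, tiny_cnn = 32L, frozen_random_conv = 64L,
         224L)  # pretrained:* default
}

#' Specify a classifier
#'
#' @param backbone `"tiny_cnn"` (three trainable conv blocks),
#'   `"frozen_random_conv"` (the same conv stack with seeded fixed weights;
#'   only the head is trained, the structural analogue of a frozen
#'   pre-trained base), or `"pretrained:<name>"` (a user-supplied frozen
#'   feature extractor, see the `backbone_fn` argument of
#'   [train_classifier()]).
#' @param head_layers 1 or 2 dense layers of 256 units before the softmax.
#' @param n_classes number of classes (>= 2).
#' @param input_side input image side in pixels; defaults to the backbone's
#'   required shape (32 for `tiny_cnn`, 64 for `frozen_random_conv`, 224
#'   for pretrained backbones) and must match it.
#' @param seed seed for weight initialisation (and the frozen filter bank).
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(backbone = "tiny_cnn", head_layers = 1L,
                            n_classes, input_side = NULL, seed = 1L) {
  known <- backbone %in% c("tiny_cnn", "frozen_random_conv") ||
    startsWith(backbone, "pretrained:")
  if (!known) stop("unknown backbone: ", backbone)
  stopifnot(head_layers %in% c(1L, 2L), n_classes >= 2)
  required <- backbone_side(backbone)
  if (is.null(input_side)) input_side <- required
  if (backbone %in% c("tiny_cnn", "frozen_random_conv") &&
      input_side != required) {
    stop(sprintf("backbone '%s' requires input_side %d", backbone, required))
  }
  if (startsWith(backbone, "pretrained:") && !input_side %in% c(224L, 299L)) {
    stop("pretrained backbones require input_side 224 or 299")
  }
  structure(list(backbone = backbone, head_layers = as.integer(head_layers),
                 n_classes = as.integer(n_classes),
                 input_side = as.integer(input_side),
                 backbone_frozen = backbone != "tiny_cnn",
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Augmentation configuration
#'
#' Exactly seven transform kinds are available; setting a range to zero (or
#' a flip to `FALSE`) disables that transform. Defaults: full rotation,
#' 10\% shifts, 10 degree shear, zoom 0.9-1.1, both flips enabled.
#'
#' @param rotation_range maximal absolute rotation in degrees.
#' @param width_shift,height_shift maximal absolute shift as a fraction of
#'   the image side.
#' @param shear_range maximal absolute shear angle in degrees.
#' @param zoom_range length-2 `(low, high)` zoom factor range; `c(1, 1)`
#'   disables zoom.
#' @param horizontal_flip,vertical_flip enable random flips.
#' @param seed base seed for augmentation draws during training.
#' @return object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_range = 180, width_shift = 0.1,
                                height_shift = 0.1, shear_range = 10,
                                zoom_range = c(0.9, 1.1),
                                horizontal_flip = TRUE, vertical_flip = TRUE,
                                seed = 1L) {
  stopifnot(rotation_range >= 0, width_shift >= 0, height_shift >= 0,
            shear_range >= 0, length(zoom_range) == 2,
            zoom_range[1] > 0, zoom_range[2] >= zoom_range[1])
  structure(list(rotation_range = rotation_range, width_shift = width_shift,
                 height_shift = height_shift, shear_range = shear_range,
                 zoom_range = zoom_range,
                 horizontal_flip = isTRUE(horizontal_flip),
                 vertical_flip = isTRUE(vertical_flip),
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

#' Null augmentation (identity)
#' @return an `augmentation_config` with every transform disabled.
#' @export
no_augmentation <- function() {
  augmentation_config(rotation_range = 0, width_shift = 0, height_shift = 0,
                      shear_range = 0, zoom_range = c(1, 1),
                      horizontal_flip = FALSE, vertical_flip = FALSE)
}

#' Training configuration
#'
#' @param epochs number of training epochs (default 50).
#' @param batch_size minibatch size (32 for full data sets, 8 for 10\%
#'   subsets by convention).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param max_grad_norm global gradient-norm clip applied before each Adam
#'   step (default 5; `Inf` disables clipping).
#' @param lr_schedule `"cosine"` (default) decays the learning rate along a
#'   half cosine from `learning_rate` to a tenth of it over the epochs,
#'   damping late-epoch oscillation; `"constant"` keeps it fixed.
#' @param seed seed for shuffling and augmentation draws.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 32L,
                         learning_rate = 1e-3, max_grad_norm = 5,
                         lr_schedule = c("cosine", "constant"),
                         seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            max_grad_norm > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_grad_norm = max_grad_norm, lr_schedule = lr_schedule,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Learning rate for a given epoch under the configured schedule.
epoch_lr <- function(tconfig, epoch) {
  if (identical(tconfig$lr_schedule %||% "constant", "constant") ||
      tconfig$epochs == 1L) {
    return(tconfig$learning_rate)
  }
  frac <- (epoch - 1) / (tconfig$epochs - 1)
  lo <- 0.1 * tconfig$learning_rate
  lo + (tconfig$learning_rate - lo) * (1 + cos(pi * frac)) / 2
}

#' Preprocess a cut-out into a network input tensor
#'
#' Pads the grey patch to a square with the cut-out's background mean
#' (mean grey over mask-0 pixels; border mean if the mask covers
#' everything), resizes to `input_side` with bilinear interpolation
#' (aspect preserved by construction), scales intensities to \[0, 1\] and
#' replicates the grey channel to three channels.
#'
#' @param cutout a `cutout` (or a bare grey matrix in \[0, 255\]).
#' @param input_side target side in pixels.
#' @return numeric array `input_side x input_side x 3` with values in
#'   \[0, 1\].
#' @export
preprocess <- function(cutout, input_side) {
  d <- if (inherits(cutout, "cutout")) dim(cutout$image) else dim(cutout)
  if (is.null(d) || any(d == 0)) stop("zero-area cut-out")
  if (inherits(cutout, "cutout")) {
    img <- cutout$image
    bgpix <- img[cutout$mask == 0L]
    fill <- if (length(bgpix)) mean(bgpix) else mean(img[c(1, nrow(img)), ])
  } else {
    img <- cutout
    fill <- mean(img[c(1, nrow(img)), ])
  }
  h <- nrow(img); w <- ncol(img)
  if (h == 0 || w == 0) stop("zero-area cut-out")
  side <- max(h, w)
  sq <- matrix(fill, side, side)
  r0 <- floor((side - h) / 2); c0 <- floor((side - w) / 2)
  sq[r0 + (1:h), c0 + (1:w)] <- img
  if (side != input_side) {
    sq <- EBImage::resize(sq, w = input_side, h = input_side)
  }
  sq <- clip01(sq / 255)
  array(sq, c(input_side, input_side, 3))
}

# Draw one random parameterisation of the seven transforms.
draw_augmentation <- function(config, side) {
  theta <- if (config$rotation_range > 0)
    stats::runif(1, -config$rotation_range, config$rotation_range) * pi / 180 else 0
  sx <- if (config$width_shift > 0)
    stats::runif(1, -config$width_shift, config$width_shift) * side else 0
  sy <- if (config$height_shift > 0)
    stats::runif(1, -config$height_shift, config$height_shift) * side else 0
  shear <- if (config$shear_range > 0)
    stats::runif(1, -config$shear_range, config$shear_range) * pi / 180 else 0
  zoom <- if (!all(config$zoom_range == 1))
    stats::runif(1, config$zoom_range[1], config$zoom_range[2]) else 1
  hf <- config$horizontal_flip && stats::runif(1) < 0.5
  vf <- config$vertical_flip && stats::runif(1) < 0.5
  list(theta = theta, shift = c(sx, sy), shear = shear, zoom = zoom,
       hflip = hf, vflip = vf)
}

augmentation_matrix <- function(par) {
  R <- matrix(c(cos(par$theta), sin(par$theta),
                -sin(par$theta), cos(par$theta)), 2, 2)
  S <- matrix(c(1, 0, tan(par$shear), 1), 2, 2)
  Fm <- diag(c(if (par$hflip) -1 else 1, if (par$vflip) -1 else 1))
  (par$zoom * R) %*% S %*% Fm
}

#' Apply one random draw of the seven-transform augmentation
#'
#' Composes flip, shear, rotation, zoom and shift into a single affine map
#' about the image centre and samples it bilinearly; regions mapped from
#' outside the image are filled with the image's border mean. With all
#' ranges zero and flips disabled the output equals the input.
#'
#' @param image preprocessed array (side x side x channels) in \[0, 1\].
#' @param config an `augmentation_config`.
#' @param draw_seed seed of this draw; the same seed gives the same output.
#' @return augmented array of identical shape and value range.
#' @export
augment <- function(image, config, draw_seed = 1L) {
  stopifnot(length(dim(image)) == 3)
  par <- with_seed(draw_seed, draw_augmentation(config, dim(image)[1]))
  if (par$theta == 0 && all(par$shift == 0) && par$shear == 0 &&
      par$zoom == 1 && !par$hflip && !par$vflip) {
    return(image)
  }
  A <- augmentation_matrix(par)
  ch1 <- image[, , 1]
  fill <- mean(ch1[c(1, nrow(ch1)), ])
  warped <- clip01(affine_warp(ch1, A, shift = par$shift, fill = fill))
  out <- image
  for (c in seq_len(dim(image)[3])) {
    out[, , c] <- if (all(image[, , c] == ch1)) warped else {
      clip01(affine_warp(image[, , c], A, shift = par$shift, fill = fill))
    }
  }
  out
}

build_network <- function(cspec) {
  with_seed(cspec$seed, {
    trainable_conv <- !cspec$backbone_frozen
    n_feat <- switch(cspec$backbone,
                     tiny_cnn = 4 * 4 * 32,
                     frozen_random_conv = 8 * 8 * 32)
    layers <- list(layer_conv(3, 8, trainable_conv), layer_relu(), layer_pool(),
                   layer_conv(8, 16, trainable_conv), layer_relu(), layer_pool(),
                   layer_conv(16, 32, trainable_conv), layer_relu(), layer_pool(),
                   layer_flatten(),
                   layer_dense(n_feat, 256), layer_relu())
    if (cspec$head_layers == 2L) {
      layers <- c(layers, list(layer_dense(256, 256), layer_relu()))
    }
    c(layers, list(layer_dense(256, cspec$n_classes)))
  })
}

item_label <- function(item) {
  if (!is.null(item$label)) as.character(item$label) else stop("item has no label")
}

item_tensor <- function(item, input_side) {
  if (is.array(item$x %||% NULL)) item$x else preprocess(item, input_side)
}

#' Train the classifier stage
#'
#' Trains the dense softmax head (and, for the `tiny_cnn` backbone, the
#' convolutional base as well) with Adam on minibatches of augmented
#' images. The model is trained exclusively on augmented versions of the
#' training items; validation items are evaluated unaugmented. The
#' final-epoch model is returned; there is no early stopping or model
#' selection.
#'
#' @param train_items list of labelled cut-outs (each a `cutout` with a
#'   `label`, or a list with a preprocessed array `x` and a `label`);
#'   at least two classes must be present.
#' @param val_items optional validation items (may be `NULL` or empty).
#' @param cspec a [classifier_spec()]; `n_classes` must match the classes
#'   present in `train_items`.
#' @param aconfig an [augmentation_config()].
#' @param tconfig a [train_config()].
#' @param backbone_fn for `pretrained:` backbones only: a function mapping
#'   an input tensor to a feature vector (the frozen external base).
#' @return object of class `diatom_classifier` with elements `spec`,
#'   `classes` (sorted), `layers`, and `history` (one row per epoch with
#'   loss/accuracy and, if validation items exist, val_loss/val_accuracy).
#' @export
train_classifier <- function(train_items, val_items = NULL, cspec,
                             aconfig = augmentation_config(),
                             tconfig = train_config(),
                             backbone_fn = NULL) {
  stopifnot(inherits(cspec, "classifier_spec"), inherits(tconfig, "train_config"))
  labels <- vapply(train_items, item_label, "")
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training set contains a single class")
  if (length(classes) != cspec$n_classes) {
    stop(sprintf("spec expects %d classes but training data has %d",
                 cspec$n_classes, length(classes)))
  }
  if (startsWith(cspec$backbone, "pretrained:")) {
    if (is.null(backbone_fn)) {
      stop("pretrained backbones need a user-supplied backbone_fn ",
           "(external weights are not bundled)")
    }
    return(train_pretrained_head(train_items, val_items, cspec, aconfig,
                                 tconfig, backbone_fn, classes))
  }
  side <- cspec$input_side
  X_all <- lapply(train_items, item_tensor, input_side = side)
  y_all <- match(labels, classes)
  n <- length(X_all)
  K <- length(classes)

  layers <- build_network(cspec)
  state <- adam_init(layers)
  t_step <- 0L

  val_eval <- NULL
  if (length(val_items)) {
    Xv <- batch_array(lapply(val_items, item_tensor, input_side = side))
    yv <- match(vapply(val_items, item_label, ""), classes)
    val_eval <- function(layers) {
      lg <- network_forward(layers, Xv, keep_cache = FALSE)$logits
      r <- softmax_ce(lg, onehot(yv, K))
      c(r$loss, mean(max.col(t(r$probs)) == yv))
    }
  }

  history <- vector("list", tconfig$epochs)
  with_seed(tconfig$seed, {
    for (epoch in seq_len(tconfig$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_hit <- 0
      for (b0 in seq(1, n, by = tconfig$batch_size)) {
        idx <- ord[b0:min(b0 + tconfig$batch_size - 1, n)]
        aug_seeds <- sample.int(2^30, length(idx))
        Xb <- batch_array(lapply(seq_along(idx), function(j) {
          augment(X_all[[idx[j]]], aconfig, draw_seed = aug_seeds[j])
        }))
        Yb <- onehot(y_all[idx], K)
        fw <- network_forward(layers, Xb)
        ce <- softmax_ce(fw$logits, Yb)
        grads <- network_backward(layers, fw$caches, ce$dLogits)
        grads <- clip_gradients(grads, tconfig$max_grad_norm %||% Inf)
        t_step <- t_step + 1L
        upd <- adam_step(layers, grads, state, epoch_lr(tconfig, epoch), t_step)
        layers <- upd$layers; state <- upd$state
        ep_loss <- ep_loss + ce$loss * length(idx)
        ep_hit <- ep_hit + sum(max.col(t(ce$probs)) == y_all[idx])
      }
      row <- data.frame(epoch = epoch, loss = ep_loss / n, accuracy = ep_hit / n)
      if (!is.null(val_eval)) {
        v <- val_eval(layers)
        row$val_loss <- v[1]; row$val_accuracy <- v[2]
      }
      history[[epoch]] <- row
    }
  })
  structure(list(spec = cspec, classes = classes, layers = layers,
                 aconfig = aconfig, tconfig = tconfig,
                 history = do.call(rbind, history)),
            class = "diatom_classifier")
}

# Head-only training on externally extracted features (pretrained mode).
train_pretrained_head <- function(train_items, val_items, cspec, aconfig,
                                  tconfig, backbone_fn, classes) {
  side <- cspec$input_side
  feats <- lapply(train_items, function(it) backbone_fn(item_tensor(it, side)))
  n_feat <- length(feats[[1]])
  y_all <- match(vapply(train_items, item_label, ""), classes)
  K <- length(classes)
  layers <- with_seed(cspec$seed, {
    l <- list(layer_dense(n_feat, 256), layer_relu())
    if (cspec$head_layers == 2L) l <- c(l, list(layer_dense(256, 256), layer_relu()))
    c(l, list(layer_dense(256, K)))
  })
  state <- adam_init(layers)
  Xf <- do.call(cbind, feats)
  t_step <- 0L
  history <- vector("list", tconfig$epochs)
  with_seed(tconfig$seed, {
    for (epoch in seq_len(tconfig$epochs)) {
      ord <- sample.int(length(y_all))
      ep_loss <- 0; ep_hit <- 0
      for (b0 in seq(1, length(y_all), by = tconfig$batch_size)) {
        idx <- ord[b0:min(b0 + tconfig$batch_size - 1, length(y_all))]
        fw <- network_forward(layers, Xf[, idx, drop = FALSE])
        ce <- softmax_ce(fw$logits, onehot(y_all[idx], K))
        grads <- network_backward(layers, fw$caches, ce$dLogits)
        grads <- clip_gradients(grads, tconfig$max_grad_norm %||% Inf)
        t_step <- t_step + 1L
        upd <- adam_step(layers, grads, state, epoch_lr(tconfig, epoch), t_step)
        layers <- upd$layers; state <- upd$state
        ep_loss <- ep_loss + ce$loss * length(idx)
        ep_hit <- ep_hit + sum(max.col(t(ce$probs)) == y_all[idx])
      }
      history[[epoch]] <- data.frame(epoch = epoch,
                                     loss = ep_loss / length(y_all),
                                     accuracy = ep_hit / length(y_all))
    }
  })
  structure(list(spec = cspec, classes = classes, layers = layers,
                 backbone_fn = backbone_fn, aconfig = aconfig,
                 tconfig = tconfig, history = do.call(rbind, history)),
            class = "diatom_classifier")
}

batch_array <- function(tensors) {
  d <- dim(tensors[[1]])
  array(unlist(tensors, use.names = FALSE), c(d, length(tensors)))
}

onehot <- function(y, K) {
  Y <- matrix(0, K, length(y))
  Y[cbind(y, seq_along(y))] <- 1
  Y
}

#' @export
print.diatom_classifier <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<diatom_classifier> %s, %d classes, %d epochs (final loss %.4f, acc %.3f)\n",
              x$spec$backbone, length(x$classes), nrow(x$history),
              h$loss, h$accuracy))
  invisible(x)
}

#' Predict classes and probabilities for new items
#'
#' @param object a trained `diatom_classifier`.
#' @param items list of cut-outs or preprocessed items (as in
#'   [train_classifier()]).
#' @param ... unused.
#' @return data frame with one row per item: `item_id` (when available),
#'   `true_label` (when available), `predicted` and one probability column
#'   `p_<class>` per class. Probabilities are softmax outputs summing to 1;
#'   the prediction is the arg-max, ties broken by class order.
#' @export
predict.diatom_classifier <- function(object, items, ...) {
  if (!length(items)) {
    out <- data.frame(item_id = character(), true_label = character(),
                      predicted = character(), stringsAsFactors = FALSE)
    for (cl in object$classes) out[[paste0("p_", cl)]] <- numeric()
    return(out)
  }
  side <- object$spec$input_side
  probs_list <- list()
  chunk <- 64L
  if (!is.null(object$backbone_fn)) {
    feats <- do.call(cbind, lapply(items, function(it)
      object$backbone_fn(item_tensor(it, side))))
    probs <- softmax_probs(network_forward(object$layers, feats,
                                           keep_cache = FALSE)$logits)
  } else {
    for (b0 in seq(1, length(items), by = chunk)) {
      idx <- b0:min(b0 + chunk - 1, length(items))
      Xb <- batch_array(lapply(items[idx], item_tensor, input_side = side))
      probs_list[[length(probs_list) + 1]] <-
        softmax_probs(network_forward(object$layers, Xb,
                                      keep_cache = FALSE)$logits)
    }
    probs <- do.call(cbind, probs_list)
  }
  pred_idx <- apply(probs, 2, which.max)  # first max = class-order tie-break
  ids <- vapply(items, function(it) {
    src <- it$source
    if (!is.null(src)) paste(src$slide_id, src$annotation_id, sep = "/")
    else NA_character_
  }, "")
  truth <- vapply(items, function(it)
    if (is.null(it$label)) NA_character_ else as.character(it$label), "")
  out <- data.frame(item_id = ids, true_label = truth,
                    predicted = object$classes[pred_idx],
                    stringsAsFactors = FALSE)
  pm <- t(probs)
  colnames(pm) <- paste0("p_", object$classes)
  cbind(out, as.data.frame(pm))
}
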