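test_that("preprocessing pads with background, rescales to [0,1] and replicates channels", {
  # constant patch: constant output at value/255
  co <- structure(list(image = matrix(128L, 30, 30),
                       mask = matrix(1L, 30, 30), label = "x"),
                  class = "cutout")
  x <- preprocess(co, 32)
  expect_equal(dim(x), c(32, 32, 3))
  expect_true(all(abs(x - 128 / 255) < 1e-6))
  expect_identical(x[, , 1], x[, , 3])

  # rectangular patch: padded to square before resizing, object centred
  img <- matrix(60L, 40, 80)  # 40 rows x 80 cols
  mask <- matrix(1L, 40, 80)
  co2 <- structure(list(image = img, mask = mask, label = "x"), class = "cutout")
  x2 <- preprocess(co2, 224)
  expect_equal(dim(x2), c(224, 224, 3))
  # the 40x80 content occupies the central 112 rows after the 80x80 pad
  expect_true(all(abs(x2[57:168, , 1] - 60 / 255) < 2 / 255))

  # value range always within [0, 1]
  set.seed(2)
  co3 <- structure(list(image = matrix(as.integer(sample(0:255, 900, TRUE)), 30),
                        mask = matrix(rbinom(900, 1, 0.4), 30), label = "x"),
                   class = "cutout")
  x3 <- preprocess(co3, 64)
  expect_gte(min(x3), 0)
  expect_lte(max(x3), 1)
  expect_error(preprocess(matrix(numeric(0), 0, 0), 32), "zero-area")
})

test_that("augmentation is identity when disabled, seeded, and shape/range preserving", {
  set.seed(6)
  img <- array(runif(32 * 32), c(32, 32, 3))
  img[, , 2] <- img[, , 1]; img[, , 3] <- img[, , 1]
  expect_identical(augment(img, no_augmentation(), draw_seed = 3), img)

  cfg <- augmentation_config()
  a1 <- augment(img, cfg, draw_seed = 11)
  a2 <- augment(img, cfg, draw_seed = 11)
  expect_identical(a1, a2)
  expect_false(identical(a1, augment(img, cfg, draw_seed = 12)))
  expect_equal(dim(a1), dim(img))
  expect_gte(min(a1), 0)
  expect_lte(max(a1), 1)
})

test_that("classifier specs validate backbone/input-side combinations", {
  cs <- classifier_spec("tiny_cnn", n_classes = 4)
  expect_equal(cs$input_side, 32L)
  expect_false(cs$backbone_frozen)
  expect_true(classifier_spec("frozen_random_conv", n_classes = 3)$backbone_frozen)
  expect_error(classifier_spec("tiny_cnn", n_classes = 4, input_side = 224),
               "requires input_side")
  expect_error(classifier_spec("resnet", n_classes = 4), "unknown backbone")
  expect_error(classifier_spec("pretrained:vgg16", n_classes = 4,
                               input_side = 64), "224 or 299")
  expect_equal(classifier_spec("pretrained:vgg16", n_classes = 4)$input_side, 224L)
})

test_that("training separates a trivially separable two-class fixture", {
  items <- disc_bar_items(20)
  # separability oracle: a mean-intensity threshold classifies perfectly
  means <- vapply(items, function(it) mean(it$x), 0)
  labs <- vapply(items, `[[`, "", "label")
  thr <- mean(tapply(means, labs, mean))
  expect_equal(mean((means < thr) == (labs == "disc")), 1)

  cs <- classifier_spec("tiny_cnn", n_classes = 2, seed = 3)
  tc <- train_config(epochs = 50, batch_size = 8, seed = 3)
  m <- train_classifier(items, NULL, cs, no_augmentation(), tc)
  expect_equal(nrow(m$history), 50)
  expect_equal(m$history$accuracy[50], 1.0)
  pred <- predict(m, items)
  expect_equal(pred$predicted, labs)
  expect_equal(rowSums(pred[, c("p_bar", "p_disc")]), rep(1, 40),
               tolerance = 1e-6)
})

test_that("training is deterministic given seeds and respects the epoch contract", {
  items <- disc_bar_items(4)
  cs <- classifier_spec("tiny_cnn", n_classes = 2, seed = 9)
  tc <- train_config(epochs = 2, batch_size = 4, seed = 9)
  m1 <- train_classifier(items, items[1:4], cs, augmentation_config(), tc)
  m2 <- train_classifier(items, items[1:4], cs, augmentation_config(), tc)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)

  tc1 <- train_config(epochs = 1, batch_size = 4, seed = 9)
  expect_equal(nrow(train_classifier(items, NULL, cs, no_augmentation(),
                                     tc1)$history), 1)
})

test_that("frozen backbones are byte-identical before and after training", {
  items <- lapply(disc_bar_items(4, side = 64), function(it) it)
  cs <- classifier_spec("frozen_random_conv", n_classes = 2, seed = 5)
  init <- diatomslide:::build_network(cs)
  tc <- train_config(epochs = 2, batch_size = 4, seed = 5)
  m <- train_classifier(items, NULL, cs, no_augmentation(), tc)
  conv_idx <- which(vapply(init, `[[`, "", "type") == "conv")
  for (i in conv_idx) {
    expect_identical(m$layers[[i]]$W, init[[i]]$W)
    expect_identical(m$layers[[i]]$b, init[[i]]$b)
  }
  # the dense head, by contrast, must have moved
  dense_idx <- which(vapply(init, `[[`, "", "type") == "dense")[1]
  expect_false(identical(m$layers[[dense_idx]]$W, init[[dense_idx]]$W))
})

test_that("training and prediction validate their class-set contracts", {
  items <- disc_bar_items(3)
  one_class <- Filter(function(it) it$label == "disc", items)
  cs <- classifier_spec("tiny_cnn", n_classes = 2)
  expect_error(train_classifier(one_class, NULL, cs, no_augmentation(),
                                train_config(epochs = 1)), "single class")
  expect_error(train_classifier(items, NULL,
                                classifier_spec("tiny_cnn", n_classes = 5),
                                no_augmentation(), train_config(epochs = 1)),
               "expects 5 classes")
  expect_error(train_classifier(items, NULL,
                                classifier_spec("pretrained:vgg16", n_classes = 2),
                                no_augmentation(), train_config(epochs = 1)),
               "backbone_fn")
  m <- train_classifier(items, NULL, cs, no_augmentation(),
                        train_config(epochs = 1, batch_size = 4, seed = 1))
  expect_equal(nrow(predict(m, list())), 0)
})

test_that("analytic gradients match finite differences on a small network", {
  set.seed(14)
  layers <- list(diatomslide:::layer_conv(2, 3), diatomslide:::layer_relu(),
                 diatomslide:::layer_pool(), diatomslide:::layer_flatten(),
                 diatomslide:::layer_dense(4 * 4 * 3, 4))
  X <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  Y <- diatomslide:::onehot(c(1, 2, 4), 4)
  fw <- diatomslide:::network_forward(layers, X)
  ce <- diatomslide:::softmax_ce(fw$logits, Y)
  gr <- diatomslide:::network_backward(layers, fw$caches, ce$dLogits)
  eps <- 1e-5
  for (li in c(1, 5)) {
    for (t in 1:10) {
      i <- sample(length(layers[[li]]$W), 1)
      pert <- layers
      pert[[li]]$W[i] <- pert[[li]]$W[i] + eps
      lp <- diatomslide:::softmax_ce(
        diatomslide:::network_forward(pert, X, keep_cache = FALSE)$logits, Y)$loss
      expect_equal(gr[[li]]$dW[i], (lp - ce$loss) / eps, tolerance = 1e-2)
    }
  }
})
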