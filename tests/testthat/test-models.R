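tiny_spec <- function(side = 16L, k = 3L, attention = "cbam")
  classifier_spec("tiny_test", input_side = side, n_classes = k,
                  attention = attention)

test_that("classifier specs validate their fields", {
  expect_s3_class(tiny_spec(), "classifier_spec")
  expect_error(classifier_spec("resnet50"), class = "fundusdr_unknown_backbone")
  expect_error(classifier_spec("tiny_test", pretrained = TRUE),
               class = "fundusdr_unknown_backbone")
  # recognized architecture without a registered constructor
  expect_error(build_classifier(classifier_spec("inception_v3")),
               class = "fundusdr_unknown_backbone")
})

test_that("predicted probability rows sum to one", {
  clf <- build_classifier(tiny_spec(), seed = 5)
  withr::with_seed(601, {
    imgs <- replicate(7, random_grid(16, 16), simplify = FALSE)
  })
  p <- predict_proba(clf, imgs)
  expect_equal(dim(p), c(7L, 3L))
  expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))

  plain <- build_classifier(tiny_spec(attention = "none"), seed = 5)
  expect_equal(rowSums(predict_proba(plain, imgs)), rep(1, 7),
               tolerance = 1e-6)
})

test_that("the attention block preserves shape, bounds and zeros", {
  withr::with_seed(602, {
    for (dims in list(c(6, 6, 8), c(4, 10, 16), c(2, 5, 5, 4))) {
      x <- array(rnorm(prod(dims)), dim = dims)
      out <- attention_block(x, seed = 3)
      expect_identical(dim(out), dim(x))
      # both gates are sigmoids, so attenuation only
      expect_true(all(abs(out) <= abs(x) + 1e-12))
    }
  })
  z <- array(0, dim = c(5, 5, 8))
  expect_equal(attention_block(z, seed = 1), z)
})

test_that("analytic gradients match numerical differentiation", {
  clf <- build_classifier(tiny_spec(side = 8L), seed = 7)
  withr::with_seed(603, g <- array(runif(8 * 8 * 3) * 255, dim = c(8, 8, 3)))
  y <- 2L
  loss_of <- function(obj) {
    p <- fundusdr:::model_forward(obj, g)$p
    -log(p[y + 1])
  }
  fw <- fundusdr:::model_forward(clf, g)
  dlogits <- fw$p; dlogits[y + 1] <- dlogits[y + 1] - 1
  grads <- fundusdr:::model_backward(clf, fw, dlogits)
  eps <- 1e-5
  withr::with_seed(604, {
    for (nm in names(clf$params)) {
      idx <- sample(length(clf$params[[nm]]),
                    min(3, length(clf$params[[nm]])))
      for (i in idx) {
        plus <- clf; plus$params[[nm]][i] <- plus$params[[nm]][i] + eps
        minus <- clf; minus$params[[nm]][i] <- minus$params[[nm]][i] - eps
        num <- (loss_of(plus) - loss_of(minus)) / (2 * eps)
        expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
      }
    }
  })
})

test_that("phase 1 freezes the backbone bit-for-bit and training is seeded", {
  sep <- separable_images(n_per_class = 8, k = 3, side = 16)
  clf <- build_classifier(tiny_spec(), seed = 11)
  before <- clf$params
  cfg <- train_config(phase1_epochs = 2, phase2_epochs = 0, batch_size = 8,
                      lr_phase1 = 1e-2, seed = 2)
  t1 <- train_two_phase(clf, sep$images, sep$labels,
                        sep$images[1:6], sep$labels[1:6], cfg)
  for (nm in grep("^bb_", names(before), value = TRUE))
    expect_identical(t1$params[[nm]], before[[nm]])
  expect_false(identical(t1$params$hd_fc_w, before$hd_fc_w))

  # same seed, same trajectory
  t2 <- train_two_phase(clf, sep$images, sep$labels,
                        sep$images[1:6], sep$labels[1:6], cfg)
  expect_identical(t1$log$loss, t2$log$loss)
  expect_identical(t1$params$hd_fc_w, t2$params$hd_fc_w)

  # phase 2 updates the backbone too
  cfg2 <- train_config(phase1_epochs = 0, phase2_epochs = 1, batch_size = 8,
                       lr_phase2 = 1e-3, seed = 2)
  t3 <- train_two_phase(clf, sep$images, sep$labels,
                        sep$images[1:6], sep$labels[1:6], cfg2)
  expect_false(identical(t3$params$bb_conv1_w, before$bb_conv1_w))

  # zero epochs leave every weight untouched
  cfg0 <- train_config(phase1_epochs = 0, phase2_epochs = 0, seed = 2)
  t0 <- train_two_phase(clf, sep$images, sep$labels,
                        sep$images[1:6], sep$labels[1:6], cfg0)
  expect_identical(t0$params, before)

  expect_error(train_two_phase(clf, list(), integer(0), sep$images,
                               sep$labels, cfg),
               class = "fundusdr_empty_dataset")
})

test_that("class-weighted losses scale each example by its grade weight", {
  clf <- build_classifier(tiny_spec(), seed = 13)
  withr::with_seed(605,
    imgs <- replicate(6, random_grid(16, 16), simplify = FALSE))
  labels <- c(0L, 0L, 1L, 1L, 2L, 2L)
  w <- class_weights(c(rep(0L, 6), 1L, 1L, 2L), n_classes = 3L)
  plain <- classifier_loss(clf, imgs, labels)
  weighted <- classifier_loss(clf, imgs, labels, class_weights = w)
  wv <- w$weight[labels + 1L]
  expect_equal(weighted, plain * wv, tolerance = 1e-12)
  # minority example outweighs a majority example by exactly the ratio
  expect_equal(weighted[5] / plain[5], w$weight[3], tolerance = 1e-12)
})

test_that("the tiny backbone masters linearly separable images", {
  sep <- separable_images(n_per_class = 50, k = 3, side = 32)
  clf <- build_classifier(tiny_spec(side = 32L), seed = 3)
  cfg <- train_config(phase1_epochs = 8, phase2_epochs = 2, batch_size = 16,
                      lr_phase1 = 0.03, lr_phase2 = 0.003, seed = 5)
  hold <- seq(1, 150, by = 5)
  clf <- train_two_phase(clf, sep$images, sep$labels,
                         sep$images[hold], sep$labels[hold], cfg)
  p <- predict_proba(clf, sep$images)
  acc <- mean(max.col(p, ties.method = "first") - 1L == sep$labels)
  expect_gte(acc, 0.9)
  expect_gte(clf$validation_f1, 0.9)
  expect_equal(nrow(clf$log), 10)
})

test_that("classifiers save and load to an identical predictor", {
  clf <- build_classifier(tiny_spec(), seed = 17)
  withr::with_seed(606,
    imgs <- replicate(3, random_grid(16, 16), simplify = FALSE))
  dir <- withr::local_tempdir()
  save_classifier(clf, dir)
  expect_true(all(file.exists(file.path(dir, c("spec.json", "weights.rds")))))
  back <- load_classifier(dir)
  expect_equal(predict_proba(back, imgs), predict_proba(clf, imgs))
  expect_equal(back$spec, clf$spec)
})

test_that("user-registered backbones plug into the same contract", {
  register_backbone("inception_v3", function(input_side, pretrained) {
    # stand-in with the tiny architecture, to exercise the registry path
    fundusdr:::tiny_test_backbone(input_side, FALSE)
  })
  on.exit(rm("inception_v3", envir = fundusdr:::.backbones))
  clf <- build_classifier(classifier_spec("inception_v3", input_side = 16L,
                                          n_classes = 3L))
  withr::with_seed(607, img <- random_grid(16, 16))
  expect_equal(sum(predict_proba(clf, img)), 1, tolerance = 1e-6)
})
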