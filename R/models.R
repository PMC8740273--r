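# Backbone registry. A backbone is an opaque pluggable feature extractor:
# a constructor returning init/forward/backward closures plus its output
# channel count. The package ships `tiny_test`, a small convolutional
# backbone that trains in seconds on one CPU; the five large ImageNet
# architectures are recognised names a user can plug an implementation
# into with register_backbone().
.backbones <- new.env(parent = emptyenv())

KNOWN_BACKBONES <- c("inception_v3", "inception_resnet_v2", "xception",
                     "resnext101", "nasnet_large", "tiny_test")

#' Register a backbone constructor
#'
#' @param name Backbone name.
#' @param constructor A function `(input_side, pretrained)` returning a list
#'   with elements `out_channels` (integer), `init(seed)` (named parameter
#'   list, names prefixed `bb_`), `forward(x, params)` returning
#'   `list(out, cache)` for one `side x side x 3` input in `[0, 1]`, and
#'   `backward(dout, cache, params)` returning `list(grads)` (named like the
#'   parameters).
#' @return `name`, invisibly.
#' @export
register_backbone <- function(name, constructor) {
  stopifnot(is.character(name), is.function(constructor))
  .backbones[[name]] <- constructor
  invisible(name)
}

#' @rdname register_backbone
#' @export
backbone_names <- function() ls(.backbones)

tiny_test_backbone <- function(input_side, pretrained = FALSE) {
  if (pretrained)
    stop_fdr("unknown_backbone",
             "tiny_test has no pretrained weights; set pretrained = FALSE")
  c1 <- 8L; c2 <- 16L
  list(
    out_channels = c2,
    init = function(seed) {
      withr::with_seed(seed, list(
        bb_conv1_w = array(rnorm(3 * 3 * 3 * c1, sd = sqrt(2 / 27)),
                           dim = c(3, 3, 3, c1)),
        bb_conv1_b = numeric(c1),
        bb_conv2_w = array(rnorm(3 * 3 * c1 * c2, sd = sqrt(2 / (9 * c1))),
                           dim = c(3, 3, c1, c2)),
        bb_conv2_b = numeric(c2)
      ))
    },
    forward = function(x, params) {
      cv1 <- conv_forward(x, params$bb_conv1_w, params$bb_conv1_b)
      r1 <- relu(cv1$out)
      p1 <- avgpool2_forward(r1)
      cv2 <- conv_forward(p1$out, params$bb_conv2_w, params$bb_conv2_b)
      r2 <- relu(cv2$out)
      p2 <- avgpool2_forward(r2)
      list(out = p2$out,
           cache = list(cv1 = cv1, r1 = r1, p1 = p1, cv2 = cv2, r2 = r2,
                        p2 = p2))
    },
    backward = function(dout, cache, params) {
      d2 <- avgpool2_backward(dout, cache$p2$cache)
      d2 <- d2 * (cache$cv2$out > 0)
      cb2 <- conv_backward(d2, cache$cv2$cache, params$bb_conv2_w)
      d1 <- avgpool2_backward(cb2$dx, cache$p1$cache)
      d1 <- d1 * (cache$cv1$out > 0)
      cb1 <- conv_backward(d1, cache$cv1$cache, params$bb_conv1_w)
      list(grads = list(bb_conv1_w = cb1$dw, bb_conv1_b = cb1$db,
                        bb_conv2_w = cb2$dw, bb_conv2_b = cb2$db))
    }
  )
}

ensure_builtin_backbones <- function() {
  if (is.null(.backbones[["tiny_test"]]))
    register_backbone("tiny_test", tiny_test_backbone)
}

#' Specify a base classifier
#'
#' A classifier is a backbone feature extractor without its top, followed
#' by an optional channel-and-spatial attention block, global average
#' pooling and a dense softmax head over the severity grades.
#'
#' @param backbone One of `inception_v3`, `inception_resnet_v2`, `xception`,
#'   `resnext101`, `nasnet_large`, `tiny_test`. Only `tiny_test` is built
#'   in; the large ImageNet architectures must be plugged in with
#'   [register_backbone()].
#' @param input_side Input image side length in pixels (default 299).
#' @param n_classes Number of output grades (default 5).
#' @param attention `"cbam"` (default) for the attention block, `"none"` to
#'   omit it.
#' @param pretrained Whether the backbone should load pretrained weights
#'   (must be `FALSE` for `tiny_test`).
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(backbone = "tiny_test", input_side = 299L,
                            n_classes = 5L, attention = c("cbam", "none"),
                            pretrained = FALSE) {
  attention <- match.arg(attention)
  stopifnot(n_classes >= 2L, input_side >= 8L)
  if (!backbone %in% KNOWN_BACKBONES)
    stop_fdr("unknown_backbone",
             sprintf("unknown backbone '%s'; known: %s", backbone,
                     paste(KNOWN_BACKBONES, collapse = ", ")))
  if (backbone == "tiny_test" && pretrained)
    stop_fdr("unknown_backbone", "tiny_test has no pretrained weights")
  structure(list(backbone = backbone, input_side = as.integer(input_side),
                 n_classes = as.integer(n_classes), attention = attention,
                 pretrained = pretrained),
            class = "classifier_spec")
}

#' Build an untrained classifier from a spec
#'
#' Instantiates the backbone from the registry, attaches the attention
#' block (when requested) and the global-average-pooling + dense softmax
#' head, and initializes all weights under `seed`.
#'
#' @param spec A [classifier_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `dr_classifier`.
#' @section Errors: `fundusdr_unknown_backbone` when the backbone has no
#'   registered constructor.
#' @export
build_classifier <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "classifier_spec"))
  ensure_builtin_backbones()
  ctor <- .backbones[[spec$backbone]]
  if (is.null(ctor))
    stop_fdr("unknown_backbone", sprintf(
      "backbone '%s' has no registered constructor; see register_backbone()",
      spec$backbone))
  bb <- ctor(spec$input_side, spec$pretrained)
  params <- bb$init(seed)
  cc <- bb$out_channels
  if (spec$attention == "cbam")
    params <- c(params, cbam_init(cc, seed = seed + 1L))
  params <- c(params, withr::with_seed(seed + 2L, list(
    hd_fc_w = matrix(rnorm(cc * spec$n_classes, sd = sqrt(1 / cc)),
                     cc, spec$n_classes),
    hd_fc_b = numeric(spec$n_classes)
  )))
  structure(list(spec = spec, backbone = bb, params = params,
                 trained = FALSE, validation_f1 = NA_real_,
                 log = tibble::tibble()),
            class = "dr_classifier")
}

# full forward pass for one pixel grid; returns probabilities and caches
model_forward <- function(object, grid) {
  x <- grid / 255
  bb <- object$backbone$forward(x, object$params)
  feat <- bb$out
  at <- NULL
  if (object$spec$attention == "cbam") {
    at <- cbam_forward(feat, object$params)
    feat <- at$out
  }
  d <- dim(feat); hw <- d[1] * d[2]
  f <- colMeans(matrix(feat, hw, d[3]))
  logits <- drop(f %*% object$params$hd_fc_w) + object$params$hd_fc_b
  z <- logits - max(logits)
  p <- exp(z) / sum(exp(z))
  list(p = p, f = f, feat_dim = d, bb = bb, at = at)
}

# backward from dlogits; returns named gradient list
model_backward <- function(object, fw, dlogits) {
  grads <- list(hd_fc_w = outer(fw$f, dlogits), hd_fc_b = dlogits)
  df <- drop(dlogits %*% t(object$params$hd_fc_w))
  d <- fw$feat_dim; hw <- d[1] * d[2]
  dfeat <- array(rep(df / hw, each = hw), dim = d)
  if (!is.null(fw$at)) {
    cb <- cbam_backward(dfeat, fw$at$cache, object$params)
    grads <- c(grads, cb$grads)
    dfeat <- cb$dx
  }
  bbg <- object$backbone$backward(dfeat, fw$bb$cache, object$params)
  c(grads, bbg$grads)
}

#' Predicted class probabilities
#'
#' @param object A `dr_classifier`.
#' @param images A list of pixel grids (or a single grid) of the spec's
#'   input side.
#' @return A samples x classes matrix; each row sums to 1.
#' @export
predict_proba <- function(object, images) {
  stopifnot(inherits(object, "dr_classifier"))
  if (!is.list(images)) images <- list(images)
  out <- t(vapply(images, function(g) model_forward(object, g)$p,
                  numeric(object$spec$n_classes)))
  matrix(out, nrow = length(images))
}

#' Per-example cross-entropy loss
#'
#' Weighted negative log-likelihood of the true grade: an example of grade
#' y contributes `weight[y] * -log p(y)`, so a minority-grade sample with
#' weight w contributes exactly w times what it would unweighted.
#'
#' @inheritParams predict_proba
#' @param labels Integer grades `0 .. n_classes - 1`.
#' @param class_weights Optional [class_weights()] tibble (or numeric vector
#'   indexed by grade + 1); default all 1.
#' @return Numeric vector of per-example losses.
#' @export
classifier_loss <- function(object, images, labels, class_weights = NULL) {
  p <- predict_proba(object, images)
  w <- weights_vector(class_weights, object$spec$n_classes)
  labels <- as.integer(labels)
  w[labels + 1L] * -log(pmax(p[cbind(seq_along(labels), labels + 1L)], 1e-12))
}

weights_vector <- function(class_weights, k) {
  if (is.null(class_weights)) return(rep(1, k))
  if (is.data.frame(class_weights)) {
    w <- rep(1, k)
    w[class_weights$grade + 1L] <- class_weights$weight
    w
  } else as.numeric(class_weights)
}

#' Training configuration for the two-phase schedule
#'
#' Phase 1 trains only the added top (attention block + head) with the
#' backbone frozen; phase 2 unfreezes everything and retrains at a lower
#' rate. The optimizer is Adam. None of these values is prescribed by the
#' classifier contract; all are exposed here.
#'
#' @param phase1_epochs,phase2_epochs Epoch counts (default 5 and 3).
#' @param batch_size Minibatch size (default 16).
#' @param lr_phase1,lr_phase2 Learning rates (defaults 1e-3 and 1e-5).
#' @param class_weights Optional [class_weights()] tibble applied to the
#'   loss.
#' @param seed Integer seed controlling shuffling; with the same seed the
#'   loss trajectory is reproducible.
#' @return A list of class `train_config`.
#' @export
train_config <- function(phase1_epochs = 5L, phase2_epochs = 3L,
                         batch_size = 16L, lr_phase1 = 1e-3,
                         lr_phase2 = 1e-5, class_weights = NULL, seed = 1L) {
  stopifnot(phase1_epochs >= 0L, phase2_epochs >= 0L, batch_size >= 1L)
  structure(list(phase1_epochs = as.integer(phase1_epochs),
                 phase2_epochs = as.integer(phase2_epochs),
                 batch_size = as.integer(batch_size),
                 lr_phase1 = lr_phase1, lr_phase2 = lr_phase2,
                 class_weights = class_weights, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a classifier with the freeze-then-fine-tune schedule
#'
#' Phase 1 updates only the attention-block and head parameters (backbone
#' parameters are bit-identical before and after); phase 2 updates all
#' parameters. After phase 2 the validation macro-F1 is recorded: it is the
#' score the ensemble weights are later derived from.
#'
#' @param object A `dr_classifier` from [build_classifier()].
#' @param train_images,valid_images Lists of pixel grids.
#' @param train_labels,valid_labels Integer grades.
#' @param config A [train_config()].
#' @return The trained `dr_classifier`, with `validation_f1` set and a
#'   training `log` tibble (`epoch`, `phase`, `loss`, `val_macro_f1`).
#' @section Errors: `fundusdr_empty_dataset` for empty inputs.
#' @export
train_two_phase <- function(object, train_images, train_labels,
                            valid_images, valid_labels,
                            config = train_config()) {
  stopifnot(inherits(object, "dr_classifier"),
            inherits(config, "train_config"))
  if (length(train_images) == 0L || length(valid_images) == 0L)
    stop_fdr("empty_dataset", "training and validation sets must be non-empty")
  stopifnot(length(train_images) == length(train_labels))
  labels <- as.integer(train_labels)
  w <- weights_vector(config$class_weights, object$spec$n_classes)

  top <- grep("^(at|hd)_", names(object$params), value = TRUE)
  log <- list()
  epoch_global <- 0L
  withr::with_seed(config$seed, {
    for (phase in 1:2) {
      n_ep <- if (phase == 1L) config$phase1_epochs else config$phase2_epochs
      lr <- if (phase == 1L) config$lr_phase1 else config$lr_phase2
      subset <- if (phase == 1L) top else names(object$params)
      if (n_ep == 0L) next
      state <- adam_init(object$params)
      for (ep in seq_len(n_ep)) {
        ord <- sample(length(train_images))
        ep_loss <- 0
        for (start in seq(1L, length(ord), by = config$batch_size)) {
          batch <- ord[start:min(start + config$batch_size - 1L, length(ord))]
          grads <- NULL
          for (i in batch) {
            fw <- model_forward(object, train_images[[i]])
            y <- labels[i] + 1L
            ep_loss <- ep_loss + w[y] * -log(max(fw$p[y], 1e-12))
            dlogits <- w[y] * fw$p
            dlogits[y] <- dlogits[y] - w[y]
            g <- model_backward(object, fw, dlogits)
            grads <- if (is.null(grads)) g else
              purrr::map2(grads, g[names(grads)], `+`)
          }
          grads <- purrr::map(grads, ~ .x / length(batch))
          upd <- adam_step(object$params, grads, state, lr, subset = subset)
          object$params <- upd$params
          state <- upd$state
        }
        epoch_global <- epoch_global + 1L
        log[[epoch_global]] <- tibble::tibble(
          epoch = epoch_global, phase = phase,
          loss = ep_loss / length(ord), val_macro_f1 = NA_real_)
      }
    }
  })
  prob <- predict_proba(object, valid_images)
  pred <- max.col(prob, ties.method = "first") - 1L
  cm <- confusion_matrix(valid_labels, pred, object$spec$n_classes)
  object$validation_f1 <- mean(per_class_scores(cm)$f1)
  if (length(log)) {
    log[[length(log)]]$val_macro_f1 <- object$validation_f1
    object$log <- dplyr::bind_rows(log)
  }
  object$trained <- TRUE
  object
}

#' Apply a channel-and-spatial attention block
#'
#' Standalone access to the attention operation used inside classifiers:
#' channel gating (shared two-layer bottleneck over spatial mean- and
#' max-pooled descriptors, sigmoid) followed by spatial gating (7x7
#' convolution over the channel mean and max maps, sigmoid). Gates lie in
#' (0, 1), so the output never exceeds the input in magnitude and has the
#' same shape; zero input maps to zero output.
#'
#' @param features A `H x W x C` feature map or an `N x H x W x C` batch.
#' @param params Optional parameter list from `cbam_init`; initialized
#'   under `seed` when omitted.
#' @param seed Integer seed for the default initialization.
#' @return An array of the same shape as `features`.
#' @export
attention_block <- function(features, params = NULL, seed = 1L) {
  d <- dim(features)
  stopifnot(length(d) %in% c(3L, 4L))
  batched <- length(d) == 4L
  cc <- d[length(d)]
  params <- params %||% cbam_init(cc, seed = seed)
  apply_one <- function(x) cbam_forward(x, params)$out
  if (!batched) return(apply_one(features))
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) out[i, , , ] <- apply_one(
    array(features[i, , , ], dim = d[-1]))
  out
}

#' Save or load a classifier
#'
#' The directory layout is `spec.json` (the [classifier_spec()] fields,
#' training state and validation F1) plus `weights.rds` (the parameter
#' list) and `log.csv` (the training log).
#'
#' @param object A `dr_classifier`.
#' @param dir Directory path.
#' @return `save_classifier()` returns `dir` invisibly; `load_classifier()`
#'   returns the restored `dr_classifier`.
#' @export
save_classifier <- function(object, dir) {
  stopifnot(inherits(object, "dr_classifier"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    c(object$spec[], list(trained = object$trained,
                          validation_f1 = object$validation_f1)),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  saveRDS(object$params, file.path(dir, "weights.rds"))
  if (nrow(object$log)) readr::write_csv(object$log, file.path(dir, "log.csv"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"))
  spec <- classifier_spec(meta$backbone, meta$input_side, meta$n_classes,
                          meta$attention, isTRUE(meta$pretrained))
  obj <- build_classifier(spec, seed = 1L)
  obj$params <- readRDS(file.path(dir, "weights.rds"))
  obj$trained <- isTRUE(meta$trained)
  obj$validation_f1 <- meta$validation_f1 %||% NA_real_
  log_path <- file.path(dir, "log.csv")
  if (file.exists(log_path))
    obj$log <- readr::read_csv(log_path, show_col_types = FALSE)
  obj
}

#' @export
print.dr_classifier <- function(x, ...) {
  cat(sprintf("<dr_classifier: %s, side %d, %d classes, attention %s, %s>\n",
              x$spec$backbone, x$spec$input_side, x$spec$n_classes,
              x$spec$attention,
              if (x$trained) sprintf("trained (val macro-F1 %.3f)",
                                     x$validation_f1) else "untrained"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.dr_classifier <- function(x, ...) x$log

#' @exportS3Method generics::glance
glance.dr_classifier <- function(x, ...) {
  tibble::tibble(backbone = x$spec$backbone,
                 input_side = x$spec$input_side,
                 n_classes = x$spec$n_classes,
                 attention = x$spec$attention,
                 n_parameters = sum(purrr::map_int(x$params, length)),
                 trained = x$trained,
                 validation_f1 = x$validation_f1)
}
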