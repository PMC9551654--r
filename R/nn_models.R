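# Standard CNN classifier architectures, defined as layer graphs on the
# package's engine. Layer shapes follow the canonical published designs, so
# parameter counts at 1000-class output match the reference values
# (VGG16: 138,357,544; MobileNetV2: 3,504,872; AlexNet: 61,100,840).

# Channel rounding used throughout MobileNetV2: nearest multiple of
# `divisor`, never below `divisor`, never more than 10% below the target.
make_divisible <- function(v, divisor = 8, min_value = NULL) {
  if (is.null(min_value)) min_value <- divisor
  new_v <- max(min_value, (floor(v + divisor / 2) %/% divisor) * divisor)
  if (new_v < 0.9 * v) new_v <- new_v + divisor
  as.integer(new_v)
}

conv_bn_act <- function(in_ch, out_ch, k = 3, stride = 1, depthwise = FALSE,
                        act = "relu6") {
  list(layer_conv(in_ch, out_ch, k, stride = stride, pad = (k - 1L) %/% 2L,
                  depthwise = depthwise, bias = FALSE),
       layer_bn(out_ch),
       layer_act(act))
}

inverted_residual <- function(in_ch, out_ch, stride, expand) {
  hidden <- as.integer(round(in_ch * expand))
  layers <- list()
  if (expand != 1) layers <- c(layers, conv_bn_act(in_ch, hidden, k = 1))
  layers <- c(layers,
              conv_bn_act(hidden, hidden, k = 3, stride = stride, depthwise = TRUE),
              list(layer_conv(hidden, out_ch, 1, bias = FALSE),
                   layer_bn(out_ch)))
  residual <- stride == 1 && in_ch == out_ch
  if (residual) {
    # zero-init the projection BN scale so the block starts as identity;
    # stabilizes from-scratch small-batch training of the deep stack
    layers[[length(layers)]]$gamma <- numeric(out_ch)
  }
  layer_block(layers, residual = residual)
}

arch_mobilenetv2 <- function(num_classes, width_mult = 1, dropout = 0.2) {
  input_channel <- make_divisible(32 * width_mult)
  last_channel <- make_divisible(1280 * max(1, width_mult))
  cfg <- list(c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
              c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))
  layers <- conv_bn_act(3, input_channel, k = 3, stride = 2)
  for (s in cfg) {
    out <- make_divisible(s[2] * width_mult)
    for (i in seq_len(s[3])) {
      layers <- c(layers, list(inverted_residual(
        input_channel, out, stride = if (i == 1) s[4] else 1, expand = s[1])))
      input_channel <- out
    }
  }
  c(layers,
    conv_bn_act(input_channel, last_channel, k = 1),
    list(layer_adaptive_avgpool(1), layer_flatten(),
         layer_dropout(dropout), layer_dense(last_channel, num_classes)))
}

arch_vgg16 <- function(num_classes, input_size = 224, dropout = 0.5) {
  cfg <- c(64, 64, NA, 128, 128, NA, 256, 256, 256, NA,
           512, 512, 512, NA, 512, 512, 512, NA)
  layers <- list()
  in_ch <- 3L
  for (v in cfg) {
    if (is.na(v)) {
      layers <- c(layers, list(layer_maxpool(2, 2)))
    } else {
      layers <- c(layers, list(layer_conv(in_ch, v, 3, pad = 1),
                               layer_act("relu")))
      in_ch <- as.integer(v)
    }
  }
  c(layers,
    list(layer_adaptive_avgpool(7), layer_flatten(),
         layer_dense(512L * 49L, 4096L), layer_act("relu"), layer_dropout(dropout),
         layer_dense(4096L, 4096L), layer_act("relu"), layer_dropout(dropout),
         layer_dense(4096L, num_classes)))
}

arch_alexnet <- function(num_classes, dropout = 0.5) {
  list(layer_conv(3, 64, 11, stride = 4, pad = 2), layer_act("relu"),
       layer_maxpool(3, 2),
       layer_conv(64, 192, 5, pad = 2), layer_act("relu"),
       layer_maxpool(3, 2),
       layer_conv(192, 384, 3, pad = 1), layer_act("relu"),
       layer_conv(384, 256, 3, pad = 1), layer_act("relu"),
       layer_conv(256, 256, 3, pad = 1), layer_act("relu"),
       layer_maxpool(3, 2),
       layer_adaptive_avgpool(6), layer_flatten(),
       layer_dropout(dropout), layer_dense(256L * 36L, 4096L), layer_act("relu"),
       layer_dropout(dropout), layer_dense(4096L, 4096L), layer_act("relu"),
       layer_dense(4096L, num_classes))
}

#' Build a CNN classifier
#'
#' Constructs one of the supported architectures with the final classifier
#' sized to `num_classes` and freshly initialized (He-normal) weights. Seed
#' the RNG before calling for reproducible initialization. `width_mult`
#' (MobileNetV2 only) scales channel counts, which together with a reduced
#' `input_size` at training time gives desk-scale variants of the same
#' architecture.
#'
#' @param name One of `"alexnet"`, `"vgg16"`, `"mobilenetv2"`.
#' @param num_classes Output classes (default 4 lodging degrees).
#' @param input_size Expected square input edge, pixels (default 224); any
#'   size compatible with the architecture's strides is accepted at forward
#'   time thanks to adaptive pooling.
#' @param width_mult Channel width multiplier for MobileNetV2.
#' @return An `lp_model` handle (mutable environment).
#' @export
build_model <- function(name = c("mobilenetv2", "alexnet", "vgg16"),
                        num_classes = 4L, input_size = 224L, width_mult = 1) {
  name <- match.arg(name)
  num_classes <- as.integer(num_classes)
  layers <- switch(name,
    mobilenetv2 = arch_mobilenetv2(num_classes, width_mult),
    vgg16 = arch_vgg16(num_classes),
    alexnet = arch_alexnet(num_classes))
  model <- new.env(parent = emptyenv())
  model$layers <- layers
  model$name <- name
  model$num_classes <- num_classes
  model$input_size <- as.integer(input_size)
  model$width_mult <- width_mult
  model$adam_t <- 0L
  class(model) <- "lp_model"
  model
}

#' @export
print.lp_model <- function(x, ...) {
  cat(sprintf("<lp_model %s: %s classes, input %dx%dx3, %s parameters>\n",
              x$name, x$num_classes, x$input_size, x$input_size,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Softmax over class logits
#'
#' Numerically stable (max-subtracted) softmax mapping logits to a
#' probability distribution; invariant to adding a constant to all logits.
#'
#' @param logits Numeric vector (one sample) or matrix `C x N`.
#' @return Probabilities of the same shape, each column summing to 1.
#' @export
softmax <- function(logits) {
  if (any(!is.finite(logits))) rlang::abort("logits must be finite")
  if (is.matrix(logits)) {
    z <- sweep(logits, 2, apply(logits, 2, max))
    e <- exp(z)
    sweep(e, 2, colSums(e), "/")
  } else {
    if (length(logits) < 2) rlang::abort("need at least 2 classes")
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

#' Class probabilities for a batch of images
#'
#' @param model An `lp_model`.
#' @param images List of `H x W x 3` arrays (values already normalized).
#' @param batch_size Forward-pass batch size.
#' @return Matrix `length(images) x num_classes` of softmax probabilities.
#' @export
predict_proba <- function(model, images, batch_size = 16L) {
  n <- length(images)
  out <- matrix(NA_real_, n, model$num_classes)
  for (lo in seq(1L, n, by = batch_size)) {
    hi <- min(n, lo + batch_size - 1L)
    x <- batch_images(images[lo:hi])
    logits <- model_forward(model, x, training = FALSE)
    out[lo:hi, ] <- t(softmax(logits))
  }
  out
}

batch_images <- function(imgs) {
  d <- dim(imgs[[1]])
  x <- array(0, c(d[1], d[2], d[3], length(imgs)))
  for (i in seq_along(imgs)) x[, , , i] <- imgs[[i]]
  x
}
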