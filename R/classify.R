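# Image dataset handling and CNN training/evaluation for the four lodging
# degrees. An image sample set is a tibble with list-column `image`
# (H x W x 3 arrays), factor `label`, `source_plot` and `augmented`.

#' Elementary image operations
#'
#' 90/270-degree rotations and horizontal/vertical flips of `H x W x 3`
#' arrays; the augmentation vocabulary. Flips are involutions and
#' `img_rot90` / `img_rot270` are mutual inverses.
#'
#' @param img Numeric array `H x W x 3`.
#' @return Transformed array.
#' @export
img_rot90 <- function(img) {
  aperm(img, c(2, 1, 3))[dim(img)[2]:1, , , drop = FALSE]
}

#' @rdname img_rot90
#' @export
img_rot270 <- function(img) {
  aperm(img, c(2, 1, 3))[, dim(img)[1]:1, , drop = FALSE]
}

#' @rdname img_rot90
#' @export
img_flip_h <- function(img) img[, dim(img)[2]:1, , drop = FALSE]

#' @rdname img_rot90
#' @export
img_flip_v <- function(img) img[dim(img)[1]:1, , , drop = FALSE]

#' Bilinear resize of an image array
#'
#' @param img Array `H x W x C`.
#' @param out_h,out_w Output size in pixels.
#' @return Resized `out_h x out_w x C` array.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  sample_axis <- function(n_in, n_out) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    src <- pmin(pmax(src, 1), n_in)
    i0 <- pmin(floor(src), n_in - 1L); i0[n_in == 1] <- 1
    list(i0 = i0, i1 = pmin(i0 + 1, n_in), t = src - i0)
  }
  ah <- sample_axis(d[1], out_h); aw <- sample_axis(d[2], out_w)
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) {
    m <- img[, , ch]
    top <- m[ah$i0, aw$i0, drop = FALSE] * (1 - aw$t)[col(matrix(0, out_h, out_w))] +
      m[ah$i0, aw$i1, drop = FALSE] * aw$t[col(matrix(0, out_h, out_w))]
    bot <- m[ah$i1, aw$i0, drop = FALSE] * (1 - aw$t)[col(matrix(0, out_h, out_w))] +
      m[ah$i1, aw$i1, drop = FALSE] * aw$t[col(matrix(0, out_h, out_w))]
    out[, , ch] <- top * (1 - ah$t) + bot * ah$t
  }
  out
}

#' Normalize image channels for network input
#'
#' Standard image-network channel normalization `(x - mean) / sd` with the
#' conventional RGB statistics.
#'
#' @param img Array `H x W x 3` in \[0, 1\].
#' @return Normalized array.
#' @export
normalize_channels <- function(img,
                               mean = c(0.485, 0.456, 0.406),
                               sd = c(0.229, 0.224, 0.225)) {
  for (ch in 1:3) img[, , ch] <- (img[, , ch] - mean[ch]) / sd[ch]
  img
}

#' Turn a height raster into a labelled image sample
#'
#' Renders the raster to RGB, resizes to a square network input with
#' bilinear resampling, and normalizes channels.
#'
#' @param raster An `lp_raster`.
#' @param label Class label.
#' @param source_plot Plot identifier.
#' @param size Square output edge, pixels.
#' @param z_min,z_max,colormap Passed to [render_image()].
#' @return One-row image-sample tibble.
#' @export
raster_to_sample <- function(raster, label, source_plot = NA_integer_,
                             size = 224L, z_min = 0, z_max = 1.2,
                             colormap = "viridis") {
  img <- render_image(raster, z_min, z_max, colormap)
  img <- resize_bilinear(img, size, size)
  tibble::tibble(image = list(normalize_channels(img)),
                 label = label, source_plot = source_plot, augmented = FALSE)
}

#' Augment an image sample set to a target size
#'
#' Keeps the originals and appends seeded random augmentations — one of
#' rotation by 90 or 270 degrees, horizontal flip, or vertical (mirror)
#' flip — of seeded randomly chosen source images until the set reaches
#' `target_total`. Labels and source plots are inherited; augmented rows
#' are flagged.
#'
#' @param samples Image-sample tibble (non-empty).
#' @param target_total Desired total count (>= nrow(samples)).
#' @param seed Integer seed.
#' @return Augmented sample tibble with `target_total` rows.
#' @export
augment_dataset <- function(samples, target_total, seed = 1L) {
  samples <- tibble::as_tibble(samples)
  n <- nrow(samples)
  if (n == 0) rlang::abort("cannot augment an empty sample set")
  if (target_total < n) rlang::abort("target_total must be >= number of originals")
  n_add <- target_total - n
  if (n_add == 0) return(samples)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  src <- sample.int(n, n_add, replace = TRUE)
  op <- sample(c("rot90", "rot270", "flip_h", "flip_v"), n_add, replace = TRUE)
  fns <- list(rot90 = img_rot90, rot270 = img_rot270,
              flip_h = img_flip_h, flip_v = img_flip_v)
  extra <- samples[src, ]
  extra$image <- purrr::map2(extra$image, op, ~ fns[[.y]](.x))
  extra$augmented <- TRUE
  dplyr::bind_rows(samples, extra)
}

# Largest-remainder apportionment of n into parts proportional to ratio.
largest_remainder <- function(n, ratio) {
  quota <- n * ratio / sum(ratio)
  base <- floor(quota)
  short <- n - sum(base)
  if (short > 0) {
    add <- order(quota - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Split an image dataset into train / validation / test
#'
#' Seeded, stratified-by-class shuffle into three disjoint parts whose
#' sizes follow `ratio` with largest-remainder rounding (1,000 samples at
#' 16:4:5 give 640 / 160 / 200). Per-class allocations are also
#' largest-remainder, then nudged minimally so the global sizes are exact.
#'
#' @param samples Image-sample tibble with a `label` column (>= 25 rows for
#'   the default ratio).
#' @param ratio Length-3 positive weights (default `c(16, 4, 5)`).
#' @param seed Integer seed.
#' @return Named list of tibbles `train`, `validation`, `test`.
#' @export
split_dataset <- function(samples, ratio = c(16, 4, 5), seed = 1L) {
  samples <- tibble::as_tibble(samples)
  stopifnot("label" %in% names(samples), length(ratio) == 3, all(ratio > 0))
  n <- nrow(samples)
  if (n < sum(ratio)) {
    rlang::abort(sprintf("need at least %d samples for a %s split",
                         sum(ratio), paste(ratio, collapse = ":")))
  }
  target <- largest_remainder(n, ratio)
  labs <- as.character(samples$label)
  classes <- sort(unique(labs))
  alloc <- t(vapply(classes, function(cl) largest_remainder(sum(labs == cl), ratio),
                    integer(3)))
  # reconcile per-class roundings with the exact global sizes
  for (iter in seq_len(1000)) {
    dev <- colSums(alloc) - target
    if (all(dev == 0)) break
    s_over <- which.max(dev); s_under <- which.min(dev)
    cand <- which(alloc[, s_over] > 0)
    cl <- cand[which.max(alloc[cand, s_over])]
    alloc[cl, s_over] <- alloc[cl, s_over] - 1L
    alloc[cl, s_under] <- alloc[cl, s_under] + 1L
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  parts <- list(integer(0), integer(0), integer(0))
  for (ci in seq_along(classes)) {
    idx <- sample(which(labs == classes[ci]))
    a <- alloc[ci, ]
    parts[[1]] <- c(parts[[1]], idx[seq_len(a[1])])
    parts[[2]] <- c(parts[[2]], idx[a[1] + seq_len(a[2])])
    parts[[3]] <- c(parts[[3]], idx[a[1] + a[2] + seq_len(a[3])])
  }
  list(train = samples[sort(parts[[1]]), ],
       validation = samples[sort(parts[[2]]), ],
       test = samples[sort(parts[[3]]), ])
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam at learning rate 0.001,
#' batch size 4, up to 400 epochs with early stopping once validation
#' accuracy has not improved for 30 consecutive epochs. `input_size` and
#' `width_mult` give desk-scale variants for CPU runs.
#'
#' @param model_name One of `"alexnet"`, `"vgg16"`, `"mobilenetv2"`.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience, epochs.
#' @param seed Integer seed covering initialization, shuffling and dropout.
#' @param input_size Square input edge the images are assumed to have.
#' @param width_mult MobileNetV2 channel multiplier.
#' @return An `lp_train_config` list.
#' @export
train_config <- function(model_name = "mobilenetv2", learning_rate = 0.001,
                         batch_size = 4L, max_epochs = 400L, patience = 30L,
                         seed = 1L, input_size = 224L, width_mult = 1) {
  stopifnot(learning_rate >= 0, batch_size >= 1, max_epochs >= 1, patience >= 1)
  structure(list(model_name = model_name, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 input_size = as.integer(input_size), width_mult = width_mult),
            class = "lp_train_config")
}

cross_entropy <- function(probs, y_idx) {
  -mean(log(pmax(probs[cbind(y_idx, seq_along(y_idx))], 1e-12)))
}

#' Train a CNN on an image dataset
#'
#' Minibatch Adam with cross-entropy loss; per-epoch validation; early
#' stopping on validation accuracy (ties keep the earlier epoch) with
#' best-validation weights restored at the end. Fully deterministic for a
#' fixed config.
#'
#' @param train,validation Image-sample tibbles (non-empty).
#' @param cfg An [lp_train_config][train_config()].
#' @param model Optionally a pre-built [build_model()] handle; by default
#'   one is built from `cfg`.
#' @return List with `model` (best weights) and `history` (tibble of
#'   per-epoch train/validation loss and accuracy).
#' @export
train_model <- function(train, validation, cfg = train_config(), model = NULL) {
  if (nrow(train) == 0 || nrow(validation) == 0) {
    rlang::abort("train and validation sets must be non-empty")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  levels_all <- levels(factor(train$label))
  if (is.null(model)) {
    model <- build_model(cfg$model_name, num_classes = length(levels_all),
                         input_size = cfg$input_size, width_mult = cfg$width_mult)
  }
  adam_init(model)
  y_train <- as.integer(factor(train$label, levels = levels_all))
  y_val <- as.integer(factor(validation$label, levels = levels_all))
  n <- nrow(train)
  history <- list()
  best_acc <- -Inf; best_state <- NULL; best_epoch <- 0L; stale <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_hits <- 0
    for (lo in seq(1L, n, by = cfg$batch_size)) {
      sel <- ord[lo:min(n, lo + cfg$batch_size - 1L)]
      x <- batch_images(train$image[sel])
      logits <- model_forward(model, x, training = TRUE)
      probs <- softmax(logits)
      ep_loss <- ep_loss + cross_entropy(probs, y_train[sel]) * length(sel)
      ep_hits <- ep_hits + sum(max.col(t(probs)) == y_train[sel])
      grad <- probs
      grad[cbind(y_train[sel], seq_along(sel))] <-
        grad[cbind(y_train[sel], seq_along(sel))] - 1
      model_backward(model, grad / length(sel))
      adam_step(model, lr = cfg$learning_rate)
    }
    val <- evaluate_batchwise(model, validation$image, y_val, cfg$batch_size)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = ep_loss / n, train_acc = ep_hits / n,
      val_loss = val$loss, val_acc = val$acc)
    if (val$acc > best_acc) {
      best_acc <- val$acc; best_state <- model_state(model)
      best_epoch <- epoch; stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= cfg$patience) break
    }
  }
  if (!is.null(best_state)) model_restore(model, best_state)
  model$best_epoch <- best_epoch
  model$class_levels <- levels_all
  list(model = model, history = dplyr::bind_rows(history))
}

evaluate_batchwise <- function(model, images, y_idx, batch_size = 16L) {
  n <- length(images)
  loss <- 0; hits <- 0
  for (lo in seq(1L, n, by = batch_size)) {
    sel <- lo:min(n, lo + batch_size - 1L)
    x <- batch_images(images[sel])
    probs <- softmax(model_forward(model, x, training = FALSE))
    loss <- loss + cross_entropy(probs, y_idx[sel]) * length(sel)
    hits <- hits + sum(max.col(t(probs)) == y_idx[sel])
  }
  list(loss = loss / n, acc = hits / n)
}

#' Predict class labels for an image sample set
#'
#' @param model Trained `lp_model` (with `class_levels` set by
#'   [train_model()], or supply `levels`).
#' @param samples Image-sample tibble.
#' @param levels Class level names, defaults to the model's.
#' @return Factor of predicted labels.
#' @export
predict_labels <- function(model, samples, levels = model$class_levels) {
  probs <- predict_proba(model, samples$image)
  factor(levels[max.col(probs)], levels = levels)
}

#' Evaluation report from truth and predictions
#'
#' Builds the confusion matrix and one-vs-rest per-class counts (TP, FP,
#' TN, FN), per-class precision / recall / F1 and binary accuracy, plus
#' overall accuracy and macro averages. Classes absent from the truth get
#' `NA` metrics and are excluded from the macro averages (with a note).
#'
#' @param truth Factor (or vector) of true labels.
#' @param predicted Factor (or vector) of predicted labels.
#' @param levels Class levels; defaults to the union, in truth's order.
#' @return An `lp_eval` object.
#' @export
eval_report <- function(truth, predicted, levels = NULL) {
  if (is.null(levels)) {
    levels <- if (is.factor(truth)) levels(truth) else
      sort(unique(c(as.character(truth), as.character(predicted))))
  }
  t_f <- factor(as.character(truth), levels = levels)
  p_f <- factor(as.character(predicted), levels = levels)
  cm <- table(truth = t_f, predicted = p_f)
  n <- sum(cm)
  per <- purrr::map_dfr(seq_along(levels), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i]); fn <- sum(cm[i, -i]); tn <- n - tp - fp - fn
    if (sum(cm[i, ]) == 0) {
      rlang::inform(paste0("class '", levels[i],
                           "' absent from truth; metrics undefined"))
      return(tibble::tibble(class = levels[i], tp = tp, fp = fp, tn = tn, fn = fn,
                            accuracy = NA_real_, precision = NA_real_,
                            recall = NA_real_, f1 = NA_real_))
    }
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- tp / (tp + fn)
    f1 <- if (is.na(prec) || prec + rec == 0) NA_real_ else
      2 * prec * rec / (prec + rec)
    tibble::tibble(class = levels[i], tp = tp, fp = fp, tn = tn, fn = fn,
                   accuracy = (tp + tn) / n, precision = prec,
                   recall = rec, f1 = f1)
  })
  structure(list(
    confusion = cm,
    per_class = per,
    accuracy = sum(diag(cm)) / n,
    macro_precision = mean(per$precision, na.rm = TRUE),
    macro_recall = mean(per$recall, na.rm = TRUE),
    macro_f1 = mean(per$f1, na.rm = TRUE),
    n = n
  ), class = "lp_eval")
}

#' Evaluate a trained model on a test set
#'
#' @param model Trained `lp_model`.
#' @param test Image-sample tibble (non-empty).
#' @return An `lp_eval` report.
#' @export
evaluate_model <- function(model, test) {
  if (nrow(test) == 0) rlang::abort("test set must be non-empty")
  pred <- predict_labels(model, test)
  eval_report(factor(test$label, levels = model$class_levels), pred,
              levels = model$class_levels)
}

#' @export
print.lp_eval <- function(x, ...) {
  cat(sprintf("Classification report (n = %d)\n", x$n))
  cat(sprintf("  accuracy %.3f | macro precision %.3f | recall %.3f | F1 %.3f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Tidy / glance methods for evaluation reports
#'
#' `tidy()` gives the per-class metric table, `glance()` the one-row
#' summary (overall accuracy and macro averages).
#'
#' @param x An `lp_eval`.
#' @param ... Unused.
#' @export
tidy.lp_eval <- function(x, ...) x$per_class

#' @rdname tidy.lp_eval
#' @export
glance.lp_eval <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1)
}
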