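test_that("augmentation ops are involutions / inverses and counts add up", {
  set.seed(51)
  img <- array(runif(12 * 12 * 3), c(12, 12, 3))
  expect_equal(img_flip_h(img_flip_h(img)), img)
  expect_equal(img_flip_v(img_flip_v(img)), img)
  expect_equal(img_rot270(img_rot90(img)), img)
  expect_equal(img_rot90(img_rot270(img)), img)

  samples <- random_image_samples(360)
  aug <- augment_dataset(samples, 1000, seed = 4)
  expect_equal(nrow(aug), 1000)
  expect_equal(sum(aug$augmented), 640)
  expect_equal(sum(!aug$augmented), 360)
  # labels inherited from source rows
  expect_true(all(aug$label %in% unique(samples$label)))
  expect_error(augment_dataset(samples[0, ], 10), "empty")
  expect_error(augment_dataset(samples, 100), ">=")
})

test_that("the 16:4:5 split yields the reference sizes and is a partition", {
  samples <- random_image_samples(1000)
  sp <- split_dataset(samples, seed = 5)
  expect_equal(sapply(sp, nrow), c(train = 640L, validation = 160L,
                                   test = 200L))
  exact <- split_dataset(random_image_samples(25), seed = 5)
  expect_equal(unname(sapply(exact, nrow)), c(16L, 4L, 5L))
  expect_error(split_dataset(random_image_samples(20)), "at least")

  # partition: disjoint cover of the source plots
  ids <- sort(unname(unlist(lapply(sp, function(df) df$source_plot))))
  expect_equal(ids, samples$source_plot)

  # stratification within one sample of the per-class ratio
  for (part in names(sp)) {
    tab <- table(sp[[part]]$label)
    expect_lte(max(tab) - min(tab), 1)
  }
})

test_that("softmax is a stable shift-invariant distribution", {
  expect_equal(softmax(rep(1.7, 4)), rep(0.25, 4))
  big <- softmax(c(1000, 0, 0, 0))
  expect_equal(big[1], 1, tolerance = 1e-9)
  expect_false(any(is.nan(big)))
  z <- c(0.3, -1, 2, 0.5)
  expect_equal(softmax(z + 7), softmax(z), tolerance = 1e-12)
  expect_equal(sum(softmax(z)), 1, tolerance = 1e-9)
  expect_error(softmax(c(1, Inf)), "finite")
})

test_that("evaluation metrics match hand evaluation of the formulas", {
  perfect <- eval_report(rep(lodging_classes(), 10), rep(lodging_classes(), 10))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_true(all(perfect$per_class$precision == 1))

  # everything predicted as one class on a balanced 4-class set
  truth <- rep(lodging_classes(), each = 10)
  onecls <- eval_report(truth, rep("severe", 40))
  expect_equal(onecls$accuracy, 0.25)

  # 2-class toy confusion [[45, 5], [10, 40]]
  t2 <- c(rep("a", 50), rep("b", 50))
  p2 <- c(rep("a", 45), rep("b", 5), rep("a", 10), rep("b", 40))
  ev <- eval_report(t2, p2)
  pc <- ev$per_class
  expect_equal(pc$precision[pc$class == "a"], 45 / 55)
  expect_equal(pc$recall[pc$class == "a"], 45 / 50)
  expect_equal(pc$accuracy[pc$class == "a"], (45 + 40) / 100)
  f1a <- 2 * (45 / 55) * (45 / 50) / (45 / 55 + 45 / 50)
  expect_equal(pc$f1[pc$class == "a"], f1a)
  expect_equal(glance(ev)$accuracy, 0.85)

  # absent class flagged undefined and excluded from macro averages
  expect_message(ev3 <- eval_report(factor(c("a", "a"), levels = c("a", "z")),
                                    factor(c("a", "a"), levels = c("a", "z"))),
                 "absent")
  expect_true(is.na(ev3$per_class$f1[2]))
  expect_equal(ev3$macro_f1, 1)
})

test_that("random guessing over balanced classes lands near macro-F1 0.25", {
  set.seed(52)
  f1s <- replicate(20, {
    truth <- rep(lodging_classes(), each = 25)
    pred <- sample(lodging_classes(), 100, replace = TRUE)
    eval_report(truth, pred)$macro_f1
  })
  expect_lt(abs(mean(f1s) - 0.25), 0.05)
})

test_that("model construction is seeded, shaped and counted correctly", {
  # a single dense 3 -> 4 layer has 3*4 + 4 = 16 parameters
  eng <- asNamespace("lodgepoint")
  d <- eng$layer_dense(3, 4)
  expect_equal(length(d$W) + length(d$b), 16)

  set.seed(6); m1 <- build_model("mobilenetv2", 4, input_size = 16,
                                 width_mult = 0.25)
  set.seed(6); m2 <- build_model("mobilenetv2", 4, input_size = 16,
                                 width_mult = 0.25)
  s1 <- eng$model_state(m1); s2 <- eng$model_state(m2)
  expect_identical(s1, s2)

  x <- array(rnorm(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  logits <- eng$model_forward(m1, x)
  expect_equal(dim(logits), c(4L, 2L))
  expect_error(build_model("resnet"), "arg")
})

test_that("a frozen validation metric stops after patience + 1 epochs", {
  samples <- solid_image_samples(6, size = 8)
  sp <- list(train = samples[1:8, ], val = samples[9:12, ])
  cfg <- train_config("mobilenetv2", learning_rate = 0, max_epochs = 50,
                      patience = 3, seed = 7, input_size = 8,
                      width_mult = 0.25, batch_size = 4)
  fit <- train_model(sp$train, sp$val, cfg)
  expect_equal(nrow(fit$history), 4) # 1 improvement + patience stale epochs
})

test_that("training is reproducible and learns separable solid images", {
  samples <- solid_image_samples(30, size = 12, means = c(0.15, 0.85))
  sp <- split_dataset(samples, seed = 8)
  cfg <- train_config("mobilenetv2", batch_size = 16, max_epochs = 20,
                      patience = 20, seed = 9, input_size = 12,
                      width_mult = 0.25)
  fit1 <- train_model(sp$train, sp$validation, cfg)
  expect_gte(max(fit1$history$val_acc), 0.95)
  ev <- evaluate_model(fit1$model, sp$test)
  expect_gte(ev$accuracy, 0.75)

  fit2 <- train_model(sp$train, sp$validation, cfg)
  expect_equal(fit1$history, fit2$history)
})
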