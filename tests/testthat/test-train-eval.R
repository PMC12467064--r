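test_that("the learning-rate schedule drops by 0.9 every two epochs", {
  cfg <- train_config()
  expect_equal(schedule_lr(cfg, 1), 4e-4)
  expect_equal(schedule_lr(cfg, 2), 4e-4)
  expect_equal(schedule_lr(cfg, 5), 4e-4 * 0.9^2)  # 0.000324
  expect_equal(schedule_lr(cfg, 60), 4e-4 * 0.9^29)
  expect_error(train_config(initial_lr = -1), class = "gaitphase_config_error")
  expect_error(train_config(max_epochs = 5, patience = 10),
               class = "gaitphase_config_error")
})

test_that("k-fold splits partition the sequences evenly and reproducibly", {
  ds <- fix_tiny_dataset()
  N <- dim(ds$x)[1]
  folds <- split_kfold(ds, folds = 10, seed = 3)
  expect_length(folds, 10)
  tests <- lapply(folds, `[[`, "test")
  expect_setequal(unlist(tests), seq_len(N))
  expect_identical(sum(lengths(tests)), N)  # pairwise disjoint
  sizes <- lengths(tests)
  expect_lte(max(sizes) - min(sizes), 1)
  for (f in folds) expect_length(intersect(f$train, f$test), 0)
  expect_identical(split_kfold(ds, folds = 10, seed = 3), folds)
  expect_error(split_kfold(ds, folds = N + 1), class = "gaitphase_config_error")
})

test_that("LOSO and cross-subject splits separate subjects strictly", {
  ds <- fix_tiny_dataset()
  folds <- split_loso(ds)
  expect_length(folds, 2)
  for (s in names(folds)) {
    expect_true(all(ds$subject_ids[folds[[s]]$test] == s))
    expect_false(any(ds$subject_ids[folds[[s]]$train] == s))
    expect_identical(length(folds[[s]]$test), sum(ds$subject_ids == s))
  }
  cs <- split_cross_subject(ds, "S02")
  expect_false(any(ds$subject_ids[cs$train] == "S02"))
  expect_true(all(ds$subject_ids[cs$test] == "S02"))
  expect_error(split_cross_subject(ds, character(0)), class = "gaitphase_config_error")
  expect_error(split_cross_subject(ds, "S99"), class = "gaitphase_config_error")

  single <- subset_dataset(ds, which(ds$subject_ids == "S01"))
  expect_error(split_loso(single), class = "gaitphase_config_error")
})

test_that("evaluation pools frames into a confusion matrix matching an R oracle", {
  ds <- fix_tiny_dataset()
  net <- instantiate_network(
    model_spec("probe", list(layer_input(4L), layer_gru(5L),
                             layer_dense(2L), layer_softmax())), seed = 4)
  rep <- evaluate(net, ds)
  # independent R-side recomputation of the pooled confusion
  p <- network_predict(net, ds$x)
  pred <- ifelse(p[, 1, ] >= p[, 2, ], 1L, 2L)
  truth <- ifelse(ds$y[, 1, ] >= 0.5, 1L, 2L)
  conf <- table(factor(truth, 1:2), factor(pred, 1:2))
  expect_identical(unname(rep$confusion), unname(matrix(as.numeric(conf), 2)))
  expect_equal(rep$n_frames, sum(conf))
  expect_equal(rep$accuracy, 100 * sum(diag(conf)) / sum(conf))
  # conservation: TP+FP+FN+TN equals evaluated frames
  expect_equal(sum(rep$confusion), dim(ds$x)[1] * dim(ds$x)[3])

  # a perfect predictor scores 100 everywhere
  perfect <- ds
  perfect$y <- array(0, dim = dim(ds$y))
  perfect$y[, 1, ][pred == 1L] <- 1
  perfect$y[, 2, ][pred == 2L] <- 1
  rep2 <- evaluate(net, perfect)
  expect_equal(rep2$accuracy, 100)
  expect_equal(rep2$f_stance, 100)
  expect_equal(rep2$f_swing, 100)
  expect_error(evaluate(net, subset_dataset(ds, integer(0))),
               class = "gaitphase_data_error")
})

test_that("F-scores follow 2PR/(P+R) on a crafted confusion", {
  # symmetric confusion TP=90, FP=10, FN=10, TN=90 -> F = 90 both classes
  rep <- structure(list(confusion = matrix(c(90, 10, 10, 90), 2)), class = "list")
  f <- function(conf, cls) {
    tp <- conf[cls, cls]
    prec <- tp / sum(conf[, cls]); rec <- tp / sum(conf[cls, ])
    100 * 2 * prec * rec / (prec + rec)
  }
  expect_equal(f(rep$confusion, 1), 90)
  expect_equal(f(rep$confusion, 2), 90)
})

test_that("training is seeded, follows the schedule, and learns the synthetic task", {
  ds <- fix_tiny_dataset()
  parts <- validation_split(ds, frac = 0.2, seed = 1)
  spec <- model_spec("tiny-train", list(layer_input(4L), layer_bilstm(16L),
                                        layer_dense(2L), layer_softmax()))
  cfg <- train_config(max_epochs = 40, batch_size = 16)
  m1 <- train_model(spec, parts$train, parts$val, cfg, seed = 2)
  m2 <- train_model(spec, parts$train, parts$val, cfg, seed = 2)
  expect_identical(m1$history$train_loss[1], m2$history$train_loss[1])
  expect_identical(m1$history, m2$history)
  expect_equal(m1$history$lr,
               vapply(seq_len(nrow(m1$history)), schedule_lr, numeric(1), cfg = cfg))
  # the envelope/label relation is close to deterministic: short training on
  # short windows already separates the phases well
  expect_gt(max(m1$history$val_acc), 85)
  expect_error(train_model(build_attention(), parts$train, parts$val, cfg),
               class = "gaitphase_config_error")
})

test_that("best_of_seeds picks the highest accuracy with a stable tie-break", {
  mk <- function(a) structure(list(accuracy = a), class = "eval_report")
  reports <- list(mk(91.0), mk(93.2), mk(92.1))
  expect_identical(best_of_seeds(reports)$accuracy, 93.2)
  expect_identical(best_of_seeds(list(mk(77)))$accuracy, 77)
  expect_identical(best_of_seeds(list(mk(90), mk(90))), mk(90))
  expect_error(best_of_seeds(list()), class = "gaitphase_data_error")
})

test_that("tidiers return tibbles with the expected columns", {
  ds <- fix_tiny_dataset()
  parts <- validation_split(ds, frac = 0.2, seed = 1)
  spec <- model_spec("tiny-g", list(layer_input(4L), layer_gru(4L),
                                    layer_dense(2L), layer_softmax()))
  m <- train_model(spec, parts$train, parts$val,
                   train_config(max_epochs = 2, batch_size = 32), seed = 1)
  expect_s3_class(tidy(m), "tbl_df")
  expect_named(tidy(m), c("epoch", "train_loss", "val_loss", "val_acc", "lr"))
  expect_identical(glance(m)$n_parameters, count_parameters(spec))
  rep <- evaluate(m, parts$val)
  expect_named(glance(rep), c("accuracy", "f_stance", "f_swing", "n_frames"))
  expect_s3_class(autoplot(m), "ggplot")
})
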