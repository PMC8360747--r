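# Architecture contract, optimisation sanity, evaluation arithmetic.

# a tiny separable image set: class-dependent block pattern + light noise
tiny_image_manifest <- function(n = 16, seed = 1) {
  set.seed(seed)
  images <- vector("list", n)
  binary <- rep(0:1, length.out = n)
  for (i in seq_len(n)) {
    base <- matrix(stats::runif(32 * 32, 0, 0.2), 32)
    if (binary[i] == 1) base[1:16, ] <- base[1:16, ] + 0.8
    else base[, 1:16] <- base[, 1:16] + 0.8
    images[[i]] <- render(base)
  }
  man <- data.frame(image = sprintf("mem_%02d.png", seq_len(n)),
                    split = rep(c("train", "val"), c(n - 4, 4)),
                    sbp = 0, dbp = 0, category = "NORMAL", binary = binary,
                    wavelet = "none", segment_length = 32L, seed = seed)
  structure(man, class = c("scalobp_manifest", "data.frame"),
            images = images, dropped = 0L)
}

test_that("the layer stack has the prescribed shapes and parameter counts", {
  model <- build_model(seed = 1)
  s <- model_summary(model)
  expect_identical(s$shapes$input, c(224L, 224L, 3L))
  expect_identical(s$shapes$conv1, c(224L, 224L, 64L))
  expect_identical(s$shapes$pool1, c(112L, 112L, 64L))
  expect_identical(s$shapes$pool2, c(56L, 56L, 128L))   # two same-pad halvings
  expect_identical(s$shapes$flatten, 401408L)
  expect_identical(s$shapes$dense1, 256L)
  expect_identical(s$shapes$output, 1L)
  expect_identical(unname(s$params["conv1"]), 1792)       # 64*(3*3*3 + 1)
  expect_identical(unname(s$params["conv2"]), 204928)     # 128*(5*5*64 + 1)
  expect_identical(unname(s$params["dense1"]), 256 * 401408 + 256)
})

test_that("malformed configs are rejected", {
  cfg <- cnn_config()
  cfg$input <- c(100L, 100L, 3L)
  expect_error(build_model(cfg), "224")
  expect_error(build_model(list()), "malformed|config")
  expect_error(train_config(epochs = 0))
})

test_that("forward scores lie in [0, 1] for arbitrary images", {
  man <- tiny_image_manifest(6)
  model <- build_model(seed = 3)
  sc <- predict_scores(model, man)
  expect_length(sc, 6)
  expect_true(all(sc > 0 & sc < 1))
})

test_that("training memorises a small separable image set deterministically", {
  man <- tiny_image_manifest(16, seed = 2)
  # keep at most one ~1.7 GB model alive at a time
  m1 <- train_cnn(build_model(seed = 9), man,
                  train_config(epochs = 8L, batch_size = 4L, seed = 9))
  h <- m1$history
  c1 <- weights_checksum(m1)
  rm(m1); gc(verbose = FALSE)
  expect_identical(nrow(h), 8L)
  # optimisation sanity: final-epoch loss below first-epoch loss
  expect_lt(h$train_loss[8], h$train_loss[1])
  # memorisation: the separable set is fit perfectly by the end
  expect_equal(h$train_acc[8], 1.0)
  # determinism: an identical seeded run gives identical weights
  m2 <- train_cnn(build_model(seed = 9), man,
                  train_config(epochs = 8L, batch_size = 4L, seed = 9))
  expect_identical(c1, weights_checksum(m2))
  expect_identical(h, m2$history)
  rm(m2); gc(verbose = FALSE)
  # and a different init differs
  expect_false(identical(weights_checksum(build_model(seed = 10)),
                         weights_checksum(build_model(seed = 9))))
})

test_that("single-class training sets are rejected", {
  man <- tiny_image_manifest(8)
  man$binary[man$split == "train"] <- 1L
  expect_error(train_cnn(build_model(seed = 1), man, train_config(epochs = 1L)),
               "both classes")
})

test_that("evaluation arithmetic matches hand-computed accuracy and AUC", {
  # perfect scores
  rc <- roc_curve(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(rc$auc, 1)
  expect_identical(rc$roc$fpr[1], 0); expect_identical(rc$roc$tpr[1], 0)
  expect_identical(utils::tail(rc$roc$fpr, 1), 1)
  expect_identical(utils::tail(rc$roc$tpr, 1), 1)
  # degenerate constant classifier on a balanced set
  labels <- rep(0:1, 50)
  rc2 <- roc_curve(rep(0.7, 100), labels)
  expect_equal(rc2$auc, 0.5)
  expect_equal(mean((rep(0.7, 100) >= 0.5) == (labels == 1)), 0.5)
  # random scores: AUC concentrates near 1/2
  set.seed(5)
  rc3 <- roc_curve(runif(2000), rep(0:1, 1000))
  expect_lt(abs(rc3$auc - 0.5), 0.05)
  # ROC is monotone nondecreasing
  expect_true(all(diff(rc3$roc$tpr) >= 0))
  expect_true(all(diff(rc3$roc$fpr) >= 0))
  expect_error(roc_curve(runif(5), rep(1, 5)), "both classes")
})

test_that("in-package AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(8)
  scores <- c(rnorm(60, 0.6, 0.2), rnorm(40, 0.4, 0.2))
  labels <- rep(c(1, 0), c(60, 40))
  ours <- roc_curve(scores, labels)$auc
  theirs <- as.numeric(suppressMessages(pROC::auc(labels, scores)))
  expect_equal(ours, theirs, tolerance = 1e-10)
})

test_that("accuracy is recomputable from the stored per-item scores", {
  man <- tiny_image_manifest(12, seed = 4)
  model <- train_cnn(build_model(seed = 2), man,
                     train_config(epochs = 2L, batch_size = 4L))
  ev <- evaluate_model(model, man, split = "val")
  expect_equal(ev$accuracy,
               mean((ev$scores >= 0.5) == (ev$labels == 1)))
  expect_gte(ev$auc, 0); expect_lte(ev$auc, 1)
  expect_error(evaluate_model(model, man, split = "nope"), "empty")
})

test_that("the grid runs one controlled cell per wavelet x length", {
  recs <- balanced_records(4, duration_s = 8, seed = 60)
  cfg <- train_config(epochs = 1L, batch_size = 8L, seed = 5)
  # tiny validation splits can land single-class; AUC is then NA (warned)
  gr <- suppressWarnings(suppressMessages(
    grid_search(recs, c("mexh", "none"), c(200L, 250L), cfg, seed = 5)))
  expect_identical(nrow(gr), 4L)
  expect_true(all(is.na(gr$error)))
  expect_true(all(gr$accuracy >= 0 & gr$accuracy <= 1))
  # cells differ only in (wavelet, length): same records, same split rule
  expect_identical(gr$n_train + gr$n_val,
                   as.integer(4L * ((8L * FS) %/% gr$segment_length)))
  expect_setequal(gr$wavelet, c("mexh", "none"))
  expect_setequal(gr$segment_length, c(200L, 250L))
})
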