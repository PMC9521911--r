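# small labelled sequence set in descriptors mode (f = 208): cheap enough for
# unit tests while exercising the full network
make_toy_sequences <- function(n_per_class = 4, seed = 5, L = 8L) {
  ds <- make_dataset(n_per_class, seed = seed)
  seqs <- lapply(seq_along(ds$volumes), function(i) {
    nodule_feature_sequence(ds$volumes[[i]], ds$masks[[i]], label = 3,
                            mode = "descriptors", L = L)
  })
  list(seqs = seqs, labels = ds$labels)
}

test_that("architecture matches the fixed per-mode layer tables", {
  s2d <- build_fusion_spec("glcm2d", f = 100)
  expect_equal(model_summary(s2d), c(
    "lstm(units=128, activation=relu, return_sequences=TRUE)",
    "lstm(units=128, activation=relu, return_sequences=FALSE)",
    "dense(units=3, activation=softmax)"))
  for (mode in c("glcm2_5d", "glcm3d", "descriptors")) {
    expect_equal(model_summary(build_fusion_spec(mode, f = 100)), c(
      "lstm(units=128, activation=relu, return_sequences=TRUE)",
      "lstm(units=128, activation=relu, return_sequences=FALSE)",
      "dense(units=32, activation=relu)",
      "dense(units=3, activation=softmax)"))
  }
  expect_error(build_fusion_spec("cnn", f = 10), "arg")
})

test_that("parameter counts follow the LSTM closed form", {
  f <- 208L
  spec <- build_fusion_spec("descriptors", f)
  w <- glcmfusion:::with_seed(1, glcmfusion:::init_fusion_weights(spec))
  count <- function(l) length(l$Wx) + length(l$Wh) + length(l$b)
  expect_equal(count(w$lstm1), 4 * (128 * (f + 128) + 128))
  expect_equal(count(w$lstm2), 4 * (128 * (128 + 128) + 128))
  total <- sum(vapply(glcmfusion:::flatten_weights(w), length, numeric(1)))
  expect_equal(total, spec$n_params)
})

test_that("untrained model predicts near-uniform probabilities", {
  toy <- make_toy_sequences(2)
  fit0 <- fit_fusion(toy$seqs, toy$labels, epochs = 0, seed = 3)
  p <- predict(fit0, toy$seqs)
  expect_true(all(abs(p - 1 / 3) < 0.15))
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6)
})

test_that("training reduces loss and reaches high accuracy on separable data", {
  ds <- make_dataset(6, seed = 17)
  seqs <- lapply(seq_along(ds$volumes), function(i) {
    nodule_feature_sequence(ds$volumes[[i]], ds$masks[[i]], label = 3, L = 8)
  })
  fit <- fit_fusion(seqs, ds$labels, epochs = 50, seed = 7)
  h <- fit$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_gte(h$accuracy[nrow(h)], 0.95)
  # reproducibility: same seed, same history
  fit2 <- fit_fusion(seqs, ds$labels, epochs = 50, seed = 7)
  expect_identical(fit$history, fit2$history)
  expect_equal(coef(fit), coef(fit2))
})

test_that("feature standardization helps the descriptor mode and round-trips", {
  toy <- make_toy_sequences(6, seed = 17)
  fit <- fit_fusion(toy$seqs, toy$labels, epochs = 30, seed = 7,
                    standardize = TRUE)
  expect_gte(fit$history$accuracy[nrow(fit$history)], 0.95)
  # scaling is stored and applied at prediction time
  expect_false(is.null(fit$scaling))
  p <- predict(fit, toy$seqs)
  expect_equal(rowSums(p), rep(1, length(toy$seqs)), tolerance = 1e-6)
  expect_gte(mean(classify(p) == toy$labels), 0.95)
})

test_that("prediction is a pure softmax function of the input", {
  toy <- make_toy_sequences(2)
  fit <- fit_fusion(toy$seqs, toy$labels, epochs = 2, seed = 1)
  p1 <- predict(fit, toy$seqs[1])
  p2 <- predict(fit, toy$seqs[1])
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0))
  expect_equal(rowSums(p1), 1, tolerance = 1e-6)
  # shape mismatch is reported with expected vs got
  bad <- toy$seqs[[1]]
  bad$steps <- bad$steps[, 1:10]
  bad$f <- 10L
  expect_error(predict(fit, list(bad)), "expects f = ")
})

test_that("masked padding steps cannot change predictions", {
  toy <- make_toy_sequences(2)
  fit <- fit_fusion(toy$seqs, toy$labels, epochs = 3, seed = 2)
  s <- toy$seqs[[1]]
  p0 <- predict(fit, list(s))
  s_pad <- s
  s_pad$steps <- rbind(s$steps, matrix(0, 3, s$f))
  s_pad$mask <- c(s$mask, rep(FALSE, 3))
  fit_pad <- fit
  fit_pad$T_max <- fit$T_max + 3L
  p1 <- predict(fit_pad, list(s_pad))
  expect_equal(p0, p1, tolerance = 1e-6)

  # an all-padding input equals the response to the zero sequence
  zero <- s
  zero$steps <- matrix(0, nrow(s$steps), s$f)
  allpad <- zero
  allpad$mask <- rep(FALSE, length(s$mask))
  expect_equal(predict(fit, list(allpad)), predict(fit, list(zero)),
               tolerance = 1e-6)
})

test_that("save / load round trip preserves predictions exactly", {
  toy <- make_toy_sequences(2)
  fit <- fit_fusion(toy$seqs, toy$labels, epochs = 2, seed = 4)
  path <- withr::local_tempfile(fileext = ".rds")
  save_fusion_model(fit, path)
  expect_true(file.exists(paste0(path, ".json")))
  fit2 <- load_fusion_model(path)
  expect_identical(predict(fit, toy$seqs), predict(fit2, toy$seqs))
})

test_that("degenerate training inputs are rejected", {
  toy <- make_toy_sequences(2)
  one_class <- rep("benign", length(toy$seqs))
  expect_error(fit_fusion(toy$seqs, one_class, epochs = 1), ">= 2 classes")
  expect_error(fit_fusion(toy$seqs, rep("weird", length(toy$seqs))),
               "labels must be among")
})

test_that("classify applies argmax with the fixed tie-break order", {
  expect_equal(as.character(classify(c(0.1, 0.7, 0.2))), "malignant")
  expect_equal(as.character(classify(c(1, 1, 1) / 3)), "benign")
  expect_equal(as.character(classify(c(0, 0, 1))), "ambiguous")
  m <- rbind(c(1, 0, 0), c(0.2, 0.2, 0.6))
  expect_equal(as.character(classify(m)), c("benign", "ambiguous"))
  expect_error(classify(c(0.5, 0.2)), "3 columns")
  expect_error(classify(c(0.9, 0.5, 0.2)), "summing to 1")
})
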