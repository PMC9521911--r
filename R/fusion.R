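#' Nodule classes
#'
#' The three texture classes, in the fixed order used for softmax outputs and
#' argmax tie-breaking: benign < malignant < ambiguous.
#' @export
fusion_classes <- c("benign", "malignant", "ambiguous")

#' Fusion network architecture for a GLCM mode
#'
#' The recurrent fusion classifier has a fixed per-mode architecture:
#'
#' * `glcm2d`: LSTM(128, relu, sequence-to-sequence) -> LSTM(128, relu,
#'   sequence-to-one) -> Dense(3, softmax);
#' * `glcm2_5d`, `glcm3d`, `descriptors`: the same two LSTM layers followed
#'   by Dense(32, relu) -> Dense(3, softmax).
#'
#' Padded steps are masked: state is carried through them unchanged, so they
#' contribute nothing to the prediction.
#'
#' @param mode one of `"glcm2d"`, `"glcm2_5d"`, `"glcm3d"`, `"descriptors"`.
#' @param f feature-vector length per step.
#' @return an object of class `fusion_spec`: list with `mode`, `f`, `layers`
#'   (list of layer descriptors), and `n_params`.
#' @export
build_fusion_spec <- function(mode = c("glcm2d", "glcm2_5d", "glcm3d",
                                       "descriptors"), f) {
  mode <- match.arg(mode)
  f <- as_count(f, "f", min = 1L)
  layers <- list(
    list(kind = "lstm", units = 128L, activation = "relu",
         return_sequences = TRUE),
    list(kind = "lstm", units = 128L, activation = "relu",
         return_sequences = FALSE)
  )
  if (mode != "glcm2d") {
    layers <- c(layers, list(list(kind = "dense", units = 32L,
                                  activation = "relu")))
  }
  layers <- c(layers, list(list(kind = "dense", units = 3L,
                                activation = "softmax")))
  np <- lstm_n_params(f, 128L) + lstm_n_params(128L, 128L)
  np <- np + if (mode == "glcm2d") (128L * 3L + 3L) else
    (128L * 32L + 32L) + (32L * 3L + 3L)
  structure(list(mode = mode, f = f, layers = layers, n_params = np),
            class = "fusion_spec")
}

#' Canonical one-line-per-layer architecture summary
#'
#' @param x a `fusion_spec` or `fusion_fit`.
#' @return character vector, one canonical string per learned layer, e.g.
#'   `"lstm(units=128, activation=relu, return_sequences=TRUE)"`.
#' @export
model_summary <- function(x) {
  spec <- if (inherits(x, "fusion_fit")) x$spec else x
  stopifnot(inherits(spec, "fusion_spec"))
  vapply(spec$layers, function(l) {
    if (l$kind == "lstm") {
      sprintf("lstm(units=%d, activation=%s, return_sequences=%s)",
              l$units, l$activation, l$return_sequences)
    } else {
      sprintf("dense(units=%d, activation=%s)", l$units, l$activation)
    }
  }, character(1))
}

#' @export
print.fusion_spec <- function(x, ...) {
  cat(sprintf("fusion_spec: mode %s, f = %d, %d parameters\n",
              x$mode, x$f, x$n_params))
  cat(paste0("  ", model_summary(x), collapse = "\n"), "\n")
  invisible(x)
}

# initialize all weights for a spec (uses session RNG)
init_fusion_weights <- function(spec) {
  w <- list(lstm1 = lstm_init(spec$f, 128L),
            lstm2 = lstm_init(128L, 128L))
  if (spec$mode == "glcm2d") {
    w$out <- dense_init(128L, 3L)
  } else {
    w$dense1 <- dense_init(128L, 32L)
    w$out <- dense_init(32L, 3L)
  }
  w
}

# flatten / unflatten weights for the optimizer
flatten_weights <- function(w) {
  out <- list()
  for (ln in names(w)) for (pn in names(w[[ln]])) {
    out[[paste(ln, pn, sep = ".")]] <- w[[ln]][[pn]]
  }
  out
}
unflatten_weights <- function(flat) {
  w <- list()
  for (k in names(flat)) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    w[[parts[1]]][[parts[2]]] <- flat[[k]]
  }
  w
}

# forward pass through the whole network.
# X: list over t of (B x f); mask: (B x T).
fusion_forward <- function(weights, spec, X, mask, want_cache = FALSE) {
  l1 <- lstm_forward(weights$lstm1, X, mask, "relu", want_cache)
  l2 <- lstm_forward(weights$lstm2, l1$H, mask, "relu", want_cache)
  h <- l2$h_last
  cache <- list(l1 = l1$cache, l2 = l2$cache, h = h)
  if (spec$mode == "glcm2d") {
    logits <- dense_forward(weights$out, h)
  } else {
    a_pre <- dense_forward(weights$dense1, h)
    a <- pmax(a_pre, 0)
    cache$a_pre <- a_pre
    cache$a <- a
    logits <- dense_forward(weights$out, a)
  }
  list(probs = softmax(logits), cache = if (want_cache) cache else NULL)
}

# backward pass; Y is (B x 3) one-hot, sw optional per-sample loss weights.
# Returns flat gradient list matching flatten_weights() names.
fusion_backward <- function(weights, spec, cache, probs, Y, sw = NULL) {
  B <- nrow(Y)
  dlogits <- if (is.null(sw)) (probs - Y) / B else
    (probs - Y) * (sw / sum(sw))
  g <- list()
  if (spec$mode == "glcm2d") {
    g[["out.W"]] <- crossprod(cache$h, dlogits)
    g[["out.b"]] <- colSums(dlogits)
    dh <- dlogits %*% t(weights$out$W)
  } else {
    g[["out.W"]] <- crossprod(cache$a, dlogits)
    g[["out.b"]] <- colSums(dlogits)
    da <- dlogits %*% t(weights$out$W)
    da_pre <- da * (cache$a_pre > 0)
    g[["dense1.W"]] <- crossprod(cache$h, da_pre)
    g[["dense1.b"]] <- colSums(da_pre)
    dh <- da_pre %*% t(weights$dense1$W)
  }
  Tn <- length(cache$l2)
  u <- 128L
  dH2 <- lapply(seq_len(Tn), function(t) matrix(0, B, u))
  dH2[[Tn]] <- dh
  b2 <- lstm_backward(weights$lstm2, cache$l2, dH2, "relu")
  g[["lstm2.Wx"]] <- b2$dWx; g[["lstm2.Wh"]] <- b2$dWh; g[["lstm2.b"]] <- b2$db
  b1 <- lstm_backward(weights$lstm1, cache$l1, b2$dX, "relu")
  g[["lstm1.Wx"]] <- b1$dWx; g[["lstm1.Wh"]] <- b1$dWh; g[["lstm1.b"]] <- b1$db
  g
}

# coerce feature sequences to a dense (n, T, f) array + (n, T) mask
sequences_to_array <- function(x, max_len = NULL) {
  if (inherits(x, "feature_sequence")) x <- list(x)
  if (is.list(x) && !is.null(x$X)) return(x)
  stopifnot(all(vapply(x, inherits, logical(1), "feature_sequence")))
  fs <- vapply(x, function(s) s$f, numeric(1))
  if (length(unique(fs)) != 1L) {
    stop_param("all sequences must share the same feature length f; got ",
               paste(unique(fs), collapse = ", "))
  }
  lens <- vapply(x, function(s) s$n_real, numeric(1))
  Tn <- max_len %||% max(lens)
  if (max(lens) > Tn) {
    stop_param("a sequence has ", max(lens), " steps but max_len = ", Tn,
               "; refusing to truncate")
  }
  n <- length(x)
  X <- array(0, dim = c(n, Tn, fs[1]))
  M <- matrix(0, n, Tn)
  for (i in seq_len(n)) {
    k <- x[[i]]$n_real
    X[i, seq_len(k), ] <- x[[i]]$steps[seq_len(k), , drop = FALSE]
    M[i, seq_len(k)] <- 1
  }
  list(X = X, M = M)
}

# z-score real steps in place; padded steps stay zero
apply_scaling <- function(X, M, scaling) {
  n <- dim(X)[1]; Tn <- dim(X)[2]; f <- dim(X)[3]
  for (t in seq_len(Tn)) {
    rows <- which(M[, t] == 1)
    if (length(rows) == 0L) next
    m <- matrix(X[rows, t, ], nrow = length(rows), ncol = f)
    m <- sweep(sweep(m, 2, scaling$center), 2, scaling$scale, "/")
    X[rows, t, ] <- m
  }
  X
}

slice_steps <- function(X, rows) {
  Tn <- dim(X)[2]
  lapply(seq_len(Tn), function(t) {
    m <- X[rows, t, , drop = FALSE]
    dim(m) <- c(length(rows), dim(X)[3])
    m
  })
}

#' Fit the LSTM fusion classifier
#'
#' Trains the recurrent fusion network (see [build_fusion_spec]) on labelled
#' feature sequences with softmax cross-entropy loss and the Adam optimizer
#' (learning rate 1e-3, batch 16 by default). Training is seeded and fully
#' reproducible: the same data, seed and settings give bit-identical weights.
#'
#' @param x list of [build_feature_sequence] objects (or a list with `X`
#'   `(n, T, f)` array and `M` `(n, T)` mask).
#' @param y labels: factor or character drawn from
#'   `c("benign", "malignant", "ambiguous")`. At least two classes must be
#'   present.
#' @param mode network mode; defaults to the sequences' mode.
#' @param epochs training epochs (default 20). `epochs = 0` returns the
#'   untrained (near-uniform) model.
#' @param batch_size minibatch size (default 16).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed for initialization and shuffling.
#' @param class_weights optional named per-class loss weights, or `TRUE` for
#'   inverse-frequency weights; default no reweighting.
#' @param standardize z-score each feature over the real (unmasked) training
#'   steps and store the scaling with the model (applied automatically at
#'   prediction). Useful for the `descriptors` mode, whose 16 summaries live
#'   on very different scales; raw GLCM probabilities train fine without it.
#' @param verbose print per-epoch loss/accuracy?
#' @return an object of class `fusion_fit` with elements `spec`, `weights`,
#'   `classes`, `history` (data frame: epoch, loss, accuracy), `T_max`, `f`.
#' @seealso [predict.fusion_fit], [classify]
#' @export
fit_fusion <- function(x, y, mode = NULL, epochs = 20L, batch_size = 16L,
                       lr = 1e-3, seed = NULL, class_weights = NULL,
                       standardize = FALSE, verbose = FALSE) {
  dat <- sequences_to_array(x)
  scaling <- NULL
  if (isTRUE(standardize)) {
    real <- which(dat$M == 1, arr.ind = TRUE)
    flat <- matrix(dat$X[cbind(rep(real[, 1], dim(dat$X)[3]),
                               rep(real[, 2], dim(dat$X)[3]),
                               rep(seq_len(dim(dat$X)[3]), each = nrow(real)))],
                   nrow = nrow(real))
    scaling <- list(center = colMeans(flat),
                    scale = pmax(apply(flat, 2, stats::sd), 1e-8))
    dat$X <- apply_scaling(dat$X, dat$M, scaling)
  }
  n <- dim(dat$X)[1]
  if (is.null(mode)) {
    mode <- if (is.list(x) && inherits(x[[1]], "feature_sequence")) {
      x[[1]]$mode
    } else stop_param("`mode` is required when x is a bare array")
  }
  y <- factor(as.character(y), levels = fusion_classes)
  if (anyNA(y)) stop_param("labels must be among: ",
                           paste(fusion_classes, collapse = ", "))
  if (length(y) != n) stop_param("length(y) must match the number of sequences")
  if (length(unique(y)) < 2L) {
    stop_param("validation error: training data must contain >= 2 classes")
  }
  epochs <- as_count(epochs, "epochs", min = 0L)
  batch_size <- as_count(batch_size, "batch_size", min = 1L)
  f <- dim(dat$X)[3]
  spec <- build_fusion_spec(mode, f)
  Y <- diag(3)[as.integer(y), , drop = FALSE]
  wvec <- rep(1, n)
  if (isTRUE(class_weights)) {
    freq <- table(y)[fusion_classes]
    cw <- as.numeric(sum(freq) / (3 * pmax(freq, 1)))
    wvec <- cw[as.integer(y)]
  } else if (is.numeric(class_weights)) {
    cw <- class_weights[fusion_classes]
    wvec <- as.numeric(cw[as.integer(y)])
  }

  run <- function() {
    weights <- init_fusion_weights(spec)
    flat <- flatten_weights(weights)
    opt <- adam_init(flat)
    hist <- data.frame(epoch = integer(0), loss = numeric(0),
                       accuracy = numeric(0))
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      tot_loss <- 0; tot_correct <- 0
      for (start in seq(1L, n, by = batch_size)) {
        rows <- perm[start:min(start + batch_size - 1L, n)]
        Xb <- slice_steps(dat$X, rows)
        Mb <- dat$M[rows, , drop = FALSE]
        Yb <- Y[rows, , drop = FALSE]
        fw <- fusion_forward(weights, spec, Xb, Mb, want_cache = TRUE)
        pt <- rowSums(fw$probs * Yb)
        wb <- wvec[rows]
        loss <- -sum(wb * log(pmax(pt, 1e-12))) / sum(wb)
        if (!is.finite(loss)) {
          stop("training diverged: non-finite loss at epoch ", ep,
               "; lower the learning rate", call. = FALSE)
        }
        grads <- fusion_backward(weights, spec, fw$cache, fw$probs, Yb,
                                 sw = wb)
        upd <- adam_update(flatten_weights(weights), grads, opt, lr = lr)
        weights <- unflatten_weights(upd$params)
        opt <- upd$state
        tot_loss <- tot_loss + loss * length(rows)
        tot_correct <- tot_correct +
          sum(max.col(fw$probs, ties.method = "first") == as.integer(y[rows]))
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = tot_loss / n,
                                     accuracy = tot_correct / n))
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f, accuracy %.3f",
                        ep, tot_loss / n, tot_correct / n))
      }
    }
    list(weights = weights, history = hist)
  }
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(spec = spec, weights = res$weights, classes = fusion_classes,
                 history = res$history, T_max = dim(dat$X)[2], f = f,
                 scaling = scaling,
                 settings = list(epochs = epochs, batch_size = batch_size,
                                 lr = lr, seed = seed)),
            class = "fusion_fit")
}

#' @export
print.fusion_fit <- function(x, ...) {
  cat(sprintf("fusion_fit: mode %s, %d steps x f = %d, %d parameters\n",
              x$spec$mode, x$T_max, x$f, x$spec$n_params))
  cat(paste0("  ", model_summary(x), collapse = "\n"), "\n")
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d epochs: loss %.4f, accuracy %.3f\n",
                last$epoch, last$loss, last$accuracy))
  } else {
    cat("  untrained (0 epochs)\n")
  }
  invisible(x)
}

#' @export
summary.fusion_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.fusion_fit")
}

#' @export
print.summary.fusion_fit <- function(x, ...) {
  print(x$fit)
  cat("training history (last 5 epochs):\n")
  h <- x$fit$history
  print(utils::tail(h, 5), row.names = FALSE)
  invisible(x)
}

#' @export
plot.fusion_fit <- function(x, ...) {
  h <- x$history
  if (nrow(h) == 0) stop("no training history to plot", call. = FALSE)
  graphics::par(mfrow = c(1, 2))
  plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "loss",
       main = "training loss", ...)
  plot(h$epoch, h$accuracy, type = "b", xlab = "epoch", ylab = "accuracy",
       main = "training accuracy", ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
coef.fusion_fit <- function(object, ...) flatten_weights(object$weights)

#' Predict class probabilities or labels
#'
#' @param object a [fit_fusion] model.
#' @param newdata feature sequences (list, single `feature_sequence`, or
#'   `X`/`M` list). Sequences longer than the model's step budget are an
#'   error.
#' @param type `"prob"` for the n x 3 probability matrix, `"class"` for a
#'   factor of argmax labels (ties broken benign < malignant < ambiguous).
#' @param ... unused.
#' @return matrix of probabilities (rows sum to 1) or a factor.
#' @export
predict.fusion_fit <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  dat <- sequences_to_array(newdata, max_len = object$T_max)
  if (dim(dat$X)[3] != object$f) {
    stop_param("feature length mismatch: model expects f = ", object$f,
               ", got ", dim(dat$X)[3])
  }
  if (dim(dat$X)[2] != object$T_max) {
    # re-pad shorter inputs to the model's step budget
    X <- array(0, dim = c(dim(dat$X)[1], object$T_max, object$f))
    M <- matrix(0, dim(dat$X)[1], object$T_max)
    X[, seq_len(dim(dat$X)[2]), ] <- dat$X
    M[, seq_len(dim(dat$X)[2])] <- dat$M
    dat <- list(X = X, M = M)
  }
  if (!is.null(object$scaling)) {
    dat$X <- apply_scaling(dat$X, dat$M, object$scaling)
  }
  n <- dim(dat$X)[1]
  fw <- fusion_forward(object$weights, object$spec,
                       slice_steps(dat$X, seq_len(n)), dat$M)
  probs <- fw$probs
  colnames(probs) <- object$classes
  if (type == "prob") probs else classify(probs)
}

#' Turn probability vectors into class labels
#'
#' Argmax over the three classes; exact ties resolve to the earlier class in
#' the order benign < malignant < ambiguous.
#'
#' @param probs numeric vector of length 3 or an n x 3 matrix of valid
#'   probability vectors.
#' @return a factor with levels `fusion_classes`.
#' @export
classify <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  if (ncol(probs) != 3L) stop_param("`probs` must have 3 columns")
  if (any(probs < -1e-9) || any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop_param("rows of `probs` must be probability vectors summing to 1")
  }
  factor(fusion_classes[max.col(probs, ties.method = "first")],
         levels = fusion_classes)
}

#' Save / load a fitted fusion model
#'
#' The model is written in R's native serialization (RDS) next to a JSON
#' manifest (`<path>.json`) describing the architecture, feature length and
#' training settings. Loading restores a model whose predictions are
#' bit-identical.
#'
#' @param fit a `fusion_fit`.
#' @param path output `.rds` path.
#' @return `path` (save) or the restored `fusion_fit` (load).
#' @export
save_fusion_model <- function(fit, path) {
  stopifnot(inherits(fit, "fusion_fit"))
  saveRDS(fit, path)
  manifest <- list(mode = fit$spec$mode, f = fit$f, T_max = fit$T_max,
                   n_params = fit$spec$n_params, layers = model_summary(fit),
                   settings = fit$settings)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_fusion_model
#' @export
load_fusion_model <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "fusion_fit"))
  fit
}
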