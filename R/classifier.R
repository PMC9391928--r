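# Multi-input convolutional classifier.
#
# One small convolutional stack per signal modality (2-D valid convolution
# -> ReLU -> max-pooling, repeated per block), features concatenated across
# modalities, dropout on the concatenated vector, then a fully connected
# ReLU layer and a K-way softmax. Trained with minibatch Adam on the
# softmax cross-entropy. Everything (im2col convolution, pooling argmax
# bookkeeping, backpropagation, Adam) is implemented here in base R with
# BLAS-backed matrix products; the default architecture is deliberately
# small (a few thousand parameters) for CPU desk scale.

#' Classifier configuration
#'
#' @param class_names character vector of K >= 2 class names (must include
#'   `"starch"` for the starch-monitoring pipeline, but any label set is
#'   accepted).
#' @param n_blocks convolutional blocks per input stack.
#' @param channels output channels of each convolution.
#' @param kernel square kernel size.
#' @param pool max-pool window (and stride).
#' @param dropout dropout rate on the concatenated feature vector, in
#'   [0, 1).
#' @param head_width width of the fully connected hidden layer.
#' @param train_fraction fraction of each class used for training
#'   (stratified), in (0, 1).
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param seed seed controlling initialization, the split, shuffling and
#'   dropout.
#' @return a `classifier_config` list.
#' @export
classifier_config <- function(class_names,
                              n_blocks = 1L, channels = 4L, kernel = 3L,
                              pool = 2L, dropout = 0.2, head_width = 32L,
                              train_fraction = 0.9, epochs = 15L,
                              batch_size = 64L, learning_rate = 1e-3,
                              seed = 1L) {
  class_names <- as.character(class_names)
  if (length(class_names) < 2L) stopf("need K >= 2 classes")
  if (anyDuplicated(class_names)) stopf("duplicate class names")
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must lie in (0, 1)")
  if (!is_number(dropout) || dropout < 0 || dropout >= 1)
    stopf("dropout must lie in [0, 1)")
  if (!is_count(n_blocks) || n_blocks < 1) stopf("n_blocks must be >= 1")
  structure(list(class_names = class_names, n_blocks = as.integer(n_blocks),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 pool = as.integer(pool), dropout = dropout,
                 head_width = as.integer(head_width),
                 train_fraction = train_fraction, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Stratified train/validation split
#'
#' Splits a fully labelled batch per class: `floor(train_fraction * n)`
#' events of each class go to training (after a seeded shuffle), the
#' remainder to validation. Deterministic in `seed`.
#'
#' @param batch an `event_batch` with no missing labels (or a character
#'   label vector).
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer vectors `train` and `validation`.
#' @export
split_train_validation <- function(batch, train_fraction = 0.9, seed = 1L) {
  labels <- if (inherits(batch, "event_batch")) batch$labels else as.character(batch)
  if (!length(labels)) stopf("empty batch")
  if (anyNA(labels)) stopf("batch must be fully labelled")
  if (!is_number(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must lie in (0, 1)")
  with_seed(seed, {
    train <- integer(0); validation <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < 2L)
        stopf("class '%s' has %d event(s); need >= 2 to populate both sets",
              cl, length(idx))
      idx <- idx[sample.int(length(idx))]
      ntr <- floor(train_fraction * length(idx))
      train <- c(train, idx[seq_len(ntr)])
      validation <- c(validation, idx[setdiff(seq_along(idx), seq_len(ntr))])
    }
    list(train = sort(train), validation = sort(validation))
  })
}

# ---- layer primitives --------------------------------------------------

# valid 2-D convolution via im2col; X: (n,h,w,c), W: (k*k*c, cout)
conv_forward <- function(X, W, b, k) {
  d <- dim(X); n <- d[1]; h <- d[2]; w <- d[3]; cin <- d[4]
  oh <- h - k + 1L; ow <- w - k + 1L
  M <- matrix(0, n * oh * ow, k * k * cin)
  q <- 0L
  for (cc in seq_len(cin)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    q <- q + 1L
    M[, q] <- X[, di:(di + oh - 1L), dj:(dj + ow - 1L), cc]
  }
  Y <- M %*% W
  Y <- sweep(Y, 2L, b, "+")
  list(out = array(Y, c(n, oh, ow, ncol(W))), M = M, in_dim = d)
}

conv_backward <- function(dY, cache, W, k) {
  d <- dim(dY); n <- d[1]; oh <- d[2]; ow <- d[3]; cout <- d[4]
  dYm <- matrix(dY, n * oh * ow, cout)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, W)
  dX <- array(0, cache$in_dim)
  q <- 0L
  for (cc in seq_len(cache$in_dim[4])) for (dj in seq_len(k)) for (di in seq_len(k)) {
    q <- q + 1L
    dX[, di:(di + oh - 1L), dj:(dj + ow - 1L), cc] <-
      dX[, di:(di + oh - 1L), dj:(dj + ow - 1L), cc] +
      array(dM[, q], c(n, oh, ow))
  }
  list(dX = dX, dW = dW, db = db)
}

# p x p max-pooling with stride p; remembers the winning offset per window
pool_forward <- function(X, p) {
  d <- dim(X); n <- d[1]; h <- d[2]; w <- d[3]; cc <- d[4]
  oh <- h %/% p; ow <- w %/% p
  best <- NULL; idx <- NULL; k <- 0L
  for (b in seq_len(p)) for (a in seq_len(p)) {
    k <- k + 1L
    sl <- X[, seq(a, by = p, length.out = oh),
            seq(b, by = p, length.out = ow), , drop = FALSE]
    if (is.null(best)) {
      best <- sl; idx <- array(1L, dim(sl))
    } else {
      upd <- sl > best
      best[upd] <- sl[upd]; idx[upd] <- k
    }
  }
  list(out = best, argmax = idx, in_dim = d)
}

pool_backward <- function(dP, cache, p) {
  dX <- array(0, cache$in_dim)
  d <- dim(dP); oh <- d[2]; ow <- d[3]
  k <- 0L
  for (b in seq_len(p)) for (a in seq_len(p)) {
    k <- k + 1L
    g <- dP * (cache$argmax == k)
    dX[, seq(a, by = p, length.out = oh),
       seq(b, by = p, length.out = ow), ] <- g
  }
  dX
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# output spatial dims of one stack given input c(h, w)
stack_out_dim <- function(shape, n_blocks, k, p) {
  h <- shape[1]; w <- shape[2]
  for (i in seq_len(n_blocks)) {
    if (k > h || k > w)
      stopf("kernel %d larger than input %dx%d at block %d", k, h, w, i)
    h <- (h - k + 1L) %/% p; w <- (w - k + 1L) %/% p
    if (h < 1 || w < 1)
      stopf("input collapses to nothing after block %d; reduce n_blocks/pool", i)
  }
  c(h, w)
}

#' Build an untrained multi-input CNN
#'
#' Instantiates one convolutional stack per input signal modality, a
#' feature concatenation across modalities and a K-way softmax head, with
#' He-initialized weights deterministic in `config$seed`. The parameter
#' count is computed and stored on the model.
#'
#' @param config a `classifier_config`.
#' @param input_shapes named list of `c(height, width)` per modality (e.g.
#'   from `templates$signal_dims` or `lapply(batch$signals, function(a)
#'   dim(a)[2:3])`).
#' @return an untrained model of class `starch_cnn`.
#' @export
build_model <- function(config, input_shapes) {
  if (!inherits(config, "classifier_config"))
    stopf("config must be a classifier_config")
  if (!length(input_shapes) || is.null(names(input_shapes)))
    stopf("input_shapes must be a named list of c(height, width)")
  K <- length(config$class_names)
  k <- config$kernel; p <- config$pool; ch <- config$channels
  arch <- list(); flat <- integer(0)
  for (nm in names(input_shapes)) {
    shape <- as.integer(input_shapes[[nm]])
    out <- stack_out_dim(shape, config$n_blocks, k, p)
    arch[[nm]] <- list(shape = shape, out = out)
    flat[nm] <- prod(out) * ch
  }
  feat_dim <- sum(flat)
  par <- with_seed(config$seed, {
    par <- list()
    for (nm in names(input_shapes)) {
      cin <- 1L
      for (i in seq_len(config$n_blocks)) {
        fan_in <- k * k * cin
        par[[sprintf("%s_conv%d_W", nm, i)]] <-
          matrix(stats::rnorm(fan_in * ch, 0, sqrt(2 / fan_in)), fan_in, ch)
        par[[sprintf("%s_conv%d_b", nm, i)]] <- numeric(ch)
        cin <- ch
      }
    }
    par$head_W1 <- matrix(stats::rnorm(feat_dim * config$head_width, 0,
                                       sqrt(2 / feat_dim)),
                          feat_dim, config$head_width)
    par$head_b1 <- numeric(config$head_width)
    par$head_W2 <- matrix(stats::rnorm(config$head_width * K, 0,
                                       sqrt(2 / config$head_width)),
                          config$head_width, K)
    par$head_b2 <- numeric(K)
    par
  })
  structure(list(config = config, class_names = config$class_names,
                 input_shapes = lapply(input_shapes, as.integer),
                 arch = arch, feat_dim = feat_dim, par = par,
                 norm = NULL, trained = FALSE,
                 n_params = sum(vapply(par, length, 1L))),
            class = "starch_cnn")
}

#' @export
print.starch_cnn <- function(x, ...) {
  cat(sprintf("<starch_cnn: %d classes, inputs [%s], %d parameters, %s>\n",
              length(x$class_names),
              paste(sprintf("%s %dx%d", names(x$input_shapes),
                            vapply(x$input_shapes, `[`, 1L, 1L),
                            vapply(x$input_shapes, `[`, 1L, 2L)),
                    collapse = "; "),
              x$n_params, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# forward pass; returns probabilities and (optionally) all caches
cnn_forward <- function(model, signals, idx, dropout_mask = NULL,
                        keep_cache = FALSE) {
  cfg <- model$config
  feats <- list(); caches <- list()
  for (nm in names(model$input_shapes)) {
    X <- signals[[nm]][idx, , , drop = FALSE]
    if (!is.null(model$norm))
      X <- (X - model$norm[[nm]]$mean) / model$norm[[nm]]$sd
    dim(X) <- c(dim(X), 1L)
    stack_cache <- list()
    for (i in seq_len(cfg$n_blocks)) {
      cv <- conv_forward(X, model$par[[sprintf("%s_conv%d_W", nm, i)]],
                         model$par[[sprintf("%s_conv%d_b", nm, i)]],
                         cfg$kernel)
      A <- cv$out; relu_mask <- A > 0; A[!relu_mask] <- 0
      pl <- pool_forward(A, cfg$pool)
      X <- pl$out
      if (keep_cache)
        stack_cache[[i]] <- list(conv = cv, relu = relu_mask, pool = pl)
    }
    feats[[nm]] <- matrix(X, nrow = length(idx))
    if (keep_cache) caches[[nm]] <- stack_cache
  }
  feat <- do.call(cbind, feats)
  featd <- if (is.null(dropout_mask)) feat else feat * dropout_mask
  Z1 <- sweep(featd %*% model$par$head_W1, 2L, model$par$head_b1, "+")
  H1 <- Z1; H1[H1 < 0] <- 0
  logits <- sweep(H1 %*% model$par$head_W2, 2L, model$par$head_b2, "+")
  prob <- softmax_rows(logits)
  out <- list(prob = prob, feat = feat, featd = featd, H1 = H1)
  if (keep_cache) out$caches <- caches
  out
}

# full backward pass; returns gradient list parallel to model$par
cnn_backward <- function(model, fwd, idx_n, onehot, dropout_mask) {
  cfg <- model$config
  grads <- list()
  dlogits <- (fwd$prob - onehot) / idx_n
  grads$head_W2 <- crossprod(fwd$H1, dlogits)
  grads$head_b2 <- colSums(dlogits)
  dH1 <- tcrossprod(dlogits, model$par$head_W2)
  dH1[fwd$H1 <= 0] <- 0
  grads$head_W1 <- crossprod(fwd$featd, dH1)
  grads$head_b1 <- colSums(dH1)
  dfeat <- tcrossprod(dH1, model$par$head_W1)
  if (!is.null(dropout_mask)) dfeat <- dfeat * dropout_mask
  off <- 0L
  for (nm in names(model$input_shapes)) {
    out <- model$arch[[nm]]$out
    fdim <- prod(out) * cfg$channels
    dX <- array(dfeat[, off + seq_len(fdim)],
                c(idx_n, out[1], out[2], cfg$channels))
    off <- off + fdim
    for (i in rev(seq_len(cfg$n_blocks))) {
      cache <- fwd$caches[[nm]][[i]]
      dA <- pool_backward(dX, cache$pool, cfg$pool)
      dA[!cache$relu] <- 0
      cb <- conv_backward(dA, cache$conv,
                          model$par[[sprintf("%s_conv%d_W", nm, i)]],
                          cfg$kernel)
      grads[[sprintf("%s_conv%d_W", nm, i)]] <- cb$dW
      grads[[sprintf("%s_conv%d_b", nm, i)]] <- cb$db
      dX <- cb$dX
    }
  }
  grads
}

#' Train the multi-input CNN
#'
#' Minibatch Adam on the softmax cross-entropy, with per-modality global
#' standardization computed on the training events, a seeded stratified
#' train/validation split, inverted dropout on the concatenated features,
#' and a validation evaluation at the end. Deterministic given
#' `config$seed` (and a fixed BLAS thread count).
#'
#' @param model an untrained (or previously trained) `starch_cnn`.
#' @param batch a fully labelled `event_batch` whose signal shapes match
#'   the model.
#' @param split optional list with `train`/`validation` index vectors; by
#'   default computed by [split_train_validation()] with the model's
#'   `train_fraction` and seed.
#' @return list with the trained `model` and a `train_report` (epoch
#'   losses, index sets, confusion matrix, overall and per-class validation
#'   accuracy).
#' @export
train_classifier <- function(model, batch, split = NULL) {
  if (!inherits(model, "starch_cnn")) stopf("model must come from build_model()")
  if (!inherits(batch, "event_batch")) stopf("batch must be an event_batch")
  if (anyNA(batch$labels)) stopf("training batch must be fully labelled")
  if (!all(batch$labels %in% model$class_names))
    stopf("labels outside the model's class set: %s",
          paste(setdiff(unique(batch$labels), model$class_names), collapse = ", "))
  check_shapes(model, batch)
  cfg <- model$config
  if (is.null(split))
    split <- split_train_validation(batch, cfg$train_fraction, cfg$seed)
  tr <- split$train; va <- split$validation
  if (!length(tr)) stopf("empty training set")

  # per-modality global standardization from the training events
  model$norm <- lapply(batch$signals[names(model$input_shapes)], function(a) {
    m <- mean(a[tr, , ]); s <- stats::sd(a[tr, , ])
    list(mean = m, sd = if (is.finite(s) && s > 0) s else 1)
  })
  names(model$norm) <- names(model$input_shapes)

  K <- length(model$class_names)
  y <- match(batch$labels, model$class_names)
  adam_m <- lapply(model$par, function(p) p * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_step <- 0L
  epoch_losses <- numeric(cfg$epochs)

  with_seed(derive_seed(cfg$seed, 3L), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- tr[sample.int(length(tr))]
      nb <- ceiling(length(ord) / cfg$batch_size)
      tot_loss <- 0
      for (b in seq_len(nb)) {
        idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size,
                                                        length(ord))]
        n_i <- length(idx)
        mask <- if (cfg$dropout > 0)
          matrix((stats::runif(n_i * model$feat_dim) >= cfg$dropout) /
                   (1 - cfg$dropout), n_i, model$feat_dim)
        else NULL
        fwd <- cnn_forward(model, batch$signals, idx, mask, keep_cache = TRUE)
        onehot <- matrix(0, n_i, K)
        onehot[cbind(seq_len(n_i), y[idx])] <- 1
        loss <- -mean(log(pmax(fwd$prob[cbind(seq_len(n_i), y[idx])], 1e-12)))
        if (!is.finite(loss))
          stopf("training diverged (non-finite loss) at epoch %d", ep)
        tot_loss <- tot_loss + loss * n_i
        grads <- cnn_backward(model, fwd, n_i, onehot, mask)
        t_step <- t_step + 1L
        for (nm in names(model$par)) {
          g <- grads[[nm]]
          adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
          adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
          mhat <- adam_m[[nm]] / (1 - beta1^t_step)
          vhat <- adam_v[[nm]] / (1 - beta2^t_step)
          model$par[[nm]] <- model$par[[nm]] -
            cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      epoch_losses[ep] <- tot_loss / length(ord)
    }
  })
  model$trained <- TRUE

  pred <- predict(model, batch[va])
  ev <- evaluate(batch$labels[va], pred$labels, model$class_names)
  report <- structure(list(epoch_losses = epoch_losses, train_idx = tr,
                           validation_idx = va, confusion = ev$confusion,
                           accuracy = ev$overall_accuracy,
                           per_class_accuracy = ev$per_class_accuracy),
                      class = "train_report")
  list(model = model, report = report)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf(paste0("<train_report: %d epochs, loss %.4f -> %.4f, ",
                     "%d train / %d validation, accuracy %.3f>\n"),
              length(x$epoch_losses), x$epoch_losses[1],
              x$epoch_losses[length(x$epoch_losses)],
              length(x$train_idx), length(x$validation_idx), x$accuracy))
  print(round(x$per_class_accuracy, 3))
  invisible(x)
}

check_shapes <- function(model, batch) {
  for (nm in names(model$input_shapes)) {
    a <- batch$signals[[nm]]
    if (is.null(a)) stopf("batch lacks signal modality '%s'", nm)
    if (!all(dim(a)[2:3] == model$input_shapes[[nm]]))
      stopf("signal '%s' shape %dx%d does not match the model's %dx%d",
            nm, dim(a)[2], dim(a)[3],
            model$input_shapes[[nm]][1], model$input_shapes[[nm]][2])
  }
}

#' Classify particle events
#'
#' @param object a `starch_cnn`.
#' @param batch an `event_batch` with matching signal shapes.
#' @param chunk events per forward-pass chunk (memory control).
#' @param ... unused.
#' @return list with `prob` (n x K matrix, rows summing to 1) and `labels`
#'   (argmax class names; ties break to the lowest class index).
#' @export
predict.starch_cnn <- function(object, batch, chunk = 512L, ...) {
  if (!inherits(batch, "event_batch")) stopf("batch must be an event_batch")
  check_shapes(object, batch)
  n <- length(batch)
  K <- length(object$class_names)
  prob <- matrix(NA_real_, n, K, dimnames = list(NULL, object$class_names))
  i <- 1L
  while (i <= n) {
    idx <- i:min(i + chunk - 1L, n)
    prob[idx, ] <- cnn_forward(object, batch$signals, idx)$prob
    i <- i + chunk
  }
  labels <- if (n > 0) object$class_names[max.col(prob, ties.method = "first")]
  else character(0)
  list(prob = prob, labels = labels)
}

#' Confusion matrix and accuracies
#'
#' @param truth character vector of true labels.
#' @param predicted character vector of predicted labels (same length).
#' @param class_names the full ordered class set.
#' @return list with `confusion` (K x K counts, rows = truth, columns =
#'   predicted), `overall_accuracy` (trace / total) and
#'   `per_class_accuracy` (diagonal / row sum; `NaN` for absent classes).
#' @export
evaluate <- function(truth, predicted, class_names) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (!length(truth)) stopf("empty label vectors")
  if (length(truth) != length(predicted))
    stopf("truth (%d) and predicted (%d) differ in length",
          length(truth), length(predicted))
  bad <- setdiff(unique(c(truth, predicted)), class_names)
  if (length(bad))
    stopf("labels outside class_names: %s", paste(bad, collapse = ", "))
  confusion <- table(factor(truth, levels = class_names),
                     factor(predicted, levels = class_names))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("truth", "predicted")
  rs <- rowSums(confusion)
  list(confusion = confusion,
       overall_accuracy = sum(diag(confusion)) / sum(confusion),
       per_class_accuracy = diag(confusion) / rs)
}
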