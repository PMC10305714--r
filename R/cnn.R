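#' CNN architecture and training hyperparameters
#'
#' Fixed topology with parameterised sizes: three convolution blocks of
#' `n_filters` kernels of width `kernel_size` (stride 1, ReLU, batch
#' normalisation), max pooling of size `pool_size` after the first block
#' only, global average pooling, dropout, and a dense softmax layer with one
#' unit per class.  Defaults: 128 kernels of width 5, pool 3, dropout 0.4,
#' batch size 32, 100 epochs, learning rate 2e-4.
#'
#' @param n_filters,kernel_size,pool_size Convolution block sizes.
#' @param dropout_rate Dropout probability in `[0, 1)` before the dense layer.
#' @param n_classes Number of output classes.
#' @param input_len,n_channels Input shape (time length x channels).
#' @param batch_size,epochs,learning_rate Training hyperparameters (Adam).
#' @param bn_momentum Running-statistics momentum for batch normalisation.
#' @param early_stopping_patience Optional integer; when set, training stops
#'   after this many epochs without validation-accuracy improvement and the
#'   best parameters are restored.
#' @param seed Seed for weight initialisation, shuffling and dropout.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(n_filters = 128L, kernel_size = 5L, pool_size = 3L,
                       dropout_rate = 0.4, n_classes = 16L,
                       input_len = 3000L, n_channels = 7L,
                       batch_size = 32L, epochs = 100L,
                       learning_rate = 2e-4, bn_momentum = 0.1,
                       early_stopping_patience = NULL, seed = 1L) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            n_filters >= 1, kernel_size >= 1, pool_size >= 1, n_classes >= 2)
  structure(list(
    n_filters = as.integer(n_filters), kernel_size = as.integer(kernel_size),
    pool_size = as.integer(pool_size), dropout_rate = dropout_rate,
    n_classes = as.integer(n_classes), input_len = as.integer(input_len),
    n_channels = as.integer(n_channels), batch_size = as.integer(batch_size),
    epochs = as.integer(epochs), learning_rate = learning_rate,
    bn_momentum = bn_momentum,
    early_stopping_patience = early_stopping_patience,
    seed = as.integer(seed)
  ), class = "cnn_config")
}

# Sequence lengths after each stage; errors when the receptive field
# exhausts the input.
cnn_layer_lengths <- function(config) {
  k <- config$kernel_size
  l1 <- config$input_len - k + 1L
  lp <- l1 %/% config$pool_size
  l2 <- lp - k + 1L
  l3 <- l2 - k + 1L
  if (l1 < 1L || lp < 1L || l2 < 1L || l3 < 1L) {
    stop(sprintf("input_len %d is too short for the receptive field",
                 config$input_len), call. = FALSE)
  }
  c(conv1 = l1, pool = lp, conv2 = l2, conv3 = l3)
}

#' Build the 1D CNN
#'
#' Initialises all weights (He-normal for convolution and dense layers,
#' unit-gain batch norm) from `config$seed`.
#'
#' @param config A [cnn_config()].
#' @return An untrained model of class `driveact_cnn`.
#' @export
build_model <- function(config = cnn_config()) {
  cnn_layer_lengths(config)  # validates the receptive field
  k <- config$kernel_size
  K <- config$n_filters
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  he <- function(fan_in, n_out) {
    matrix(rnorm(fan_in * n_out, 0, sqrt(2 / fan_in)), fan_in, n_out)
  }
  params <- list(
    W1 = he(k * config$n_channels, K), b1 = numeric(K),
    g1 = rep(1, K), be1 = numeric(K),
    W2 = he(k * K, K), b2 = numeric(K), g2 = rep(1, K), be2 = numeric(K),
    W3 = he(k * K, K), b3 = numeric(K), g3 = rep(1, K), be3 = numeric(K),
    Wd = he(K, config$n_classes), bd = numeric(config$n_classes)
  )
  running <- list(rm1 = numeric(K), rv1 = rep(1, K),
                  rm2 = numeric(K), rv2 = rep(1, K),
                  rm3 = numeric(K), rv3 = rep(1, K))
  structure(list(config = config, params = params, running = running,
                 trained = FALSE, history = NULL),
            class = "driveact_cnn")
}

#' @rdname build_model
#' @param model A `driveact_cnn`.
#' @return `count_parameters()`: the number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.driveact_cnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<driveact_cnn: 3 x conv(%d, k=%d) + BN, pool %d, GAP, dropout %.2f, dense %d; %s, %s parameters>\n",
    cfg$n_filters, cfg$kernel_size, cfg$pool_size, cfg$dropout_rate,
    cfg$n_classes, if (x$trained) "trained" else "untrained",
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Categorical cross-entropy
#'
#' `-sum(t * log(p))` for a one-hot truth vector `t` and predicted
#' probabilities `p`.
#'
#' @param truth One-hot (or probability) truth vector.
#' @param probs Predicted probability vector of the same length.
#' @return Non-negative scalar loss.
#' @export
cross_entropy <- function(truth, probs) {
  stopifnot(length(truth) == length(probs))
  active <- truth > 0
  -sum(truth[active] * log(probs[active]))
}

# (N, L, C) array -> (L, C, N) cube for the compiled kernels
inputs_to_cube <- function(x) aperm(x, c(2, 3, 1))

onehot <- function(y, n_classes) {
  m <- matrix(0, n_classes, length(y))
  m[cbind(y + 1L, seq_along(y))] <- 1
  m
}

#' Train the CNN
#'
#' Minimises categorical cross-entropy with Adam (learning rate and batch
#' size from the config), recording per-epoch training and validation loss
#' and accuracy.  All randomness (shuffling, dropout masks) is driven by the
#' config seed, so training is deterministic.
#'
#' @param model A `driveact_cnn` from [build_model()].
#' @param x_train,y_train Training inputs, an `(n, input_len, n_channels)`
#'   array and integer class codes `0 .. n_classes-1`.
#' @param x_val,y_val Optional validation set in the same layout.
#' @param epochs Override for `config$epochs`.
#' @param verbose Print one line per epoch.
#' @return The trained model, with a `history` data frame (epoch, loss,
#'   accuracy, val_loss, val_accuracy).
#' @export
cnn_train <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                      epochs = NULL, verbose = FALSE) {
  cfg <- model$config
  if (is.null(epochs)) epochs <- cfg$epochs
  n <- dim(x_train)[1]
  if (is.null(n) || n == 0L) stop("empty training set", call. = FALSE)
  if (length(y_train) != n) stop("x/y length mismatch", call. = FALSE)
  if (any(y_train < 0 | y_train >= cfg$n_classes)) {
    stop("training labels outside 0..n_classes-1", call. = FALSE)
  }
  has_val <- !is.null(x_val) && dim(x_val)[1] > 0
  if (!is.null(x_val) && !has_val) stop("empty validation set", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed + 1L)

  params <- model$params
  running <- model$running
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  t_step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  keep <- 1 - cfg$dropout_rate
  K <- cfg$n_filters
  hist_rows <- vector("list", epochs)
  best <- list(acc = -Inf, params = params, running = running, epoch = 0L)
  stall <- 0L

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xb <- inputs_to_cube(x_train[idx, , , drop = FALSE])
      yb <- onehot(y_train[idx], cfg$n_classes)
      mask <- if (cfg$dropout_rate > 0) {
        matrix(rbinom(K * length(idx), 1L, keep) / keep, K, length(idx))
      } else {
        matrix(1, K, length(idx))
      }
      step <- cpp_cnn_train_step(xb, yb, params, running, mask,
                                 cfg$pool_size, cfg$bn_momentum)
      if (!is.finite(step$loss)) {
        stop(sprintf("non-finite loss at epoch %d (diverged); try a lower learning rate",
                     ep), call. = FALSE)
      }
      running <- step$running
      t_step <- t_step + 1L
      corr1 <- 1 - beta1^t_step
      corr2 <- 1 - beta2^t_step
      for (nm in names(params)) {
        g <- step$grads[[nm]]
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
        params[[nm]] <- params[[nm]] - cfg$learning_rate *
          (adam_m[[nm]] / corr1) / (sqrt(adam_v[[nm]] / corr2) + adam_eps)
      }
      ep_loss <- ep_loss + step$loss * length(idx)
      pred <- max.col(t(step$probs), ties.method = "first") - 1L
      ep_correct <- ep_correct + sum(pred == y_train[idx])
    }
    row <- data.frame(epoch = ep, loss = ep_loss / n, accuracy = ep_correct / n,
                      val_loss = NA_real_, val_accuracy = NA_real_)
    if (has_val) {
      ev <- eval_forward(x_val, params, running, cfg)
      row$val_loss <- ev$loss_of(y_val)
      row$val_accuracy <- mean(ev$labels == y_val)
    }
    hist_rows[[ep]] <- row
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  acc %.3f  val_acc %s\n", ep,
                  row$loss, row$accuracy,
                  ifelse(is.na(row$val_accuracy), "-",
                         sprintf("%.3f", row$val_accuracy))))
    }
    if (!is.null(cfg$early_stopping_patience) && has_val) {
      if (row$val_accuracy > best$acc + 1e-12) {
        best <- list(acc = row$val_accuracy, params = params,
                     running = running, epoch = ep)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg$early_stopping_patience) break
      }
    }
  }
  if (!is.null(cfg$early_stopping_patience) && has_val && best$epoch > 0L) {
    params <- best$params
    running <- best$running
  }
  model$params <- params
  model$running <- running
  model$trained <- TRUE
  model$history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null, logical(1))])
  model
}

# Batched eval-mode forward pass; returns probabilities, argmax labels and a
# cross-entropy closure.
eval_forward <- function(x, params, running, cfg, batch = 64L) {
  n <- dim(x)[1]
  probs <- matrix(NA_real_, n, cfg$n_classes)
  feats <- matrix(NA_real_, n, cfg$n_filters)
  for (start in seq(1L, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out <- cpp_cnn_eval(inputs_to_cube(x[idx, , , drop = FALSE]),
                        params, running, cfg$pool_size)
    probs[idx, ] <- t(out$probs)
    feats[idx, ] <- t(out$features)
  }
  labels <- max.col(probs, ties.method = "first") - 1L
  list(
    probs = probs, labels = labels, features = feats,
    loss_of = function(y) {
      eps <- 1e-12
      -mean(log(probs[cbind(seq_len(n), y + 1L)] + eps))
    }
  )
}

#' Predict class probabilities and labels
#'
#' Evaluation-mode forward pass (dropout off, batch norm uses running
#' statistics): repeated calls on the same inputs give identical output.
#' The label is the probability argmax; ties break toward the lowest class
#' code.
#'
#' @param object A trained `driveact_cnn`.
#' @param x Inputs, an `(n, input_len, n_channels)` array.
#' @param ... Unused.
#' @return List with `probabilities` (`n x n_classes`, rows sum to 1),
#'   `labels` (integer codes) and `features` (the pooled embedding,
#'   `n x n_filters`, usable with [pca_embed()]).
#' @export
predict.driveact_cnn <- function(object, x, ...) {
  cfg <- object$config
  d <- dim(x)
  if (length(d) != 3L || d[2] != cfg$input_len || d[3] != cfg$n_channels) {
    stop(sprintf("inputs must be an (n, %d, %d) array", cfg$input_len,
                 cfg$n_channels), call. = FALSE)
  }
  ev <- eval_forward(x, object$params, object$running, cfg)
  list(probabilities = ev$probs, labels = ev$labels, features = ev$features)
}

#' Stratified train/validation/test split
#'
#' First a 9:1 split into (training pool, test), then an 8:2 split of the
#' pool into (train, validation), giving 72% / 18% / 10% of the whole.
#' Within each stage the per-class allocation uses largest-remainder
#' rounding so the global fractions are met while classes stay balanced;
#' items are shuffled within class by the seed.
#'
#' @param labels Integer class codes, one per item (length >= 10).
#' @param test_fraction,val_fraction The 9:1 and 8:2 stage fractions.
#' @param seed Shuffle seed.
#' @return List of disjoint, exhaustive 1-based index vectors `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(labels, test_fraction = 0.1, val_fraction = 0.2,
                          seed = 1L) {
  n <- length(labels)
  if (n < 10L) stop("dataset must contain at least 10 items", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  classes <- sort(unique(labels))
  pools <- lapply(classes, function(cl) {
    idx <- which(labels == cl)
    idx[sample.int(length(idx))]
  })
  counts <- lengths(pools)

  n_test <- round(n * test_fraction)
  take_test <- largest_remainder(counts, n_test)
  n_val <- round((n - n_test) * val_fraction)
  take_val <- largest_remainder(counts - take_test, n_val)

  test <- integer(0); val <- integer(0); train <- integer(0)
  for (i in seq_along(pools)) {
    p <- pools[[i]]
    test <- c(test, utils::head(p, take_test[i]))
    rest <- utils::tail(p, length(p) - take_test[i])
    val <- c(val, utils::head(rest, take_val[i]))
    train <- c(train, utils::tail(rest, length(rest) - take_val[i]))
  }
  list(train = sort(train), validation = sort(val), test = sort(test))
}

# Apportion `total` over classes proportionally to `counts`.
largest_remainder <- function(counts, total) {
  if (total <= 0L || sum(counts) == 0L) return(integer(length(counts)))
  quota <- counts * total / sum(counts)
  base <- pmin(floor(quota), counts)
  rem <- total - sum(base)
  if (rem > 0) {
    frac <- quota - floor(quota)
    frac[base >= counts] <- -1  # cannot take more than the class holds
    ord <- order(frac, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
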