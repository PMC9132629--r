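# Three-layer backpropagation network: input -> sigmoid hidden -> sigmoid
# output, trained by gradient descent with momentum on the squared-error
# surrogate of RMSE. One-hot targets; RMSE is what is logged and what
# drives early stopping and hidden-size selection.

#' Numerically stable logistic sigmoid
#'
#' `1 / (1 + exp(-x))`, computed branch-wise so it neither overflows nor
#' underflows for |x| up to several hundred.
#'
#' @param x numeric vector or matrix.
#' @return values in (0, 1), same shape as `x`.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' Root mean square error
#'
#' `sqrt(mean((outputs - targets)^2))` over all entries.
#'
#' @param outputs numeric matrix (or vector) of network outputs.
#' @param targets one-hot target matrix of the same shape.
#' @return a nonnegative scalar.
#' @export
rmse <- function(outputs, targets) {
  fail_if(length(outputs) == 0L, "rmse of empty input is undefined")
  fail_if(!identical(dim(outputs), dim(targets)) &&
            length(outputs) != length(targets),
          "outputs and targets must have the same shape")
  sqrt(mean((outputs - targets)^2))
}

#' Training configuration for the backpropagation network
#'
#' @param hidden_sizes_grid candidate hidden-node counts for
#'   [select_hidden_size()].
#' @param learning_rate positive step size.
#' @param momentum momentum coefficient in \[0, 1).
#' @param max_epochs epoch budget.
#' @param batch_mode `"per_sample"` (stochastic, shuffled each epoch) or
#'   `"full_batch"` (one mean-gradient step per epoch).
#' @param early_stop_patience epochs without validation-RMSE improvement
#'   before stopping.
#' @param validation_fraction fraction of the training rows carved off
#'   (stratified, seeded) for early stopping and model selection. On very
#'   small data the carved set can be empty, in which case training RMSE
#'   is used instead.
#' @param weight_init_scale weights start uniform in
#'   `±weight_init_scale / sqrt(fan_in)`.
#' @param standardize z-score the inputs with training-set statistics
#'   (stored in the model, reapplied at prediction); raw n-gram counts
#'   saturate sigmoid units otherwise.
#' @param seed integer seed for initialization, the validation split and
#'   the per-epoch shuffles.
#' @return an object of class `bpnn_config`.
#' @export
bpnn_config <- function(hidden_sizes_grid = c(4L, 8L, 16L, 32L, 64L),
                        learning_rate = 0.1, momentum = 0.9,
                        max_epochs = 500L,
                        batch_mode = c("per_sample", "full_batch"),
                        early_stop_patience = 20L,
                        validation_fraction = 0.2,
                        weight_init_scale = 1,
                        standardize = TRUE,
                        seed = 1L) {
  batch_mode <- match.arg(batch_mode)
  fail_if(learning_rate < 0, "learning_rate must be nonnegative")
  fail_if(length(hidden_sizes_grid) == 0L, "hidden size grid is empty")
  fail_if(!(momentum >= 0 && momentum < 1), "momentum must be in [0, 1)")
  fail_if(!(validation_fraction > 0 && validation_fraction < 1),
          "validation_fraction must be in (0, 1)")
  fail_if(weight_init_scale <= 0, "weight_init_scale must be positive")
  structure(list(hidden_sizes_grid = sort(as.integer(hidden_sizes_grid)),
                 learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 batch_mode = batch_mode,
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 weight_init_scale = weight_init_scale,
                 standardize = isTRUE(standardize),
                 seed = as.integer(seed)),
            class = "bpnn_config")
}

# bare model container (weights already on the standardized input scale)
new_bpnn <- function(W1, b1, W2, b2, class_names,
                     center = NULL, scale = NULL) {
  structure(list(W_in_hidden = W1, b_hidden = b1,
                 W_hidden_out = W2, b_out = b2,
                 n_hidden = ncol(W1), class_names = class_names,
                 center = center, scale = scale),
            class = "bpnn")
}

#' Initialize a network with seeded uniform weights
#'
#' Weights uniform in `±scale / sqrt(fan_in)`, biases zero.
#'
#' @param n_in,n_hidden,n_out layer sizes.
#' @param class_names output class names (length `n_out`).
#' @param weight_init_scale see [bpnn_config()].
#' @param seed integer seed.
#' @return a `bpnn` model object.
#' @export
bpnn_init <- function(n_in, n_hidden, n_out, class_names = NULL,
                      weight_init_scale = 1, seed = 1L) {
  if (is.null(class_names)) class_names <- as.character(seq_len(n_out))
  with_seed(seed, {
    r1 <- weight_init_scale / sqrt(n_in)
    r2 <- weight_init_scale / sqrt(n_hidden)
    new_bpnn(matrix(stats::runif(n_in * n_hidden, -r1, r1), n_in, n_hidden),
             numeric(n_hidden),
             matrix(stats::runif(n_hidden * n_out, -r2, r2), n_hidden, n_out),
             numeric(n_out), class_names)
  })
}

#' Forward pass
#'
#' Hidden activations `h = sigmoid(x W1 + b1)` and output activations
#' `o = sigmoid(h W2 + b2)`; the pre-activation sums are the units' net
#' excitation. Accepts a single row or a matrix of rows. No input
#' standardization is applied here — `x` is taken as-is.
#'
#' @param model a `bpnn`.
#' @param x numeric vector (one document) or matrix (rows = documents)
#'   whose width equals the input dimension.
#' @return list with `hidden` and `output` activation matrices.
#' @export
bpnn_forward <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  fail_if(ncol(x) != nrow(model$W_in_hidden),
          sprintf("input has %d features; model expects %d",
                  ncol(x), nrow(model$W_in_hidden)))
  H <- sigmoid(sweep(x %*% model$W_in_hidden, 2L, model$b_hidden, `+`))
  O <- sigmoid(sweep(H %*% model$W_hidden_out, 2L, model$b_out, `+`))
  list(hidden = H, output = O)
}

#' Backward pass: gradients of the squared-error loss
#'
#' For loss `L = 0.5 * sum((o - t)^2)` (the surrogate whose minimizer is
#' also the RMSE minimizer): output deltas `(o - t) * o * (1 - o)`,
#' hidden deltas backpropagated through `W2` times `h * (1 - h)`, weight
#' gradients as outer products with each layer's inputs.
#'
#' @param model a `bpnn`.
#' @param x a single input row (numeric vector).
#' @param target one-hot numeric vector, length = number of outputs.
#' @return list of gradients `W_in_hidden`, `b_hidden`, `W_hidden_out`,
#'   `b_out`, matching the model's shapes.
#' @export
bpnn_backward <- function(model, x, target) {
  fail_if(length(target) != ncol(model$W_hidden_out),
          "target length must equal the output dimension")
  fwd <- bpnn_forward(model, x)
  h <- drop(fwd$hidden); o <- drop(fwd$output)
  delta_o <- (o - target) * o * (1 - o)
  delta_h <- drop(model$W_hidden_out %*% delta_o) * h * (1 - h)
  list(W_in_hidden = outer(as.numeric(x), delta_h),
       b_hidden = delta_h,
       W_hidden_out = outer(h, delta_o),
       b_out = delta_o)
}

# one-hot matrix from 0-based codes
one_hot <- function(labels, K) {
  Tm <- matrix(0, length(labels), K)
  Tm[cbind(seq_along(labels), labels + 1L)] <- 1
  Tm
}

# Stratified validation row indices (can be empty on tiny classes).
# Rows with identical feature vectors — the duplicates an oversampled
# matrix contains — always land on the same side of the split; otherwise
# validation RMSE rewards memorizing duplicated rows and early stopping
# locks onto overfit snapshots.
validation_rows <- function(X, labels, K, fraction, seed) {
  key <- apply(X, 1L, paste, collapse = ",")
  gid <- match(key, unique(key))
  with_seed(seed, {
    unlist(lapply(seq_len(K) - 1L, function(k) {
      cls <- labels == k
      gs <- unique(gid[cls])
      n_val <- floor(length(gs) * fraction)
      if (n_val == 0L) return(integer())
      pick <- gs[sample.int(length(gs), n_val)]
      sort(which(cls & gid %in% pick))
    }), use.names = FALSE)
  })
}

#' Fit a three-layer backpropagation network
#'
#' Targets are one-hot class indicators. Per-sample gradient descent with
#' momentum (sample order reshuffled every epoch under the seed), or one
#' mean-gradient step per epoch in full-batch mode. A stratified
#' validation split is carved from the training rows; training stops at
#' `max_epochs` or when validation RMSE has not improved for
#' `early_stop_patience` epochs, and the returned model is the snapshot
#' with the best validation RMSE.
#'
#' @param x a training `feature_matrix` with at least two classes.
#' @param n_hidden hidden-layer size.
#' @param config a [bpnn_config()].
#' @return an object of class `bpnn` with the weight matrices, biases,
#'   class names, input standardization parameters, and `history` (data
#'   frame of per-epoch training and validation RMSE).
#' @seealso [select_hidden_size()], [predict.bpnn()]
#' @export
bpnn <- function(x, n_hidden = 16L, config = bpnn_config()) {
  stopifnot(inherits(x, "feature_matrix"), inherits(config, "bpnn_config"))
  K <- length(x$class_names)
  fail_if(length(unique(x$labels)) < 2L,
          "training data must contain at least two classes")
  X <- x$values
  center <- scale_ <- NULL
  if (config$standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2L, stats::sd)
    scale_[scale_ < 1e-8] <- 1
    X <- sweep(sweep(X, 2L, center, `-`), 2L, scale_, `/`)
  }
  dimnames(X) <- NULL  # keeps weight matrices free of name clutter
  Tm <- one_hot(x$labels, K)
  val <- validation_rows(X, x$labels, K, config$validation_fraction,
                         stage_seed(config$seed, "bpnn_val"))
  fit <- setdiff(seq_len(nrow(X)), val)
  Xf <- X[fit, , drop = FALSE]; Tf <- Tm[fit, , drop = FALSE]
  Xv <- X[val, , drop = FALSE]; Tv <- Tm[val, , drop = FALSE]
  has_val <- length(val) > 0L

  model <- bpnn_init(ncol(X), n_hidden, K, x$class_names,
                     config$weight_init_scale,
                     stage_seed(config$seed, paste0("bpnn_init", n_hidden)))
  W1 <- model$W_in_hidden; b1 <- model$b_hidden
  W2 <- model$W_hidden_out; b2 <- model$b_out
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- b2 * 0
  lr <- config$learning_rate; mom <- config$momentum
  n_fit <- nrow(Xf)

  fwd_all <- function(M, W1, b1, W2, b2) {
    H <- sigmoid(sweep(M %*% W1, 2L, b1, `+`))
    sigmoid(sweep(H %*% W2, 2L, b2, `+`))
  }
  best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2, rmse = Inf, epoch = 0L)
  hist_train <- hist_val <- numeric(config$max_epochs)
  stall <- 0L; n_epochs <- 0L

  with_seed(stage_seed(config$seed, paste0("bpnn_train", n_hidden)), {
    for (epoch in seq_len(config$max_epochs)) {
      if (config$batch_mode == "per_sample") {
        for (i in sample.int(n_fit)) {
          xi <- Xf[i, ]
          h_in <- drop(xi %*% W1) + b1
          h <- 1 / (1 + exp(-h_in))
          o_in <- drop(h %*% W2) + b2
          o <- 1 / (1 + exp(-o_in))
          delta_o <- (o - Tf[i, ]) * o * (1 - o)
          delta_h <- drop(W2 %*% delta_o) * h * (1 - h)
          vW2 <- mom * vW2 - lr * outer(h, delta_o)
          vb2 <- mom * vb2 - lr * delta_o
          vW1 <- mom * vW1 - lr * outer(xi, delta_h)
          vb1 <- mom * vb1 - lr * delta_h
          W2 <- W2 + vW2; b2 <- b2 + vb2
          W1 <- W1 + vW1; b1 <- b1 + vb1
        }
      } else {
        H <- sigmoid(sweep(Xf %*% W1, 2L, b1, `+`))
        O <- sigmoid(sweep(H %*% W2, 2L, b2, `+`))
        Do <- (O - Tf) * O * (1 - O)
        Dh <- (Do %*% t(W2)) * H * (1 - H)
        vW2 <- mom * vW2 - lr * crossprod(H, Do) / n_fit
        vb2 <- mom * vb2 - lr * colMeans(Do)
        vW1 <- mom * vW1 - lr * crossprod(Xf, Dh) / n_fit
        vb1 <- mom * vb1 - lr * colMeans(Dh)
        W2 <- W2 + vW2; b2 <- b2 + vb2
        W1 <- W1 + vW1; b1 <- b1 + vb1
      }
      tr_rmse <- rmse(fwd_all(Xf, W1, b1, W2, b2), Tf)
      vl_rmse <- if (has_val) rmse(fwd_all(Xv, W1, b1, W2, b2), Tv)
                 else tr_rmse
      hist_train[epoch] <- tr_rmse; hist_val[epoch] <- vl_rmse
      n_epochs <- epoch
      if (vl_rmse < best$rmse - 1e-12) {
        best <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                     rmse = vl_rmse, epoch = epoch)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) break
      }
    }
  })
  out <- new_bpnn(best$W1, best$b1, best$W2, best$b2, x$class_names,
                  center, scale_)
  out$history <- data.frame(epoch = seq_len(n_epochs),
                            train_rmse = hist_train[seq_len(n_epochs)],
                            val_rmse = hist_val[seq_len(n_epochs)])
  out$val_rmse <- best$rmse
  out$best_epoch <- best$epoch
  out$has_validation <- has_val
  out$config <- config
  out
}

#' Choose the hidden-layer size by validation RMSE
#'
#' Trains one network per candidate size on the same seeded stratified
#' train/validation split and keeps the size whose best validation RMSE
#' is lowest; exact ties go to the smaller network.
#'
#' @param x a training `feature_matrix`.
#' @param config a [bpnn_config()]; `hidden_sizes_grid` supplies the
#'   candidates.
#' @return list with `best` (the chosen size), `table` (data frame of
#'   size and validation RMSE) and `models` (the fitted candidates,
#'   named by size).
#' @export
select_hidden_size <- function(x, config = bpnn_config()) {
  grid <- config$hidden_sizes_grid
  models <- lapply(grid, function(h) bpnn(x, h, config))
  rmses <- vapply(models, function(mdl) mdl$val_rmse, numeric(1))
  best <- grid[which.min(rmses)]  # grid ascending: tie -> smaller size
  list(best = best,
       table = data.frame(n_hidden = grid, val_rmse = rmses),
       models = stats::setNames(models, grid))
}

#' Predict classes with a fitted network
#'
#' Applies the stored input standardization, runs the forward pass and
#' assigns each row the class with the largest output activation; ties
#' break toward the lowest class index.
#'
#' @param object a fitted `bpnn`.
#' @param newdata a `feature_matrix` or bare numeric matrix with the
#'   model's input width.
#' @param type `"class"` for integer 0-based codes (default), `"prob"`
#'   for the raw output activations, `"label"` for class names.
#' @param ... unused.
#' @return integer codes, a matrix of activations, or class names.
#' @export
predict.bpnn <- function(object, newdata, type = c("class", "prob", "label"),
                         ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_matrix")) newdata$values
       else as.matrix(newdata)
  if (!is.null(object$center))
    X <- sweep(sweep(X, 2L, object$center, `-`), 2L, object$scale, `/`)
  O <- bpnn_forward(object, X)$output
  if (type == "prob") return(O)
  codes <- max.col(O, ties.method = "first") - 1L
  if (type == "class") codes else object$class_names[codes + 1L]
}

#' @export
print.bpnn <- function(x, ...) {
  cat(sprintf("Three-layer backpropagation network: %d -> %d -> %d\n",
              nrow(x$W_in_hidden), x$n_hidden, ncol(x$W_hidden_out)))
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  if (!is.null(x$val_rmse))
    cat(sprintf("  best %s RMSE %.4f at epoch %d (of %d run)\n",
                if (isTRUE(x$has_validation)) "validation" else "training",
                x$val_rmse, x$best_epoch, nrow(x$history)))
  invisible(x)
}

#' @export
summary.bpnn <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("RMSE history (last 5 epochs):\n")
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.bpnn <- function(x, ...) {
  stopifnot(!is.null(x$history))
  with(x$history, {
    graphics::plot(epoch, train_rmse, type = "l", ylim = range(c(train_rmse, val_rmse)),
         xlab = "epoch", ylab = "RMSE", main = "BPNN training", ...)
    graphics::lines(epoch, val_rmse, lty = 2)
  })
  graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Persist / load a fitted network as plain text
#'
#' Shapes, weights, biases, standardization parameters and class names
#' in a single JSON file.
#'
#' @param model a `bpnn`.
#' @param path destination file.
#' @return `path` (write) or a `bpnn` (read).
#' @export
write_bpnn <- function(model, path) {
  stopifnot(inherits(model, "bpnn"))
  payload <- list(W_in_hidden = model$W_in_hidden,
                  b_hidden = model$b_hidden,
                  W_hidden_out = model$W_hidden_out,
                  b_out = model$b_out,
                  class_names = model$class_names,
                  center = model$center, scale = model$scale)
  jsonlite::write_json(payload, path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_bpnn
#' @export
read_bpnn <- function(path) {
  p <- jsonlite::fromJSON(path)
  new_bpnn(as.matrix(p$W_in_hidden), as.numeric(p$b_hidden),
           as.matrix(p$W_hidden_out), as.numeric(p$b_out),
           as.character(p$class_names),
           if (is.null(p$center)) NULL else as.numeric(p$center),
           if (is.null(p$scale)) NULL else as.numeric(p$scale))
}
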