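#' Instantiate an untrained network
#'
#' Builds the layer weights for a [cnn_config()] with deterministic
#' Xavier-uniform initialisation under `init_seed`, and verifies that the
#' instantiated parameter total equals the closed-form
#' [count_parameters()].
#'
#' @param config A [cnn_config()].
#' @param init_seed Integer seed for weight initialisation.
#' @return An object of class `cnn_model`: list with `net` (weights),
#'   `config`, `parameter_count`, `init_seed`.
#' @export
build_model <- function(config = cnn_config(), init_seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  net <- init_net(config, init_seed)
  total <- net_param_total(net)
  expected <- count_parameters(config)
  if (total != expected)  # internal consistency guard
    stop(sprintf("instantiated parameters (%d) != closed-form count (%d)",
                 total, expected))
  structure(list(net = net, config = config,
                 parameter_count = as.integer(total),
                 init_seed = as.integer(init_seed)),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> untrained, %d parameters\n", x$parameter_count))
  print(x$config)
  invisible(x)
}

#' Forward pass: per-segment class scores
#'
#' @param object A `cnn_model` or fitted `fibrocnn` object.
#' @param x Segment matrix (segments x `input_len`), or a single segment.
#' @return Numeric matrix (segments x 2) of raw class scores; softmax of a
#'   row gives the class probabilities.
#' @export
cnn_forward <- function(object, x) {
  net <- object$net; config <- object$config
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != config$input_len)
    stop(sprintf("segments have %d samples, network expects %d",
                 ncol(x), config$input_len))
  net_forward(net, x, config)$scores
}

#' @describeIn build_model Per-segment prediction from an (un)trained
#'   `cnn_model`; same interface as [predict.fibrocnn()].
#' @param object,newdata,type,... See [predict.fibrocnn()].
#' @export
predict.cnn_model <- function(object, newdata,
                              type = c("class", "prob", "score"), ...) {
  predict.fibrocnn(object, newdata, type = match.arg(type))
}

#' Fit the 1-D CNN fibrosis classifier
#'
#' Trains the compact 1-D CNN on normalized RF segments with the Adam
#' optimizer and softmax cross-entropy loss. Mini-batches are reshuffled
#' every epoch under `train_seed`; the last incomplete batch is kept.
#' Training is fully deterministic for fixed data and seeds. By default the
#' final-epoch weights are returned (the schedule is a fixed number of
#' epochs); with `keep_best = TRUE` the epoch with the lowest validation
#' loss is restored instead.
#'
#' @param x Numeric matrix of training segments (segments x `input_len`),
#'   typically from [windows_to_segments()] after [build_task_dataset()].
#' @param y Integer 0/1 label per segment (1 = higher-fibrosis group).
#' @param x_val,y_val Optional validation segments/labels for the per-epoch
#'   validation loss.
#' @param config Architecture ([cnn_config()]).
#' @param epochs Training epochs (default 100).
#' @param batch_size Mini-batch size (default 256).
#' @param lr Adam learning rate (default 1e-3).
#' @param betas Adam moment decays (default `c(0.9, 0.999)`).
#' @param eps Adam epsilon.
#' @param init_seed,train_seed Seeds for initialisation and batch shuffling.
#' @param keep_best Restore the best-validation-loss epoch (default FALSE).
#' @param verbose Print per-epoch losses.
#' @return An object of class `fibrocnn`: the trained network plus
#'   `loss_history` (data.frame epoch/train/val), `config`, seeds, and the
#'   best-epoch index. Methods: [predict.fibrocnn()], `print`, `summary`,
#'   `coef` (weight arrays), `plot` (loss curves).
#' @examples
#' \donttest{
#' cfg <- cnn_config(input_len = 256)
#' x <- matrix(runif(40 * 256), 40)
#' y <- rep(0:1, each = 20)
#' fit <- fibrocnn(x, y, config = cfg, epochs = 2, batch_size = 16)
#' predict(fit, x[1:3, ], type = "prob")
#' }
#' @export
fibrocnn <- function(x, y, x_val = NULL, y_val = NULL,
                     config = cnn_config(), epochs = 100L, batch_size = 256L,
                     lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8,
                     init_seed = 1L, train_seed = 1L,
                     keep_best = FALSE, verbose = FALSE) {
  stopifnot(is.matrix(x), is.numeric(x))
  y <- as.integer(y)
  if (nrow(x) == 0L) stop("empty training set")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (!all(y %in% 0:1)) stop("labels must be 0/1")
  if (ncol(x) != config$input_len)
    stop(sprintf("segments have %d samples, network expects %d",
                 ncol(x), config$input_len))
  if (epochs < 1L || batch_size < 1L || lr <= 0) stop("invalid training configuration")
  has_val <- !is.null(x_val)
  if (has_val && length(y_val) != nrow(x_val))
    stop("length(y_val) must equal nrow(x_val)")

  model <- build_model(config, init_seed)
  net <- model$net
  adam <- adam_init(net)
  n <- nrow(x)
  hist_train <- numeric(epochs)
  hist_val <- rep(NA_real_, epochs)
  best <- list(loss = Inf, epoch = NA_integer_, net = NULL)
  step <- 0L

  with_seed(train_seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq.int(1L, n, by = batch_size)
      ep_loss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        fwd <- net_forward(net, x[idx, , drop = FALSE], config,
                           keep_cache = TRUE)
        sx <- softmax_xent(fwd$scores, y[idx])
        if (!is.finite(sx$loss))
          stop(sprintf("training diverged: non-finite loss at epoch %d", ep))
        grads <- net_backward(net, fwd, sx$dscores, config)
        step <- step + 1L
        upd <- adam_step(net, grads, adam, lr, betas, eps, step)
        net <- upd$net; adam <- upd$state
        ep_loss <- ep_loss + sx$loss * length(idx)
      }
      hist_train[ep] <- ep_loss / n
      if (has_val) {
        vs <- net_forward(net, x_val, config)$scores
        hist_val[ep] <- softmax_xent(vs, as.integer(y_val))$loss
        if (hist_val[ep] < best$loss)
          best <- list(loss = hist_val[ep], epoch = ep, net = net)
      }
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %s", ep, hist_train[ep],
                        if (has_val) sprintf("%.4f", hist_val[ep]) else "-"))
    }
  })

  final_net <- if (keep_best && !is.null(best$net)) best$net else net
  structure(list(net = final_net, config = config,
                 parameter_count = model$parameter_count,
                 loss_history = data.frame(epoch = seq_len(epochs),
                                           train = hist_train,
                                           val = hist_val),
                 best_epoch = best$epoch, keep_best = keep_best,
                 n_train = n, batch_size = as.integer(batch_size),
                 lr = lr, betas = betas,
                 init_seed = as.integer(init_seed),
                 train_seed = as.integer(train_seed),
                 call = match.call()),
            class = "fibrocnn")
}

adam_init <- function(net) {
  zero_like <- function(l) list(W = array(0, dim(l$W)), b = numeric(length(l$b)))
  list(m = list(conv = lapply(net$conv, zero_like), fc = lapply(net$fc, zero_like)),
       v = list(conv = lapply(net$conv, zero_like), fc = lapply(net$fc, zero_like)))
}

adam_step <- function(net, grads, state, lr, betas, eps, t) {
  b1 <- betas[1L]; b2 <- betas[2L]
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  upd <- function(par, g, m, v) {
    m$W <- b1 * m$W + (1 - b1) * g$W; m$b <- b1 * m$b + (1 - b1) * g$b
    v$W <- b2 * v$W + (1 - b2) * g$W^2; v$b <- b2 * v$b + (1 - b2) * g$b^2
    par$W <- par$W - lr * (m$W / c1) / (sqrt(v$W / c2) + eps)
    par$b <- par$b - lr * (m$b / c1) / (sqrt(v$b / c2) + eps)
    list(par = par, m = m, v = v)
  }
  for (grp in c("conv", "fc")) {
    for (i in seq_along(net[[grp]])) {
      r <- upd(net[[grp]][[i]], grads[[grp]][[i]],
               state$m[[grp]][[i]], state$v[[grp]][[i]])
      net[[grp]][[i]] <- r$par
      state$m[[grp]][[i]] <- r$m
      state$v[[grp]][[i]] <- r$v
    }
  }
  list(net = net, state = state)
}

#' Predict from a fitted fibrosis classifier
#'
#' @param object A fitted [fibrocnn()] model.
#' @param newdata Segment matrix (segments x `input_len`).
#' @param type `"class"` for 0/1 per segment (argmax of the two class
#'   scores), `"prob"` for softmax probabilities (segments x 2), `"score"`
#'   for raw network outputs.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.fibrocnn <- function(object, newdata,
                             type = c("class", "prob", "score"), ...) {
  type <- match.arg(type)
  scores <- cnn_forward(object, newdata)
  switch(type,
         score = scores,
         prob = {
           z <- exp(scores - apply(scores, 1L, max))
           z / rowSums(z)
         },
         class = as.integer(scores[, 2L] > scores[, 1L]))
}

#' @export
print.fibrocnn <- function(x, ...) {
  cat(sprintf("<fibrocnn> 1-D CNN fibrosis classifier, %d parameters\n",
              x$parameter_count))
  ep <- nrow(x$loss_history)
  cat(sprintf("  trained %d epochs on %d segments (batch %d, Adam lr %g)\n",
              ep, x$n_train, x$batch_size, x$lr))
  cat(sprintf("  final training loss %.4f", x$loss_history$train[ep]))
  if (!all(is.na(x$loss_history$val)))
    cat(sprintf(", validation loss %.4f (best epoch %d)",
                x$loss_history$val[ep], x$best_epoch))
  cat("\n")
  invisible(x)
}

#' @export
summary.fibrocnn <- function(object, ...) {
  cfg <- object$config
  h <- object$loss_history
  out <- list(config = cfg, parameter_count = object$parameter_count,
              epochs = nrow(h), n_train = object$n_train,
              final_train_loss = h$train[nrow(h)],
              final_val_loss = h$val[nrow(h)], best_epoch = object$best_epoch)
  class(out) <- "summary.fibrocnn"
  out
}

#' @export
print.summary.fibrocnn <- function(x, ...) {
  print(x$config)
  cat(sprintf("epochs %d, training segments %d\n", x$epochs, x$n_train))
  cat(sprintf("final train loss %.4f; final val loss %s; best epoch %s\n",
              x$final_train_loss,
              ifelse(is.na(x$final_val_loss), "-", sprintf("%.4f", x$final_val_loss)),
              ifelse(is.na(x$best_epoch), "-", x$best_epoch)))
  invisible(x)
}

#' @export
coef.fibrocnn <- function(object, ...) object$net

#' Plot training diagnostics
#'
#' Training (and, when available, validation) loss per epoch.
#'
#' @param x A fitted [fibrocnn()] model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.fibrocnn <- function(x, ...) {
  h <- x$loss_history
  has_val <- !all(is.na(h$val))
  graphics::matplot(h$epoch, cbind(h$train, if (has_val) h$val),
                    type = "l", lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", bty = "n",
                   legend = c("training", if (has_val) "validation"),
                   lty = 1, col = c("black", "red3"))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the weights and the embedded
#' architecture configuration.
#'
#' @param object A `fibrocnn` or `cnn_model` object.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored object (load), invisibly/visibly.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, c("fibrocnn", "cnn_model")))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)
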