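# Standard feed-forward baseline: linear layers with SELU activations and a
# sigmoid output head, trained on the same loss/split contracts as the
# NN-log-reg.

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

selu <- function(x) SELU_LAMBDA * ifelse(x > 0, x, SELU_ALPHA * (exp(x) - 1))
selu_grad <- function(x) SELU_LAMBDA * ifelse(x > 0, 1, SELU_ALPHA * exp(x))

#' Initialize standard-ANN parameters
#'
#' The reference architecture has five linear layers of 1000, 1000, 1000, 32
#' and 1 neurons with SELU activations between them and a sigmoid on the final
#' unit; `hidden` controls the widths of the four hidden layers so the same
#' architecture can be exercised at desk scale.
#'
#' @param n_genes input length G.
#' @param hidden integer vector of hidden-layer widths.
#' @param seed integer seed.
#' @return list of class `ann_params` with per-layer weight matrices `W` and
#'   bias vectors `b`.
#' @export
init_ann_params <- function(n_genes, hidden = c(1000L, 1000L, 1000L, 32L),
                            seed = 1L) {
  sizes <- c(as.integer(n_genes), as.integer(hidden), 1L)
  local_seed(seed, {
    layers <- lapply(seq_len(length(sizes) - 1L), function(l) {
      lim <- 1 / sqrt(sizes[l])
      list(W = matrix(stats::runif(sizes[l + 1L] * sizes[l], -lim, lim),
                      sizes[l + 1L], sizes[l]),
           b = numeric(sizes[l + 1L]))
    })
    structure(layers, sizes = sizes, class = "ann_params")
  })
}

#' Standard-ANN forward pass
#'
#' @param params an `ann_params` object.
#' @param x numeric vector of length G or an n x G matrix.
#' @return probability (vector when `x` is a matrix).
#' @export
ann_forward <- function(params, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) != attr(params, "sizes")[1]) {
    stop("input has ", ncol(x), " columns but the network expects ",
         attr(params, "sizes")[1], call. = FALSE)
  }
  A <- x
  L <- length(params)
  for (l in seq_len(L)) {
    Z <- add_bias(tcrossprod(A, params[[l]]$W), params[[l]]$b)
    A <- if (l < L) selu(Z) else sigmoid(Z)
  }
  p <- drop(A)
  if (vec) p[1] else p
}

ann_gradients <- function(params, X, y) {
  n <- nrow(X)
  L <- length(params)
  As <- vector("list", L + 1L); Zs <- vector("list", L)
  As[[1]] <- X
  for (l in seq_len(L)) {
    Zs[[l]] <- add_bias(tcrossprod(As[[l]], params[[l]]$W), params[[l]]$b)
    As[[l + 1L]] <- if (l < L) selu(Zs[[l]]) else sigmoid(Zs[[l]])
  }
  grads <- vector("list", L)
  dZ <- (As[[L + 1L]] - y) / n          # n x 1, BCE + sigmoid head
  for (l in rev(seq_len(L))) {
    grads[[l]] <- list(W = crossprod(dZ, As[[l]]), b = colSums(dZ))
    if (l > 1L) {
      dA <- dZ %*% params[[l]]$W
      dZ <- dA * selu_grad(Zs[[l - 1L]])
    }
  }
  grads
}

#' Train the standard-ANN baseline
#'
#' Same training loop as [nn_logreg_train()] (Adam, early stopping on
#' validation loss, seed-deterministic) applied to the feed-forward SELU
#' architecture of [init_ann_params()].
#'
#' @inheritParams nn_logreg_train
#' @return object of class `standard_ann_model` with `params`, `gene_names`,
#'   `config`, `best_epoch` and `history`.
#' @export
standard_ann_train <- function(train, validation,
                               config = train_config(hidden = c(1000L, 1000L,
                                                                1000L, 32L))) {
  if (length(unique(train$targets)) < 2L) {
    stop("training set contains a single class; cannot train", call. = FALSE)
  }
  tr <- dataset_xy(train, config)
  va <- dataset_xy(validation, config)
  params <- init_ann_params(length(train$gene_names), config$hidden,
                            seed = config$seed)
  state <- list(m = rapply(unclass(params), function(p) p * 0, how = "list"),
                v = rapply(unclass(params), function(p) p * 0, how = "list"),
                t = 0L)
  n <- nrow(tr$X)
  bs <- min(config$batch_size, n)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  wait <- 0L
  local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      idx <- if (bs < n) sample.int(n) else seq_len(n)
      for (start in seq(1L, n, by = bs)) {
        rows <- idx[start:min(start + bs - 1L, n)]
        grads <- ann_gradients(params, tr$X[rows, , drop = FALSE], tr$y[rows])
        state$t <- state$t + 1L
        corr1 <- 1 - 0.9^state$t; corr2 <- 1 - 0.999^state$t
        for (l in seq_along(params)) {
          for (nm in c("W", "b")) {
            g <- grads[[l]][[nm]]
            state$m[[l]][[nm]] <- 0.9 * state$m[[l]][[nm]] + 0.1 * g
            state$v[[l]][[nm]] <- 0.999 * state$v[[l]][[nm]] + 0.001 * g^2
            params[[l]][[nm]] <- params[[l]][[nm]] -
              config$learning_rate * (state$m[[l]][[nm]] / corr1) /
              (sqrt(state$v[[l]][[nm]] / corr2) + 1e-8)
          }
        }
      }
      train_loss <- bce_loss(ann_forward(params, tr$X), tr$y, config$clamp)
      val_loss <- bce_loss(ann_forward(params, va$X), va$y, config$clamp)
      if (!is.finite(train_loss) || !is.finite(val_loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      }
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss))
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  structure(list(params = best$params, gene_names = train$gene_names,
                 config = config, best_epoch = best$epoch, history = hist),
            class = "standard_ann_model")
}

#' @export
predict.standard_ann_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_dataset")) {
    dataset_xy(newdata, object$config)$X
  } else {
    if (object$config$log1p) log1p(newdata) else newdata
  }
  ann_forward(object$params, X)
}
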