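#' Initialize hypernetwork parameters
#'
#' The NN-log-reg holds eight parameter arrays: three hidden linear layers
#' (`W_A`/`b_A` maps the G-gene input to H units, `W_B`/`b_B` maps H to H,
#' `W_C`/`b_C` maps H back to G) and a final scalar affine head
#' (`w_D`, `b_D`).  Weights are drawn uniformly in
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`, biases start at zero; all draws are
#' fixed by `seed`.
#'
#' @param n_genes G, the input length (genes after TCR exclusion).
#' @param hidden H, the shared width of the three hidden layers.
#' @param seed integer seed.
#' @return list of class `hypernet_params` with elements `W_A`, `b_A`, `W_B`,
#'   `b_B`, `W_C`, `b_C`, `w_D`, `b_D` and attributes `G`, `H`.
#' @export
init_hypernet_params <- function(n_genes, hidden = 1000L, seed = 1L) {
  G <- as.integer(n_genes); H <- as.integer(hidden)
  local_seed(seed, {
    u <- function(nr, nc) {
      lim <- 1 / sqrt(nc)
      matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
    }
    # w_D starts at 1, not near zero: with per-cell-normalized inputs the
    # attention-weighted sum is almost constant at initialization, so a
    # near-zero head weight would leave the whole hypernetwork gradient-free
    # (a saddle at the class base rate).
    p <- list(W_A = u(H, G), b_A = numeric(H),
              W_B = u(H, H), b_B = numeric(H),
              W_C = u(G, H), b_C = numeric(G),
              w_D = 1, b_D = 0)
    structure(p, G = G, H = H, class = "hypernet_params")
  })
}

#' Zero-valued hypernetwork parameters
#'
#' Useful as a reference point: with all parameters zero the adaptive weights
#' are uniform (1/G) and the model output is exactly 0.5 for any input.
#'
#' @inheritParams init_hypernet_params
#' @return a `hypernet_params` object with every entry 0.
#' @export
zero_hypernet_params <- function(n_genes, hidden = 1000L) {
  G <- as.integer(n_genes); H <- as.integer(hidden)
  structure(list(W_A = matrix(0, H, G), b_A = numeric(H),
                 W_B = matrix(0, H, H), b_B = numeric(H),
                 W_C = matrix(0, G, H), b_C = numeric(G),
                 w_D = 0, b_D = 0),
            G = G, H = H, class = "hypernet_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

add_bias <- function(M, b) M + rep(b, each = nrow(M))

check_input_matrix <- function(params, x) {
  G <- attr(params, "G")
  if (is.null(dim(x))) {
    if (length(x) != G) {
      stop("input length ", length(x), " does not match G = ", G, call. = FALSE)
    }
    x <- matrix(x, nrow = 1L)
  } else if (ncol(x) != G) {
    stop("input has ", ncol(x), " columns but G = ", G, call. = FALSE)
  }
  if (any(!is.finite(x))) stop("input contains non-finite values", call. = FALSE)
  x
}

# Shared forward pass; returns all intermediates needed for the backward pass.
hypernet_pass <- function(params, X) {
  H1 <- tanh(add_bias(tcrossprod(X, params$W_A), params$b_A))   # n x H
  H2 <- tanh(add_bias(tcrossprod(H1, params$W_B), params$b_B))  # n x H
  S <- sigmoid(add_bias(tcrossprod(H2, params$W_C), params$b_C)) # n x G
  E <- exp(S - apply(S, 1L, max))
  A <- E / rowSums(E)                                            # n x G
  AX <- rowSums(A * X)
  P <- sigmoid(params$b_D + params$w_D * AX)
  list(H1 = H1, H2 = H2, S = S, A = A, AX = AX, P = P)
}

#' Adaptive weights: the hypernetwork forward pass
#'
#' Computes, for one cell's expression vector `x` (or row-wise for a matrix),
#' the per-gene adaptive weight vector
#' `a = softmax(sigmoid(b_C + W_C tanh(b_B + W_B tanh(b_A + W_A x))))`.
#' Every weight is strictly positive and each cell's weights sum to 1; they
#' are the model's per-cell gene attention and the basis of feature
#' importance.
#'
#' @param params a `hypernet_params` object.
#' @param x numeric vector of length G, or an n x G matrix.
#' @return vector of length G, or an n x G matrix of adaptive weights.
#' @export
hypernet_forward <- function(params, x) {
  vec <- is.null(dim(x))
  A <- hypernet_pass(params, check_input_matrix(params, x))$A
  if (vec) drop(A) else A
}

#' Model output: adaptive logistic regression
#'
#' The malignancy probability of a cell is
#' `p = sigmoid(b_D + w_D * sum(a * x))` with `a = hypernet_forward(params, x)`
#' -- a logistic regression whose gene weights are set, per cell, by the
#' hypernetwork.
#'
#' @inheritParams hypernet_forward
#' @return probability in (0,1); a vector when `x` is a matrix.
#' @export
model_forward <- function(params, x) {
  vec <- is.null(dim(x))
  P <- hypernet_pass(params, check_input_matrix(params, x))$P
  if (vec) P[1] else P
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1-y) log(1-p))`, with `p` clamped away from 0 and 1
#' to keep the logarithm finite.
#'
#' @param p probability vector.
#' @param y 0/1 target vector of the same length.
#' @param clamp clamping bound (default 1e-12).
#' @return scalar loss.
#' @export
bce_loss <- function(p, y, clamp = 1e-12) {
  if (length(p) != length(y)) {
    stop("length mismatch: ", length(p), " probabilities vs ", length(y),
         " targets", call. = FALSE)
  }
  p <- pmin(pmax(p, clamp), 1 - clamp)
  -mean(y * log(p) + (1 - y) * log1p(-p))
}

# Analytic gradients of bce_loss(model_forward(params, X), y) w.r.t. every
# parameter array.  Derivation: with z = b_D + w_D * sum(a*x),
# dL/dz = (p - y)/n; softmax backprop ds = a*(da - sum(a*da)); the rest is
# standard chain rule through sigmoid and tanh layers.
nnlogreg_gradients <- function(params, X, y, clamp = 1e-12) {
  n <- nrow(X)
  f <- hypernet_pass(params, X)
  Pc <- pmin(pmax(f$P, clamp), 1 - clamp)
  dZ <- (Pc - y) / n                                   # n
  g_bD <- sum(dZ)
  g_wD <- sum(dZ * f$AX)
  dA <- (params$w_D * dZ) * X                          # n x G
  dS <- f$A * (dA - rowSums(f$A * dA))                 # softmax jacobian
  dPreC <- dS * f$S * (1 - f$S)                        # n x G
  g_WC <- crossprod(dPreC, f$H2)                       # G x H
  g_bC <- colSums(dPreC)
  dH2 <- dPreC %*% params$W_C                          # n x H
  dPreB <- dH2 * (1 - f$H2^2)
  g_WB <- crossprod(dPreB, f$H1)
  g_bB <- colSums(dPreB)
  dH1 <- dPreB %*% params$W_B
  dPreA <- dH1 * (1 - f$H1^2)
  g_WA <- crossprod(dPreA, X)                          # H x G
  g_bA <- colSums(dPreA)
  list(W_A = g_WA, b_A = g_bA, W_B = g_WB, b_B = g_bB,
       W_C = g_WC, b_C = g_bC, w_D = g_wD, b_D = g_bD)
}

# One Adam step over a named list of parameter arrays.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / corr1) / (sqrt(state$v[[nm]] / corr2) + eps)
  }
  list(params = params, state = state)
}

init_adam <- function(params) {
  zeros <- lapply(unclass(params)[c("W_A", "b_A", "W_B", "b_B",
                                    "W_C", "b_C", "w_D", "b_D")],
                  function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

dataset_xy <- function(ds, config) {
  X <- ds$matrix
  if (config$log1p) X <- log1p(X)
  list(X = X, y = ds$targets)
}

#' Train the NN-log-reg classifier
#'
#' Minimizes the binary cross-entropy of [model_forward()] by gradient
#' descent, monitoring the validation loss for early stopping and returning
#' the parameters of the best validation epoch.  Training is deterministic
#' given the config seed: the same data, seed and config produce identical
#' parameters and history.
#'
#' The optimization is staged to suit the architecture's geometry (see the
#' methods vignette for the full rationale):
#'
#' * The hypernetwork starts *silent*: `W_A = 0` and near-zero `W_C`, so the
#'   adaptive weights begin uniform and the model begins as a calibrated
#'   logistic regression; cell-dependent attention grows only as gradients
#'   support it.
#' * The attention logits (`b_C` and the rows of `W_C`, one per gene) are
#'   updated by proximal gradient descent with an L1 penalty, preconditioned
#'   by per-gene expression scale -- the analogue of a standardized sparse
#'   logistic fit.  The penalty is `attention_l1` times the largest
#'   standardized logit gradient at initialization (the smallest penalty
#'   that keeps all logits at zero), mirroring how penalized-regression
#'   software anchors its path.
#' * The head gain `w_D` is held at 1 for `gain_release` epochs while
#'   attention forms (its early gradient only sees uniform-attention noise
#'   and would otherwise collapse it), then trained by plain gradient
#'   descent.  `b_D` is parameterized relative to the mean attention-weighted
#'   input so the gain and intercept do not form a stiff, degenerate pair.
#' * The deep tensors (`W_A`, `b_A`, `W_B`, `b_B`) train throughout with a
#'   heavily damped Adam step.
#'
#' @param train,validation `labeled_dataset`s; both classes must be present
#'   in the training set.
#' @param config a [train_config()].
#' @return object of class `nnlogreg_model`: the `hypernet_params` at the
#'   best validation epoch, the gene names, the config, the best epoch index
#'   and a `history` data.frame of per-epoch train/validation losses and
#'   validation AUC.
#' @export
nn_logreg_train <- function(train, validation, config = train_config()) {
  if (length(unique(train$targets)) < 2L) {
    stop("training set contains a single class; cannot train", call. = FALSE)
  }
  if (!identical(train$gene_names, validation$gene_names)) {
    stop("train and validation gene names differ", call. = FALSE)
  }
  tr <- dataset_xy(train, config)
  va <- dataset_xy(validation, config)
  G <- length(train$gene_names)
  H <- as.integer(config$hidden)
  n <- nrow(tr$X)

  params <- init_hypernet_params(G, H, seed = config$seed)
  params$W_A[] <- 0
  params$W_C <- params$W_C * 0.05
  mu0 <- mean(rowMeans(tr$X))
  ybar <- mean(tr$y)
  cD <- log(ybar / (1 - ybar))       # b_D = cD - w_D * mu0 (centered head)
  params$w_D <- 1
  params$b_D <- cD - params$w_D * mu0

  # per-gene preconditioner: updates in standardized units
  sdg <- apply(tr$X, 2, stats::sd)
  sdg[sdg == 0] <- mean(sdg[sdg > 0])
  pre <- mean(sdg) / sdg
  g0 <- nnlogreg_gradients(params, tr$X, tr$y, clamp = config$clamp)
  lam_max <- max(abs(g0$b_C * pre))
  if (lam_max <= 0) lam_max <- 1
  lam <- config$attention_l1 * lam_max
  lr_g <- 0.05 / lam_max
  rowshrink <- sqrt(H)

  state <- init_adam(params)
  deep <- c("W_A", "b_A", "W_B", "b_B")
  bs <- min(config$batch_size, n)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- vector("list", config$epochs)
  wait <- 0L
  local_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      idx <- if (bs < n) sample.int(n) else seq_len(n)
      for (start in seq(1L, n, by = bs)) {
        rows <- idx[start:min(start + bs - 1L, n)]
        g <- nnlogreg_gradients(params, tr$X[rows, , drop = FALSE],
                                tr$y[rows], clamp = config$clamp)
        # head: plain gradient steps in the centered parameterization
        if (epoch > config$gain_release) {
          params$w_D <- params$w_D - 0.02 * (g$w_D - mu0 * g$b_D)
        }
        cD <- cD - 0.5 * g$b_D
        params$b_D <- cD - params$w_D * mu0
        # deep tensors: damped Adam
        state$t <- state$t + 1L
        c1 <- 1 - 0.9^state$t; c2 <- 1 - 0.999^state$t
        for (nm in deep) {
          state$m[[nm]] <- 0.9 * state$m[[nm]] + 0.1 * g[[nm]]
          state$v[[nm]] <- 0.999 * state$v[[nm]] + 0.001 * g[[nm]]^2
          params[[nm]] <- params[[nm]] - 0.001 * config$learning_rate *
            (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + 1e-8)
        }
        # attention logits: standardized proximal L1 steps
        wd <- max(abs(params$w_D), 0.1)
        params$b_C <- params$b_C - lr_g * pre * g$b_C / wd
        params$b_C <- sign(params$b_C) * pmax(abs(params$b_C) - lr_g * pre * lam, 0)
        params$W_C <- params$W_C - lr_g * pre * g$W_C / wd
        rn <- sqrt(rowSums(params$W_C^2))
        params$W_C <- params$W_C *
          pmax(1 - lr_g * pre * lam * rowshrink / pmax(rn, 1e-12), 0)
      }
      train_loss <- bce_loss(model_forward(params, tr$X), tr$y, config$clamp)
      pv <- model_forward(params, va$X)
      val_loss <- bce_loss(pv, va$y, config$clamp)
      if (!is.finite(train_loss) || !is.finite(val_loss)) {
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
      }
      val_auc <- if (length(unique(va$y)) > 1L) {
        roc_curve(pv, va$y)$auc
      } else NA_real_
      hist[[epoch]] <- c(epoch = epoch, train_loss = train_loss,
                         val_loss = val_loss, val_auc = val_auc)
      if (val_loss < best$loss - 1e-12) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        # the gain-release schedule defines a minimum training duration:
        # stopping inside the frozen-gain phase would return a half-formed fit
        if (wait >= config$patience &&
            epoch >= config$gain_release + config$patience) break
      }
    }
  })
  hist <- as.data.frame(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  structure(list(params = best$params, gene_names = train$gene_names,
                 config = config, best_epoch = best$epoch,
                 history = hist),
            class = "nnlogreg_model")
}

#' @export
print.nnlogreg_model <- function(x, ...) {
  cat("NN-log-reg model: G =", attr(x$params, "G"),
      "genes, H =", attr(x$params, "H"),
      "| best epoch", x$best_epoch, "of", nrow(x$history),
      sprintf("(val loss %.4f)\n", min(x$history$val_loss)))
  invisible(x)
}

#' Predict malignancy probabilities
#'
#' @param object a trained `nnlogreg_model`.
#' @param newdata a `labeled_dataset` or a cells x genes matrix with G
#'   columns (same gene order as training).
#' @param ... unused.
#' @return numeric vector of probabilities, one per row, order preserved.
#' @export
predict.nnlogreg_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "labeled_dataset")) {
    if (!identical(newdata$gene_names, object$gene_names)) {
      stop("gene names of newdata differ from the training genes",
           call. = FALSE)
    }
    dataset_xy(newdata, object$config)$X
  } else {
    if (object$config$log1p) log1p(newdata) else newdata
  }
  model_forward(object$params, X)
}
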