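#' Network architecture specification
#'
#' The regression network shares a trunk of four fully-connected
#' rectified-linear layers (512, 256, 128, 64 units) followed by dropout
#' (rate 0.2), then splits into one branch per target parameter: a 32-unit
#' rectified-linear hidden layer, dropout 0.2, and a single sigmoid output.
#' The one-pulse variant regresses 5 targets (AM1-3, SB1, SB2; 251,141
#' trainable weights including biases); the two-pulse variant adds GFR1-3
#' (8 branches). Dropout layers add no trainable weights.
#'
#' @param model "one_pulse" or "two_pulses", or NULL when `targets` is
#'   given explicitly.
#' @param input_size feature-vector length (132 for all-windows profiles,
#'   126 for no-shortest).
#' @param trunk hidden-layer widths of the shared trunk.
#' @param branch_hidden width of each branch's hidden layer.
#' @param dropout dropout rate after the last trunk layer and after each
#'   branch hidden layer.
#' @param targets character vector of target names (overrides `model`).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(model = c("one_pulse", "two_pulses"),
                         input_size = 132L,
                         trunk = c(512L, 256L, 128L, 64L),
                         branch_hidden = 32L,
                         dropout = 0.2,
                         targets = NULL) {
  if (is.null(targets)) {
    model <- match.arg(model)
    targets <- c("AM1", "AM2", "AM3", "SB1", "SB2")
    if (model == "two_pulses") targets <- c(targets, "GFR1", "GFR2", "GFR3")
  } else {
    model <- "custom"
  }
  structure(list(model = model, input_size = as.integer(input_size),
                 trunk = as.integer(trunk),
                 branch_hidden = as.integer(branch_hidden),
                 dropout = dropout, targets = targets),
            class = "network_spec")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build (initialise) a network from its specification
#'
#' @param spec a [network_spec()].
#' @return an object of class `nn_model` carrying the weight matrices and a
#'   `n_weights` field with the trainable-parameter count (biases included).
#'   Initialisation is Glorot-uniform and consumes the current RNG state.
#' @export
build_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  sizes <- c(spec$input_size, spec$trunk)
  trunk <- lapply(seq_along(spec$trunk), function(i) {
    list(W = glorot(sizes[i], sizes[i + 1]), b = numeric(sizes[i + 1]))
  })
  last <- spec$trunk[length(spec$trunk)]
  branches <- lapply(spec$targets, function(t) {
    list(W1 = glorot(last, spec$branch_hidden),
         b1 = numeric(spec$branch_hidden),
         W2 = glorot(spec$branch_hidden, 1L),
         b2 = numeric(1L))
  })
  names(branches) <- spec$targets
  model <- structure(list(spec = spec, trunk = trunk, branches = branches),
                     class = "nn_model")
  model$n_weights <- count_weights(model)
  model
}

#' Trainable-weight count of a network (biases included)
#' @param model an `nn_model`.
#' @return integer.
#' @export
count_weights <- function(model) {
  n <- 0L
  for (l in model$trunk) n <- n + length(l$W) + length(l$b)
  for (br in model$branches) {
    n <- n + length(br$W1) + length(br$b1) + length(br$W2) + length(br$b2)
  }
  n
}

#' @export
print.nn_model <- function(x, ...) {
  cat("Branched fully-connected network (", x$spec$model, "): input ",
      x$spec$input_size, " -> trunk [",
      paste(x$spec$trunk, collapse = ", "), "] -> ",
      length(x$spec$targets), " branches (",
      paste(x$spec$targets, collapse = ", "), ")\n", sep = "")
  cat("  trainable weights:", format(x$n_weights, big.mark = ","), "\n")
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

addb <- function(Z, b) sweep(Z, 2, b, `+`)

# Forward pass. With training = TRUE draws dropout masks (inverted dropout)
# and returns the caches needed by the backward pass.
nn_forward <- function(model, X, training = FALSE) {
  spec <- model$spec
  h <- X
  cache <- list(h_in = list(), z = list())
  for (i in seq_along(model$trunk)) {
    cache$h_in[[i]] <- h
    z <- addb(h %*% model$trunk[[i]]$W, model$trunk[[i]]$b)
    cache$z[[i]] <- z
    h <- pmax(z, 0)
  }
  if (training && spec$dropout > 0) {
    mask <- matrix(runif(length(h)) >= spec$dropout, nrow(h)) /
      (1 - spec$dropout)
  } else mask <- NULL
  h_drop <- if (is.null(mask)) h else h * mask
  cache$h_trunk <- h; cache$mask_trunk <- mask; cache$h_drop <- h_drop
  p <- length(spec$targets)
  Y <- matrix(NA_real_, nrow(X), p, dimnames = list(NULL, spec$targets))
  cache$branch <- vector("list", p)
  for (j in seq_len(p)) {
    br <- model$branches[[j]]
    zb <- addb(h_drop %*% br$W1, br$b1)
    hb <- pmax(zb, 0)
    if (training && spec$dropout > 0) {
      mb <- matrix(runif(length(hb)) >= spec$dropout, nrow(hb)) /
        (1 - spec$dropout)
    } else mb <- NULL
    hb_drop <- if (is.null(mb)) hb else hb * mb
    zo <- addb(hb_drop %*% br$W2, br$b2)
    Y[, j] <- sigmoid(zo)
    cache$branch[[j]] <- list(zb = zb, hb_drop = hb_drop, mask = mb)
  }
  list(Y = Y, cache = cache)
}

# Backward pass for the mean-squared-error loss; returns gradients with the
# same structure as the model weights.
nn_backward <- function(model, X, Y_true, fwd) {
  spec <- model$spec
  Y <- fwd$Y; cache <- fwd$cache
  n <- nrow(X); p <- ncol(Y)
  dY <- 2 * (Y - Y_true) / (n * p)
  grads <- list(trunk = vector("list", length(model$trunk)),
                branches = vector("list", p))
  dh_drop <- matrix(0, n, ncol(cache$h_drop))
  for (j in seq_len(p)) {
    br <- model$branches[[j]]
    bc <- cache$branch[[j]]
    y <- Y[, j]
    dzo <- matrix(dY[, j] * y * (1 - y), n, 1)
    gW2 <- crossprod(bc$hb_drop, dzo)
    gb2 <- colSums(dzo)
    dhb <- dzo %*% t(br$W2)
    if (!is.null(bc$mask)) dhb <- dhb * bc$mask
    dzb <- dhb * (bc$zb > 0)
    gW1 <- crossprod(cache$h_drop, dzb)
    gb1 <- colSums(dzb)
    dh_drop <- dh_drop + dzb %*% t(br$W1)
    grads$branches[[j]] <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }
  dh <- if (is.null(cache$mask_trunk)) dh_drop else
    dh_drop * cache$mask_trunk
  for (i in rev(seq_along(model$trunk))) {
    dz <- dh * (cache$z[[i]] > 0)
    grads$trunk[[i]] <- list(W = crossprod(cache$h_in[[i]], dz),
                             b = colSums(dz))
    if (i > 1L) dh <- dz %*% t(model$trunk[[i]]$W)
  }
  grads
}

adam_state_like <- function(model) {
  zero <- function(x) lapply(x, function(p) p * 0)
  list(m = list(trunk = lapply(model$trunk, zero),
                branches = lapply(model$branches, zero)),
       v = list(trunk = lapply(model$trunk, zero),
                branches = lapply(model$branches, zero)),
       t = 0L)
}

adam_update <- function(model, grads, state, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(w, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (i in seq_along(model$trunk)) {
    for (nm in c("W", "b")) {
      r <- upd(model$trunk[[i]][[nm]], grads$trunk[[i]][[nm]],
               state$m$trunk[[i]][[nm]], state$v$trunk[[i]][[nm]])
      model$trunk[[i]][[nm]] <- r$w
      state$m$trunk[[i]][[nm]] <- r$m
      state$v$trunk[[i]][[nm]] <- r$v
    }
  }
  for (j in seq_along(model$branches)) {
    for (nm in c("W1", "b1", "W2", "b2")) {
      r <- upd(model$branches[[j]][[nm]], grads$branches[[j]][[nm]],
               state$m$branches[[j]][[nm]], state$v$branches[[j]][[nm]])
      model$branches[[j]][[nm]] <- r$w
      state$m$branches[[j]][[nm]] <- r$m
      state$v$branches[[j]][[nm]] <- r$v
    }
  }
  list(model = model, state = state)
}

mse_loss <- function(Y_hat, Y) mean((Y_hat - Y)^2)

#' Predict scaled targets for a feature matrix
#'
#' @param model a trained `nn_model`.
#' @param X numeric matrix (rows = profiles) or a single feature vector.
#' @return matrix of predictions on the scaled \[0, 1\] target scale.
#' @export
predict_network <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  if (ncol(X) != model$spec$input_size) {
    stop("feature size ", ncol(X), " does not match network input size ",
         model$spec$input_size)
  }
  nn_forward(model, X, training = FALSE)$Y
}
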