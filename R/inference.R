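#' Map mating parameters to the scaled \[0, 1\] training targets
#'
#' AM and GFR already live in \[0, 1\] and pass through unchanged; SB1 and
#' SB2 are mapped linearly from their natural \[-1, 1\] range to \[0, 1\]
#' so that all targets are weighted equally by the mean-squared-error loss.
#'
#' @param params a [mating_params()] object.
#' @param include_gfr append scaled GFR targets?
#' @return named numeric vector of scaled targets (AM1-3, SB1, SB2
#'   \[, GFR1-3\]).
#' @export
scale_targets <- function(params, include_gfr = !is.null(params$gfr)) {
  stopifnot(inherits(params, "mating_params"))
  if (any(abs(params$sb[1:2]) > 1 + 1e-12)) {
    stop("SB values outside the natural [-1, 1] range cannot be scaled")
  }
  out <- c(AM1 = params$am[1], AM2 = params$am[2], AM3 = params$am[3],
           SB1 = (params$sb[1] + 1) / 2, SB2 = (params$sb[2] + 1) / 2)
  if (include_gfr) {
    if (is.null(params$gfr)) stop("no GFR values to scale")
    out <- c(out, GFR1 = params$gfr[1], GFR2 = params$gfr[2],
             GFR3 = params$gfr[3])
  }
  out
}

#' Inverse of [scale_targets()]
#'
#' @param y named (or positionally ordered) scaled target vector of length
#'   5 or 8.
#' @return a [mating_params()] object on the natural scale.
#' @export
unscale_targets <- function(y) {
  y <- as.numeric(y)
  if (!length(y) %in% c(5L, 8L)) stop("expected 5 or 8 scaled targets")
  gfr <- if (length(y) == 8L) pmin(pmax(y[6:8], 0), 1)
  mating_params(am = pmin(pmax(y[1:3], 0), 1),
                sb = 2 * pmin(pmax(y[4:5], 0), 1) - 1, gfr = gfr)
}

#' Training configuration
#'
#' Adam optimiser, mean-squared-error loss, 40 epochs at batch size 64; a
#' 0.2 validation split is carved out of the 0.8 training portion of each
#' random 0.8/0.2 train/test split.
#'
#' @param epochs,batch_size,validation_split,test_split,learning_rate
#'   training hyper-parameters (defaults as stated above).
#' @return an object of class `training_config`.
#' @export
training_config <- function(epochs = 40L, batch_size = 64L,
                            validation_split = 0.2, test_split = 0.2,
                            learning_rate = 1e-3) {
  stopifnot(validation_split > 0, validation_split < 1,
            test_split >= 0, test_split < 1, epochs >= 1, batch_size >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 validation_split = validation_split,
                 test_split = test_split,
                 learning_rate = learning_rate),
            class = "training_config")
}

#' Train a network on a (features, scaled targets) dataset
#'
#' Mini-batch Adam on the mean-squared-error loss, with per-epoch training
#' and validation loss recorded. Deterministic given the RNG state at entry
#' (seed beforehand).
#'
#' @param model an `nn_model` from [build_network()].
#' @param features numeric matrix, rows = flattened normalised profiles.
#' @param targets numeric matrix of scaled targets, one column per network
#'   branch.
#' @param config a [training_config()].
#' @return the trained `nn_model` with a `history` data.frame
#'   (epoch, train_loss, val_loss).
#' @export
train_network <- function(model, features, targets, config = training_config()) {
  stopifnot(inherits(model, "nn_model"), inherits(config, "training_config"))
  features <- as.matrix(features); targets <- as.matrix(targets)
  if (ncol(features) != model$spec$input_size) {
    stop("feature size ", ncol(features), " does not match network input ",
         model$spec$input_size)
  }
  if (ncol(targets) != length(model$spec$targets)) {
    stop("target count does not match the network branches")
  }
  n <- nrow(features)
  n_val <- max(1L, floor(config$validation_split * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- features[tr_idx, , drop = FALSE]; Ytr <- targets[tr_idx, , drop = FALSE]
  Xval <- features[val_idx, , drop = FALSE]; Yval <- targets[val_idx, , drop = FALSE]
  state <- adam_state_like(model)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nrow(Xtr))
    ep_loss <- 0; n_seen <- 0L
    for (start in seq(1L, nrow(Xtr), by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, nrow(Xtr))]
      Xb <- Xtr[idx, , drop = FALSE]; Yb <- Ytr[idx, , drop = FALSE]
      fwd <- nn_forward(model, Xb, training = TRUE)
      grads <- nn_backward(model, Xb, Yb, fwd)
      r <- adam_update(model, grads, state, lr = config$learning_rate)
      model <- r$model; state <- r$state
      ep_loss <- ep_loss + mse_loss(fwd$Y, Yb) * length(idx)
      n_seen <- n_seen + length(idx)
    }
    val_loss <- mse_loss(nn_forward(model, Xval)$Y, Yval)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / n_seen,
                                   val_loss = val_loss))
  }
  model$history <- hist
  model
}

#' Evaluate a trained network on a held-out test set
#'
#' @param model a trained `nn_model`.
#' @param features,targets test features and scaled targets.
#' @param n_confusion_bins equal-width bins on \[0, 1\] for the
#'   true-vs-predicted confusion matrices (default 5).
#' @return list with per-parameter `mse`, `r2`, `confusion` (list of
#'   matrices, rows = true bin, cols = predicted bin) and the raw
#'   `predictions`.
#' @export
evaluate_network <- function(model, features, targets,
                             n_confusion_bins = 5L) {
  features <- as.matrix(features); targets <- as.matrix(targets)
  if (nrow(features) == 0L) stop("empty test set")
  Y <- predict_network(model, features)
  p <- ncol(Y)
  mse <- r2 <- setNames(numeric(p), model$spec$targets)
  confusion <- setNames(vector("list", p), model$spec$targets)
  brk <- seq(0, 1, length.out = n_confusion_bins + 1L)
  for (j in seq_len(p)) {
    res <- Y[, j] - targets[, j]
    mse[j] <- mean(res^2)
    ss_tot <- sum((targets[, j] - mean(targets[, j]))^2)
    r2[j] <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_
    tb <- cut(pmin(pmax(targets[, j], 0), 1 - 1e-12), brk,
              include.lowest = TRUE, labels = FALSE)
    pb <- cut(pmin(pmax(Y[, j], 0), 1 - 1e-12), brk,
              include.lowest = TRUE, labels = FALSE)
    confusion[[j]] <- table(factor(tb, levels = seq_len(n_confusion_bins)),
                            factor(pb, levels = seq_len(n_confusion_bins)))
  }
  list(mse = mse, r2 = r2, confusion = confusion, predictions = Y)
}

#' Train an ensemble of networks
#'
#' Each member gets its own seed and its own independent random 0.8/0.2
#' train/test split of the dataset; member test MSEs are recorded.
#'
#' @param features,targets the full dataset (scaled targets).
#' @param K ensemble size (>= 2).
#' @param spec a [network_spec()].
#' @param config a [training_config()].
#' @param seed master seed; member seeds are derived from it.
#' @param normalization normalization tag of the training profiles, checked
#'   again at prediction time.
#' @return an object of class `nn_ensemble`.
#' @export
train_ensemble <- function(features, targets, K = 10L,
                           spec = network_spec("one_pulse"),
                           config = training_config(), seed = 1L,
                           normalization = "divided_by_total") {
  if (K < 2L) stop("an ensemble needs K >= 2 members")
  features <- as.matrix(features); targets <- as.matrix(targets)
  n <- nrow(features)
  member_seeds <- seed + seq_len(K) * 1000L
  members <- vector("list", K)
  test_mse <- matrix(NA_real_, K, length(spec$targets),
                     dimnames = list(NULL, spec$targets))
  for (k in seq_len(K)) {
    set.seed(member_seeds[k])
    n_test <- max(1L, floor(config$test_split * n))
    test_idx <- sample.int(n, n_test)
    tr_idx <- setdiff(seq_len(n), test_idx)
    model <- build_network(spec)
    model <- train_network(model, features[tr_idx, , drop = FALSE],
                           targets[tr_idx, , drop = FALSE], config)
    ev <- evaluate_network(model, features[test_idx, , drop = FALSE],
                           targets[test_idx, , drop = FALSE])
    test_mse[k, ] <- ev$mse
    model$test_idx <- test_idx
    members[[k]] <- model
  }
  structure(list(members = members, spec = spec, seed = seed,
                 member_seeds = member_seeds, test_mse = test_mse,
                 normalization = normalization),
            class = "nn_ensemble")
}

#' @export
print.nn_ensemble <- function(x, ...) {
  cat("Ensemble of", length(x$members), "networks (", x$spec$model,
      "); mean test MSE:", signif(mean(x$test_mse), 4), "\n")
  invisible(x)
}

#' Predict mating parameters with ensemble confidence intervals
#'
#' Applies every ensemble member to the profile and reports, per parameter,
#' the mean and the 2.5/97.5 percentiles across members, mapped back to the
#' natural parameter scale (SB in \[-1, 1\]).
#'
#' @param ensemble an [train_ensemble()] result.
#' @param profile a normalised `tract_profile` (its normalization tag must
#'   match the ensemble's training data) or a bare feature vector.
#' @return an object of class `ensemble_prediction`: data.frame with
#'   columns `parameter`, `mean`, `lower`, `upper` (natural scale), plus a
#'   `scaled` matrix attribute of the raw member outputs.
#' @export
predict_with_ci <- function(ensemble, profile) {
  stopifnot(inherits(ensemble, "nn_ensemble"))
  if (inherits(profile, "tract_profile")) {
    if (!identical(profile$normalization, ensemble$normalization)) {
      stop("profile normalization ('", profile$normalization,
           "') does not match the ensemble's training normalization ('",
           ensemble$normalization, "')")
    }
    x <- flatten_profile(profile)
  } else {
    x <- as.numeric(profile)
  }
  preds <- t(vapply(ensemble$members,
                    function(m) drop(predict_network(m, x)),
                    numeric(length(ensemble$spec$targets))))
  colnames(preds) <- ensemble$spec$targets
  scaled_mean <- colMeans(preds)
  scaled_lo <- apply(preds, 2, quantile, probs = 0.025, names = FALSE)
  scaled_hi <- apply(preds, 2, quantile, probs = 0.975, names = FALSE)
  to_nat <- function(v) {
    out <- v
    sb_cols <- grepl("^SB", names(v))
    out[sb_cols] <- 2 * v[sb_cols] - 1
    out
  }
  nm <- setNames(ensemble$spec$targets, ensemble$spec$targets)
  mean_nat <- to_nat(setNames(scaled_mean, nm))
  lo_nat <- to_nat(setNames(scaled_lo, nm))
  hi_nat <- to_nat(setNames(scaled_hi, nm))
  res <- data.frame(parameter = ensemble$spec$targets, mean = mean_nat,
                    lower = lo_nat, upper = hi_nat, row.names = NULL)
  attr(res, "scaled") <- preds
  class(res) <- c("ensemble_prediction", "data.frame")
  res
}
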