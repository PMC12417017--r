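# Sequence windowing and a compact recurrent sequence classifier trained
# with Adam and cross-entropy: the default architecture behind the
# pluggable sequence-model interface.

#' Build centered sequence windows on a participant-wise basis
#'
#' Window length is `2 x length_minutes` epochs; the window for center
#' epoch i spans half the window backward and forward.  Windows never mix
#' participants; positions outside a participant's recording are
#' zero-padded and masked.  Inputs are z-normalized with training-set
#' statistics (`norm_stats`); when NULL the statistics are computed from
#' the supplied data and attached, so they can be reused for validation
#' and test windows.
#'
#' @param features Matrix or `feature_matrix` of per-epoch inputs.
#' @param labels Factor of stage labels (the center epoch's label).
#' @param ids Participant id per row.
#' @param length_minutes Window length in minutes (10, 25 or 50).
#' @param norm_stats Optional list(center, scale) from the training set.
#' @return A `sequence_dataset`: `windows` (n x L x F array), `mask`
#'   (n x L), `labels`, `ids`, `length_epochs`, `norm_stats`.
#' @export
make_sequences <- function(features, labels, ids, length_minutes = 10,
                           norm_stats = NULL) {
  X <- as_matrix_features(features)
  y <- as.factor(labels)
  stopifnot(nrow(X) == length(y), length(ids) == length(y))
  L <- as.integer(2 * length_minutes)
  half <- L %/% 2L
  if (is.null(norm_stats)) norm_stats <- standardize_fit(X)
  Z <- standardize_apply(X, norm_stats)
  n <- nrow(Z); f <- ncol(Z)
  win <- array(0, dim = c(n, L, f))
  mask <- matrix(FALSE, n, L)
  for (block in split(seq_len(n), factor(ids, levels = unique(ids)))) {
    nb <- length(block)
    for (j in seq_len(nb)) {
      # center j covers relative epochs [j - half, j + half - 1]
      rel <- (j - half):(j + half - 1L)
      ok <- rel >= 1 & rel <= nb
      row <- block[j]
      win[row, which(ok), ] <- Z[block[rel[ok]], , drop = FALSE]
      mask[row, which(ok)] <- TRUE
    }
  }
  structure(list(windows = win, mask = mask, labels = y, ids = ids,
                 length_epochs = L, norm_stats = norm_stats,
                 feature_names = colnames(X)),
            class = "sequence_dataset")
}

rnn_init <- function(f, hidden, k, seed) {
  with_seed(seed, list(
    Wx = matrix(rnorm(f * hidden, 0, 1 / sqrt(f)), f, hidden),
    Wh = matrix(rnorm(hidden * hidden, 0, 1 / sqrt(hidden)), hidden, hidden),
    b = numeric(hidden),
    Wo = matrix(rnorm(hidden * k, 0, 1 / sqrt(hidden)), hidden, k),
    bo = numeric(k)))
}

# forward pass to the center step; returns hidden states (for backprop)
# and class probabilities at the center
rnn_forward <- function(par, Xb, center) {
  n <- dim(Xb)[1]; hsz <- ncol(par$Wx)
  Hs <- vector("list", center)
  H <- matrix(0, n, hsz)
  for (t in seq_len(center)) {
    H <- tanh(Xb[, t, , drop = FALSE][, 1, ] %*% par$Wx + H %*% par$Wh +
              matrix(par$b, n, hsz, byrow = TRUE))
    Hs[[t]] <- H
  }
  logits <- H %*% par$Wo + matrix(par$bo, n, ncol(par$Wo), byrow = TRUE)
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  list(Hs = Hs, probs = e / rowSums(e))
}

rnn_backward <- function(par, Xb, center, fwd, y_onehot) {
  n <- dim(Xb)[1]
  g <- lapply(par, function(p) p * 0)
  dlogits <- (fwd$probs - y_onehot) / n
  g$Wo <- t(fwd$Hs[[center]]) %*% dlogits
  g$bo <- colSums(dlogits)
  dH <- dlogits %*% t(par$Wo)
  for (t in center:1) {
    Ht <- fwd$Hs[[t]]
    dA <- dH * (1 - Ht^2)
    g$Wx <- g$Wx + t(Xb[, t, , drop = FALSE][, 1, ]) %*% dA
    Hprev <- if (t > 1) fwd$Hs[[t - 1]] else matrix(0, n, ncol(Ht))
    g$Wh <- g$Wh + t(Hprev) %*% dA
    g$b <- g$b + colSums(dA)
    dH <- dA %*% t(par$Wh)
  }
  g
}

rnn_loss <- function(par, ds, center) {
  fwd <- rnn_forward(par, ds$windows, center)
  p <- fwd$probs[cbind(seq_along(ds$labels), as.integer(ds$labels))]
  -mean(log(pmax(p, 1e-12)))
}

#' Train the recurrent sequence classifier
#'
#' A stacked-free single-layer tanh recurrent network reading the window up
#' to its center epoch, with a softmax head over the stage classes, trained
#' with Adam and cross-entropy.  Each time a new minimum validation loss is
#' found the parameters are checkpointed; the checkpointed model is
#' returned.  Training and validation sets must be disjoint by
#' participant.
#'
#' @param train,val `sequence_dataset`s (validation built with the
#'   training `norm_stats`).
#' @param hidden Hidden-state size (default 16).
#' @param epochs Training epochs (0 returns the initial-weights model).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed RNG seed; fixed seed gives identical parameters.
#' @return A `sleep_model` with `algorithm = "lstm"`.
#' @export
fit_sequence_model <- function(train, val = NULL, hidden = 16, epochs = 20,
                               lr = 0.01, batch_size = 64, seed = 1) {
  stopifnot(inherits(train, "sequence_dataset"))
  if (!is.null(val) && length(intersect(unique(train$ids),
                                        unique(val$ids))))
    stopf("train and validation sets share participants")
  classes <- levels(train$labels)
  f <- dim(train$windows)[3]
  L <- train$length_epochs
  center <- L %/% 2L + 1L
  center <- min(center, L)
  par <- rnn_init(f, hidden, length(classes), derive_seed(seed, 1))
  best <- list(par = par, loss = Inf)
  if (!is.null(val)) best$loss <- rnn_loss(par, val, center)
  if (epochs > 0) {
    mom <- lapply(par, function(p) p * 0)
    vel <- lapply(par, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0
    n <- dim(train$windows)[1]
    onehot <- diag(length(classes))[as.integer(train$labels), , drop = FALSE]
    for (ep in seq_len(epochs)) {
      ord <- with_seed(derive_seed(seed, 10 + ep), sample(n))
      for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
        Xb <- train$windows[bs, , , drop = FALSE]
        fwd <- rnn_forward(par, Xb, center)
        g <- rnn_backward(par, Xb, center, fwd,
                          onehot[bs, , drop = FALSE])
        step <- step + 1
        for (nm in names(par)) {
          mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
          vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
          mhat <- mom[[nm]] / (1 - b1^step)
          vhat <- vel[[nm]] / (1 - b2^step)
          par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      cur <- if (is.null(val)) rnn_loss(par, train, center)
             else rnn_loss(par, val, center)
      if (!is.finite(cur)) stopf("divergent (non-finite) training loss")
      if (cur < best$loss) best <- list(par = par, loss = cur)
    }
  }
  structure(list(algorithm = "lstm", classes = classes,
                 feature_names = train$feature_names,
                 preproc = train$norm_stats,
                 est = list(par = best$par, hidden = hidden,
                            length_epochs = L, center = center),
                 metadata = list(seed = seed, val_loss = best$loss,
                                 epochs = epochs, lr = lr)),
            class = "sleep_model")
}

predict_rnn <- function(object, newdata) {
  stopifnot(inherits(newdata, "sequence_dataset"))
  if (dim(newdata$windows)[1] == 0)
    return(factor(character(0), levels = object$classes))
  fwd <- rnn_forward(object$est$par, newdata$windows, object$est$center)
  factor(object$classes[max.col(fwd$probs)], levels = object$classes)
}
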