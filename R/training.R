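#' Training configuration
#'
#' Mini-batch stochastic optimization with the AMSGrad variant of Adam, L2
#' weight regularization, input-layer dropout, and a schedule that halves the
#' learning rate when the validation loss shows no improvement for
#' `plateau_patience` epochs. Default hyperparameters are the values selected
#' by the hyperband search at reference scale (`lr = 0.009765`, `dr = 0.2`,
#' `reg = 0.01`) with batch size 5.
#'
#' @param lr Learning rate.
#' @param dropout_rate Input-layer dropout rate (`dr`).
#' @param l2_factor L2 weight-regularization factor (`reg`).
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param plateau_factor,plateau_patience Learning-rate schedule: multiply by
#'   `plateau_factor` after `plateau_patience` epochs without validation-loss
#'   improvement.
#' @param seed Integer seed controlling shuffling, dropout and initialization
#'   done inside [train()].
#' @export
train_config <- function(lr = 0.009765, dropout_rate = 0.2, l2_factor = 0.01,
                         batch_size = 5L, epochs = 40L, plateau_factor = 0.5,
                         plateau_patience = 4L, seed = 1L) {
  stopifnot(lr >= 0, dropout_rate >= 0, dropout_rate < 1, l2_factor >= 0)
  structure(list(lr = lr, dropout_rate = dropout_rate, l2_factor = l2_factor,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- dataset assembly -----------------------------------------------------

#' Assemble classifier training data from annotated slices
#'
#' Images are min-max normalized and down-sized (anti-aliased bicubic) to the
#' classifier input size; targets follow the one-hot convention (1,0) thigh /
#' (0,1) leg, i.e. class index 0 = thigh, 1 = leg.
#'
#' @param slices List of `annotated_slice`.
#' @param size Classifier input side length.
#' @export
as_classifier_data <- function(slices, size = 128L) {
  imgs <- lapply(slices, function(s) {
    img <- normalize_intensity(s$image)
    if (nrow(img) > size || ncol(img) > size)
      img <- downsize_for_classifier(img, size)
    img
  })
  x <- array(0, c(size, size, 1, length(slices)))
  for (i in seq_along(imgs)) x[, , 1, i] <- imgs[[i]]
  y <- vapply(slices, function(s) if (s$district == "thigh") 0L else 1L, 0L)
  list(x = x, y = y)
}

#' Assemble segmenter training data from annotated slices
#'
#' Images are min-max normalized; weight maps default to 1 everywhere when
#' not supplied (unweighted cross-entropy).
#'
#' @param slices List of `annotated_slice`.
#' @param weight_maps Optional list of per-slice weight matrices (computed
#'   after augmentation, since warping changes border geometry).
#' @export
as_segmenter_data <- function(slices, weight_maps = NULL) {
  n <- length(slices)
  d <- dim(slices[[1]]$image)
  x <- array(0, c(d[1], d[2], 1, n))
  labels <- array(0L, c(d, n))
  weights <- array(1, c(d, n))
  for (i in seq_len(n)) {
    x[, , 1, i] <- normalize_intensity(slices[[i]]$image)
    labels[, , i] <- slices[[i]]$labels
    if (!is.null(weight_maps)) weights[, , i] <- weight_maps[[i]]
  }
  list(x = x, labels = labels, weights = weights)
}

# ---- optimizer and schedule ----------------------------------------------

make_amsgrad <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p$env[[p$f]] * 0)
  st$v <- st$m
  st$vhat <- st$m
  st$t <- 0L
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

amsgrad_step <- function(st, params, lr, l2_factor) {
  st$t <- st$t + 1L
  corr <- sqrt(1 - st$beta2^st$t) / (1 - st$beta1^st$t)
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$env[[p$g]]
    if (is.null(g)) next
    if (l2_factor > 0 && p$decay) g <- g + l2_factor * p$env[[p$f]]
    st$m[[i]] <- st$beta1 * st$m[[i]] + (1 - st$beta1) * g
    st$v[[i]] <- st$beta2 * st$v[[i]] + (1 - st$beta2) * g^2
    st$vhat[[i]] <- pmax(st$vhat[[i]], st$v[[i]])
    p$env[[p$f]] <- p$env[[p$f]] -
      lr * corr * st$m[[i]] / (sqrt(st$vhat[[i]]) + st$eps)
  }
}

#' Reduce-on-plateau learning-rate scheduler
#'
#' Stateful scheduler: call `sched$update(loss)` once per epoch; when the
#' monitored loss has not improved for `patience` consecutive epochs the
#' learning rate is multiplied by `factor` (and the wait counter reset).
#'
#' @param lr Initial learning rate.
#' @param factor Multiplicative reduction factor.
#' @param patience Epochs without improvement before reducing.
#' @export
plateau_scheduler <- function(lr, factor = 0.5, patience = 4L) {
  e <- new.env()
  e$lr <- lr; e$best <- Inf; e$wait <- 0L
  e$update <- function(loss) {
    if (loss < e$best - 1e-12) {
      e$best <- loss
      e$wait <- 0L
    } else {
      e$wait <- e$wait + 1L
      if (e$wait >= patience) {
        e$lr <- e$lr * factor
        e$wait <- 0L
      }
    }
    e$lr
  }
  e
}

# ---- loss + gradient on a mini-batch --------------------------------------

classifier_batch <- function(net, x, y, training = TRUE) {
  logits <- classifier_forward(net, x, training)
  p <- softmax_cols(logits)
  n <- ncol(p)
  onehot <- matrix(0, 2, n)
  onehot[cbind(y + 1L, seq_len(n))] <- 1
  loss <- mean(-colSums(onehot * log(pmax(p, PROB_EPS))))
  if (!is.finite(loss))
    return(list(loss = loss, metric = NA_real_, dlogits = NULL))
  acc <- mean((apply(p, 2, which.max) - 1L) == y)
  list(loss = loss, metric = acc, dlogits = (p - onehot) / n)
}

segmenter_batch <- function(net, x, labels, weights, training = TRUE) {
  logits <- segmenter_forward(net, x, training)
  p <- softmax_pixelwise(logits)
  d <- dim(p)
  n <- d[4]
  dlogits <- p
  loss <- 0
  dsc <- numeric(n)
  rr <- as.vector(row(matrix(0, d[1], d[2])))
  cc <- as.vector(col(matrix(0, d[1], d[2])))
  for (i in seq_len(n)) {
    lab <- labels[, , i]
    w <- weights[, , i]
    idx <- cbind(rr, cc, as.vector(lab) + 1L, i)
    pl <- pmax(p[idx], PROB_EPS)
    loss <- loss + (-sum(as.vector(w) * log(pl)))
    if (!is.finite(loss))
      return(list(loss = loss, metric = NA_real_, dlogits = NULL))
    dlogits[idx] <- dlogits[idx] - 1
    for (ch in seq_len(d[3]))
      dlogits[, , ch, i] <- dlogits[, , ch, i] * w
    dsc[i] <- dice_coefficient(argmax_labels(p[, , , i]), lab)$mean
  }
  list(loss = loss / n, metric = mean(dsc, na.rm = TRUE),
       dlogits = dlogits / n)
}

argmax_labels <- function(prob) {  # (H, W, K) -> H x W integer labels
  d <- dim(prob)
  m <- matrix(prob, nrow = d[1] * d[2])
  matrix(max.col(m, ties.method = "first") - 1L, d[1], d[2])
}

eval_on <- function(net, data, batch_size = 8L) {
  if (net$kind == "classifier") {
    n <- dim(data$x)[4]
    loss <- 0; correct <- 0
    for (b in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
      r <- classifier_batch(net, data$x[, , , b, drop = FALSE], data$y[b],
                            training = FALSE)
      loss <- loss + r$loss * length(b)
      correct <- correct + r$metric * length(b)
    }
    list(loss = loss / n, metric = correct / n)
  } else {
    n <- dim(data$x)[4]
    loss <- 0; dsc <- numeric(n)
    for (i in seq_len(n)) {
      p <- net_forward(net, data$x[, , , i, drop = FALSE], training = FALSE)
      lab <- data$labels[, , i]
      loss <- loss + weighted_cross_entropy(p[, , , 1], lab,
                                            data$weights[, , i])
      dsc[i] <- dice_coefficient(argmax_labels(p[, , , 1]), lab)$mean
    }
    list(loss = loss / n, metric = mean(dsc, na.rm = TRUE))
  }
}

# ---- training loop --------------------------------------------------------

#' Train a network
#'
#' Mini-batch AMSGrad optimization of the categorical (classifier) or
#' weighted (segmenter) cross-entropy, with L2 regularization on kernels,
#' input-layer dropout, and the reduce-on-plateau learning-rate schedule
#' monitoring the validation loss. Epoch-end losses and metrics (categorical
#' accuracy / mean Dice) are evaluated in inference mode on both splits.
#' Fully seeded; training can be resumed by passing the returned `state`.
#'
#' @param net A `muscleseg_net`.
#' @param train_data From [as_classifier_data()] or [as_segmenter_data()]
#'   (the latter carrying precomputed weight maps).
#' @param val_data Optional validation data of the same form.
#' @param config A [train_config()].
#' @param state Optional optimizer/scheduler state from a previous call, to
#'   resume training.
#' @param verbose Print per-epoch progress.
#' @return List with `network` (trained in place), `history` (data.frame:
#'   epoch, lr, train/validation loss and metric) and `state`.
#' @export
train <- function(net, train_data, val_data = NULL, config = train_config(),
                  state = NULL, verbose = FALSE) {
  n <- dim(train_data$x)[4]
  if (n == 0) stop("empty training set")
  params <- all_params(net)
  net$dropout_rate <- config$dropout_rate
  if (is.null(state)) {
    state <- new.env(parent = emptyenv())
    state$opt <- make_amsgrad(params)
    state$sched <- plateau_scheduler(config$lr, config$plateau_factor,
                                     config$plateau_patience)
    state$epoch <- 0L
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(config$seed)
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    restore_rng_state(state$rng)
  }
  history <- vector("list", config$epochs)
  is_cls <- net$kind == "classifier"
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_metric <- 0; ep_n <- 0
    for (b in batches) {
      r <- if (is_cls)
        classifier_batch(net, train_data$x[, , , b, drop = FALSE],
                         train_data$y[b])
      else
        segmenter_batch(net, train_data$x[, , , b, drop = FALSE],
                        train_data$labels[, , b, drop = FALSE],
                        train_data$weights[, , b, drop = FALSE])
      if (!is.finite(r$loss))
        stop("training diverged: non-finite loss at epoch ", state$epoch + ep)
      net_backward(net, r$dlogits)
      amsgrad_step(state$opt, params, state$sched$lr, config$l2_factor)
      ep_loss <- ep_loss + r$loss * length(b)
      ep_metric <- ep_metric + r$metric * length(b)
      ep_n <- ep_n + length(b)
    }
    # training loss/metric are the running epoch averages accumulated during
    # the pass; validation is evaluated in inference mode at epoch end
    tr <- list(loss = ep_loss / ep_n, metric = ep_metric / ep_n)
    vl <- if (!is.null(val_data)) eval_on(net, val_data) else
      list(loss = NA_real_, metric = NA_real_)
    lr_now <- state$sched$lr
    monitored <- if (!is.null(val_data)) vl$loss else tr$loss
    state$sched$update(monitored)
    history[[ep]] <- data.frame(
      epoch = state$epoch + ep, lr = lr_now,
      train_loss = tr$loss, train_metric = tr$metric,
      val_loss = vl$loss, val_metric = vl$metric)
    if (verbose)
      message(sprintf("epoch %3d lr %.5g loss %.4f metric %.4f val %.4f/%.4f",
                      state$epoch + ep, lr_now, tr$loss, tr$metric,
                      vl$loss, vl$metric))
  }
  state$epoch <- state$epoch + config$epochs
  state$rng <- get_rng_state()
  list(network = net, history = do.call(rbind, history), state = state)
}

# ---- hyperband ------------------------------------------------------------

#' Hyperband hyperparameter search
#'
#' Successive-halving brackets over a discrete space of `(lr, dr, reg)`
#' configurations within the intervals `(0.0001, 0.01] x [0, 0.5] x [0, 0.1]`,
#' scoring each configuration by its validation metric (categorical accuracy
#' or Dice). Epoch budgets are allocated adaptively with reduction factor
#' `eta`; surviving configurations resume training from their checkpoints.
#'
#' @param make_net Function of no arguments returning a fresh network.
#' @param train_data,val_data Datasets as for [train()].
#' @param space data.frame with columns `lr`, `dr`, `reg`.
#' @param max_epochs Maximum epochs per configuration.
#' @param batch_size Mini-batch size (fixed across the search).
#' @param eta Halving factor.
#' @param seed Integer seed.
#' @return List with `config` (best row of `space` as a list), `score`,
#'   and `log` (one row per (bracket, trial, rung) evaluation).
#' @export
hyperband_search <- function(make_net, train_data, val_data, space,
                             max_epochs = 20L, batch_size = 5L, eta = 3,
                             seed = 1L) {
  if (NROW(space) == 0) stop("empty hyperparameter space")
  stopifnot(all(c("lr", "dr", "reg") %in% names(space)))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  s_max <- floor(log(max_epochs) / log(eta))
  B <- (s_max + 1) * max_epochs
  log_rows <- list()
  best <- list(score = -Inf, config = NULL)
  for (s in seq(s_max, 0)) {
    n_cfg <- ceiling(B / max_epochs * eta^s / (s + 1))
    r0 <- max_epochs * eta^(-s)
    pick <- sample.int(NROW(space), n_cfg, replace = TRUE)
    trials <- lapply(pick, function(k) {
      cfg <- as.list(space[k, c("lr", "dr", "reg")])
      list(cfg = cfg, net = make_net(), state = NULL, epochs = 0L,
           seed = sample.int(.Machine$integer.max - 1L, 1))
    })
    for (i in seq(0, s)) {
      n_i <- floor(n_cfg * eta^(-i))
      budget <- max(1L, as.integer(round(r0 * eta^i)))
      scores <- numeric(length(trials))
      for (k in seq_along(trials)) {
        tr <- trials[[k]]
        add <- max(0L, budget - tr$epochs)
        if (add > 0) {
          cfg <- train_config(lr = tr$cfg$lr, dropout_rate = tr$cfg$dr,
                              l2_factor = tr$cfg$reg,
                              batch_size = batch_size, epochs = add,
                              seed = tr$seed)
          res <- train(tr$net, train_data, val_data, cfg, state = tr$state)
          trials[[k]]$state <- res$state
          trials[[k]]$epochs <- budget
        }
        sc <- eval_on(trials[[k]]$net, val_data)$metric
        scores[k] <- sc
        log_rows[[length(log_rows) + 1]] <- data.frame(
          bracket = s, rung = i, lr = tr$cfg$lr, dr = tr$cfg$dr,
          reg = tr$cfg$reg, epochs = budget, score = sc)
        if (sc > best$score) best <- list(score = sc, config = tr$cfg)
      }
      keep <- max(1L, floor(n_i / eta))
      if (i < s) trials <- trials[order(scores, decreasing = TRUE)[seq_len(keep)]]
    }
  }
  list(config = best$config, score = best$score,
       log = do.call(rbind, log_rows))
}
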