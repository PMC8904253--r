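# Embedding-space decoding: spatiotemporal neural windows -> feed-forward
# regressor into embedding space -> word classification by cosine distance,
# softmax over labels, and frequency-weighted one-vs-rest ROC-AUC, with
# contiguous temporal folds, nested electrode selection, and ensembling.

#' Bin neural windows around word onsets
#'
#' Per event, the signal is averaged into `n_bins` bins of `bin_ms` each,
#' spanning `n_bins * bin_ms` centered on `onset + lag` (default: ten
#' 62.5-ms bins spanning 625 ms; 32 samples per bin at 512 Hz). Events whose
#' window falls outside the recording are dropped with a warning.
#'
#' @param rec preprocessed `nlx_recording`
#' @param events `nlx_events`
#' @param lag_ms center lag (ms)
#' @param n_bins number of bins (default 10)
#' @param bin_ms bin width in ms (default 62.5)
#' @return 3-d array events x electrodes x bins, with attribute `keep`
#' @export
bin_windows <- function(rec, events, lag_ms, n_bins = 10, bin_ms = 62.5) {
  stopifnot(inherits(rec, "nlx_recording"), inherits(events, "nlx_events"))
  span <- n_bins * bin_ms
  smp_per_bin <- bin_ms / 1000 * rec$fs
  center <- round((events$onset_s + lag_ms / 1000) * rec$fs) + 1
  start <- round(center - span / 2000 * rec$fs)
  keep <- which(start >= 1 & start + round(n_bins * smp_per_bin) - 1 <= ncol(rec$signal))
  if (length(keep) < nrow(events)) {
    warning(sprintf("%d event(s) with windows outside the recording dropped",
                    nrow(events) - length(keep)))
  }
  ne <- nrow(rec$signal)
  out <- array(NA_real_, c(length(keep), ne, n_bins))
  for (b in seq_len(n_bins)) {
    from <- start[keep] + round((b - 1) * smp_per_bin)
    to <- start[keep] + round(b * smp_per_bin) - 1
    out[, , b] <- window_means(rec$signal, from, to)
  }
  structure(out, keep = keep, lag_ms = lag_ms, bin_ms = bin_ms)
}

#' Contiguous temporal folds with train/dev/test rotation
#'
#' Splits the (time-ordered) events into `n_folds` contiguous folds of
#' near-equal size. Rotation `i` uses fold `i` as the test set, the next fold
#' (cyclically) as the development set for early stopping, and the remaining
#' folds for training.
#'
#' @param n_events number of events
#' @param n_folds number of folds (default 5, >= 3)
#' @return list with `fold` (per-event fold id) and `rotations` (list of
#'   `train`/`dev`/`test` index vectors)
#' @export
temporal_folds <- function(n_events, n_folds = 5) {
  if (n_folds < 3) stop("need >= 3 folds for train/dev/test roles")
  fold <- as.integer(cut(seq_len(n_events), breaks = n_folds, labels = FALSE))
  rotations <- lapply(seq_len(n_folds), function(t) {
    dev <- t %% n_folds + 1
    list(test = which(fold == t), dev = which(fold == dev),
         train = which(!fold %in% c(t, dev)))
  })
  list(fold = fold, rotations = rotations)
}

#' Nested electrode selection per test fold
#'
#' For each rotation, runs the phase-randomization max-statistic encoding
#' significance procedure on the train+dev events only (the test fold never
#' touches the selection), and returns the significant electrode set.
#'
#' @param rec preprocessed `nlx_recording`
#' @param events `nlx_events`
#' @param emb `nlx_embedding` used for the selection encoding
#' @param folds result of [temporal_folds()]
#' @param lags_ms lag grid for the selection encoding
#' @param n_perm permutations (reduced counts are typical at desk scale)
#' @param q FDR level (default 0.01)
#' @param seed integer seed
#' @return list of integer electrode index vectors, one per rotation
#' @export
nested_electrode_selection <- function(rec, events, emb, folds,
                                       lags_ms = seq(-500, 500, by = 100),
                                       n_perm = 200, q = 0.01, seed = 1) {
  lapply(seq_along(folds$rotations), function(i) {
    rot <- folds$rotations[[i]]
    idx <- sort(c(rot$train, rot$dev))
    ev <- events[idx, , drop = FALSE]
    class(ev) <- c("nlx_events", "data.frame")
    sig <- electrode_significance(
      rec, ev, new_embedding(unclass(emb)[idx, , drop = FALSE], "derived"),
      lags_ms = lags_ms, n_perm = n_perm, q = q, seed = child_seed(seed, i))
    sel <- sig$significant
    if (length(sel) == 0) {
      stop("no electrode passed selection; increase SNR, events, or q")
    }
    sel
  })
}

# ---- feed-forward MLP regressor (ReLU, Adam, MSE, early stopping) --------

mlp_init <- function(sizes) {
  L <- length(sizes) - 1
  lapply(seq_len(L), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0,
                                 sqrt(2 / fan_in)), sizes[l], sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
}

mlp_forward <- function(params, X, dropout = 0, train = FALSE) {
  a <- X
  cache <- list()
  L <- length(params)
  for (l in seq_len(L)) {
    z <- a %*% params[[l]]$W
    z <- sweep(z, 2, params[[l]]$b, "+")
    if (l < L) {
      h <- pmax(z, 0)
      if (train && dropout > 0) {
        mask <- matrix(stats::runif(length(h)) >= dropout, nrow(h), ncol(h))
        h <- h * mask / (1 - dropout)
        cache[[l]] <- list(a_in = a, z = z, mask = mask)
      } else {
        cache[[l]] <- list(a_in = a, z = z, mask = NULL)
      }
      a <- h
    } else {
      cache[[l]] <- list(a_in = a, z = z)
      a <- z
    }
  }
  list(out = a, cache = cache)
}

mlp_grad <- function(params, fw, Y, dropout = 0) {
  L <- length(params)
  n <- nrow(Y)
  delta <- 2 * (fw$out - Y) / (n * ncol(Y))   # d MSE / d out
  grads <- vector("list", L)
  for (l in rev(seq_len(L))) {
    cc <- fw$cache[[l]]
    grads[[l]] <- list(W = crossprod(cc$a_in, delta),
                       b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(params[[l]]$W)
      cp <- fw$cache[[l - 1]]
      act_grad <- (cp$z > 0) * 1
      if (!is.null(cp$mask)) act_grad <- act_grad * cp$mask / (1 - dropout)
      delta <- delta * act_grad
    }
  }
  grads
}

#' Train a feed-forward decoder network
#'
#' Multilayer perceptron (ReLU hidden layers, linear output) trained with
#' Adam to minimize the MSE of predicted embeddings, with early stopping on a
#' development set: training stops when the dev MSE has not improved for
#' `patience` epochs, and the best-dev weights are returned. Deterministic
#' for a fixed seed.
#'
#' @param X training inputs (cases x features), e.g. flattened binned windows
#' @param Y training targets (cases x embedding dims)
#' @param X_dev,Y_dev development set for early stopping
#' @param hidden hidden-layer sizes (default c(64, 32))
#' @param dropout dropout rate on hidden activations (default 0.2)
#' @param lr Adam learning rate
#' @param batch_size minibatch size
#' @param max_epochs maximum epochs
#' @param patience early-stopping patience (epochs)
#' @param seed integer seed (initialization and batch order)
#' @return object of class `nlx_decoder`: list with `params`, `dev_mse`,
#'   `epochs_run`, and the input standardization (`x_center`, `x_scale`)
#' @export
train_decoder <- function(X, Y, X_dev, Y_dev, hidden = c(64, 32),
                          dropout = 0.2, lr = 1e-3, batch_size = 32,
                          max_epochs = 300, patience = 10, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd); x_scale[x_scale == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  Xd <- sweep(sweep(as.matrix(X_dev), 2, x_center), 2, x_scale, "/")
  sizes <- c(ncol(X), hidden, ncol(Y))
  with_seed(seed, {
    params <- mlp_init(sizes)
    m_st <- v_st <- rapply(params, function(x) x * 0, how = "replace")
    best <- list(mse = Inf, params = params, epoch = 0)
    t_step <- 0
    n <- nrow(Xs)
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = batch_size)) {
        bi <- ord[start:min(start + batch_size - 1, n)]
        fw <- mlp_forward(params, Xs[bi, , drop = FALSE], dropout, train = TRUE)
        gr <- mlp_grad(params, fw, Y[bi, , drop = FALSE], dropout)
        t_step <- t_step + 1
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        for (l in seq_along(params)) {
          for (nm in c("W", "b")) {
            m_st[[l]][[nm]] <- b1 * m_st[[l]][[nm]] + (1 - b1) * gr[[l]][[nm]]
            v_st[[l]][[nm]] <- b2 * v_st[[l]][[nm]] + (1 - b2) * gr[[l]][[nm]]^2
            mhat <- m_st[[l]][[nm]] / (1 - b1^t_step)
            vhat <- v_st[[l]][[nm]] / (1 - b2^t_step)
            params[[l]][[nm]] <- params[[l]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
          }
        }
      }
      dev_pred <- mlp_forward(params, Xd)$out
      if (any(!is.finite(dev_pred))) stop(sprintf(
        "decoder training diverged (NaN) at epoch %d, seed %d", epoch, seed))
      dev_mse <- mean((dev_pred - as.matrix(Y_dev))^2)
      if (dev_mse < best$mse - 1e-12) {
        best <- list(mse = dev_mse, params = params, epoch = epoch)
      } else if (epoch - best$epoch >= patience) break
    }
    structure(list(params = best$params, dev_mse = best$mse,
                   epochs_run = epoch, x_center = x_center, x_scale = x_scale),
              class = "nlx_decoder")
  })
}

#' Predict embeddings with a trained decoder
#' @param decoder an `nlx_decoder`
#' @param X inputs (cases x features)
#' @return matrix of predicted embeddings
#' @export
predict_decoder <- function(decoder, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, decoder$x_center), 2, decoder$x_scale, "/")
  mlp_forward(decoder$params, Xs)$out
}

cosine_distance_to <- function(pred, ref) {
  # pred: n x d; ref: m x d; returns n x m cosine distances in [0, 2]
  pn <- sqrt(rowSums(pred^2))
  rn <- sqrt(rowSums(ref^2))
  zero <- pn == 0
  pn[zero] <- 1
  d <- 1 - (pred %*% t(ref)) / (pn %o% rn)
  if (any(zero)) {
    warning("zero-norm predicted embedding; distance set to maximal (2)")
    d[zero, ] <- 2
  }
  d
}

#' Ensemble label scores from decoder predictions
#'
#' For each test event and word label: the cosine distance from the predicted
#' embedding to every instance of that label is averaged across instances,
#' negated into a score, averaged across the ensemble's decoders, and finally
#' passed through a softmax over labels.
#'
#' @param decoders list of `nlx_decoder`s (>= 1)
#' @param X_test test inputs
#' @param label_embs named list: per label, a matrix of that label's instance
#'   embeddings (typically the training-set instances)
#' @return list with `probs` (events x labels, rows sum to 1) and `scores`
#'   (pre-softmax negated mean distances)
#' @export
ensemble_label_scores <- function(decoders, X_test, label_embs) {
  if (length(decoders) < 1) stop("need at least one decoder")
  labels <- names(label_embs)
  n <- nrow(as.matrix(X_test))
  acc <- matrix(0, n, length(labels), dimnames = list(NULL, labels))
  for (dec in decoders) {
    pred <- predict_decoder(dec, X_test)
    for (j in seq_along(labels)) {
      d <- cosine_distance_to(pred, as.matrix(label_embs[[j]]))
      acc[, j] <- acc[, j] + (-rowMeans(d))
    }
  }
  scores <- acc / length(decoders)
  list(probs = softmax_rows(scores), scores = scores)
}

#' One-vs-rest ROC-AUC per label, frequency-weighted
#'
#' Per label, the AUC is the rank statistic (Mann-Whitney) of that label's
#' scores for positive versus negative test events; labels lacking positives
#' or negatives are excluded with a warning. The summary AUC is the mean
#' weighted by the labels' test-set frequencies.
#'
#' @param scores events x labels score matrix (higher = more likely)
#' @param true_labels per-event true label (character, matching colnames)
#' @return list with `auc_per_label`, `weights`, `weighted_auc`, `n_labels`
#' @export
roc_auc_weighted <- function(scores, true_labels) {
  labels <- colnames(scores)
  if (length(unique(true_labels)) < 2) stop("need >= 2 distinct labels")
  auc <- rep(NA_real_, length(labels)); names(auc) <- labels
  for (j in seq_along(labels)) {
    pos <- true_labels == labels[j]
    if (!any(pos) || all(pos)) next
    rk <- rank(scores[, j])
    n1 <- sum(pos); n0 <- sum(!pos)
    auc[j] <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  scored <- !is.na(auc)
  if (!all(scored)) {
    warning(sprintf("%d label(s) without positives in the test set excluded",
                    sum(!scored)))
  }
  freq <- table(factor(true_labels, levels = labels))[scored]
  w <- as.numeric(freq) / sum(freq)
  list(auc_per_label = auc[scored], weights = w,
       weighted_auc = sum(w * auc[scored]), n_labels = sum(scored))
}

#' Full decoding pipeline across lags
#'
#' Per lag: bin spatiotemporal windows, build contiguous temporal folds,
#' optionally select electrodes on train+dev data only, train an ensemble of
#' decoders (randomized initialization and batch order) into the embedding
#' space, score test events by averaged cosine distance to each eligible
#' label's instances, and evaluate with frequency-weighted one-vs-rest
#' ROC-AUC. Labels need `min_repetitions` training-set occurrences to be
#' scored.
#'
#' @param rec preprocessed `nlx_recording`
#' @param events `nlx_events`
#' @param emb `nlx_embedding` target space
#' @param lags_ms lag grid (ms)
#' @param n_folds temporal folds (default 5)
#' @param ensemble decoders per fold (default 10)
#' @param min_repetitions training-set repetitions required per scored label
#' @param electrode_selection `"none"` (use all electrodes) or `"nested"`
#' @param n_bins,bin_ms window binning parameters
#' @param hidden,dropout,lr,batch_size,max_epochs,patience decoder training
#'   parameters, see [train_decoder()]
#' @param selection_args list of arguments for
#'   [nested_electrode_selection()] when `electrode_selection = "nested"`
#' @param return_scores keep each fold's test-event score matrix and labels
#'   (for downstream checks such as label permutations)
#' @param seed integer seed
#' @return object of class `nlx_decoding`: per lag, the fold AUCs, their mean
#'   and s.e., plus configuration
#' @export
run_decoding <- function(rec, events, emb, lags_ms = c(-150, 0, 150),
                         n_folds = 5, ensemble = 10, min_repetitions = 5,
                         electrode_selection = c("none", "nested"),
                         n_bins = 10, bin_ms = 62.5, hidden = c(64, 32),
                         dropout = 0.2, lr = 1e-3, batch_size = 32,
                         max_epochs = 300, patience = 10,
                         selection_args = list(), return_scores = FALSE,
                         seed = 1) {
  electrode_selection <- match.arg(electrode_selection)
  res <- vector("list", length(lags_ms))
  for (li in seq_along(lags_ms)) {
    bw <- bin_windows(rec, events, lags_ms[li], n_bins, bin_ms)
    keep <- attr(bw, "keep")
    ev <- events[keep, , drop = FALSE]
    class(ev) <- c("nlx_events", "data.frame")
    Yemb <- unclass(emb)[keep, , drop = FALSE]
    folds <- temporal_folds(nrow(ev), n_folds)
    sel <- if (electrode_selection == "nested") {
      do.call(nested_electrode_selection,
              c(list(rec = rec, events = ev,
                     emb = new_embedding(Yemb, "derived"), folds = folds,
                     seed = child_seed(seed, 100 + li)), selection_args))
    } else {
      rep(list(seq_len(dim(bw)[2])), n_folds)
    }
    fold_auc <- numeric(n_folds)
    fold_detail <- vector("list", n_folds)
    for (fi in seq_len(n_folds)) {
      rot <- folds$rotations[[fi]]
      el <- sel[[fi]]
      flat <- matrix(bw[, el, , drop = FALSE], nrow(ev),
                     length(el) * n_bins)
      decs <- lapply(seq_len(ensemble), function(k) {
        train_decoder(flat[rot$train, , drop = FALSE],
                      Yemb[rot$train, , drop = FALSE],
                      flat[rot$dev, , drop = FALSE],
                      Yemb[rot$dev, , drop = FALSE],
                      hidden = hidden, dropout = dropout, lr = lr,
                      batch_size = batch_size, max_epochs = max_epochs,
                      patience = patience,
                      seed = child_seed(seed, 1000 * li + 10 * fi + k))
      })
      tr_tokens <- ev$token[rot$train]
      eligible <- names(which(table(tr_tokens) >= min_repetitions))
      if (length(eligible) < 2) stop("fewer than 2 labels meet the repetition rule")
      label_embs <- lapply(eligible, function(lb) {
        Yemb[rot$train[tr_tokens == lb], , drop = FALSE]
      })
      names(label_embs) <- eligible
      sc <- ensemble_label_scores(decs, flat[rot$test, , drop = FALSE],
                                  label_embs)
      test_tokens <- ev$token[rot$test]
      in_lab <- test_tokens %in% eligible
      roc <- suppressWarnings(
        roc_auc_weighted(sc$probs[in_lab, , drop = FALSE], test_tokens[in_lab]))
      fold_auc[fi] <- roc$weighted_auc
      fold_detail[[fi]] <- list(auc = roc, n_test = sum(in_lab),
                                electrodes = el)
      if (return_scores) {
        fold_detail[[fi]]$scores <- sc$probs[in_lab, , drop = FALSE]
        fold_detail[[fi]]$labels <- test_tokens[in_lab]
      }
    }
    res[[li]] <- list(lag_ms = lags_ms[li], fold_auc = fold_auc,
                      mean_auc = mean(fold_auc),
                      se_auc = stats::sd(fold_auc) / sqrt(n_folds),
                      folds = fold_detail)
  }
  structure(list(lags_ms = lags_ms, by_lag = res,
                 mean_auc = vapply(res, `[[`, numeric(1), "mean_auc"),
                 se_auc = vapply(res, `[[`, numeric(1), "se_auc"),
                 ensemble = ensemble),
            class = "nlx_decoding")
}

#' @export
print.nlx_decoding <- function(x, ...) {
  cat("<nlx_decoding> frequency-weighted ROC-AUC by lag:\n")
  print(data.frame(lag_ms = x$lags_ms, auc = round(x$mean_auc, 3),
                   se = round(x$se_auc, 4)))
  invisible(x)
}
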