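# Decoding: window binning, temporal folds, decoder training, ensemble
# scoring, ROC-AUC, and leakage control.

test_that("binned windows have the right geometry", {
  ev <- make_events(c("a", "b"), c(2, 4))
  fs <- 512
  # constant signal: all bins equal
  rec <- new_recording(matrix(1.5, 3, 8 * fs), fs, stage = "smoothed")
  bw <- bin_windows(rec, ev, lag_ms = 0)
  expect_equal(dim(bw), c(2, 3, 10))
  expect_true(all(bw == 1.5))
  # at fs = 512 each 62.5-ms bin holds 32 samples: a step placed exactly at
  # the window midpoint fills the last 5 bins only
  x <- numeric(8 * fs)
  onset_smp <- round(2 * fs) + 1
  x[(onset_smp):(8 * fs)] <- 1     # step at onset (= window midpoint, lag 0)
  rec2 <- new_recording(rbind(x), fs, stage = "smoothed")
  bw2 <- bin_windows(rec2, make_events("a", 2), lag_ms = 0)
  expect_true(all(bw2[1, 1, 1:5] < 0.05))
  expect_true(all(bw2[1, 1, 6:10] > 0.95))
  # out-of-range events dropped with a warning
  expect_warning(bw3 <- bin_windows(rec, make_events(c("a", "b"), c(0.1, 4)),
                                    lag_ms = 0), "dropped")
  expect_equal(attr(bw3, "keep"), 2L)
})

test_that("temporal folds are contiguous partitions with rotating roles", {
  tf <- temporal_folds(100, 5)
  expect_equal(as.vector(table(tf$fold)), rep(20, 5))
  expect_true(all(diff(tf$fold) >= 0))     # contiguous in time
  # every event is in exactly one test fold across rotations
  test_cover <- sort(unlist(lapply(tf$rotations, `[[`, "test")))
  expect_equal(test_cover, 1:100)
  for (rot in tf$rotations) {
    expect_equal(sort(c(rot$train, rot$dev, rot$test)), 1:100)
    expect_equal(length(intersect(rot$train, rot$test)), 0)
    expect_equal(length(intersect(rot$dev, rot$test)), 0)
  }
  expect_error(temporal_folds(100, 2), "3 folds")
})

test_that("rank-based AUC equals brute-force pairwise counting", {
  set.seed(1)
  for (i in 1:10) {
    n <- sample(10:50, 1)
    labels <- sample(c("u", "v", "w"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("u", "v", "w")))
    scores[cbind(1:n, match(labels, colnames(scores)))] <-
      scores[cbind(1:n, match(labels, colnames(scores)))] + sample(c(0, 1), n, TRUE)
    roc <- suppressWarnings(roc_auc_weighted(scores, labels))
    for (lb in names(roc$auc_per_label)) {
      expect_equal(roc$auc_per_label[[lb]], auc_brute(scores[, lb], labels == lb),
                   tolerance = 1e-12)
    }
    expect_true(all(roc$auc_per_label >= 0 & roc$auc_per_label <= 1))
    expect_equal(sum(roc$weights), 1, tolerance = 1e-12)
  }
  # independent library cross-check on one case
  set.seed(11)
  lab2 <- sample(c("m", "n"), 40, replace = TRUE)
  sc2 <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("m", "n")))
  mine <- suppressWarnings(roc_auc_weighted(sc2, lab2))$auc_per_label[["m"]]
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab2 == "m",
                                        predictor = sc2[, "m"],
                                        quiet = TRUE, direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-10)
  # perfectly separating scores give AUC 1 everywhere; random scores ~ 0.5
  labels <- rep(c("a", "b"), each = 25)
  perfect <- cbind(a = c(rep(1, 25), rep(0, 25)), b = c(rep(0, 25), rep(1, 25)))
  expect_true(all(roc_auc_weighted(perfect, labels)$auc_per_label == 1))
  set.seed(2)
  rand_auc <- replicate(40, {
    roc_auc_weighted(cbind(a = rnorm(50), b = rnorm(50)), labels)$weighted_auc
  })
  expect_lt(abs(mean(rand_auc) - 0.5), 0.03)
  expect_error(roc_auc_weighted(perfect, rep("a", 50)), "distinct")
})

test_that("AUC is invariant to monotone transforms; softmax keeps row order", {
  set.seed(3)
  scores <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, letters[1:3]))
  labels <- sample(letters[1:3], 20, replace = TRUE)
  a1 <- suppressWarnings(roc_auc_weighted(scores, labels))
  a2 <- suppressWarnings(roc_auc_weighted(2 * scores + 7, labels))
  a3 <- suppressWarnings(roc_auc_weighted(exp(scores), labels))
  expect_equal(a1$auc_per_label, a2$auc_per_label, tolerance = 1e-12)
  expect_equal(a1$auc_per_label, a3$auc_per_label, tolerance = 1e-12)
  sm <- neurolex:::softmax_rows(scores)
  expect_equal(t(apply(sm, 1, order)), t(apply(scores, 1, order)))
  expect_equal(rowSums(sm), rep(1, 20), tolerance = 1e-12)
})

test_that("the decoder learns linear maps, refuses noise, and is deterministic", {
  set.seed(4)
  n <- 700; p <- 40; d <- 8
  X <- matrix(rnorm(n * p), n, p)
  W <- matrix(rnorm(p * d) / sqrt(p), p, d)
  Y <- X %*% W + 0.05 * matrix(rnorm(n * d), n, d)
  tr <- 1:500; dv <- 501:700
  dec <- train_decoder(X[tr, ], Y[tr, ], X[dv, ], Y[dv, ], dropout = 0,
                       lr = 0.01, batch_size = 64, patience = 25,
                       max_epochs = 400, seed = 5)
  expect_lt(dec$dev_mse, 0.1 * mean(apply(Y, 2, stats::var)))
  # pure-noise targets: dev MSE ~ target variance (no learning possible)
  Yn <- matrix(rnorm(n * d), n, d)
  decn <- train_decoder(X[tr, ], Yn[tr, ], X[dv, ], Yn[dv, ], dropout = 0,
                        lr = 0.005, max_epochs = 60, seed = 6)
  expect_gt(decn$dev_mse, 0.7 * mean(apply(Yn, 2, stats::var)))
  # determinism under a fixed seed
  dec2 <- train_decoder(X[tr, ], Y[tr, ], X[dv, ], Y[dv, ], dropout = 0,
                        lr = 0.01, batch_size = 64, patience = 25,
                        max_epochs = 400, seed = 5)
  expect_identical(dec$params, dec2$params)
})

test_that("ensemble scoring matches plain scores for one decoder and finds matches", {
  set.seed(7)
  d <- 6
  label_embs <- list(a = matrix(rnorm(2 * d), 2, d), b = matrix(rnorm(3 * d), 3, d))
  # decoder stub: identity passthrough via a linear network is overkill;
  # score directly through the exported surface with a single trained net
  X <- matrix(rnorm(40 * 5), 40, 5)
  Y <- X %*% matrix(rnorm(5 * d), 5, d)
  dec <- train_decoder(X[1:30, ], Y[1:30, ], X[31:40, ], Y[31:40, ],
                       dropout = 0, max_epochs = 30, seed = 8)
  one <- ensemble_label_scores(list(dec), X[31:40, ], label_embs)
  again <- ensemble_label_scores(list(dec, dec), X[31:40, ], label_embs)
  expect_equal(one$scores, again$scores, tolerance = 1e-12)
  expect_equal(rowSums(one$probs), rep(1, 10), tolerance = 1e-12)
  # predicted embedding equal to a label instance: that label wins
  probe <- label_embs$a[1, , drop = FALSE]
  dist_a <- mean(1 - probe %*% t(label_embs$a) /
                   (sqrt(sum(probe^2)) * sqrt(rowSums(label_embs$a^2))))
  dist_b <- mean(1 - probe %*% t(label_embs$b) /
                   (sqrt(sum(probe^2)) * sqrt(rowSums(label_embs$b^2))))
  expect_lt(dist_a, dist_b)
  expect_error(ensemble_label_scores(list(), X, label_embs), "at least one")
})

test_that("decoding finds planted signal, stays at chance on null data, and does not leak", {
  vocab <- gen_vocabulary(25, 1.1, 1)
  ev <- gen_word_events(vocab, 450, 0.35, 2)
  emb <- gen_embeddings(ev, 12, "static", seed = 3)
  gen <- gen_neural_recording(ev, emb, lag_kernel_gaussian(150, 80),
                              n_electrodes = 12, fs = 128, snr = 8, seed = 4)
  dr <- run_decoding(gen$recording, ev, emb, lags_ms = c(150), n_folds = 5,
                     ensemble = 2, lr = 5e-3, batch_size = 64,
                     max_epochs = 120, patience = 8, seed = 5)
  expect_gt(dr$mean_auc[1], 0.8)
  # null data: chance
  gen0 <- gen_neural_recording(ev, emb, lag_kernel_gaussian(150, 80),
                               n_electrodes = 12, fs = 128, snr = 0, seed = 6)
  dr0 <- run_decoding(gen0$recording, ev, emb, lags_ms = c(150), n_folds = 5,
                      ensemble = 2, lr = 5e-3, batch_size = 64,
                      max_epochs = 40, patience = 5, seed = 7)
  expect_lt(abs(dr0$mean_auc[1] - 0.5), 0.06)
  # no leakage: permuting test labels only collapses the planted-signal AUC
  lag_res <- dr$by_lag[[1]]$folds[[1]]
  # recompute AUC with permuted labels through the same scored surface
  vocab_lab <- names(lag_res$auc$auc_per_label)
  set.seed(8)
  # rebuild scores for fold 1 via the exported pipeline pieces
  bw <- bin_windows(gen$recording, ev, 150)
  keep <- attr(bw, "keep")
  evk <- ev[keep, , drop = FALSE]; class(evk) <- c("nlx_events", "data.frame")
  tf <- temporal_folds(nrow(evk), 5)
  rot <- tf$rotations[[1]]
  flat <- matrix(bw, dim(bw)[1], dim(bw)[2] * dim(bw)[3])
  Yemb <- unclass(emb)[keep, , drop = FALSE]
  dec <- train_decoder(flat[rot$train, ], Yemb[rot$train, ],
                       flat[rot$dev, ], Yemb[rot$dev, ], lr = 5e-3,
                       batch_size = 64, max_epochs = 120, patience = 8,
                       dropout = 0.2, seed = 9)
  tr_tok <- evk$token[rot$train]
  eligible <- names(which(table(tr_tok) >= 5))
  label_embs <- lapply(eligible, function(lb) {
    Yemb[rot$train[tr_tok == lb], , drop = FALSE]
  })
  names(label_embs) <- eligible
  sc <- ensemble_label_scores(list(dec), flat[rot$test, ], label_embs)
  te_tok <- evk$token[rot$test]
  in_lab <- te_tok %in% eligible
  auc_true <- suppressWarnings(
    roc_auc_weighted(sc$probs[in_lab, ], te_tok[in_lab]))$weighted_auc
  auc_perm <- suppressWarnings(
    roc_auc_weighted(sc$probs[in_lab, ], sample(te_tok[in_lab])))$weighted_auc
  expect_gt(auc_true, 0.75)
  expect_lt(abs(auc_perm - 0.5), 0.12)
})

test_that("nested electrode selection keeps tuned electrodes out-of-fold", {
  sc <- small_scene(n_words = 220, dim = 5, snr = 3, seed = 61,
                    n_electrodes = 6, fs = 64)
  tf <- temporal_folds(nrow(sc$events), 5)
  sel <- nested_electrode_selection(sc$rec, sc$events, sc$emb, tf,
                                    lags_ms = c(100, 200), n_perm = 150,
                                    seed = 7)
  expect_equal(length(sel), 5)
  # high SNR: essentially all electrodes selected in every fold
  expect_true(all(vapply(sel, length, integer(1)) >= 5))
})
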