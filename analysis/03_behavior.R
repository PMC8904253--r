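#!/usr/bin/env Rscript
# Behavioral and model-prediction analyses on the synthetic dataset:
# per-word predictability scores from 50 simulated raters, the top-5/top-1
# accuracy split, predictor calibration, rater/model agreement, n-gram
# baselines, and a context-window sweep.

suppressPackageStartupMessages(library(neurolex))
dir.create("results", showWarnings = FALSE)

seed <- 101
ds <- simulate_dataset(default_config(seed = seed))
ev <- ds$events
dists <- ds$dists
beh <- gen_behavioral_responses(ev, dists, n_raters = 50, seed = seed + 1)

scores <- predictability_score(beh, ev)
cat(sprintf("mean predictability score: %.1f%% (s.e. %.2f%%)\n",
            100 * mean(scores), 100 * sd(scores) / sqrt(length(scores))))

top5 <- accuracy_split(dists, 5)
top1 <- accuracy_split(dists, 1)
cat(sprintf("top-5 accuracy split: %.1f%% correct / %.1f%% incorrect; top-1: %.1f%%\n",
            100 * mean(top5), 100 * (1 - mean(top5)), 100 * mean(top1)))

# calibration of the model's top-1 probability against its top-1 accuracy
top1_idx <- apply(dists$probs, 1, which.max)
assigned <- dists$probs[cbind(seq_len(nrow(ev)), top1_idx)]
cal <- calibration_curve(assigned, top1_idx == dists$actual)
utils::write.csv(cal, "results/calibration.csv", row.names = FALSE)

# agreement between the model's top-1 and the raters' modal guess
modal <- apply(beh, 2, function(g) names(sort(table(g), decreasing = TRUE))[1])
model_top <- ds$vocab$types[top1_idx]
actual <- ev$token
ag <- agreement_rate(model_top, modal, model_top == actual, modal == actual)
cat(sprintf("model/rater top-1 agreement: %.1f%%; jointly correct %.1f%%, jointly incorrect %.1f%%\n",
            100 * ag$agreement, 100 * ag$quadrants["both_correct"],
            100 * ag$quadrants["both_incorrect"]))

# n-gram baseline over the event stream + correlation with predictability
ng <- ngram_fit(ev$token, n = 2, smoothing = "add_k", k = 1)
png <- ngram_prob_events(ng, ev$token)
ok <- is.finite(png)
cat(sprintf("bigram (add-1) probability vs predictability: r = %.3f\n",
            cor(png[ok], scores[ok])))

# context-window sweep with a predictor that queries the model distribution
predictor <- function(ctx, actual) {
  i <- length(ctx) + 1
  w <- min(length(ctx), 64)
  # probability mass the model puts on the actual word, degraded for
  # short context windows
  p <- dists$probs[i, match(actual, ds$vocab$types)]
  p * (w / 64) + (1 - w / 64) / length(ds$vocab$types)
}
sweep_res <- context_window_sweep(predictor, ev, c(2, 4, 8, 16, 32, 64, 128),
                                  scores)
print(sweep_res, row.names = FALSE)
utils::write.csv(sweep_res, "results/context_sweep.csv", row.names = FALSE)

summary <- data.frame(
  measure = c("mean_predictability", "top5_accuracy", "top1_accuracy",
              "agreement", "bigram_r"),
  value = c(mean(scores), mean(top5), mean(top1), ag$agreement,
            cor(png[ok], scores[ok])))
utils::write.csv(summary, "results/behavior_summary.csv", row.names = FALSE)
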