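#!/usr/bin/env Rscript
# Optional full-scale profile (NOT part of the test suite: multi-day CPU).
#
# Reproduces the study-scale training run for one population pair: 12,000
# simulations per scenario per demographic model (three models, 144,000
# tensors of shape (2, 44, 128)), the full ResNet-34 preset, Adam with the
# published settings, a 1,000-per-scenario evaluation set, and the
# 0.75..0.95 threshold sweep. Precision-level expectations at P = 0.9
# (presence precision ~95%, directionality > 90% except ELtoIL in ILa-ELs
# ~85%) are stochastic and depend on fixture-model fidelity; they are
# checked here, outside the CI budget.
#
# Usage: Rscript scripts/full_scale.R --pair ILa-ELw --out runs/full --seed 1

suppressPackageStartupMessages(library(introscan))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(pair = "ILa-ELw", out = "runs/full", seed = 1L)
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  opt[[key]] <- args[i + 1L]
  i <- i + 2L
}
seed <- as.integer(opt$seed)

models <- lapply(1:3, function(k) lynx_model(opt$pair, k))
samples <- if (opt$pair == "ILa-ELs") {
  c(ILa = 22L, ELs = 12L)
} else {
  c(ILa = 22L, ELw = 20L)
}

message("building 144,000-tensor training set (12,000 x 4 x 3) ...")
store <- build_training_set(models, per_scenario = 12000L,
                            dir = file.path(opt$out, "tensors"),
                            seed = derive_seed(seed, "train-set"),
                            region_bp = 1.1e6, H = 44L, samples = samples)
print(manifest_summary(store))
stopifnot(manifest_summary(store)$total == 144000L)

message("training full ResNet-34 preset ...")
net <- build_network(c(2L, 44L, 128L), "paper",
                     seed = derive_seed(seed, "init"))
fit <- train_discriminator(store, train_config(seed = seed), net = net,
                           verbose = TRUE)
save_checkpoint(fit$net, file.path(opt$out, "checkpoint.rds"))
write_history(fit$history, file.path(opt$out, "history.csv"))

message("evaluating 1,000 simulations per scenario ...")
labels <- rep(SCENARIO_CLASSES, 1000L)
eseed <- derive_seed(seed, "eval")
specs <- introscan:::with_seed(eseed, lapply(labels, draw_scenario))
ex <- list()
for (beg in seq(1L, length(specs), by = 500L)) {
  idx <- beg:min(beg + 499L, length(specs))
  ex <- c(ex, simulate_examples(models[[1L]], specs[idx], region_bp = 1.1e6,
                                seed = eseed + beg, samples = samples))
}
probs <- predict_examples(fit$net, ex, H = 44L, seed = eseed)
sweep_tab <- evaluate_thresholds(probs, labels)
print(sweep_tab)
write.csv(sweep_tab, file.path(opt$out, "threshold_sweep.csv"),
          row.names = FALSE)

at9 <- sweep_tab[sweep_tab$p == 0.9, ]
message(sprintf("presence precision at P = 0.9: %.3f (study reports ~0.95)",
                at9$presence_precision))
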