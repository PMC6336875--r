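#!/usr/bin/env Rscript
# Stage 5 — decision-tree models of binarized permissibility from synthetic
# protein properties: Spearman property correlations, depth-4 CART with
# 10-fold cross-validation, feature importances, and category withholding.
#
# Reads:  results/truth.tsv, results/profile_<domain>_*.tsv
# Writes: results/property_correlations.tsv, results/model_performance.tsv,
#         results/top_features.tsv

suppressMessages(library(dipscan))
seed <- 1

truth <- read.delim("results/truth.tsv")
truth <- structure(truth,
                   domains = sub("^p_se_", "",
                                 grep("^p_se_", names(truth), value = TRUE)))
feats <- simulate_features(truth, effect_size = 1.0, seed = seed + 4)
cats <- attr(feats, "categories")
domains <- attr(truth, "domains")

perf <- list()
for (d in domains) {
  g <- read_profile(sprintf("results/profile_%s_mean.tsv", d))
  b <- read_profile(sprintf("results/profile_%s_binary.tsv", d))
  keep <- !is.na(b$score) & trim_near_zero(matrix(g$score), eps = 1e-4,
                                           max_fraction = 0.5)
  y <- b$score[keep]
  x <- as.matrix(feats)[keep, ]

  rho <- property_correlation(
    matrix(g$score[keep], dimnames = list(which(keep), d)),
    feats[keep, ])
  if (d == domains[1]) {
    write.table(data.frame(feature = colnames(rho),
                           category = cats[colnames(rho)],
                           rho = round(rho[1, ], 3)),
                "results/property_correlations.tsv", sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  cv <- cross_validate(x, y, k = 10, seed = seed)
  tree <- fit_tree(x, y)
  tf <- top_features(tree, n = 4)
  wh_dyn <- withhold_features(x, y, "dynamic", categories = cats,
                              k = 10, seed = seed)
  perf[[d]] <- data.frame(
    domain = d, n_trained = length(y),
    coverage = coverage_report(length(y), nrow(truth))$percent_string,
    cv_auc = round(cv$auc, 3),
    auc_without_dynamic = round(wh_dyn$withheld$auc, 3),
    top_feature = tf$feature[1],
    top_importance = round(tf$importance[1], 3))
  cat(sprintf("%s: trained on %s, CV AUC %.3f (%.3f without dynamic), top feature %s\n",
              d, perf[[d]]$coverage, cv$auc, wh_dyn$withheld$auc,
              tf$feature[1]))
}
write.table(do.call(rbind, perf), "results/model_performance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# feature ranking of the first domain's full-data tree
g1 <- read_profile(sprintf("results/profile_%s_mean.tsv", domains[1]))
b1 <- read_profile(sprintf("results/profile_%s_binary.tsv", domains[1]))
k1 <- !is.na(b1$score)
write.table(top_features(fit_tree(as.matrix(feats)[k1, ], b1$score[k1]),
                         n = 10),
            "results/top_features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
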