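#!/usr/bin/env Rscript
# Step 5 -- external validation in the held-out 30%.
#
# Predicts every validation imputation with the pooled learning-data
# coefficients (knots frozen on learning data) and reports the percent
# change in predictive accuracy from learning to validation data.

library(intersmoke)

learn_imp <- readRDS("results/learn_imp.rds")
valid_imp <- readRDS("results/valid_imp.rds")
sel <- readRDS("results/selection.rds")

keep_cur <- function(set) {
  set$completed <- lapply(set$completed, function(tab) {
    tab[tab$smoker_status == "current", , drop = FALSE]
  })
  set
}

val_m <- external_validate(sel$mtss3$final, keep_cur(learn_imp),
                           keep_cur(valid_imp), rule = "pdi")
val_q <- external_validate(sel$qa$final, learn_imp, valid_imp,
                           rule = "brier")

cat(sprintf("motivation: PDI %.4f (learning) -> %.4f (validation), change %.1f%%\n",
            val_m$score_learn, val_m$score_valid, val_m$change_pct))
cat(sprintf("quit attempt: Brier %.4f (learning) -> %.4f (validation), change %.1f%% on the accuracy scale\n",
            val_q$score_learn, val_q$score_valid, val_q$change_pct))

out <- data.frame(
  outcome = c("mtss3", "qa"),
  rule = c("pdi", "brier"),
  score_learning = c(val_m$score_learn, val_q$score_learn),
  score_validation = c(val_m$score_valid, val_q$score_valid),
  accuracy_change_pct = c(val_m$change_pct, val_q$change_pct)
)
write.csv(out, "results/external_validation.csv", row.names = FALSE)
cat("written: results/external_validation.csv\n")
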