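#!/usr/bin/env Rscript
# Step 2 -- split into learning/validation data and impute separately.
#
# 70/30 random split, then chained-equations multiple imputation run
# independently in each part (m = 10 for learning, m = 20 for
# validation) so that validation-data information never leaks into the
# learning-data imputations.

library(intersmoke)

cohort <- read_survey("results/survey.csv")
parts <- split_learning_validation(cohort, fraction = 0.7, seed = 101)
cat("learning n =", nrow(parts$learning),
    "; validation n =", nrow(parts$validation), "\n")

t0 <- Sys.time()
learn_imp <- chained_imputation(parts$learning, m = 10, iterations = 10,
                                seed = 102)
valid_imp <- chained_imputation(parts$validation, m = 20, iterations = 10,
                                seed = 103)
cat("imputation finished in",
    round(as.numeric(Sys.time() - t0, units = "mins"), 1), "min;",
    "variables imputed:", paste(learn_imp$variables_imputed, collapse = ", "),
    "\n")

saveRDS(parts, "results/split.rds")
saveRDS(learn_imp, "results/learn_imp.rds")
saveRDS(valid_imp, "results/valid_imp.rds")

manifest <- list(
  m_learn = learn_imp$m, m_valid = valid_imp$m,
  iterations = learn_imp$iterations,
  seed_learn = learn_imp$seed, seed_valid = valid_imp$seed,
  variables = learn_imp$variables_imputed
)
jsonlite::write_json(manifest, "results/imputation_manifest.json",
                     auto_unbox = TRUE, pretty = TRUE)
cat("written: results/learn_imp.rds, results/valid_imp.rds\n")
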