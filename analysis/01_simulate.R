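#!/usr/bin/env Rscript
# Step 1 -- simulate the synthetic survey cohort.
#
# Generates 13 245 past-year smokers (the survey's 2016-2020 sample
# size) from the default generator: covariate margins, outcome models
# (with the age x income and sex x education interactions) and
# selective missing-at-random missingness.  Writes the cohort and a
# margins summary under results/.

library(intersmoke)

dir.create("results", showWarnings = FALSE)
set.seed(20160601)

cfg <- generator_config(n_records = 13245, seed = 20160601)
cohort <- recode_outcomes(simulate_survey(cfg))
write_survey(cohort, "results/survey.csv")
saveRDS(cfg, "results/generator_config.rds")

margin <- function(x) round(100 * prop.table(table(x, useNA = "ifany")), 1)
cat("Cohort of", nrow(cohort), "past-year smokers\n")
cat(sprintf("  age mean (sd): %.1f (%.1f)\n", mean(cohort$age), sd(cohort$age)))
cat("  sex (%):\n"); print(margin(cohort$sex))
cat("  education (%):\n"); print(margin(cohort$education))
cat("  collapsed motivation, current smokers (%):\n")
print(margin(cohort$mtss3[cohort$smoker_status == "current"]))
cat(sprintf("  at least one past-year quit attempt: %.1f%% (missing %.1f%%)\n",
            100 * mean(cohort$qa == "yes", na.rm = TRUE),
            100 * mean(is.na(cohort$qa))))

margins <- data.frame(
  variable = c("age_mean", "age_sd", "pct_female", "pct_current",
               "pct_qa_yes_observed", "pct_mtss_missing"),
  value = c(mean(cohort$age), sd(cohort$age),
            100 * mean(cohort$sex == "female"),
            100 * mean(cohort$smoker_status == "current"),
            100 * mean(cohort$qa == "yes", na.rm = TRUE),
            100 * mean(is.na(cohort$mtss_level)))
)
write.csv(margins, "results/table1_margins.csv", row.names = FALSE)
cat("written: results/survey.csv, results/table1_margins.csv\n")
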