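#!/usr/bin/env Rscript
# Simulate the three-diet rearing experiment at its reference
# parameterisation (cohorts of 47, 55 and 53 eggs on O. ununguis, P. taxi
# and pine pollen) and write the individual-level record table.

library(phytodemog)

seed <- 20210721
dir.create("results", showWarnings = FALSE)

configs <- default_diet_configs(seed = seed)
records <- generate_experiment(configs, seed = seed)
write_records(records, "results/records.csv")

cat(sprintf("Simulated %d individuals across %d diets (seed %d):\n",
            nrow(records), length(configs), seed))
print(table(records$diet, records$died_in_stage))
cat("\nRecords written to results/records.csv\n")
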