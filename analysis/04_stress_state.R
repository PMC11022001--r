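#!/usr/bin/env Rscript
# Step 4 - stress-state quantification and reference-table checks: the
# systole-peak wall stress of the identified material under each stimulus,
# the provisional stress-to-pressure criterion ratio, and the
# self-consistency report over the embedded published tables.

source("analysis/00_config.R")
out <- results_dir("reporting")

id_path <- file.path("results", "identification", "identification.json")
stopifnot(file.exists(id_path))
id <- jsonlite::read_json(id_path, simplifyVector = TRUE)
stress <- read.csv(file.path("results", "identification", "stress_state.csv"))

cat(sprintf("stress state for identified material (a = %.1f kPa, b = %.2f):\n",
            id$a_hat, id$b_hat))
print(stress, row.names = FALSE)
write.csv(stress, file.path(out, "stress_state.csv"), row.names = FALSE)

chk <- reproduce_reference_values()
write.csv(chk, file.path(out, "reference_value_checks.csv"), row.names = FALSE)
cat(sprintf("\nreference-table consistency: %d/%d items reproduced\n",
            sum(chk$pass), nrow(chk)))
print(chk, row.names = FALSE)

tab <- assemble_study_table()
write.csv(tab, file.path(out, "study_table.csv"), row.names = FALSE)
cat("\nassembled per-subject study table written to",
    file.path(out, "study_table.csv"), "\n")
cat("criterion ratio <sigma1>/<P> is provisional: the combination of\n")
cat("stress components entering a rupture criterion is not settled.\n")
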