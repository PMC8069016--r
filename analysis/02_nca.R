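#!/usr/bin/env Rscript
# Step 2: non-compartmental analysis of the simulated study.
#
# Per-rat linear-trapezoidal AUC with log-linear tail, terminal slope by
# best-adjusted-r2 suffix selection, clearance, volumes, MRT, Cmax/Tmax;
# group mean +/- SD summaries; relative bioavailability of the oral extract
# groups against the 75 mg/kg pure-rutin reference.

suppressPackageStartupMessages(library(rutinpk))
study <- read_pk_dataset("results/study.csv")

res <- nca_study(study)
write.csv(res, "results/nca_subjects.csv", row.names = FALSE)
sm <- nca_group_summary(res)
write.csv(sm, "results/nca_groups.csv", row.names = FALSE)

gmean <- function(g, p) sm$mean[sm$group == g & sm$parameter == p]
cat("Group-mean AUC0-INF (ng*h/mL):\n")
for (g in sort(unique(res$group)))
  cat(sprintf("  group %2d: %10.1f\n", g, gmean(g, "AUC0_INF")))

# oral relative bioavailability vs the lowest-dose pure-rutin group (75)
doses <- c(`8` = 7.4, `9` = 11.1, `10` = 14.8)
frel <- data.frame(
  group = as.integer(names(doses)),
  dose_ruteq = unname(doses),
  Frel = vapply(names(doses), function(g)
    relative_bioavailability(gmean(as.integer(g), "AUC0_INF"), doses[[g]],
                             gmean(3, "AUC0_INF"), 75), numeric(1)))
write.csv(frel, "results/frel.csv", row.names = FALSE)
cat("Relative bioavailability of quercetin conjugates (vs rutin 75 mg/kg):\n")
print(frel, row.names = FALSE)
cat("Dose-normalised exposure is several-fold higher from the extract,\n")
cat("mirroring the matrix effect the models encode via the dose-group\n")
cat("covariates. Tables in results/nca_subjects.csv, results/nca_groups.csv\n")
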