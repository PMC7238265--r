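#!/usr/bin/env Rscript
# Regenerates inst/extdata/fixture_seed42.csv: a compact 53-subject synthetic
# dataset (reduced Day-1 PK subset, ADDL/II dose shorthand) used by the
# regression tests. Run from the repository root with the package installed.
library(pkpdco)

design <- trial_design(n_subjects = 53, pk_day_starts = 0,
                       pk_offsets = c(0.5), pk_offsets_h = c(1, 2),
                       trough_times = numeric(0),
                       fev1_weeks = c(-2, 0, 4, 12), ecp_weeks = c(0, 4, 12),
                       act_weeks = c(0, 4, 12))
d <- generate_trial(design, default_parameters(), default_population(),
                    seed = 42)
first <- d$EVID == 1 & d$TIME == 0
d$ADDL[first] <- 167
d$II[first] <- 12
d <- d[!(d$EVID == 1 & d$TIME > 0), ]
d$DV <- signif(d$DV, 5)
d$AGE <- round(d$AGE)
d$WT <- round(d$WT)
d$HT <- round(d$HT)
write_dataset(d, "inst/extdata/fixture_seed42.csv")
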