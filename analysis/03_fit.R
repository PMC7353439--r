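#!/usr/bin/env Rscript
# Stage 3: nonlinear fitting of the dissolution parameters.
#
# With porous-shell control established in stage 2, the particle samples are
# fitted for (De, N0) by MSE minimization; the membrane-complexed copper is
# fitted with the Nernst-Brunner first-order law for (k, C_sat). 95%
# confidence half-widths come from the linearized covariance at the optimum.

suppressPackageStartupMessages(library(shrinkcore))
spec <- particle_spec_cu()
truth <- jsonlite::read_json("results/data/truth.json")

read_s <- function(file, m0_g)
  read_dissolution_csv(file, volume_l = 1, initial_copper_g = m0_g)

analyses <- list(
  analyze_dissolution(
    read_s("results/data/cu_nps_suspension.csv",
           truth$cu_nps_suspension$N0 * particle_mass(spec) * 1e3),
    spec, C_s = truth$cu_nps_suspension$C_s,
    sample_name = "Cu-NPs suspension"),
  analyze_dissolution(
    read_s("results/data/cu_nps_membrane.csv",
           truth$cu_nps_membrane$N0 * particle_mass(spec) * 1e3),
    spec, C_s = truth$cu_nps_membrane$C_s,
    sample_name = "(PA+Cu-NPs)/PS membrane"),
  analyze_dissolution(
    read_s("results/data/cu_mpd_membrane.csv", truth$cu_mpd_membrane$nb_C_sat * 1),
    spec, model = "nernst_brunner",
    sample_name = "(PA+Cu-mPD)/PS membrane")
)

tab <- fit_table(analyses)
print(tab, digits = 4)
write.csv(tab, "results/fit_parameters.csv", row.names = FALSE)
write_report_json(analyses, "results/fit_report.json")

rel <- function(est, tru) sprintf("%+.1f%%", 100 * (est - tru) / tru)
cat(sprintf("\nDe recovery, suspension: fitted %.3g vs truth %.3g (%s)\n",
            tab$D_e[1], truth$cu_nps_suspension$constant,
            rel(tab$D_e[1], truth$cu_nps_suspension$constant)))
cat(sprintf("C_sat recovery, Cu-mPD: fitted %.3g mg/L vs truth %.3g (%s)\n",
            tab$C_sat_mg_l[3], kg_per_m3_to_mg_per_l(truth$cu_mpd_membrane$nb_C_sat),
            rel(tab$C_sat_mg_l[3],
                kg_per_m3_to_mg_per_l(truth$cu_mpd_membrane$nb_C_sat))))
cat("tables written to results/fit_parameters.csv and results/fit_report.json\n")
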