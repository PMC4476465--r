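#!/usr/bin/env Rscript
# Generate the synthetic study inputs: activity cohorts for each lighting
# condition (sizes matching the behavioral experiments: LD 35, DD 20, LL 30,
# dark/light pulse 11) and a diel expression time course (5000 genes, 12
# samples every 4 h over two days, 180 planted rhythmic genes in five phase
# groups). Everything downstream (02-04) reads from results/sim/.

suppressPackageStartupMessages(library(dielrhythm))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 20150617L

cohorts <- list(
  LD = activity_sim_spec(35, 72, "LD", seed = seed),
  DD = activity_sim_spec(20, 72, "DD", seed = seed + 1L),
  LL = activity_sim_spec(30, 72, "LL", seed = seed + 2L),
  dark_pulse = activity_sim_spec(11, 96, "dark_pulse",
                                 pulse_window = c(33, 1), pulse_shift_h = 2,
                                 seed = seed + 3L),
  light_pulse = activity_sim_spec(11, 96, "light_pulse",
                                  pulse_window = c(21, 1), seed = seed + 4L))

for (nm in names(cohorts)) {
  spec <- cohorts[[nm]]
  co <- simulate_activity_cohort(spec)
  write_activity_csv(co$traces, file.path(out, paste0("activity_", nm, ".csv")))
  write_light_schedule(spec$schedule, file.path(out, paste0("schedule_", nm, ".yaml")))
  message(sprintf("[%s] %d animals x %d h (rhythmic: %s)",
                  nm, spec$n_animals, spec$duration_h, co$truth$rhythmic))
}

espec <- expression_sim_spec(5000, frac_rhythmic = 180 / 5000,
                             phases_zt = c(1, 5, 9, 13, 17),
                             seed = seed + 5L)
expr <- simulate_expression_timecourse(espec)
write_counts_tsv(expr$counts, file.path(out, "counts.tsv"))
write.table(data.frame(gene_id = names(expr$truth$rhythmic_flag),
                       rhythmic = expr$truth$rhythmic_flag,
                       true_phase_zt = expr$truth$true_phase_zt),
            file.path(out, "expression_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("[expression] %d genes x %d samples, %d planted rhythmic",
                nrow(expr$counts), ncol(expr$counts),
                sum(expr$truth$rhythmic_flag)))
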