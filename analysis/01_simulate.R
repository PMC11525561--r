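#!/usr/bin/env Rscript
# Generates every synthetic input the downstream analyses consume, with
# ground truth recorded in JSON sidecars: five-replicate distance
# trajectories for six "compounds" spanning weak to strong activators,
# kinetic plates for a control and a strong activator, dose-response
# plates, and a 200-compound screening library.

suppressPackageStartupMessages(library(lcatpam))

seed <- 20240
out <- "results/sim"
dir.create(file.path(out, "trajectories"), recursive = TRUE, showWarnings = FALSE)

## Trajectories: one mean distance per compound; the generating line
## activity% = 200 * distance(nm) - 250 maps them onto 110-250% of control
compounds <- data.frame(
  compound_id = c("ctrl", "weak", "mid1", "mid2", "strong", "top"),
  mean_distance = c(1.80, 1.95, 2.10, 2.20, 2.35, 2.50))
compounds$true_activity <- 200 * compounds$mean_distance - 250

for (i in seq_len(nrow(compounds))) {
  trs <- gen_trajectory(mean_distance = compounds$mean_distance[i],
                        stationary_sd = 0.05, correlation_time = 5,
                        n_frames = 200, dt = 1, n_replicates = 5,
                        seed = seed + i)
  for (r in seq_along(trs))
    write_multimodel_pdb(trs[[r]], file.path(
      out, "trajectories",
      sprintf("%s_rep%d.pdb", compounds$compound_id[i], r)))
}
write.csv(compounds, file.path(out, "compounds_truth.csv"), row.names = FALSE)

## Kinetic plates: control enzyme vs an activator that raises Vmax ~70%
plates <- rbind(
  gen_mm_assay(vmax = 8.66, km = 11.59, noise_sd_fraction = 0.02,
               condition_label = "LCAT", seed = seed + 101)$plate,
  gen_mm_assay(vmax = 14.78, km = 8.37, noise_sd_fraction = 0.02,
               condition_label = "LCAT+activator", seed = seed + 102)$plate)
std <- gen_mm_assay(seed = seed + 101)$standard_curve
write.csv(plates, file.path(out, "mm_plate.csv"), row.names = FALSE)
write.csv(std, file.path(out, "standard_curve.csv"), row.names = FALSE)

## Dose-response plate: activator with EC50 0.1 uM reaching 250% of control
dr <- gen_dose_response(ec50 = 0.1, top = 250, bottom = 100, hill = 1,
                        noise_sd = 8, n_replicates = 3, seed = seed + 201)
write.csv(dr$responses, file.path(out, "dose_response.csv"), row.names = FALSE)

## Screening library
gl <- gen_compound_library(200, seed = seed + 301)
write.csv(gl$library, file.path(out, "compound_library.csv"), row.names = FALSE)

jsonlite::write_json(
  list(seed = seed,
       trajectory = list(stationary_sd = 0.05, correlation_time = 5,
                         n_frames = 200, dt = 1, n_replicates = 5),
       activity_line = list(slope = 200, intercept = -250),
       mm = list(LCAT = c(vmax = 8.66, km = 11.59),
                 `LCAT+activator` = c(vmax = 14.78, km = 8.37)),
       dose_response = dr$truth,
       library_expected_counts = as.list(gl$expected_counts)),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cat("simulated", nrow(compounds), "compounds x 5 trajectory replicates,",
    "2 kinetic plate conditions, 1 dose-response plate,",
    "and a 200-compound library under", out, "\n")
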