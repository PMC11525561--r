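#!/usr/bin/env Rscript
# Activity calibration and prediction: fits the linear distance->activity
# model on reference compounds (distances measured by 02_distance.R, true
# activities from the generating line) and predicts the remaining
# compounds' activities with 95% prediction intervals, ranking them
# against the no-PAM control level (100%).

suppressPackageStartupMessages(library(lcatpam))

dist_tab <- read.csv("results/distance_summaries.csv")
truth <- read.csv("results/sim/compounds_truth.csv")

# first four compounds serve as the calibration panel, the rest are
# treated as unknowns predicted from their trajectories alone
calib_ids <- truth$compound_id[1:4]
cand_ids <- setdiff(truth$compound_id, calib_ids)

calibration <- data.frame(
  compound_id = calib_ids,
  distance = dist_tab$mean[match(calib_ids, dist_tab$label)],
  activity_pct = truth$true_activity[match(calib_ids, truth$compound_id)])
candidates <- data.frame(
  compound_id = cand_ids,
  distance = dist_tab$mean[match(cand_ids, dist_tab$label)])

out <- run_calibrate_predict(calibration, candidates,
                             reference_activity_pct = 100)
print(out$model)
calibration_to_json(out$model, "results/calibration_model.json")
write.csv(out$ranking, "results/predicted_ranking.csv", row.names = FALSE)

cat("predicted candidate activities (percent of no-PAM control):\n")
print(out$ranking[, c("compound_id", "predicted_activity_pct",
                      "interval_low", "interval_high", "activator")],
      row.names = FALSE)
true_act <- truth$true_activity[match(out$ranking$compound_id,
                                      truth$compound_id)]
cat(sprintf("max |predicted - generating| activity: %.2f%%\n",
            max(abs(out$ranking$predicted_activity_pct - true_act))))
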