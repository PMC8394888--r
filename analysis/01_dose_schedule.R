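#!/usr/bin/env Rscript
# Chronic-irradiation dosimetry: builds the stepwise MED escalation calendar
# (1 -> 2 -> 4 -> 6 MED/week, Mon/Wed/Fri sessions), reports weekly and
# cumulative doses and session exposure times at the measured source
# irradiance of 4.5 mW/cm2.

library(uvskin)
dir.create("results", showWarnings = FALSE)

sched <- build_schedule(med_mj_cm2 = 300, total_weeks = 12,
                        last_irradiation_week = 11)
print(sched)

wd <- weekly_dose(sched)
wd$cumulative_med <- cumsum(wd$dose_med)
wd$session_exposure_s <- ifelse(
  wd$dose_med > 0, round(exposure_time(wd$dose_mj_cm2 / 3, 4.5), 1), 0)
print(wd)

tot <- cumulative_dose(sched)
cat(sprintf("\nTotal over the experiment: %g MED = %g mJ/cm2\n",
            tot$dose_med, tot$dose_mj_cm2))
cat(sprintf("Irradiating through week 12 instead would give %g MED.\n",
            cumulative_dose(build_schedule(last_irradiation_week = 12))$dose_med))

# acute-erythema arm: single narrow-band UVB exposures at 15 mW/cm2
acute <- data.frame(dose_mj_cm2 = c(9450, 13500, 18450))
acute$exposure_s <- exposure_time(acute$dose_mj_cm2, 15)
cat("\nAcute UVB exposure times (150 W/m2 source):\n")
print(acute)

write_schedule_csv(sched, "results/dose_schedule.csv")
write_report(list(total_med = tot$dose_med, total_mj_cm2 = tot$dose_mj_cm2,
                  weekly_med = wd$dose_med,
                  acute_exposure_s = acute$exposure_s),
             "results/dose_summary.json")
cat("\nwrote results/dose_schedule.csv, results/dose_summary.json\n")
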