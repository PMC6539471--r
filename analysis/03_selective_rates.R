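#!/usr/bin/env Rscript
# Selective-excitation rate analysis (designs 2 and 3): precursor T1 from
# arrested-perfusion decays, decay correction, constant-concentration window,
# and per-excitation production rates normalized to tissue ATP.
#
# Design 2 (arrest + selective readout): the precursor decay under the small
# effective angle yields T1 directly; each 90-degree lactate excitation reads
# only the product accumulated over one TR.
# Design 3 (continuous flow): the arrest-derived T1 corrects the precursor,
# the 10%-of-first-maximum rule picks the constant-concentration window, and
# rates come from the windowed signal ratios.

library(hpldh)

dir.create("results", showWarnings = FALSE)
set.seed(20240902)

truth <- kinetic_params(k_1st = 1.5e-4, T1_precursor = 53.4,
                        T1_product = 25, M0 = 1)
atp <- 11.4      # nmole tissue ATP in the probe-visible volume
theta_p <- 5     # deg, precursor effective angle under the selective pulse
rho <- sin(theta_p * pi / 180)  # precursor/product response in this scheme

## ---- design 2: arrested perfusion, selective readout -------------------
sc2 <- acquisition_scheme(TR = 12, nutation_precursor = theta_p,
                         nutation_product = 90, n_samples = 12)
g2 <- generate_arrest_selective(truth, sc2, quench = 4, quench_TR = 2,
                                pre_delay = 5)
write_series(g2$series, "results/design2_series.csv")

analysis <- which(!g2$quench_mask)
t1fit <- fit_t1_eq1(g2$series$times[analysis],
                    g2$series$precursor[analysis], sc2)
cat("Design 2 precursor T1 from the pulsed decay:\n")
print(t1fit)

rep2 <- run_pipeline(list(design = "arrest_selective", series = g2$series,
                          TR = 12, theta_p = theta_p, rho = rho,
                          atp_nmole = atp,
                          quench_mask = which(g2$quench_mask)))
cat("\nDesign 2 report:\n")
print(rep2)

## ---- design 3: continuous flow ------------------------------------------
sc3 <- acquisition_scheme(TR = 12, nutation_precursor = theta_p,
                         nutation_product = 90, n_samples = 30)
g3 <- generate_continuous_flow(truth, sc3)
write_series(g3$series, "results/design3_series.csv")

rep3 <- run_pipeline(list(design = "continuous_flow", series = g3$series,
                          TR = 12, theta_p = theta_p, rho = rho,
                          atp_nmole = atp,
                          T1_precursor = t1fit$T1))
cat("\nDesign 3 report (T1 carried over from the arrested measurement):\n")
print(rep3)

rates <- data.frame(
  design = c("arrest_selective", "continuous_flow"),
  T1_precursor_s = c(rep2$T1_precursor_s, rep3$T1_precursor_s),
  n_window = c(length(rep2$window_indices), length(rep3$window_indices)),
  mean_rate_nmole_min_nmoleATP = c(rep2$mean_rate_nmole_min_nmoleATP,
                                   rep3$mean_rate_nmole_min_nmoleATP),
  sd_rate = c(rep2$sd_rate_nmole_min_nmoleATP,
              rep3$sd_rate_nmole_min_nmoleATP))
write.csv(rates, "results/selective_rates.csv", row.names = FALSE)

cat(sprintf("\nGenerator comparison: instantaneous k-rate = %.2f, measured %.2f (arrest) / %.2f (flow) nmole/min/nmole ATP\n",
            truth$k_1st * 7000 * 60 / atp,
            rep2$mean_rate_nmole_min_nmoleATP,
            rep3$mean_rate_nmole_min_nmoleATP))
cat("(the per-excitation readout sits slightly below the instantaneous rate\n")
cat(" because the product relaxes during each repetition interval)\n")
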