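#!/usr/bin/env Rscript
# Excitation profiles of the acquisition pulses and the selective response
# ratio rho.
#
# The selective lactate readout uses a 2.5 ms sinc pulse calibrated to 90
# degrees, centered on lactate, with pyruvate (or its hydrate) sitting 214 Hz
# off-resonance. This script simulates the Bloch response of that pulse and
# of the 12-degree non-selective pulse across offsets, writes the profiles,
# and reports rho = precursor response / product response.
#
# Finding: at these parameters the sinc excitation band (~ +-1600 Hz for 3
# side-lobe pairs) dwarfs the 214 Hz separation, so the simulated pulse is
# nearly non-selective at the pyruvate offset and rho is close to 1. A
# measured rho can therefore be supplied to the rate analysis instead of the
# simulated one; both are tabulated here for several side-lobe counts.

library(hpldh)

dir.create("results", showWarnings = FALSE)

offsets <- seq(-2500, 2500, by = 25)

sel <- pulse_shape("sinc", 2.5e-3, calibrated_angle = 90, lobes = 3)
prof_sel <- simulate_pulse(sel, offsets)
write_pulse_profile(prof_sel, "results/pulse_profile_sinc90.tsv")

hard <- pulse_shape("hard", 0.5e-3, calibrated_angle = 12)
prof_hard <- simulate_pulse(hard, offsets)
write_pulse_profile(prof_hard, "results/pulse_profile_hard12.tsv")

rho_tab <- do.call(rbind, lapply(c(1L, 3L, 5L), function(lb) {
  sh <- pulse_shape("sinc", 2.5e-3, 90, lobes = lb)
  r <- simulate_pulse(sh, c(0, 214))$transverse_response
  data.frame(lobes = lb,
             response_product_0Hz = r[1],
             response_precursor_214Hz = r[2],
             rho = response_ratio(0, 214, sh))
}))
write.csv(rho_tab, "results/rho_table.csv", row.names = FALSE)

cat("Selective pulse response at 0 / 214 Hz and rho:\n")
print(rho_tab, row.names = FALSE)
cat(sprintf(
  "\nNon-selective hard pulse: response varies by %.3g%% over +-214 Hz.\n",
  100 * diff(range(simulate_pulse(hard,
    seq(-214, 214, by = 10))$transverse_response)) /
    max(prof_hard$transverse_response)))
cat("The simulated 2.5 ms sinc is close to non-selective at 214 Hz;\n")
cat("rate analyses accept a measured rho where one is available.\n")
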