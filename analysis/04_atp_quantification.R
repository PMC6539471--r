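#!/usr/bin/env Rscript
# 31P gamma-ATP quantification against an external standard, and its role in
# normalizing production rates.
#
# A synthetic sample/standard integral pair is generated at a known tissue
# ATP amount under the tissue acquisition scheme (50 deg, TR 1.1 s) and a
# fully relaxed standard acquisition, quantified back with saturation and
# scan-count corrections, and a noise study (5% integral noise, 100 seeds)
# bounds the recovery bias.

library(hpldh)

dir.create("results", showWarnings = FALSE)
set.seed(20240903)

true_atp <- 11.4                                   # nmole, study average
sample_meta <- list(flip_angle = 50, TR = 1.1, n_scans = 256, T1 = 1.0)
standard_meta <- list(flip_angle = 90, TR = 8, n_scans = 16, T1 = 4.0)
standard_amount <- atp_standard_amount(volume_mL = 0.5)   # 111 mM standard

pair <- generate_p31_pair(true_atp, sample_meta, standard_meta,
                          standard_amount)
q <- quantify_atp(pair$sample, pair$standard, pair$standard_amount)
cat("Noiseless round trip:\n")
print(q)

est <- vapply(1:100, function(seed) {
  p <- generate_p31_pair(true_atp, sample_meta, standard_meta,
                         standard_amount,
                         noise = noise_model(0.05, seed = seed))
  quantify_atp(p$sample, p$standard, p$standard_amount)$atp_amount
}, numeric(1))

cat(sprintf("\n5%% integral noise, 100 seeds: mean %.3f nmole (bias %+.2f%%), sd %.3f\n",
            mean(est), 100 * (mean(est) - true_atp) / true_atp, sd(est)))

sat <- data.frame(flip_angle_deg = 50, TR_s = 1.1, T1_s = 1.0,
                  saturation_factor = saturation_factor(50, 1.1, 1.0))
out <- data.frame(
  quantity = c("true_atp_nmole", "recovered_noiseless_nmole",
               "mc_mean_nmole", "mc_sd_nmole", "mc_bias_percent"),
  value = c(true_atp, q$atp_amount, mean(est), sd(est),
            100 * (mean(est) - true_atp) / true_atp))
write.csv(out, "results/atp_quantification.csv", row.names = FALSE)
write.csv(sat, "results/saturation_factor.csv", row.names = FALSE)

cat(sprintf("\nSaturation factor of the tissue acquisition (50 deg, TR 1.1 s, T1 1 s): %.4f\n",
            sat$saturation_factor))
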