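#!/usr/bin/env Rscript
# Step 1: generate the synthetic study material - speckle phantoms with a
# single hypoechoic nerve cross-section per frame, paired ground-truth masks
# and simulated-rater tracings, for both acquisition sites. Writes a small
# gallery of triplets plus a CSA summary table under results/phantoms/.

library(usnerveseg)

out <- "results/phantoms"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

summarise_site <- function(site, n = 60, seed) {
  spec <- phantom_spec(site)
  pairs <- simulate_phantom_dataset(n, spec, rater_model(), seed = seed)
  for (p in pairs[1:5]) write_phantom(p, file.path(out, site))
  areas <- vapply(pairs, function(p) p$meta$true_area, numeric(1))
  manual <- vapply(pairs, function(p)
    sum(p$manual_mask) * spec$pixel_spacing^2, numeric(1))
  data.frame(site = site, n = n,
             csa_mean = mean(areas), csa_sd = sd(areas),
             manual_mean = mean(manual), manual_sd = sd(manual))
}

tab <- rbind(summarise_site("wrist", seed = 1), summarise_site("forearm", seed = 2))
write.csv(tab, file.path(out, "csa_summary.csv"), row.names = FALSE)
print(tab, digits = 3)
message("Wrist phantoms are larger and shallower than forearm phantoms; ",
        "simulated-rater CSAs track the polygon ground truth.")
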