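#!/usr/bin/env Rscript
# Step 2: apply the 11-variant intensity-augmentation protocol (3 CLAHE
# settings, 4 gamma values, 3 speckle levels, plus the retained original) to
# a second dataset of 35 wrist and 26 forearm stills, mirroring the
# published dataset expansion: 35 -> 385 and 26 -> 286 image-mask pairs.

library(usnerveseg)

out <- "results/augmentation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cv <- canvas_spec()

expand_site <- function(site, n, seed) {
  stills <- preprocess_pairs(
    simulate_phantom_dataset(n, phantom_spec(site), seed = seed,
                             id_prefix = paste0(site, "2")), cv)
  aug <- expand_dataset(stills, augmentation_spec(), seed = seed + 1)
  manifest <- augmentation_manifest(aug)
  write.csv(manifest, file.path(out, paste0(site, "_manifest.csv")),
            row.names = FALSE)
  message(sprintf("%s: %d stills -> %d augmented pairs", site, n, length(aug)))
  aug
}

aug_w <- expand_site("wrist", 35, seed = 11)
aug_f <- expand_site("forearm", 26, seed = 21)
stopifnot(length(aug_w) == 385, length(aug_f) == 286)
message("Masks are copied bit-exactly; only image intensities differ ",
        "across the 11 variants of each still.")
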