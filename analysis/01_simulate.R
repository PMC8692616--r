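#!/usr/bin/env Rscript
# Stage 1 — simulate the multimodal measurement campaign.
#
# Draws the default 63-pool panel (9 cat / 12 cow / 21 human / 21 pig),
# renders every measurement replicate (2x wide-line 1H, 2x 1H MAS, 2x 13C
# CP-MAS, 5x TD-NMR, 3x FT-IR, 1x DTG per pool) and the 10-fibre tensile
# replicate table, and writes everything in plain text under results/data/.

library(mdselect)

seed <- 1L
out <- "results/data"
ds <- simulate_dataset(seed = seed)
man <- write_dataset(ds, out, overwrite = TRUE)

cat(sprintf("simulated %d pools, %d spectra (%d rows), %d tensile rows\n",
            man$n_samples, man$n_spectra, man$spectra_rows, man$property_rows))
cat(sprintf("species counts: %s\n",
            paste(names(table(ds$latents$species)), table(ds$latents$species),
                  sep = "=", collapse = " ")))
cat(sprintf("planted informative descriptors: %s\n",
            paste(ds$truth$informative_descriptor_ids, collapse = ", ")))
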