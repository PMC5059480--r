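#!/usr/bin/env Rscript
# Step 3: simulate excited-state absorption bands from the fixture stick
# spectra (Gaussian broadening, 0.7 eV FWHM in the energy domain) and
# decompose transient spectra into non-negative combinations of the four
# state bands - the early (UV-band maximum) and late (visible-band maximum)
# spectra of the fitted synthetic data.

library(thiodyn)

out_dir <- "results/03_esa"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

grid <- seq(320, 710, by = 1)
sticks <- fixture_sticks()
bands <- lapply(sticks, broaden, fwhm_ev = 0.7, grid = grid)
band_tab <- data.frame(wavelength_nm = grid,
                       vapply(bands, `[[`, numeric(length(grid)), "intensity"))
names(band_tab)[-1] <- names(bands)
utils::write.table(band_tab, file.path(out_dir, "bands.tsv"), sep = "\t",
                   row.names = FALSE, quote = FALSE)
for (nm in names(bands)) {
  message(sprintf("%-9s band maximum at %.0f nm", nm,
                  grid[which.max(bands[[nm]]$intensity)]))
}

# transient spectra of the synthetic experiment at the two anchor delays
g <- generate_tas(tas_gen_config(seed = 1, noise_sd = 0, chirp = c(0, 0, 0)))
for (delay in c(320, 3760)) {
  j <- which.min(abs(g$map$delays - delay))
  target <- g$map$amplitudes[, j]
  keep <- !g$map$mask[, j]
  comps <- lapply(bands, function(b) {
    list(wavelengths = g$map$wavelengths[keep],
         intensity = stats::approx(b$wavelengths, b$intensity,
                                   g$map$wavelengths[keep])$y,
         state_label = b$state_label)
  })
  fit <- fit_combination(comps, target[keep])
  message(sprintf("delay %4.0f fs: %s (rms %.3f mOD)", delay,
                  paste(sprintf("%s %.0f%%", names(fit$percent), fit$percent),
                        collapse = ", "), fit$residual_rms))
  yaml::write_yaml(list(delay_fs = delay,
                        percent = as.list(round(fit$percent, 1)),
                        residual_rms = fit$residual_rms),
                   file.path(out_dir, sprintf("combination_%dfs.yaml", delay)))
}
write_run_manifest(out_dir, "spectra", list(fwhm_ev = 0.7), seed = 1)
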