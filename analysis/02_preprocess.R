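#!/usr/bin/env Rscript
# Condition the raw spectra: crop to the 200-1700 cm^-1 fingerprint region,
# remove the quintic background, Savitzky-Golay smooth (window 5, degree 2)
# and standardize each spectrum to mean 0 / sd 1.

suppressMessages(library(apsers))

set <- read_spectra("results/data/raw")
pp <- preprocess_set(set)
write_spectra(pp, "results/data/preprocessed")
cat(sprintf("preprocessed %d spectra; per-spectrum |mean| <= %.1e, |sd - 1| <= %.1e\n",
            n_spectra(pp),
            max(abs(colMeans(pp$intensities))),
            max(abs(apply(pp$intensities, 2, sd) - 1))))
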