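# shared fixtures, all generated in code

# canonical design at reduced repetition counts (keeps tests fast while
# preserving the 7-band x 4-contrast grid the fits need)
small_design <- function(reps = c(3, 3, 5, 5)) {
  experimentDesign(reps = reps)
}

# a CbmExperiment built from explicit components
make_se <- function(betas, trials, ecc = NULL, r2 = NULL) {
  V <- nrow(betas)
  vox <- data.frame(voxel = seq_len(V),
                    eccentricity = if (is.null(ecc)) rep(3, V) else ecc,
                    r2 = if (is.null(r2)) rep(0.2, V) else r2)
  CbmExperiment(betas, trials, vox)
}

# a minimal trial table row set
trial_rows <- function(kind, category = NA_integer_, freq = NA_real_,
                       sigma = 0, n = 1L) {
  data.frame(trial = seq_len(n), kind = kind, category = category,
             freq = freq, sigma = sigma)
}

# V1-like generating parameters at a small voxel count
small_truth <- function(V = 60, seed = 1, ...) {
  groundTruth(V = V, nCategories = 10L, seed = seed, ...)
}

# geometric mean
gmean <- function(x) exp(mean(log(x)))
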