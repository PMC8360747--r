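# shared fixtures: small deterministic records and specs

FS <- 125

quiet_spec <- function(name) suppressWarnings(wavelet_spec(name))

clean_profile <- function(sbp = 110, dbp = 72, hr = 60, seed = 3L) {
  subject_profile(sbp, dbp, heart_rate = hr, wander_amplitude = 0,
                  noise_sd = 0, seed = seed)
}

clean_record <- function(sbp = 110, dbp = 72, hr = 70, duration_s = 10,
                         seed = 5L) {
  generate_record(clean_profile(sbp, dbp, hr, seed), duration_s, FS)
}

# a small balanced noiseless cohort shared by the CNN tests
balanced_records <- function(n_records = 4, duration_s = 10, seed = 100L) {
  generate_dataset(n_records, c(1, 0, 1, 0) / 2, base_seed = seed,
                   duration_s = duration_s, wander_amplitude = 0,
                   noise_sd = 0)
}

all_wavelet_names <- c("fbsp", "shan", "cgau1", "morl", "mexh", "gaus1")
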