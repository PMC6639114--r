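#!/usr/bin/env Rscript
# Build the two fricative continua (100 ms and 300 ms cue durations), write
# the stimulus WAVs and an example session schedule, and verify that the
# synthesized endpoint spectra carry their peaks where the design puts them.

library(phonocat)
dir.create("results/stimuli", recursive = TRUE, showWarnings = FALSE)

for (cond in c(short = 0.100, long = 0.300)) {
  spec <- continuum_spec(fricative_duration = cond)
  name <- names(which(c(short = 0.100, long = 0.300) == cond))
  for (s in seq_len(spec$n_steps)) {
    w <- synthesize_stimulus(s, spec, seed = 1000 + s)
    write_wav(w, sprintf("results/stimuli/%s_%d.wav", name, s))
  }
  write.csv(design_continuum(spec),
            sprintf("results/stimuli/continuum_%s.csv", name),
            row.names = FALSE)
}

spec_long <- continuum_spec(fricative_duration = 0.300)
sched <- make_session_schedule(spec_long, "short", reps_per_step = 5,
                               n_blocks = 6, seed = 7)
write.csv(sched, "results/stimuli/schedule_example.csv", row.names = FALSE)

# spectral verification of the endpoints
pk1 <- estimate_spectral_peaks(synthesize_fricative(1, spec_long, seed = 11))
pk7 <- estimate_spectral_peaks(synthesize_fricative(7, spec_long, seed = 11))
cat("endpoint 1 ('sh'-like) spectral peaks (Hz):",
    paste(round(pk1$freq_hz), collapse = ", "), "\n")
cat("endpoint 7 ('s'-like) spectral peaks (Hz):",
    paste(round(pk7$freq_hz), collapse = ", "), "\n")
cat(sprintf("highest peak of endpoint 7: %.0f Hz (designed 6500)\n",
            max(pk7$freq_hz)))
cat("wrote", 2 * spec_long$n_steps, "stimuli and the example schedule under results/stimuli/\n")
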