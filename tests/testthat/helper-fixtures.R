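# Shared fixtures, generated in code. Small and seeded; nothing on disk.

fixture_canonical_windows <- function(n, seed, length = 70L) {
  sim <- simulate_transcriptome(n = n, length_dist = length,
                                subtype_mix = c(CANONICAL = 1), seed = seed)
  list(sequences = vapply(sim$transcripts, `[[`, "", "sequence"),
       sim = sim)
}

fixture_motif_free <- function(n, seed, length = 70L) {
  sim <- simulate_transcriptome(n = n, length_dist = length,
                                plant_prob = 0, seed = seed)
  vapply(sim$transcripts, `[[`, "", "sequence")
}

fixture_binary_data <- function(n_per_class, seed) {
  pos <- fixture_canonical_windows(n_per_class, seed)$sequences
  neg <- fixture_motif_free(n_per_class, seed + 1L)
  data.frame(sequence = c(pos, neg),
             label = rep(c("rG4", "non-rG4"), each = n_per_class),
             row.names = NULL)
}

# near-deterministic 8-position PWM (long enough that an exact match clears
# the 1e-4 exact-null policy)
fixture_pwm8 <- function(id = "SITE8", hot = c(1, 2, 3, 4, 1, 3, 2, 4),
                         p_hot = 0.97) {
  m <- matrix((1 - p_hot) / 3, 4, length(hot))
  m[cbind(hot, seq_along(hot))] <- p_hot
  pwm(id, sweep(m, 2, colSums(m), "/"))
}

tmp_path <- function(ext) tempfile(fileext = ext)
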