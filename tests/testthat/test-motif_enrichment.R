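test_that("PWM validation and MEME round-trip", {
  m <- matrix(0.25, 4, 6)
  p <- pwm("M1", m)
  expect_equal(p$length, 6L)
  expect_error(pwm("bad", matrix(c(0.5, 0.5, 0.5, 0.5), 4, 1) * 2),
               "sum to 1")
  f <- tmp_path(".meme")
  write_meme_pwms(list(M1 = p, S8 = fixture_pwm8("S8")), f)
  back <- read_meme_pwms(f)
  expect_named(back, c("M1", "S8"))
  expect_equal(back$S8$matrix, fixture_pwm8("S8")$matrix,
               tolerance = 1e-5)
})

test_that("uniform PWM yields zero log-odds and no hits", {
  p <- pwm("U", matrix(0.25, 4, 4))
  sc <- pwm_scan(c("ACGUACGU", "GGGGGGGG"), p)
  expect_equal(sum(sc$has_hit), 0L)
  lo <- g4scan:::pwm_log_odds(p)
  expect_true(all(abs(lo) < 1e-10))
})

test_that("near-deterministic PWM hits exactly at string-match offsets", {
  # GAGC, scanned with a relaxed policy since a 4-mer cannot reach 1e-4
  m <- matrix(0.001, 4, 4); m[cbind(c(3, 1, 3, 2), 1:4)] <- 0.997
  p <- pwm("DET", sweep(m, 2, colSums(m), "/"))
  fl <- c("AAGAGCAA", "UUUUUUUU", "GAGCGAGC")
  sc <- pwm_scan(fl, p, p_value = 5e-3)
  oracle <- lapply(fl, function(s) {
    g <- gregexpr("GAGC", s)[[1L]]
    if (g[1L] == -1L) integer(0) else as.integer(g)
  })
  expect_equal(sc$has_hit, lengths(oracle) > 0)
  expect_equal(split(sc$hits$offset, sc$hits$seq_index)[["1"]], oracle[[1]])
  expect_equal(split(sc$hits$offset, sc$hits$seq_index)[["3"]], oracle[[3]])
  # flank shorter than the motif: no hit, no error
  expect_false(pwm_scan("AG", p, p_value = 5e-3)$has_hit)
})

test_that("the exact null distribution sums to one and matches simulation", {
  p <- fixture_pwm8()
  nd <- pwm_null_distribution(p)
  expect_equal(sum(nd$prob), 1, tolerance = 1e-9)
  thr <- pwm_score_threshold(p, 1e-4)
  expect_true(is.finite(thr))
  # Monte-Carlo cross-check of the tail mass
  set.seed(31)
  lo <- g4scan:::pwm_log_odds(p)
  sims <- replicate(20000, sum(lo[cbind(sample(4, 8, TRUE), 1:8)]))
  emp <- mean(sims >= thr)
  expect_lt(emp, 5e-4)
})

test_that("flank splitting excludes the motif and the score gap", {
  seqs <- fixture_canonical_windows(6, seed = 71)$sequences
  scores <- c(0.9, 0.1, 0.5, 0.95, 0.05, 0.65)
  sp <- split_forming_flanks(seqs, scores = scores)
  expect_length(sp$forming, 2L)
  expect_length(sp$nonforming, 2L)
  expect_equal(sp$excluded, 2L)
  # flanks no longer contain the full motif
  m1 <- find_motifs(seqs[1])
  expect_equal(unname(nchar(sp$forming[1])),
               unname(nchar(seqs[1])) - (m1$end[1] - m1$start[1] + 1L))
  expect_warning(split_forming_flanks("AUAUAUAUAU", scores = 0.9),
                 "skipped")
})

test_that("enrichment arithmetic matches direct evaluation of the statistic", {
  eps <- 1e-6
  # fractions 0.5 vs 0.25 -> ~1; equal -> 0; 0.5 vs 0 -> ~18.93
  expect_equal(log2((0.5 + eps) / (0.25 + eps)), 1, tolerance = 1e-4)
  expect_equal(log2((0.3 + eps) / (0.3 + eps)), 0)
  expect_equal(log2((0.5 + eps) / eps), 18.93, tolerance = 1e-3)
})

test_that("Fisher p equals the brute-force hypergeometric tail", {
  tail_p <- function(hf, nf, hn, nn) {
    # P(X >= hf) with X hypergeometric over the fixed margins
    K <- hf + hn; N <- nf + nn
    xs <- max(0, K - nn):min(K, nf)
    num <- vapply(xs, function(x) choose(nf, x) * choose(nn, K - x), 0)
    sum(num[xs >= hf]) / sum(num)
  }
  expect_equal(tail_p(2, 2, 0, 2), 1 / 6)
  set.seed(7)
  for (i in 1:40) {
    nf <- sample(2:10, 1); nn <- sample(2:10, 1)
    hf <- sample(0:nf, 1); hn <- sample(0:nn, 1)
    fp <- fisher.test(matrix(c(hf, nf - hf, hn, nn - hn), 2),
                      alternative = "greater")$p.value
    expect_equal(fp, tail_p(hf, nf, hn, nn), tolerance = 1e-12)
  }
})

test_that("enrich reports planted motifs and respects the filters", {
  p8 <- fixture_pwm8()
  f1 <- simulate_flanks(200, 40, seed = 41)
  f2 <- simulate_flanks(200, 40, seed = 42)
  pf <- plant_pwm_sites(f1, p8, 0.4, seed = 43)
  pn <- plant_pwm_sites(f2, p8, 0.05, seed = 44)
  decoy <- fixture_pwm8("DECOY", hot = c(4, 3, 2, 1, 4, 2, 3, 1))
  out <- enrich(pf$sequences, pn$sequences, list(SITE8 = p8,
                                                 DECOY = decoy))
  site <- out[out$motif == "SITE8", ]
  expect_true(site$reported)
  expect_gt(site$log2_fc, 1)
  expect_lt(site$q, 0.05)
  expect_false(out$reported[out$motif == "DECOY"])
  # antisymmetry of the fold change when the groups swap
  swapped <- enrich(pn$sequences, pf$sequences, list(SITE8 = p8))
  expect_equal(swapped$log2_fc, -site$log2_fc, tolerance = 1e-4)
  expect_error(enrich(character(0), pn$sequences, list(SITE8 = p8)),
               "non-empty")
})
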