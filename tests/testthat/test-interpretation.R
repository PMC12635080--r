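linear_surrogate <- function(Tn = 10, H = 4, seed = 3) {
  set.seed(seed)
  W <- matrix(rnorm(Tn * H), Tn, H)
  Xin <- matrix(rnorm(Tn * H), Tn, H)
  X0 <- matrix(rnorm(Tn * H), Tn, H)
  list(model = list(embed = function(s)
    if (identical(s, "input")) Xin else X0,
    f = function(X) sum(X * W), grad = function(X) W),
    W = W, Xin = Xin, X0 = X0)
}

test_that("IG equals the closed form for a linear model at any step count", {
  for (steps in c(1L, 5L, 200L)) {
    ls <- linear_surrogate()
    pr <- integrated_attributions(ls$model, "input", "base", steps = steps)
    expect_equal(pr$token_attr, rowSums((ls$Xin - ls$X0) * ls$W),
                 tolerance = 1e-8)
    expect_equal(pr$completeness$attr_sum, pr$completeness$f_diff,
                 tolerance = 1e-8)
  }
  expect_error(integrated_attributions(linear_surrogate()$model, "input",
                                       "base", steps = 0L), "steps")
})

test_that("IG of an input against itself is zero", {
  ls <- linear_surrogate()
  ls$model$embed <- function(s) ls$Xin
  pr <- integrated_attributions(ls$model, "input", "input", steps = 10)
  expect_equal(pr$token_attr, rep(0, 10))
})

test_that("baseline selection returns the median-nearest references", {
  # 1-D surrogate: representations {0, 1, 2, 10}, median 1.5
  reps <- matrix(c(0, 1, 2, 10), 4, 1)
  out <- select_reference_baselines(NULL, c("s1", "s2", "s3", "s4"), n = 3,
                                    representations = reps)
  expect_setequal(out, c("s2", "s3", "s1"))
  # identical representations: first n by position
  reps2 <- matrix(1, 4, 1)
  out2 <- select_reference_baselines(NULL, c("a", "b", "c", "d"), n = 2,
                                     representations = reps2)
  expect_equal(unclass(out2)[1:2], c("a", "b"))
  expect_error(select_reference_baselines(NULL, "a", n = 3,
                                          representations = matrix(1)),
               "smaller")
})

test_that("significance flags come from t-tests with BH correction", {
  set.seed(8)
  ref <- rnorm(1000)
  scores <- list(null1 = rnorm(20), null2 = rnorm(20),
                 hot = rnorm(20, mean = 10))
  out <- significant_kmers(scores, ref)
  expect_false(out$significant[out$token == "null1"])
  expect_true(out$significant[out$token == "hot"])
  # identical degenerate distributions are not significant
  out2 <- significant_kmers(list(x = rep(1, 5)), rep(1, 100))
  expect_equal(out2$p, 1)
  expect_error(significant_kmers(list(x = rnorm(5)), numeric(0)), "empty")
  expect_error(significant_kmers(list(x = 1), ref), ">= 2")
})

test_that("positional projection takes the max over covering significant tokens", {
  # hand-built profile: 30-nt sequence, motif at 13-18
  seq30 <- paste0(strrep("A", 12), "GGGGGG", strrep("U", 12))
  token_attr <- rep(0, 25)
  token_attr[5] <- 0.2   # covers nt 5-10
  token_attr[6] <- 0.5   # covers nt 6-11
  prof <- structure(list(token_attr = token_attr,
                         kmers = substring(seq30, 1:25, 6:30),
                         token_start = 1:25, motif_span = c(13L, 18L),
                         k = 6L), class = "attribution_profile")
  sig <- token_attr != 0
  pos <- positional_attribution(prof, sig, k = 1)
  expect_equal(pos$score[pos$position == 7], 0.5)   # covered by both
  expect_equal(pos$score[pos$position == 5], 0.2)   # only token 5
  expect_equal(pos$score[pos$position == 12], 0)    # non-significant cover
  expect_false(any(pos$position %in% 13:18))        # motif zeroed out
  expect_true(all(pos$position >= 13 - 20 & pos$position <= 18 + 20))
})

test_that("IG completeness holds on the mini-LM", {
  dat <- fixture_binary_data(60, seed = 31)
  sc <- finetune_classifier(NULL, dat, task = "binary",
                            cfg = model_config(seed = 5), epochs = 2)
  model <- sc$model
  neg <- dat$sequence[dat$label == "non-rG4"][1:12]
  bl <- select_reference_baselines(model, neg, n = 3)
  pos1 <- dat$sequence[dat$label == "rG4"][1]
  pr <- integrated_attributions(model, pos1, bl, steps = 200)
  co <- pr$completeness
  rel <- abs(co$attr_sum - co$f_diff) / pmax(abs(co$f_diff), 1e-12)
  expect_true(all(rel < 0.01))
  # motif zeroing
  m <- find_motifs(pos1)
  pr2 <- integrated_attributions(model, pos1, bl, steps = 20,
                                 motif_span = c(m$start[1], m$end[1]))
  overlap <- pr2$token_start <= m$end[1] &
    pr2$token_start + 5L >= m$start[1]
  expect_true(all(pr2$token_attr[overlap] == 0))
})

test_that("perturbation scan flips only G and C and tracks counts", {
  orc <- oracle_scorer()
  sims <- fixture_canonical_windows(6, seed = 51)
  ps <- flank_perturbation(orc, sims$sequences, flank = 20)
  expect_true(all(ps$records$mutation %in% c("G->C", "C->G")))
  expect_true(all(abs(ps$records$rel_position) <= 20))
  # oracle invariance: flank substitutions that do not create a canonical
  # motif leave the score unchanged
  expect_true(mean(ps$records$delta == 0) > 0.9)
  # counts per cell equal the number of carrying sequences
  agg <- aggregate(seq_index ~ mutation + rel_position, ps$records,
                   length)
  m <- merge(ps$cells, agg, by = c("mutation", "rel_position"))
  expect_equal(m$n, m$seq_index)
  # sequences without a canonical motif are skipped with a warning
  expect_warning(flank_perturbation(orc, "AUAUAUAUAUAUAU"), "skipped")
})

test_that("trained-model perturbation shows G->C more destabilizing near the motif", {
  # a moderately trained model (one epoch, mid-range probabilities) is the
  # responsive regime for single-base flank perturbations; a saturated
  # model pins its outputs near 1 and the deltas fall to noise level
  dat <- fixture_binary_data(150, seed = 61)
  sc <- finetune_classifier(NULL, dat, task = "binary",
                            cfg = model_config(seed = 6), epochs = 1)
  seqs <- dat$sequence[dat$label == "rG4"][1:30]
  ps <- flank_perturbation(sc, seqs, flank = 20, min_wt = 0.4)
  expect_gt(nrow(ps$records), 100)
  near <- abs(ps$records$rel_position) <= 10
  mg <- mean(ps$records$delta[near & ps$records$mutation == "G->C"])
  mc <- mean(ps$records$delta[near & ps$records$mutation == "C->G"])
  expect_lt(mg, mc)
})
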