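# The transformer itself is checked numerically (gradient check) and
# behaviourally (MLM learnability, classifier separability); training sizes
# are kept small so the whole file runs in well under two minutes.

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- model_config(layers = 2, heads = 2, hidden = 8, ffn = 16,
                      max_len = 12, seed = 7)
  vocab <- kmer_vocab(2)
  m <- init_mini_lm(cfg, vocab, n_classes = 2)
  set.seed(42)
  B <- 2L; T <- 6L
  ids <- matrix(sample(6:20, B * T, TRUE), B, T)
  ids[, 1] <- vocab$cls; ids[2, 6] <- vocab$pad
  mask <- matrix(TRUE, B, T); mask[2, 6] <- FALSE
  y <- c(1L, 2L)
  loss_fn <- function(params) {
    m2 <- m; m2$params <- params
    fw <- g4scan:::tf_forward(m2, ids, mask)
    g4scan:::head_classifier(m2, fw$Hf, mask, labels = y)$loss
  }
  fw <- g4scan:::tf_forward(m, ids, mask)
  hc <- g4scan:::head_classifier(m, fw$Hf, mask, labels = y)
  bw <- g4scan:::tf_backward(m, fw$cache, hc$dHf)
  grads <- bw$grads; grads$cls <- hc$g_cls
  grads <- g4scan:::align_grads(m$params, grads)
  eps <- 1e-5
  paths <- list(c("pos_emb"), c("cls", "W"), c("L1", "q", "W"),
                c("L1", "v", "W"), c("L1", "f1", "W"), c("L2", "f2", "W"),
                c("L2", "ln1_g"), c("lnf_g"))
  getv <- function(l, pa) { for (nm in pa) l <- l[[nm]]; l }
  setv <- function(l, pa, val) {
    if (length(pa) == 1L) { l[[pa]] <- val; return(l) }
    l[[pa[1L]]] <- setv(l[[pa[1L]]], pa[-1L], val); l
  }
  for (pa in paths) {
    arr <- getv(m$params, pa)
    i <- sample(length(arr), 1)
    v <- arr; v[i] <- v[i] + eps
    num <- (loss_fn(setv(m$params, pa, v)) - loss_fn(m$params)) / eps
    ana <- getv(grads, pa)[i]
    expect_equal(num, ana, tolerance = 1e-2)
  }
})

test_that("untrained MLM loss sits at the uniform baseline; training lowers it", {
  corpus <- rep(paste0(strrep("GGGA", 8), strrep("ACGU", 8)), 30)
  cfg <- model_config(pretrain_steps = 0L, seed = 5)
  m0 <- pretrain_mlm(corpus, cfg, steps = 0L)
  expect_lt(abs(m0$held_out_ce - m0$baseline_ce) / m0$baseline_ce, 0.1)
  m <- pretrain_mlm(corpus, model_config(pretrain_steps = 60L, seed = 5))
  expect_lt(m$held_out_ce, m$baseline_ce)
  # determinism: same seed, same final held-out loss
  m2 <- pretrain_mlm(corpus, model_config(pretrain_steps = 60L, seed = 5))
  expect_identical(m$held_out_ce, m2$held_out_ce)
  expect_error(pretrain_mlm(character(0)), "empty corpus")
})

test_that("fine-tuned classifier separates motif from motif-free sequences", {
  dat <- fixture_binary_data(150, seed = 31)
  set.seed(1)
  idx <- sample(nrow(dat))
  tr <- dat[idx[1:220], ]; te <- dat[idx[221:300], ]
  sc <- finetune_classifier(NULL, tr, task = "binary",
                            cfg = model_config(seed = 5), epochs = 2)
  expect_s3_class(sc, "g4_scorer")
  s <- score_sequences(sc, te$sequence)
  expect_true(all(s >= 0 & s <= 1))
  expect_gt(roc_auc(s, te$label == "rG4"), 0.9)
  # predictions correlate positively with G4Hunter on G-rich inputs
  gh <- score_sequences(g4hunter_scorer(), te$sequence)
  expect_gt(cor(s, gh, method = "spearman"), 0)
  expect_error(finetune_classifier(NULL, data.frame(sequence = "ACGUACGU",
                                                    label = "rG4")),
               "two classes")
})

test_that("multiclass head returns a normalized distribution", {
  suite <- generate_subtype_suite(20, subtypes = c("CANONICAL", "UNKNOWN"),
                                  seed = 12)
  dat <- data.frame(sequence = suite$sequence, label = suite$subtype)
  sc <- finetune_classifier(NULL, dat, task = "multiclass",
                            cfg = model_config(seed = 3), epochs = 1)
  pm <- sc$predict_prob(dat$sequence[c(1, 25)])
  expect_equal(rowSums(pm), c(1, 1), tolerance = 1e-6)
  expect_true(all(pm >= 0 & pm <= 1))
  expect_setequal(colnames(pm), c("CANONICAL", "UNKNOWN"))
})

test_that("checkpoints round-trip through a single archive", {
  dat <- fixture_binary_data(20, seed = 77)
  sc <- finetune_classifier(NULL, dat, task = "binary",
                            cfg = model_config(seed = 9), epochs = 1)
  f <- tmp_path(".rds")
  save_checkpoint(sc, f)
  sc2 <- load_checkpoint(f)
  s <- dat$sequence[1:5]
  expect_equal(score_sequences(sc, s), score_sequences(sc2, s))
})

test_that("rank-formula ROC-AUC agrees with an independent implementation", {
  set.seed(55)
  for (i in 1:10) {
    scores <- c(rnorm(40, 1), rnorm(60))
    labels <- rep(c(TRUE, FALSE), c(40, 60))
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(labels, scores, quiet = TRUE))))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
  expect_true(is.na(roc_auc(rnorm(5), rep(TRUE, 5))))
})

test_that("cross-validation partitions stratified folds and scores oracles", {
  dat <- fixture_binary_data(25, seed = 41)
  oracle_factory <- function(tr) oracle_scorer()
  cv <- cross_validate(dat, oracle_factory, k = 5, seed = 3)
  expect_equal(nrow(cv$per_fold), 5L)
  expect_equal(unname(cv$mean["accuracy"]), 1)
  expect_equal(unname(cv$mean["roc_auc"]), 1)
  # constant scorer: AUC 0.5
  const_factory <- function(tr)
    new_scorer("const", "probabilistic", function(s) rep(0.5, length(s)))
  cv2 <- cross_validate(dat, const_factory, k = 5, seed = 3)
  expect_equal(unname(cv2$mean["roc_auc"]), 0.5)
  # fold partition property
  fold <- g4scan:::stratified_folds(dat$label, 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  sizes <- table(fold)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_equal(sum(sizes), nrow(dat))
  expect_error(cross_validate(dat, oracle_factory, k = 26),
               "smallest class")
})

test_that("binary dataset construction follows the published recipe", {
  pos <- fixture_canonical_windows(40, seed = 6, length = 120L)
  pos_seqs <- c(pos$sequences, pos$sequences[1:5])  # duplicates collapse
  bg <- simulate_transcriptome(n = 60, length_dist = 300L,
                               subtype_mix = c(RELAXED_NEG = 1), seed = 7)
  dat <- build_binary_dataset(pos_seqs, bg$transcripts, seed = 8)
  expect_equal(sum(dat$label == "rG4"), 40L)
  # ratio within 10% of 1:1 when background is ample
  expect_lt(abs(sum(dat$label == "non-rG4") / 40 - 1), 0.1)
  # every negative matches the relaxed regex
  negs <- dat$sequence[dat$label == "non-rG4"]
  expect_true(all(vapply(negs, function(s)
    nrow(g4scan:::relaxed_matches(s)) > 0, TRUE)))
  # labels interleave
  expect_equal(dat$label[1:4], c("rG4", "non-rG4", "rG4", "non-rG4"))
  # determinism
  dat2 <- build_binary_dataset(pos_seqs, bg$transcripts, seed = 8)
  expect_identical(dat, dat2)
  # per-bin cap
  cand <- do.call(rbind, lapply(bg$transcripts, function(tx)
    g4scan:::relaxed_matches(tx$sequence)))
  expect_true(nrow(cand) >= 40)
})

test_that("bin cap limits long-pattern over-representation", {
  pos <- fixture_canonical_windows(30, seed = 16, length = 120L)$sequences
  bg <- simulate_transcriptome(n = 40, length_dist = 300L,
                               subtype_mix = c(RELAXED_NEG = 1), seed = 17)
  dat_capped <- suppressWarnings(
    build_binary_dataset(pos, bg$transcripts, bin_cap = 5L, seed = 18))
  expect_warning(
    build_binary_dataset(pos, bg$transcripts, bin_cap = 1L, seed = 18),
    "background exhausted")
  expect_lte(sum(dat_capped$label == "non-rG4"), 25L)  # 5 bins x cap 5
})

test_that("multiclass dataset labels delegate to the rule engine", {
  suite <- generate_subtype_suite(5, subtypes = c("CANONICAL",
                                                  "TWO_QUARTET",
                                                  "UNKNOWN"), seed = 21)
  dat <- build_multiclass_dataset(suite$sequence)
  expect_equal(sort(unique(dat$label)),
               sort(c("CANONICAL", "TWO_QUARTET", "UNKNOWN")))
  expect_equal(dat$label, suite$subtype[match(dat$sequence,
                                              suite$sequence)])
})
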