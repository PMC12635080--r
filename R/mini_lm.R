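# Dataset construction, MLM pre-training, fine-tuning and k-fold evaluation
# for the mini k-mer language model.

RELAXED_G4_PATTERN <- "G{2,}[ACGU]{1,30}G{2,}[ACGU]{1,30}G{2,}[ACGU]{1,30}G{2,}"

# leftmost non-overlapping matches of the relaxed putative-G4 regex,
# extended to maximal G-runs at both edges
relaxed_matches <- function(sequence) {
  m <- gregexpr(RELAXED_G4_PATTERN, sequence, perl = TRUE)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(start = integer(), end = integer()))
  st <- as.integer(m); en <- st + attr(m, "match.length") - 1L
  # extend left edge over any preceding Gs (maximal-run rule)
  for (i in seq_along(st)) {
    while (st[i] > 1L && substr(sequence, st[i] - 1L, st[i] - 1L) == "G")
      st[i] <- st[i] - 1L
    while (en[i] < nchar(sequence) &&
           substr(sequence, en[i] + 1L, en[i] + 1L) == "G")
      en[i] <- en[i] + 1L
  }
  data.frame(start = st, end = en)
}

#' Build the binary rG4 / non-rG4 training dataset
#'
#' Positives are deduplicated by exact sequence and, when transcript context
#' is supplied, extended with transcript flanks up to 70 nt. Negatives are
#' matches of the relaxed putative-G4 pattern G2+ (N1-30 G2+)x3 in background
#' transcripts, centered in windows whose lengths are drawn from the
#' empirical positive-length distribution; per 10-nt match-length bin
#' (10-60 nt) at most `bin_cap` negatives are kept (seeded sampling).
#'
#' @param positives character vector of positive rG4 sequences, or a
#'   data.frame with columns transcript_id, start, end (requires
#'   `transcripts`).
#' @param background_transcripts list of `transcript` objects assumed free
#'   of true rG4s.
#' @param transcripts optional list of `transcript` objects providing flanks
#'   for data.frame positives.
#' @param target_length flank-extension ceiling (default 70).
#' @param bin_cap per-bin negative cap (default 1200).
#' @param seed RNG seed.
#' @return data.frame with columns sequence, label ("rG4"/"non-rG4"),
#'   source; labels interleaved. Attribute `negative_shortfall` reports how
#'   many negatives were missing when the background was exhausted.
#' @export
build_binary_dataset <- function(positives, background_transcripts,
                                 transcripts = NULL, target_length = 70L,
                                 bin_cap = 1200L, seed = 1L) {
  if (is.data.frame(positives)) {
    stopifnot(!is.null(transcripts))
    pos_seq <- vapply(seq_len(nrow(positives)), function(i) {
      tx <- transcripts[[positives$transcript_id[i]]]
      extract_flanked_window(tx, c(positives$start[i], positives$end[i]),
                             target_length)$sequence
    }, "")
  } else {
    pos_seq <- normalize_rna(positives)
  }
  pos_seq <- unique(pos_seq)
  n_pos <- length(pos_seq)
  pos_len <- nchar(pos_seq)

  # collect relaxed-regex matches from the background
  cand <- do.call(rbind, lapply(background_transcripts, function(tx) {
    m <- relaxed_matches(tx$sequence)
    if (!nrow(m)) return(NULL)
    cbind(m, transcript_id = tx$id)
  }))
  set.seed(seed)
  neg_seq <- character()
  if (!is.null(cand) && nrow(cand)) {
    cand$len <- cand$end - cand$start + 1L
    cand <- cand[cand$len >= 10L & cand$len <= 60L, , drop = FALSE]
    cand$bin <- pmin((cand$len - 10L) %/% 10L, 4L)
    keep <- unlist(lapply(split(seq_len(nrow(cand)), cand$bin), function(i) {
      if (length(i) > bin_cap) sample(i, bin_cap) else i
    }), use.names = FALSE)
    cand <- cand[sample(keep), , drop = FALSE]  # shuffled
    take <- min(nrow(cand), n_pos)
    for (i in seq_len(take)) {
      tx <- background_transcripts[[cand$transcript_id[i]]]
      want <- max(pos_len[sample.int(length(pos_len), 1L)], cand$len[i])
      win <- extract_flanked_window(tx, c(cand$start[i], cand$end[i]),
                                    target_length = want)
      neg_seq <- c(neg_seq, win$sequence)
    }
    neg_seq <- unique(neg_seq)
  }
  shortfall <- n_pos - length(neg_seq)
  if (shortfall > 0L)
    warning("background exhausted: ", shortfall,
            " negative sequence(s) short of the requested count")
  out <- data.frame(
    sequence = c(pos_seq, neg_seq),
    label = c(rep("rG4", n_pos), rep("non-rG4", length(neg_seq))),
    source = c(rep("experimental-positive", n_pos),
               rep("regex-negative", length(neg_seq))))
  # interleave the two labels
  ord <- order(c(seq_len(n_pos), seq_len(length(neg_seq))),
               c(rep(0L, n_pos), rep(1L, length(neg_seq))))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "negative_shortfall") <- max(shortfall, 0L)
  out
}

#' Build the eight-class rG4 subtype dataset
#'
#' Each deduplicated positive is labeled by the hierarchical rule engine;
#' flank extension mirrors the binary recipe when transcript context is
#' given.
#'
#' @inheritParams build_binary_dataset
#' @param config a [pattern_config()].
#' @return data.frame with columns sequence, label (subtype), source.
#' @export
build_multiclass_dataset <- function(positives, transcripts = NULL,
                                     target_length = 70L,
                                     config = pattern_config()) {
  if (is.data.frame(positives)) {
    stopifnot(!is.null(transcripts))
    seqs <- vapply(seq_len(nrow(positives)), function(i) {
      tx <- transcripts[[positives$transcript_id[i]]]
      extract_flanked_window(tx, c(positives$start[i], positives$end[i]),
                             target_length)$sequence
    }, "")
  } else {
    seqs <- normalize_rna(positives)
  }
  seqs <- unique(seqs)
  labs <- vapply(seqs, function(s) classify_subtype(s, config)$subtype, "",
                 USE.NAMES = FALSE)
  data.frame(sequence = seqs, label = labs,
             source = "experimental-positive")
}

# sample MLM masking for one batch; returns flat row indices, targets and
# the masked ids matrix
apply_mlm_mask <- function(ids, mask, vocab, frac) {
  B <- nrow(ids); T <- ncol(ids)
  content <- mask & ids != vocab$cls & ids != vocab$sep
  sel <- integer(); tgt <- integer()
  masked <- ids
  for (b in seq_len(B)) {
    pos <- which(content[b, ])
    n <- max(1L, round(frac * length(pos)))
    pick <- if (length(pos) == 1L) pos else sample(pos, n)
    r <- stats::runif(length(pick))
    ids_b <- ids[b, pick]
    new <- ifelse(r < 0.8, vocab$mask,
                  ifelse(r < 0.9,
                         sample(seq_len(vocab$size - vocab$n_special),
                                length(pick), replace = TRUE) +
                           vocab$n_special,
                         ids_b))
    masked[b, pick] <- new
    sel <- c(sel, (b - 1L) * T + pick)
    tgt <- c(tgt, ids_b)
  }
  list(sel = sel, targets = tgt, ids = masked)
}

mlm_eval_ce <- function(model, id_list, seed = 99L) {
  set.seed(seed)
  vocab <- model$vocab
  total <- 0; n <- 0L
  batches <- split(id_list, ceiling(seq_along(id_list) / 16))
  for (bl in batches) {
    pb <- pad_batch(bl, vocab$pad)
    mk <- apply_mlm_mask(pb$ids, pb$mask, vocab, model$cfg$mask_frac)
    fw <- tf_forward(model, mk$ids, pb$mask)
    hm <- head_mlm(model, fw$Hf, mk$sel, mk$targets)
    total <- total + hm$loss * length(mk$sel)
    n <- n + length(mk$sel)
  }
  total / n
}

#' Pre-train the mini language model with masked-token prediction
#'
#' Standard BERT-style masked language modeling over overlapping 6-mer
#' tokens: a fraction of content tokens is selected per sequence (80%
#' replaced by [MASK], 10% by a random k-mer, 10% left unchanged) and the
#' model is trained to recover the original tokens. A held-out slice (10%)
#' monitors masked-token cross-entropy against the uniform-vocabulary
#' baseline log(vocab size).
#'
#' @param corpus character vector of RNA sequences.
#' @param cfg a [model_config()].
#' @param steps optional override of `cfg$pretrain_steps`.
#' @return a `mini_lm` with fields `held_out_ce` and `baseline_ce`.
#' @export
pretrain_mlm <- function(corpus, cfg = model_config(), steps = NULL) {
  if (!length(corpus)) stop("empty corpus")
  if (is.null(steps)) steps <- cfg$pretrain_steps
  vocab <- kmer_vocab()
  model <- init_mini_lm(cfg, vocab)
  enc <- lapply(normalize_rna(corpus), encode_sequence, vocab = vocab,
                max_tokens = cfg$max_len - 2L)
  n_hold <- max(1L, floor(length(enc) * 0.1))
  hold <- enc[seq_len(n_hold)]
  train <- if (length(enc) > n_hold) enc[-seq_len(n_hold)] else enc
  set.seed(cfg$seed)
  state <- adam_init(model$params)
  for (s in seq_len(steps)) {
    bi <- sample(length(train), min(cfg$pretrain_batch, length(train)),
                 replace = length(train) < cfg$pretrain_batch)
    pb <- pad_batch(train[bi], vocab$pad)
    mk <- apply_mlm_mask(pb$ids, pb$mask, vocab, cfg$mask_frac)
    fw <- tf_forward(model, mk$ids, pb$mask)
    hm <- head_mlm(model, fw$Hf, mk$sel, mk$targets)
    bw <- tf_backward(model, fw$cache, hm$dHf)
    grads <- bw$grads
    grads$mlm <- hm$g_mlm
    grads <- align_grads(model$params, grads)
    up <- adam_step(model$params, grads, state, cfg$pretrain_lr)
    model$params <- up$params; state <- up$state
  }
  model$held_out_ce <- mlm_eval_ce(model, hold)
  model$baseline_ce <- log(vocab$size)
  model
}

label_levels <- function(labels, task) {
  if (task == "binary") {
    lev <- c("non-rG4", "rG4")
    if (!all(labels %in% lev)) lev <- sort(unique(labels))
    lev
  } else {
    intersect(SUBTYPE_LEVELS, unique(labels))
  }
}

#' Fine-tune the mini language model into a probabilistic scorer
#'
#' Attaches a classification head (mean-pooled final hidden states, softmax)
#' and fine-tunes all parameters with Adam. Binary task: 2 epochs by
#' default; multiclass: 5.
#'
#' @param language_model a pre-trained `mini_lm` (or `NULL` to fine-tune
#'   from a fresh initialization of `cfg`).
#' @param dataset data.frame with columns sequence, label (>= 2 classes).
#' @param task "binary" or "multiclass".
#' @param cfg config used when `language_model` is NULL.
#' @param epochs optional override.
#' @return a probabilistic `g4_scorer`; `score_sequences()` returns the
#'   positive-class probability (binary) or the top-class probability
#'   (multiclass); the `predict_prob` element returns the full class
#'   distribution for the multiclass task.
#' @export
finetune_classifier <- function(language_model, dataset,
                                task = c("binary", "multiclass"),
                                cfg = model_config(), epochs = NULL) {
  task <- match.arg(task)
  labs <- as.character(dataset$label)
  lev <- label_levels(labs, task)
  if (length(unique(labs)) < 2L)
    stop("dataset must contain at least two classes")
  model <- if (is.null(language_model))
    init_mini_lm(cfg, kmer_vocab(), n_classes = length(lev))
  else language_model
  cfg <- model$cfg
  if (ncol(model$params$cls$W) != length(lev)) {
    set.seed(cfg$seed + 1L)
    model$params$cls <- init_linear(cfg$hidden, length(lev))
    model$n_classes <- length(lev)
  }
  if (is.null(epochs))
    epochs <- if (task == "binary") cfg$epochs_binary else
      cfg$epochs_multiclass
  vocab <- model$vocab
  enc <- lapply(normalize_rna(dataset$sequence), encode_sequence,
                vocab = vocab, max_tokens = cfg$max_len - 2L)
  y <- match(labs, lev)
  set.seed(cfg$seed + 2L)
  state <- adam_init(model$params)
  n <- length(enc)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$finetune_batch))
    for (bi in batches) {
      pb <- pad_batch(enc[bi], vocab$pad)
      fw <- tf_forward(model, pb$ids, pb$mask)
      hc <- head_classifier(model, fw$Hf, pb$mask, labels = y[bi])
      bw <- tf_backward(model, fw$cache, hc$dHf)
      grads <- bw$grads
      grads$cls <- hc$g_cls
      grads <- align_grads(model$params, grads)
      up <- adam_step(model$params, grads, state, cfg$finetune_lr)
      model$params <- up$params; state <- up$state
    }
  }
  mini_lm_scorer(model, lev, task)
}

#' Wrap a fine-tuned mini model in the scorer contract
#'
#' @param model a `mini_lm` with a fitted classification head.
#' @param levels class labels in head order.
#' @param task "binary" or "multiclass".
#' @return a `g4_scorer`.
#' @export
mini_lm_scorer <- function(model, levels, task = "binary") {
  predict_prob <- function(seqs) {
    seqs <- normalize_rna(as.character(seqs))
    enc <- lapply(seqs, encode_sequence, vocab = model$vocab,
                  max_tokens = model$cfg$max_len - 2L)
    out <- matrix(0, length(enc), length(levels),
                  dimnames = list(NULL, levels))
    batches <- split(seq_along(enc), ceiling(seq_along(enc) / 32))
    for (bi in batches) {
      pb <- pad_batch(enc[bi], model$vocab$pad)
      fw <- tf_forward(model, pb$ids, pb$mask)
      out[bi, ] <- head_classifier(model, fw$Hf, pb$mask)$probs
    }
    out
  }
  score_fun <- if (task == "binary") {
    pos <- if ("rG4" %in% levels) "rG4" else levels[length(levels)]
    function(seqs) predict_prob(seqs)[, pos]
  } else {
    function(seqs) apply(predict_prob(seqs), 1L, max)
  }
  sc <- new_scorer("mini_lm", "probabilistic", score_fun, model = model)
  sc$predict_prob <- predict_prob
  sc$levels <- levels
  sc$task <- task
  sc
}

#' Save / load a mini-LM scorer checkpoint
#'
#' The checkpoint is a single portable archive holding the weights, the
#' tokenizer vocabulary and the model configuration.
#'
#' @param scorer a `g4_scorer` from [finetune_classifier()] (or a raw
#'   `mini_lm`).
#' @param path file path.
#' @return `load_checkpoint` returns the restored object.
#' @export
save_checkpoint <- function(scorer, path) {
  obj <- if (inherits(scorer, "g4_scorer"))
    list(kind = "scorer", model = scorer$model, levels = scorer$levels,
         task = scorer$task)
  else list(kind = "model", model = scorer)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (identical(obj$kind, "scorer"))
    mini_lm_scorer(obj$model, obj$levels, obj$task)
  else obj$model
}

#' ROC-AUC by the rank (Mann-Whitney) formula
#'
#' @param scores numeric scores.
#' @param labels logical or 0/1 vector (TRUE = positive).
#' @return scalar AUC.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Precision-recall AUC (average precision)
#'
#' @inheritParams roc_auc
#' @return scalar average precision.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab]) / sum(lab)
}

stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of a scorer factory
#'
#' Folds partition the data with per-class balance; fold sizes differ by at
#' most one per class. Reports accuracy, ROC-AUC and PR-AUC per fold and
#' their means; multiclass AUCs are macro one-vs-rest.
#'
#' @param dataset data.frame with sequence, label.
#' @param scorer_factory function(train_df) -> probabilistic `g4_scorer`.
#' @param k number of folds (default 10; must not exceed the smallest class).
#' @param seed fold-assignment seed.
#' @return list with `per_fold` (data.frame) and `mean` (named numeric).
#' @export
cross_validate <- function(dataset, scorer_factory, k = 10L, seed = 1L) {
  labs <- as.character(dataset$label)
  min_class <- min(table(labs))
  if (k > min_class)
    stop("k = ", k, " exceeds the smallest class size (", min_class, ")")
  fold <- stratified_folds(labs, k, seed)
  lev <- sort(unique(labs))
  binary <- length(lev) == 2L
  rows <- lapply(seq_len(k), function(f) {
    tr <- dataset[fold != f, , drop = FALSE]
    te <- dataset[fold == f, , drop = FALSE]
    sc <- scorer_factory(tr)
    if (binary) {
      pos <- if (!is.null(sc$levels)) {
        if ("rG4" %in% sc$levels) "rG4" else sc$levels[length(sc$levels)]
      } else lev[2L]
      s <- score_sequences(sc, te$sequence)
      truth <- te$label == pos
      data.frame(fold = f, accuracy = mean((s >= 0.5) == truth),
                 roc_auc = roc_auc(s, truth), pr_auc = pr_auc(s, truth))
    } else {
      pm <- sc$predict_prob(te$sequence)
      pred <- colnames(pm)[max.col(pm)]
      present <- intersect(colnames(pm), unique(te$label))
      aucs <- vapply(present, function(cl)
        roc_auc(pm[, cl], te$label == cl), 0)
      praucs <- vapply(present, function(cl)
        pr_auc(pm[, cl], te$label == cl), 0)
      data.frame(fold = f, accuracy = mean(pred == te$label),
                 roc_auc = mean(aucs, na.rm = TRUE),
                 pr_auc = mean(praucs, na.rm = TRUE))
    }
  })
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, c("accuracy", "roc_auc", "pr_auc")]))
}
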