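# Miniature BERT-style encoder over k-mer tokens, written directly on top of
# base-R matrix algebra. Forward, analytic backward (including gradients with
# respect to the input embeddings, needed for integrated gradients) and an
# Adam optimizer. Batches are stored as (B*T) x H matrices with rows ordered
# sequence-major, i.e. row (b-1)*T + t holds token t of sequence b.

#' k-mer vocabulary for the mini language model
#'
#' Special tokens first ([PAD], [UNK], [CLS], [SEP], [MASK]), then all 4^k
#' k-mers over A/C/G/U in lexicographic order.
#'
#' @param k k-mer size (default 6).
#' @return list with `tokens`, `index` (named integer lookup), `k`, and the
#'   ids of the special tokens.
#' @export
kmer_vocab <- function(k = 6L) {
  specials <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")
  kmers <- do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "U")), k),
                                       stringsAsFactors = FALSE)[, k:1])
  kmers <- sort(kmers)
  tokens <- c(specials, kmers)
  list(tokens = tokens,
       index = stats::setNames(seq_along(tokens), tokens),
       k = as.integer(k),
       pad = 1L, unk = 2L, cls = 3L, sep = 4L, mask = 5L,
       n_special = 5L, size = length(tokens))
}

#' Encode a sequence as token ids ([CLS] ... [SEP])
#'
#' @param sequence RNA sequence (length >= k).
#' @param vocab a [kmer_vocab()].
#' @param max_tokens content-token cap per chunk.
#' @return integer vector of ids for the first chunk (desk-scale inputs fit
#'   in one chunk).
#' @export
encode_sequence <- function(sequence, vocab, max_tokens = 510L) {
  ch <- tokenize_kmers(sequence, k = vocab$k, max_tokens = max_tokens)[[1L]]
  ids <- unname(vocab$index[ch$tokens])
  ids[is.na(ids)] <- vocab$unk
  c(vocab$cls, ids, vocab$sep)
}

#' Configuration of the mini language model
#'
#' Desk-scale defaults exercise the mechanism on a laptop-class budget; the
#' published full-scale values (6 layers, 6 heads, pre-training lr 4e-4 with
#' an effective batch of 250 for 200k steps, fine-tuning lr 2e-4 batch 32)
#' are expressible through the same fields.
#'
#' @param layers,heads,hidden,ffn transformer dimensions; `heads` must
#'   divide `hidden`.
#' @param max_len maximum token positions (with [CLS]/[SEP]).
#' @param mask_frac MLM masking fraction.
#' @param pretrain_lr,pretrain_steps,pretrain_batch MLM pre-training knobs.
#' @param finetune_lr,finetune_batch fine-tuning knobs.
#' @param epochs_binary,epochs_multiclass fine-tuning epochs per task.
#' @param seed RNG seed for initialization and batching.
#' @return list of class `model_config`.
#' @export
model_config <- function(layers = 2L, heads = 2L, hidden = 64L, ffn = 128L,
                         max_len = 96L, mask_frac = 0.15,
                         pretrain_lr = 1e-3, pretrain_steps = 300L,
                         pretrain_batch = 32L,
                         finetune_lr = 1e-3, finetune_batch = 32L,
                         epochs_binary = 2L, epochs_multiclass = 5L,
                         seed = 1L) {
  stopifnot(layers >= 1L, heads >= 1L, hidden %% heads == 0L, ffn >= 1L,
            mask_frac > 0, mask_frac < 1)
  structure(as.list(environment()), class = "model_config")
}

init_linear <- function(nin, nout, sd = 0.02) {
  list(W = matrix(stats::rnorm(nin * nout, 0, sd), nin, nout),
       b = numeric(nout))
}

#' Initialize mini language model parameters
#'
#' @param cfg a [model_config()].
#' @param vocab a [kmer_vocab()].
#' @param n_classes size of the classification head (default 2).
#' @return list of class `mini_lm` with `params`, `cfg`, `vocab`.
#' @export
init_mini_lm <- function(cfg, vocab = kmer_vocab(), n_classes = 2L) {
  set.seed(cfg$seed)
  H <- cfg$hidden
  p <- list(
    tok_emb = matrix(stats::rnorm(vocab$size * H, 0, 0.02), vocab$size, H),
    pos_emb = matrix(stats::rnorm(cfg$max_len * H, 0, 0.02), cfg$max_len, H),
    lnf_g = rep(1, H), lnf_b = numeric(H),
    mlm = init_linear(H, vocab$size),
    cls = init_linear(H, n_classes))
  for (l in seq_len(cfg$layers)) {
    p[[paste0("L", l)]] <- list(
      ln1_g = rep(1, H), ln1_b = numeric(H),
      q = init_linear(H, H), k = init_linear(H, H), v = init_linear(H, H),
      o = init_linear(H, H),
      ln2_g = rep(1, H), ln2_b = numeric(H),
      f1 = init_linear(H, cfg$ffn), f2 = init_linear(cfg$ffn, H))
  }
  structure(list(params = p, cfg = cfg, vocab = vocab,
                 n_classes = as.integer(n_classes)), class = "mini_lm")
}

#' @export
print.mini_lm <- function(x, ...) {
  cat(sprintf("<mini_lm> %d layer(s), %d head(s), hidden %d, vocab %d\n",
              x$cfg$layers, x$cfg$heads, x$cfg$hidden, x$vocab$size))
  invisible(x)
}

add_bias <- function(X, b) X + rep(b, each = nrow(X))

# GELU activation (the BERT-family feed-forward nonlinearity); smooth, so
# path integrals in attribution analyses converge at second order
gelu <- function(x) x * stats::pnorm(x)
gelu_prime <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

ln_forward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  va <- rowMeans(Xc * Xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- Xc * inv
  list(Y = add_bias(xhat * rep(g, each = nrow(X)), b), xhat = xhat,
       inv = inv)
}

ln_backward <- function(dY, cache, g) {
  n <- nrow(dY)
  dxhat <- dY * rep(g, each = n)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * cache$xhat)
  dX <- cache$inv * (dxhat - m1 - cache$xhat * m2)
  list(dX = dX, dg = colSums(dY * cache$xhat), db = colSums(dY))
}

# ids: B x T integer matrix (pad = vocab$pad); mask: B x T logical
# input_emb: optional (B*T) x H matrix replacing the token-embedding lookup
# (positional embeddings are still added) -- the integration variable for IG.
tf_forward <- function(model, ids, mask, input_emb = NULL) {
  p <- model$params; cfg <- model$cfg
  B <- nrow(ids); T <- ncol(ids); H <- cfg$hidden
  dh <- H %/% cfg$heads
  tokE <- if (is.null(input_emb))
    p$tok_emb[as.vector(t(ids)), , drop = FALSE] else input_emb
  X <- tokE + p$pos_emb[rep(seq_len(T), B), , drop = FALSE]
  cache <- list(B = B, T = T, ids = ids, mask = mask, X0 = X)
  for (l in seq_len(cfg$layers)) {
    lay <- p[[paste0("L", l)]]
    lc <- list(X_in = X)
    ln1 <- ln_forward(X, lay$ln1_g, lay$ln1_b)
    Q <- add_bias(ln1$Y %*% lay$q$W, lay$q$b)
    K <- add_bias(ln1$Y %*% lay$k$W, lay$k$b)
    V <- add_bias(ln1$Y %*% lay$v$W, lay$v$b)
    O <- matrix(0, B * T, H)
    P_list <- vector("list", B * cfg$heads)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T + 1L):(b * T)
      km <- mask[b, ]
      for (a in seq_len(cfg$heads)) {
        cols <- ((a - 1L) * dh + 1L):(a * dh)
        S <- (Q[rows, cols, drop = FALSE] %*%
                t(K[rows, cols, drop = FALSE])) / sqrt(dh)
        S[, !km] <- -1e9
        S <- S - apply(S, 1L, max)
        E <- exp(S)
        P <- E / rowSums(E)
        P_list[[(b - 1L) * cfg$heads + a]] <- P
        O[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
      }
    }
    A <- add_bias(O %*% lay$o$W, lay$o$b)
    X <- X + A
    ln2 <- ln_forward(X, lay$ln2_g, lay$ln2_b)
    Z1 <- add_bias(ln2$Y %*% lay$f1$W, lay$f1$b)
    R1 <- gelu(Z1)
    X <- X + add_bias(R1 %*% lay$f2$W, lay$f2$b)
    lc$ln1 <- ln1; lc$Q <- Q; lc$K <- K; lc$V <- V; lc$O <- O
    lc$P_list <- P_list; lc$ln2 <- ln2; lc$R1 <- R1; lc$Z1 <- Z1
    cache[[paste0("L", l)]] <- lc
  }
  lnf <- ln_forward(X, p$lnf_g, p$lnf_b)
  cache$lnf <- lnf; cache$X_pre_lnf <- X
  list(Hf = lnf$Y, cache = cache)
}

zero_like <- function(p) {
  rapply(p, function(x) x * 0, how = "replace")
}

# dHf: gradient at the final-LN output. Returns list(grads, dX0) where dX0
# is the gradient at the token-embedding matrix (before positional add).
tf_backward <- function(model, cache, dHf) {
  p <- model$params; cfg <- model$cfg
  B <- cache$B; T <- cache$T; H <- cfg$hidden
  dh <- H %/% cfg$heads
  g <- list()
  lb <- ln_backward(dHf, cache$lnf, p$lnf_g)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dX <- lb$dX
  for (l in rev(seq_len(cfg$layers))) {
    lay <- p[[paste0("L", l)]]
    lc <- cache[[paste0("L", l)]]
    gl <- list()
    # FFN block: X_out = X_mid + relu(LN2(X_mid) W1 + b1) W2 + b2
    dR1W2 <- dX                       # gradient into the FFN branch
    gl$f2 <- list(W = t(lc$R1) %*% dR1W2, b = colSums(dR1W2))
    dR1 <- dR1W2 %*% t(lay$f2$W)
    dZ1 <- dR1 * gelu_prime(lc$Z1)
    gl$f1 <- list(W = t(lc$ln2$Y) %*% dZ1, b = colSums(dZ1))
    dLn2 <- dZ1 %*% t(lay$f1$W)
    lb2 <- ln_backward(dLn2, lc$ln2, lay$ln2_g)
    gl$ln2_g <- lb2$dg; gl$ln2_b <- lb2$db
    dX <- dX + lb2$dX                 # residual + branch
    # attention block: X_mid = X_in + (O Wo + bo)
    dA <- dX
    gl$o <- list(W = t(lc$O) %*% dA, b = colSums(dA))
    dO <- dA %*% t(lay$o$W)
    dQ <- matrix(0, B * T, H); dK <- matrix(0, B * T, H)
    dV <- matrix(0, B * T, H)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T + 1L):(b * T)
      for (a in seq_len(cfg$heads)) {
        cols <- ((a - 1L) * dh + 1L):(a * dh)
        P <- lc$P_list[[(b - 1L) * cfg$heads + a]]
        dOb <- dO[rows, cols, drop = FALSE]
        dV[rows, cols] <- t(P) %*% dOb
        dP <- dOb %*% t(lc$V[rows, cols, drop = FALSE])
        dS <- P * (dP - rowSums(dP * P))
        dS <- dS / sqrt(dh)
        dQ[rows, cols] <- dS %*% lc$K[rows, cols, drop = FALSE]
        dK[rows, cols] <- t(dS) %*% lc$Q[rows, cols, drop = FALSE]
      }
    }
    Y1 <- lc$ln1$Y
    gl$q <- list(W = t(Y1) %*% dQ, b = colSums(dQ))
    gl$k <- list(W = t(Y1) %*% dK, b = colSums(dK))
    gl$v <- list(W = t(Y1) %*% dV, b = colSums(dV))
    dLn1 <- dQ %*% t(lay$q$W) + dK %*% t(lay$k$W) + dV %*% t(lay$v$W)
    lb1 <- ln_backward(dLn1, lc$ln1, lay$ln1_g)
    gl$ln1_g <- lb1$dg; gl$ln1_b <- lb1$db
    dX <- dX + lb1$dX
    g[[paste0("L", l)]] <- gl
  }
  # embedding gradients
  dX0 <- dX
  dtok <- matrix(0, nrow(p$tok_emb), H)
  idx <- as.vector(t(cache$ids))
  # accumulate by token id
  agg <- rowsum(dX0, group = idx)
  dtok[as.integer(rownames(agg)), ] <- agg
  dpos <- rowsum(dX0, group = rep(seq_len(T), B))
  dpos_full <- matrix(0, nrow(p$pos_emb), H)
  dpos_full[seq_len(T), ] <- dpos
  g$tok_emb <- dtok; g$pos_emb <- dpos_full
  list(grads = g, dX0 = dX0)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# cross-entropy head on a subset of rows (MLM) or pooled rows (classifier)
head_mlm <- function(model, Hf, sel, targets) {
  p <- model$params
  logits <- add_bias(Hf[sel, , drop = FALSE] %*% p$mlm$W, p$mlm$b)
  Pm <- softmax_rows(logits)
  n <- length(sel)
  loss <- -mean(log(pmax(Pm[cbind(seq_len(n), targets)], 1e-12)))
  dlog <- Pm
  dlog[cbind(seq_len(n), targets)] <- dlog[cbind(seq_len(n), targets)] - 1
  dlog <- dlog / n
  gW <- t(Hf[sel, , drop = FALSE]) %*% dlog
  gb <- colSums(dlog)
  dHf <- matrix(0, nrow(Hf), ncol(Hf))
  dHf[sel, ] <- dlog %*% t(p$mlm$W)
  list(loss = loss, dHf = dHf, g_mlm = list(W = gW, b = gb))
}

pool_mean <- function(Hf, mask) {
  B <- nrow(mask); T <- ncol(mask); H <- ncol(Hf)
  pooled <- matrix(0, B, H)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    pooled[b, ] <- colMeans(Hf[rows[mask[b, ]], , drop = FALSE])
  }
  pooled
}

head_classifier <- function(model, Hf, mask, labels = NULL) {
  p <- model$params
  B <- nrow(mask); T <- ncol(mask)
  pooled <- pool_mean(Hf, mask)
  logits <- add_bias(pooled %*% p$cls$W, p$cls$b)
  Pm <- softmax_rows(logits)
  out <- list(probs = Pm)
  if (!is.null(labels)) {
    loss <- -mean(log(pmax(Pm[cbind(seq_len(B), labels)], 1e-12)))
    dlog <- Pm
    dlog[cbind(seq_len(B), labels)] <- dlog[cbind(seq_len(B), labels)] - 1
    dlog <- dlog / B
    out$loss <- loss
    out$g_cls <- list(W = t(pooled) %*% dlog, b = colSums(dlog))
    dpooled <- dlog %*% t(p$cls$W)
    dHf <- matrix(0, nrow(Hf), ncol(Hf))
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * T + 1L):(b * T)
      nb <- sum(mask[b, ])
      dHf[rows[mask[b, ]], ] <- matrix(dpooled[b, ] / nb, nb, ncol(Hf),
                                       byrow = TRUE)
    }
    out$dHf <- dHf
  }
  out
}

# classifier-head forward + gradient of one scalar output (probability of
# class `target`) with respect to the token embeddings -- used by IG.
classifier_prob_grad <- function(model, ids, mask, target = 2L,
                                 input_emb = NULL) {
  fw <- tf_forward(model, ids, mask, input_emb = input_emb)
  hc <- head_classifier(model, fw$Hf, mask)
  Pm <- hc$probs
  B <- nrow(mask); T <- ncol(mask); H <- ncol(fw$Hf)
  # d prob_target / d logits = p_t * (1[j = t] - p_j)
  dlog <- -Pm * Pm[, target]
  dlog[, target] <- dlog[, target] + Pm[, target]
  pooled <- pool_mean(fw$Hf, mask)
  dpooled <- dlog %*% t(model$params$cls$W)
  dHf <- matrix(0, nrow(fw$Hf), H)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * T + 1L):(b * T)
    nb <- sum(mask[b, ])
    dHf[rows[mask[b, ]], ] <- matrix(dpooled[b, ] / nb, nb, H, byrow = TRUE)
  }
  bw <- tf_backward(model, fw$cache, dHf)
  list(prob = Pm[, target], dX0 = bw$dX0)
}

# arrange a grads list to match the parameter structure exactly (Adam maps
# by position); missing pieces become zeros
align_grads <- function(template, values) {
  if (!is.list(template)) {
    if (is.null(values)) return(template * 0)
    return(values)
  }
  out <- lapply(names(template), function(nm)
    align_grads(template[[nm]], values[[nm]]))
  names(out) <- names(template)
  out
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}

# pad a list of id vectors into ids/mask matrices
pad_batch <- function(id_list, pad) {
  T <- max(lengths(id_list))
  B <- length(id_list)
  ids <- matrix(pad, B, T)
  mask <- matrix(FALSE, B, T)
  for (b in seq_len(B)) {
    n <- length(id_list[[b]])
    ids[b, seq_len(n)] <- id_list[[b]]
    mask[b, seq_len(n)] <- TRUE
  }
  list(ids = ids, mask = mask)
}
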