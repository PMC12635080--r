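# Integrated-gradients attribution over 6-mer tokens with reference-baseline
# selection, significance filtering, positional projection, and the flank
# G<->C perturbation scan.

#' Mean final hidden-state representation of sequences under the mini-LM
#'
#' @param model a `mini_lm`.
#' @param sequences character vector.
#' @return matrix, one row per sequence.
#' @export
model_representations <- function(model, sequences) {
  enc <- lapply(normalize_rna(sequences), encode_sequence,
                vocab = model$vocab, max_tokens = model$cfg$max_len - 2L)
  out <- matrix(0, length(enc), model$cfg$hidden)
  for (i in seq_along(enc)) {
    pb <- pad_batch(enc[i], model$vocab$pad)
    fw <- tf_forward(model, pb$ids, pb$mask)
    out[i, ] <- colMeans(fw$Hf)
  }
  out
}

#' Select reference baselines nearest the median representation
#'
#' Computes the model representation (mean final hidden state) of every
#' negative sequence, takes the coordinate-wise median over the set, and
#' returns the `n` sequences nearest to it in Euclidean distance.
#' Ties break deterministically by position/id.
#'
#' @param model a `mini_lm` (or a precomputed representation matrix via
#'   `representations`).
#' @param negative_set character vector of baseline-class sequences
#'   (size >= n).
#' @param n number of baselines (default 3).
#' @param representations optional precomputed matrix (rows align with
#'   `negative_set`).
#' @return character vector of `n` baseline sequences, with attribute
#'   `index` giving their positions in `negative_set`.
#' @export
select_reference_baselines <- function(model, negative_set, n = 3L,
                                       representations = NULL) {
  if (length(negative_set) < n)
    stop("negative set smaller than the requested number of baselines")
  R <- if (is.null(representations))
    model_representations(model, negative_set) else representations
  med <- apply(R, 2L, stats::median)
  d <- sqrt(rowSums((R - rep(med, each = nrow(R)))^2))
  idx <- order(d, seq_along(d))[seq_len(n)]
  structure(negative_set[idx], index = idx)
}

# trim or repeated-crop a baseline token-id vector to a target content
# length (ids exclude CLS/SEP here)
fit_baseline_ids <- function(ids, target_len) {
  n <- length(ids)
  if (n >= target_len) return(ids[seq_len(target_len)])
  rep_len(ids, target_len)
}

#' Integrated-gradients attribution over 6-mer tokens
#'
#' Straight-line path in token-embedding space from each baseline embedding
#' to the input embedding; Riemann-sum (midpoint) gradient integration with
#' `steps` steps; per-token attribution is the path-averaged gradient times
#' the embedding displacement, summed over embedding dimensions, then
#' averaged over baselines. Supports the mini-LM (model function =
#' probability of the positive class) or any custom model exposing
#' `embed(tokens)`, `f(X)`, `grad(X)`.
#'
#' @param model a `mini_lm` scorer model, or a list with `embed`, `f`,
#'   `grad` for surrogate models.
#' @param sequence input RNA sequence.
#' @param baselines character vector of baseline sequences.
#' @param steps number of integration steps (default 200).
#' @param motif_span optional c(start, end) motif interval (nt coordinates);
#'   attributions of 6-mers overlapping it are zeroed.
#' @param target classifier head column for the class of interest
#'   (mini-LM only; default the last, the positive class).
#' @return list of class `attribution_profile`: `token_attr` (one scalar per
#'   content token), `kmers`, `token_start` (nt start of each token),
#'   `completeness` (per-baseline sum of attributions and model-output
#'   difference), `motif_span`.
#' @export
integrated_attributions <- function(model, sequence, baselines, steps = 200L,
                                    motif_span = NULL, target = NULL) {
  if (steps < 1L) stop("steps must be >= 1")
  is_mini <- inherits(model, "mini_lm")
  if (is_mini) {
    vocab <- model$vocab
    ids_full <- encode_sequence(sequence, vocab,
                                max_tokens = model$cfg$max_len - 2L)
    content <- ids_full[-c(1L, length(ids_full))]
    Tn <- length(content)
    if (is.null(target)) target <- ncol(model$params$cls$W)
    base_ids <- lapply(baselines, function(b) {
      idsb <- encode_sequence(b, vocab, max_tokens = model$cfg$max_len - 2L)
      fit_baseline_ids(idsb[-c(1L, length(idsb))], Tn)
    })
    ids_mat <- matrix(ids_full, 1L)
    mask <- matrix(TRUE, 1L, length(ids_full))
    emb_of <- function(ids) model$params$tok_emb[ids, , drop = FALSE]
    x_in <- emb_of(ids_full)
    f_grad <- function(E) {
      r <- classifier_prob_grad(model, ids_mat, mask, target = target,
                                input_emb = E)
      list(f = r$prob, g = r$dX0)
    }
  } else {
    x_in <- model$embed(sequence)
    Tn <- nrow(x_in) - if (!is.null(model$n_special)) model$n_special else 0L
    f_grad <- function(E) list(f = model$f(E), g = model$grad(E))
  }
  n_base <- length(baselines)
  attr_mat <- matrix(0, n_base, if (is_mini) Tn else nrow(x_in))
  completeness <- data.frame(baseline = seq_len(n_base), attr_sum = 0,
                             f_diff = 0)
  for (bi in seq_len(n_base)) {
    x0 <- if (is_mini) {
      e <- x_in
      e[2:(Tn + 1L), ] <- emb_of(base_ids[[bi]])
      e                       # [CLS]/[SEP] rows shared between endpoints
    } else model$embed(baselines[bi])
    diff <- x_in - x0
    grad_sum <- matrix(0, nrow(x_in), ncol(x_in))
    for (s in seq_len(steps)) {
      alpha <- (s - 0.5) / steps
      grad_sum <- grad_sum + f_grad(x0 + alpha * diff)$g
    }
    avg_grad <- grad_sum / steps
    per_row <- rowSums(avg_grad * diff)
    rows <- if (is_mini) 2:(Tn + 1L) else seq_len(nrow(x_in))
    attr_mat[bi, ] <- per_row[rows]
    completeness$attr_sum[bi] <- sum(per_row)
    completeness$f_diff[bi] <- f_grad(x_in)$f - f_grad(x0)$f
  }
  token_attr <- colMeans(attr_mat)
  k <- if (is_mini) vocab$k else NA_integer_
  token_start <- seq_along(token_attr)
  kmers <- if (is_mini)
    substring(normalize_rna(sequence), token_start, token_start + k - 1L)
  else rep(NA_character_, length(token_attr))
  if (!is.null(motif_span) && is_mini) {
    tok_end <- token_start + k - 1L
    overlap <- token_start <= motif_span[2L] & tok_end >= motif_span[1L]
    token_attr[overlap] <- 0
  }
  structure(list(token_attr = token_attr, kmers = kmers,
                 token_start = token_start, motif_span = motif_span,
                 completeness = completeness, k = k),
            class = "attribution_profile")
}

#' Flag significantly attributed k-mer tokens
#'
#' Two-sided t-test of each token's attribution scores against a random
#' reference set of token attributions, Benjamini-Hochberg adjusted across
#' tokens; flags set at q < alpha. Degenerate (zero-variance, identical)
#' comparisons short-circuit to p = 1.
#'
#' @param token_scores named list: one numeric vector of attribution
#'   observations per token (>= 2 observations each).
#' @param random_token_scores numeric reference attribution sample.
#' @param alpha FDR threshold (default 0.05).
#' @return data.frame: token, mean_attr, p, q, significant.
#' @export
significant_kmers <- function(token_scores, random_token_scores,
                              alpha = 0.05) {
  if (!length(random_token_scores)) stop("empty reference set")
  p <- vapply(token_scores, function(x) {
    if (length(x) < 2L) stop("need >= 2 observations per token")
    if (stats::sd(x) == 0 && stats::sd(random_token_scores) == 0 &&
        isTRUE(all.equal(mean(x), mean(random_token_scores)))) return(1)
    if (stats::sd(x) == 0 && stats::sd(random_token_scores) == 0)
      return(0)
    stats::t.test(x, random_token_scores)$p.value
  }, 0)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(token = names(token_scores),
             mean_attr = vapply(token_scores, mean, 0),
             p = p, q = q, significant = q < alpha, row.names = NULL)
}

#' Project significant 6-mer attributions onto positions / short k-mers
#'
#' Each nucleotide (k = 1), 2-mer or 3-mer receives the maximum attribution
#' over the significant 6-mer tokens covering it; positions covered only by
#' non-significant tokens score 0. Restricted to `flank` nt on each side of
#' the motif; positions inside the motif score 0.
#'
#' @param profile an `attribution_profile`.
#' @param significant logical vector aligned with `profile$token_attr`.
#' @param k projection size (1, 2 or 3).
#' @param flank window half-width around the motif (default 20 nt).
#' @return data.frame: position (start of the k-mer, nt coordinates),
#'   rel_position (relative to the motif span; negative = upstream), kmer,
#'   score.
#' @export
positional_attribution <- function(profile, significant, k = 1L,
                                   flank = 20L) {
  stopifnot(k %in% 1:3, length(significant) == length(profile$token_attr))
  span <- profile$motif_span
  if (is.null(span)) stop("profile lacks a motif span")
  tok_k <- profile$k
  L <- max(profile$token_start) + tok_k - 1L
  pos <- setdiff(seq_len(L - k + 1L),
                 (span[1L] - k + 1L):span[2L])   # k-mers overlapping motif: 0
  pos <- pos[pos >= span[1L] - flank & pos + k - 1L <= span[2L] + flank]
  pos <- pos[pos >= 1L]
  score <- vapply(pos, function(p) {
    cover <- profile$token_start <= p &
      profile$token_start + tok_k - 1L >= p + k - 1L
    cover <- cover & significant
    if (!any(cover)) 0 else max(profile$token_attr[cover])
  }, 0)
  rel <- ifelse(pos < span[1L], pos - span[1L], pos - span[2L])
  data.frame(position = pos, rel_position = rel,
             kmer = substring(paste(profile$kmers[1L],
                                    paste(substring(profile$kmers[-1L],
                                                    tok_k, tok_k),
                                          collapse = ""), sep = ""),
                              pos, pos + k - 1L),
             score = score)
}

#' Flank G<->C perturbation scan
#'
#' For every G and C within up to `flank` nt on each side of the canonical
#' motif of each high-confidence rG4 sequence, scores one mutant carrying
#' the single G->C or C->G substitution and aggregates the mean delta by
#' (mutation type, position relative to the motif). A and U positions are
#' never perturbed. Sequences without a canonical motif are skipped with a
#' warning.
#'
#' @param scorer probabilistic `g4_scorer`.
#' @param sequences character vector.
#' @param motif_spans list of c(start, end) per sequence (NULL entries are
#'   located with [find_motifs()]).
#' @param flank flank width (default 60).
#' @param min_wt minimum wild-type score to include a sequence (default 0.7).
#' @return list of class `perturbation_summary`: `cells` data.frame
#'   (mutation, rel_position, mean_delta, n) and `records` per-perturbation
#'   rows.
#' @export
flank_perturbation <- function(scorer, sequences, motif_spans = NULL,
                               flank = 60L, min_wt = 0.7) {
  recs <- list()
  skipped <- 0L
  for (i in seq_along(sequences)) {
    s <- normalize_rna(sequences[i])
    span <- if (!is.null(motif_spans) && !is.null(motif_spans[[i]]))
      motif_spans[[i]]
    else {
      m <- find_motifs(s, "CANONICAL")
      if (!nrow(m)) NULL else c(m$start[1L], m$end[1L])
    }
    if (is.null(span)) { skipped <- skipped + 1L; next }
    wt <- score_sequences(scorer, s)
    if (wt <= min_wt) next
    L <- nchar(s)
    pos <- c(seq.int(max(1L, span[1L] - flank), span[1L] - 1L),
             seq.int(span[2L] + 1L, min(L, span[2L] + flank)))
    pos <- pos[pos >= 1L & pos <= L]
    ch <- substring(s, pos, pos)
    keep <- ch %in% c("G", "C")
    pos <- pos[keep]; ch <- ch[keep]
    if (!length(pos)) next
    muts <- vapply(seq_along(pos), function(j) {
      m <- s
      substr(m, pos[j], pos[j]) <- if (ch[j] == "G") "C" else "G"
      m
    }, "")
    sc <- score_sequences(scorer, muts)
    rel <- ifelse(pos < span[1L], pos - span[1L], pos - span[2L])
    recs[[length(recs) + 1L]] <- data.frame(
      seq_index = i,
      mutation = ifelse(ch == "G", "G->C", "C->G"),
      position = pos, rel_position = rel, delta = sc - wt)
  }
  if (skipped)
    warning(skipped, " sequence(s) without a canonical motif skipped")
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(seq_index = integer(), mutation = character(),
               position = integer(), rel_position = integer(),
               delta = numeric())
  cells <- if (nrow(records)) {
    agg <- stats::aggregate(delta ~ mutation + rel_position, records,
                            function(x) c(mean = mean(x), n = length(x)))
    data.frame(mutation = agg$mutation, rel_position = agg$rel_position,
               mean_delta = agg$delta[, "mean"], n = agg$delta[, "n"])
  } else data.frame(mutation = character(), rel_position = integer(),
                    mean_delta = numeric(), n = numeric())
  structure(list(cells = cells, records = records),
            class = "perturbation_summary")
}
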