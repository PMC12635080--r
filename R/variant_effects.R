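# Delta-score computation for variants, categorical calls under the two
# published threshold schemes, per-variant reduction and the
# negative-background FDR estimator.

#' Window policy for variant-centric and transcriptome scanning
#'
#' @param window window size in nt (default 70).
#' @param stride stride for sliding-window transcript scans (default 10;
#'   irrelevant for variant-centered scoring).
#' @param mode "variant_centered" or "sliding".
#' @return list of class `window_policy`.
#' @export
window_policy <- function(window = 70L, stride = 10L,
                          mode = c("variant_centered", "sliding")) {
  mode <- match.arg(mode)
  list(window = as.integer(window), stride = as.integer(stride), mode = mode)
}

variant_window <- function(L, position, window) {
  half <- window %/% 2L
  ws <- position - half + (1L - window %% 2L)
  ws <- max(1L, min(ws, L - window + 1L))
  ws <- max(1L, ws)
  we <- min(L, ws + window - 1L)
  c(ws, we)
}

#' Delta score of a variant on a transcript
#'
#' Scores identically-placed windows containing the variant on the wild-type
#' and mutated sequence with a probabilistic scorer; delta is mutant minus
#' wild-type.
#'
#' @param scorer probabilistic `g4_scorer`.
#' @param tx a `transcript`.
#' @param variant a `sequence_variant`.
#' @param policy a [window_policy()].
#' @param scheme threshold scheme used for the categorical call
#'   ("GNOMAD" or "PMBB").
#' @return one-row data.frame (a delta record): transcript_id, position,
#'   ref, alt, wt_score, mut_score, delta, category, scheme.
#' @export
delta_score <- function(scorer, tx, variant, policy = window_policy(),
                        scheme = c("GNOMAD", "PMBB")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(scorer, "g4_scorer"))
  if (scorer$type != "probabilistic")
    stop("delta_score requires a probabilistic scorer")
  wt_seq <- tx$sequence
  mut_seq <- apply_variant(tx, variant)   # also validates ref
  span <- variant_window(nchar(wt_seq), variant$position, policy$window)
  wt <- score_sequences(scorer, substr(wt_seq, span[1L], span[2L]))
  mut <- score_sequences(scorer, substr(mut_seq, span[1L], span[2L]))
  delta <- mut - wt
  rec <- data.frame(transcript_id = tx$id, position = variant$position,
                    ref = variant$ref, alt = variant$alt,
                    wt_score = wt, mut_score = mut, delta = delta,
                    category = NA_character_, scheme = scheme)
  rec$category <- categorize(rec, scheme)
  rec
}

#' Categorical call for a delta record under a named threshold scheme
#'
#' GNOMAD scheme: BREAKING iff wild-type score > 0.7 and mutant score < 0.3;
#' NON_BREAKING iff wild-type > 0.7 and |delta| <= 0.02; otherwise OTHER.
#' PMBB scheme: BREAKING iff wild-type > 0.5 and delta <= -0.2; FORMING iff
#' wild-type < 0.5 and delta >= +0.2; otherwise OTHER. Records matching
#' neither band are retained as OTHER for auditability.
#'
#' @param record data.frame with wt_score, mut_score, delta (vectorized).
#' @param scheme "GNOMAD" or "PMBB".
#' @return character vector of categories.
#' @export
categorize <- function(record, scheme = c("GNOMAD", "PMBB")) {
  scheme <- match.arg(scheme)
  wt <- record$wt_score; mut <- record$mut_score; d <- record$delta
  stopifnot(all(wt >= 0 & wt <= 1), all(mut >= 0 & mut <= 1))
  if (scheme == "GNOMAD") {
    ifelse(wt > 0.7 & mut < 0.3, "BREAKING",
           ifelse(wt > 0.7 & abs(d) <= 0.02, "NON_BREAKING", "OTHER"))
  } else {
    ifelse(wt > 0.5 & d <= -0.2, "BREAKING",
           ifelse(wt < 0.5 & d >= 0.2, "FORMING", "OTHER"))
  }
}

#' Reduce per-transcript delta records to one per variant
#'
#' Retains, for each variant key, the record with the minimum delta (the
#' most disruptive transcript instance); ties break by lexicographic
#' transcript id.
#'
#' @param records data.frame of delta records with columns position, ref,
#'   alt, transcript_id, delta (and any others, carried through).
#' @param key columns identifying a variant (default position/ref/alt).
#' @return data.frame with one row per variant.
#' @export
reduce_min_delta <- function(records, key = c("position", "ref", "alt")) {
  if (!nrow(records)) stop("empty record set")
  kf <- interaction(records[key], drop = TRUE)
  picks <- vapply(split(seq_len(nrow(records)), kf), function(i) {
    i[order(records$delta[i], records$transcript_id[i])][1L]
  }, 0L)
  out <- records[sort(picks), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the false discovery rate on an rG4-free background
#'
#' Scores sliding windows over transcripts assumed to contain no true rG4
#' and reports the fraction of windows exceeding the probability threshold
#' (high-scoring predictions are false positives by construction). The
#' denominator counts windows, not transcripts.
#'
#' @param scorer probabilistic `g4_scorer`.
#' @param negative_transcripts list of `transcript` objects (or character
#'   sequences).
#' @param threshold false-positive call threshold (default 0.7).
#' @param policy a [window_policy()]; the sliding mode is used.
#' @return list with `fdr`, `n_windows`, `n_positive`.
#' @export
estimate_fdr <- function(scorer, negative_transcripts, threshold = 0.7,
                         policy = window_policy(mode = "sliding")) {
  seqs <- vapply(negative_transcripts, function(tx)
    if (inherits(tx, "transcript")) tx$sequence else normalize_rna(tx), "")
  wins <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L <= policy$window) return(s)
    st <- unique(c(seq.int(1L, L - policy$window + 1L, by = policy$stride),
                   L - policy$window + 1L))
    substring(s, st, st + policy$window - 1L)
  }))
  if (!length(wins)) stop("no windows scored")
  sc <- score_sequences(scorer, wins)
  list(fdr = mean(sc > threshold), n_windows = length(wins),
       n_positive = sum(sc > threshold))
}
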