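#' Default decision thresholds for the reference scorers
#'
#' @param cgcc cGcC detection threshold (default 4.5).
#' @param g4hunter G4Hunter detection threshold (default 0.9).
#' @param probability probability threshold for probabilistic scorers.
#' @return named list.
#' @export
scorer_thresholds <- function(cgcc = 4.5, g4hunter = 0.9,
                              probability = 0.5) {
  stopifnot(is.finite(cgcc), is.finite(g4hunter), is.finite(probability))
  list(cgcc = cgcc, g4hunter = g4hunter, probability = probability)
}

#' G4Hunter per-base scores
#'
#' Each base inside a maximal G-run of length l scores min(l, 4); each base
#' of a C-run scores -min(l, 4); A and U score 0.
#'
#' @param sequence normalized RNA sequence.
#' @return integer vector, one score per base.
#' @export
g4hunter_base_scores <- function(sequence) {
  sequence <- normalize_rna(sequence)
  ch <- strsplit(sequence, "")[[1L]]
  r <- rle(ch)
  val <- ifelse(r$values == "G", pmin(r$lengths, 4L),
                ifelse(r$values == "C", -pmin(r$lengths, 4L), 0L))
  rep(as.integer(val), r$lengths)
}

new_score_profile <- function(scorer_name, window_size, starts, scores) {
  structure(list(scorer_name = scorer_name,
                 window_size = as.integer(window_size),
                 window_starts = as.integer(starts),
                 window_scores = as.numeric(scores),
                 sequence_score = max(scores)),
            class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat(sprintf("<score_profile %s> window %d, %d window(s), max %.4g\n",
              x$scorer_name, x$window_size, length(x$window_scores),
              x$sequence_score))
  invisible(x)
}

window_starts <- function(L, window) {
  if (L <= window) 1L else seq_len(L - window + 1L)
}

#' G4Hunter sliding-window score profile
#'
#' The window score is the arithmetic mean of [g4hunter_base_scores()] over
#' the window; the sequence score is the maximum over windows. When the
#' sequence is shorter than the window, the single window is the whole
#' sequence.
#'
#' @param sequence RNA sequence.
#' @param window window size in nt (default 60).
#' @return a `score_profile`.
#' @export
g4hunter_score <- function(sequence, window = 60L) {
  base <- g4hunter_base_scores(sequence)
  L <- length(base)
  w <- min(window, L)
  cs <- cumsum(c(0, base))
  st <- window_starts(L, window)
  sc <- (cs[st + w] - cs[st]) / w
  new_score_profile("g4hunter", window, st, sc)
}

#' cGcC sliding-window score profile
#'
#' Ratio-type scorer: within each window, maximal G-runs and C-runs are
#' weighted by run length (per-base weights for runs of length 1, 2 and >= 3,
#' defaults 10/20/30) and the score is
#' (G-weight + pseudocount) / (C-weight + pseudocount).
#' The sequence score is the maximum over windows.
#'
#' @param sequence RNA sequence.
#' @param window window size in nt (default 60).
#' @param weights per-base run weights, indexed by capped run length.
#' @param pseudocount added to numerator and denominator (default 1).
#' @return a `score_profile`.
#' @export
cgcc_score <- function(sequence, window = 60L, weights = c(10, 20, 30),
                       pseudocount = 1) {
  sequence <- normalize_rna(sequence)
  ch <- strsplit(sequence, "")[[1L]]
  L <- length(ch)
  w <- min(window, L)
  st <- window_starts(L, window)
  run_weight <- function(sub, base) {
    r <- rle(sub)
    sel <- r$values == base
    if (!any(sel)) return(0)
    len <- r$lengths[sel]
    sum(len * weights[pmin(len, length(weights))])
  }
  sc <- vapply(st, function(s) {
    sub <- ch[s:(s + w - 1L)]
    gs <- run_weight(sub, "G"); cs <- run_weight(sub, "C")
    (gs + pseudocount) / (cs + pseudocount)
  }, 0)
  new_score_profile("cgcc", window, st, sc)
}

#' Construct a scorer object
#'
#' The common scorer contract used by every downstream stage: a scorer is a
#' named object exposing `score_sequences(seqs)` returning one scalar per
#' sequence. `type` is "probabilistic" (scores in [0, 1]) or "raw"
#' (scorer-native scale); downstream threshold schemes are scheme-specific
#' and never unit-converted.
#'
#' @param name scorer name.
#' @param type "probabilistic" or "raw".
#' @param score_sequences function(character vector) -> numeric vector.
#' @param model optional underlying model object.
#' @return object of class `g4_scorer`.
#' @export
new_scorer <- function(name, type, score_sequences, model = NULL) {
  stopifnot(type %in% c("probabilistic", "raw"), is.function(score_sequences))
  structure(list(name = name, type = type,
                 score_sequences = score_sequences, model = model),
            class = "g4_scorer")
}

#' @export
print.g4_scorer <- function(x, ...) {
  cat(sprintf("<g4_scorer %s> (%s)\n", x$name, x$type))
  invisible(x)
}

#' Score sequences with any scorer
#'
#' @param scorer a `g4_scorer`.
#' @param sequences character vector.
#' @return numeric vector of sequence scores.
#' @export
score_sequences <- function(scorer, sequences) {
  stopifnot(inherits(scorer, "g4_scorer"))
  out <- scorer$score_sequences(as.character(sequences))
  if (scorer$type == "probabilistic" &&
      any(out < -1e-9 | out > 1 + 1e-9, na.rm = TRUE))
    stop("probabilistic scorer ", scorer$name, " returned scores outside [0,1]")
  out
}

#' Reference scorers wrapped in the common contract
#'
#' `g4hunter_scorer()` and `cgcc_scorer()` expose the window scorers on their
#' native scales; `oracle_scorer()` is the exact rule engine (probability 1
#' when the canonical four-G-run pattern is present, 0 otherwise), used as a
#' deterministic stand-in for a trained model in tests and FDR estimation.
#'
#' @param window window size in nt.
#' @param config a [pattern_config()] (oracle only).
#' @return a `g4_scorer`.
#' @export
g4hunter_scorer <- function(window = 60L) {
  new_scorer("g4hunter", "raw", function(seqs)
    vapply(seqs, function(s) g4hunter_score(s, window)$sequence_score, 0,
           USE.NAMES = FALSE))
}

#' @rdname g4hunter_scorer
#' @export
cgcc_scorer <- function(window = 60L) {
  new_scorer("cgcc", "raw", function(seqs)
    vapply(seqs, function(s) cgcc_score(s, window)$sequence_score, 0,
           USE.NAMES = FALSE))
}

#' @rdname g4hunter_scorer
#' @export
oracle_scorer <- function(config = pattern_config()) {
  new_scorer("oracle", "probabilistic", function(seqs)
    vapply(seqs, function(s)
      as.numeric(nrow(find_motifs(s, "CANONICAL", config)) > 0L), 0,
      USE.NAMES = FALSE))
}

#' Score a FASTA/character set with a scorer, profile-style
#'
#' @param scorer a `g4_scorer` built from a window scorer, or the name
#'   "g4hunter"/"cgcc".
#' @param sequences named character vector.
#' @param window window size.
#' @return data.frame: id, scorer, window, max_score, argmax_start.
#' @export
score_table <- function(scorer, sequences, window = 60L) {
  profs <- switch(if (is.character(scorer)) scorer else scorer$name,
    g4hunter = lapply(sequences, g4hunter_score, window = window),
    cgcc = lapply(sequences, cgcc_score, window = window),
    stop("score_table supports the g4hunter and cgcc window scorers"))
  data.frame(
    id = if (is.null(names(sequences))) as.character(seq_along(sequences))
         else names(sequences),
    scorer = vapply(profs, `[[`, "", "scorer_name"),
    window = vapply(profs, `[[`, 0L, "window_size"),
    max_score = vapply(profs, `[[`, 0, "sequence_score"),
    argmax_start = vapply(profs, function(p)
      p$window_starts[which.max(p$window_scores)], 0L),
    row.names = NULL)
}
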