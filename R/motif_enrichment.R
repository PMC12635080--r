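# Flank extraction around canonical motifs, PWM scanning with an exact null
# distribution, and the log2 fold-enrichment statistic with Fisher/BH
# filtering.

#' Construct a position probability matrix (PWM)
#'
#' @param id motif identifier.
#' @param matrix 4 x L numeric matrix, rows A/C/G/U, columns summing to 1.
#' @return object of class `pwm`.
#' @export
pwm <- function(id, matrix) {
  matrix <- as.matrix(matrix)
  stopifnot(nrow(matrix) == 4L, all(matrix >= 0))
  if (any(abs(colSums(matrix) - 1) > 1e-6))
    stop("PWM columns must sum to 1")
  rownames(matrix) <- c("A", "C", "G", "U")
  structure(list(id = as.character(id), matrix = matrix,
                 length = ncol(matrix)), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s> length %d\n", x$id, x$length))
  invisible(x)
}

#' Read PWMs from a MEME minimal-format motif file
#'
#' @param path file path.
#' @return named list of `pwm` objects.
#' @export
read_meme_pwms <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path)
  starts <- grep("^MOTIF\\s", lines)
  out <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    h <- grep("^letter-probability matrix", lines[(s + 1L):length(lines)])[1L]
    h <- s + h
    w <- sub(".*w=\\s*(\\d+).*", "\\1", lines[h])
    w <- as.integer(w)
    block <- lines[(h + 1L):(h + w)]
    mat <- vapply(block, function(ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1L]])[1:4], numeric(4))
    out[[id]] <- pwm(id, unname(mat))
  }
  out
}

#' Write PWMs in MEME minimal format
#'
#' @param pwms named list of `pwm` objects.
#' @param path output path.
#' @export
write_meme_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 U 0.25", ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      p$length), con)
    for (j in seq_len(p$length))
      writeLines(paste(sprintf("%.6f", p$matrix[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

# log-odds column scores vs a uniform background, with pseudocount
pwm_log_odds <- function(p, pseudocount = 1e-3, background = 0.25) {
  log2((p$matrix + pseudocount) / (1 + 4 * pseudocount) / background)
}

#' Exact null distribution of PWM log-odds scores
#'
#' Under a uniform i.i.d. background, the log-odds score of a random window
#' is a sum of independent per-column draws. The distribution is computed
#' exactly by discretising column scores to a fixed grid (default 1e-3) and
#' convolving column by column.
#'
#' @param p a `pwm`.
#' @param pseudocount log-odds pseudocount.
#' @param grid discretisation step for the score axis.
#' @return list with `score` (grid values) and `prob`.
#' @export
pwm_null_distribution <- function(p, pseudocount = 1e-3, grid = 1e-3) {
  lo <- round(pwm_log_odds(p, pseudocount) / grid)
  offset <- sum(apply(lo, 2L, min))
  width <- sum(apply(lo, 2L, max)) - offset + 1L
  prob <- numeric(width)
  prob[1L] <- 1
  cur_min <- 0L
  for (j in seq_len(ncol(lo))) {
    nxt <- numeric(width)
    cmin <- min(lo[, j])
    for (b in 1:4) {
      sh <- lo[b, j] - cmin
      nxt[(1L + sh):width] <- nxt[(1L + sh):width] +
        0.25 * prob[1:(width - sh)]
    }
    prob <- nxt
    cur_min <- cur_min + cmin
  }
  list(score = (seq_len(width) - 1L + offset) * grid, prob = prob)
}

#' Score threshold for a PWM at a null p-value
#'
#' Smallest score s with P(S >= s) < p under the exact null.
#'
#' @param p a `pwm`.
#' @param p_value tail probability (default 1e-4).
#' @param pseudocount,grid passed to [pwm_null_distribution()].
#' @return scalar threshold (Inf when no score is that extreme).
#' @export
pwm_score_threshold <- function(p, p_value = 1e-4, pseudocount = 1e-3,
                                grid = 1e-3) {
  nd <- pwm_null_distribution(p, pseudocount, grid)
  tail <- rev(cumsum(rev(nd$prob)))
  ok <- which(tail < p_value)
  if (!length(ok)) return(Inf)
  nd$score[ok[1L]]
}

#' Scan flank sequences with a PWM
#'
#' Log-odds scoring against a uniform background at every offset; a
#' sequence "has the motif" when any offset reaches the threshold policy
#' (default: null p < 1e-4 under the exact score distribution). Flanks
#' shorter than the motif simply yield no hit.
#'
#' @param flanks character vector of flank sequences.
#' @param p a `pwm`.
#' @param p_value threshold policy (null tail probability).
#' @param threshold explicit score threshold overriding `p_value`.
#' @param pseudocount log-odds pseudocount.
#' @return list with `has_hit` (logical per sequence) and `hits`
#'   (data.frame: seq_index, offset, score).
#' @export
pwm_scan <- function(flanks, p, p_value = 1e-4, threshold = NULL,
                     pseudocount = 1e-3) {
  if (is.null(threshold))
    threshold <- pwm_score_threshold(p, p_value, pseudocount)
  lo <- pwm_log_odds(p, pseudocount)
  W <- p$length
  hits <- list()
  has_hit <- logical(length(flanks))
  for (i in seq_along(flanks)) {
    s <- flanks[i]
    L <- nchar(s)
    if (L < W) next
    ch <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "U"))
    sc <- vapply(seq_len(L - W + 1L), function(o)
      sum(lo[cbind(ch[o:(o + W - 1L)], seq_len(W))]), 0)
    hit <- which(sc >= threshold)
    if (length(hit)) {
      has_hit[i] <- TRUE
      hits[[length(hits) + 1L]] <- data.frame(seq_index = i, offset = hit,
                                              score = sc[hit])
    }
  }
  list(has_hit = has_hit,
       hits = if (length(hits)) do.call(rbind, hits) else
         data.frame(seq_index = integer(), offset = integer(),
                    score = numeric()),
       threshold = threshold)
}

#' Split sequences into rG4-forming and non-forming flank sets
#'
#' Sequences are scored with a probabilistic scorer; those above `form_thr`
#' contribute their motif flanks to the forming set, those below
#' `nonform_thr` to the non-forming set, and the band in between is
#' excluded. Both flanks of one motif are one flanking-sequence unit: they
#' are concatenated (motif excluded) so "unique sequences with a hit" counts
#' rG4 loci.
#'
#' @param sequences character vector, each containing a canonical motif.
#' @param scores precomputed sequence scores (or NULL to compute with
#'   `scorer`).
#' @param scorer probabilistic `g4_scorer` used when `scores` is NULL.
#' @param form_thr,nonform_thr thresholds (defaults 0.7 / 0.3).
#' @param config a [pattern_config()].
#' @return list with `forming`, `nonforming` (character vectors of flank
#'   units) and `excluded` count.
#' @export
split_forming_flanks <- function(sequences, scores = NULL, scorer = NULL,
                                 form_thr = 0.7, nonform_thr = 0.3,
                                 config = pattern_config()) {
  sequences <- normalize_rna(sequences)
  if (is.null(scores)) {
    stopifnot(!is.null(scorer))
    scores <- score_sequences(scorer, sequences)
  }
  stopifnot(length(scores) == length(sequences))
  forming <- character(); nonforming <- character()
  skipped <- 0L; excluded <- 0L
  for (i in seq_along(sequences)) {
    m <- find_motifs(sequences[i], "CANONICAL", config)
    if (!nrow(m)) { skipped <- skipped + 1L; next }
    L <- nchar(sequences[i])
    fl <- paste0(substr(sequences[i], 1L, m$start[1L] - 1L),
                 substr(sequences[i], m$end[1L] + 1L, L))
    if (scores[i] > form_thr) forming <- c(forming, fl)
    else if (scores[i] < nonform_thr) nonforming <- c(nonforming, fl)
    else excluded <- excluded + 1L
  }
  if (skipped)
    warning(skipped, " sequence(s) without a canonical motif skipped")
  list(forming = forming, nonforming = nonforming, excluded = excluded)
}

#' Motif enrichment in forming vs non-forming flanks
#'
#' For each PWM: unique-sequence hit counts in both groups, log2 fold
#' enrichment of hit fractions with an epsilon guard,
#' log2((f_forming + eps) / (f_nonforming + eps)), a one-sided Fisher exact
#' test on the 2x2 table (enrichment in the forming group), and BH
#' correction across motifs. Reported rows satisfy the hit, q and
#' fold-change filters; the full table is returned with a `reported` flag.
#'
#' @param forming,nonforming character vectors of flank units.
#' @param pwms named list of `pwm` objects.
#' @param epsilon numerical-stability constant (default 1e-6).
#' @param min_hits minimum total hits across groups (default 5).
#' @param q_max,fc_min report filters (defaults 0.05 and 1).
#' @param p_value PWM scan threshold policy.
#' @return data.frame: motif, n_forming_with_hit, n_forming_total,
#'   n_nonforming_with_hit, n_nonforming_total, log2_fc, p, q, reported.
#' @export
enrich <- function(forming, nonforming, pwms, epsilon = 1e-6,
                   min_hits = 5L, q_max = 0.05, fc_min = 1,
                   p_value = 1e-4) {
  nf <- length(forming); nn <- length(nonforming)
  if (nf == 0L || nn == 0L) stop("both groups must be non-empty")
  rows <- lapply(pwms, function(p) {
    hf <- sum(pwm_scan(forming, p, p_value)$has_hit)
    hn <- sum(pwm_scan(nonforming, p, p_value)$has_hit)
    log2_fc <- log2((hf / nf + epsilon) / (hn / nn + epsilon))
    tab <- matrix(c(hf, nf - hf, hn, nn - hn), 2L)
    pv <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(motif = p$id, n_forming_with_hit = hf, n_forming_total = nf,
               n_nonforming_with_hit = hn, n_nonforming_total = nn,
               log2_fc = log2_fc, p = pv)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$reported <- (out$n_forming_with_hit + out$n_nonforming_with_hit) >=
    min_hits & out$q < q_max & out$log2_fc > fc_min
  out
}
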