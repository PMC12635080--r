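# Seeded generators producing every input the other modules need, with
# known ground truth. All generators are pure functions of (parameters,
# seed).

sample_bases <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, U = (1 - gc) / 2)
  sample(names(probs), n, replace = TRUE, prob = probs)
}

random_loop <- function(len) {
  # loops avoid G so planted run structure is exactly as designed
  paste(sample(c("A", "C", "U"), len, replace = TRUE), collapse = "")
}

# remove canonical motifs outside a protected span by switching one G of
# the motif's first G-run (outside the span) to C; used so transcripts
# planted with non-canonical patterns carry no accidental canonical rG4
scrub_canonical_outside <- function(s, keep, config = pattern_config()) {
  repeat {
    m <- find_motifs(s, "CANONICAL", config)
    m <- m[m$end < keep[1L] | m$start > keep[2L], , drop = FALSE]
    if (!nrow(m)) return(s)
    sub <- substr(s, m$start[1L], m$end[1L])
    g3 <- regexpr("GGG", sub, fixed = TRUE)
    p <- m$start[1L] + as.integer(g3)  # middle G of the first run
    substr(s, p, p) <- "C"
  }
}

# remove every relaxed putative-G4 match from a sequence by switching one
# guanine of a GG dinucleotide inside the match to C; each edit destroys a
# G-run of length >= 2, so the loop terminates quickly, and the G+C content
# is untouched
scrub_g4_patterns <- function(s) {
  repeat {
    m <- relaxed_matches(s)
    if (!nrow(m)) return(s)
    sub <- substr(s, m$start[1L], m$end[1L])
    gg <- regexpr("GG", sub, fixed = TRUE)
    p <- m$start[1L] + as.integer(gg)  # second G of the first GG
    substr(s, p, p) <- "C"
  }
}

#' Generate one motif sequence from a subtype's pattern grammar
#'
#' @param subtype one of the structural subtype names (CANONICAL, LONGLOOP,
#'   BULGES, TWO_QUARTET, POTENTIAL_GQ_40, POTENTIAL_G_TRIPLEX_40,
#'   G_RICH_40, UNKNOWN).
#' @param config a [pattern_config()].
#' @return character motif sequence.
#' @export
generate_subtype_motif <- function(subtype, config = pattern_config()) {
  lo <- config$canonical_loop
  loops <- function(n, bounds = lo)
    vapply(sample(seq(bounds[1L], bounds[2L]), n, replace = TRUE),
           random_loop, "")
  runs <- function(n, len_min = 3L, len_max = 4L)
    vapply(sample(seq(len_min, len_max), n, replace = TRUE),
           function(l) strrep("G", l), "")
  switch(subtype,
    CANONICAL = {
      r <- runs(4L); l <- loops(3L)
      paste0(r[1L], l[1L], r[2L], l[2L], r[3L], l[3L], r[4L])
    },
    LONGLOOP = {
      r <- runs(4L); l <- loops(3L)
      which_long <- sample(3L, 1L)
      l[which_long] <- random_loop(sample(seq(config$longloop_loop[1L],
                                              config$longloop_loop[2L]), 1L))
      paste0(r[1L], l[1L], r[2L], l[2L], r[3L], l[3L], r[4L])
    },
    BULGES = {
      r <- runs(4L, 3L, 3L); l <- loops(3L)
      bi <- sample(4L, 1L)
      split_at <- sample(2L, 1L)   # G|GG or GG|G
      r[bi] <- paste0(strrep("G", split_at),
                      sample(c("A", "C", "U"), 1L),
                      strrep("G", 3L - split_at))
      paste0(r[1L], l[1L], r[2L], l[2L], r[3L], l[3L], r[4L])
    },
    TWO_QUARTET = {
      l <- loops(3L, config$two_quartet_loop)
      paste0("GG", l[1L], "GG", l[2L], "GG", l[3L], "GG")
    },
    POTENTIAL_GQ_40 = {
      # four G3 runs with one relaxed loop too long for the structural
      # classes but short enough to keep G content above the threshold
      l <- loops(3L, c(1L, 2L))
      li <- sample(3L, 1L)
      long_lo <- max(config$longloop_loop[2L], config$two_quartet_loop[2L]) + 1L
      l[li] <- random_loop(sample(seq(long_lo,
                                      min(long_lo + 3L,
                                          config$relaxed_loop[2L])), 1L))
      paste0("GGG", l[1L], "GGG", l[2L], "GGG", l[3L], "GGG")
    },
    POTENTIAL_G_TRIPLEX_40 = {
      r <- runs(3L); l <- loops(2L)
      paste0(r[1L], l[1L], r[2L], l[2L], r[3L])
    },
    G_RICH_40 = {
      # isolated Gs alternating with non-G: G-rich, no G-run of >= 2
      n <- sample(14:24, 1L)
      paste(vapply(seq_len(n), function(i)
        if (i %% 2L == 1L) "G" else sample(c("A", "U"), 1L), ""),
        collapse = "")
    },
    UNKNOWN = paste(sample(c("A", "U"), sample(14:24, 1L), replace = TRUE),
                    collapse = ""),
    RELAXED_NEG = {
      # matches the relaxed putative-G4 pattern (four G>=2 runs, loops up
      # to 30) but never the canonical one: runs of exactly two guanines
      l <- vapply(sample(1:9, 3L, replace = TRUE), random_loop, "")
      li <- sample(3L, 1L)
      l[li] <- random_loop(sample(10:20, 1L))
      paste0("GG", l[1L], "GG", l[2L], "GG", l[3L], "GG")
    },
    stop("unknown subtype ", subtype))
}

motif_self_class <- function(motif, subtype, config) {
  call <- classify_subtype(motif, config)
  call$subtype == subtype
}

#' Generate a labeled suite of standalone subtype sequences
#'
#' Each sequence is constructed from one subtype's grammar and re-rolled
#' until the hierarchical classifier's correct answer is that subtype (the
#' construction guarantees this after few tries; collisions arise only from
#' random loop content).
#'
#' @param n_per_class sequences per subtype.
#' @param subtypes subtype names (default all eight).
#' @param config a [pattern_config()].
#' @param seed RNG seed.
#' @return data.frame: sequence, subtype.
#' @export
generate_subtype_suite <- function(n_per_class = 25L,
                                   subtypes = SUBTYPE_LEVELS,
                                   config = pattern_config(), seed = 1L) {
  set.seed(seed)
  rows <- lapply(subtypes, function(st) {
    seqs <- character(n_per_class)
    for (i in seq_len(n_per_class)) {
      repeat {
        m <- generate_subtype_motif(st, config)
        if (motif_self_class(m, st, config)) break
      }
      seqs[i] <- m
    }
    data.frame(sequence = seqs, subtype = st)
  })
  do.call(rbind, rows)
}

#' Simulate a transcriptome with planted rG4 motifs
#'
#' Background bases are i.i.d. at the requested GC content; one motif per
#' transcript is drawn from the subtype mix, generated from that subtype's
#' grammar and planted at a recorded position with non-G buffer bases at
#' both boundaries. Plants whose local window does not classify to the
#' intended subtype are re-rolled.
#'
#' @param n number of transcripts.
#' @param length_dist transcript lengths: a single length, a vector sampled
#'   from, or a function(n) -> lengths.
#' @param gc background GC fraction (default 0.5).
#' @param subtype_mix named probabilities over subtypes (must sum to 1);
#'   default all canonical. The pseudo-class "RELAXED_NEG" plants sequences
#'   matching the relaxed putative-G4 pattern but not the canonical one,
#'   emulating background transcripts that feed the negative training set.
#' @param plant_prob probability a transcript carries a motif (default 1).
#' @param seed RNG seed.
#' @param config a [pattern_config()].
#' @return list: `transcripts` (named list of `transcript`), `truth`
#'   (data.frame transcript_id, start, end, subtype).
#' @export
simulate_transcriptome <- function(n = 50L, length_dist = 500L, gc = 0.5,
                                   subtype_mix = c(CANONICAL = 1),
                                   plant_prob = 1, seed = 1L,
                                   config = pattern_config()) {
  if (abs(sum(subtype_mix) - 1) > 1e-8)
    stop("subtype_mix must sum to 1")
  set.seed(seed)
  lens <- if (is.function(length_dist)) length_dist(n)
          else if (length(length_dist) == 1L) rep(length_dist, n)
          else sample(length_dist, n, replace = TRUE)
  txs <- list(); truth <- list()
  for (i in seq_len(n)) {
    id <- sprintf("tx%04d", i)
    L <- lens[i]
    bg <- sample_bases(L, gc)
    planted <- stats::runif(1) < plant_prob
    if (planted) {
      st <- sample(names(subtype_mix), 1L, prob = subtype_mix)
      repeat {
        motif <- generate_subtype_motif(st, config)
        ml <- nchar(motif)
        if (ml + 2L > L) stop("transcript too short for motif (", L, " nt)")
        pos <- sample.int(L - ml - 1L, 1L) + 1L
        seqv <- bg
        seqv[c(pos - 1L, pos + ml)] <- sample(c("A", "U"), 2L,
                                              replace = TRUE)
        seqv[pos:(pos + ml - 1L)] <- strsplit(motif, "")[[1L]]
        s <- paste(seqv, collapse = "")
        if (st != "CANONICAL")
          s <- scrub_canonical_outside(s, c(pos, pos + ml - 1L), config)
        # local window check: the plant must classify as intended
        win <- substr(s, max(1L, pos - 5L), min(L, pos + ml + 4L))
        if (st == "RELAXED_NEG") {
          if (nrow(relaxed_matches(win)) &&
              !nrow(find_motifs(win, "CANONICAL", config))) break
        } else if (classify_subtype(win, config)$subtype == st) break
      }
      txs[[id]] <- transcript(id, s)
      truth[[length(truth) + 1L]] <- data.frame(
        transcript_id = id, start = pos, end = pos + ml - 1L, subtype = st)
    } else {
      # motif-free background: scrub any relaxed putative-G4 match by
      # swapping one G of a GG dinucleotide to C (GC content preserved;
      # canonical motifs are a subset of relaxed matches)
      s <- scrub_g4_patterns(paste(bg, collapse = ""))
      txs[[id]] <- transcript(id, s)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(transcript_id = character(), start = integer(),
               end = integer(), subtype = character())
  list(transcripts = txs, truth = truth)
}

#' Simulate a variant table with selection structure
#'
#' Breaking variants substitute a G inside a planted motif's G-run with a
#' non-G base; neutral variants hit flank positions outside the motif. MAFs
#' are drawn per regime (defaults: breaking Beta(0.3, 30), neutral
#' Beta(0.5, 30); the "null" regime draws both from the neutral Beta).
#' Allele numbers are drawn near a configurable maximum; constraint Z and
#' raw CADD scores are drawn with a configurable mean shift for breaking
#' variants.
#'
#' @param sim output of [simulate_transcriptome()].
#' @param n_breaking,n_neutral variant counts.
#' @param regime "selection" or "null".
#' @param breaking_beta,neutral_beta Beta(shape1, shape2) MAF parameters.
#' @param max_an maximum sequenced alleles (default 152312).
#' @param cadd_shift mean raw-CADD elevation of breaking variants.
#' @param seed RNG seed.
#' @return data.frame: variant, transcript_id, pos, ref, alt, truth
#'   ("breaking"/"neutral"), MAF, AN, constraint_z, cadd_raw, region,
#'   rg4_length, subtype.
#' @export
simulate_variants <- function(sim, n_breaking = 200L, n_neutral = 200L,
                              regime = c("selection", "null"),
                              breaking_beta = c(0.3, 30),
                              neutral_beta = c(0.5, 30),
                              max_an = 152312L, cadd_shift = 2,
                              seed = 1L) {
  regime <- match.arg(regime)
  truth <- sim$truth
  if (!nrow(truth)) stop("no planted motifs to target")
  set.seed(seed)
  pick_row <- function() truth[sample.int(nrow(truth), 1L), ]
  mk <- function(kind, n) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        tr <- pick_row()
        tx <- sim$transcripts[[tr$transcript_id]]
        if (kind == "breaking") {
          gpos <- tr$start - 1L +
            which(strsplit(substr(tx$sequence, tr$start, tr$end),
                           "")[[1L]] == "G")
          if (!length(gpos)) next
          # require a substitution that actually destroys the planted
          # structure (e.g. the edge base of a G4 run leaves G3 intact and
          # is not a breaking variant)
          ws <- max(1L, tr$start - 5L)
          we <- min(nchar(tx$sequence), tr$end + 5L)
          win <- substr(tx$sequence, ws, we)
          alt <- sample(c("A", "C", "U"), 1L)
          p <- NA_integer_
          for (cand in gpos[sample.int(length(gpos))]) {
            mut <- win
            substr(mut, cand - ws + 1L, cand - ws + 1L) <- alt
            disrupts <- if (tr$subtype == "CANONICAL")
              !nrow(find_motifs(mut, "CANONICAL"))
            else TRUE   # non-canonical plants: any G-run hit counts
            if (disrupts) { p <- cand; break }
          }
          if (is.na(p)) next
          ref <- "G"
        } else {
          L <- nchar(tx$sequence)
          flank <- setdiff(seq_len(L),
                           max(1L, tr$start - 2L):min(L, tr$end + 2L))
          if (!length(flank)) next
          p <- flank[sample.int(length(flank), 1L)]
          ref <- substr(tx$sequence, p, p)
          alt <- sample(setdiff(c("A", "C", "G", "U"), ref), 1L)
        }
        break
      }
      out[[i]] <- data.frame(
        transcript_id = tr$transcript_id, pos = p, ref = ref, alt = alt,
        truth = kind, rg4_length = tr$end - tr$start + 1L,
        subtype = tr$subtype)
    }
    do.call(rbind, out)
  }
  tab <- rbind(mk("breaking", n_breaking), mk("neutral", n_neutral))
  nb <- sum(tab$truth == "breaking")
  bpars <- if (regime == "null") neutral_beta else breaking_beta
  tab$MAF <- NA_real_
  tab$MAF[tab$truth == "breaking"] <- stats::rbeta(nb, bpars[1L], bpars[2L])
  tab$MAF[tab$truth == "neutral"] <- stats::rbeta(nrow(tab) - nb,
                                                  neutral_beta[1L],
                                                  neutral_beta[2L])
  tab$AN <- round(max_an * stats::runif(nrow(tab), 0.7, 1))
  tab$constraint_z <- stats::rnorm(nrow(tab))
  tab$cadd_raw <- stats::rnorm(nrow(tab)) +
    ifelse(tab$truth == "breaking", cadd_shift, 0)
  tab$region <- sample(c("FIVE_UTR", "THREE_UTR"), nrow(tab),
                       replace = TRUE)
  tab$variant <- sprintf("%s:%d%s>%s", tab$transcript_id, tab$pos,
                         tab$ref, tab$alt)
  rownames(tab) <- NULL
  tab
}

#' Plant PWM consensus sites into flank sequences
#'
#' Writes a site sampled column-by-column from the PWM into each sequence
#' with the given per-sequence rate, at a random feasible position;
#' positions are recorded. Sequences shorter than the motif keep their
#' original content.
#'
#' @param flank_sequences character vector.
#' @param p a `pwm`.
#' @param rate per-sequence planting probability.
#' @param seed RNG seed.
#' @return list: `sequences` (modified vector), `truth` (data.frame
#'   seq_index, start, end, site).
#' @export
plant_pwm_sites <- function(flank_sequences, p, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  set.seed(seed)
  seqs <- normalize_rna(flank_sequences)
  truth <- list()
  for (i in seq_along(seqs)) {
    if (stats::runif(1) >= rate) next
    L <- nchar(seqs[i])
    if (L < p$length) next
    site <- paste(vapply(seq_len(p$length), function(j)
      sample(c("A", "C", "G", "U"), 1L, prob = p$matrix[, j]), ""),
      collapse = "")
    pos <- sample.int(L - p$length + 1L, 1L)
    substr(seqs[i], pos, pos + p$length - 1L) <- site
    truth[[length(truth) + 1L]] <- data.frame(
      seq_index = i, start = pos, end = pos + p$length - 1L, site = site)
  }
  list(sequences = seqs,
       truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(seq_index = integer(), start = integer(),
                    end = integer(), site = character()))
}

#' Simulate random flank sequences (uniform background)
#'
#' @param n number of sequences.
#' @param length sequence length (single value or vector).
#' @param gc GC fraction.
#' @param seed RNG seed.
#' @return character vector.
#' @export
simulate_flanks <- function(n, length = 40L, gc = 0.5, seed = 1L) {
  set.seed(seed)
  lens <- rep_len(length, n)
  vapply(lens, function(L) paste(sample_bases(L, gc), collapse = ""), "")
}
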