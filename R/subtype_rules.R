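SUBTYPE_LEVELS <- c("CANONICAL", "LONGLOOP", "BULGES", "TWO_QUARTET",
                    "POTENTIAL_GQ_40", "POTENTIAL_G_TRIPLEX_40",
                    "G_RICH_40", "UNKNOWN")

#' Pattern configuration for the rG4 subtype rule engine
#'
#' Every loop bound and content threshold of the hierarchical classifier is
#' an explicit knob. Defaults encode the classical scheme: canonical rG4s
#' are four runs of >= 3 G separated by 1-7 nt loops; a long loop relaxes
#' exactly one loop to 8-12 nt; a bulged rG4 allows a single 1-nt non-G
#' interruption in one run; a two-quartet rG4 uses four runs of >= 2 G with
#' loops 1-9 nt; the "potential" classes relax loops to 1-30 nt and require
#' at least 40 percent guanine over the full input.
#'
#' @param canonical_loop c(min, max) loop bounds for canonical motifs.
#' @param longloop_loop c(min, max) bounds for the single long loop.
#' @param bulge_size size of the single bulge (nt) in a bulged run.
#' @param two_quartet_loop loop bounds for two-quartet motifs.
#' @param relaxed_loop loop bounds for the potential-G-quadruplex class.
#' @param g_content_threshold minimum full-sequence G fraction for the
#'   G-content classes.
#' @return list of class `pattern_config`.
#' @export
pattern_config <- function(canonical_loop = c(1L, 7L),
                           longloop_loop = c(8L, 12L),
                           bulge_size = 1L,
                           two_quartet_loop = c(1L, 9L),
                           relaxed_loop = c(1L, 30L),
                           g_content_threshold = 0.40) {
  stopifnot(all(canonical_loop > 0), all(longloop_loop > 0),
            bulge_size > 0, all(two_quartet_loop > 0), all(relaxed_loop > 0),
            canonical_loop[2L] < longloop_loop[2L])
  structure(list(canonical_loop = as.integer(canonical_loop),
                 longloop_loop = as.integer(longloop_loop),
                 bulge_size = as.integer(bulge_size),
                 two_quartet_loop = as.integer(two_quartet_loop),
                 relaxed_loop = as.integer(relaxed_loop),
                 g_content_threshold = g_content_threshold),
            class = "pattern_config")
}

# maximal G-runs of a sequence: data.frame(start, end, len)
g_runs <- function(sequence) {
  m <- gregexpr("G+", sequence)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(), end = integer(), len = integer()))
  }
  st <- as.integer(m); ln <- attr(m, "match.length")
  data.frame(start = st, end = st + ln - 1L, len = ln)
}

# candidate run units for subtype matching. A "plain" unit is a maximal
# G-run with len >= min_g. A "bulged" unit joins two adjacent maximal runs
# separated by exactly `bulge` non-G nt with combined G count >= 3.
run_units <- function(runs, min_g, bulge = NULL) {
  units <- if (nrow(runs)) {
    keep <- runs$len >= min_g
    data.frame(start = runs$start[keep], end = runs$end[keep],
               bulged = rep(FALSE, sum(keep)))
  } else data.frame(start = integer(), end = integer(), bulged = logical())
  if (!is.null(bulge) && nrow(runs) > 1L) {
    gap <- runs$start[-1L] - runs$end[-nrow(runs)] - 1L
    glen <- runs$len[-nrow(runs)] + runs$len[-1L]
    ok <- gap == bulge & glen >= 3L
    if (any(ok)) {
      i <- which(ok)
      units <- rbind(units,
                     data.frame(start = runs$start[i], end = runs$end[i + 1L],
                                bulged = TRUE))
    }
  }
  units[order(units$start, units$end), , drop = FALSE]
}

# scan ordered, non-overlapping 4-tuples (or n-tuples) of units whose gaps
# satisfy per-gap loop bounds; returns the leftmost spans, optionally all.
scan_units <- function(units, n_units, gap_ok, unit_ok = NULL,
                       all_matches = FALSE) {
  k <- nrow(units)
  if (k < n_units) return(list())
  res <- list()
  # depth-first over unit combinations, pruned by ordering; unit counts per
  # sequence are small so this is cheap
  recurse <- function(chosen, next_i) {
    if (length(chosen) == n_units) {
      if (is.null(unit_ok) || unit_ok(units[chosen, , drop = FALSE])) {
        res[[length(res) + 1L]] <<- c(units$start[chosen[1L]],
                                      units$end[chosen[n_units]])
        return(TRUE)
      }
      return(FALSE)
    }
    if (next_i > k) return(FALSE)
    for (j in next_i:k) {
      if (length(chosen)) {
        gap <- units$start[j] - units$end[chosen[length(chosen)]] - 1L
        if (gap < 0L) next
        if (!gap_ok(gap, length(chosen))) next
      }
      hit <- recurse(c(chosen, j), j + 1L)
      if (hit && !all_matches) return(TRUE)
    }
    FALSE
  }
  if (all_matches) {
    recurse(integer(), 1L)
    res
  } else {
    for (s in seq_len(k)) {
      if (recurse(s, s + 1L)) return(res)
    }
    list()
  }
}

match_class <- function(sequence, class, config) {
  runs <- g_runs(sequence)
  switch(class,
    CANONICAL = {
      u <- run_units(runs, 3L)
      scan_units(u, 4L, function(gap, i)
        gap >= config$canonical_loop[1L] && gap <= config$canonical_loop[2L])
    },
    LONGLOOP = {
      u <- run_units(runs, 3L)
      lo <- config$canonical_loop; hi <- config$longloop_loop
      # exactly one loop in the long range, the rest canonical
      res <- list()
      for (long_at in 1:3) {
        m <- scan_units(u, 4L, function(gap, i) {
          if (i == long_at) gap >= hi[1L] && gap <= hi[2L]
          else gap >= lo[1L] && gap <= lo[2L]
        })
        if (length(m)) res <- c(res, m)
      }
      if (length(res)) {
        st <- vapply(res, `[`, 0, 1L)
        res[which.min(st)]
      } else list()
    },
    BULGES = {
      u <- run_units(runs, 3L, bulge = config$bulge_size)
      scan_units(u, 4L,
                 function(gap, i) gap >= config$canonical_loop[1L] &&
                   gap <= config$canonical_loop[2L],
                 unit_ok = function(ch) sum(ch$bulged) == 1L)
    },
    TWO_QUARTET = {
      u <- run_units(runs, 2L)
      scan_units(u, 4L, function(gap, i)
        gap >= config$two_quartet_loop[1L] &&
          gap <= config$two_quartet_loop[2L])
    },
    POTENTIAL_GQ_40 = {
      u <- run_units(runs, 2L)
      scan_units(u, 4L, function(gap, i)
        gap >= config$relaxed_loop[1L] && gap <= config$relaxed_loop[2L])
    },
    POTENTIAL_G_TRIPLEX_40 = {
      u <- run_units(runs, 3L)
      scan_units(u, 3L, function(gap, i)
        gap >= config$canonical_loop[1L] && gap <= config$canonical_loop[2L])
    },
    stop("unknown class ", class))
}

#' Find rG4 motif spans matching a subtype pattern
#'
#' Returns leftmost, non-overlapping matches. G-runs are maximal: a run of
#' four or more guanines is never split to manufacture a loop.
#'
#' @param sequence normalized RNA sequence.
#' @param pattern subtype pattern name (default "CANONICAL").
#' @param config a [pattern_config()].
#' @return data.frame with columns start, end (1-based closed spans); zero
#'   rows when nothing matches.
#' @export
find_motifs <- function(sequence, pattern = "CANONICAL",
                        config = pattern_config()) {
  sequence <- normalize_rna(sequence)
  spans <- data.frame(start = integer(), end = integer())
  offset <- 0L
  rest <- sequence
  repeat {
    m <- match_class(rest, pattern, config)
    if (!length(m)) break
    sp <- m[[1L]]
    spans <- rbind(spans, data.frame(start = sp[1L] + offset,
                                     end = sp[2L] + offset))
    if (sp[2L] >= nchar(rest)) break
    offset <- offset + sp[2L]
    rest <- substr(rest, sp[2L] + 1L, nchar(rest))
  }
  spans
}

g_content <- function(sequence) {
  L <- nchar(sequence)
  if (L == 0L) return(0)
  lengths(regmatches(sequence, gregexpr("G", sequence))) / L
}

#' Classify a G-rich sequence into one of eight rG4 subtype classes
#'
#' Hierarchical assignment: when a sequence matches several class patterns
#' it receives the class with the highest predicted structural stability
#' (canonical > long loop > bulges > two-quartet > potential G-quadruplex >
#' potential G-triplex > G-rich > unknown). The three G-content classes
#' additionally require a full-sequence guanine fraction at or above the
#' configured threshold. The leftmost motif span of the winning class is
#' reported.
#'
#' @param sequence RNA sequence, length >= 8.
#' @param config a [pattern_config()].
#' @return list of class `subtype_call` with fields subtype, rank,
#'   motif_span (or NULL), matched_pattern.
#' @export
classify_subtype <- function(sequence, config = pattern_config()) {
  sequence <- normalize_rna(sequence)
  if (nchar(sequence) < 8L) stop("sequence too short to classify (< 8 nt)")
  gc_ok <- g_content(sequence) >= config$g_content_threshold
  structural <- c("CANONICAL", "LONGLOOP", "BULGES", "TWO_QUARTET")
  for (i in seq_along(structural)) {
    m <- match_class(sequence, structural[i], config)
    if (length(m)) {
      return(new_subtype_call(structural[i], i, m[[1L]], structural[i]))
    }
  }
  if (gc_ok) {
    m <- match_class(sequence, "POTENTIAL_GQ_40", config)
    if (length(m)) {
      return(new_subtype_call("POTENTIAL_GQ_40", 5L, m[[1L]],
                              "four G>=2 runs, relaxed loops, G>=40%"))
    }
    m <- match_class(sequence, "POTENTIAL_G_TRIPLEX_40", config)
    if (length(m)) {
      return(new_subtype_call("POTENTIAL_G_TRIPLEX_40", 6L, m[[1L]],
                              "three G>=3 runs, G>=40%"))
    }
    return(new_subtype_call("G_RICH_40", 7L, NULL, "G>=40%"))
  }
  new_subtype_call("UNKNOWN", 8L, NULL, "no rule matched")
}

new_subtype_call <- function(subtype, rank, span, pattern) {
  structure(list(subtype = subtype, rank = as.integer(rank),
                 motif_span = if (is.null(span)) NULL else as.integer(span),
                 matched_pattern = pattern),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  sp <- if (is.null(x$motif_span)) "-" else
    paste(x$motif_span, collapse = "-")
  cat(sprintf("<subtype_call> %s (rank %d) span %s [%s]\n",
              x$subtype, x$rank, sp, x$matched_pattern))
  invisible(x)
}

#' Classify many sequences into subtype classes
#'
#' @param sequences named character vector.
#' @param config a [pattern_config()].
#' @return data.frame: id, subtype, rank, motif_start, motif_end, pattern.
#' @export
classify_subtypes <- function(sequences, config = pattern_config()) {
  calls <- lapply(sequences, classify_subtype, config = config)
  data.frame(
    id = if (is.null(names(sequences))) as.character(seq_along(sequences))
         else names(sequences),
    subtype = vapply(calls, `[[`, "", "subtype"),
    rank = vapply(calls, `[[`, 0L, "rank"),
    motif_start = vapply(calls, function(x)
      if (is.null(x$motif_span)) NA_integer_ else x$motif_span[1L], 0L),
    motif_end = vapply(calls, function(x)
      if (is.null(x$motif_span)) NA_integer_ else x$motif_span[2L], 0L),
    pattern = vapply(calls, `[[`, "", "matched_pattern"),
    row.names = NULL)
}
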