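RNA_ALPHABET <- c("A", "C", "G", "U")
REGION_LABELS <- c("FIVE_UTR", "CDS", "THREE_UTR")

#' Normalize a nucleotide sequence to uppercase RNA
#'
#' Uppercases and converts T to U. Any character outside A/C/G/U after
#' normalization is an error.
#'
#' @param x character vector of sequences.
#' @return character vector over the A/C/G/U alphabet.
#' @export
normalize_rna <- function(x) {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGU]", x)
  if (any(bad)) {
    stop("sequence(s) contain characters outside A/C/G/U(/T): ",
         paste(which(bad), collapse = ", "))
  }
  x
}

#' Construct a transcript object
#'
#' A transcript couples an id, a normalized RNA sequence and an optional set
#' of labeled regions (FIVE_UTR, CDS, THREE_UTR) in 1-based closed transcript
#' coordinates.
#'
#' @param id transcript identifier.
#' @param sequence nucleotide sequence (T accepted, normalized to U).
#' @param regions optional data.frame with columns start, end, label.
#' @return an object of class `transcript`.
#' @export
transcript <- function(id, sequence, regions = NULL) {
  sequence <- normalize_rna(sequence)
  L <- nchar(sequence)
  if (is.null(regions)) {
    regions <- data.frame(start = integer(), end = integer(),
                          label = character())
  } else {
    stopifnot(all(c("start", "end", "label") %in% names(regions)))
    if (nrow(regions)) {
      if (any(regions$start < 1L | regions$end > L | regions$start > regions$end))
        stop("region interval out of bounds for transcript ", id)
      if (!all(regions$label %in% REGION_LABELS))
        stop("unknown region label for transcript ", id)
      for (lab in unique(regions$label)) {
        r <- regions[regions$label == lab, , drop = FALSE]
        r <- r[order(r$start), , drop = FALSE]
        if (nrow(r) > 1L && any(r$start[-1L] <= r$end[-nrow(r)]))
          stop("overlapping ", lab, " intervals for transcript ", id)
      }
    }
  }
  structure(list(id = as.character(id), sequence = unname(sequence),
                 regions = regions), class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s> %d nt, %d region(s)\n",
              x$id, nchar(x$sequence), nrow(x$regions)))
  invisible(x)
}

#' Load transcripts from FASTA (plus optional region annotations)
#'
#' Sequences are normalized to uppercase RNA. Records containing characters
#' outside A/C/G/U/T are rejected; their ids are reported via the
#' `rejected` attribute (and a warning).
#'
#' @param fasta_path path to a (multi-record) FASTA file.
#' @param regions_path optional path to a 4-column TSV
#'   (transcript_id, start, end, label).
#' @return named list of `transcript` objects, with attribute `rejected`
#'   holding the ids of dropped records.
#' @export
load_transcripts <- function(fasta_path, regions_path = NULL) {
  if (!file.exists(fasta_path)) stop("missing file: ", fasta_path)
  ss <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  regions <- NULL
  if (!is.null(regions_path)) {
    if (!file.exists(regions_path)) stop("missing file: ", regions_path)
    regions <- utils::read.table(regions_path, sep = "\t", header = FALSE,
                                 col.names = c("transcript_id", "start",
                                               "end", "label"),
                                 stringsAsFactors = FALSE)
    unknown <- setdiff(regions$transcript_id, ids)
    if (length(unknown))
      stop("region annotation references unknown transcript(s): ",
           paste(unknown, collapse = ", "))
  }
  out <- list()
  rejected <- character()
  for (i in seq_along(ids)) {
    reg <- NULL
    if (!is.null(regions)) {
      reg <- regions[regions$transcript_id == ids[i],
                     c("start", "end", "label"), drop = FALSE]
      if (!nrow(reg)) reg <- NULL
    }
    tx <- tryCatch(transcript(ids[i], seqs[i], reg), error = function(e) e)
    if (inherits(tx, "error")) {
      if (grepl("interval out of bounds|overlapping|unknown region",
                conditionMessage(tx)))
        stop(tx)
      rejected <- c(rejected, ids[i])
    } else {
      out[[ids[i]]] <- tx
    }
  }
  if (length(rejected))
    warning("rejected ", length(rejected), " record(s) with invalid ",
            "characters: ", paste(rejected, collapse = ", "))
  attr(out, "rejected") <- rejected
  out
}

#' Tokenize a sequence into overlapping k-mers, chunked
#'
#' Consecutive tokens overlap in k-1 bases. The full token list (L-k+1
#' tokens) is split into consecutive chunks of at most `max_tokens` content
#' tokens; chunks do not share tokens. Each chunk carries [CLS]/[SEP] flags.
#'
#' @param sequence RNA sequence (length >= k).
#' @param k k-mer size (default 6).
#' @param max_tokens maximum content tokens per chunk (default 510).
#' @return list of chunks; each a list with `tokens`, `chunk_index`,
#'   `cls`, `sep`.
#' @export
tokenize_kmers <- function(sequence, k = 6L, max_tokens = 510L) {
  sequence <- normalize_rna(sequence)
  L <- nchar(sequence)
  if (L < k) stop("sequence shorter than k (", L, " < ", k, ")")
  n <- L - k + 1L
  toks <- substring(sequence, seq_len(n), seq_len(n) + k - 1L)
  starts <- seq.int(1L, n, by = max_tokens)
  lapply(seq_along(starts), function(i) {
    idx <- starts[i]:min(starts[i] + max_tokens - 1L, n)
    list(tokens = toks[idx], chunk_index = i, cls = TRUE, sep = TRUE)
  })
}

#' Reconstruct the subsequence covered by one token chunk
#'
#' @param chunk one element of [tokenize_kmers()] output.
#' @return character scalar.
#' @export
detokenize_chunk <- function(chunk) {
  toks <- chunk$tokens
  if (!length(toks)) return("")
  paste0(toks[1L], paste(substring(toks[-1L], nchar(toks[1L]),
                                   nchar(toks[1L])), collapse = ""))
}

#' Construct a single-nucleotide sequence variant
#'
#' @param transcript_id transcript identifier.
#' @param position 1-based transcript coordinate.
#' @param ref,alt single reference/alternate bases (RNA).
#' @return object of class `sequence_variant`.
#' @export
sequence_variant <- function(transcript_id, position, ref, alt) {
  ref <- normalize_rna(ref); alt <- normalize_rna(alt)
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L)
  if (ref == alt) stop("ref and alt are identical (", ref, ")")
  structure(list(transcript_id = as.character(transcript_id),
                 position = as.integer(position), ref = ref, alt = alt),
            class = "sequence_variant")
}

#' Apply a single-nucleotide variant to a transcript sequence
#'
#' @param tx a `transcript` (or plain sequence string when `variant` carries
#'   no transcript check context).
#' @param variant a `sequence_variant`.
#' @return the mutated sequence (character scalar).
#' @export
apply_variant <- function(tx, variant) {
  seq <- if (inherits(tx, "transcript")) tx$sequence else normalize_rna(tx)
  p <- variant$position
  if (p < 1L || p > nchar(seq)) stop("variant position out of bounds")
  obs <- substr(seq, p, p)
  if (obs != variant$ref) {
    stop("reference mismatch at position ", p, ": transcript has ", obs,
         ", variant expects ", variant$ref)
  }
  substr(seq, p, p) <- variant$alt
  seq
}

#' Extract a flank-extended window around a motif
#'
#' Extends a motif span symmetrically up to `target_length`; the left flank
#' gets the extra base when the total flank is odd. Truncation at transcript
#' ends shifts the remainder to the other side, without padding. A motif
#' longer than `target_length` is returned as-is with a warning flag.
#'
#' @param tx a `transcript` or plain sequence.
#' @param motif_span integer vector c(start, end), 1-based closed.
#' @param target_length window size ceiling (default 70).
#' @return list with `sequence`, `start`, `end`, `motif_span` (relative to
#'   the window) and `truncated_motif` flag.
#' @export
extract_flanked_window <- function(tx, motif_span, target_length = 70L) {
  seq <- if (inherits(tx, "transcript")) tx$sequence else normalize_rna(tx)
  L <- nchar(seq)
  ms <- as.integer(motif_span[1L]); me <- as.integer(motif_span[2L])
  if (ms < 1L || me > L || ms > me) stop("motif span outside transcript")
  mlen <- me - ms + 1L
  if (mlen >= target_length) {
    return(list(sequence = substr(seq, ms, me), start = ms, end = me,
                motif_span = c(1L, mlen),
                truncated_motif = mlen > target_length))
  }
  extra <- target_length - mlen
  left_want <- ceiling(extra / 2)
  right_want <- extra - left_want
  left_avail <- ms - 1L; right_avail <- L - me
  left <- min(left_want, left_avail)
  right <- min(right_want, right_avail)
  # redistribute what a transcript end could not supply to the other side
  right <- min(right + (extra - left - right), right_avail)
  left <- min(left + (extra - left - right), left_avail)
  ws <- ms - left; we <- me + right
  list(sequence = substr(seq, ws, we), start = ws, end = we,
       motif_span = c(ms - ws + 1L, me - ws + 1L), truncated_motif = FALSE)
}

#' Read a variant table (TSV)
#'
#' Expected columns: transcript_id, pos, ref, alt (header optional when the
#' columns appear in this order).
#'
#' @param path TSV file path.
#' @return list of `sequence_variant` objects.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  first <- readLines(path, n = 1L)
  header <- grepl("transcript_id", first, fixed = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = header,
                           stringsAsFactors = FALSE)
  if (!header) names(tab)[1:4] <- c("transcript_id", "pos", "ref", "alt")
  lapply(seq_len(nrow(tab)), function(i) {
    sequence_variant(tab$transcript_id[i], tab$pos[i], tab$ref[i], tab$alt[i])
  })
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or list of `transcript` objects.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs) && length(seqs) && inherits(seqs[[1L]], "transcript")) {
    nm <- vapply(seqs, `[[`, "", "id")
    seqs <- stats::setNames(vapply(seqs, `[[`, "", "sequence"), nm)
  }
  ss <- Biostrings::BStringSet(unlist(seqs))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
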