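# Population-genetic comparison suite: call-rate filtering, constraint
# matching and the battery of tests applied to rG4-altering variants.

#' Filter variants by call rate
#'
#' Keeps rows with an observed allele number of at least `frac` of the
#' maximum sequenced alleles.
#'
#' @param rows data.frame with an `AN` column.
#' @param max_alleles maximum number of sequenced alleles (default 152312).
#' @param frac minimum call-rate fraction (default 0.8).
#' @return filtered data.frame.
#' @export
filter_call_rate <- function(rows, max_alleles = 152312L, frac = 0.8) {
  stopifnot("AN" %in% names(rows))
  rows[rows$AN >= frac * max_alleles, , drop = FALSE]
}

largest_remainder <- function(weights, n) {
  raw <- weights / sum(weights) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Constraint-matched subsampling
#'
#' Group A's empirical quartiles (ties to the lower bin) define the bins;
#' from group B, per-bin counts reproducing group A's bin occupancy
#' (largest-remainder rounding when `n` differs from `nrow(group_a)`) are
#' sampled without replacement.
#'
#' @param group_a,group_b data.frames with a `constraint_z` column.
#' @param n_bins number of quantile bins (default 4, quartiles).
#' @param n total matched sample size (default `nrow(group_a)`).
#' @param seed RNG seed.
#' @return subsample of `group_b` with attribute `bin_counts`.
#' @export
constraint_matched_sample <- function(group_a, group_b, n_bins = 4L,
                                      n = nrow(group_a), seed = 1L) {
  stopifnot(nrow(group_a) > 0L, nrow(group_b) > 0L)
  br <- unname(stats::quantile(group_a$constraint_z,
                               probs = seq(0, 1, length.out = n_bins + 1L)))
  br[1L] <- -Inf; br[n_bins + 1L] <- Inf
  # degenerate quantiles (massed constraint scores) collapse bins
  br <- unique(br)
  n_bins <- length(br) - 1L
  # ties at a boundary go to the lower bin: right-closed cut
  bin_a <- cut(group_a$constraint_z, br, labels = FALSE, right = TRUE)
  bin_b <- cut(group_b$constraint_z, br, labels = FALSE, right = TRUE)
  occ <- tabulate(bin_a, n_bins)
  want <- largest_remainder(occ, n)
  set.seed(seed)
  idx <- integer()
  for (q in seq_len(n_bins)) {
    if (want[q] == 0L) next
    avail <- which(bin_b == q)
    if (length(avail) < want[q])
      stop("group_b lacks variants in constraint bin ", q, " (need ",
           want[q], ", have ", length(avail), ")")
    idx <- c(idx, sample(avail, want[q]))
  }
  out <- group_b[idx, , drop = FALSE]
  attr(out, "bin_counts") <- want
  out
}

#' Compare allele frequencies of breaking vs non-breaking variants
#'
#' Tests the alternative that breaking-variant MAFs are stochastically
#' smaller. One-tailed Kolmogorov-Smirnov by default (statistic D), with a
#' one-tailed Mann-Whitney U alternative (statistic W).
#'
#' @param breaking,nonbreaking numeric MAF vectors (>= 2 each).
#' @param test "ks" or "mwu".
#' @return list: statistic, p, test, n_breaking, n_nonbreaking.
#' @export
compare_maf <- function(breaking, nonbreaking, test = c("ks", "mwu")) {
  test <- match.arg(test)
  if (length(breaking) < 2L || length(nonbreaking) < 2L)
    stop("both samples need >= 2 observations")
  if (test == "ks") {
    # smaller MAFs => CDF of `breaking` lies above: ks.test alternative
    # "greater" tests exactly that for x vs y
    ht <- suppressWarnings(stats::ks.test(breaking, nonbreaking,
                                          alternative = "greater"))
  } else {
    ht <- suppressWarnings(stats::wilcox.test(breaking, nonbreaking,
                                              alternative = "less"))
  }
  list(statistic = unname(ht$statistic), p = ht$p.value, test = test,
       n_breaking = length(breaking), n_nonbreaking = length(nonbreaking))
}

#' Fraction of rare variants
#'
#' @param rows data.frame with `MAF` (or a bare numeric vector).
#' @param threshold rarity cutoff, strict `<` (default 0.001).
#' @return scalar fraction.
#' @export
rare_fraction <- function(rows, threshold = 0.001) {
  maf <- if (is.data.frame(rows)) rows$MAF else rows
  if (!length(maf)) stop("empty input")
  mean(maf < threshold)
}

#' Stratify variants by rG4 length
#'
#' Rows between the bounds are excluded from both strata.
#'
#' @param rows data.frame with `rg4_length`.
#' @param short_max inclusive upper bound of the short stratum (default 22).
#' @param long_min inclusive lower bound of the long stratum (default 28;
#'   31 for the stricter definition).
#' @return list with `short` and `long` data.frames.
#' @export
length_stratify <- function(rows, short_max = 22L, long_min = 28L) {
  stopifnot("rg4_length" %in% names(rows))
  list(short = rows[rows$rg4_length <= short_max, , drop = FALSE],
       long = rows[rows$rg4_length >= long_min, , drop = FALSE])
}

#' Mean and SD of delta scores across CADD bins
#'
#' Equal-width bins over the CADD range; empty bins are absent from the
#' output.
#'
#' @param rows data.frame with `cadd_raw` and `delta`.
#' @param n_bins number of bins (default 10).
#' @return data.frame: bin, cadd_mid, mean_delta, sd_delta, n.
#' @export
cadd_bin_trend <- function(rows, n_bins = 10L) {
  stopifnot(all(c("cadd_raw", "delta") %in% names(rows)))
  if (!nrow(rows)) return(data.frame(bin = integer(), cadd_mid = numeric(),
                                     mean_delta = numeric(),
                                     sd_delta = numeric(), n = integer()))
  rng <- range(rows$cadd_raw)
  if (diff(rng) == 0) {
    return(data.frame(bin = 1L, cadd_mid = rng[1L],
                      mean_delta = mean(rows$delta),
                      sd_delta = stats::sd(rows$delta), n = nrow(rows)))
  }
  br <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  b <- cut(rows$cadd_raw, br, include.lowest = TRUE, labels = FALSE)
  occ <- sort(unique(b))
  data.frame(bin = occ,
             cadd_mid = (br[occ] + br[occ + 1L]) / 2,
             mean_delta = vapply(occ, function(q)
               mean(rows$delta[b == q]), 0),
             sd_delta = vapply(occ, function(q) {
               x <- rows$delta[b == q]
               if (length(x) < 2L) 0 else stats::sd(x)
             }, 0),
             n = vapply(occ, function(q) sum(b == q), 0L))
}

#' Chi-square test of a subtype-distribution shift
#'
#' Standard chi-square on the 2 x K contingency of the two count vectors;
#' categories with zero total count are dropped with a warning.
#'
#' @param counts_a,counts_b named integer vectors over matching categories.
#' @return list: statistic, df, p, dropped.
#' @export
subtype_distribution_shift <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b))
  if (!is.null(names(counts_a)) && !is.null(names(counts_b)))
    counts_b <- counts_b[names(counts_a)]
  tot <- counts_a + counts_b
  dropped <- names(counts_a)[tot == 0]
  if (length(dropped))
    warning("dropping zero-total categories: ",
            paste(dropped, collapse = ", "))
  keep <- tot > 0
  if (sum(keep) < 2L) stop("fewer than two non-empty categories")
  ht <- suppressWarnings(stats::chisq.test(rbind(counts_a[keep],
                                                 counts_b[keep])))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, dropped = dropped)
}

welch_anova <- function(groups) {
  ht <- stats::oneway.test(value ~ g,
                           data = data.frame(
                             value = unlist(groups),
                             g = factor(rep(seq_along(groups),
                                            lengths(groups)))),
                           var.equal = FALSE)
  list(statistic = unname(ht$statistic), df1 = unname(ht$parameter[1L]),
       df2 = unname(ht$parameter[2L]), p = ht$p.value)
}

games_howell <- function(groups) {
  k <- length(groups)
  nm <- names(groups)
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, stats::var, 0)
  n <- lengths(groups)
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    t <- (m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                     (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(t) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      group1 = nm[i], group2 = nm[j], diff = m[i] - m[j],
      statistic = t, df = df, p_adj = p)
  }
  do.call(rbind, out)
}

dunn_bh <- function(groups) {
  k <- length(groups)
  nm <- names(groups)
  x <- unlist(groups)
  g <- rep(seq_len(k), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- vapply(seq_len(k), function(i) mean(r[g == i]), 0)
  n <- lengths(groups)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  out <- list()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    z <- (rbar[i] - rbar[j]) / se
    out[[length(out) + 1L]] <- data.frame(
      group1 = nm[i], group2 = nm[j], statistic = z,
      p = 2 * stats::pnorm(-abs(z)))
  }
  tab <- do.call(rbind, out)
  tab$p_adj <- stats::p.adjust(tab$p, method = "BH")
  tab
}

#' Omnibus and pairwise tests of delta scores across rG4 subtypes
#'
#' Default mode: Welch's ANOVA omnibus followed by Games-Howell pairwise
#' contrasts (Tukey-studentized, Welch degrees of freedom). Rank-based
#' alternative: Kruskal-Wallis omnibus followed by Dunn's test with
#' Benjamini-Hochberg correction. Methods are never mixed within one call.
#'
#' @param delta_groups named list of numeric vectors (>= 2 groups, each
#'   n >= 3).
#' @param method "welch_games_howell" or "kruskal_dunn".
#' @return list: omnibus (list), pairwise (data.frame), method.
#' @export
delta_by_subtype_test <- function(delta_groups,
                                  method = c("welch_games_howell",
                                             "kruskal_dunn")) {
  method <- match.arg(method)
  if (length(delta_groups) < 2L) stop("need at least two groups")
  if (any(lengths(delta_groups) < 3L)) stop("each group needs n >= 3")
  if (is.null(names(delta_groups)))
    names(delta_groups) <- paste0("g", seq_along(delta_groups))
  if (method == "welch_games_howell") {
    if (any(vapply(delta_groups, stats::var, 0) == 0 &
            lengths(delta_groups) < 2L))
      stop("zero-variance group with n < 2")
    omni <- welch_anova(delta_groups)
    pw <- games_howell(delta_groups)
  } else {
    ht <- stats::kruskal.test(delta_groups)
    omni <- list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value)
    pw <- dunn_bh(delta_groups)
  }
  list(omnibus = omni, pairwise = pw, method = method)
}

#' Pathogenicity contrast for clinically annotated variants
#'
#' Three readouts: (i) one-sided Mann-Whitney U testing whether pathogenic
#' deltas are more negative than benign; (ii) fold enrichment, the
#' pathogenic fraction among structure-abolishing rows (delta <= threshold)
#' over the pathogenic fraction among all rows; (iii) a binomial tail
#' p-value for the pathogenic count in the abolishing subset at the
#' baseline rate.
#'
#' @param rows data.frame with `clinsig` ("BENIGN"/"PATHOGENIC") and
#'   `delta`.
#' @param disrupt_thr abolishing-delta threshold (default -0.5).
#' @return list: mwu_p, fold_enrichment (NA when no abolishing rows),
#'   binom_p, n_disrupting, n_pathogenic_disrupting, baseline_fraction.
#' @export
pathogenicity_contrast <- function(rows, disrupt_thr = -0.5) {
  stopifnot(all(c("clinsig", "delta") %in% names(rows)))
  path <- rows$clinsig == "PATHOGENIC"
  mwu <- suppressWarnings(stats::wilcox.test(rows$delta[path],
                                             rows$delta[!path],
                                             alternative = "less"))
  base <- mean(path)
  dis <- rows$delta <= disrupt_thr
  if (!any(dis)) {
    return(list(mwu_p = mwu$p.value, fold_enrichment = NA_real_,
                binom_p = NA_real_, n_disrupting = 0L,
                n_pathogenic_disrupting = 0L, baseline_fraction = base))
  }
  frac_dis <- mean(path[dis])
  bt <- stats::binom.test(sum(path[dis]), sum(dis), p = base,
                          alternative = "greater")
  list(mwu_p = mwu$p.value, fold_enrichment = frac_dis / base,
       binom_p = bt$p.value, n_disrupting = sum(dis),
       n_pathogenic_disrupting = sum(path[dis]), baseline_fraction = base)
}

#' Read a variant annotation table (TSV)
#'
#' Column dictionary: variant (key), MAF, AN, constraint_z, cadd_raw,
#' region, category, subtype, rg4_length, delta, clinsig -- any subset is
#' accepted; downstream functions check for what they need.
#'
#' @param path TSV path with a header line.
#' @return data.frame.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
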