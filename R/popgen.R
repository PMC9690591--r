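#' Per-variant alternate-allele frequencies
#'
#' Frequencies are computed over non-missing genotypes only. Variants with
#' no genotyped sample in the chosen subset get `NA` (undefined) and are
#' excluded from dependent statistics.
#'
#' @param callset a [cnv_callset].
#' @param pop population label, or `NULL` for the whole cohort.
#' @return numeric vector of frequencies, one per record, named by
#'   `record_id`.
#' @export
allele_freqs <- function(callset, pop = NULL) {
  cols <- if (is.null(pop)) seq_along(callset$samples) else pop_indices(callset, pop)
  g <- callset$geno[, cols, drop = FALSE]
  ng <- rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / (2 * ng)
  p[ng == 0] <- NA_real_
  stats::setNames(p, callset$variants$record_id)
}

#' Per-variant Fst between two populations
#'
#' For each autosomal variant, with alternate-allele frequencies `p_a` and
#' `p_b` in the two populations, the pooled frequency is the unweighted
#' mean `pbar = (p_a + p_b)/2`, and
#' \deqn{H_t = 2\bar p(1-\bar p), \quad
#'       H_s = \tfrac12\{2p_a(1-p_a) + 2p_b(1-p_b)\}, \quad
#'       F_{st} = (H_t - H_s)/H_t,}
#' with `Fst` defined as 0 at sites monomorphic in the pool (`Ht = 0`).
#' No sample-size correction is applied (the raw heterozygosity form), so
#' per-variant values are upward-biased at small n; the scan ranks are what
#' matter downstream. Records on sex chromosomes are omitted, as are
#' records with no genotyped sample in either population (counted in the
#' `n_excluded` attribute).
#'
#' @param callset a labelled [cnv_callset].
#' @param pop_a,pop_b population labels.
#' @param sex_chroms chromosome names to exclude (default `c("X", "Y")`).
#' @param weight_by_n if `TRUE`, weight `pbar` and `Hs` by the number of
#'   genotyped samples instead of equally.
#' @return data.frame with columns `record_id`, `chrom`, `pos`, `end`,
#'   `svtype`, `p_a`, `p_b`, `ht`, `hs`, `fst`; attribute `n_excluded`
#'   counts records dropped for undefined frequencies.
#' @export
fst_per_variant <- function(callset, pop_a, pop_b, sex_chroms = c("X", "Y"),
                            weight_by_n = FALSE) {
  ia <- pop_indices(callset, pop_a)
  ib <- pop_indices(callset, pop_b)
  v <- callset$variants
  auto <- !v$chrom %in% sex_chroms

  ga <- callset$geno[, ia, drop = FALSE]
  gb <- callset$geno[, ib, drop = FALSE]
  na_ <- rowSums(!is.na(ga)); nb_ <- rowSums(!is.na(gb))
  pa <- rowSums(ga, na.rm = TRUE) / (2 * na_)
  pb <- rowSums(gb, na.rm = TRUE) / (2 * nb_)

  ok <- auto & na_ > 0 & nb_ > 0
  n_excluded <- sum(auto & !(na_ > 0 & nb_ > 0))

  pa <- pa[ok]; pb <- pb[ok]
  if (weight_by_n) {
    wa <- na_[ok] / (na_[ok] + nb_[ok]); wb <- 1 - wa
  } else {
    wa <- wb <- 0.5
  }
  pbar <- wa * pa + wb * pb
  ht <- 2 * pbar * (1 - pbar)
  hs <- wa * 2 * pa * (1 - pa) + wb * 2 * pb * (1 - pb)
  fst <- ifelse(ht > 0, (ht - hs) / ht, 0)

  out <- data.frame(record_id = v$record_id[ok], chrom = v$chrom[ok],
                    pos = v$pos[ok], end = v$end[ok], svtype = v$svtype[ok],
                    p_a = pa, p_b = pb, ht = ht, hs = hs, fst = fst,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Select the top fraction of an Fst scan
#'
#' Ranks variants by Fst (descending), breaking ties by `record_id`
#' (ascending), and flags the first `ceiling(fraction * N)` as selected.
#' The threshold reported is the Fst of the last selected variant.
#'
#' @param results data.frame from [fst_per_variant()] (needs `record_id`,
#'   `fst`).
#' @param fraction top fraction to select (default 0.01).
#' @return a list with `threshold`, `n_selected`, and `results` — the input
#'   with a logical `selected` column added (original row order preserved).
#' @export
select_top_fraction <- function(results, fraction = 0.01) {
  n <- nrow(results)
  if (n < 1) stop("empty Fst scan")
  stopifnot(fraction > 0, fraction <= 1)
  k <- ceiling(fraction * n)
  o <- order(-results$fst, results$record_id)
  sel_ids <- results$record_id[o[seq_len(k)]]
  results$selected <- results$record_id %in% sel_ids
  list(threshold = results$fst[o[k]], n_selected = k, results = results)
}

#' Allele-frequency spectrum of a population
#'
#' Variants segregating in the population (`p > 0`) are binned into
#' `n_bins` right-closed intervals `((k-1)/n, k/n]`; with the default 10
#' bins these are the 0–0.1, 0.1–0.2, ..., 0.9–1 classes. Variants absent
#' from the population (`p = 0` or undefined) are excluded.
#'
#' @param callset a labelled [cnv_callset].
#' @param pop population label.
#' @param n_bins number of bins (default 10).
#' @param by_type also tabulate per svtype (default `TRUE`).
#' @return data.frame with columns `svtype` (including a pooled `"all"`
#'   row set), `bin` (1-based), `lower`, `upper`, `count`.
#' @export
frequency_spectrum <- function(callset, pop, n_bins = 10L, by_type = TRUE) {
  stopifnot(n_bins >= 1)
  p <- allele_freqs(callset, pop)
  keep <- !is.na(p) & p > 0
  p <- p[keep]
  svtype <- callset$variants$svtype[keep]
  bin <- pmin(pmax(ceiling(p * n_bins), 1L), n_bins)

  tab_for <- function(sel, label) {
    counts <- tabulate(bin[sel], nbins = n_bins)
    data.frame(svtype = label, bin = seq_len(n_bins),
               lower = (seq_len(n_bins) - 1) / n_bins,
               upper = seq_len(n_bins) / n_bins, count = counts,
               stringsAsFactors = FALSE)
  }
  out <- tab_for(rep(TRUE, length(bin)), "all")
  if (by_type)
    for (t in c("DEL", "DUP", "INS")) out <- rbind(out, tab_for(svtype == t, t))
  rownames(out) <- NULL
  out
}

#' Shared and population-unique variant counts
#'
#' A variant is "present" in a population when its alternate-allele
#' frequency there is defined and positive. Returns the Venn partition of
#' variants present in at least one of the two populations.
#'
#' @param callset a labelled [cnv_callset].
#' @param pop_a,pop_b population labels.
#' @return list with `n_shared`, `n_unique_a`, `n_unique_b`; the three sum
#'   to the number of variants present somewhere.
#' @export
callset_comparison <- function(callset, pop_a, pop_b) {
  pa <- allele_freqs(callset, pop_a)
  pb <- allele_freqs(callset, pop_b)
  in_a <- !is.na(pa) & pa > 0
  in_b <- !is.na(pb) & pb > 0
  list(n_shared = sum(in_a & in_b),
       n_unique_a = sum(in_a & !in_b),
       n_unique_b = sum(!in_a & in_b))
}

#' Callset summary statistics
#'
#' Per-type counts and length statistics over the variants present in a
#' population (`p > 0`), or over all records when `pop` is `NULL`. Lengths
#' are `|svlen|`; the mean is additionally reported rounded to the nearest
#' bp for display.
#'
#' @param callset a [cnv_callset].
#' @param pop population label or `NULL`.
#' @return list with `n_del`, `n_dup`, `n_ins`, `n_total`, `total_length`,
#'   `mean_length`, `mean_length_bp` (rounded), `median_length`. For an
#'   empty selection the counts are 0 and the length statistics `NA`.
#' @export
callset_summary <- function(callset, pop = NULL) {
  v <- callset$variants
  if (!is.null(pop)) {
    p <- allele_freqs(callset, pop)
    v <- v[!is.na(p) & p > 0, , drop = FALSE]
  }
  len <- abs(v$svlen)
  n <- nrow(v)
  list(
    n_del = sum(v$svtype == "DEL"),
    n_dup = sum(v$svtype == "DUP"),
    n_ins = sum(v$svtype == "INS"),
    n_total = n,
    total_length = if (n) sum(as.numeric(len)) else 0,
    mean_length = if (n) mean(len) else NA_real_,
    mean_length_bp = if (n) round(mean(len)) else NA_real_,
    median_length = if (n) stats::median(len) else NA_real_
  )
}
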