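#' QC configuration
#'
#' Site-level filters applied after merging: a cap on absolute SV length,
#' a one-sided excess-heterozygosity exact-test floor, a missingness cap,
#' and an exclusive minor-allele-frequency floor.
#'
#' @param max_abs_svlen maximum `|svlen|` in bp (default 1e7).
#' @param min_exchet_p minimum excess-het p-value (default 0.05, inclusive).
#' @param max_f_missing maximum fraction of missing genotypes (default 0.2,
#'   inclusive).
#' @param min_maf exclusive MAF floor (default 0: monomorphic sites fail).
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(max_abs_svlen = 10000000L, min_exchet_p = 0.05,
                      max_f_missing = 0.2, min_maf = 0) {
  stopifnot(max_abs_svlen >= 1, min_exchet_p >= 0, min_exchet_p <= 1,
            max_f_missing >= 0, max_f_missing <= 1, min_maf >= 0, min_maf < 1)
  structure(list(max_abs_svlen = max_abs_svlen, min_exchet_p = min_exchet_p,
                 max_f_missing = max_f_missing, min_maf = min_maf),
            class = "qc_config")
}

#' Genotype-state counts at a site
#'
#' @param record an `sv_record` (see [callset_record()]), or a dosage vector.
#' @return a list of class `site_counts` with `n_hom_ref`, `n_het`,
#'   `n_hom_alt`, `n_missing`; the four counts sum to the cohort size.
#' @export
site_counts <- function(record) {
  g <- if (is.list(record)) record$geno else record
  structure(list(n_hom_ref = sum(g == 0L, na.rm = TRUE),
                 n_het = sum(g == 1L, na.rm = TRUE),
                 n_hom_alt = sum(g == 2L, na.rm = TRUE),
                 n_missing = sum(is.na(g))),
            class = "site_counts")
}

#' One-sided excess-heterozygosity exact test
#'
#' Levene's conditional distribution of the heterozygote count given the
#' allele counts at a biallelic diploid site assigns
#' \deqn{P(n_{het}=k) \propto \frac{N!}{n_{AA}!\,k!\,n_{aa}!}\,2^k}
#' to every heterozygote count `k` of matching parity, where the homozygote
#' counts are determined by `k` and the allele counts. The test returns the
#' upper tail `P(n_het >= observed)` — small values flag a heterozygote
#' excess relative to Hardy-Weinberg. This is the ExcHet statistic of
#' standard VCF toolchains; the mid-p variant is not used.
#'
#' The distribution is built by the numerically stable parity recurrence
#' `P(k+2)/P(k) = (nA-k)(na-k) / ((k+1)(k+2))` and normalized.
#'
#' @param counts a [site_counts()] (or list with `n_hom_ref`, `n_het`,
#'   `n_hom_alt`).
#' @return p-value in (0, 1\]; monomorphic sites return exactly 1.
#' @export
exc_het_pvalue <- function(counts) {
  nAA <- counts$n_hom_ref; nhet <- counts$n_het; naa <- counts$n_hom_alt
  N <- nAA + nhet + naa
  if (N < 1) stop("excess-het test needs at least one genotyped sample")
  nA <- 2L * nAA + nhet
  na <- 2L * naa + nhet
  rare <- min(nA, na)
  if (rare == 0L) return(1)          # one allele absent: degenerate
  k_min <- rare %% 2L
  ks <- seq.int(k_min, rare, by = 2L)
  w <- numeric(length(ks))
  w[1] <- 1
  if (length(ks) > 1) {
    for (t in 1:(length(ks) - 1)) {
      k <- ks[t]
      w[t + 1] <- w[t] * (nA - k) * (na - k) / ((k + 1) * (k + 2))
      if (w[t + 1] > 1e300) w <- w / 1e300   # rescale; only ratios matter
    }
  }
  sum(w[ks >= nhet]) / sum(w)
}

#' Fraction of missing genotypes
#'
#' @param counts a [site_counts()].
#' @return `n_missing / cohort size`.
#' @export
f_missing <- function(counts) {
  n <- counts$n_hom_ref + counts$n_het + counts$n_hom_alt + counts$n_missing
  if (n < 1) stop("empty cohort")
  counts$n_missing / n
}

#' Minor allele frequency
#'
#' Computed over non-missing genotypes only: with
#' `p = (2 n_hom_alt + n_het) / (2 n_genotyped)`, returns `min(p, 1 - p)`.
#'
#' @param counts a [site_counts()].
#' @return fraction in \[0, 0.5\].
#' @export
maf <- function(counts) {
  ng <- counts$n_hom_ref + counts$n_het + counts$n_hom_alt
  if (ng < 1) stop("MAF undefined with zero genotyped samples")
  p <- (2 * counts$n_hom_alt + counts$n_het) / (2 * ng)
  min(p, 1 - p)
}

#' Apply site-level quality control
#'
#' Retains records satisfying all four rules:
#' `|svlen| <= max_abs_svlen`, excess-het p `>= min_exchet_p`,
#' missingness `<= max_f_missing`, and MAF `> min_maf`. The rules are
#' independent, so their application commutes; surviving records are
#' returned unaltered. Records with zero genotyped samples have undefined
#' ExcHet/MAF and fail those rules (they always also fail the missingness
#' cap at any threshold below 1).
#'
#' @param callset a [cnv_callset].
#' @param cfg a [qc_config()].
#' @return a list with `callset` (retained records) and `report`, a
#'   data.frame over all input records with the per-rule values, per-rule
#'   pass flags, `kept`, and `failed` (semicolon-joined names of failed
#'   rules, `""` for retained records).
#' @export
apply_qc <- function(callset, cfg = qc_config()) {
  validate_callset(callset)
  v <- callset$variants
  n <- nrow(v)
  g <- callset$geno
  n_samp <- length(callset$samples)

  exchet <- numeric(n); fmiss <- numeric(n); mafv <- numeric(n)
  for (i in seq_len(n)) {
    sc <- site_counts(g[i, ])
    fmiss[i] <- if (n_samp) sc$n_missing / n_samp else 1
    ng <- sc$n_hom_ref + sc$n_het + sc$n_hom_alt
    if (ng >= 1) {
      exchet[i] <- exc_het_pvalue(sc)
      mafv[i] <- maf(sc)
    } else {
      exchet[i] <- NA_real_
      mafv[i] <- NA_real_
    }
  }

  pass_svlen <- abs(v$svlen) <= cfg$max_abs_svlen
  pass_exchet <- !is.na(exchet) & exchet >= cfg$min_exchet_p
  pass_fmiss <- fmiss <= cfg$max_f_missing
  pass_maf <- !is.na(mafv) & mafv > cfg$min_maf
  kept <- pass_svlen & pass_exchet & pass_fmiss & pass_maf

  failed <- vapply(seq_len(n), function(i) {
    paste(c("svlen", "exchet", "fmissing", "maf")[
      !c(pass_svlen[i], pass_exchet[i], pass_fmiss[i], pass_maf[i])],
      collapse = ";")
  }, character(1))

  report <- data.frame(
    record_id = v$record_id, svlen = v$svlen, exchet_p = exchet,
    f_missing = fmiss, maf = mafv,
    pass_svlen = pass_svlen, pass_exchet = pass_exchet,
    pass_fmissing = pass_fmiss, pass_maf = pass_maf,
    kept = kept, failed = failed, stringsAsFactors = FALSE
  )

  out <- callset
  out$variants <- v[kept, , drop = FALSE]
  out$geno <- g[kept, , drop = FALSE]
  out <- sort_callset(out)
  list(callset = out, report = report)
}
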