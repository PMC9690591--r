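# Shared fixtures and independent oracles.

# Quick callset builder: `rows` is a data.frame of variant fields, `geno` a
# matrix (rows = variants) of dosages.
make_cs <- function(rows, geno, pop = NULL) {
  samples <- colnames(geno)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(geno)))
  cnv_callset(rows, geno, samples, pop = pop)
}

# One-row variant table.
vrow <- function(id, chrom, pos, end, svtype, svlen = NULL) {
  if (is.null(svlen))
    svlen <- if (svtype == "INS") 100L else (end - pos + 1L) * (if (svtype == "DEL") -1L else 1L)
  data.frame(record_id = id, chrom = chrom, pos = as.integer(pos),
             end = as.integer(end), svtype = svtype, svlen = as.integer(svlen),
             stringsAsFactors = FALSE)
}

# Independent excess-heterozygosity oracle: absolute Levene probabilities
# from log-factorials (no recurrence, no normalization trick).
exchet_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  N <- n_hom_ref + n_het + n_hom_alt
  nA <- 2 * n_hom_ref + n_het
  na <- 2 * n_hom_alt + n_het
  rare <- min(nA, na)
  if (rare == 0) return(1)
  ks <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(ks, function(k) {
    nAA <- (nA - k) / 2; naa <- (na - k) / 2
    lfactorial(N) - lfactorial(nAA) - lfactorial(k) - lfactorial(naa) +
      k * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * N)
  }, numeric(1))
  sum(exp(logp[ks >= n_het]))
}

# Random small callset exercising every svtype, overlap regime and
# missingness pattern; coordinates squeezed so overlaps are common.
random_callset <- function(n_rec, n_samp = 6, chroms = c("chr1", "chr2")) {
  svtype <- sample(c("DEL", "DUP", "INS"), n_rec, replace = TRUE)
  pos <- sample.int(2000, n_rec, replace = TRUE)
  len <- sample(50:400, n_rec, replace = TRUE)
  end <- ifelse(svtype == "INS", pos, pos + len - 1L)
  rows <- data.frame(
    record_id = sprintf("r%03d", seq_len(n_rec)),
    chrom = sample(chroms, n_rec, replace = TRUE),
    pos = as.integer(pos), end = as.integer(end), svtype = svtype,
    svlen = as.integer(ifelse(svtype == "DEL", -len, len)),
    stringsAsFactors = FALSE)
  geno <- matrix(sample(c(0:2, NA), n_rec * n_samp, replace = TRUE,
                        prob = c(0.4, 0.25, 0.2, 0.15)), n_rec, n_samp)
  make_cs(rows, geno)
}

# Brute-force merge oracle: enumerate every same-chrom same-type pair,
# re-derive the edge predicate with inline arithmetic, and take connected
# components with igraph.
brute_components <- function(callset, cfg = merge_config()) {
  v <- callset$variants; g <- callset$geno; n <- nrow(v)
  edges <- matrix(integer(0), 0, 2)
  for (i in seq_len(max(0, n - 1))) for (j in (i + 1):n) {
    if (n < 2) break
    if (v$chrom[i] != v$chrom[j] || v$svtype[i] != v$svtype[j]) next
    if (v$svtype[i] == "INS") {
      la <- abs(v$svlen[i]); lb <- abs(v$svlen[j])
      loc <- abs(v$pos[i] - v$pos[j]) <= cfg$ins_breakpoint_window &&
        min(la, lb) / max(la, lb) >= cfg$dupins_overlap
    } else {
      inter <- min(v$end[i], v$end[j]) - max(v$pos[i], v$pos[j]) + 1
      ro <- if (inter <= 0) 0 else
        min(inter / (v$end[i] - v$pos[i] + 1), inter / (v$end[j] - v$pos[j] + 1))
      loc <- ro >= if (v$svtype[i] == "DEL") cfg$del_overlap else cfg$dupins_overlap
    }
    if (!loc) next
    both <- !is.na(g[i, ]) & !is.na(g[j, ])
    conc <- if (!any(both)) 0 else sum(g[i, both] == g[j, both]) / sum(both)
    if (conc >= cfg$concordance_min) edges <- rbind(edges, c(i, j))
  }
  gr <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) gr <- igraph::add_edges(gr, t(edges))
  comp <- igraph::components(gr)$membership
  # canonical partition signature keyed by record_id
  split(v$record_id, comp)
}

# Partition signature (order-free) for comparing clusterings.
partition_sig <- function(groups) {
  canon <- lapply(groups, function(g) sort(g))
  canon <- canon[order(vapply(canon, `[`, character(1), 1))]
  unname(canon)
}

# Tiny two-population callset with prescribed per-population dosage rows.
two_pop_cs <- function(geno_a, geno_b, svtype = "DEL", chrom = "chr1") {
  n_rec <- nrow(geno_a)
  rows <- do.call(rbind, lapply(seq_len(n_rec), function(i)
    vrow(sprintf("v%02d", i), chrom, 1000L * i, 1000L * i + 499L, svtype)))
  geno <- cbind(geno_a, geno_b)
  samples <- c(sprintf("a%02d", seq_len(ncol(geno_a))),
               sprintf("b%02d", seq_len(ncol(geno_b))))
  colnames(geno) <- samples
  pop <- stats::setNames(rep(c("A", "B"), c(ncol(geno_a), ncol(geno_b))), samples)
  cnv_callset(rows, geno, samples, pop = pop)
}
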