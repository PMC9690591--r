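#' Simulation configuration
#'
#' Parameters of the two-population diploid CNV cohort generator. Defaults
#' mirror the study design the package targets: a 45-sample domestic
#' population (`popA`) versus a 19-sample wild population (`popB`),
#' deletion-dominated callsets, CNV lengths from 50 bp up to 100 kb
#' (log-uniform; insertions 50-1000 bp), sporadic missing genotypes, and a
#' fraction of calls re-emitted as jittered near-duplicates to exercise
#' merging.
#'
#' @param n_variants number of distinct variants to simulate.
#' @param n_pop_a,n_pop_b population sizes (defaults 45 and 19).
#' @param fst_param Balding-Nichols differentiation parameter `F` in
#'   \[0, 1).
#' @param type_mix named proportions over DEL/DUP/INS (must sum to 1).
#' @param len_range_deldup,len_range_ins log-uniform length ranges in bp.
#' @param genome named integer vector of chromosome lengths; includes a
#'   small `X` by default so sex-chromosome exclusion is exercised.
#' @param p_missing per-genotype missingness probability.
#' @param dup_rate fraction of variants re-emitted as jittered duplicates.
#' @param jitter_bp maximum coordinate jitter of a duplicate; the effective
#'   jitter is also capped at 5% of the variant length so an injected
#'   duplicate always stays above the default merge thresholds.
#' @param pop_labels labels for the two populations.
#' @param seed integer seed; every draw derives from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_variants = 2000L, n_pop_a = 45L, n_pop_b = 19L,
                       fst_param = 0.2,
                       type_mix = c(DEL = 0.70, DUP = 0.05, INS = 0.25),
                       len_range_deldup = c(50, 100000),
                       len_range_ins = c(50, 1000),
                       genome = c(chr1 = 50000000L, chr2 = 40000000L,
                                  chr3 = 30000000L, chr4 = 20000000L,
                                  X = 10000000L),
                       p_missing = 0.02, dup_rate = 0.10, jitter_bp = 50L,
                       pop_labels = c("popA", "popB"), seed = 1L) {
  if (n_variants < 1) stop("n_variants must be >= 1")
  if (n_pop_a < 1 || n_pop_b < 1) stop("population sizes must be >= 1")
  if (fst_param < 0 || fst_param >= 1) stop("fst_param must be in [0, 1)")
  if (!setequal(names(type_mix), c("DEL", "DUP", "INS")) ||
      abs(sum(type_mix) - 1) > 1e-8 || any(type_mix < 0))
    stop("type_mix must be named DEL/DUP/INS proportions summing to 1")
  if (p_missing < 0 || p_missing > 1 || dup_rate < 0 || dup_rate > 1)
    stop("p_missing and dup_rate must be in [0, 1]")
  if (is.null(names(genome)) || any(genome < 1))
    stop("genome must be a named vector of positive chromosome lengths")
  structure(list(n_variants = as.integer(n_variants),
                 n_pop_a = as.integer(n_pop_a), n_pop_b = as.integer(n_pop_b),
                 fst_param = fst_param, type_mix = type_mix[c("DEL", "DUP", "INS")],
                 len_range_deldup = len_range_deldup,
                 len_range_ins = len_range_ins, genome = genome,
                 p_missing = p_missing, dup_rate = dup_rate,
                 jitter_bp = as.integer(jitter_bp), pop_labels = pop_labels,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Internal: log-uniform integer lengths in [lo, hi].
rloguniform <- function(n, lo, hi) {
  pmax(1L, as.integer(round(exp(stats::runif(n, log(lo), log(hi))))))
}

#' Simulate a two-population CNV cohort
#'
#' Allele frequencies follow the Balding-Nichols model: each variant draws
#' an ancestral frequency `p ~ U(0.05, 0.95)`, then population frequencies
#' `p_a, p_b ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` independently (for `F = 0`
#' both equal `p` exactly). Genotypes are Binomial(2, p_pop) per sample —
#' Hardy-Weinberg within populations, no linkage between variants.
#' Coordinates are uniform over the configured genome with type-specific
#' log-uniform lengths. A `dup_rate` fraction of variants is re-emitted
#' with jittered coordinates and the same underlying genotypes (each copy
#' receives independent missingness), so injected duplicates always merge
#' under default thresholds. Ancestral frequencies are bounded away from
#' 0/1, but finite-sample draws can still be monomorphic — such sites are
#' kept deliberately to exercise the MAF filter.
#'
#' @param cfg a [sim_config()].
#' @return list with `callset` (a labelled, sorted [cnv_callset]) and
#'   `truth`, a data.frame with per-record `p_anc`, `p_a`, `p_b` and
#'   `duplicate_of` (`NA` for original calls). Fully reproducible from
#'   `cfg$seed`.
#' @export
simulate_callset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  nv <- cfg$n_variants
  F <- cfg$fst_param
  n_a <- cfg$n_pop_a; n_b <- cfg$n_pop_b

  p_anc <- stats::runif(nv, 0.05, 0.95)
  if (F == 0) {
    p_a <- p_b <- p_anc
  } else {
    shp1 <- p_anc * (1 - F) / F
    shp2 <- (1 - p_anc) * (1 - F) / F
    p_a <- stats::rbeta(nv, shp1, shp2)
    p_b <- stats::rbeta(nv, shp1, shp2)
  }

  svtype <- sample(names(cfg$type_mix), nv, replace = TRUE, prob = cfg$type_mix)
  len <- integer(nv)
  ii <- svtype %in% c("DEL", "DUP")
  len[ii] <- rloguniform(sum(ii), cfg$len_range_deldup[1], cfg$len_range_deldup[2])
  len[!ii] <- rloguniform(sum(!ii), cfg$len_range_ins[1], cfg$len_range_ins[2])

  chrom <- sample(names(cfg$genome), nv, replace = TRUE,
                  prob = as.numeric(cfg$genome))
  pos <- integer(nv)
  for (cn in unique(chrom)) {
    w <- chrom == cn
    room <- pmax(1L, cfg$genome[[cn]] - len[w])
    pos[w] <- 1L + as.integer(floor(stats::runif(sum(w)) * room))
  }
  end <- ifelse(svtype == "INS", pos, pos + len - 1L)
  svlen <- ifelse(svtype == "DEL", -len, len)

  geno_true <- matrix(NA_integer_, nv, n_a + n_b)
  geno_true[, seq_len(n_a)] <- stats::rbinom(nv * n_a, 2, rep(p_a, n_a))
  geno_true[, n_a + seq_len(n_b)] <- stats::rbinom(nv * n_b, 2, rep(p_b, n_b))

  # near-duplicate injection
  n_dup <- as.integer(round(cfg$dup_rate * nv))
  dup_src <- if (n_dup) sort(sample.int(nv, n_dup)) else integer(0)
  dmax <- pmin(cfg$jitter_bp, pmax(0L, as.integer(floor(0.05 * len[dup_src]))))
  shift <- if (n_dup) as.integer(round(stats::runif(n_dup, -dmax, dmax))) else integer(0)

  ids <- sprintf("sv%05d", seq_len(nv))
  dup_ids <- sprintf("%s_dup", ids[dup_src])
  all_chrom <- c(chrom, chrom[dup_src])
  all_pos <- c(pos, pmax(1L, pos[dup_src] + shift))
  all_len <- c(len, len[dup_src])
  all_type <- c(svtype, svtype[dup_src])
  all_end <- ifelse(all_type == "INS", all_pos, all_pos + all_len - 1L)
  all_svlen <- ifelse(all_type == "DEL", -all_len, all_len)
  all_ids <- c(ids, dup_ids)
  geno_all <- rbind(geno_true, geno_true[dup_src, , drop = FALSE])

  # independent per-copy missingness
  if (cfg$p_missing > 0) {
    mask <- matrix(stats::runif(length(geno_all)) < cfg$p_missing,
                   nrow(geno_all), ncol(geno_all))
    geno_all[mask] <- NA_integer_
  }

  samples <- c(sprintf("%s_%02d", cfg$pop_labels[1], seq_len(n_a)),
               sprintf("%s_%02d", cfg$pop_labels[2], seq_len(n_b)))
  pop <- stats::setNames(rep(cfg$pop_labels, c(n_a, n_b)), samples)

  callset <- cnv_callset(
    variants = data.frame(record_id = all_ids, chrom = all_chrom,
                          pos = all_pos, end = as.integer(all_end),
                          svtype = all_type, svlen = as.integer(all_svlen),
                          stringsAsFactors = FALSE),
    geno = geno_all, samples = samples, pop = pop, contigs = cfg$genome
  )

  truth <- data.frame(
    record_id = all_ids,
    p_anc = c(p_anc, p_anc[dup_src]),
    p_a = c(p_a, p_a[dup_src]),
    p_b = c(p_b, p_b[dup_src]),
    duplicate_of = c(rep(NA_character_, nv), ids[dup_src]),
    stringsAsFactors = FALSE
  )
  truth <- truth[match(callset$variants$record_id, truth$record_id), ]
  rownames(truth) <- NULL
  list(callset = callset, truth = truth)
}

#' Simulate gene models with planted test coordinates
#'
#' Lays out non-overlapping genes (2-8 exons, UTRs, alternating strands,
#' one non-coding gene, one closely spaced gene pair) on the first
#' configured chromosome and returns, alongside the models, a table of
#' coordinates constructed to fall in every one of the 11 annotation
#' classes — including the combined `UTR3_UTR5` and
#' `upstream_downstream` classes, which require the gene pair.
#'
#' @param cfg a [sim_config()] (supplies the genome and seed).
#' @param n_genes number of genes (minimum 4).
#' @param upstream_bp flank size the planted upstream/downstream/intergenic
#'   coordinates assume (default 1000, matching [classify_variant()]).
#' @return list with `models` (list of [gene_model]) and `planted`, a
#'   data.frame with `class`, `chrom`, `pos`, `end`.
#' @export
simulate_gene_models <- function(cfg = sim_config(), n_genes = 10L,
                                 upstream_bp = 1000L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_genes < 4) stop("need at least 4 genes (isolated, ncRNA, and a pair)")
  set.seed(cfg$seed + 7L)
  chrom <- names(cfg$genome)[1]
  glen <- cfg$genome[[1]]

  gap_iso <- 3L * upstream_bp          # isolation cushion between genes
  gap_pair <- 400L                     # close pair: inside both flanks

  make_gene <- function(id, start, strand, n_ex, coding = TRUE) {
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    int_len <- if (n_ex > 1) sample(200:800, n_ex - 1, replace = TRUE) else integer(0)
    starts <- integer(n_ex); ends <- integer(n_ex)
    cur <- start
    for (k in seq_len(n_ex)) {
      starts[k] <- cur; ends[k] <- cur + ex_len[k] - 1L
      if (k < n_ex) cur <- ends[k] + int_len[k] + 1L
    }
    exons <- data.frame(start = starts, end = ends)
    if (!coding)
      return(gene_model(paste0("gene_", id), paste0("tx_", id), chrom, strand, exons))
    # UTR5: 60 bp at the 5' end; UTR3: 80 bp at the 3' end (strand-aware)
    if (strand == "+") {
      utr5 <- data.frame(start = starts[1], end = starts[1] + 59L)
      utr3 <- data.frame(start = ends[n_ex] - 79L, end = ends[n_ex])
    } else {
      utr5 <- data.frame(start = ends[n_ex] - 59L, end = ends[n_ex])
      utr3 <- data.frame(start = starts[1], end = starts[1] + 79L)
    }
    # carve the UTRs out of the terminal exons
    cds <- exons
    if (strand == "+") {
      cds$start[1] <- utr5$end + 1L
      cds$end[n_ex] <- utr3$start - 1L
    } else {
      cds$start[1] <- utr3$end + 1L
      cds$end[n_ex] <- utr5$start - 1L
    }
    cds <- cds[cds$start <= cds$end, , drop = FALSE]
    gene_model(paste0("gene_", id), paste0("tx_", id), chrom, strand, exons,
               cds = cds, utr5 = utr5, utr3 = utr3)
  }

  models <- list()
  cursor <- 10L * upstream_bp
  # gene 1: isolated coding, + strand, >= 2 exons (planting workhorse)
  g1 <- make_gene(1L, cursor, "+", sample(3:8, 1))
  models[[1]] <- g1
  cursor <- max(g1$exons$end) + gap_iso
  # gene 2: non-coding
  g2 <- make_gene(2L, cursor, sample(c("+", "-"), 1), sample(2:4, 1), coding = FALSE)
  models[[2]] <- g2
  cursor <- max(g2$exons$end) + gap_iso
  # genes 3 & 4: close coding pair on +, for combined classes
  g3 <- make_gene(3L, cursor, "+", sample(2:5, 1))
  models[[3]] <- g3
  g4 <- make_gene(4L, max(g3$exons$end) + gap_pair + 1L, "+", sample(2:5, 1))
  models[[4]] <- g4
  cursor <- max(g4$exons$end) + gap_iso
  # remaining genes: random structure
  if (n_genes > 4) {
    for (id in 5:n_genes) {
      g <- make_gene(id, cursor, sample(c("+", "-"), 1), sample(2:8, 1),
                     coding = stats::runif(1) > 0.2)
      models[[id]] <- g
      cursor <- max(g$exons$end) + gap_iso
    }
  }
  if (cursor + 10L * upstream_bp > glen)
    stop("genome too small for ", n_genes, " genes")

  ex <- g1$exons; n_ex <- nrow(ex)
  int1_s <- ex$end[1] + 1L; int1_e <- ex$start[2] - 1L
  planted <- rbind(
    data.frame(class = "exonic", pos = ex$start[2] + 50L, end = ex$start[2] + 59L),
    data.frame(class = "splicing", pos = int1_s, end = int1_s + 1L),
    data.frame(class = "ncRNA", pos = g2$exons$start[1] + 10L,
               end = g2$exons$start[1] + 19L),
    data.frame(class = "UTR5", pos = ex$start[1] + 5L, end = ex$start[1] + 20L),
    data.frame(class = "UTR3", pos = ex$end[n_ex] - 20L, end = ex$end[n_ex] - 5L),
    data.frame(class = "UTR3_UTR5",
               pos = max(g3$exons$end) - 40L,
               end = min(g4$exons$start) + 30L),
    data.frame(class = "intronic", pos = (int1_s + int1_e) %/% 2L,
               end = (int1_s + int1_e) %/% 2L + 1L),
    data.frame(class = "upstream", pos = ex$start[1] - 500L,
               end = ex$start[1] - 491L),
    data.frame(class = "downstream", pos = ex$end[n_ex] + 491L,
               end = ex$end[n_ex] + 500L),
    data.frame(class = "upstream_downstream",
               pos = max(g3$exons$end) + gap_pair %/% 2L,
               end = max(g3$exons$end) + gap_pair %/% 2L + 1L),
    data.frame(class = "intergenic", pos = cursor + 5L * upstream_bp,
               end = cursor + 5L * upstream_bp + 9L)
  )
  planted$chrom <- chrom
  planted <- planted[, c("class", "chrom", "pos", "end")]
  list(models = models, planted = planted)
}
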