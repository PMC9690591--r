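#' Merging configuration
#'
#' Thresholds for group-level de-redundancy of SV calls. Deletions merge at
#' 50% reciprocal overlap, duplications at 90%; insertions (point events)
#' merge when breakpoints fall within a window and lengths agree to the
#' same 90% ratio. In every case the genotype vectors must agree for at
#' least `concordance_min` of the jointly genotyped samples.
#'
#' @param del_overlap minimum reciprocal overlap for DEL pairs (default 0.5).
#' @param dupins_overlap minimum reciprocal overlap for DUP pairs, and
#'   minimum length ratio for INS pairs (default 0.9).
#' @param concordance_min minimum genotype concordance (default 0.95).
#' @param ins_breakpoint_window maximum INS breakpoint distance in bp
#'   (default 100).
#' @return a list of class `merge_config`.
#' @export
merge_config <- function(del_overlap = 0.5, dupins_overlap = 0.9,
                         concordance_min = 0.95, ins_breakpoint_window = 100L) {
  fr <- c(del_overlap, dupins_overlap, concordance_min)
  if (any(fr <= 0 | fr > 1)) stop("overlap/concordance fractions must be in (0, 1]")
  if (ins_breakpoint_window < 0) stop("ins_breakpoint_window must be >= 0")
  structure(list(del_overlap = del_overlap, dupins_overlap = dupins_overlap,
                 concordance_min = concordance_min,
                 ins_breakpoint_window = as.integer(ins_breakpoint_window)),
            class = "merge_config")
}

#' Reciprocal overlap of two interval variants
#'
#' For two DEL or DUP records on the same chromosome, returns
#' `min(I/len_a, I/len_b)` where `I` is the length of the intersection of
#' the 1-based inclusive intervals; 0 when disjoint or on different
#' chromosomes. Insertions are point events and have no interval overlap —
#' use [ins_similarity()].
#'
#' @param a,b `sv_record` objects (or any list with `chrom`, `pos`, `end`,
#'   `svtype`).
#' @return fraction in \[0, 1\].
#' @export
reciprocal_overlap <- function(a, b) {
  if (a$svtype == "INS" || b$svtype == "INS")
    stop("reciprocal_overlap is undefined for INS; use ins_similarity()")
  if (a$chrom != b$chrom) return(0)
  inter <- min(a$end, b$end) - max(a$pos, b$pos) + 1
  if (inter <= 0) return(0)
  min(inter / (a$end - a$pos + 1), inter / (b$end - b$pos + 1))
}

#' Insertion equivalence test
#'
#' Two insertions are considered the same event when their breakpoints lie
#' within `window` bp and their lengths agree to at least `length_ratio`
#' (smaller/larger).
#'
#' @param a,b INS `sv_record` objects on the same chromosome.
#' @param window maximum breakpoint distance in bp.
#' @param length_ratio minimum length ratio (default 0.9).
#' @return logical.
#' @export
ins_similarity <- function(a, b, window = 100L, length_ratio = 0.9) {
  if (a$svtype != "INS" || b$svtype != "INS")
    stop("ins_similarity requires two INS records")
  if (a$chrom != b$chrom) return(FALSE)
  la <- abs(a$svlen); lb <- abs(b$svlen)
  abs(a$pos - b$pos) <= window && min(la, lb) / max(la, lb) >= length_ratio
}

#' Genotype concordance between two records
#'
#' Fraction of samples, among those genotyped in *both* records, whose
#' dosage states agree. Missingness never counts as agreement: with no
#' jointly genotyped sample the concordance is 0, so an all-missing record
#' can never pass a concordance gate.
#'
#' @param a,b `sv_record` objects with dosage vectors over the same samples.
#' @return fraction in \[0, 1\].
#' @export
genotype_concordance <- function(a, b) {
  ga <- a$geno; gb <- b$geno
  if (length(ga) != length(gb)) stop("genotype vectors differ in length")
  both <- !is.na(ga) & !is.na(gb)
  if (!any(both)) return(0)
  sum(ga[both] == gb[both]) / sum(both)
}

#' Group-level de-redundancy of a callset
#'
#' Single-linkage clustering of same-type, same-chromosome records: an edge
#' joins two records when they satisfy the type-specific location criterion
#' (DEL: reciprocal overlap >= `del_overlap`; DUP: reciprocal overlap >=
#' `dupins_overlap`; INS: [ins_similarity()]) *and* their genotype
#' concordance is at least `concordance_min`. One representative — the
#' member with the fewest missing genotypes, ties broken by smallest
#' (pos, end, record_id) — is emitted per cluster.
#'
#' A sorted sweep restricts pair evaluation to records within reachable
#' distance, so the pass is near-linear after sorting; the resulting
#' partition is identical to brute-force connected components.
#'
#' @param callset a [cnv_callset].
#' @param cfg a [merge_config()].
#' @return a list with `callset` (representatives only, canonical order) and
#'   `clusters`, a data.frame with columns `representative_id`, `size` and
#'   list-column `member_ids`. Cluster sizes sum to the input record count.
#' @export
merge_callset <- function(callset, cfg = merge_config()) {
  validate_callset(callset)
  cs <- sort_callset(callset)
  v <- cs$variants
  g <- cs$geno
  n <- nrow(v)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }

  concord <- function(i, j) {
    both <- !is.na(g[i, ]) & !is.na(g[j, ])
    if (!any(both)) return(0)
    sum(g[i, both] == g[j, both]) / sum(both)
  }

  for (grp in split(seq_len(n), list(v$chrom, v$svtype), drop = TRUE)) {
    m <- length(grp)
    if (m < 2) next
    svt <- v$svtype[grp[1]]
    pos <- v$pos[grp]; end <- v$end[grp]
    cmax_end <- cummax(end)
    for (jj in 2:m) {
      for (ii in (jj - 1):1) {
        if (svt == "INS") {
          if (pos[jj] - pos[ii] > cfg$ins_breakpoint_window) break
          hit <- ins_similarity(
            list(svtype = "INS", chrom = "", pos = pos[ii], svlen = v$svlen[grp[ii]]),
            list(svtype = "INS", chrom = "", pos = pos[jj], svlen = v$svlen[grp[jj]]),
            window = cfg$ins_breakpoint_window,
            length_ratio = cfg$dupins_overlap)
        } else {
          if (pos[jj] > cmax_end[ii]) break
          inter <- min(end[ii], end[jj]) - max(pos[ii], pos[jj]) + 1
          if (inter <= 0) { hit <- FALSE } else {
            ro <- min(inter / (end[ii] - pos[ii] + 1), inter / (end[jj] - pos[jj] + 1))
            hit <- ro >= if (svt == "DEL") cfg$del_overlap else cfg$dupins_overlap
          }
        }
        if (hit && concord(grp[ii], grp[jj]) >= cfg$concordance_min)
          unite(grp[ii], grp[jj])
      }
    }
  }

  comp <- vapply(seq_len(n), find, integer(1))
  n_missing <- rowSums(is.na(g))
  reps <- vapply(split(seq_len(n), comp), function(members) {
    members[order(n_missing[members], v$pos[members], v$end[members],
                  v$record_id[members])][1]
  }, integer(1))

  clusters <- data.frame(
    representative_id = v$record_id[reps],
    size = vapply(split(seq_len(n), comp), length, integer(1)),
    stringsAsFactors = FALSE
  )
  clusters$member_ids <- lapply(split(v$record_id, comp), identity)
  o <- order(match(clusters$representative_id, v$record_id))
  clusters <- clusters[o, , drop = FALSE]
  rownames(clusters) <- NULL

  keep <- sort(unname(reps))
  out <- cs
  out$variants <- v[keep, , drop = FALSE]
  out$geno <- g[keep, , drop = FALSE]
  out <- sort_callset(out)
  list(callset = out, clusters = clusters)
}
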