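#' Dosage matrix from a callset
#'
#' @param callset a [cnv_callset].
#' @return integer matrix, samples x variants, entries 0/1/2 with `NA` for
#'   missing genotypes; dimnames are sample ids and record ids.
#' @export
build_dosage <- function(callset) {
  t(callset$geno)
}

#' PCA of a dosage matrix
#'
#' Missing entries are imputed with the per-variant mean dosage; columns
#' are centered and, when `scale = TRUE`, divided by `sqrt(phat (1 - phat))`
#' with `phat` the column allele frequency — the normalization of
#' SMARTPCA. Variants left with zero variance are dropped. The
#' decomposition is the (deterministic) LAPACK SVD via [stats::prcomp()].
#'
#' @param m dosage matrix from [build_dosage()].
#' @param scale use allele-frequency scaling (default `TRUE`).
#' @return list of class `cnv_pca` with `coordinates` (samples x
#'   components) and `explained_fraction` (per component; non-increasing,
#'   sums to 1 over all retained components).
#' @export
pca_dosage <- function(m, scale = TRUE) {
  if (nrow(m) < 2) stop("PCA needs at least two samples")
  mu <- colMeans(m, na.rm = TRUE)
  mu[is.nan(mu)] <- 0                     # all-missing column -> constant 0
  x <- m
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mu[j]
  x <- sweep(x, 2, mu)
  keep <- colSums(x != 0) > 0
  if (!any(keep)) stop("no variance: every variant is constant")
  x <- x[, keep, drop = FALSE]
  if (scale) {
    phat <- mu[keep] / 2
    x <- sweep(x, 2, sqrt(phat * (1 - phat)), "/")
  }
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  lambda <- pc$sdev^2
  structure(list(coordinates = pc$x,
                 explained_fraction = lambda / sum(lambda)),
            class = "cnv_pca")
}

#' @export
print.cnv_pca <- function(x, ...) {
  ef <- x$explained_fraction
  cat("cnv_pca:", nrow(x$coordinates), "samples,", length(ef), "components\n")
  k <- min(5, length(ef))
  cat("  explained:", paste(sprintf("PC%d=%.2f%%", seq_len(k), 100 * ef[seq_len(k)]),
                            collapse = "  "), "\n")
  invisible(x)
}

#' Allele-sharing distance matrix
#'
#' For samples `i`, `j`, the distance is the mean of
#' `|dosage_i - dosage_j| / 2` over variants genotyped in both samples —
#' 0 for identical genotypes, 1 for opposite homozygotes everywhere.
#'
#' @param m dosage matrix from [build_dosage()].
#' @return symmetric matrix with zero diagonal, dimnames = sample ids.
#' @export
allele_sharing_distance <- function(m) {
  n <- nrow(m)
  if (n < 2) stop("need at least two samples")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      both <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (!any(both))
        stop("samples ", rownames(m)[i], " and ", rownames(m)[j],
             " share no genotyped variant")
      d[i, j] <- d[j, i] <- mean(abs(m[i, both] - m[j, both])) / 2
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined (ties broken
#' by the smallest index pair), branch lengths follow the rate-corrected
#' formulas, and the matrix is reduced; the run finishes with the standard
#' three-taxon resolution, yielding an unrooted tree. Negative branch
#' lengths are clamped to zero with the difference transferred to the
#' sister branch unless `clamp = FALSE`.
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   row/column names.
#' @param clamp clamp negative branch lengths (default `TRUE`).
#' @param digits significant digits for branch lengths in the Newick
#'   string (default 10).
#' @return Newick string (with terminating `;`) with branch lengths and no
#'   internal node labels.
#' @export
nj_tree <- function(d, clamp = TRUE, digits = 10) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least two taxa")
  if (!isTRUE(all.equal(d, t(d), check.attributes = FALSE)) ||
      any(d < 0) || any(diag(d) != 0))
    stop("distance matrix must be symmetric, non-negative, with zero diagonal")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  frag <- labs
  bl <- function(x) sprintf("%.*g", digits, x)
  pair_branches <- function(li, lj, dij) {
    if (clamp) {
      if (li < 0) { lj <- dij; li <- 0 }
      if (lj < 0) { li <- dij; lj <- 0 }
    }
    c(li, lj)
  }

  while (n > 3) {
    r <- rowSums(d)
    q <- (n - 2) * d - outer(r, r, "+")
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (q[i, j] < bq) { bq <- q[i, j]; best <- c(i, j) }
    i <- best[1]; j <- best[2]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    l2 <- pair_branches(li, lj, d[i, j])
    new_frag <- sprintf("(%s:%s,%s:%s)", frag[i], bl(l2[1]), frag[j], bl(l2[2]))
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    d[i, ] <- dn; d[, i] <- dn; d[i, i] <- 0
    frag[i] <- new_frag
    keep <- setdiff(seq_len(n), j)
    d <- d[keep, keep, drop = FALSE]
    frag <- frag[keep]
    n <- n - 1
  }

  if (n == 2) {
    h <- d[1, 2] / 2
    return(sprintf("(%s:%s,%s:%s);", frag[1], bl(h), frag[2], bl(h)))
  }
  a <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  cc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (clamp) {
    tr <- c(a, b, cc)
    for (k in which(tr < 0)) tr[k] <- 0
    a <- tr[1]; b <- tr[2]; cc <- tr[3]
  }
  sprintf("(%s:%s,%s:%s,%s:%s);", frag[1], bl(a), frag[2], bl(b), frag[3], bl(cc))
}
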