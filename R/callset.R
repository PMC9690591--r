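#' Cohort CNV callset
#'
#' A `cnv_callset` bundles a table of structural variants (deletions,
#' duplications, insertions) with the diploid genotypes of every sample in a
#' cohort. Genotypes are stored as alternate-allele dosages: 0 (homozygous
#' reference), 1 (heterozygous), 2 (homozygous alternate), `NA` (missing).
#'
#' @param variants data.frame with columns `record_id`, `chrom`, `pos`,
#'   `end`, `svtype` (one of `"DEL"`, `"DUP"`, `"INS"`) and `svlen`
#'   (signed base pairs: negative for DEL, positive for DUP/INS).
#'   Coordinates are VCF-native: 1-based, inclusive `[pos, end]`; for INS
#'   `end == pos`.
#' @param geno integer matrix of dosages, one row per variant and one column
#'   per sample; values 0/1/2 or `NA`.
#' @param samples character vector of sample identifiers, matching the
#'   columns of `geno`.
#' @param pop optional named character vector mapping every sample to a
#'   population label.
#' @param contigs optional named integer vector of contig lengths (bp), used
#'   to emit `##contig` header lines when writing VCF.
#'
#' @return An object of class `cnv_callset`: a list with elements
#'   `variants`, `geno`, `samples`, `pop` and `contigs`, with records sorted
#'   by (chrom, pos, end, svtype, record_id).
#' @export
cnv_callset <- function(variants, geno, samples, pop = NULL, contigs = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  obj <- structure(
    list(variants = variants, geno = geno, samples = as.character(samples),
         pop = pop, contigs = contigs),
    class = "cnv_callset"
  )
  validate_callset(obj)
  sort_callset(obj)
}

#' Validate a cnv_callset
#'
#' Checks the structural invariants: column presence, svtype/svlen sign
#' conventions, coordinate sanity (`end >= pos` for DEL/DUP, `end == pos`
#' for INS), dosage codes, genotype-matrix alignment, and (when present)
#' that every sample carries exactly one population label.
#'
#' @param x a `cnv_callset`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_callset <- function(x) {
  stopifnot(inherits(x, "cnv_callset"))
  v <- x$variants
  need <- c("record_id", "chrom", "pos", "end", "svtype", "svlen")
  missing_cols <- setdiff(need, names(v))
  if (length(missing_cols))
    stop("variants table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(v$record_id))
    stop("duplicate record_id values in callset")
  if (!all(v$svtype %in% c("DEL", "DUP", "INS")))
    stop("svtype must be one of DEL, DUP, INS")
  if (any(abs(v$svlen) < 1))
    stop("|svlen| must be >= 1 for every record")
  if (any(v$svtype == "DEL" & v$svlen >= 0))
    stop("DEL records must have negative svlen")
  if (any(v$svtype != "DEL" & v$svlen <= 0))
    stop("DUP/INS records must have positive svlen")
  bad_iv <- v$svtype %in% c("DEL", "DUP") & v$end < v$pos
  if (any(bad_iv))
    stop("end < pos for record(s): ", paste(v$record_id[bad_iv], collapse = ", "))
  bad_ins <- v$svtype == "INS" & v$end != v$pos
  if (any(bad_ins))
    stop("INS records must have end == pos: ",
         paste(v$record_id[bad_ins], collapse = ", "))
  if (nrow(x$geno) != nrow(v))
    stop("genotype matrix rows (", nrow(x$geno), ") != records (", nrow(v), ")")
  if (ncol(x$geno) != length(x$samples))
    stop("genotype matrix columns (", ncol(x$geno), ") != samples (",
         length(x$samples), ")")
  gvals <- x$geno[!is.na(x$geno)]
  if (length(gvals) && !all(gvals %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  if (!is.null(x$pop)) {
    if (is.null(names(x$pop)) || !setequal(names(x$pop), x$samples) ||
        length(x$pop) != length(x$samples))
      stop("pop must be a named vector with exactly one label per sample")
  }
  invisible(x)
}

#' Sort a callset into canonical order
#'
#' Records are ordered by (chrom, pos, end, svtype, record_id); the ordering
#' is total, so any callset has a unique canonical form.
#'
#' @param x a `cnv_callset`.
#' @return the callset with records (and genotype rows) reordered.
#' @export
sort_callset <- function(x) {
  v <- x$variants
  o <- order(v$chrom, v$pos, v$end, v$svtype, v$record_id)
  x$variants <- v[o, , drop = FALSE]
  rownames(x$variants) <- NULL
  x$geno <- x$geno[o, , drop = FALSE]
  rownames(x$geno) <- x$variants$record_id
  colnames(x$geno) <- x$samples
  x
}

#' @export
print.cnv_callset <- function(x, ...) {
  cat("cnv_callset:", nrow(x$variants), "records,", length(x$samples),
      "samples\n")
  tab <- table(factor(x$variants$svtype, levels = c("DEL", "DUP", "INS")))
  cat("  types:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
  if (!is.null(x$pop)) {
    pt <- table(x$pop)
    cat("  populations:", paste(names(pt), pt, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Extract a single record
#'
#' @param x a `cnv_callset`.
#' @param i record index or record_id.
#' @return an `sv_record`: a list with the variant fields plus its dosage
#'   vector aligned to the cohort samples.
#' @export
callset_record <- function(x, i) {
  if (is.character(i)) i <- match(i, x$variants$record_id)
  if (is.na(i) || i < 1 || i > nrow(x$variants)) stop("no such record")
  v <- x$variants[i, ]
  structure(
    list(record_id = v$record_id, chrom = v$chrom, pos = v$pos, end = v$end,
         svtype = v$svtype, svlen = v$svlen,
         geno = stats::setNames(x$geno[i, ], x$samples)),
    class = "sv_record"
  )
}

#' Construct a single structural-variant record
#'
#' Convenience constructor used mainly in examples and tests.
#'
#' @param record_id identifier.
#' @param chrom chromosome name.
#' @param pos 1-based start.
#' @param end 1-based inclusive end (ignored for INS: forced to `pos`).
#' @param svtype `"DEL"`, `"DUP"` or `"INS"`.
#' @param svlen signed length in bp; if missing, derived from the interval
#'   (negated for DEL).
#' @param geno dosage vector (0/1/2/NA).
#' @return an `sv_record`.
#' @export
sv_record <- function(record_id, chrom, pos, end = NULL, svtype, svlen = NULL,
                      geno = integer(0)) {
  if (svtype == "INS") {
    end <- pos
    if (is.null(svlen)) stop("INS records need an explicit svlen")
  } else {
    if (is.null(end)) stop("DEL/DUP records need an end coordinate")
    if (is.null(svlen)) svlen <- (end - pos + 1L) * (if (svtype == "DEL") -1L else 1L)
  }
  structure(
    list(record_id = record_id, chrom = chrom, pos = as.integer(pos),
         end = as.integer(end), svtype = svtype, svlen = as.integer(svlen),
         geno = geno),
    class = "sv_record"
  )
}

# Internal: population -> sample-column indices, with validation.
pop_indices <- function(callset, pop) {
  if (is.null(callset$pop)) stop("callset has no population labels; read_popmap() first")
  if (!pop %in% callset$pop) stop("unknown population label: ", pop)
  which(callset$pop[callset$samples] == pop)
}
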