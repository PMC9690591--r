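#' Gene model
#'
#' A `gene_model` describes one transcript: its exon structure, coding
#' intervals, and UTRs, all in 1-based inclusive coordinates. A transcript
#' with no CDS is a non-coding RNA (`biotype = "ncRNA"`).
#'
#' @param gene_id gene identifier.
#' @param transcript_id transcript identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (sorted, non-overlapping).
#' @param cds data.frame of coding intervals (may be empty).
#' @param utr5,utr3 data.frames of UTR intervals (may be empty).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, transcript_id, chrom, strand, exons,
                       cds = empty_iv(), utr5 = empty_iv(), utr3 = empty_iv()) {
  stopifnot(strand %in% c("+", "-"))
  norm_iv <- function(df) {
    df <- df[order(df$start), c("start", "end"), drop = FALSE]
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    rownames(df) <- NULL
    df
  }
  exons <- norm_iv(exons)
  cds <- norm_iv(cds); utr5 <- norm_iv(utr5); utr3 <- norm_iv(utr3)
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap in transcript ", transcript_id)
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
         biotype = if (nrow(cds)) "coding" else "ncRNA"),
    class = "gene_model"
  )
}

empty_iv <- function() data.frame(start = integer(0), end = integer(0))

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s:%d-%d [%s] %d exon(s), %s\n",
              x$transcript_id, x$gene_id, x$chrom, min(x$exons$start),
              max(x$exons$end), x$strand, nrow(x$exons), x$biotype))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/transcript/exon/CDS/UTR features linked by `ID`/`Parent`
#' attributes and assembles one [gene_model] per transcript. Transcripts
#' with no CDS children are flagged `ncRNA`.
#'
#' @param path path to a GFF3 file.
#' @return a list of [gene_model] objects.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path)
  type <- as.character(gr$type)
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID)
         else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(S4Vectors::mcols(gr)))
    vapply(as.list(gr$Parent), function(p) if (length(p)) p[[1]] else NA_character_,
           character(1))
  else rep(NA_character_, length(gr))

  known_ids <- ids[!is.na(ids)]
  orphan <- !is.na(parents) & !parents %in% known_ids
  if (any(orphan)) {
    i <- which(orphan)[1]
    stop("feature ", if (!is.na(ids[i])) ids[i] else paste0("#", i),
         " (", type[i], ") references unknown Parent '", parents[i], "'")
  }

  tx_types <- c("mRNA", "transcript", "ncRNA", "lnc_RNA", "miRNA", "snoRNA",
                "snRNA", "tRNA", "rRNA", "pseudogenic_transcript")
  tx_idx <- which(type %in% tx_types)
  child_of <- function(tx_id, child_type) {
    sel <- which(type == child_type & parents == tx_id)
    if (!length(sel)) return(empty_iv())
    df <- data.frame(start = BiocGenerics::start(gr)[sel],
                     end = BiocGenerics::end(gr)[sel])
    df[order(df$start), , drop = FALSE]
  }

  models <- lapply(tx_idx, function(i) {
    tx_id <- ids[i]
    if (is.na(tx_id)) stop("transcript feature #", i, " lacks an ID attribute")
    gene_model(
      gene_id = if (!is.na(parents[i])) parents[i] else tx_id,
      transcript_id = tx_id,
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      strand = as.character(BiocGenerics::strand(gr))[i],
      exons = child_of(tx_id, "exon"),
      cds = child_of(tx_id, "CDS"),
      utr5 = child_of(tx_id, "five_prime_UTR"),
      utr3 = child_of(tx_id, "three_prime_UTR")
    )
  })
  models
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA/ncRNA, exon, CDS and UTR features with `ID`/`Parent`
#' links; the output round-trips through [read_gff3()]. Used mainly to
#' materialize synthetic gene models from [simulate_gene_models()].
#'
#' @param models list of [gene_model] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, start, end, strand, attrs)
    sprintf("%s\tcnvpopscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attrs)
  for (m in models) {
    gstart <- min(m$exons$start); gend <- max(m$exons$end)
    lines <- c(lines,
      fmt(m$chrom, "gene", gstart, gend, m$strand,
          sprintf("ID=%s", m$gene_id)),
      fmt(m$chrom, if (m$biotype == "coding") "mRNA" else "ncRNA",
          gstart, gend, m$strand,
          sprintf("ID=%s;Parent=%s", m$transcript_id, m$gene_id)))
    emit <- function(df, type) {
      if (!nrow(df)) return(character(0))
      fmt(m$chrom, type, df$start, df$end, m$strand,
          sprintf("Parent=%s", m$transcript_id))
    }
    lines <- c(lines, emit(m$exons, "exon"), emit(m$cds, "CDS"),
               emit(m$utr5, "five_prime_UTR"), emit(m$utr3, "three_prime_UTR"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Attach population labels from a two-column map
#'
#' Reads a headerless tab-separated file with columns (sample_id,
#' population) and attaches the labels to a callset. Every callset sample
#' must appear in the map; samples in the map but not in the callset are
#' tolerated with a warning.
#'
#' @param path path to the popmap TSV.
#' @param callset a [cnv_callset].
#' @return the callset with `pop` filled in.
#' @export
read_popmap <- function(path, callset) {
  pm <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sample", "population"),
                          colClasses = "character")
  if (anyDuplicated(pm$sample))
    stop("duplicate sample id(s) in popmap: ",
         paste(unique(pm$sample[duplicated(pm$sample)]), collapse = ", "))
  absent <- setdiff(callset$samples, pm$sample)
  if (length(absent))
    stop("popmap lacks sample(s): ", paste(absent, collapse = ", "))
  extra <- setdiff(pm$sample, callset$samples)
  if (length(extra))
    warning("popmap contains sample(s) absent from callset: ",
            paste(extra, collapse = ", "))
  keep <- pm$sample %in% callset$samples
  callset$pop <- stats::setNames(pm$population[keep], pm$sample[keep])[callset$samples]
  validate_callset(callset)
  callset
}

#' Write a population map
#'
#' @param callset a labelled [cnv_callset].
#' @param path output path (headerless two-column TSV).
#' @return `path`, invisibly.
#' @export
write_popmap <- function(callset, path) {
  if (is.null(callset$pop)) stop("callset has no population labels")
  utils::write.table(
    data.frame(sample = callset$samples, population = callset$pop[callset$samples]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
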