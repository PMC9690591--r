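#' Annotation classes
#'
#' The 11 mutually exclusive positional classes a variant can take with
#' respect to a set of gene models, in precedence order.
#'
#' @return character vector of class names.
#' @export
annotation_classes <- function() {
  c("exonic", "splicing", "ncRNA", "UTR5", "UTR3", "UTR3_UTR5", "intronic",
    "upstream", "downstream", "upstream_downstream", "intergenic")
}

# Internal: does [s,e] overlap any interval row of df?
overlaps_any <- function(s, e, df) {
  nrow(df) > 0 && any(df$start <= e & df$end >= s)
}

#' Classify one variant against gene models
#'
#' The variant interval is `[pos, end]` (a single base at `pos` for INS).
#' Hits are evaluated across all transcripts and combined with first-match
#' precedence: CDS overlap of a coding transcript (`exonic`); overlap of an
#' intron within `splice_bp` of an exon boundary (`splicing`); exon overlap
#' of a non-coding transcript (`ncRNA`); UTR overlap (`UTR3_UTR5` when both
#' a 5' and a 3' UTR are hit, else `UTR5`/`UTR3`); any intron overlap
#' (`intronic`); strand-aware promoter-side window within `upstream_bp` of
#' the transcription start (`upstream`) and the symmetric window past the
#' transcription end (`downstream`), with `upstream_downstream` when both
#' apply; otherwise `intergenic`. The vocabulary and precedence follow the
#' ANNOVAR convention.
#'
#' Note a coding transcript's non-CDS exon overlap contributes only through
#' its UTR intervals; exon overlap decides `exonic` solely via CDS.
#'
#' @param record an `sv_record` (or list with `chrom`, `pos`, `end`,
#'   `svtype`).
#' @param genes list of [gene_model] objects.
#' @param upstream_bp size of the upstream/downstream windows (default 1000).
#' @param splice_bp intronic distance from an exon boundary that counts as
#'   splice-affecting (default 2).
#' @return one element of [annotation_classes()].
#' @export
classify_variant <- function(record, genes, upstream_bp = 1000L, splice_bp = 2L) {
  s <- record$pos
  e <- if (record$svtype == "INS") record$pos else record$end

  hit_utr5 <- hit_utr3 <- hit_intron <- hit_splice <- hit_nc <- FALSE
  hit_up <- hit_down <- FALSE

  for (m in genes) {
    if (m$chrom != record$chrom) next
    tx_start <- min(m$exons$start); tx_end <- max(m$exons$end)

    if (s <= tx_end && e >= tx_start) {
      if (m$biotype == "coding" && overlaps_any(s, e, m$cds)) return("exonic")
      # introns: gaps between consecutive exons
      if (nrow(m$exons) > 1) {
        for (k in seq_len(nrow(m$exons) - 1)) {
          int_s <- m$exons$end[k] + 1L; int_e <- m$exons$start[k + 1] - 1L
          if (int_s > int_e) next
          if (s <= int_e && e >= int_s) {
            hit_intron <- TRUE
            donor_e <- min(int_s + splice_bp - 1L, int_e)
            accept_s <- max(int_e - splice_bp + 1L, int_s)
            if ((s <= donor_e && e >= int_s) || (s <= int_e && e >= accept_s))
              hit_splice <- TRUE
          }
        }
      }
      if (m$biotype == "ncRNA" && overlaps_any(s, e, m$exons)) hit_nc <- TRUE
      if (overlaps_any(s, e, m$utr5)) hit_utr5 <- TRUE
      if (overlaps_any(s, e, m$utr3)) hit_utr3 <- TRUE
    }

    # strand-aware flanks
    if (m$strand == "+") {
      up_s <- tx_start - upstream_bp; up_e <- tx_start - 1L
      dn_s <- tx_end + 1L; dn_e <- tx_end + upstream_bp
    } else {
      up_s <- tx_end + 1L; up_e <- tx_end + upstream_bp
      dn_s <- tx_start - upstream_bp; dn_e <- tx_start - 1L
    }
    if (s <= up_e && e >= up_s) hit_up <- TRUE
    if (s <= dn_e && e >= dn_s) hit_down <- TRUE
  }

  if (hit_splice) return("splicing")
  if (hit_nc) return("ncRNA")
  if (hit_utr5 && hit_utr3) return("UTR3_UTR5")
  if (hit_utr5) return("UTR5")
  if (hit_utr3) return("UTR3")
  if (hit_intron) return("intronic")
  if (hit_up && hit_down) return("upstream_downstream")
  if (hit_up) return("upstream")
  if (hit_down) return("downstream")
  "intergenic"
}

#' Classify every variant in a callset
#'
#' @param callset a [cnv_callset].
#' @param genes list of [gene_model] objects.
#' @inheritParams classify_variant
#' @return data.frame with `record_id` and `class`.
#' @export
annotate_callset <- function(callset, genes, upstream_bp = 1000L, splice_bp = 2L) {
  v <- callset$variants
  cls <- vapply(seq_len(nrow(v)), function(i) {
    classify_variant(list(chrom = v$chrom[i], pos = v$pos[i], end = v$end[i],
                          svtype = v$svtype[i]),
                     genes, upstream_bp, splice_bp)
  }, character(1))
  data.frame(record_id = v$record_id, class = cls, stringsAsFactors = FALSE)
}

#' Tabulate annotation classes
#'
#' @param classes character vector of classes (one per variant) or the
#'   data.frame from [annotate_callset()].
#' @return data.frame with one row per class in [annotation_classes()]
#'   order and a `count` column; counts sum to the number of variants.
#' @export
summarize_annotation <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$class
  lv <- annotation_classes()
  bad <- setdiff(unique(classes), lv)
  if (length(bad)) stop("unknown annotation class(es): ", paste(bad, collapse = ", "))
  data.frame(class = lv,
             count = as.integer(table(factor(classes, levels = lv))),
             stringsAsFactors = FALSE)
}
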