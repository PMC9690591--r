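#' Read a structural-variant VCF into a callset
#'
#' Parses a VCF 4.2 file whose records carry `SVTYPE` and `SVLEN` (and, for
#' DEL/DUP, `END`) in INFO and `GT` as the first FORMAT field, as produced
#' by SV genotypers. Only biallelic DEL/DUP/INS records are accepted.
#'
#' Genotype tokens are reduced to dosages: `0/0` and `0|0` map to 0; `0/1`,
#' `1/0` and their phased forms to 1; `1/1` (phased or not) to 2; `./.`,
#' `.|.` and bare `.` to missing. Phasing is discarded — downstream
#' statistics only use dosage.
#'
#' @param path path to a VCF file (plain text or bgzipped).
#' @return a [cnv_callset] without population labels, sorted by
#'   (chrom, pos). `##contig` lengths, when present, are retained for
#'   round-tripping through [write_sv_vcf()].
#' @seealso [write_sv_vcf()], [read_popmap()]
#' @export
read_sv_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n_meta <- length(vcf@meta)
  n <- nrow(fix)
  samples <- if (ncol(vcf@gt) > 1) colnames(vcf@gt)[-1] else character(0)

  contigs <- parse_contig_meta(vcf@meta)

  if (n == 0) {
    return(cnv_callset(
      variants = data.frame(record_id = character(0), chrom = character(0),
                            pos = integer(0), end = integer(0),
                            svtype = character(0), svlen = integer(0)),
      geno = matrix(integer(0), 0, length(samples)),
      samples = samples, contigs = contigs
    ))
  }

  line_no <- function(i) n_meta + 1L + i   # meta + #CHROM header + record
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi))
    stop("multiallelic ALT not supported (line ",
         line_no(which(multi)[1]), "); split or drop these records")

  info <- fix[, "INFO"]
  svtype <- info_field(info, "SVTYPE")
  svlen <- suppressWarnings(as.integer(info_field(info, "SVLEN")))
  endf <- suppressWarnings(as.integer(info_field(info, "END")))

  if (anyNA(svtype))
    stop("INFO/SVTYPE missing at line ", line_no(which(is.na(svtype))[1]))
  bad_type <- !svtype %in% c("DEL", "DUP", "INS")
  if (any(bad_type))
    stop("unknown SVTYPE '", svtype[which(bad_type)[1]], "' at line ",
         line_no(which(bad_type)[1]))
  if (anyNA(svlen))
    stop("INFO/SVLEN missing or non-numeric at line ",
         line_no(which(is.na(svlen))[1]))
  need_end <- svtype %in% c("DEL", "DUP")
  if (any(need_end & is.na(endf)))
    stop("INFO/END missing for DEL/DUP at line ",
         line_no(which(need_end & is.na(endf))[1]))

  pos <- as.integer(fix[, "POS"])
  end <- ifelse(svtype == "INS", pos, endf)
  id <- fix[, "ID"]
  blank <- is.na(id) | id == "."
  id[blank] <- sprintf("sv%d", which(blank))

  geno <- matrix(NA_integer_, n, length(samples))
  if (length(samples)) {
    gt <- vcf@gt[, -1, drop = FALSE]
    tok <- sub(":.*$", "", gt)
    geno[] <- gt_to_dosage(tok, line_no)
  }

  cnv_callset(
    variants = data.frame(record_id = id, chrom = fix[, "CHROM"], pos = pos,
                          end = as.integer(end), svtype = svtype,
                          svlen = svlen, stringsAsFactors = FALSE),
    geno = geno, samples = samples, contigs = contigs
  )
}

# Internal: extract one KEY=value INFO field; NA where absent.
info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep(NA_character_, length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

# Internal: ##contig=<ID=...,length=...> lines -> named integer vector.
parse_contig_meta <- function(meta) {
  cl <- grep("^##contig=<", meta, value = TRUE)
  if (!length(cl)) return(NULL)
  ids <- sub('^##contig=<.*?ID=([^,>]+).*$', "\\1", cl)
  lens <- rep(NA_integer_, length(cl))
  has_len <- grepl("length=", cl)
  lens[has_len] <- as.integer(sub("^.*length=([0-9]+).*$", "\\1", cl[has_len]))
  stats::setNames(lens, ids)
}

# Internal: genotype token matrix -> integer dosage matrix.
gt_to_dosage <- function(tok, line_no) {
  map <- c("0/0" = 0L, "0|0" = 0L,
           "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
           "1/1" = 2L, "1|1" = 2L)
  d <- matrix(map[tok], nrow(tok), ncol(tok))
  miss <- tok %in% c("./.", ".|.", ".") | is.na(tok)
  unknown <- is.na(d) & !miss
  if (any(unknown)) {
    i <- arrayInd(which(unknown)[1], dim(tok))[1]
    stop("unrecognized GT token '", tok[unknown][1], "' at line ", line_no(i))
  }
  d
}

#' Write a callset as a plain-text structural-variant VCF
#'
#' Emits a minimal VCF 4.2 file: `##contig` lines (with lengths when the
#' callset carries them), INFO definitions for SVTYPE/END/SVLEN, a GT
#' FORMAT definition, and one body line per record in canonical sort order.
#' The output round-trips through [read_sv_vcf()]; writing, re-reading and
#' writing again reproduces byte-identical body lines.
#'
#' @param callset a [cnv_callset].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(callset, path) {
  validate_callset(callset)
  cs <- sort_callset(callset)
  v <- cs$variants

  contigs <- cs$contigs
  if (is.null(contigs)) {
    nm <- unique(v$chrom)
    contigs <- stats::setNames(rep(NA_integer_, length(nm)), nm)
  }
  contig_lines <- ifelse(
    is.na(contigs),
    sprintf("##contig=<ID=%s>", names(contigs)),
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs)
  )

  header <- c(
    "##fileformat=VCFv4.2",
    contig_lines,
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position of the variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Signed length of the variant">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cs$samples), collapse = "\t")
  )

  gt_str <- c("0/0", "0/1", "1/1")
  body <- character(nrow(v))
  if (nrow(v)) {
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d", v$svtype, v$end, v$svlen)
    for (i in seq_len(nrow(v))) {
      g <- cs$geno[i, ]
      gcol <- ifelse(is.na(g), "./.", gt_str[g + 1L])
      body[i] <- paste(c(v$chrom[i], v$pos[i], v$record_id[i], "N",
                         sprintf("<%s>", v$svtype[i]), ".", "PASS", info[i],
                         "GT", gcol), collapse = "\t")
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}
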