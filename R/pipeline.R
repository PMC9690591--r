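#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Exactly
#' one of `input` (paths to an SV VCF, a popmap, and optionally a GFF3) or
#' `simulation` (arguments for [sim_config()]) must be given.
#'
#' @param input list with `vcf`, `popmap`, optional `gff3`.
#' @param simulation list of [sim_config()] arguments (may be empty for
#'   all defaults).
#' @param merge list of [merge_config()] arguments.
#' @param qc list of [qc_config()] arguments.
#' @param pop_a,pop_b population labels; defaulted from the simulation
#'   labels or the popmap's first two labels.
#' @param top_fraction selection-scan fraction (default 0.01).
#' @param n_bins spectrum bins (default 10).
#' @param sex_chromosomes chromosome names excluded from the Fst scan.
#' @param n_genes genes to simulate when annotating simulated data.
#' @param out_dir output directory.
#' @param seed integer seed, forwarded to the simulator.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            merge = list(), qc = list(),
                            pop_a = NULL, pop_b = NULL,
                            top_fraction = 0.01, n_bins = 10L,
                            sex_chromosomes = c("X", "Y"),
                            n_genes = 10L, out_dir = "cnvpopscan_run",
                            seed = 1L) {
  if (is.null(input) == is.null(simulation))
    stop("exactly one of 'input' and 'simulation' must be configured")
  if (!is.null(input) && (is.null(input$vcf) || is.null(input$popmap)))
    stop("input configuration needs 'vcf' and 'popmap' paths")
  structure(list(input = input, simulation = simulation, merge = merge,
                 qc = qc, pop_a = pop_a, pop_b = pop_b,
                 top_fraction = top_fraction, n_bins = as.integer(n_bins),
                 sex_chromosomes = sex_chromosomes,
                 n_genes = as.integer(n_genes), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full CNV population-genomics pipeline
#'
#' Executes, in order: input (simulation or loading), group-level merging,
#' site QC, the population-genetic summaries (Fst scan with top-fraction
#' selection, spectra, shared/unique comparison, per-population summary),
#' annotation against gene models when available, and structure inference
#' (PCA and NJ tree). Every stage writes its artifact as plain text under
#' `cfg$out_dir`, and a manifest records each artifact's MD5 digest, the
#' stage parameters, and wall time. Re-running with an identical
#' configuration reproduces identical digests.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest data.frame, invisibly; also written as
#'   `manifest.tsv`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(0), artifact = character(0),
                         md5 = character(0), parameters = character(0),
                         seconds = numeric(0), stringsAsFactors = FALSE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  cat("", file = log_path)
  note <- function(msg) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  add <- function(stage, paths, params, secs) {
    for (p in paths)
      manifest <<- rbind(manifest, data.frame(
        stage = stage, artifact = basename(p),
        md5 = unname(tools::md5sum(p)), parameters = params,
        seconds = round(secs, 3), stringsAsFactors = FALSE))
  }
  timed <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    list(val = val, secs = proc.time()[["elapsed"]] - t0)
  }
  stage_guard <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  genes <- NULL
  # -- input ----------------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    note("stage input: simulating cohort")
    tm <- timed(stage_guard("input", {
      sim_args <- cfg$simulation
      sim_args$seed <- cfg$seed
      scfg <- do.call(sim_config, sim_args)
      sim <- simulate_callset(scfg)
      gm <- simulate_gene_models(scfg, n_genes = cfg$n_genes)
      vcf <- file.path(cfg$out_dir, "sim.vcf")
      write_sv_vcf(sim$callset, vcf)
      write_popmap(sim$callset, file.path(cfg$out_dir, "sim.popmap.tsv"))
      write_gff3(gm$models, file.path(cfg$out_dir, "sim.gff3"))
      write_tsv(sim$truth, file.path(cfg$out_dir, "sim.truth.tsv"))
      list(callset = sim$callset, genes = gm$models, scfg = scfg)
    }))
    callset <- tm$val$callset
    genes <- tm$val$genes
    add("input", file.path(cfg$out_dir,
                           c("sim.vcf", "sim.popmap.tsv", "sim.gff3", "sim.truth.tsv")),
        sprintf("seed=%d;n_variants=%d;fst_param=%g", cfg$seed,
                tm$val$scfg$n_variants, tm$val$scfg$fst_param), tm$secs)
  } else {
    note("stage input: loading callset")
    tm <- timed(stage_guard("input", {
      cs <- read_sv_vcf(cfg$input$vcf)
      cs <- read_popmap(cfg$input$popmap, cs)
      if (!is.null(cfg$input$gff3)) genes <<- read_gff3(cfg$input$gff3)
      cs
    }))
    callset <- tm$val
    add("input", c(cfg$input$vcf, cfg$input$popmap),
        sprintf("vcf=%s", basename(cfg$input$vcf)), tm$secs)
  }
  pops <- unique(unname(callset$pop[callset$samples]))
  pop_a <- if (is.null(cfg$pop_a)) pops[1] else cfg$pop_a
  pop_b <- if (is.null(cfg$pop_b)) pops[2] else cfg$pop_b

  # -- merge ----------------------------------------------------------------
  note("stage merge: group-level de-redundancy")
  mcfg <- do.call(merge_config, cfg$merge)
  tm <- timed(stage_guard("merge", merge_callset(callset, mcfg)))
  merged <- tm$val$callset
  clusters <- tm$val$clusters
  clusters_flat <- data.frame(
    representative_id = clusters$representative_id, size = clusters$size,
    member_ids = vapply(clusters$member_ids, paste, character(1), collapse = ","))
  write_sv_vcf(merged, file.path(cfg$out_dir, "merged.vcf"))
  write_tsv(clusters_flat, file.path(cfg$out_dir, "clusters.tsv"))
  add("merge", file.path(cfg$out_dir, c("merged.vcf", "clusters.tsv")),
      sprintf("del_overlap=%g;dupins_overlap=%g;concordance=%g",
              mcfg$del_overlap, mcfg$dupins_overlap, mcfg$concordance_min),
      tm$secs)
  note(sprintf("  %d -> %d records", nrow(callset$variants), nrow(merged$variants)))

  # -- qc -------------------------------------------------------------------
  note("stage qc: site filters")
  qcfg <- do.call(qc_config, cfg$qc)
  tm <- timed(stage_guard("qc", apply_qc(merged, qcfg)))
  qc_cs <- tm$val$callset
  write_sv_vcf(qc_cs, file.path(cfg$out_dir, "qc.vcf"))
  write_tsv(tm$val$report, file.path(cfg$out_dir, "qc_report.tsv"))
  add("qc", file.path(cfg$out_dir, c("qc.vcf", "qc_report.tsv")),
      sprintf("max_abs_svlen=%d;min_exchet_p=%g;max_f_missing=%g;min_maf=%g",
              qcfg$max_abs_svlen, qcfg$min_exchet_p, qcfg$max_f_missing,
              qcfg$min_maf), tm$secs)
  note(sprintf("  %d -> %d records", nrow(merged$variants), nrow(qc_cs$variants)))

  # -- popgen ---------------------------------------------------------------
  note("stage popgen: Fst scan, spectra, comparison, summaries")
  tm <- timed(stage_guard("popgen", {
    fst <- fst_per_variant(qc_cs, pop_a, pop_b, sex_chroms = cfg$sex_chromosomes)
    sel <- select_top_fraction(fst, cfg$top_fraction)
    write_tsv(sel$results, file.path(cfg$out_dir, "fst.tsv"))
    for (p in c(pop_a, pop_b))
      write_tsv(frequency_spectrum(qc_cs, p, n_bins = cfg$n_bins),
                file.path(cfg$out_dir, sprintf("spectrum_%s.tsv", p)))
    cmp <- callset_comparison(qc_cs, pop_a, pop_b)
    write_tsv(data.frame(shared = cmp$n_shared, unique_a = cmp$n_unique_a,
                         unique_b = cmp$n_unique_b),
              file.path(cfg$out_dir, "venn.tsv"))
    summ <- do.call(rbind, lapply(list(pop_a, pop_b, NULL), function(p) {
      s <- callset_summary(qc_cs, p)
      data.frame(population = if (is.null(p)) "all" else p,
                 n_del = s$n_del, n_dup = s$n_dup, n_ins = s$n_ins,
                 n_total = s$n_total, total_length = s$total_length,
                 mean_length_bp = s$mean_length_bp,
                 median_length = s$median_length)
    }))
    write_tsv(summ, file.path(cfg$out_dir, "summary.tsv"))
    sel
  }))
  add("popgen", file.path(cfg$out_dir,
                          c("fst.tsv", sprintf("spectrum_%s.tsv", c(pop_a, pop_b)),
                            "venn.tsv", "summary.tsv")),
      sprintf("pop_a=%s;pop_b=%s;top_fraction=%g", pop_a, pop_b,
              cfg$top_fraction), tm$secs)
  note(sprintf("  %d variants scanned, %d selected (threshold %.4f)",
               nrow(tm$val$results), tm$val$n_selected, tm$val$threshold))

  # -- annotate -------------------------------------------------------------
  if (!is.null(genes)) {
    note("stage annotate: classifying variants against gene models")
    tm <- timed(stage_guard("annotate", {
      ann <- annotate_callset(qc_cs, genes)
      write_tsv(ann, file.path(cfg$out_dir, "annotation.tsv"))
      write_tsv(summarize_annotation(ann),
                file.path(cfg$out_dir, "annotation_summary.tsv"))
      ann
    }))
    add("annotate",
        file.path(cfg$out_dir, c("annotation.tsv", "annotation_summary.tsv")),
        sprintf("n_genes=%d", length(genes)), tm$secs)
  }

  # -- structure ------------------------------------------------------------
  note("stage structure: PCA and NJ tree")
  tm <- timed(stage_guard("structure", {
    dm <- build_dosage(qc_cs)
    pca <- pca_dosage(dm)
    coords <- data.frame(sample = rownames(pca$coordinates),
                         population = unname(qc_cs$pop[rownames(pca$coordinates)]),
                         pca$coordinates[, seq_len(min(10, ncol(pca$coordinates))),
                                         drop = FALSE])
    write_tsv(coords, file.path(cfg$out_dir, "pca_coords.tsv"))
    write_tsv(data.frame(component = seq_along(pca$explained_fraction),
                         explained_fraction = pca$explained_fraction),
              file.path(cfg$out_dir, "pca_explained.tsv"))
    nwk <- nj_tree(allele_sharing_distance(dm))
    writeLines(nwk, file.path(cfg$out_dir, "nj_tree.nwk"))
    pca
  }))
  add("structure", file.path(cfg$out_dir,
                             c("pca_coords.tsv", "pca_explained.tsv", "nj_tree.nwk")),
      "distance=allele_sharing;pca_scale=smartpca", tm$secs)
  note(sprintf("  PC1 %.2f%%, PC2 %.2f%%",
               100 * tm$val$explained_fraction[1],
               100 * tm$val$explained_fraction[2]))

  write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  note("pipeline complete")
  invisible(manifest)
}
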