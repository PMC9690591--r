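# A hand-built locus: one coding gene on +, one on -, one ncRNA gene.
#   gplus: exons [1000,1500] and [2500,3000]; UTR5 [1000,1099]; CDS
#   [1100,1500]+[2500,2900]; UTR3 [2901,3000]; intron [1501,2499].
gplus <- gene_model("g1", "t1", "chr1", "+",
                    exons = data.frame(start = c(1000L, 2500L), end = c(1500L, 3000L)),
                    cds = data.frame(start = c(1100L, 2500L), end = c(1500L, 2900L)),
                    utr5 = data.frame(start = 1000L, end = 1099L),
                    utr3 = data.frame(start = 2901L, end = 3000L))
gminus <- gene_model("g2", "t2", "chr1", "-",
                     exons = data.frame(start = 20000L, end = 21000L),
                     cds = data.frame(start = 20100L, end = 20900L),
                     utr5 = data.frame(start = 20901L, end = 21000L),
                     utr3 = data.frame(start = 20000L, end = 20099L))
gnc <- gene_model("g3", "t3", "chr2", "+",
                  exons = data.frame(start = c(5000L, 6000L), end = c(5400L, 6400L)))
genes <- list(gplus, gminus, gnc)

del <- function(pos, end, chrom = "chr1")
  list(chrom = chrom, pos = pos, end = end, svtype = "DEL")
ins <- function(pos, chrom = "chr1")
  list(chrom = chrom, pos = pos, end = pos, svtype = "INS")

test_that("classification follows the precedence order", {
  expect_equal(classify_variant(del(1200, 1300), genes), "exonic")
  # overlaps CDS and intron: exonic wins
  expect_equal(classify_variant(del(1400, 1600), genes), "exonic")
  # strictly inside the intron, away from boundaries
  expect_equal(classify_variant(del(1600, 1700), genes), "intronic")
  # first two intronic bases = splice donor region
  expect_equal(classify_variant(del(1501, 1502), genes), "splicing")
  expect_equal(classify_variant(ins(2498), genes), "splicing")   # acceptor side
  # third intronic base is no longer splicing
  expect_equal(classify_variant(ins(1503), genes), "intronic")
  expect_equal(classify_variant(del(1020, 1040), genes), "UTR5")
  expect_equal(classify_variant(del(2950, 2960), genes), "UTR3")
  expect_equal(classify_variant(del(5100, 5200, "chr2"), genes), "ncRNA")
  expect_equal(classify_variant(del(30000, 30100), genes), "intergenic")
})

test_that("flank classes are strand-aware", {
  # 500 bp 5' of the + strand TSS
  expect_equal(classify_variant(ins(500), genes), "upstream")
  expect_equal(classify_variant(ins(3500), genes), "downstream")
  # minus-strand gene: upstream lies at coordinates ABOVE the span
  expect_equal(classify_variant(ins(21500), genes), "upstream")
  expect_equal(classify_variant(ins(19500), genes), "downstream")
  # outside the window
  expect_equal(classify_variant(ins(22100), genes), "intergenic")
  # window size is honored
  expect_equal(classify_variant(ins(22100), genes, upstream_bp = 2000), "upstream")
})

test_that("combined classes arise from hits on different transcripts", {
  # two adjacent + genes, 600 bp apart
  ga <- gene_model("ga", "ta", "chr3", "+",
                   exons = data.frame(start = 1000L, end = 2000L),
                   cds = data.frame(start = 1060L, end = 1920L),
                   utr5 = data.frame(start = 1000L, end = 1059L),
                   utr3 = data.frame(start = 1921L, end = 2000L))
  gb <- gene_model("gb", "tb", "chr3", "+",
                   exons = data.frame(start = 2600L, end = 3600L),
                   cds = data.frame(start = 2660L, end = 3520L),
                   utr5 = data.frame(start = 2600L, end = 2659L),
                   utr3 = data.frame(start = 3521L, end = 3600L))
  pair <- list(ga, gb)
  expect_equal(classify_variant(ins(2300, "chr3"), pair), "upstream_downstream")
  expect_equal(classify_variant(del(1950, 2630, "chr3"), pair), "UTR3_UTR5")
})

test_that("widening the flank window never demotes a variant to intergenic", {
  gm <- simulate_gene_models(sim_config(seed = 31), n_genes = 8)
  set.seed(31)
  span <- range(unlist(lapply(gm$models, function(m) c(m$exons$start, m$exons$end))))
  for (i in 1:40) {
    pos <- sample(seq(max(1, span[1] - 3000), span[2] + 3000), 1)
    v <- del(pos, pos + 9L)
    narrow <- classify_variant(v, gm$models, upstream_bp = 500)
    wide <- classify_variant(v, gm$models, upstream_bp = 5000)
    if (narrow %in% c("upstream", "downstream", "upstream_downstream"))
      expect_false(wide == "intergenic")
    if (narrow == "intergenic")
      expect_true(wide %in% c("intergenic", "upstream", "downstream",
                              "upstream_downstream"))
  }
})

test_that("planted coordinates from the simulator classify as planted", {
  for (seed in c(2, 13)) {
    gm <- simulate_gene_models(sim_config(seed = seed), n_genes = 10)
    got <- vapply(seq_len(nrow(gm$planted)), function(i)
      classify_variant(list(chrom = gm$planted$chrom[i], pos = gm$planted$pos[i],
                            end = gm$planted$end[i], svtype = "DEL"),
                       gm$models), character(1))
    expect_equal(got, gm$planted$class)
    expect_setequal(gm$planted$class, annotation_classes())
  }
})

test_that("annotation summaries count every class exactly once", {
  classes <- c("exonic", "exonic", "intronic", "intergenic", "UTR5")
  tab <- summarize_annotation(classes)
  expect_equal(nrow(tab), 11)
  expect_equal(sum(tab$count), length(classes))
  expect_equal(tab$count[tab$class == "exonic"], 2L)
  # permutation invariance
  expect_equal(summarize_annotation(rev(classes)), tab)
  expect_error(summarize_annotation(c("exonic", "weird")), "unknown")
})
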