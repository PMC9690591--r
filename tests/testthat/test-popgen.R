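# dosage-row shorthand: counts of (hom_ref, het, hom_alt, missing)
drow <- function(rr, het, aa, miss = 0)
  c(rep(0L, rr), rep(1L, het), rep(2L, aa), rep(NA_integer_, miss))

test_that("allele frequencies use non-missing genotypes in the subset", {
  cs <- two_pop_cs(rbind(drow(0, 0, 4), drow(2, 2, 0), drow(0, 0, 0, 4)),
                   rbind(drow(2, 0, 0), drow(2, 0, 0), drow(1, 1, 0)))
  pa <- allele_freqs(cs, "A")
  expect_equal(unname(pa), c(1, 0.25, NA))
  expect_equal(unname(allele_freqs(cs, "B")[3]), 0.25)
  pooled <- allele_freqs(cs)
  expect_equal(unname(pooled[1]), 8 / 12)
  expect_error(allele_freqs(cs, "C"), "unknown population")
})

test_that("per-variant Fst reproduces the heterozygosity formula", {
  # fixed difference, equal frequencies, and the 0.2/0.8 worked case
  cs <- two_pop_cs(rbind(drow(0, 0, 5), drow(1, 2, 2), drow(3, 2, 0),
                         drow(5, 0, 0)),
                   rbind(drow(5, 0, 0), drow(1, 2, 2), drow(0, 2, 3),
                         drow(5, 0, 0)))
  res <- fst_per_variant(cs, "A", "B")
  expect_equal(res$p_a, c(1, 0.6, 0.2, 0))
  expect_equal(res$p_b, c(0, 0.6, 0.8, 0))
  expect_equal(res$fst[1], 1)                      # fixed difference
  expect_equal(res$fst[2], 0)                      # identical frequencies
  expect_equal(res$ht[3], 0.5)
  expect_equal(res$hs[3], 0.32)
  expect_equal(res$fst[3], 0.36)
  expect_equal(res$fst[4], 0)                      # monomorphic pool: defined 0
  expect_true(all(res$fst >= 0 & res$fst <= 1))
  expect_true(all(res$hs <= res$ht + 1e-12))
})

test_that("Fst is invariant under allele relabeling", {
  set.seed(21)
  for (trial in 1:10) {
    ga <- matrix(sample(0:2, 60, TRUE), 6, 10)
    gb <- matrix(sample(0:2, 30, TRUE), 6, 5)
    cs <- two_pop_cs(ga, gb)
    cs_flip <- two_pop_cs(2L - ga, 2L - gb)
    expect_equal(fst_per_variant(cs_flip, "A", "B")$fst,
                 fst_per_variant(cs, "A", "B")$fst, tolerance = 1e-12)
  }
})

test_that("sex chromosomes and ungenotyped records are excluded from the scan", {
  rows <- rbind(vrow("a1", "chr1", 1000, 1499, "DEL"),
                vrow("x1", "X", 2000, 2499, "DEL"),
                vrow("a2", "chr2", 3000, 3499, "DEL"))
  geno <- rbind(c(0L, 1L, 2L, 1L), c(1L, 1L, 0L, 0L), c(NA, NA, 1L, 1L))
  colnames(geno) <- sprintf("s%d", 1:4)
  pop <- stats::setNames(c("A", "A", "B", "B"), colnames(geno))
  cs <- cnv_callset(rows, geno, colnames(geno), pop = pop)
  res <- fst_per_variant(cs, "A", "B")
  expect_equal(res$record_id, "a1")        # X dropped; a2 has no A genotypes
  expect_equal(attr(res, "n_excluded"), 1)
})

test_that("top-fraction selection uses ceil(k) and record_id tie-breaks", {
  res <- data.frame(record_id = sprintf("v%03d", 1:100),
                    fst = seq(0.99, 0, length.out = 100))
  sel <- select_top_fraction(res, 0.01)
  expect_equal(sel$n_selected, 1)
  expect_equal(sel$threshold, max(res$fst))
  expect_equal(res$record_id[sel$results$selected], "v001")
  # five-way tie at the top: still exactly one selected, smallest id
  res2 <- res; res2$fst[1:5] <- 0.999; res2$record_id[1:5] <- c("e", "d", "a", "b", "c")
  sel2 <- select_top_fraction(res2, 0.01)
  expect_equal(sum(sel2$results$selected), 1)
  expect_equal(res2$record_id[sel2$results$selected], "a")
  # ceil: 150 records at 1% -> 2
  res3 <- data.frame(record_id = sprintf("v%03d", 1:150),
                     fst = seq(1, 0, length.out = 150))
  expect_equal(select_top_fraction(res3, 0.01)$n_selected, 2)
})

test_that("frequency spectra use right-closed bins and exclude absent variants", {
  ga <- rbind(drow(9, 1, 0),      # p = 0.05  -> bin 1
              drow(8, 2, 0),      # p = 0.10  -> bin 1 (right edge)
              drow(7, 3, 0),      # p = 0.15  -> bin 2
              drow(0, 0, 10),     # p = 1.0   -> bin 10
              drow(10, 0, 0))     # p = 0     -> excluded
  gb <- matrix(0L, 5, 4)
  cs <- two_pop_cs(ga, gb)
  spec <- frequency_spectrum(cs, "A")
  all_counts <- spec$count[spec$svtype == "all"]
  expect_equal(all_counts[1], 2)
  expect_equal(all_counts[2], 1)
  expect_equal(all_counts[10], 1)
  expect_equal(sum(all_counts), 4)
  p <- allele_freqs(cs, "A")
  expect_equal(sum(all_counts), sum(p > 0, na.rm = TRUE))
  # per-type tables sum to the pooled table
  by_type <- tapply(spec$count[spec$svtype != "all"], spec$bin[spec$svtype != "all"], sum)
  expect_equal(unname(as.vector(by_type)), all_counts)
})

test_that("shared/unique comparison partitions the present variants", {
  ga <- rbind(drow(3, 1, 0), drow(4, 0, 0), drow(2, 2, 0), drow(4, 0, 0))
  gb <- rbind(drow(1, 1, 0), drow(1, 1, 0), drow(2, 0, 0), drow(2, 0, 0))
  cs <- two_pop_cs(ga, gb)
  cmp <- callset_comparison(cs, "A", "B")
  expect_equal(cmp$n_shared, 1)
  expect_equal(cmp$n_unique_a, 1)
  expect_equal(cmp$n_unique_b, 1)
  pa <- allele_freqs(cs, "A"); pb <- allele_freqs(cs, "B")
  n_present <- sum((!is.na(pa) & pa > 0) | (!is.na(pb) & pb > 0))
  expect_equal(cmp$n_shared + cmp$n_unique_a + cmp$n_unique_b, n_present)
})

test_that("callset summaries count present variants and |svlen| lengths", {
  rows <- rbind(vrow("d1", "chr1", 1000, 1999, "DEL"),    # len 1000
                vrow("u1", "chr1", 5000, 5299, "DUP"),    # len 300
                vrow("i1", "chr1", 9000, 9000, "INS", svlen = 200L),
                vrow("d2", "chr2", 1000, 1499, "DEL"))    # absent in A
  geno <- rbind(c(1L, 1L, 0L, 0L), c(0L, 1L, 1L, 0L), c(2L, 0L, 0L, 1L),
                c(0L, 0L, 1L, 1L))
  colnames(geno) <- sprintf("s%d", 1:4)
  pop <- stats::setNames(c("A", "A", "B", "B"), colnames(geno))
  cs <- cnv_callset(rows, geno, colnames(geno), pop = pop)
  s_all <- callset_summary(cs)
  expect_equal(s_all$n_total, 4)
  expect_equal(s_all$total_length, 1000 + 300 + 200 + 500)
  s_a <- callset_summary(cs, "A")
  expect_equal(c(s_a$n_del, s_a$n_dup, s_a$n_ins), c(1, 1, 1))
  expect_equal(s_a$total_length, 1500)
  expect_equal(s_a$mean_length_bp, 500)
  expect_equal(s_a$median_length, 300)
  empty <- callset_summary(
    cnv_callset(rows[0, ], matrix(integer(0), 0, 4), colnames(geno)))
  expect_equal(empty$n_total, 0)
  expect_true(is.na(empty$mean_length))
})
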