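fixture_partitions <- function() {
  iso1 <- list(data.frame(start = c(100, 500), end = c(200, 600)))
  iso2 <- list(data.frame(start = c(2000, 2800), end = c(2300, 3000)))
  list(
    g1 = partition_snhg(gene_model("g1", "chr1", "+", iso1),
                        data.frame(sno_id = "s1", start = 300, end = 350)),
    g2 = partition_snhg(gene_model("g2", "chr1", "+", iso2),
                        data.frame(sno_id = "s2", start = 2400, end = 2500)))
}

test_that("reads are assigned by majority overlap with the stated tie priority", {
  parts <- fixture_partitions()
  reads <- data.frame(
    chrom = "chr1",
    start = c(120, 290, 120, 700),
    end   = c(170, 320, 170, 800),
    sample = c("a", "a", "b", "a"))
  ct <- assign_reads(reads, parts)
  expect_equal(ct$counts["g1:Exon", "a"], 1L)     # fully exonic read
  expect_equal(ct$counts["g1:Snorna", "a"], 1L)   # 10 nt Pre vs 20 nt Snorna
  expect_equal(ct$counts["g1:Exon", "b"], 1L)
  expect_equal(sum(ct$counts), 3L)                # read outside hosts ignored
  # exact tie in overlapped bases resolves by class priority
  tie <- assign_reads(data.frame(chrom = "chr1", start = 290, end = 310,
                                 sample = "a"), parts)
  expect_equal(tie$counts["g1:Snorna", "a"], 1L)
})

test_that("random reads match the brute-force maximal-overlap oracle and conserve per-host counts", {
  set.seed(11)
  parts <- fixture_partitions()
  n <- 1000
  reads <- data.frame(
    chrom = sample(c("chr1", "chrX"), n, replace = TRUE, prob = c(0.95, 0.05)),
    start = sample(0:3500, n, replace = TRUE),
    sample = sample(c("a", "b"), n, replace = TRUE))
  reads$end <- reads$start + sample(20:120, n, replace = TRUE)
  ct <- assign_reads(reads, parts)
  want <- oracle_assign(reads, parts)
  tab <- table(paste(want[!is.na(want)],
                     reads$sample[!is.na(want)], sep = "@"))
  for (key in names(tab)) {
    ks <- strsplit(key, "@", fixed = TRUE)[[1]]
    expect_equal(ct$counts[ks[1], ks[2]], unname(tab[[key]]),
                 label = sprintf("count for %s", key))
  }
  # conservation: every host-overlapping read counted exactly once
  expect_equal(sum(ct$counts), sum(!is.na(want)))
  d <- attr(ct, "diagnostics")
  expect_equal(d$unknown_chrom, sum(reads$chrom == "chrX"))
})

test_that("median-of-ratios size factors satisfy the definitional examples and scaling", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(c("f1", "f2", "f3"), c("A", "B")))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-10)
  ident <- cbind(A = c(5, 9, 14), B = c(5, 9, 14))
  rownames(ident) <- paste0("f", 1:3)
  expect_equal(unname(size_factors(ident)), c(1, 1))
  # multiplying one sample's counts by c multiplies its factor by c relative
  # to the others (the geometric-mean denominator rebalances both samples)
  m2 <- m; m2[, "B"] <- m2[, "B"] * 5
  sf <- size_factors(m); sf2 <- size_factors(m2)
  expect_equal((sf2[["B"]] / sf2[["A"]]) / (sf[["B"]] / sf[["A"]]), 5,
               tolerance = 1e-10)
  # scaling every sample together leaves the factors unchanged
  expect_equal(size_factors(m * 7), sf, tolerance = 1e-10)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "nonzero")
})

test_that("fpkm follows its formula and is linear in counts", {
  m <- matrix(c(100, 0, 50), ncol = 1, dimnames = list(c("a", "b", "c"), "s"))
  got <- fpkm(m, lengths = c(a = 1000, b = 1000, c = 500),
              totals = c(1e6, 1e6, 2e6)[1])
  expect_equal(unname(got[, 1]), c(100, 0, 100 * 50 / (0.5 * 100)))
  got2 <- fpkm(matrix(50, 1, 1, dimnames = list("a", "s")),
               lengths = c(a = 500), totals = 2e6)
  expect_equal(unname(got2[1, 1]), 50)
  # doubling counts and totals together leaves FPKM unchanged
  expect_equal(fpkm(m * 2, lengths = c(a = 1000, b = 1000, c = 500),
                    totals = 2e6),
               fpkm(m, lengths = c(a = 1000, b = 1000, c = 500),
                    totals = 1e6))
  expect_error(fpkm(m, lengths = c(a = 1000, b = 1000, c = 500), totals = 0))
})
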