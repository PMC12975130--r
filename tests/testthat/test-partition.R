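test_that("a single intronic snoRNA splits its intron into Pre and Post by strand", {
  iso <- list(data.frame(start = c(100, 500), end = c(200, 600)))
  sno <- data.frame(sno_id = "s1", start = 300, end = 350)

  p <- partition_snhg(gene_model("g", "chr1", "+", iso), sno)
  expect_equal(p$region, c("Exon", "Pre", "Snorna", "Post", "Exon"))
  expect_equal(p$start, c(100, 200, 300, 350, 500))
  expect_equal(p$end, c(200, 300, 350, 500, 600))

  m <- partition_snhg(gene_model("g", "chr1", "-", iso), sno)
  expect_equal(m$region, c("Exon", "Post", "Snorna", "Pre", "Exon"))
  expect_equal(m$start, p$start)
})

test_that("isoform exon-union merging matches the per-base oracle on the worked case", {
  model <- gene_model("g", "chr1", "+", list(
    data.frame(start = c(0, 400), end = c(100, 500)),
    data.frame(start = c(0, 250, 400), end = c(100, 300, 500))))
  sno <- data.frame(sno_id = "s1", start = 150, end = 200)
  p <- partition_snhg(model, sno)
  expect_equal(p$region,
               c("Exon", "Pre", "Snorna", "Post", "Exon", "OtherIntron", "Exon"))
  expect_equal(p$start, c(0, 100, 150, 200, 250, 300, 400))
  expect_equal(p$end, c(100, 150, 200, 250, 300, 400, 500))
  # per-base oracle equivalence
  ob <- oracle_base_labels(model, sno)
  pb <- partition_base_labels(p)
  expect_equal(pb$label[order(pb$pos)], ob$label)
})

test_that("interval partition equals the per-base classifier on random gene models", {
  set.seed(42)
  n_checked <- 0
  for (i in 1:60) {
    model <- random_gene_model()
    snos <- random_snos_for(model)
    if (is.null(snos)) next
    p <- partition_snhg(model, snos)
    ob <- oracle_base_labels(model, snos)
    pb <- partition_base_labels(p)
    pb <- pb[order(pb$pos), ]
    expect_identical(pb$label, ob$label)
    expect_identical(pb$sno, ob$sno)
    # segments tile the merged span with no zero-length pieces
    expect_true(all(p$end > p$start))
    expect_equal(sum(p$end - p$start), nrow(ob))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 30)
})

test_that("strand handling is geometrically consistent", {
  # flipping the strand at fixed coordinates swaps Pre and Post
  iso <- list(data.frame(start = c(100, 500), end = c(200, 600)))
  sno <- data.frame(sno_id = "s1", start = 300, end = 350)
  p_plus <- partition_snhg(gene_model("g", "chr1", "+", iso), sno)
  p_minus <- partition_snhg(gene_model("g", "chr1", "-", iso), sno)
  swap <- c(Exon = "Exon", Pre = "Post", Post = "Pre", Snorna = "Snorna",
            OtherIntron = "OtherIntron")
  expect_equal(unname(swap[p_minus$region]), p_plus$region)

  # reflecting coordinates AND flipping strand is the identity on
  # transcription orientation: labels are preserved at mirrored positions
  set.seed(7)
  for (i in 1:20) {
    model <- random_gene_model()
    snos <- random_snos_for(model)
    if (is.null(snos)) next
    p <- partition_snhg(model, snos)
    C <- 20000L
    mirror <- gene_model(
      model$gene_id, model$chrom, if (model$strand == "+") "-" else "+",
      lapply(model$isoforms, function(e)
        data.frame(start = C - e$end, end = C - e$start)))
    msnos <- data.frame(sno_id = snos$sno_id, start = C - snos$end,
                        end = C - snos$start)
    pm <- partition_snhg(mirror, msnos)
    back <- data.frame(start = C - pm$end, end = C - pm$start,
                       region = pm$region, sno_id = pm$sno_id)
    back <- back[order(back$start), ]
    expect_equal(back$start, p$start)
    expect_equal(back$end, p$end)
    expect_equal(back$region, p$region)
    expect_equal(back$sno_id, p$sno_id)
  }
})

test_that("exonic snoRNAs exclude the host; out-of-span snoRNAs are input errors", {
  iso <- list(data.frame(start = c(100, 500), end = c(200, 600)))
  m <- gene_model("g", "chr1", "+", iso)
  ex_overlap <- partition_snhg(m, data.frame(sno_id = "s1", start = 150,
                                             end = 250))
  expect_s3_class(ex_overlap, "snhg_excluded")
  expect_match(attr(ex_overlap, "diagnostic"), "overlaps the exon union")
  expect_error(partition_snhg(m, data.frame(sno_id = "s1", start = 700,
                                            end = 750)),
               class = "snhg_input_error")
})

test_that("partition_all handles empty input, valid hosts, exclusions and duplicates", {
  expect_equal(partition_all(list(), data.frame(sno_id = character(0),
                                                host_id = character(0),
                                                start = integer(0),
                                                end = integer(0)))$partitions,
               list())
  iso <- list(data.frame(start = c(100, 500), end = c(200, 600)))
  g1 <- gene_model("g1", "chr1", "+", iso)
  g2 <- gene_model("g2", "chr1", "+", iso)
  snos <- data.frame(sno_id = c("a", "b"), host_id = c("g1", "g2"),
                     start = c(300, 150), end = c(350, 250))
  res <- partition_all(list(g1, g2), snos)
  expect_named(res$partitions, "g1")
  expect_length(res$diagnostics, 1)
  expect_error(partition_all(list(g1, g1), snos[1, ]),
               class = "snhg_input_error")
})
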