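# Region readers, promoter extension, PIR filtering and PIR-promoter linkage.

test_that("read_bed parses promoters, PIRs and malformed input", {
  p <- write_lines_tmp(c("# header", "chr1\t100\t200\tGENE1",
                         "chr2\t500\t900\tGENE2"))
  prom <- read_bed(p, kind = "promoter")
  expect_equal(prom$chrom, c("chr1", "chr2"))
  expect_equal(prom$gene, c("GENE1", "GENE2"))
  expect_equal(prom$tss, c(150, 700))
  expect_equal(prom$start, c(100, 500))

  q <- write_lines_tmp(c("track name=x", "chr1\t10\t20\tmyPIR", "chr1\t30\t40"))
  pir <- read_bed(q, kind = "pir")
  expect_equal(pir$id, c("myPIR", "chr1:30-40"))
  expect_true(all(is.na(pir$support_count)))

  expect_warning(empty <- read_bed(write_lines_tmp(character()), "pir"),
                 "no records")
  expect_equal(nrow(empty), 0)

  expect_error(read_bed(write_lines_tmp("chr1\t300\t250"), "pir"),
               "end <= start at line 1")
  expect_error(read_bed(write_lines_tmp(c("chr1\t1\t5", "chr1\t9")), "pir"),
               "line 2")
  expect_error(read_bed(write_lines_tmp("chr1\t100\t200"), "promoter"),
               "line 1")
})

test_that("extend_promoters anchors on the TSS midpoint and clamps at 0", {
  prom <- data.frame(chrom = "chr1", start = c(5000, 300), end = c(5001, 301),
                     id = c("p1", "p2"), gene = c("A", "B"),
                     tss = c(5000, 300))
  ext <- extend_promoters(prom, 1000)
  expect_equal(ext$start, c(4000, 0))
  expect_equal(ext$end, c(6000, 1300))
  expect_equal(ext$id, prom$id)
  expect_identical(extend_promoters(prom, 0), prom)
})

test_that("PIR peak support counts samples, not peaks", {
  pirs <- data.frame(chrom = "chr1", start = c(0, 5000, 9000),
                     end = c(1000, 6000, 10000),
                     id = c("a", "b", "c"), support_count = NA_integer_)
  peaks <- data.frame(
    chrom = "chr1",
    start = c(500, 700, 100, 200, 300, 5500),
    end   = c(600, 800, 150, 250, 350, 5600),
    sample_id = c("s1", "s2", "s1", "s1", "s1", "s1"),
    mark = c("H3K27ac", "H3K27ac", "H3K4me1", "H3K4me1", "H3K4me1",
             "H3K9me3"))
  kept <- filter_pirs_by_peaks(pirs, peaks)
  # a: samples s1+s2 -> retained; b: only an H3K9me3 peak -> no support;
  # c: nothing; three H3K4me1 peaks in s1 alone still count as one sample
  expect_equal(kept$id, "a")
  expect_equal(kept$support_count, 2L)
  expect_error(filter_pirs_by_peaks(pirs, NULL), "disable")
  expect_true(all(filter_pirs_by_peaks(pirs, peaks,
                                       min_samples = 1)$support_count >= 1))
})

test_that("interaction linkage emits edges for anchors in either order", {
  prom <- data.frame(chrom = "chr1", start = c(4000, 8000),
                     end = c(6000, 10000), id = c("p1", "p2"),
                     gene = c("G1", "G2"), tss = c(5000, 9000))
  pirs <- data.frame(chrom = "chr1", start = 100000, end = 101000, id = "e1")
  # anchor A on the PIR, anchor B on promoter 1
  ia <- data.frame(chrom_a = "chr1", start_a = 100000, end_a = 101000,
                   chrom_b = "chr1", start_b = 4500, end_b = 5500,
                   source = "x")
  e1 <- link_by_interactions(prom, pirs, ia)
  expect_equal(e1, data.frame(pir_id = "e1", promoter_id = "p1"))
  # swapped anchors give the same edge
  ib <- ia[, c(4:6, 1:3, 7)]
  names(ib) <- names(ia)
  expect_equal(link_by_interactions(prom, pirs, ib), e1)
  # an anchor spanning both promoters yields two edges
  ic <- ia
  ic$start_b <- 4500; ic$end_b <- 9500
  e2 <- link_by_interactions(prom, pirs, ic)
  expect_setequal(e2$promoter_id, c("p1", "p2"))
  # duplicated records collapse to one edge (idempotence)
  expect_equal(link_by_interactions(prom, pirs, rbind(ia, ia, ia)), e1)
  # record matching nothing -> no edge, message
  id <- ia; id$start_a <- 5e6; id$end_a <- 5e6 + 10
  expect_message(e4 <- link_by_interactions(prom, pirs, id), "matched no")
  expect_equal(nrow(e4), 0)
})

test_that("nearest linkage picks the closest TSS, ties toward lower coord", {
  prom <- data.frame(chrom = "chr1", start = c(3000, 6000),
                     end = c(5000, 8000), id = c("p1", "p2"),
                     gene = c("G1", "G2"), tss = c(4000, 7000))
  pirs <- data.frame(chrom = "chr1", start = 4900, end = 5100, id = "e1")
  expect_equal(link_by_nearest(prom, pirs)$promoter_id, "p1")  # mid 5000
  # equidistant between 4000 and 6000 -> lower tss
  prom2 <- prom; prom2$tss <- c(4000, 6000)
  expect_equal(link_by_nearest(prom2, pirs)$promoter_id, "p1")
  # exactly one edge per linkable PIR
  pirs2 <- data.frame(chrom = "chr1", start = c(0, 4900, 9000),
                      end = c(200, 5100, 9200), id = c("x", "y", "z"))
  e <- link_by_nearest(prom, pirs2)
  expect_equal(nrow(e), 3)
  expect_equal(anyDuplicated(e$pir_id), 0)
  # PIR on a promoter-free chromosome dropped with warning
  pirs3 <- rbind(pirs2, data.frame(chrom = "chrX", start = 1, end = 50,
                                   id = "w"))
  expect_warning(e3 <- link_by_nearest(prom, pirs3), "dropped")
  expect_false("w" %in% e3$pir_id)
})

test_that("linkage structure is invariant under a constant coordinate shift", {
  set.seed(42)
  sim <- tiny_sim(n_genes = 15, seed = 11)
  prom <- extend_promoters(sim$promoters)
  shift <- function(df, by) { df$start <- df$start + by; df$end <- df$end + by
    if (!is.null(df$tss)) df$tss <- df$tss + by; df }
  ints <- sim$interactions
  ints_s <- ints
  ints_s[c("start_a", "end_a", "start_b", "end_b")] <-
    ints_s[c("start_a", "end_a", "start_b", "end_b")] + 12345
  e0 <- link_by_interactions(prom, sim$pirs, ints)
  e1 <- link_by_interactions(shift(prom, 12345), shift(sim$pirs, 12345),
                             ints_s)
  expect_equal(e0[order(e0$pir_id), ], e1[order(e1$pir_id), ],
               ignore_attr = TRUE)
  n0 <- link_by_nearest(prom, sim$pirs)
  n1 <- link_by_nearest(shift(prom, 12345), shift(sim$pirs, 12345))
  expect_equal(n0[order(n0$pir_id), ], n1[order(n1$pir_id), ],
               ignore_attr = TRUE)
})

test_that("sample sheets and gene sets are read and validated", {
  ss <- write_lines_tmp(c("track_path\tcondition\tmark\tsample_id",
                          "a.bg\tA\tH3K27ac\ts1", "b.bg\tB\tH3K27ac\ts2"),
                        ext = ".tsv")
  sheet <- read_sample_sheet(ss)
  expect_equal(nrow(sheet), 2)
  bad <- write_lines_tmp(c("track_path\tcondition\tmark\tsample_id",
                           "a.bg\tA\tH3K27ac\ts1"), ext = ".tsv")
  expect_error(read_sample_sheet(bad), "lacks samples")

  gs1 <- write_lines_tmp(c("TP53", "MYC", "# note", "MYC"), ext = ".txt")
  sets <- read_gene_sets(gs1)
  expect_equal(length(sets), 1)
  expect_setequal(sets[[1]], c("TP53", "MYC"))
  gs2 <- write_lines_tmp(c("cmg\tTP53", "cmg\tMYC", "tsg\tALB"),
                         ext = ".txt")
  sets2 <- read_gene_sets(gs2)
  expect_setequal(names(sets2), c("cmg", "tsg"))
  expect_equal(sets2$tsg, "ALB")
})
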