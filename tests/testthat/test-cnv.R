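test_that("log2 ratios are total-read adjusted with pseudocount safety", {
  bins <- data.frame(chrom = "chr1", start = (0:9) * 100 + 1,
                     end = (1:10) * 100,
                     tumor_reads = (1:10) * 20, normal_reads = (1:10) * 10)
  lr <- log2Ratio(bins)          # same pattern, different totals
  expect_equal(lr$log2_ratio, rep(0, 10), tolerance = 1e-12)

  b2 <- bins
  b2$tumor_reads[5] <- b2$tumor_reads[5] * 2
  lr2 <- log2Ratio(b2)
  expected <- log2((b2$tumor_reads[5] / sum(b2$tumor_reads)) /
                     (b2$normal_reads[5] / sum(b2$normal_reads)))
  expect_equal(lr2$log2_ratio[5], expected)
  expect_gt(lr2$log2_ratio[5], 0.8)  # near 1, shrunk by the total rebalance

  b3 <- bins
  b3$tumor_reads[1] <- 0L
  lr3 <- log2Ratio(b3, pseudocount = 0.5)
  expect_true(is.finite(lr3$log2_ratio[1]) && lr3$log2_ratio[1] < 0)

  b4 <- bins
  b4$normal_reads <- 0L
  expect_error(log2Ratio(b4), "normal coverage")
})

test_that("CBS finds a +2 step within 2 bins and leaves nulls whole", {
  set.seed(51)
  x <- rnorm(100, 0, 0.1)
  x[51:100] <- x[51:100] + 2
  bins <- data.frame(chrom = "chr1", start = (0:99) * 1e6 + 1,
                     end = (1:100) * 1e6, log2_ratio = x)
  seg <- cbsSegment(bins, seed = 52)
  expect_equal(nrow(seg), 2L)
  expect_lte(abs(seg$end[1] / 1e6 - 50), 2)
  expect_equal(seg$mean_log2[2] - seg$mean_log2[1], 2, tolerance = 0.1)

  for (s in 1:3) {
    null <- data.frame(chrom = "chr1", start = bins$start, end = bins$end,
                       log2_ratio = rnorm(100, 0, 0.1))
    expect_equal(nrow(cbsSegment(null, seed = s)), 1L)
  }

  const <- data.frame(chrom = "chr1", start = bins$start, end = bins$end,
                      log2_ratio = rep(0.7, 100))
  cs <- cbsSegment(const, seed = 1)
  expect_equal(nrow(cs), 1L)
  expect_equal(cs$mean_log2, 0.7)
  expect_equal(cs$n_bins, 100L)
})

test_that("segmentation preserves the genome-wide mean", {
  set.seed(53)
  x <- c(rnorm(40, 0, 0.1), rnorm(30, 1.5, 0.1), rnorm(30, -1, 0.1))
  bins <- data.frame(chrom = "chr1", start = (0:99) * 1e6 + 1,
                     end = (1:100) * 1e6, log2_ratio = x)
  seg <- cbsSegment(bins, seed = 54)
  expect_equal(sum(seg$n_bins * seg$mean_log2) / sum(seg$n_bins), mean(x),
               tolerance = 1e-9)
  expect_equal(sum(seg$n_bins), 100L)
})

test_that("gene-level calls use length-weighted means and +/-2 screening", {
  genes <- data.frame(gene = "X", chrom = "chr1", start = 100, end = 1099)
  seg1 <- data.frame(chrom = "chr1", start = 1, end = 5000, n_bins = 5,
                     mean_log2 = 2.5)
  expect_equal(callGeneCnv(seg1, genes)$call, "gain")
  seg2 <- seg1; seg2$mean_log2 <- 1.9
  expect_equal(callGeneCnv(seg2, genes)$call, "neutral")
  seg2$mean_log2 <- -2.5
  expect_equal(callGeneCnv(seg2, genes)$call, "loss")

  # 90% of the gene at 3.0, 10% at 0.0 -> weighted mean 2.7
  segs <- data.frame(chrom = "chr1", start = c(100, 1000),
                     end = c(999, 1099), n_bins = c(9, 1),
                     mean_log2 = c(3, 0))
  out <- callGeneCnv(segs, genes)
  expect_equal(out$mean_log2, 2.7)
  expect_equal(out$call, "gain")
  # raising the gain threshold cannot create a gain
  expect_equal(callGeneCnv(segs, genes, gainThr = 3)$call, "neutral")

  off <- data.frame(gene = "Y", chrom = "chr2", start = 1, end = 10)
  expect_true(is.na(callGeneCnv(seg1, off)$call))
})

test_that("stage frequency counts lesions over the 0.3 threshold", {
  prof <- matrix(0, nrow = 10, ncol = 4)
  stages <- rep("AAH", 10)
  sf <- stageFrequency(prof, stages)
  expect_true(all(sf$gain == 0) && all(sf$loss == 0))

  prof2 <- rbind(matrix(0, 7, 4), matrix(1, 3, 4))
  sf2 <- stageFrequency(prof2, rep("MIA", 10))
  expect_equal(unname(sf2$gain["MIA", 1]), 0.3)
  # boundary: loss is inclusive at -thr, gain strict at thr
  sf3 <- stageFrequency(matrix(c(0.3, -0.3), 1, 2), "AIS")
  expect_equal(unname(sf3$gain["AIS", 1]), 0)
  expect_equal(unname(sf3$loss["AIS", 2]), 1)
})

test_that("the AI caller finds injected blocks and nothing else", {
  set.seed(61)
  baf <- 0.5 + rnorm(200, 0, 0.03)
  baf[81:130] <- 0.65 + rnorm(50, 0, 0.03)
  sites <- data.frame(chrom = "chr1", pos = 1:200, baf = baf)
  ev <- detectAi(sites)
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$start - 81), 3)
  expect_lte(abs(ev$end - 130), 3)

  flat <- data.frame(chrom = "chr1", pos = 1:200, baf = rep(0.5, 200))
  expect_equal(nrow(detectAi(flat)), 0L)

  # imbalanced stretches shorter than min_run never become events
  alt <- data.frame(chrom = "chr1", pos = 1:200,
                    baf = rep(c(rep(0.65, 5), rep(0.5, 5)), 20))
  expect_equal(nrow(detectAi(alt, minRun = 10)), 0L)

  few <- data.frame(chrom = "chr1", pos = 1:5, baf = rep(0.9, 5))
  expect_equal(nrow(detectAi(few)), 0L)
})

test_that("lesion AI count is the maximum over regions", {
  set.seed(62)
  mkSites <- function(nBlocks) {
    baf <- 0.5 + rnorm(300, 0, 0.03)
    for (b in seq_len(nBlocks)) {
      st <- 1 + (b - 1) * 100
      baf[st:(st + 40)] <- 0.65 + rnorm(41, 0, 0.03)
    }
    data.frame(chrom = "chr1", pos = 1:300, baf = baf)
  }
  r1 <- newRegion("L1_R1", 0.6, makeCall(), hetBafSites = mkSites(1))
  r2 <- newRegion("L1_R2", 0.6, makeCall(region_id = "L1_R2"),
                  hetBafSites = mkSites(3))
  lesion <- newLesion("L1", "P1", "ADC", list(r1, r2))
  cnt <- countAiEvents(lesion)
  expect_equal(unname(cnt$per_region), c(1L, 3L))
  expect_equal(cnt$lesion, 3L)
})
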