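test_that("SNV filter enforces every rule with the stated boundaries", {
  t <- filterThresholds()
  low_vaf <- makeCall(tumor_alt = 4L, tumor_depth = 100L)   # VAF 0.04
  v <- filterSnv(low_vaf, t)
  expect_false(v$pass)
  expect_match(v$reasons, "vaf_tumor")

  lod_edge <- makeCall(lod = 10)                            # strict > 10
  v <- filterSnv(lod_edge, t)
  expect_false(v$pass)
  expect_match(v$reasons, "lod")
  expect_true(filterSnv(makeCall(lod = 10.01), t)$pass)

  v <- filterSnv(makeCall(), t)                             # passing call
  expect_true(v$pass)
  expect_identical(v$reasons, "")

  zero_depth <- makeCall(tumor_alt = 0L, tumor_depth = 0L, vaf_tumor = 0)
  v <- filterSnv(zero_depth, t)                             # no div error
  expect_false(v$pass)
  expect_match(v$reasons, "depth_tumor")
})

test_that("indel filter uses strict depth rules and the 4-read support floor", {
  t <- filterThresholds()
  base <- makeCall(variant_class = "INDEL", ref = "A", alt = "AT",
                   context41 = NA, tumor_alt = 10L, tumor_depth = 100L,
                   normal_depth = 30L)
  expect_true(filterIndel(base, t)$pass)

  few <- base; few$tumor_alt <- 3L; few$vaf_tumor <- 0.03
  few$tumor_alt <- 3L; few$tumor_depth <- 40L; few$vaf_tumor <- 3 / 40
  v <- filterIndel(few, t)
  expect_false(v$pass)
  expect_match(v$reasons, "indel_alt_reads")

  edge <- base; edge$tumor_depth <- 15L; edge$tumor_alt <- 5L
  edge$vaf_tumor <- 5 / 15
  v <- filterIndel(edge, t)                                # strict > 15
  expect_false(v$pass)
  expect_match(v$reasons, "indel_tumor_reads")
  expect_true(filterIndel(transform(edge, tumor_depth = 16L), t)$pass)
})

test_that("consensus keeps keys seen by at least two callers, once", {
  sets <- list(mutect = c("k1", "k2", "k3"),
               vardict = c("k2", "k3", "k3"),
               muse = "k3")
  out <- consensusFilter(sets)
  expect_setequal(out, c("k2", "k3"))
  expect_equal(sum(out == "k3"), 1L)
  expect_length(consensusFilter(list(mutect = "k1")), 0L)
})

test_that("the filter cascade is idempotent and respects caller counts", {
  cohort <- simulateCohort(tinyConfig(seed = 11))
  calls <- variantCalls(lesions(cohort)[[3]])
  once <- applyFilterCascade(calls)
  twice <- applyFilterCascade(once)
  expect_identical(once, twice)
  single <- makeCall(callers = "mutect")
  expect_equal(nrow(applyFilterCascade(single)), 0L)
})

test_that("forced calling rescues relaxed-threshold evidence in siblings", {
  key_call <- makeCall(pos = 500L)
  weak <- makeCall(pos = 500L, region_id = "L1_R2", tumor_alt = 2L,
                   tumor_depth = 160L, lod = 3, callers = "mutect")
  lesion <- makeLesion(key_call, weak)
  pres <- forcedCall(lesion, "chr1:500:C:T")
  expect_true(pres[["L1_R1"]])
  expect_true(pres[["L1_R2"]])  # alt 2, VAF 0.0125

  weaker <- weak; weaker$tumor_alt <- 1L; weaker$vaf_tumor <- 1 / 160
  lesion2 <- makeLesion(key_call, weaker)
  expect_false(forcedCall(lesion2, "chr1:500:C:T")[["L1_R2"]])

  unpassed <- makeLesion(makeCall(pos = 500L, lod = 5),
                         makeCall(pos = 500L, region_id = "L1_R2", lod = 5))
  expect_error(forcedCall(unpassed, "chr1:500:C:T"), "did not pass")
})

test_that("transition fractions stratify by VAF and flag artifact samples", {
  ct <- do.call(rbind, lapply(1:3, function(i) makeCall(pos = i)))
  other <- do.call(rbind, lapply(4:10, function(i)
    makeCall(pos = i, ref = "A", alt = "G", context41 = ctxFor("AAA"))))
  tf <- transitionFraction(rbind(ct, other))
  expect_equal(tf$above, 0.3)
  expect_true(is.na(tf$below))

  empty <- transitionFraction(emptyVariantTable())
  expect_true(is.na(empty$overall))

  expect_true(flagArtifactSample(0.60))
  expect_false(flagArtifactSample(0.5625))  # strictly "over"
  expect_false(flagArtifactSample(0))
})

test_that("artifact-spiked regions show the low-VAF transition excess", {
  set.seed(42)
  cfg <- tinyConfig(seed = 42, artifactRate = 60)
  lesion <- lesions(simulateCohort(cfg))[["MIA_01"]]
  raw <- variantCalls(lesion)
  tf <- transitionFraction(raw[raw$variant_class == "SNV", ])
  expect_gt(tf$below, tf$above)
})

test_that("mutation burden counts the union and drop modes never increase it", {
  shared <- do.call(rbind, lapply(1:10, function(i)
    makeCall(pos = i * 10L, ref = "A", alt = "G", context41 = ctxFor("AAA"))))
  r2 <- shared; r2$region_id <- "L1_R2"
  private <- do.call(rbind, lapply(1:5, function(i)
    makeCall(pos = 1000L + i, ref = "A", alt = "C",
             context41 = ctxFor("AAA"))))
  lesion <- makeLesion(rbind(shared, private), r2)

  b <- mutationBurden(lesion, "all", exomeMb = 30)
  expect_equal(b$count, 15L)
  expect_equal(mutationBurden(lesion, "all", exomeMb = 15)$per_mb, 1)

  labels <- data.frame(key = mutationKey(rbind(shared, private)),
                       clonal = c(rep(TRUE, 10), rep(FALSE, 5)))
  bp <- mutationBurden(lesion, "drop_private_subclonal", 30,
                       clonality = labels)
  expect_equal(bp$count, 10L)

  allct <- do.call(rbind, lapply(1:6, function(i) makeCall(pos = i)))
  bt <- mutationBurden(makeLesion(allct), "drop_transitions", 30)
  expect_equal(bt$count, 0L)
  expect_lte(bp$count, b$count)
})

test_that("cancer-gene annotation reports hotspots and TSG truncations", {
  genes <- data.frame(gene = c("EGFR", "TP53", "KRAS"),
                      role = c("oncogene", "TSG", "oncogene"),
                      hotspots = c("L858R,T790M", "", "G12C"))
  calls <- rbind(
    cbind(makeCall(pos = 1L, gene = "EGFR", effect = "nonsynonymous"),
          protein_change = "L858R"),
    cbind(makeCall(pos = 2L, gene = "TP53", effect = "frameshift"),
          protein_change = NA),
    cbind(makeCall(pos = 3L, gene = "KRAS", effect = "nonsynonymous"),
          protein_change = "Q61H"),
    cbind(makeCall(pos = 4L, gene = NA, effect = "nonsynonymous"),
          protein_change = "X1Y"))
  out <- annotateCancerGenes(calls, genes)
  expect_equal(out$pos, c(1L, 2L))
  expect_equal(out$rule, c("hotspot", "tsg_truncating"))
})
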