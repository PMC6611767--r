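test_that("simulation is deterministic given the seed", {
  a <- simulateCohort(tinyConfig(seed = 5))
  b <- simulateCohort(tinyConfig(seed = 5))
  expect_identical(variantCalls(a), variantCalls(b))
  expect_identical(cohortTruth(a), cohortTruth(b))
  c2 <- simulateCohort(tinyConfig(seed = 6))
  expect_false(identical(variantCalls(a), variantCalls(c2)))
})

test_that("zero lesions give an empty cohort with a warning", {
  cfg <- simulationConfig(lesionsPerStage = c(AAH = 0, AIS = 0, MIA = 0,
                                              ADC = 0))
  expect_warning(co <- simulateCohort(cfg), "zero lesions")
  expect_length(lesions(co), 0L)
})

test_that("per-stage true burden tracks the configured means", {
  cfg <- simulationConfig(seed = 3,
                          lesionsPerStage = c(AAH = 6, AIS = 6, MIA = 6,
                                              ADC = 6))
  co <- simulateCohort(cfg)
  truth <- cohortTruth(co)
  byStage <- vapply(ipnStages(), function(s) {
    mean(vapply(truth[grep(s, names(truth))], function(t) t$nMutations,
                numeric(1)))
  }, numeric(1))
  # Poisson means: 6-lesion averages stay within ~4 sd of the target
  for (s in ipnStages()) {
    mu <- cfg$meanBurden[[s]]
    expect_lt(abs(byStage[[s]] - mu), 4 * sqrt(mu / 6))
  }
  expect_true(all(diff(byStage) > 0))
})

test_that("clone trees honour the sweep and diversify regimes", {
  set.seed(9)
  solo <- simulateCloneTree(1, 3)
  expect_equal(solo$ccf, matrix(1, 1, 3))

  for (i in 1:20) {
    tr <- simulateCloneTree(4, 3, "sweep", dominance = 0.9)
    expect_true(all(tr$occupancy[1, ] >= 0.9 - 1e-9))
    expect_true(all(tr$occupancy >= -1e-9))
    # lineage consistency: child CCF never exceeds its parent's
    for (j in 2:4)
      expect_true(all(tr$ccf[j, ] <= tr$ccf[tr$parent[j], ] + 1e-9))
  }

  privateSeen <- vapply(1:100, function(i) {
    tr <- simulateCloneTree(4, 3, "diversify")
    any(vapply(2:4, function(j) sum(tr$ccf[j, ] > 0) == 1L, logical(1)))
  }, logical(1))
  expect_gt(mean(privateSeen), 0.9)
})

test_that("read counts follow the CCF-VAF mapping", {
  set.seed(4)
  rc <- simulateReadCounts(0, 0.6, n = 50)
  expect_true(all(rc$tumor_alt == 0))

  rc <- simulateReadCounts(0.5, 0.5, copyNumber = 2, multiplicity = 1,
                           depthMean = 400, n = 4000)
  expect_equal(mean(rc$tumor_alt / rc$tumor_depth), 0.125, tolerance = 0.02)

  rc <- simulateReadCounts(1, 1, copyNumber = 2, multiplicity = 1,
                           depthMean = 2000, n = 500)
  expect_equal(mean(rc$tumor_alt / rc$tumor_depth), 0.5, tolerance = 0.01)

  expect_error(simulateReadCounts(1, 1, copyNumber = 1, multiplicity = 2),
               "VAF exceeds 1")
})

test_that("signature draws follow the mixture and edge cases", {
  R <- syntheticSignatures(4)
  set.seed(8)
  ch <- simulateSignatureMutations(c(1, 0, 0, 0), 10000, R)
  emp <- as.numeric(table(factor(ch, levels = trinucleotideChannels()))) /
    10000
  expect_lt(sum(abs(emp - R[, 1])), 0.05)
  expect_true(all(ch %in% trinucleotideChannels()[R[, 1] > 0]))
  expect_length(simulateSignatureMutations(c(1, 0, 0, 0), 0, R), 0L)
  expect_error(simulateSignatureMutations(c(1, 0), 10, R))
})

test_that("FFPE artifact injection has the stated signature", {
  reg <- newRegion("L1_R1", 0.6, makeCall())
  set.seed(10)
  same <- injectFfpeArtifacts(reg, 0)
  expect_identical(same$region@calls, reg@calls)

  out <- injectFfpeArtifacts(reg, 80)
  added <- out$region@calls[-1, ]
  expect_gt(nrow(added), 40)
  expect_true(all((added$ref == "C" & added$alt == "T") |
                    (added$ref == "G" & added$alt == "A")))
  expect_true(all(added$vaf_tumor < 0.10))
  expect_true(all(added$lod < 10))
  expect_true(all(!grepl(",", added$callers)))  # single caller
  expect_true(all(nchar(added$context41) == 41L))
  expect_identical(mutationKey(added), out$truth$key)
})

test_that("artifact rate zero leaves the cohort truth artifact-free", {
  co <- simulateCohort(tinyConfig(seed = 2, artifactRate = 0))
  nArt <- sum(vapply(cohortTruth(co), function(t) nrow(t$artifacts),
                     numeric(1)))
  expect_equal(nArt, 0)
})

test_that("every emitted call traces to a truth record", {
  co <- simulateCohort(tinyConfig(seed = 13))
  for (lid in names(lesions(co))) {
    calls <- variantCalls(lesions(co)[[lid]])
    truth <- cohortTruth(co)[[lid]]
    known <- c(truth$mutations$key, truth$artifacts$key)
    expect_true(all(mutationKey(calls) %in% known))
  }
})
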