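test_that("channel classification follows the pyrimidine convention", {
  snv <- makeCall()                      # ACG centre, C>T
  expect_equal(classifyChannel(snv), "A[C>T]G")
  # purine reference: reverse complement onto the same channel
  rc <- makeCall(ref = "G", alt = "A", context41 = ctxFor("CGT"))
  expect_equal(classifyChannel(rc), "A[C>T]G")
  amb <- makeCall(context41 = ctxFor("NCG"))
  expect_true(is.na(classifyChannel(amb)))
  expect_error(classifyChannel(makeCall(context41 = ctxFor("AAG"))),
               "centre base")
})

test_that("spectra are invariant under strand flip of every input", {
  co <- simulateCohort(tinyConfig(seed = 21))
  calls <- variantCalls(lesions(co)[[4]])
  calls <- calls[calls$variant_class == "SNV", ]
  flipped <- calls
  flipped$context41 <- reverseComplement(calls$context41)
  flipped$ref <- chartr("ACGT", "TGCA", calls$ref)
  flipped$alt <- chartr("ACGT", "TGCA", calls$alt)
  expect_identical(mutationSpectrum(calls), mutationSpectrum(flipped))
  a <- apobecEnrichment(calls)
  b <- apobecEnrichment(flipped)
  expect_equal(a$enrichment, b$enrichment)
  expect_equal(a$tcw_mut, b$tcw_mut)
})

test_that("deconstruction recovers exact and sampled exposures", {
  R <- syntheticSignatures(5)
  exact <- deconstructSignatures(round(R[, 2] * 2000), R)
  expect_equal(unname(exact$weights[2]), 1, tolerance = 1e-6)
  expect_equal(exact$unexplained, 0, tolerance = 1e-6)

  set.seed(31)
  ch <- simulateSignatureMutations(c(1, 0, 0, 0, 0), 1000, R)
  spec <- stats::setNames(
    as.integer(table(factor(ch, levels = trinucleotideChannels()))),
    trinucleotideChannels())
  d <- deconstructSignatures(spec, R)
  expect_gte(unname(d$weights[1]), 0.95)

  expect_false(deconstructSignatures(round(R[, 1] * 99), R)$evaluated)
  expect_error(deconstructSignatures(integer(96), R), "all-zero")
})

test_that("deconstruction is scale invariant and weights stay normalised", {
  R <- syntheticSignatures(5)
  set.seed(32)
  ch <- simulateSignatureMutations(c(0.5, 0.3, 0.2, 0, 0), 800, R)
  spec <- stats::setNames(
    as.integer(table(factor(ch, levels = trinucleotideChannels()))),
    trinucleotideChannels())
  d1 <- deconstructSignatures(spec, R)
  d2 <- deconstructSignatures(spec * 7L, R)
  expect_equal(d1$weights, d2$weights, tolerance = 1e-9)
  expect_true(all(d1$weights >= 0))
  expect_equal(sum(d1$weights) + d1$unexplained, 1, tolerance = 1e-3)
  # pruning floor: retained weights clear 0.06
  expect_true(all(d1$weights[d1$weights > 0] >= 0.06))
})

test_that("two-signature mixtures are recovered within L1 0.10", {
  R <- syntheticSignatures(5)
  truthW <- c(0.6, 0.4, 0, 0, 0)
  l1 <- vapply(1:10, function(i) {
    set.seed(100 + i)
    ch <- simulateSignatureMutations(truthW, 1000, R)
    spec <- stats::setNames(
      as.integer(table(factor(ch, levels = trinucleotideChannels()))),
      trinucleotideChannels())
    sum(abs(deconstructSignatures(spec, R)$weights - truthW))
  }, numeric(1))
  expect_lt(stats::median(l1), 0.10)
})

test_that("APOBEC enrichment matches direct motif counting", {
  # ten C>T calls at a TCA centre inside a fixed, motif-counted window;
  # C-rich flanks keep the motif density below the mutation rate
  win <- ctxFor("TCA", flank = "C")
  calls <- do.call(rbind, lapply(1:10, function(i)
    makeCall(pos = i * 7L, ref = "C", alt = "T", context41 = win)))
  countAll <- function(s, pat) {
    hits <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (hits[1] == -1) 0L else length(hits)
  }
  tcw <- 10 * (countAll(win, "(?=TC[AT])") + countAll(win, "(?=[AT]GA)"))
  cg <- 10 * (countAll(win, "C") + countAll(win, "G"))
  res <- apobecEnrichment(calls)
  expect_equal(res$tcw_mut, 10L)
  expect_equal(res$c_mut, 10L)
  expect_equal(res$enrichment, (10 / tcw) / (10 / cg))
  expect_gt(res$enrichment, 1)

  expect_true(is.na(apobecEnrichment(calls[1:9, ])$enrichment))
})

test_that("mutations spread uniformly over C sites score near 1", {
  # windows of random composition; mutate the centre C of each, so the
  # mutated sites carry no motif preference beyond the window base mix
  scoreFor <- function(seed) {
    set.seed(seed)
    mk <- function(i) {
      flanks <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                      collapse = "")
      ctx <- paste0(substr(flanks, 1, 20), "C", substr(flanks, 21, 40))
      makeCall(pos = i, ref = "C", alt = sample(c("T", "G"), 1),
               context41 = ctx)
    }
    apobecEnrichment(do.call(rbind, lapply(1:1000, mk)))$enrichment
  }
  med <- stats::median(vapply(1:5, scoreFor, numeric(1)))
  expect_equal(med, 1.0, tolerance = 0.2)
})
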