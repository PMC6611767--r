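test_that("presence matrices record filter passes and forced rescues", {
  m1 <- makeCall(pos = 10L)
  m2 <- makeCall(pos = 20L)
  m3 <- makeCall(pos = 30L)
  r2only <- makeCall(pos = 10L, region_id = "L1_R2")
  lesion <- makeLesion(rbind(m1, m2, m3), r2only)
  pm <- presenceMatrix(lesion, rescue = FALSE)
  expect_setequal(rownames(pm), c("L1_R1", "L1_R2", "NORMAL"))
  expect_equal(sort(unname(colSums(pm))), c(1L, 1L, 2L))
  expect_true(all(pm["NORMAL", ] == 0L))

  # sub-threshold evidence in the sibling flips 0 to 1 under rescue
  weak <- makeCall(pos = 20L, region_id = "L1_R2", tumor_alt = 3L,
                   tumor_depth = 150L, lod = 2, callers = "mutect")
  lesion2 <- makeLesion(rbind(m1, m2, m3), rbind(r2only, weak))
  key <- "chr1:20:C:T"
  expect_equal(presenceMatrix(lesion2, rescue = FALSE)["L1_R2", key], 0L)
  expect_equal(presenceMatrix(lesion2, rescue = TRUE)["L1_R2", key], 1L)

  none <- makeLesion(makeCall(lod = 1), makeCall(lod = 1,
                                                 region_id = "L1_R2"))
  expect_equal(ncol(presenceMatrix(none)), 0L)
})

test_that("Hamming distances count differing columns", {
  m <- rbind(A = c(1, 1, 1), B = c(1, 0, 0), NORMAL = c(0, 0, 0))
  d <- hammingDistances(m)
  expect_equal(d["A", "B"], 2L)
  expect_equal(d["A", "NORMAL"], 3L)
  expect_equal(d["B", "NORMAL"], 1L)
  expect_true(all(diag(d) == 0L))
  expect_identical(d, t(d))
})

test_that("neighbor joining recovers additive trees exactly", {
  # ((A:1,B:2):1,C:3,D:4) with internal edge 1: additive path distances
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tree <- neighborJoining(d)
  paths <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(paths, d, tolerance = 1e-9)
  # AB vs CD split present
  expect_true(ape::is.monophyletic(ape::root(tree, "D"), c("A", "B")))
})

test_that("three taxa give the unique topology with clamped lengths", {
  m <- rbind(A = c(1, 1, 0), B = c(1, 0, 1), NORMAL = c(0, 0, 0))
  tree <- neighborJoining(hammingDistances(m))
  expect_equal(ape::Ntip(tree), 3L)
  expect_true(all(tree$edge.length >= 0))
})

test_that("Wagner parsimony scores match hand-derived cases", {
  m <- rbind(NORMAL = rep(0L, 6),
             A = c(1L, 1L, 1L, 0L, 0L, 0L),
             B = c(1L, 1L, 1L, 1L, 1L, 0L))
  m <- m[, colSums(m) > 0]
  fit <- wagnerParsimony(m, "exhaustive")
  expect_equal(fit$score, 5L)                    # 3 trunk + 2 private to B
  expect_equal(sum(fit$tree$edge.length), 5)

  same <- rbind(NORMAL = rep(0L, 4), A = rep(1L, 4), B = rep(1L, 4),
                C = rep(1L, 4))
  expect_equal(wagnerParsimony(same, "exhaustive")$score, 4L)

  onecol <- rbind(NORMAL = 0L, A = 1L, B = 1L, C = 1L)
  colnames(onecol) <- "k1"
  expect_equal(wagnerParsimony(onecol, "exhaustive")$score, 1L)
})

test_that("parsimony scores agree with an independent implementation", {
  set.seed(81)
  for (i in 1:5) {
    n <- sample(4:6, 1)
    m <- matrix(rbinom(n * 10, 1, 0.5), n, 10,
                dimnames = list(c(paste0("R", seq_len(n - 1)), "NORMAL"),
                                paste0("c", 1:10)))
    m["NORMAL", ] <- 0L
    m <- m[, colSums(m) > 0, drop = FALSE]
    fit <- wagnerParsimony(m, "exhaustive")
    dat <- phangorn::phyDat(m, type = "USER", levels = c(0L, 1L))
    oracle <- min(vapply(
      phangorn::allTrees(nrow(m), rooted = FALSE, tip.label = rownames(m)),
      function(tr) phangorn::parsimony(tr, dat), numeric(1)))
    expect_equal(fit$score, oracle)
    # lower bound: each carried column needs at least one change
    expect_gte(fit$score, ncol(m))
    # heuristic search reaches the exhaustive optimum on small inputs
    expect_equal(wagnerParsimony(m, "nj_seeded_nni")$score, fit$score)
  }
})

test_that("exhaustive search refuses oversized inputs", {
  m <- matrix(1L, 9, 2,
              dimnames = list(c(paste0("R", 1:8), "NORMAL"), c("a", "b")))
  m["NORMAL", ] <- 0L
  expect_error(wagnerParsimony(m, "exhaustive"), "at most 8")
})

test_that("trunk statistics count ubiquitous columns", {
  m <- rbind(NORMAL = rep(0L, 10),
             A = c(rep(1L, 8), 1L, 0L),
             B = c(rep(1L, 8), 0L, 1L))
  tb <- trunkBranchStats(m)
  expect_equal(tb$n_trunk, 8L)
  expect_equal(tb$trunk_proportion, 0.8)

  disjoint <- rbind(NORMAL = rep(0L, 4), A = c(1L, 1L, 0L, 0L),
                    B = c(0L, 0L, 1L, 1L))
  expect_equal(trunkBranchStats(disjoint)$trunk_proportion, 0)

  perm <- m[, sample(ncol(m))]
  rownames(perm) <- c("NORMAL", "X", "Y")
  expect_equal(trunkBranchStats(perm)$trunk_proportion, 0.8)

  single <- m[c("NORMAL", "A"), ]
  expect_false(trunkBranchStats(single)$evaluated)
})

test_that("sweep lesions carry a higher trunk proportion than diversified", {
  set.seed(82)
  trunkFor <- function(regime) {
    tr <- simulateCloneTree(4, 3, regime)
    clone <- sample(1:4, 60, replace = TRUE, prob = c(0.5, rep(0.5 / 3, 3)))
    present <- tr$ccf[clone, ] > 0
    keep <- rowSums(present) > 0
    mean(rowSums(present[keep, , drop = FALSE]) == 3)
  }
  sweep <- vapply(1:50, function(i) trunkFor("sweep"), numeric(1))
  div <- vapply(1:50, function(i) trunkFor("diversify"), numeric(1))
  expect_gt(mean(sweep), mean(div))
})
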