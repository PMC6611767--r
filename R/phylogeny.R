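#' Binary mutation-presence matrix for a set of lesions of one patient
#'
#' Rows are regions (plus an all-zero germline row labelled
#' \code{"NORMAL"}); columns are mutation keys. An entry is 1 when the
#' mutation passed the primary filters in that region, or — when
#' \code{rescue} is on — when forced calling finds relaxed-threshold
#' evidence there for a key that passed elsewhere in the same lesion.
#'
#' @param lesionList a \code{\linkS4class{Lesion}} or list of lesions
#'   (typically all lesions of one patient).
#' @param thresholds a \code{\linkS4class{FilterThresholds}}.
#' @param rescue apply within-lesion forced calling (default TRUE).
#' @return Integer matrix with named rows/columns; all-zero columns never
#'   occur (every key passed somewhere).
#' @export
presenceMatrix <- function(lesionList, thresholds = filterThresholds(),
                           rescue = TRUE) {
  if (is(lesionList, "Lesion")) lesionList <- list(lesionList)
  t <- thresholds
  rows <- list()
  for (les in lesionList) {
    regs <- regions(les)
    passed <- lapply(regs, function(r)
      unique(mutationKey(applyFilterCascade(r@calls, t))))
    lesionKeys <- unique(unlist(passed))
    for (i in seq_along(regs)) {
      r <- regs[[i]]
      present <- passed[[i]]
      if (rescue && length(lesionKeys)) {
        pileKeys <- mutationKey(r@calls)
        idx <- match(setdiff(lesionKeys, present), pileKeys)
        cand <- setdiff(lesionKeys, present)[!is.na(idx)]
        idx <- idx[!is.na(idx)]
        if (length(idx)) {
          rowi <- r@calls[idx, ]
          vaf <- ifelse(rowi$tumor_depth > 0,
                        rowi$tumor_alt / rowi$tumor_depth, 0)
          ok <- rowi$tumor_alt >= t@rescueAltReadsMin & vaf >= t@rescueVafMin
          present <- c(present, cand[ok])
        }
      }
      rows[[r@regionId]] <- present
    }
  }
  allKeys <- sort(unique(unlist(rows)))
  m <- matrix(0L, nrow = length(rows) + 1L, ncol = length(allKeys),
              dimnames = list(c(names(rows), "NORMAL"), allKeys))
  for (rn in names(rows)) m[rn, rows[[rn]]] <- 1L
  m
}

#' Pairwise Hamming distances between presence-matrix rows
#'
#' @param m binary matrix (regions + NORMAL as rows).
#' @return Symmetric integer distance matrix (number of differing
#'   columns).
#' @export
hammingDistances <- function(m) {
  stopifnot(nrow(m) >= 2)
  d <- as.matrix(stats::dist(m, method = "manhattan"))
  storage.mode(d) <- "integer"
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining; negative branch lengths are
#' clamped to zero with a warning. With exactly three taxa the unique
#' unrooted topology is returned.
#'
#' @param d symmetric distance matrix with row/column names.
#' @return An \code{ape} \code{phylo} tree.
#' @export
neighborJoining <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 tip.label = rownames(d), edge.length = c(d[1, 2] / 2,
                                                          d[1, 2] / 2),
                 Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  if (any(tree$edge.length < -1e-9))
    warning("negative NJ branch length(s) clamped to 0")
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

## Fitch parsimony on binary characters, vectorised over columns.
## Returns total score and per-edge change counts for the tree rooted at
## the NORMAL tip (state 0 at the root).
.fitchBinary <- function(tree, m) {
  if (!"NORMAL" %in% tree$tip.label) {
    rooted <- ape::root(tree, outgroup = tree$tip.label[1],
                        resolve.root = TRUE)
  } else {
    rooted <- ape::root(tree, outgroup = "NORMAL", resolve.root = TRUE)
  }
  edge <- rooted$edge
  nTip <- length(rooted$tip.label)
  nNode <- nTip + rooted$Nnode
  nChar <- ncol(m)
  ## state sets as two logical matrices: can0 / can1 per node x char
  can0 <- matrix(FALSE, nNode, nChar)
  can1 <- matrix(FALSE, nNode, nChar)
  tipStates <- m[rooted$tip.label, , drop = FALSE]
  can0[seq_len(nTip), ] <- tipStates == 0L
  can1[seq_len(nTip), ] <- tipStates == 1L
  score <- 0L
  ord <- rev(ape::postorder(rooted))  # edges; process children before parents
  ## bottom-up: iterate nodes in postorder
  children <- split(edge[, 2], edge[, 1])
  postNodes <- unique(edge[ape::postorder(rooted), 1])
  for (nd in postNodes) {
    kids <- children[[as.character(nd)]]
    i0 <- rep(TRUE, nChar); i1 <- rep(TRUE, nChar)
    u0 <- rep(FALSE, nChar); u1 <- rep(FALSE, nChar)
    for (k in kids) {
      i0 <- i0 & can0[k, ]; i1 <- i1 & can1[k, ]
      u0 <- u0 | can0[k, ]; u1 <- u1 | can1[k, ]
    }
    disjoint <- !(i0 | i1)
    ## pairwise Fitch: with >2 children count (children carrying minority
    ## state - 1) changes; binary trees after root resolution, so the
    ## standard union rule applies
    score <- score + sum(disjoint)
    can0[nd, ] <- ifelse(disjoint, u0, i0)
    can1[nd, ] <- ifelse(disjoint, u1, i1)
  }
  ## top-down assignment, root prefers state 0 (germline)
  state <- matrix(NA_integer_, nNode, nChar)
  rootNode <- setdiff(edge[, 1], edge[, 2])[1]
  state[rootNode, ] <- ifelse(can0[rootNode, ], 0L, 1L)
  for (e in rev(ape::postorder(rooted))) {
    par <- edge[e, 1]; child <- edge[e, 2]
    ps <- state[par, ]
    keep <- (ps == 0L & can0[child, ]) | (ps == 1L & can1[child, ])
    state[child, ] <- ifelse(keep, ps, 1L - ps)
  }
  edgeChanges <- vapply(seq_len(nrow(edge)), function(e)
    sum(state[edge[e, 1], ] != state[edge[e, 2], ]), integer(1))
  list(score = sum(edgeChanges), rooted = rooted,
       edge_changes = edgeChanges)
}

#' Wagner parsimony tree for a binary presence matrix
#'
#' Minimises the total number of character changes (binary characters
#' with free reversals; with germline rooting reversals are effectively
#' never optimal). \code{"exhaustive"} search enumerates every unrooted
#' topology (up to 8 leaves), breaking score ties by the
#' lexicographically smallest Newick string; \code{"nj_seeded_nni"} starts
#' from the neighbor-joining tree and improves it by
#' nearest-neighbour-interchange search. Branch lengths are the parsimony
#' changes assigned to each edge.
#'
#' @param m binary presence matrix including the NORMAL row.
#' @param search "exhaustive" or "nj_seeded_nni".
#' @return List with \code{tree} (rooted at NORMAL, branch lengths =
#'   assigned changes) and \code{score}.
#' @export
wagnerParsimony <- function(m, search = c("exhaustive", "nj_seeded_nni")) {
  search <- match.arg(search)
  labels <- rownames(m)
  stopifnot(length(labels) >= 3)
  if (search == "exhaustive") {
    if (length(labels) > 8)
      stop("exhaustive search supports at most 8 leaves; ",
           "use search = \"nj_seeded_nni\"")
    trees <- phangorn::allTrees(length(labels), rooted = FALSE,
                                tip.label = labels)
    scored <- lapply(trees, .fitchBinary, m = m)
    scores <- vapply(scored, function(s) s$score, integer(1))
    best <- which(scores == min(scores))
    if (length(best) > 1) {
      nwk <- vapply(best, function(i)
        ape::write.tree(scored[[i]]$rooted), character(1))
      best <- best[order(nwk)[1]]
    }
    fit <- scored[[best]]
  } else {
    start <- neighborJoining(hammingDistances(m))
    dat <- phangorn::phyDat(m, type = "USER", levels = c(0L, 1L))
    opt <- suppressMessages(
      phangorn::optim.parsimony(start, dat, method = "fitch", trace = 0))
    fit <- .fitchBinary(opt, m)
  }
  tree <- fit$rooted
  tree$edge.length <- as.numeric(fit$edge_changes)
  list(tree = tree, score = fit$score)
}

#' Trunk and branch mutation statistics
#'
#' Trunk mutations are present in every sampled region (germline row
#' excluded); their proportion among all columns is the early-event
#' fraction. Invariant to column permutation and region relabelling.
#'
#' @param m binary presence matrix including the NORMAL row.
#' @return List with evaluated, n_trunk, n_branch and trunk_proportion
#'   (\code{evaluated = FALSE} with fewer than two non-germline regions).
#' @export
trunkBranchStats <- function(m) {
  regs <- setdiff(rownames(m), "NORMAL")
  if (length(regs) < 2) return(list(evaluated = FALSE))
  sub <- m[regs, , drop = FALSE]
  nTrunk <- sum(colSums(sub) == length(regs))
  total <- ncol(sub)
  list(evaluated = TRUE, n_trunk = nTrunk, n_branch = total - nTrunk,
       trunk_proportion = if (total > 0) nTrunk / total else NA_real_)
}
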