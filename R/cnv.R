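#' Per-bin coverage log2 ratios
#'
#' \code{log2((tumor_i / T) / (normal_i / N))} after adjusting each sample
#' for its total mapped reads; a pseudocount keeps zero bins finite.
#'
#' @param bins data.frame with chrom, start, end, tumor_reads,
#'   normal_reads (1-based closed, non-overlapping).
#' @param pseudocount added to both counts of a bin when either is zero
#'   (default 0.5).
#' @return \code{bins} with an added \code{log2_ratio} column.
#' @export
log2Ratio <- function(bins, pseudocount = 0.5) {
  tTot <- sum(bins$tumor_reads)
  nTot <- sum(bins$normal_reads)
  if (nTot == 0) stop("all-zero normal coverage")
  if (tTot == 0) stop("all-zero tumor coverage")
  t <- bins$tumor_reads
  n <- bins$normal_reads
  zero <- t == 0 | n == 0
  t[zero] <- t[zero] + pseudocount
  n[zero] <- n[zero] + pseudocount
  bins$log2_ratio <- log2((t / tTot) / (n / nTot))
  bins
}

## max circular two-sample statistic over arcs (i, j] of x; returns the
## statistic and the maximising boundaries
.maxArcStat <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(list(stat = 0, i = 0L, j = n))
  cs <- c(0, cumsum(x))
  best <- 0; bi <- 0L; bj <- n
  for (i in 0:(n - 2L)) {
    j <- (i + 1L):n
    len <- j - i
    keep <- len < n
    j <- j[keep]; len <- len[keep]
    if (!length(j)) next
    m1 <- (cs[j + 1L] - cs[i + 1L]) / len
    m0 <- (cs[n + 1L] - cs[j + 1L] + cs[i + 1L]) / (n - len)
    stat <- abs(m1 - m0) / (s * sqrt(1 / len + 1 / (n - len)))
    k <- which.max(stat)
    if (stat[k] > best) { best <- stat[k]; bi <- i; bj <- j[k] }
  }
  list(stat = best, i = bi, j = bj)
}

.cbsOne <- function(x, alpha, minWidth, nPerm) {
  n <- length(x)
  if (n < 2 * minWidth) return(n)  # single segment: breakpoints after bin n
  obs <- .maxArcStat(x)
  if (obs$stat == 0) return(n)
  ## permutation p with early exit once p > alpha is certain
  exceed <- 0L
  limit <- floor(alpha * nPerm)
  for (b in seq_len(nPerm)) {
    if (.maxArcStat(sample(x))$stat >= obs$stat) {
      exceed <- exceed + 1L
      if (exceed > limit) return(n)
    }
  }
  cuts <- sort(unique(c(obs$i, obs$j)))
  cuts <- cuts[cuts > 0 & cuts < n]
  if (!length(cuts)) return(n)
  bounds <- c(0L, cuts, n)
  out <- integer(0)
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k] + 1L; hi <- bounds[k + 1L]
    out <- c(out, bounds[k] + .cbsOne(x[lo:hi], alpha, minWidth, nPerm))
  }
  sort(unique(out))
}

#' Circular binary segmentation of log2 ratios
#'
#' Recursive splitting at the maximal circular two-sample statistic;
#' a split is accepted when its permutation p-value falls below
#' \code{alpha}. Segments narrower than \code{minWidth} bins are merged
#' into the neighbour with the closer mean. The bin-weighted mean of the
#' segment means equals the global mean of the input by construction.
#'
#' @param bins data.frame with chrom, start, end, log2_ratio (bins ordered
#'   by position within chromosome; see \code{\link{log2Ratio}}).
#' @param alpha significance level for accepting a split (default 0.01).
#' @param minWidth minimum segment width in bins (default 3).
#' @param nPerm permutations per candidate split (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return data.frame of segments: chrom, start, end, n_bins, mean_log2.
#' @export
cbsSegment <- function(bins, alpha = 0.01, minWidth = 3, nPerm = 1000,
                       seed = 1L) {
  set.seed(seed)
  out <- list()
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    x <- b$log2_ratio
    ends <- .cbsOne(x, alpha, minWidth, nPerm)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    seg <- data.frame(chrom = ch, start = b$start[starts],
                      end = b$end[ends], n_bins = ends - starts + 1L,
                      mean_log2 = vapply(seq_along(ends), function(k)
                        mean(x[starts[k]:ends[k]]), numeric(1)),
                      stringsAsFactors = FALSE)
    ## merge undersized segments into the nearer-mean neighbour
    while (nrow(seg) > 1 && any(seg$n_bins < minWidth)) {
      k <- which.min(seg$n_bins)
      nb <- if (k == 1) 2L
            else if (k == nrow(seg)) k - 1L
            else if (abs(seg$mean_log2[k - 1] - seg$mean_log2[k]) <=
                     abs(seg$mean_log2[k + 1] - seg$mean_log2[k])) k - 1L
            else k + 1L
      lo <- min(k, nb); hi <- max(k, nb)
      nb2 <- seg$n_bins[lo] + seg$n_bins[hi]
      seg$mean_log2[lo] <- (seg$mean_log2[lo] * seg$n_bins[lo] +
                              seg$mean_log2[hi] * seg$n_bins[hi]) / nb2
      seg$n_bins[lo] <- nb2
      seg$end[lo] <- seg$end[hi]
      seg <- seg[-hi, , drop = FALSE]
    }
    out[[ch]] <- seg
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Gene-level copy-number calls
#'
#' Each gene gets the length-weighted mean log2 ratio of its overlapping
#' segments; gain when the mean strictly exceeds \code{gainThr}, loss when
#' strictly below \code{lossThr}. The default thresholds (+/-2) screen for
#' high-amplitude events in cancer genes; the 0.3 threshold used for
#' recurrence plots is a separate, explicit parameter of
#' \code{\link{stageFrequency}}.
#'
#' @param segments segment data.frame (chrom, start, end, mean_log2).
#' @param genes data.frame with gene, chrom, start, end (1-based closed).
#' @param gainThr,lossThr log2 thresholds.
#' @return data.frame with gene, mean_log2 and call in
#'   \{gain, loss, neutral\} (\code{NA} when no segment overlaps).
#' @export
callGeneCnv <- function(segments, genes, gainThr = 2, lossThr = -2) {
  res <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    s <- segments[segments$chrom == g$chrom & segments$start <= g$end &
                    segments$end >= g$start, , drop = FALSE]
    if (nrow(s) == 0)
      return(data.frame(gene = g$gene, mean_log2 = NA_real_,
                        call = NA_character_))
    w <- pmin(s$end, g$end) - pmax(s$start, g$start) + 1
    m <- sum(w * s$mean_log2) / sum(w)
    call <- if (m > gainThr) "gain" else if (m < lossThr) "loss" else "neutral"
    data.frame(gene = g$gene, mean_log2 = m, call = call)
  })
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Stage-wise frequency of copy-number gains and losses per bin
#'
#' For each stage and genome bin, the fraction of lesions whose mean log2
#' ratio at that bin exceeds \code{thr} (gain) or is at most \code{-thr}
#' (loss) — the recurrence summary underlying stage-comparison plots.
#'
#' @param profiles numeric matrix, lesions x bins, of per-bin mean log2
#'   ratios on a common grid (rownames = lesion ids).
#' @param stages character vector of stage labels, one per lesion row.
#' @param thr log2 threshold (default 0.3).
#' @return List of two matrices \code{gain} and \code{loss}
#'   (stage x bin fractions); stages with zero lesions are omitted.
#' @export
stageFrequency <- function(profiles, stages, thr = 0.3) {
  stopifnot(nrow(profiles) == length(stages))
  present <- intersect(ipnStages(), unique(stages))
  gain <- t(vapply(present, function(s)
    colMeans(profiles[stages == s, , drop = FALSE] > thr), numeric(ncol(profiles))))
  loss <- t(vapply(present, function(s)
    colMeans(profiles[stages == s, , drop = FALSE] <= -thr), numeric(ncol(profiles))))
  rownames(gain) <- rownames(loss) <- present
  list(gain = gain, loss = loss)
}

## Viterbi path of the two-state folded-BAF HMM; state 2 = imbalanced
.viterbiAi <- function(x, pSwitch, deviation, emissionSd) {
  n <- length(x)
  e <- cbind(stats::dnorm(x, 0, emissionSd, log = TRUE),
             stats::dnorm(x, deviation, emissionSd, log = TRUE))
  lStay <- log(1 - pSwitch); lSwitch <- log(pSwitch)
  v <- matrix(-Inf, n, 2)
  ptr <- matrix(1L, n, 2)
  v[1, ] <- log(0.5) + e[1, ]
  for (i in 2:n) {
    for (s in 1:2) {
      cand <- v[i - 1, ] + ifelse(1:2 == s, lStay, lSwitch)
      ptr[i, s] <- which.max(cand)
      v[i, s] <- max(cand) + e[i, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(v[n, ])
  for (i in (n - 1):1) path[i] <- ptr[i + 1, path[i + 1]]
  path
}

#' Detect allelic-imbalance events from heterozygous-site BAFs
#'
#' A two-state hidden Markov model over the folded B-allele frequency
#' \code{|BAF - 0.5|}: a balanced state centred at 0 and an imbalanced
#' state centred at \code{deviation}, Gaussian emissions, symmetric switch
#' probability. Maximal Viterbi runs of the imbalanced state spanning at
#' least \code{minRun} sites become events. This is an unphased
#' simplification of haplotype-based imbalance callers with the same event
#' semantics (contiguous runs of imbalanced heterozygous sites).
#'
#' @param hetBafSites data.frame with chrom, pos, baf (ordered by position
#'   within chromosome).
#' @param pSwitch state switch probability (default 0.001).
#' @param deviation imbalanced-state folded-BAF centre (default 0.1).
#' @param minRun minimum sites per event (default 10).
#' @param emissionSd Gaussian emission standard deviation (default 0.03,
#'   the typical folded-BAF noise scale at exome depth).
#' @return data.frame of events: chrom, start, end, n_het_sites,
#'   mean_baf_deviation.
#' @export
detectAi <- function(hetBafSites, pSwitch = 0.001, deviation = 0.1,
                     minRun = 10, emissionSd = 0.03) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_het_sites = integer(0),
                      mean_baf_deviation = numeric(0))
  if (nrow(hetBafSites) < minRun) return(empty)
  out <- list()
  for (ch in unique(hetBafSites$chrom)) {
    s <- hetBafSites[hetBafSites$chrom == ch, , drop = FALSE]
    s <- s[order(s$pos), , drop = FALSE]
    if (nrow(s) < 2) next
    x <- abs(s$baf - 0.5)
    path <- .viterbiAi(x, pSwitch, deviation, emissionSd)
    r <- rle(path == 2L)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= minRun
    for (k in which(keep)) {
      idx <- starts[k]:ends[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s$pos[starts[k]], end = s$pos[ends[k]],
        n_het_sites = length(idx), mean_baf_deviation = mean(x[idx]))
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Allelic-imbalance event counts for a lesion
#'
#' Events are called per region; the lesion-level count is the maximum
#' over its regions (per-region counts are also returned).
#'
#' @param lesion a \code{\linkS4class{Lesion}} whose regions carry
#'   \code{hetBafSites}.
#' @param ... passed to \code{\link{detectAi}}.
#' @return List with \code{per_region} (named integer vector) and
#'   \code{lesion} (max count).
#' @export
countAiEvents <- function(lesion, ...) {
  perRegion <- vapply(regions(lesion), function(r) {
    if (nrow(r@hetBafSites) == 0) return(0L)
    nrow(detectAi(r@hetBafSites, ...))
  }, integer(1))
  names(perRegion) <- vapply(regions(lesion), function(r) r@regionId,
                             character(1))
  list(per_region = perRegion,
       lesion = if (length(perRegion)) max(perRegion) else 0L)
}
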