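#' Mutant multiplicity from VAF, purity and copy number
#'
#' \code{m = round(vaf / purity * (purity * cnt + 2 * (1 - purity)))},
#' clipped to \[1, cnt\].
#'
#' @param vaf tumor variant allele frequency.
#' @param purity tumor purity in (0, 1].
#' @param cnt total tumor copy number at the locus (>= 1).
#' @return Integer multiplicity (vectorised).
#' @export
estimateMultiplicity <- function(vaf, purity, cnt = 2) {
  stopifnot(all(purity > 0), all(purity <= 1), all(cnt >= 1))
  m <- round(vaf / purity * (purity * cnt + 2 * (1 - purity)))
  as.integer(pmin(pmax(m, 1), cnt))
}

#' Cancer cell fraction with a 95% interval and clonality call
#'
#' Point estimate \code{ccf = vaf * (purity*cnt + 2*(1-purity)) /
#' (purity*m)}; the 95% interval is the Jeffreys
#' \code{Beta(alt + 0.5, depth - alt + 0.5)} interval on the VAF mapped
#' through the same linear transform (boundary-adjusted at alt = 0 and
#' alt = depth). A mutation is clonal when the interval overlaps 1 — the
#' same downstream rule as full posterior-sampling clonality callers, with
#' a closed-form interval in place of MCMC. CCFs above 1 are kept (they
#' flag multiplicity misestimation) but clipped at 1.5 for reporting.
#'
#' @param alt,depth tumor alt and total read counts (vectorised).
#' @param purity tumor purity in (0, 1].
#' @param cnt total copy number (default 2 when no segment overlaps).
#' @param m multiplicity; estimated from the VAF when \code{NULL}.
#' @return data.frame with ccf, ci_low, ci_high, multiplicity, clonal.
#' @export
computeCcf <- function(alt, depth, purity, cnt = 2, m = NULL) {
  stopifnot(all(depth > 0))
  if (any(purity <= 0)) stop("purity must be positive")
  vaf <- alt / depth
  if (is.null(m)) m <- estimateMultiplicity(vaf, purity, cnt)
  scale <- (purity * cnt + 2 * (1 - purity)) / (purity * m)
  ccf <- vaf * scale
  lowVaf <- ifelse(alt == 0, 0,
                   stats::qbeta(0.025, alt + 0.5, depth - alt + 0.5))
  highVaf <- ifelse(alt == depth, 1,
                    stats::qbeta(0.975, alt + 0.5, depth - alt + 0.5))
  data.frame(
    ccf = pmin(ccf, 1.5), ci_low = pmin(lowVaf * scale, 1.5),
    ci_high = pmin(highVaf * scale, 1.5), multiplicity = m,
    clonal = lowVaf * scale <= 1 & highVaf * scale >= 1
  )
}

#' Lesion-level clonality summary
#'
#' A mutation is lesion-clonal iff it is present in every region of the
#' lesion and its 95% CCF interval overlaps 1 in every region where it was
#' measured (the conservative multi-region conjunction). Lesions with
#' fewer than \code{minSnvs} mutations in the union are not evaluated.
#'
#' @param ccfTable data.frame with one row per mutation per region:
#'   columns key, region_id, ccf, ci_low, ci_high, clonal.
#' @param nRegions number of regions in the lesion.
#' @param minSnvs minimum union mutation count (default 10).
#' @param exomeMb burden denominator for clonal/subclonal burdens.
#' @return List with evaluated, n_clonal, n_subclonal, proportion_clonal,
#'   clonal_burden and subclonal_burden (per Mb), and the per-mutation
#'   label table.
#' @export
lesionClonality <- function(ccfTable, nRegions, minSnvs = 10, exomeMb = 36) {
  keys <- unique(ccfTable$key)
  if (length(keys) < minSnvs)
    return(list(evaluated = FALSE, n_mutations = length(keys)))
  perKey <- vapply(keys, function(k) {
    rows <- ccfTable[ccfTable$key == k, , drop = FALSE]
    length(unique(rows$region_id)) == nRegions && all(rows$clonal)
  }, logical(1))
  nClonal <- sum(perKey)
  nSub <- length(keys) - nClonal
  list(evaluated = TRUE, n_clonal = nClonal, n_subclonal = nSub,
       proportion_clonal = nClonal / length(keys),
       clonal_burden = nClonal / exomeMb, subclonal_burden = nSub / exomeMb,
       labels = data.frame(key = keys, clonal = unname(perKey),
                           stringsAsFactors = FALSE))
}

#' CCF table for a lesion
#'
#' Convenience wrapper: computes per-mutation, per-region CCF estimates
#' for (already filtered) calls of a lesion, defaulting to copy number 2
#' where no segment information is supplied.
#'
#' @param lesion a \code{\linkS4class{Lesion}}.
#' @param calls optional filtered call table (default: the lesion's calls
#'   through \code{\link{applyFilterCascade}}).
#' @param thresholds filter thresholds used when \code{calls} is NULL.
#' @return data.frame with key, region_id and the \code{\link{computeCcf}}
#'   columns.
#' @export
lesionCcfTable <- function(lesion, calls = NULL,
                           thresholds = filterThresholds()) {
  if (is.null(calls)) calls <- applyFilterCascade(variantCalls(lesion),
                                                  thresholds)
  if (nrow(calls) == 0)
    return(data.frame(key = character(0), region_id = character(0),
                      ccf = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0), multiplicity = integer(0),
                      clonal = logical(0)))
  pur <- purity(lesion)[calls$region_id]
  est <- computeCcf(calls$tumor_alt, calls$tumor_depth, pur)
  cbind(data.frame(key = mutationKey(calls), region_id = calls$region_id,
                   stringsAsFactors = FALSE), est)
}

#' Binomial-mixture clustering of mutation CCFs
#'
#' A simplified stand-in for Dirichlet-process clonal clustering: a
#' one-dimensional binomial mixture over alt/depth counts with cluster
#' CCF centres, fitted by EM for k = 1..kMax and selected by BIC.
#' Deterministic given the seed (quantile-spread initial centres plus a
#' seeded jitter).
#'
#' @param alt,depth integer vectors of tumor alt and depth per mutation.
#' @param purity tumor purity used to map CCF centres to expected VAF
#'   (cnt = 2, m = 1 mapping).
#' @param kMax maximum cluster count (default 6).
#' @param seed integer seed.
#' @return List with k, assignment (integer vector), means (cluster CCF
#'   centres) and bic per k.
#' @export
clusterCcf <- function(alt, depth, purity, kMax = 6, seed = 1L) {
  n <- length(alt)
  if (n < 10) stop("at least 10 mutations are required for clustering")
  set.seed(seed)
  toVaf <- function(ccf) purity * ccf / 2  # cnt = 2, m = 1
  obsCcf <- pmin((alt / depth) * 2 / purity, 1.5)
  fitK <- function(k) {
    centres <- stats::quantile(obsCcf, probs = (seq_len(k) - 0.5) / k,
                               names = FALSE) +
      stats::rnorm(k, 0, 0.01)
    centres <- pmin(pmax(centres, 0.01), 1.5)
    weights <- rep(1 / k, k)
    ll <- -Inf
    for (iter in 1:200) {
      dens <- vapply(seq_len(k), function(j)
        stats::dbinom(alt, depth, pmin(toVaf(centres[j]), 0.999)) *
          weights[j], numeric(n))
      dens <- matrix(dens, n, k)
      rowTot <- rowSums(dens)
      rowTot[rowTot == 0] <- .Machine$double.xmin
      resp <- dens / rowTot
      newLl <- sum(log(rowTot))
      weights <- colMeans(resp)
      centres <- vapply(seq_len(k), function(j) {
        num <- sum(resp[, j] * alt); den <- sum(resp[, j] * depth)
        if (den == 0) centres[j] else
          pmin(pmax((num / den) * 2 / purity, 1e-3), 1.5)
      }, numeric(1))
      if (newLl - ll < 1e-8) { ll <- newLl; break }
      ll <- newLl
    }
    nPar <- 2 * k - 1
    list(ll = ll, bic = -2 * ll + nPar * log(n), centres = centres,
         weights = weights)
  }
  if (length(unique(obsCcf)) == 1L) {
    return(list(k = 1L, assignment = rep(1L, n),
                means = unique(obsCcf), bic = NA_real_))
  }
  fits <- lapply(seq_len(kMax), fitK)
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  k <- which.min(bics)
  best <- fits[[k]]
  dens <- vapply(seq_len(k), function(j)
    stats::dbinom(alt, depth, pmin(toVaf(best$centres[j]), 0.999)) *
      best$weights[j], numeric(n))
  dens <- matrix(dens, n, k)
  list(k = k, assignment = max.col(dens), means = best$centres, bic = bics)
}
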