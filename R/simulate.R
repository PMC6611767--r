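#' Simulation configuration for a synthetic multi-region cohort
#'
#' Defaults encode the study conditions the package emulates: four ordered
#' histologic stages with progressively increasing mutation burden, mean
#' sequencing depth 150x, purity between 0.4 (the macrodissection floor) and
#' 0.8, low-VAF C>T FFPE artifact spikes, demarcated copy-number burden
#' (rare in AAH, prevalent later) and allelic-imbalance burden rising
#' steeply from AIS to MIA/ADC. The clonal architecture follows a selective
#' sweep in AIS/MIA/ADC (founder clone dominant) and a diversification
#' regime in AAH, so that the clonal-mutation proportion and trunk
#' proportion rise with stage.
#'
#' @param seed integer master seed; every random draw flows from it via
#'   per-lesion substreams.
#' @param lesionsPerStage named counts for AAH/AIS/MIA/ADC.
#' @param meanBurden named per-stage mean true mutation count per lesion.
#' @param exomeMb target territory in Mb (burden denominator).
#' @param regionsRange min/max regions per lesion.
#' @param cloneRange min/max clones per lesion.
#' @param depthMean,depthDispersion negative-binomial read depth model.
#' @param purityRange uniform purity range.
#' @param artifactRate expected FFPE artifact calls per region.
#' @param clonalFraction named per-stage probability that a mutation belongs
#'   to the founder clone.
#' @param regime named per-stage clone-tree regime, "sweep" or "diversify".
#' @param dominance founder dominance threshold for the sweep regime.
#' @param referenceSignatures 96 x K column-stochastic matrix used to draw
#'   trinucleotide contexts.
#' @param exposures named per-stage exposure vectors over the reference
#'   columns (each sums to 1).
#' @param cnvRate named per-stage expected copy-number segments per lesion.
#' @param aiRate named per-stage expected allelic-imbalance blocks per
#'   lesion.
#' @param genomeBins bins per chromosome of the synthetic 4-chromosome,
#'   1-Mb-binned genome map.
#' @param hetSitesPerRegion germline heterozygous sites with BAF per region.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulationConfig <- function(seed = 1L,
                             lesionsPerStage = c(AAH = 5, AIS = 5, MIA = 5, ADC = 5),
                             meanBurden = c(AAH = 40, AIS = 80, MIA = 140, ADC = 200),
                             exomeMb = 36,
                             regionsRange = c(2L, 3L),
                             cloneRange = c(2L, 5L),
                             depthMean = 150, depthDispersion = 10,
                             purityRange = c(0.4, 0.8),
                             artifactRate = 10,
                             clonalFraction = c(AAH = 0.30, AIS = 0.55,
                                                MIA = 0.60, ADC = 0.70),
                             regime = c(AAH = "diversify", AIS = "sweep",
                                        MIA = "sweep", ADC = "sweep"),
                             dominance = 0.9,
                             referenceSignatures = syntheticSignatures(5),
                             exposures = NULL,
                             cnvRate = c(AAH = 0.2, AIS = 1.5, MIA = 2.5, ADC = 3.5),
                             aiRate = c(AAH = 0.3, AIS = 1, MIA = 4, ADC = 6),
                             genomeBins = 50L,
                             hetSitesPerRegion = 600L) {
  k <- ncol(referenceSignatures)
  if (is.null(exposures)) {
    ## mild stage-specific tilt over the synthetic signatures
    base <- rep(1 / k, k)
    exposures <- lapply(seq_along(ipnStages()), function(i) {
      w <- base
      w[(i - 1) %% k + 1] <- w[(i - 1) %% k + 1] + 0.3
      w / sum(w)
    })
    names(exposures) <- ipnStages()
  }
  cfg <- list(seed = as.integer(seed), lesionsPerStage = lesionsPerStage,
              meanBurden = meanBurden, exomeMb = exomeMb,
              regionsRange = regionsRange, cloneRange = cloneRange,
              depthMean = depthMean, depthDispersion = depthDispersion,
              purityRange = purityRange, artifactRate = artifactRate,
              clonalFraction = clonalFraction, regime = regime,
              dominance = dominance,
              referenceSignatures = referenceSignatures,
              exposures = exposures, cnvRate = cnvRate, aiRate = aiRate,
              genomeBins = as.integer(genomeBins),
              hetSitesPerRegion = as.integer(hetSitesPerRegion))
  stopifnot(all(unlist(cfg$lesionsPerStage) >= 0),
            all(cfg$meanBurden >= 0), all(cfg$artifactRate >= 0),
            all(cfg$purityRange > 0), all(cfg$purityRange <= 1),
            all(cfg$clonalFraction >= 0), all(cfg$clonalFraction <= 1),
            all(cfg$regime %in% c("sweep", "diversify")),
            cfg$dominance > 0, cfg$dominance <= 1,
            all(abs(vapply(cfg$exposures, sum, numeric(1)) - 1) < 1e-8))
  class(cfg) <- "simulation_config"
  cfg
}

.chromNames <- function() paste0("chr", 1:4)
.binSizeBp <- 1e6

## double arithmetic avoids 32-bit overflow for large master seeds
.lesionSeed <- function(seed, i)
  as.integer((as.numeric(seed) * 10007 + i * 131) %% 2147483647)

## negative-binomial depth, floored at 1 read
.rdepth <- function(n, mean, disp) pmax(1L, stats::rnbinom(n, mu = mean, size = disp))

#' Simulate a clone tree with per-region cancer cell fractions
#'
#' The tree is rooted at the founder clone (CCF 1 in every region). Under
#' the \code{"sweep"} regime the founder's exclusive cell fraction is at
#' least \code{dominance} in every region (subclones are kept small: a
#' selective sweep has purged competing lineages). Under \code{"diversify"}
#' each subclone has a home region where it reaches a substantial fraction,
#' with a small probability of spilling into other regions, producing
#' region-private subclones.
#'
#' @param nClones number of clones (>= 1), clone 1 is the founder.
#' @param nRegions number of regions (>= 1).
#' @param regime "sweep" or "diversify".
#' @param dominance founder dominance floor for the sweep regime.
#' @return List with \code{parent} (integer vector, 0 for the root),
#'   \code{ccf} (nClones x nRegions matrix of lineage CCFs) and
#'   \code{occupancy} (exclusive per-clone cell fractions, columns sum to
#'   at most 1).
#' @export
simulateCloneTree <- function(nClones, nRegions, regime = c("sweep", "diversify"),
                              dominance = 0.9) {
  regime <- match.arg(regime)
  stopifnot(nClones >= 1, nRegions >= 1)
  parent <- integer(nClones)
  if (nClones > 1)
    for (j in 2:nClones) parent[j] <- sample.int(j - 1L, 1L)
  for (try in 1:50) {
    ccf <- matrix(0, nClones, nRegions)
    ccf[1, ] <- 1
    if (nClones > 1) {
      home <- sample.int(nRegions, nClones - 1L, replace = TRUE)
      for (j in 2:nClones) {
        for (r in seq_len(nRegions)) {
          if (regime == "sweep") {
            ccf[j, r] <- stats::runif(1, 0, 1) * min(ccf[parent[j], r],
                                                     1 - dominance)
          } else {
            if (r == home[j - 1L]) {
              ccf[j, r] <- stats::runif(1, 0.3, 0.8)
            } else if (stats::runif(1) < 0.25) {
              ccf[j, r] <- stats::runif(1, 0, 0.3)
            }
            ccf[j, r] <- min(ccf[j, r], ccf[parent[j], r])
          }
        }
      }
      ## siblings of one parent must fit inside the parent lineage; under a
      ## sweep the root's children must additionally leave the founder with
      ## an exclusive fraction of at least `dominance`
      for (r in seq_len(nRegions)) {
        for (p in unique(parent[parent > 0])) {
          kids <- which(parent == p)
          budget <- if (p == 1 && regime == "sweep")
            ccf[p, r] - dominance else ccf[p, r]
          s <- sum(ccf[kids, r])
          if (s > budget && s > 0) ccf[kids, r] <- ccf[kids, r] * budget / s
        }
      }
    }
    occ <- ccf
    if (nClones > 1)
      for (p in unique(parent[parent > 0]))
        occ[p, ] <- occ[p, ] - colSums(ccf[which(parent == p), , drop = FALSE])
    if (regime == "sweep" || nClones == 1) break
    ## diversify must show at least two clones at >= 0.2 somewhere
    if (any(colSums(occ >= 0.2) >= 2)) break
  }
  list(parent = parent, ccf = ccf, occupancy = occ)
}

#' Draw tumor read counts for one mutation in one region
#'
#' The generative inverse of the CCF model: the expected VAF is
#' \code{purity * multiplicity * ccf / (purity * copyNumber + 2 * (1 - purity))}
#' and the alt count is binomial at a negative-binomial depth.
#'
#' @param trueCcf cancer cell fraction in \[0, 1\].
#' @param purity tumor purity in (0, 1].
#' @param copyNumber total tumor copy number at the locus.
#' @param multiplicity mutated copies (1..copyNumber).
#' @param depthMean,depthDispersion depth model parameters.
#' @param n number of independent draws.
#' @return data.frame with tumor_alt and tumor_depth.
#' @export
simulateReadCounts <- function(trueCcf, purity, copyNumber = 2,
                               multiplicity = 1, depthMean = 150,
                               depthDispersion = 10, n = 1) {
  stopifnot(trueCcf >= 0, trueCcf <= 1, purity > 0, purity <= 1)
  expVaf <- purity * multiplicity * trueCcf /
    (purity * copyNumber + 2 * (1 - purity))
  if (expVaf > 1 + 1e-12)
    stop("expected VAF exceeds 1: inconsistent multiplicity/copy number")
  depth <- .rdepth(n, depthMean, depthDispersion)
  alt <- stats::rbinom(n, depth, min(expVaf, 1))
  data.frame(tumor_alt = alt, tumor_depth = depth)
}

#' Draw trinucleotide channels from a signature mixture
#'
#' @param exposures non-negative weights over the matrix columns, summing
#'   to 1.
#' @param n number of mutations.
#' @param signatureMatrix 96 x K column-stochastic matrix.
#' @return Character vector of n channel names.
#' @export
simulateSignatureMutations <- function(exposures, n, signatureMatrix) {
  stopifnot(length(exposures) == ncol(signatureMatrix), all(exposures >= 0),
            abs(sum(exposures) - 1) < 1e-6, nrow(signatureMatrix) == 96L)
  if (n == 0) return(character(0))
  p <- as.numeric(signatureMatrix %*% exposures)
  sample(trinucleotideChannels(), n, replace = TRUE, prob = p)
}

## 41-nt context whose centre trinucleotide realises `channel`, on a random
## strand; returns ref, alt and context
.contextFromChannel <- function(channels) {
  n <- length(channels)
  f5 <- substr(channels, 1, 1)
  ref <- substr(channels, 3, 3)
  alt <- substr(channels, 5, 5)
  f3 <- substr(channels, 7, 7)
  flip <- stats::runif(n) < 0.5
  tri <- paste0(f5, ref, f3)
  tri[flip] <- reverseComplement(tri[flip])
  ref[flip] <- .complement(ref[flip])
  alt[flip] <- .complement(alt[flip])
  rand <- function(k) vapply(seq_len(k), function(i)
    paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE), collapse = ""),
    character(1))
  ctx <- paste0(rand(n), tri, rand(n))
  data.frame(ref = ref, alt = alt, context41 = ctx, stringsAsFactors = FALSE)
}

.callerNames <- c("mutect", "somaticsniper", "freebayes", "vardict", "muse")

#' Inject FFPE artifact calls into a region
#'
#' Artifacts are non-recurrent C>T or G>A calls with VAF below 0.10 (Beta
#' shaped, mode near 0.03), LOD below 10 and a single supporting caller —
#' the signature of formalin-induced cytosine deamination.
#'
#' @param region a \code{\linkS4class{Region}}.
#' @param rate expected number of artifact calls (Poisson).
#' @param depthMean,depthDispersion depth model.
#' @param lesionInfo named list with patient_id/lesion_id used for the
#'   appended rows (defaults taken from existing calls when present).
#' @return List with the modified region and a data.frame of the injected
#'   truth records (key, artifact = TRUE).
#' @export
injectFfpeArtifacts <- function(region, rate, depthMean = 150,
                                depthDispersion = 10, lesionInfo = NULL) {
  stopifnot(rate >= 0)
  n <- stats::rpois(1, rate)
  if (n == 0)
    return(list(region = region, truth = data.frame(key = character(0),
                                                    artifact = logical(0))))
  calls <- region@calls
  pid <- if (!is.null(lesionInfo)) lesionInfo$patient_id
         else if (nrow(calls)) calls$patient_id[1] else "P?"
  lid <- if (!is.null(lesionInfo)) lesionInfo$lesion_id
         else if (nrow(calls)) calls$lesion_id[1] else "L?"
  isCT <- stats::runif(n) < 0.5
  ref <- ifelse(isCT, "C", "G")
  alt <- ifelse(isCT, "T", "A")
  rand19 <- function() vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE), collapse = ""),
    character(1))
  ctx <- paste0(rand19(), sample(c("A", "C", "G", "T"), n, TRUE), ref,
                sample(c("A", "C", "G", "T"), n, TRUE))
  ## 19 left flank + centre trinucleotide + 19 right flank = 41 nt
  ctx <- paste0(ctx, vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 19, replace = TRUE), collapse = ""),
    character(1)))
  vaf <- 0.10 * stats::rbeta(n, 1.5, 3.5)
  depth <- .rdepth(n, depthMean, depthDispersion)
  altReads <- pmax(1L, stats::rbinom(n, depth, vaf))
  ndepth <- .rdepth(n, depthMean, depthDispersion)
  pos <- sample.int(length(.chromNames()) * 50L * .binSizeBp, n)
  chromIdx <- (pos - 1) %/% (50L * .binSizeBp)
  new <- data.frame(
    patient_id = pid, lesion_id = lid, region_id = region@regionId,
    chrom = .chromNames()[chromIdx + 1],
    pos = as.integer(pos - chromIdx * 50L * .binSizeBp),
    ref = ref, alt = alt, variant_class = "SNV",
    tumor_alt = pmin(altReads, depth), tumor_depth = depth,
    normal_alt = 0L, normal_depth = ndepth,
    vaf_tumor = pmin(altReads, depth) / depth, vaf_normal = 0,
    lod = stats::runif(n, 2, 10),
    callers = sample(.callerNames, n, replace = TRUE),
    context41 = ctx, gene = NA_character_, effect = NA_character_,
    stringsAsFactors = FALSE
  )
  merged <- if (nrow(calls)) rbind(calls[names(new)], new) else new
  region@calls <- merged
  list(region = region,
       truth = data.frame(key = mutationKey(new), artifact = TRUE,
                          stringsAsFactors = FALSE))
}

## simulate one lesion; returns list(lesion, truth)
.simulateLesion <- function(lid, pid, stg, smoker, cfg) {
  nRegions <- sample(seq(cfg$regionsRange[1], cfg$regionsRange[2]), 1)
  nClones <- sample(seq(cfg$cloneRange[1], cfg$cloneRange[2]), 1)
  tree <- simulateCloneTree(nClones, nRegions, cfg$regime[[stg]],
                            cfg$dominance)
  nMut <- stats::rpois(1, cfg$meanBurden[[stg]])
  clone <- rep(1L, nMut)
  if (nClones > 1 && nMut > 0) {
    sub <- stats::runif(nMut) >= cfg$clonalFraction[[stg]]
    clone[sub] <- sample(2:nClones, sum(sub), replace = TRUE)
  }
  chans <- simulateSignatureMutations(cfg$exposures[[stg]], nMut,
                                      cfg$referenceSignatures)
  ctx <- .contextFromChannel(chans)
  nChrom <- length(.chromNames())
  gpos <- sample.int(nChrom * cfg$genomeBins * .binSizeBp, nMut)
  chromIdx <- (gpos - 1) %/% (cfg$genomeBins * .binSizeBp)
  chrom <- .chromNames()[chromIdx + 1]
  pos <- as.integer(gpos - chromIdx * cfg$genomeBins * .binSizeBp)
  gene <- paste0("G", sample.int(500, nMut, replace = TRUE))
  effect <- sample(c("nonsynonymous", "other", "truncating", "frameshift"),
                   nMut, replace = TRUE, prob = c(0.5, 0.4, 0.05, 0.05))
  key <- paste(chrom, pos, ctx$ref, ctx$alt, sep = ":")

  ## copy-number truth segments
  nCnv <- stats::rpois(1, cfg$cnvRate[[stg]])
  cnvSeg <- data.frame(chrom = character(0), startBin = integer(0),
                       endBin = integer(0), log2 = numeric(0))
  if (nCnv > 0) {
    for (i in seq_len(nCnv)) {
      ch <- sample(.chromNames(), 1)
      len <- sample(5:15, 1)
      st <- sample.int(cfg$genomeBins - len + 1L, 1)
      mag <- if (stats::runif(1) < 0.1) stats::runif(1, 2.2, 3)
             else stats::runif(1, 0.4, 1.2)
      cnvSeg <- rbind(cnvSeg, data.frame(
        chrom = ch, startBin = st, endBin = st + len - 1L,
        log2 = mag * sample(c(-1, 1), 1)))
    }
  }
  ## allelic-imbalance truth blocks (site indices per chromosome stream)
  nAi <- stats::rpois(1, cfg$aiRate[[stg]])

  regionsList <- vector("list", nRegions)
  truthArtifacts <- data.frame(key = character(0), artifact = logical(0))
  for (r in seq_len(nRegions)) {
    pur <- stats::runif(1, cfg$purityRange[1], cfg$purityRange[2])
    ccf <- tree$ccf[clone, r]
    expVaf <- pur * 1 * ccf / (pur * 2 + 2 * (1 - pur))
    depth <- .rdepth(nMut, cfg$depthMean, cfg$depthDispersion)
    alt <- stats::rbinom(nMut, depth, pmin(expVaf, 1))
    ndepth <- .rdepth(nMut, cfg$depthMean, cfg$depthDispersion)
    lod <- ifelse(alt > 0, pmax(0, 2.0 * alt + stats::rnorm(nMut)), 0)
    nCallers <- pmin(5L, 2L + stats::rbinom(nMut, 3, 0.5))
    callers <- vapply(nCallers, function(k)
      paste(c("mutect", sample(setdiff(.callerNames, "mutect"), k - 1L)),
            collapse = ","), character(1))
    calls <- data.frame(
      patient_id = pid, lesion_id = lid, region_id = paste0(lid, "_R", r),
      chrom = chrom, pos = pos, ref = ctx$ref, alt = ctx$alt,
      variant_class = "SNV", tumor_alt = alt, tumor_depth = depth,
      normal_alt = 0L, normal_depth = ndepth,
      vaf_tumor = ifelse(depth > 0, alt / depth, 0), vaf_normal = 0,
      lod = lod, callers = callers, context41 = ctx$context41,
      gene = gene, effect = effect, stringsAsFactors = FALSE
    )
    ## coverage bins with the shared CNV profile, depth-scaled
    bins <- expand.grid(bin = seq_len(cfg$genomeBins),
                        chrom = .chromNames(), stringsAsFactors = FALSE)
    logr <- numeric(nrow(bins))
    if (nrow(cnvSeg) > 0)
      for (i in seq_len(nrow(cnvSeg)))
        logr[bins$chrom == cnvSeg$chrom[i] & bins$bin >= cnvSeg$startBin[i] &
               bins$bin <= cnvSeg$endBin[i]] <- cnvSeg$log2[i]
    normalReads <- stats::rnbinom(nrow(bins), mu = 1000, size = 100)
    tumorReads <- stats::rnbinom(nrow(bins), mu = 1000 * 2^logr, size = 100)
    cov <- data.frame(chrom = bins$chrom,
                      start = (bins$bin - 1L) * .binSizeBp + 1,
                      end = bins$bin * .binSizeBp,
                      tumor_reads = tumorReads, normal_reads = normalReads)
    ## heterozygous-site BAFs with shared AI blocks
    nSites <- cfg$hetSitesPerRegion
    siteChromIdx <- sort(sample.int(nChrom, nSites, replace = TRUE))
    sitePos <- integer(nSites)
    for (ci in seq_len(nChrom)) {
      idx <- which(siteChromIdx == ci)
      sitePos[idx] <- sort(sample.int(cfg$genomeBins * .binSizeBp,
                                      length(idx)))
    }
    baf <- 0.5 + stats::rnorm(nSites, 0, 0.03)
    aiBlocks <- data.frame(startIdx = integer(0), endIdx = integer(0))
    if (nAi > 0) {
      for (i in seq_len(nAi)) {
        len <- sample(25:50, 1)
        st <- sample.int(max(1L, nSites - len), 1)
        idx <- st:(st + len - 1L)
        baf[idx] <- 0.5 + sample(c(-1, 1), len, replace = TRUE) *
          (0.15 + stats::rnorm(len, 0, 0.02))
        aiBlocks <- rbind(aiBlocks,
                          data.frame(startIdx = st, endIdx = st + len - 1L))
      }
    }
    baf <- pmin(pmax(baf, 0), 1)
    het <- data.frame(chrom = .chromNames()[siteChromIdx], pos = sitePos,
                      baf = baf)
    reg <- newRegion(paste0(lid, "_R", r), pur, calls, cov, het)
    inj <- injectFfpeArtifacts(reg, cfg$artifactRate, cfg$depthMean,
                               cfg$depthDispersion,
                               list(patient_id = pid, lesion_id = lid))
    regionsList[[r]] <- inj$region
    if (nrow(inj$truth)) {
      inj$truth$region_id <- paste0(lid, "_R", r)
      truthArtifacts <- rbind(truthArtifacts, inj$truth)
    }
  }
  lesion <- newLesion(lid, pid, stg, regionsList, smoker)
  truth <- list(
    parent = tree$parent, ccf = tree$ccf, occupancy = tree$occupancy,
    regime = cfg$regime[[stg]],
    mutations = data.frame(key = key, clone = clone, artifact = FALSE,
                           stringsAsFactors = FALSE),
    artifacts = truthArtifacts, cnvSegments = cnvSeg, nAiBlocks = nAi,
    exposures = cfg$exposures[[stg]], nMutations = nMut
  )
  list(lesion = lesion, truth = truth)
}

#' Simulate a synthetic multi-region cohort with ground truth
#'
#' Deterministic given the configuration seed: each lesion draws from its
#' own seeded substream, so cohorts are reproducible and individual lesions
#' are stable under changes to the others.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return An \code{\linkS4class{IpnCohort}} whose \code{truth} slot holds
#'   one ground-truth record per lesion.
#' @export
#' @examples
#' cohort <- simulateCohort(simulationConfig(seed = 1,
#'   lesionsPerStage = c(AAH = 1, AIS = 1, MIA = 1, ADC = 1)))
#' cohort
simulateCohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  counts <- config$lesionsPerStage
  total <- sum(unlist(counts))
  if (total == 0) {
    warning("zero lesions requested; returning empty cohort")
    return(newIpnCohort(list(), list(), unclass(config)))
  }
  lesionsList <- list()
  truthList <- list()
  idx <- 0L
  for (stg in ipnStages()) {
    nStg <- if (stg %in% names(counts)) counts[[stg]] else 0
    for (i in seq_len(nStg)) {
      idx <- idx + 1L
      set.seed(.lesionSeed(config$seed, idx))
      lid <- sprintf("%s_%02d", stg, i)
      pid <- sprintf("P%03d", idx)
      smoker <- stats::runif(1) < 0.5
      sim <- .simulateLesion(lid, pid, stg, smoker, config)
      lesionsList[[lid]] <- sim$lesion
      truthList[[lid]] <- sim$truth
    }
  }
  newIpnCohort(lesionsList, truthList, unclass(config))
}
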