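#' Per-call SNV filter
#'
#' A somatic SNV passes when tumor VAF >= 0.05, normal VAF <= 0.01, tumor
#' depth >= 20x, normal depth >= 10x and mutation LOD strictly > 10 (the
#' raised LOD floor targets FFPE deamination artifacts, which cluster at
#' low LOD). Every violated rule is reported.
#'
#' @param calls variant-call data.frame of SNVs (vectorised).
#' @param thresholds a \code{\linkS4class{FilterThresholds}}.
#' @return data.frame with logical \code{pass} and a semicolon-joined
#'   \code{reasons} string per call (empty when passing).
#' @export
filterSnv <- function(calls, thresholds = filterThresholds()) {
  stopifnot(all(calls$variant_class == "SNV"))
  t <- thresholds
  n <- nrow(calls)
  vafT <- ifelse(calls$tumor_depth > 0, calls$tumor_alt / calls$tumor_depth, 0)
  vafN <- ifelse(calls$normal_depth > 0,
                 calls$normal_alt / calls$normal_depth, 0)
  rules <- cbind(
    vaf_tumor = vafT < t@snvVafTumorMin,
    vaf_normal = vafN > t@snvVafNormalMax,
    depth_tumor = calls$tumor_depth < t@snvDepthTumorMin,
    depth_normal = calls$normal_depth < t@snvDepthNormalMin,
    lod = !(calls$lod > t@lodMin)
  )
  .verdict(rules, n)
}

#' Per-call indel filter
#'
#' An indel passes when tumor depth > 15, normal depth > 6, at least 4
#' reads support the indel, tumor VAF >= 0.05 and normal VAF <= 0.01.
#'
#' @inheritParams filterSnv
#' @return As \code{\link{filterSnv}}.
#' @export
filterIndel <- function(calls, thresholds = filterThresholds()) {
  stopifnot(all(calls$variant_class == "INDEL"))
  t <- thresholds
  vafT <- ifelse(calls$tumor_depth > 0, calls$tumor_alt / calls$tumor_depth, 0)
  vafN <- ifelse(calls$normal_depth > 0,
                 calls$normal_alt / calls$normal_depth, 0)
  rules <- cbind(
    indel_tumor_reads = calls$tumor_depth < t@indelTumorReadsMin,
    indel_normal_reads = calls$normal_depth < t@indelNormalReadsMin,
    indel_alt_reads = calls$tumor_alt < t@indelAltReadsMin,
    vaf_tumor = vafT < t@snvVafTumorMin,
    vaf_normal = vafN > t@snvVafNormalMax
  )
  .verdict(rules, nrow(calls))
}

.verdict <- function(rules, n) {
  if (n == 0)
    return(data.frame(pass = logical(0), reasons = character(0)))
  reasons <- apply(rules, 1, function(x)
    paste(colnames(rules)[x], collapse = ";"))
  data.frame(pass = !apply(rules, 1, any), reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Multi-caller consensus filter
#'
#' Keeps mutation keys detected by at least \code{minCallers} independent
#' somatic callers.
#'
#' @param callsByCaller named list mapping caller name to a character
#'   vector of mutation keys.
#' @param minCallers concordance threshold (default 2).
#' @return Character vector of keys present in >= minCallers sets.
#' @export
consensusFilter <- function(callsByCaller, minCallers = 2) {
  stopifnot(length(callsByCaller) >= 1)
  tab <- table(unlist(lapply(callsByCaller, unique)))
  names(tab)[tab >= minCallers]
}

#' Apply the full somatic filter cascade to a call table
#'
#' SNVs run through the per-call SNV rules plus the >= 2-caller consensus
#' (the \code{callers} column, comma-separated); indels run through the
#' indel rules alone. Idempotent: filtering a filtered table changes
#' nothing.
#'
#' @param calls variant-call data.frame.
#' @param thresholds a \code{\linkS4class{FilterThresholds}}.
#' @return The subset of \code{calls} that passes.
#' @export
applyFilterCascade <- function(calls, thresholds = filterThresholds()) {
  if (nrow(calls) == 0) return(calls)
  pass <- logical(nrow(calls))
  snv <- calls$variant_class == "SNV"
  if (any(snv)) {
    v <- filterSnv(calls[snv, , drop = FALSE], thresholds)
    nCall <- vapply(strsplit(calls$callers[snv], ","),
                    function(x) length(unique(x)), integer(1))
    pass[snv] <- v$pass & nCall >= thresholds@minCallers
  }
  if (any(!snv)) {
    v <- filterIndel(calls[!snv, , drop = FALSE], thresholds)
    pass[!snv] <- v$pass
  }
  calls[pass, , drop = FALSE]
}

#' Forced calling of shared loci across regions of one lesion
#'
#' For a mutation key that passed the primary filters in at least one
#' region, every other region is re-examined at relaxed evidence
#' thresholds (VAF >= 0.01 and >= 2 supporting reads): multi-region lesions
#' share their mutation loci, so sub-threshold signal at a locus already
#' validated elsewhere in the same lesion is rescued rather than discarded.
#'
#' @param lesion a \code{\linkS4class{Lesion}}; every region's call table
#'   acts as its pileup (rows with low or zero alt counts included).
#' @param key mutation key "chrom:pos:ref:alt".
#' @param thresholds a \code{\linkS4class{FilterThresholds}}.
#' @return Named logical vector over region ids: presence after rescue.
#' @export
forcedCall <- function(lesion, key, thresholds = filterThresholds()) {
  t <- thresholds
  regs <- regions(lesion)
  passedSomewhere <- any(vapply(regs, function(r) {
    f <- applyFilterCascade(r@calls, t)
    key %in% mutationKey(f)
  }, logical(1)))
  if (!passedSomewhere)
    stop("key ", key, " did not pass primary filters in any region")
  out <- vapply(regs, function(r) {
    i <- match(key, mutationKey(r@calls))
    if (is.na(i)) return(FALSE)  # locus absent from this region's pileup
    row <- r@calls[i, ]
    vaf <- if (row$tumor_depth > 0) row$tumor_alt / row$tumor_depth else 0
    row$tumor_alt >= t@rescueAltReadsMin && vaf >= t@rescueVafMin
  }, logical(1))
  names(out) <- vapply(regs, function(r) r@regionId, character(1))
  out
}

.isTransition <- function(calls) {
  (calls$ref == "C" & calls$alt == "T") | (calls$ref == "G" & calls$alt == "A")
}

#' C>T/G>A transition fractions by VAF stratum
#'
#' FFPE artifacts concentrate in the low-VAF stratum, so an excess of
#' transitions below the split is the per-sample artifact signal.
#'
#' @param calls SNV call data.frame.
#' @param vafSplit VAF boundary between strata (default 0.10; calls with
#'   VAF < split fall in the lower stratum).
#' @return List with \code{below}, \code{above} and \code{overall}
#'   transition fractions (\code{NA} for empty strata) plus stratum sizes.
#' @export
transitionFraction <- function(calls, vafSplit = 0.10) {
  stopifnot(all(calls$variant_class == "SNV"))
  if (nrow(calls) == 0)
    return(list(below = NA_real_, above = NA_real_, overall = NA_real_,
                n_below = 0L, n_above = 0L))
  vaf <- ifelse(calls$tumor_depth > 0, calls$tumor_alt / calls$tumor_depth, 0)
  tr <- .isTransition(calls)
  lo <- vaf < vafSplit
  frac <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  list(below = frac(tr[lo]), above = frac(tr[!lo]), overall = mean(tr),
       n_below = sum(lo), n_above = sum(!lo))
}

#' Flag a sample as artifact-dominated
#'
#' A sample is flagged when its overall C>T/G>A fraction strictly exceeds
#' the cutoff (default 0.5625, the top-5% boundary of a reference frozen
#' lung adenocarcinoma cohort).
#'
#' @param fracOverall overall transition fraction in \[0, 1\].
#' @param cutoff flag threshold.
#' @return Logical.
#' @export
flagArtifactSample <- function(fracOverall, cutoff = 0.5625) {
  stopifnot(is.na(fracOverall) || (fracOverall >= 0 && fracOverall <= 1))
  !is.na(fracOverall) & fracOverall > cutoff
}

#' Mutation burden of a lesion
#'
#' Counts the union of passing mutations over all regions. Conservative
#' variants: \code{drop_private_subclonal} removes mutations seen in
#' exactly one region and labelled subclonal there;
#' \code{drop_transitions} removes all C>T/G>A calls. Both modes can only
#' lower the burden.
#'
#' @param lesion a \code{\linkS4class{Lesion}} (call tables are assumed
#'   already filtered).
#' @param mode one of "all", "drop_private_subclonal", "drop_transitions".
#' @param exomeMb burden denominator in Mb (default 36).
#' @param clonality optional data.frame with key, region_id and a logical
#'   \code{clonal} column (required for drop_private_subclonal).
#' @return List with \code{count} and \code{per_mb}.
#' @export
mutationBurden <- function(lesion, mode = c("all", "drop_private_subclonal",
                                            "drop_transitions"),
                           exomeMb = 36, clonality = NULL) {
  mode <- match.arg(mode)
  calls <- variantCalls(lesion)
  if (nrow(calls) == 0) return(list(count = 0L, per_mb = 0))
  calls$key <- mutationKey(calls)
  keep <- unique(calls$key)
  if (mode == "drop_transitions") {
    keep <- setdiff(keep, unique(calls$key[.isTransition(calls)]))
  } else if (mode == "drop_private_subclonal") {
    if (is.null(clonality))
      stop("clonality labels are required for drop_private_subclonal")
    nRegions <- tapply(calls$region_id, calls$key,
                       function(x) length(unique(x)))
    private <- names(nRegions)[nRegions == 1]
    sub <- unique(clonality$key[!clonality$clonal])
    keep <- setdiff(keep, intersect(private, sub))
  }
  list(count = length(keep), per_mb = length(keep) / exomeMb)
}

#' Report driver events in known cancer genes
#'
#' A call is reportable when (i) it is nonsynonymous in a known cancer gene
#' and matches a previously reported hotspot variant, or (ii) it is a
#' frameshift or truncating event in a tumor suppressor gene.
#'
#' @param calls variant-call data.frame with \code{gene}, \code{effect} and
#'   optionally \code{protein_change} columns.
#' @param cancerGenes data.frame with columns gene, role ("oncogene" or
#'   "TSG") and \code{hotspots} (comma-separated known protein changes,
#'   may be empty).
#' @return The reportable subset of \code{calls} with a \code{rule} column
#'   ("hotspot" or "tsg_truncating").
#' @export
annotateCancerGenes <- function(calls, cancerGenes) {
  if (nrow(calls) == 0) {
    calls$rule <- character(0)
    return(calls)
  }
  hasGene <- !is.na(calls$gene) & nzchar(calls$gene)
  idx <- match(calls$gene, cancerGenes$gene)
  known <- hasGene & !is.na(idx)
  pc <- if ("protein_change" %in% names(calls)) calls$protein_change
        else rep(NA_character_, nrow(calls))
  hotspotLists <- strsplit(cancerGenes$hotspots, ",")
  isHotspot <- known & calls$effect %in% "nonsynonymous" &
    mapply(function(p, i) !is.na(p) && p %in% hotspotLists[[i]],
           pc, ifelse(is.na(idx), 1L, idx))
  isTsgTrunc <- known & cancerGenes$role[idx] %in% "TSG" &
    calls$effect %in% c("frameshift", "truncating")
  out <- calls[isHotspot | isTsgTrunc, , drop = FALSE]
  out$rule <- ifelse(isHotspot[isHotspot | isTsgTrunc],
                     "hotspot", "tsg_truncating")
  out
}
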