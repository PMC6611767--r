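#' @import methods
NULL

#' Histologic stages of early lung adenocarcinoma
#'
#' The four ordered stages used throughout the package: atypical adenomatous
#' hyperplasia (AAH, preneoplasia), adenocarcinoma in situ (AIS, preinvasive),
#' minimally invasive adenocarcinoma (MIA) and invasive adenocarcinoma (ADC).
#'
#' @return Character vector of the four stage labels, in biological order.
#' @export
#' @examples
#' ipnStages()
ipnStages <- function() c("AAH", "AIS", "MIA", "ADC")

## canonical column set of a variant table; extra columns are preserved
.variantColumns <- c(
  "patient_id", "lesion_id", "region_id", "chrom", "pos", "ref", "alt",
  "variant_class", "tumor_alt", "tumor_depth", "normal_alt", "normal_depth",
  "vaf_tumor", "vaf_normal", "lod", "callers", "context41", "gene", "effect"
)

.requiredVariantColumns <- c(
  "patient_id", "lesion_id", "region_id", "chrom", "pos", "ref", "alt",
  "variant_class", "tumor_alt", "tumor_depth", "normal_alt", "normal_depth",
  "lod", "callers"
)

#' Validate a variant-call table
#'
#' Checks the invariants of a table of somatic calls: counts are non-negative,
#' alt reads never exceed depth, ref differs from alt, VAFs (recomputed when
#' depth > 0) lie in \[0, 1\], and any 41-nt context has length 41 with its
#' centre base equal to the reference allele for SNVs. Coordinates are 1-based
#' and closed everywhere in this package.
#'
#' @param calls data.frame of variant calls.
#' @return Invisibly, the validated (and VAF-completed) data.frame. Errors
#'   name the first offending row.
#' @export
validateVariantCalls <- function(calls) {
  stopifnot(is.data.frame(calls))
  missing <- setdiff(.requiredVariantColumns, names(calls))
  if (length(missing) > 0)
    stop("variant table is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(calls) == 0) {
    if (!"vaf_tumor" %in% names(calls)) calls$vaf_tumor <- numeric(0)
    if (!"vaf_normal" %in% names(calls)) calls$vaf_normal <- numeric(0)
    return(invisible(calls))
  }
  .firstBad <- function(bad, what) {
    if (any(bad, na.rm = TRUE))
      stop(sprintf("row %d: %s", which(bad)[1], what))
  }
  .firstBad(!is.finite(calls$pos) | calls$pos < 1 | calls$pos != round(calls$pos),
            "malformed 1-based position")
  for (col in c("tumor_alt", "tumor_depth", "normal_alt", "normal_depth"))
    .firstBad(calls[[col]] < 0, paste0("negative count in ", col))
  .firstBad(calls$tumor_alt > calls$tumor_depth, "tumor_alt exceeds tumor_depth")
  .firstBad(calls$normal_alt > calls$normal_depth, "normal_alt exceeds normal_depth")
  .firstBad(calls$ref == calls$alt, "ref equals alt")
  .firstBad(!calls$variant_class %in% c("SNV", "INDEL"), "unknown variant_class")
  ## complete VAFs from counts where depth allows
  if (!"vaf_tumor" %in% names(calls))
    calls$vaf_tumor <- ifelse(calls$tumor_depth > 0,
                              calls$tumor_alt / calls$tumor_depth, 0)
  if (!"vaf_normal" %in% names(calls))
    calls$vaf_normal <- ifelse(calls$normal_depth > 0,
                               calls$normal_alt / calls$normal_depth, 0)
  if ("context41" %in% names(calls)) {
    has <- !is.na(calls$context41) & nzchar(calls$context41)
    .firstBad(has & nchar(calls$context41) != 41L, "context41 not 41 nt")
    snv <- has & calls$variant_class == "SNV"
    .firstBad(snv & substr(calls$context41, 21, 21) != calls$ref,
              "context41 centre base differs from ref")
  }
  invisible(calls)
}

#' Filter thresholds for the somatic variant cascade
#'
#' Boundary semantics follow the source conventions of each rule: thresholds
#' stated as strict (LOD > 10, indel tumor reads > 15, normal reads > 6,
#' artifact-sample fraction over 0.5625) are strict; "at least"/"minimum"
#' thresholds are inclusive.
#'
#' @slot snvVafTumorMin minimum tumor VAF for SNVs (inclusive).
#' @slot snvVafNormalMax maximum normal VAF (inclusive).
#' @slot snvDepthTumorMin minimum tumor depth (inclusive).
#' @slot snvDepthNormalMin minimum normal depth (inclusive).
#' @slot lodMin LOD must strictly exceed this.
#' @slot minCallers minimum number of concordant callers for SNVs.
#' @slot indelTumorReadsMin tumor depth must strictly exceed 15 (stored as 16,
#'   compared with >=).
#' @slot indelNormalReadsMin normal depth must strictly exceed 6 (stored as 7).
#' @slot indelAltReadsMin minimum indel-supporting reads (inclusive).
#' @slot rescueVafMin relaxed VAF threshold for forced calling (inclusive).
#' @slot rescueAltReadsMin relaxed alt-read threshold for forced calling.
#' @slot artifactSampleCutoff sample flagged when its C>T/G>A fraction
#'   strictly exceeds this.
#' @export
setClass("FilterThresholds", representation(
  snvVafTumorMin = "numeric", snvVafNormalMax = "numeric",
  snvDepthTumorMin = "numeric", snvDepthNormalMin = "numeric",
  lodMin = "numeric", minCallers = "numeric",
  indelTumorReadsMin = "numeric", indelNormalReadsMin = "numeric",
  indelAltReadsMin = "numeric",
  rescueVafMin = "numeric", rescueAltReadsMin = "numeric",
  artifactSampleCutoff = "numeric"
), prototype(
  snvVafTumorMin = 0.05, snvVafNormalMax = 0.01,
  snvDepthTumorMin = 20, snvDepthNormalMin = 10,
  lodMin = 10, minCallers = 2,
  indelTumorReadsMin = 16, indelNormalReadsMin = 7, indelAltReadsMin = 4,
  rescueVafMin = 0.01, rescueAltReadsMin = 2,
  artifactSampleCutoff = 0.5625
))

setValidity("FilterThresholds", function(object) {
  vals <- vapply(slotNames(object), function(s) slot(object, s), numeric(1))
  if (any(vals < 0)) return("all thresholds must be >= 0")
  if (object@rescueVafMin > object@snvVafTumorMin)
    return("rescue VAF threshold must not exceed the primary threshold")
  if (object@rescueAltReadsMin > object@indelAltReadsMin)
    return("rescue alt-read threshold must not exceed the primary threshold")
  TRUE
})

#' Construct filter thresholds
#'
#' @param ... named overrides of any slot of
#'   \code{\linkS4class{FilterThresholds}}.
#' @return A \code{FilterThresholds} object.
#' @export
#' @examples
#' filterThresholds()
#' filterThresholds(lodMin = 6.3)
filterThresholds <- function(...) new("FilterThresholds", ...)

#' One multi-region sampled territory of a lesion
#'
#' @slot regionId character scalar, unique within its lesion.
#' @slot purity fraction of diseased cells, in (0, 1]; macrodissection
#'   guarantees a floor of about 0.4 in practice.
#' @slot calls data.frame of somatic variant calls (see
#'   \code{\link{validateVariantCalls}}).
#' @slot coverageBins optional data.frame with chrom, start, end,
#'   tumor_reads, normal_reads (1-based closed bins).
#' @slot hetBafSites optional data.frame with chrom, pos, baf at germline
#'   heterozygous sites.
#' @export
setClass("Region", representation(
  regionId = "character", purity = "numeric", calls = "data.frame",
  coverageBins = "data.frame", hetBafSites = "data.frame"
))

setValidity("Region", function(object) {
  if (length(object@regionId) != 1L || !nzchar(object@regionId))
    return("regionId must be a non-empty scalar")
  if (length(object@purity) != 1L || object@purity <= 0 || object@purity > 1)
    return("purity must lie in (0, 1]")
  TRUE
})

#' Construct a Region
#' @param regionId scalar id.
#' @param purity diseased-cell fraction in (0, 1].
#' @param calls variant-call data.frame (validated).
#' @param coverageBins,hetBafSites optional tables.
#' @return A \code{\linkS4class{Region}}.
#' @export
newRegion <- function(regionId, purity, calls = emptyVariantTable(),
                      coverageBins = data.frame(), hetBafSites = data.frame()) {
  calls <- validateVariantCalls(calls)
  new("Region", regionId = as.character(regionId), purity = purity,
      calls = calls, coverageBins = coverageBins, hetBafSites = hetBafSites)
}

#' A lesion (indeterminate pulmonary nodule) with one or more regions
#'
#' @slot lesionId,patientId character scalars.
#' @slot stage one of \code{ipnStages()}.
#' @slot smoker logical.
#' @slot regions list of \code{\linkS4class{Region}}.
#' @slot noduleFeatures optional named list of clinical/radiologic features
#'   for risk scoring (see \code{\link{brockLogOdds}}).
#' @export
setClass("Lesion", representation(
  lesionId = "character", patientId = "character", stage = "character",
  smoker = "logical", regions = "list", noduleFeatures = "list"
))

setValidity("Lesion", function(object) {
  if (!object@stage %in% ipnStages())
    return(paste("stage must be one of", paste(ipnStages(), collapse = ", ")))
  if (length(object@regions) < 1L) return("a lesion needs at least one region")
  if (!all(vapply(object@regions, is, logical(1), "Region")))
    return("regions must be Region objects")
  ids <- vapply(object@regions, function(r) r@regionId, character(1))
  if (anyDuplicated(ids)) return("region ids must be unique within a lesion")
  TRUE
})

#' Construct a Lesion
#' @param lesionId,patientId scalar ids.
#' @param stage one of \code{ipnStages()}.
#' @param regions list of \code{\linkS4class{Region}} objects.
#' @param smoker logical smoking status of the patient.
#' @param noduleFeatures optional named list for risk scoring.
#' @return A \code{\linkS4class{Lesion}}.
#' @export
newLesion <- function(lesionId, patientId, stage, regions, smoker = FALSE,
                      noduleFeatures = list()) {
  new("Lesion", lesionId = as.character(lesionId),
      patientId = as.character(patientId), stage = stage,
      smoker = smoker, regions = regions, noduleFeatures = noduleFeatures)
}

#' A multi-region cohort with optional simulation ground truth
#'
#' @slot lesions list of \code{\linkS4class{Lesion}} objects.
#' @slot truth named list (by lesion id) of simulation ground-truth records
#'   (clone tree, per-region clone CCFs, per-mutation assignment and artifact
#'   flags); empty for real data.
#' @slot config the \code{\link{simulationConfig}} list used, if simulated.
#' @export
setClass("IpnCohort", representation(
  lesions = "list", truth = "list", config = "list"
))

setValidity("IpnCohort", function(object) {
  if (!all(vapply(object@lesions, is, logical(1), "Lesion")))
    return("lesions must be Lesion objects")
  TRUE
})

#' Construct an IpnCohort
#' @param lesions list of \code{\linkS4class{Lesion}}.
#' @param truth optional named list of ground-truth records.
#' @param config optional simulation configuration list.
#' @return An \code{\linkS4class{IpnCohort}}.
#' @export
newIpnCohort <- function(lesions, truth = list(), config = list()) {
  names(lesions) <- vapply(lesions, function(l) l@lesionId, character(1))
  new("IpnCohort", lesions = lesions, truth = truth, config = config)
}

#' An empty variant table with the canonical columns
#' @return Zero-row data.frame with the canonical variant columns.
#' @export
emptyVariantTable <- function() {
  df <- data.frame(
    patient_id = character(0), lesion_id = character(0),
    region_id = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), variant_class = character(0),
    tumor_alt = integer(0), tumor_depth = integer(0),
    normal_alt = integer(0), normal_depth = integer(0),
    vaf_tumor = numeric(0), vaf_normal = numeric(0), lod = numeric(0),
    callers = character(0), context41 = character(0),
    gene = character(0), effect = character(0),
    stringsAsFactors = FALSE
  )
  df
}

setMethod("show", "Region", function(object) {
  cat("Region", object@regionId,
      sprintf("| purity %.2f | %d calls\n", object@purity, nrow(object@calls)))
})

setMethod("show", "Lesion", function(object) {
  cat(sprintf("Lesion %s (%s, patient %s, %s)\n", object@lesionId,
              object@stage, object@patientId,
              if (object@smoker) "smoker" else "non-smoker"))
  cat(sprintf("  %d region(s), %d calls total\n", length(object@regions),
              sum(vapply(object@regions, function(r) nrow(r@calls), numeric(1)))))
})

setMethod("show", "IpnCohort", function(object) {
  st <- vapply(object@lesions, function(l) l@stage, character(1))
  cat(sprintf("IpnCohort: %d lesions (%s)%s\n", length(object@lesions),
              paste(sprintf("%s=%d", ipnStages(),
                            vapply(ipnStages(), function(s) sum(st == s),
                                   numeric(1))), collapse = ", "),
              if (length(object@truth)) " with simulation truth" else ""))
})
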