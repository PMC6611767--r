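#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("lesionId", function(x) standardGeneric("lesionId"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))
#' @rdname accessors
#' @export
setGeneric("smoker", function(x) standardGeneric("smoker"))
#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))
#' @rdname accessors
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))
#' @rdname accessors
#' @export
setGeneric("variantCalls", function(x, ...) standardGeneric("variantCalls"))
#' @rdname accessors
#' @export
setGeneric("lesions", function(x) standardGeneric("lesions"))
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' Accessors for cohort, lesion and region objects
#'
#' \code{variantCalls} on a \code{Lesion} or \code{IpnCohort} returns the
#' row-bound calls of all regions; on a \code{Region} its own call table.
#' \code{purity} on a \code{Lesion} returns the named per-region purities.
#'
#' @param x a \code{\linkS4class{Region}}, \code{\linkS4class{Lesion}} or
#'   \code{\linkS4class{IpnCohort}}.
#' @param ... unused.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
setMethod("lesionId", "Lesion", function(x) x@lesionId)
#' @rdname accessors
setMethod("patientId", "Lesion", function(x) x@patientId)
#' @rdname accessors
setMethod("stage", "Lesion", function(x) x@stage)
#' @rdname accessors
setMethod("smoker", "Lesion", function(x) x@smoker)
#' @rdname accessors
setMethod("regions", "Lesion", function(x) x@regions)
#' @rdname accessors
setMethod("purity", "Region", function(x) x@purity)
#' @rdname accessors
setMethod("purity", "Lesion", function(x) {
  p <- vapply(x@regions, function(r) r@purity, numeric(1))
  names(p) <- vapply(x@regions, function(r) r@regionId, character(1))
  p
})
#' @rdname accessors
setMethod("variantCalls", "Region", function(x, ...) x@calls)
#' @rdname accessors
setMethod("variantCalls", "Lesion", function(x, ...) {
  do.call(rbind, c(lapply(x@regions, function(r) r@calls),
                   list(make.row.names = FALSE)))
})
#' @rdname accessors
setMethod("variantCalls", "IpnCohort", function(x, ...) {
  do.call(rbind, c(lapply(x@lesions, variantCalls),
                   list(make.row.names = FALSE)))
})
#' @rdname accessors
setMethod("lesions", "IpnCohort", function(x) x@lesions)
#' @rdname accessors
setMethod("cohortTruth", "IpnCohort", function(x) x@truth)

#' Mutation keys for a call table
#'
#' Locus identity is the exact (chrom, pos, ref, alt) tuple; it is how loci
#' are matched across regions and callers.
#'
#' @param calls variant-call data.frame.
#' @return Character vector of "chrom:pos:ref:alt" keys.
#' @export
mutationKey <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}
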