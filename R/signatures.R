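#' Non-negative signature deconstruction of a 96-channel spectrum
#'
#' Finds non-negative per-signature weights minimising the Euclidean
#' distance between the normalised spectrum and the reference mixture,
#' then iteratively removes signatures with weight below
#' \code{weightFloor} and refits until all surviving weights clear the
#' floor. Lesions with fewer than \code{minSnvs} mutations are not
#' evaluated (small spectra overfit). Scale-invariant: the spectrum is
#' normalised before fitting.
#'
#' @param spectrum named 96-vector of channel counts
#'   (\code{\link{mutationSpectrum}}).
#' @param reference 96 x K column-stochastic matrix
#'   (\code{\link{readSignatureMatrix}} / \code{\link{syntheticSignatures}}).
#' @param minSnvs minimum total mutations to evaluate (default 100).
#' @param weightFloor minimum retained weight (default 0.06).
#' @return List with \code{evaluated}; when evaluated: \code{weights}
#'   (named over all reference columns, zeros for removed signatures),
#'   \code{unexplained} residual fraction and \code{nSnvs}.
#' @export
deconstructSignatures <- function(spectrum, reference, minSnvs = 100,
                                  weightFloor = 0.06) {
  stopifnot(length(spectrum) == 96L, nrow(reference) == 96L)
  total <- sum(spectrum)
  if (total == 0) stop("all-zero spectrum")
  if (total < minSnvs)
    return(list(evaluated = FALSE, nSnvs = total))
  p <- as.numeric(spectrum) / total
  sigs <- colnames(reference)
  active <- seq_along(sigs)
  repeat {
    fit <- pracma::lsqnonneg(reference[, active, drop = FALSE], p)
    w <- fit$x
    if (length(active) == 1L || all(w >= weightFloor)) break
    drop <- which.min(w)
    if (w[drop] >= weightFloor) break
    active <- active[-drop]
  }
  weights <- stats::setNames(numeric(length(sigs)), sigs)
  weights[active] <- w
  if (sum(weights) > 1) weights <- weights / sum(weights)
  list(evaluated = TRUE, weights = weights,
       unexplained = max(0, 1 - sum(weights)), nSnvs = total)
}

.countMotif <- function(strings, pattern) {
  vapply(gregexpr(pattern, strings, perl = TRUE), function(m)
    if (m[1] == -1L) 0L else length(m), integer(1))
}

#' APOBEC TCW enrichment score
#'
#' Measures the strength of mutagenesis at the TCW motif (W = A or T), the
#' preferred APOBEC cytidine deaminase substrate. The score is
#' \deqn{E = (tcw_{mut}/tcw_{ctx}) / (c_{mut}/c_{ctx})}
#' where \code{tcw_mut} counts C>T/C>G mutations at TCW (and their
#' reverse-complement, G>A/G>C at WGA), \code{c_mut} counts all C>T/C>G
#' (and G>A/G>C) mutations, and the context terms count TCW motifs (both
#' strands) and C/G bases within the 41-nt windows around the mutated
#' sites. A score near 1 indicates no motif preference. Lesions with fewer
#' than \code{minSnvs} SNVs, or degenerate denominators, are reported as
#' missing.
#'
#' @param calls variant-call data.frame; SNVs with a 41-nt context are
#'   used.
#' @param minSnvs minimum SNV count to evaluate (default 10).
#' @return List with \code{enrichment} (or \code{NA}), \code{p_value}
#'   (one-sided Fisher test of motif excess; reported, not used for
#'   filtering), and the component counts \code{n_snvs}, \code{tcw_mut},
#'   \code{c_mut}, \code{tcw_context}, \code{c_context}.
#' @export
apobecEnrichment <- function(calls, minSnvs = 10) {
  use <- calls$variant_class == "SNV" & !is.na(calls$context41) &
    nchar(calls$context41) == 41L
  calls <- calls[use, , drop = FALSE]
  n <- nrow(calls)
  empty <- list(enrichment = NA_real_, p_value = NA_real_, n_snvs = n,
                tcw_mut = NA_integer_, c_mut = NA_integer_,
                tcw_context = NA_integer_, c_context = NA_integer_)
  if (n < minSnvs) return(empty)
  ctx <- toupper(calls$context41)
  ref <- calls$ref
  alt <- calls$alt
  cType <- (ref == "C" & alt %in% c("T", "G")) |
    (ref == "G" & alt %in% c("A", "C"))
  f5 <- substr(ctx, 20, 20)
  f3 <- substr(ctx, 22, 22)
  atMotif <- (ref == "C" & f5 == "T" & f3 %in% c("A", "T")) |
    (ref == "G" & f3 == "A" & f5 %in% c("A", "T"))
  tcwMut <- sum(cType & atMotif)
  cMut <- sum(cType)
  tcwCtx <- sum(.countMotif(ctx, "(?=TC[AT])")) +
    sum(.countMotif(ctx, "(?=[AT]GA)"))
  cCtx <- sum(.countMotif(ctx, "C")) + sum(.countMotif(ctx, "G"))
  out <- list(enrichment = NA_real_, p_value = NA_real_, n_snvs = n,
              tcw_mut = tcwMut, c_mut = cMut, tcw_context = tcwCtx,
              c_context = cCtx)
  if (cMut == 0 || tcwCtx == 0 || cCtx == 0) return(out)
  out$enrichment <- (tcwMut / tcwCtx) / (cMut / cCtx)
  out$p_value <- stats::fisher.test(
    matrix(c(tcwMut, cMut - tcwMut, tcwCtx, cCtx - tcwCtx), 2),
    alternative = "greater")$p.value
  out
}
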