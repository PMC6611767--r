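#' The 96 pyrimidine-centred trinucleotide channels
#'
#' Lexicographic order "A[C>A]A", "A[C>A]C", ..., "T[T>G]T" (5' flank major,
#' then substitution, then 3' flank), the row order used by all spectra and
#' signature matrices in this package.
#'
#' @return Character vector of length 96.
#' @export
trinucleotideChannels <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (f5 in bases)
    for (ref in c("C", "T"))
      for (alt in setdiff(bases, ref))
        for (f3 in bases)
          out <- c(out, paste0(f5, "[", ref, ">", alt, "]", f3))
  out
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA strings (ACGTN).
#' @return Reverse-complemented strings.
#' @export
reverseComplement <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), ""),
         function(b) paste(rev(b), collapse = ""), character(1))
}

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

#' Classify SNVs into trinucleotide channels
#'
#' Calls with a purine reference are reverse-complemented onto the
#' pyrimidine-centred channel (strand symmetry). Calls whose trinucleotide
#' contains an ambiguous base, or non-SNVs, get \code{NA}.
#'
#' @param calls variant-call data.frame with \code{context41} present; the
#'   21st base of each context must equal the reference allele.
#' @return Character vector of channel names (or \code{NA}), same length as
#'   \code{nrow(calls)}.
#' @export
#' @examples
#' calls <- data.frame(variant_class = "SNV", ref = "C", alt = "T",
#'                     context41 = paste0(strrep("A", 19), "ACG",
#'                                        strrep("A", 19)))
#' classifyChannel(calls)  # "A[C>T]G"
classifyChannel <- function(calls) {
  n <- nrow(calls)
  out <- rep(NA_character_, n)
  if (n == 0) return(out)
  ok <- calls$variant_class == "SNV" & !is.na(calls$context41) &
    nchar(calls$context41) == 41L
  if (!any(ok)) return(out)
  ctx <- calls$context41[ok]
  ref <- calls$ref[ok]
  alt <- calls$alt[ok]
  centre <- substr(ctx, 21, 21)
  if (any(centre != ref))
    stop("context centre base differs from ref at row ",
         which(ok)[which(centre != ref)[1]])
  f5 <- substr(ctx, 20, 20)
  f3 <- substr(ctx, 22, 22)
  pur <- ref %in% c("A", "G")
  ## purine reference: flip to the opposite strand
  tmp5 <- f5
  f5[pur] <- .complement(f3[pur])
  f3[pur] <- .complement(tmp5[pur])
  ref[pur] <- .complement(ref[pur])
  alt[pur] <- .complement(alt[pur])
  chan <- paste0(f5, "[", ref, ">", alt, "]", f3)
  chan[!paste0(f5, ref, f3) %in% .allTrinucs()] <- NA_character_
  out[ok] <- chan
  out
}

.allTrinucs <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, c("C", "T"), b, stringsAsFactors = FALSE)
  paste0(g[[1]], g[[2]], g[[3]])
}

#' Build a 96-channel mutation spectrum
#'
#' @param calls variant-call data.frame (SNVs with contexts are counted;
#'   other rows are ignored).
#' @return Named integer vector of length 96 (channel counts).
#' @export
mutationSpectrum <- function(calls) {
  chans <- trinucleotideChannels()
  counts <- stats::setNames(integer(96), chans)
  cl <- classifyChannel(calls)
  tab <- table(factor(cl[!is.na(cl)], levels = chans))
  counts[] <- as.integer(tab)
  counts
}

#' Synthetic reference signature matrix
#'
#' A deterministic, clearly synthetic stand-in for a curated reference
#' signature set: signature j concentrates 80% of its mass on 8 channels
#' disjoint from those of the other signatures, with the remaining 20%
#' spread uniformly. Columns are well separated (pairwise cosine similarity
#' below 0.25), which is what exposure-recovery testing needs; the matrix
#' carries no claim of biological realism.
#'
#' @param k number of signatures (1..12).
#' @return 96 x k column-stochastic matrix, columns "synth1".."synthk".
#' @export
syntheticSignatures <- function(k = 5) {
  stopifnot(k >= 1, k <= 12)
  chans <- trinucleotideChannels()
  m <- matrix(0.2 / 96, nrow = 96, ncol = k,
              dimnames = list(chans, paste0("synth", seq_len(k))))
  for (j in seq_len(k)) {
    peaks <- ((0:7) * 12 + (j - 1)) %% 96 + 1
    m[peaks, j] <- m[peaks, j] + 0.8 / 8
  }
  m
}
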