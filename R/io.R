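#' Read a MAF-like tab-delimited variant table
#'
#' Expects a header naming at least the canonical columns; unknown extra
#' columns are preserved as opaque annotations. The \code{callers} column is
#' a comma-separated list of caller names per call. Coordinates are 1-based.
#'
#' @param path path to a tab-delimited file.
#' @return Validated variant-call data.frame (possibly zero rows).
#' @seealso \code{\link{validateVariantCalls}} for the enforced invariants.
#' @export
readVariantTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = NA, check.names = FALSE)
  missing <- setdiff(.requiredVariantColumns, names(df))
  if (length(missing) > 0)
    stop("variant table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  validateVariantCalls(df)
  df
}

#' Write a variant table
#'
#' Inverse of \code{\link{readVariantTable}}; the round trip is lossless for
#' all defined columns.
#'
#' @param calls variant-call data.frame.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeVariantTable <- function(calls, path) {
  validateVariantCalls(calls)
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write copy-number segments in SEG format
#'
#' Standard SEG columns: sample, chrom, start, end, num.mark, seg.mean
#' (tab-delimited, 1-based closed coordinates).
#'
#' @param segments data.frame with columns sample (optional; a single
#'   \code{sample} argument may be given instead), chrom, start, end, n_bins,
#'   mean_log2.
#' @param path output path.
#' @param sample sample id used when \code{segments} has no sample column.
#' @return Invisibly, \code{path}.
#' @export
writeSeg <- function(segments, path, sample = "sample1") {
  if (!"sample" %in% names(segments)) segments$sample <- sample
  stopifnot(all(c("chrom", "start", "end", "n_bins", "mean_log2") %in%
                  names(segments)))
  ## reject overlapping segments within one chromosome of one sample
  sp <- split(segments, list(segments$sample, segments$chrom), drop = TRUE)
  for (s in sp) {
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
      stop("overlapping segments on ", s$chrom[1], " of sample ", s$sample[1])
  }
  out <- data.frame(ID = segments$sample, chrom = segments$chrom,
                    loc.start = segments$start, loc.end = segments$end,
                    num.mark = segments$n_bins, seg.mean = segments$mean_log2)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG file
#' @param path SEG file path.
#' @return data.frame with sample, chrom, start, end, n_bins, mean_log2.
#' @export
readSeg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(sample = df[[1]], chrom = as.character(df[[2]]),
             start = df[[3]], end = df[[4]], n_bins = df[[5]],
             mean_log2 = df[[6]], stringsAsFactors = FALSE)
}

#' Write a phylogenetic tree as Newick
#'
#' The germline leaf must be labelled \code{"NORMAL"}; branch lengths must be
#' non-negative and every leaf labelled.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeNewickTree <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    stop("all leaves must be labelled")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("branch lengths must be non-negative")
  if (!"NORMAL" %in% tree$tip.label)
    stop("germline leaf 'NORMAL' missing from tree")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Newick file path.
#' @return An \code{ape} \code{phylo} object.
#' @export
readNewickTree <- function(path) ape::read.tree(path)

#' Read a 96 x K reference signature matrix
#'
#' Rows are the 96 pyrimidine-centred trinucleotide channels in lexicographic
#' "A[C>A]A" ... "T[T>G]T" order (row names in column 1); columns are
#' signature names. Columns are renormalised to sum to 1.
#'
#' @param path tab-delimited matrix file.
#' @return Numeric 96 x K matrix with channel row names.
#' @export
readSignatureMatrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  chans <- trinucleotideChannels()
  if (nrow(m) != 96L) stop("signature matrix must have 96 rows")
  if (!identical(rownames(m), chans)) {
    if (!all(chans %in% rownames(m)))
      stop("signature matrix rows must be the 96 trinucleotide channels")
    m <- m[chans, , drop = FALSE]
  }
  sweep(m, 2, colSums(m), "/")
}

#' Write a signature matrix
#' @param m 96 x K matrix with channel row names.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeSignatureMatrix <- function(m, path) {
  utils::write.table(data.frame(channel = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
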