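# fixtures are built in code; coordinates are 1-based closed throughout

# one variant-call row with passing defaults, overridable per field
makeCall <- function(...) {
  row <- list(
    patient_id = "P1", lesion_id = "L1", region_id = "L1_R1",
    chrom = "chr1", pos = 1000L, ref = "C", alt = "T",
    variant_class = "SNV", tumor_alt = 20L, tumor_depth = 100L,
    normal_alt = 0L, normal_depth = 50L, vaf_tumor = 0.2, vaf_normal = 0,
    lod = 30, callers = "mutect,vardict",
    context41 = paste0(strrep("A", 19), "ACG", strrep("A", 19)),
    gene = NA_character_, effect = NA_character_
  )
  over <- list(...)
  row[names(over)] <- over
  if (!"vaf_tumor" %in% names(over) && row$tumor_depth > 0)
    row$vaf_tumor <- row$tumor_alt / row$tumor_depth
  as.data.frame(row, stringsAsFactors = FALSE)
}

makeCalls <- function(...) do.call(rbind, list(...))

# context with a given centre trinucleotide (ref = middle base)
ctxFor <- function(tri, flank = "A") {
  paste0(strrep(flank, 19), tri, strrep(flank, 19))
}

# a small two-region lesion built from explicit call tables
makeLesion <- function(callsR1, callsR2 = NULL, stage = "MIA",
                       purity = c(0.6, 0.6), lesionId = "L1") {
  regs <- list(newRegion(paste0(lesionId, "_R1"), purity[1], callsR1))
  if (!is.null(callsR2))
    regs <- c(regs, list(newRegion(paste0(lesionId, "_R2"), purity[2],
                                   callsR2)))
  newLesion(lesionId, "P1", stage, regs)
}

# brute-force one-sided Fisher tail by enumerating all tables at fixed
# margins (independent of phyper)
bruteFisherGreater <- function(tab) {
  K <- tab[1, 1] + tab[2, 1]
  n1 <- sum(tab[1, ])
  N <- sum(tab)
  xs <- max(0, K + n1 - N):min(K, n1)
  probs <- vapply(xs, function(x)
    choose(K, x) * choose(N - K, n1 - x) / choose(N, n1), numeric(1))
  sum(probs[xs >= tab[1, 1]])
}

tinyConfig <- function(seed = 1, n = 1, ...) {
  simulationConfig(seed = seed,
                   lesionsPerStage = c(AAH = n, AIS = n, MIA = n, ADC = n),
                   ...)
}
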