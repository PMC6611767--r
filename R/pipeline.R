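#' Per-lesion metrics table
#'
#' Runs the filter cascade and every per-lesion analysis on one lesion:
#' mutation burden (all three modes), transition fractions and the
#' artifact-sample flag, APOBEC enrichment, signature deconstruction,
#' clonality, trunk proportion, allelic-imbalance count, copy-number
#' altered fraction and the Brock risk score (when nodule features are
#' available). Minimum-mutation rules (>= 100 SNVs for signatures, >= 10
#' for APOBEC and clonality) are enforced here so exclusions are
#' centralised and logged.
#'
#' @param lesion a \code{\linkS4class{Lesion}}.
#' @param thresholds a \code{\linkS4class{FilterThresholds}}.
#' @param reference 96 x K signature matrix (NULL skips deconstruction).
#' @param exomeMb burden denominator in Mb.
#' @param cnvThr log2 threshold for the per-bin altered fraction.
#' @param aiParams named list of \code{\link{detectAi}} overrides.
#' @return List with \code{metrics} (one-row data.frame),
#'   \code{exposures} (named weights or NULL) and \code{exclusions}
#'   (character vector of rule names that withheld an analysis).
#' @export
lesionMetrics <- function(lesion, thresholds = filterThresholds(),
                          reference = NULL, exomeMb = 36, cnvThr = 0.3,
                          aiParams = list()) {
  exclusions <- character(0)
  calls <- variantCalls(lesion)
  filtered <- applyFilterCascade(calls, thresholds)
  snvs <- filtered[filtered$variant_class == "SNV", , drop = FALSE]

  ## FFPE QC on the filtered SNVs
  tf <- transitionFraction(snvs)
  flagged <- flagArtifactSample(tf$overall, thresholds@artifactSampleCutoff)
  if (isTRUE(flagged)) exclusions <- c(exclusions, "artifact_flag")

  ## clonality (>= 10 mutations in the union)
  ccf <- lesionCcfTable(lesion, filtered, thresholds)
  clon <- lesionClonality(ccf, length(regions(lesion)), minSnvs = 10,
                          exomeMb = exomeMb)
  if (!clon$evaluated) exclusions <- c(exclusions, "min_snv_clonality")

  ## burdens
  bAll <- mutationBurden(lesion, "all", exomeMb)
  bTrans <- mutationBurden(lesion, "drop_transitions", exomeMb)
  bPriv <- if (clon$evaluated) {
    lab <- merge(data.frame(key = unique(mutationKey(filtered)),
                            stringsAsFactors = FALSE),
                 clon$labels, all.x = TRUE)
    lab$clonal[is.na(lab$clonal)] <- FALSE
    mutationBurden(lesion, "drop_private_subclonal", exomeMb,
                   clonality = lab)
  } else list(count = NA_integer_, per_mb = NA_real_)

  ## APOBEC (>= 10 SNVs)
  ap <- apobecEnrichment(snvs, minSnvs = 10)
  if (is.na(ap$enrichment) && ap$n_snvs < 10)
    exclusions <- c(exclusions, "min_snv_apobec")

  ## signature deconstruction (>= 100 SNVs)
  exposures <- NULL
  if (!is.null(reference)) {
    spec <- mutationSpectrum(snvs)
    if (sum(spec) == 0) {
      exclusions <- c(exclusions, "min_snv_signatures")
    } else {
      dec <- deconstructSignatures(spec, reference, minSnvs = 100)
      if (dec$evaluated) exposures <- dec$weights
      else exclusions <- c(exclusions, "min_snv_signatures")
    }
  }

  ## trunk proportion (>= 2 regions)
  pm <- presenceMatrix(lesion, thresholds)
  tb <- trunkBranchStats(pm)

  ## allelic imbalance
  ai <- do.call(countAiEvents, c(list(lesion), aiParams))

  ## copy-number altered fraction, bins averaged over regions
  cnvFrac <- NA_real_
  covRegions <- Filter(function(r) nrow(r@coverageBins) > 0, regions(lesion))
  if (length(covRegions)) {
    prof <- rowMeans(vapply(covRegions, function(r)
      log2Ratio(r@coverageBins)$log2_ratio,
      numeric(nrow(covRegions[[1]]@coverageBins))))
    cnvFrac <- mean(abs(prof) > cnvThr)
  }

  ## Brock risk score
  risk <- NA_real_
  nf <- lesion@noduleFeatures
  if (length(nf) > 0)
    risk <- brockProbability(do.call(brockLogOdds, nf))

  metrics <- data.frame(
    lesion_id = lesionId(lesion), patient_id = patientId(lesion),
    stage = stage(lesion), smoker = smoker(lesion),
    n_regions = length(regions(lesion)),
    n_mutations = bAll$count, tmb_per_mb = bAll$per_mb,
    tmb_no_transitions = bTrans$per_mb,
    tmb_no_private_subclonal = bPriv$per_mb,
    transition_frac_below = tf$below, transition_frac_above = tf$above,
    transition_frac_overall = tf$overall,
    artifact_flagged = isTRUE(flagged),
    apobec_enrichment = ap$enrichment,
    proportion_clonal = if (clon$evaluated) clon$proportion_clonal
                        else NA_real_,
    clonal_burden = if (clon$evaluated) clon$clonal_burden else NA_real_,
    subclonal_burden = if (clon$evaluated) clon$subclonal_burden
                       else NA_real_,
    trunk_proportion = if (tb$evaluated) tb$trunk_proportion else NA_real_,
    ai_events = ai$lesion, cnv_altered_fraction = cnvFrac,
    risk_score = risk, stringsAsFactors = FALSE
  )
  list(metrics = metrics, exposures = exposures, exclusions = exclusions)
}

#' Stage-comparison report for per-lesion metrics
#'
#' For each metric: per-stage means with t-based 95% confidence
#' intervals, the Kruskal-Wallis p-value across stages, Tukey pairwise
#' comparisons, and the one-sided smoker-versus-non-smoker Wilcoxon test
#' within each stage (smokers tending larger).
#'
#' @param metrics per-lesion metrics data.frame
#'   (\code{\link{runPipeline}} output).
#' @param metricCols metric column names to compare.
#' @return List with \code{kruskal} (data.frame metric / statistic /
#'   p_value), \code{stage_means}, \code{tukey} (named list) and
#'   \code{smoker_wilcoxon} (data.frame).
#' @export
stageReport <- function(metrics,
                        metricCols = c("tmb_per_mb", "proportion_clonal",
                                       "trunk_proportion", "ai_events",
                                       "apobec_enrichment",
                                       "cnv_altered_fraction",
                                       "risk_score")) {
  stages <- intersect(ipnStages(), unique(metrics$stage))
  stopifnot(length(stages) >= 2)
  kw <- list(); means <- list(); tuk <- list(); smk <- list()
  for (mc in metricCols) {
    if (!mc %in% names(metrics)) next
    vals <- metrics[[mc]]
    ok <- !is.na(vals)
    if (!any(ok)) next
    groups <- lapply(stages, function(s) vals[ok & metrics$stage == s])
    names(groups) <- stages
    groups <- groups[lengths(groups) > 0]
    if (length(groups) >= 2) {
      k <- kruskalWallis(groups)
      kw[[mc]] <- data.frame(metric = mc, statistic = k$statistic,
                             p_value = k$p_value)
      if (all(lengths(groups) >= 2))
        tuk[[mc]] <- tukeyPairwise(groups)
    }
    means[[mc]] <- do.call(rbind, lapply(names(groups), function(s) {
      x <- groups[[s]]
      ci <- if (length(x) >= 2 && stats::sd(x) > 0)
        stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
      else 0
      data.frame(metric = mc, stage = s, n = length(x), mean = mean(x),
                 ci_low = mean(x) - ci, ci_high = mean(x) + ci)
    }))
    for (s in names(groups)) {
      a <- vals[ok & metrics$stage == s & metrics$smoker]
      b <- vals[ok & metrics$stage == s & !metrics$smoker]
      if (length(a) >= 1 && length(b) >= 1) {
        w <- wilcoxonOneSided(a, b, "greater")
        smk[[paste(mc, s)]] <- data.frame(metric = mc, stage = s,
                                          p_value = w$p_value)
      }
    }
  }
  list(kruskal = do.call(rbind, c(kw, list(make.row.names = FALSE))),
       stage_means = do.call(rbind, c(means, list(make.row.names = FALSE))),
       tukey = tuk,
       smoker_wilcoxon = do.call(rbind, c(smk,
                                          list(make.row.names = FALSE))))
}

#' Run the full per-lesion pipeline over a cohort
#'
#' Applies \code{\link{lesionMetrics}} to every lesion, assembles the
#' per-lesion metrics table, signature exposure matrix, centralised
#' exclusion log, per-lesion parsimony trees (lesions with >= 2 regions)
#' and the stage-comparison report. Deterministic: identical inputs give
#' identical outputs.
#'
#' @param cohort an \code{\linkS4class{IpnCohort}}.
#' @param thresholds a \code{\linkS4class{FilterThresholds}}.
#' @param reference 96 x K signature matrix (NULL skips deconstruction).
#' @param exomeMb burden denominator.
#' @param trees build per-lesion Wagner parsimony trees (default TRUE).
#' @param report build the stage-comparison report (needs >= 2 stages).
#' @return List with metrics, exposures, exclusions, trees and
#'   stage_report.
#' @export
runPipeline <- function(cohort, thresholds = filterThresholds(),
                        reference = syntheticSignatures(5), exomeMb = 36,
                        trees = TRUE, report = TRUE) {
  if (length(lesions(cohort)) == 0) {
    warning("empty cohort: empty report")
    return(list(metrics = data.frame(), exposures = NULL,
                exclusions = list(), trees = list(), stage_report = NULL))
  }
  rows <- list(); expos <- list(); excl <- list(); treeList <- list()
  for (les in lesions(cohort)) {
    lm <- tryCatch(
      lesionMetrics(les, thresholds, reference, exomeMb),
      error = function(e) stop("pipeline failed at lesion ",
                               lesionId(les), ": ", conditionMessage(e)))
    rows[[lesionId(les)]] <- lm$metrics
    if (!is.null(lm$exposures)) expos[[lesionId(les)]] <- lm$exposures
    if (length(lm$exclusions)) excl[[lesionId(les)]] <- lm$exclusions
    if (trees && length(regions(les)) >= 2) {
      pm <- presenceMatrix(les, thresholds)
      if (ncol(pm) >= 1)
        treeList[[lesionId(les)]] <-
          wagnerParsimony(pm, "nj_seeded_nni")
    }
  }
  metrics <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  exposures <- if (length(expos)) do.call(rbind, expos) else NULL
  rep <- NULL
  if (report && length(unique(metrics$stage)) >= 2)
    rep <- stageReport(metrics)
  list(metrics = metrics, exposures = exposures, exclusions = excl,
       trees = treeList, stage_report = rep)
}
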