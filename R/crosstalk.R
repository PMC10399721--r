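#' Intersect tumor-expressed ligands with stroma-expressed receptors
#'
#' A candidate is any tumor-expressed ligand with at least one cognate
#' receptor (per the compendium) expressed in the stroma; its receptor set
#' is that intersection. The headline counts are the number of candidate
#' ligands and the number of distinct receptors across candidates.
#'
#' @param tumorLigands character vector of tumor-expressed canonical
#'   ligand symbols.
#' @param stromaReceptors character vector of stroma-expressed canonical
#'   receptor symbols.
#' @param compendium an [LRCompendium-class].
#' @return `DataFrame` with columns `ligand` and `receptors`
#'   (`CharacterList`), one row per candidate, in `tumorLigands` order;
#'   counts in `metadata()` (`nLigands`, `nReceptors`).
#' @export
intersectCrosstalk <- function(tumorLigands, stromaReceptors, compendium) {
  stopifnot(is(compendium, "LRCompendium"))
  tumorLigands <- unique(as.character(tumorLigands))
  stromaReceptors <- unique(as.character(stromaReceptors))
  recs <- lapply(tumorLigands, function(l)
    intersect(receptorsOf(compendium, l), stromaReceptors))
  hit <- lengths(recs) > 0L
  out <- DataFrame(ligand = tumorLigands[hit],
                   receptors = CharacterList(recs[hit]))
  metadata(out) <- list(nLigands = sum(hit),
                        nReceptors = length(unique(unlist(recs[hit]))))
  out
}

#' Rank candidate ligands by combination-arm upregulation
#'
#' Descending by combo-vs-control log2 ratio, ties broken by symbol; the
#' first element is the headline ligand.
#'
#' @param ligands character vector of candidate ligand symbols.
#' @param contrasts data.frame from [contrastTable()] containing combo
#'   results for every ligand.
#' @param species compartment (default `"human"`).
#' @return data.frame with columns `ligand`, `combo_log2ratio`, ordered.
#' @export
rankByUpregulation <- function(ligands, contrasts, species = "human") {
  sub <- contrasts[contrasts$species == species &
                     contrasts$condition == "combo", , drop = FALSE]
  lr <- sub$log2ratio[match(ligands, sub$gene)]
  if (anyNA(lr))
    stop(sprintf("no combo contrast for ligand(s): %s",
                 paste(ligands[is.na(lr)], collapse = ", ")))
  ord <- order(-lr, ligands, method = "radix")
  data.frame(ligand = ligands[ord], combo_log2ratio = lr[ord],
             row.names = NULL)
}

#' Run the full crosstalk pipeline
#'
#' Executes, in order: cross-hybridizing probe removal, probe
#' significance prefilter, largest-mean probe-to-gene collapse, expression
#' calls, per-condition contrasts with BH adjustment, ligand-receptor
#' intersection, detection of ligands regulated only under the combination
#' arm, and ranking by combo log2 ratio. Deterministic given its inputs.
#' Where the prefilter acts is configurable (see `prefilter`): by default
#' it restricts only the differential-detection track, so that genes that
#' are expressed but not modulated still contribute to the
#' expressed-ligand/receptor intersection.
#'
#' @param se probe-level `SummarizedExperiment` (see [loadExpression()]).
#' @param compendium an [LRCompendium-class].
#' @param blacklist character vector of cross-hybridizing probe ids;
#'   probes flagged `cross_hyb` in the annotation are removed as well.
#' @param alpha significance threshold for both the prefilter and the
#'   condition-specific call (default 0.05).
#' @param pMode `"raw"` or `"bh"` p-values for the condition-specific call.
#' @param variance `"pooled"` or `"welch"` contrast engine.
#' @param floor expression-call floor (`"auto"` = per-species median).
#' @param scope conditions scanned by the expression call.
#' @param prefilter where the probe significance prefilter acts.
#'   `"detection"` (default): expression calls and contrasts use all
#'   blacklist-cleaned genes, and the prefilter gates only which genes are
#'   eligible for the condition-specific call — an unmodulated but
#'   expressed receptor still counts as expressed, matching the reported
#'   behaviour of stromal receptors that were not modulated by any
#'   treatment. `"global"`: the prefilter removes probes before collapse,
#'   so every downstream stage sees only significant probes. `"off"`: no
#'   prefilter.
#' @param outDir optional directory; when given, report TSVs and a run
#'   manifest are written via [writeCrosstalkReport()].
#' @return A [CrosstalkReport-class].
#' @export
runCrosstalk <- function(se, compendium, blacklist = character(),
                         alpha = 0.05, pMode = c("raw", "bh"),
                         variance = c("pooled", "welch"), floor = "auto",
                         scope = pipelineConditions(),
                         prefilter = c("detection", "global", "off"),
                         outDir = NULL) {
  pMode <- match.arg(pMode)
  variance <- match.arg(variance)
  prefilter <- match.arg(prefilter)
  if (nrow(se) == 0L || ncol(se) == 0L)
    stop("[load] expression input is empty")
  se <- .stage("blacklist", {
    bl <- union(blacklist, rownames(se)[rowData(se)$cross_hyb %in% TRUE])
    removeCrossHybridizing(se, bl)
  })
  detectable <- NULL  # genes eligible for the condition-specific call
  if (prefilter != "off") {
    keep <- .stage("prefilter",
                   significancePrefilter(probePvalues(se, variance), alpha))
    if (prefilter == "global") {
      se <- se[keep, ]
    } else {
      rdk <- rowData(se)[keep, , drop = FALSE]
      detectable <- unique(paste(rdk$species, rdk$gene))
    }
  }
  gse <- .stage("collapse", collapseToGenes(se))
  call <- .stage("expression_call", expressionCall(gse, floor, scope))
  tumorLigands <- expressedGenes(call, "human")
  stromaReceptors <- expressedGenes(call, "mouse")
  contrasts <- .stage("contrasts", contrastTable(gse, variance))
  cand <- .stage("intersect",
                 intersectCrosstalk(tumorLigands, stromaReceptors,
                                    compendium))
  eligible <- if (is.null(detectable)) cand$ligand
  else intersect(cand$ligand, sub("^human ", "",
                                  grep("^human ", detectable, value = TRUE)))
  combo <- .stage("condition_specific",
                  conditionSpecificLigands(contrasts, eligible, alpha,
                                           pMode))
  ## by construction the combo-specific set excludes monotherapy hits
  pcol <- if (pMode == "raw") "p_raw" else "p_bh"
  for (cc in c("brafi", "anti_vegfa")) {
    mono <- contrasts$gene[contrasts$species == "human" &
                             contrasts$condition == cc &
                             contrasts[[pcol]] < alpha]
    stopifnot(length(intersect(combo, mono)) == 0L)
  }
  ranking <- .stage("rank", rankByUpregulation(combo, contrasts))
  sig <- function(cc) {
    sub <- contrasts[contrasts$species == "human" &
                       contrasts$condition == cc, , drop = FALSE]
    sub[[pcol]][match(cand$ligand, sub$gene)] < alpha
  }
  lrCombo <- {
    sub <- contrasts[contrasts$species == "human" &
                       contrasts$condition == "combo", , drop = FALSE]
    sub$log2ratio[match(cand$ligand, sub$gene)]
  }
  cand$sig_brafi <- sig("brafi")
  cand$sig_anti_vegfa <- sig("anti_vegfa")
  cand$sig_combo <- sig("combo")
  cand$combo_log2ratio <- lrCombo
  report <- new("CrosstalkReport",
                candidates = cand,
                comboSpecific = as.character(ranking$ligand),
                nLigands = metadata(cand)$nLigands,
                nReceptors = metadata(cand)$nReceptors,
                contrasts = contrasts,
                params = list(alpha = alpha, pMode = pMode,
                              variance = variance, floor = floor,
                              scope = scope, prefilter = prefilter))
  if (!is.null(outDir)) writeCrosstalkReport(report, outDir)
  report
}

#' Write a crosstalk report to TSV files
#'
#' Writes `crosstalk_report.tsv` (candidate table),
#' `combo_specific_ligands.tsv` (ranked) and one
#' `contrasts_<species>_<condition>.tsv` per contrast family (columns
#' gene, log2ratio, p_raw, p_bh), plus a `manifest.txt` naming parameters
#' and files.
#'
#' @param report a [CrosstalkReport-class].
#' @param dir output directory (created if absent).
#' @return Invisibly, the files written.
#' @export
writeCrosstalkReport <- function(report, dir) {
  stopifnot(is(report, "CrosstalkReport"))
  .ensureDir(dir)
  files <- character()
  cand <- report@candidates
  df <- data.frame(ligand = cand$ligand,
                   receptors = vapply(cand$receptors, paste, "",
                                      collapse = ","),
                   sig_brafi = cand$sig_brafi,
                   sig_anti_vegfa = cand$sig_anti_vegfa,
                   sig_combo = cand$sig_combo,
                   combo_log2ratio = cand$combo_log2ratio)
  f <- file.path(dir, "crosstalk_report.tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  rk <- rankByUpregulation(report@comboSpecific, report@contrasts)
  rk <- data.frame(rank = seq_len(nrow(rk)), rk)
  f <- file.path(dir, "combo_specific_ligands.tsv")
  utils::write.table(rk, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)
  ct <- report@contrasts
  for (sp in unique(ct$species)) {
    for (cc in unique(ct$condition)) {
      sub <- ct[ct$species == sp & ct$condition == cc,
                c("gene", "log2ratio", "p_raw", "p_bh")]
      f <- file.path(dir, sprintf("contrasts_%s_%s.tsv", sp, cc))
      utils::write.table(sub, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
    }
  }
  .writeManifest(dir, c(report@params,
                        list(files = basename(files))))
  invisible(files)
}

#' @describeIn candidates candidate table of the report
#' @export
setMethod("candidates", "CrosstalkReport", function(x) x@candidates)

#' @describeIn comboSpecificLigands ranked combo-specific ligands
#' @export
setMethod("comboSpecificLigands", "CrosstalkReport",
          function(x) x@comboSpecific)

#' @describeIn contrastResults per-gene contrast statistics
#' @export
setMethod("contrastResults", "CrosstalkReport", function(x) x@contrasts)

#' @describeIn crosstalkCounts headline counts of the report
#' @export
setMethod("crosstalkCounts", "CrosstalkReport", function(x) {
  c(ligands = x@nLigands, receptors = x@nReceptors,
    combo_specific = length(x@comboSpecific))
})

setMethod("show", "CrosstalkReport", function(object) {
  cat(sprintf("CrosstalkReport: %d candidate ligand(s), %d distinct receptor(s)\n",
              object@nLigands, object@nReceptors))
  cs <- object@comboSpecific
  cat(sprintf("combo-specific ligand(s): %d\n", length(cs)))
  if (length(cs))
    cat(sprintf("  top-ranked: %s\n", cs[1]))
})
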