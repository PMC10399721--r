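#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generators. The
#' defaults are a scaled-down but structurally faithful stand-in for the
#' study design they emulate: a dual-species xenograft microarray with
#' four arms of 3 replicates, 1-3 probes per gene, a cross-hybridizing
#' probe subset, five ligands up-regulated (+5 log2) only in the
#' combination arm plus decoy effects in the monotherapy arms, a 60-pair
#' compendium hosting the planted pairs, and caliper cohorts started at
#' ~250 mm^3 with planted CR/DR/SR/NR response classes.
#'
#' @param seed integer RNG seed; every generator is a pure function of
#'   (config, seed).
#' @param nGenesHuman,nGenesMouse genes per compartment.
#' @param probesPerGene integer vector the per-gene probe count is drawn
#'   from uniformly.
#' @param nPerCondition replicates per arm.
#' @param baselineMean,baselineSd log2 baseline intensity distribution.
#' @param probeOffsetSd sd of per-probe baseline offsets.
#' @param noiseSd sd of independent normal noise on the log2 scale.
#' @param nPlanted number of combo-specific planted ligands.
#' @param plantedEffect log2 shift applied to planted ligands in the combo
#'   arm only.
#' @param nDecoys ligands shifted in a monotherapy arm (alternating
#'   between the two monotherapies).
#' @param decoyEffect log2 shift of decoy ligands.
#' @param crossHybFraction fraction of eligible probes flagged
#'   cross-hybridizing.
#' @param crossHybComboShift spurious log2 shift cross-hybridizing probes
#'   carry in the combo arm (what the blacklist protects against).
#' @param compendiumSize number of compendium interactions (planted +
#'   decoy pairs plus fillers over non-expressed symbols).
#' @param armSpec named list: arm label -> named integer vector of planted
#'   class counts (names among CR/DR/SR/NR).
#' @param baselineVolume tumor volume at treatment start (mm^3).
#' @param growthRate exponential growth rate per day (untreated/NR).
#' @param crDecay,drDecay,srDecay exponential decay rates per day of the
#'   CR, DR and SR phases.
#' @param drPlateau DR plateau as a fraction of baseline.
#' @param srNadirDay day (post treatment start) the SR nadir is reached.
#' @param srRegrow SR regrowth rate per day after the nadir.
#' @param detectionFloor volume (mm^3) below which a tumor is recorded as
#'   0 (no palpable tumor).
#' @param endpointVolume volume surrogate endpoint for survival records.
#' @param treatmentStartDay,studyEnd,measureEvery measurement schedule
#'   (days).
#' @param growthNoiseSd sd of multiplicative lognormal measurement noise
#'   (0 = noiseless).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nGenesHuman = 200L, nGenesMouse = 150L,
                      probesPerGene = 1:3, nPerCondition = 3L,
                      baselineMean = 7, baselineSd = 1.5,
                      probeOffsetSd = 0.5, noiseSd = 0.25,
                      nPlanted = 5L, plantedEffect = 5,
                      nDecoys = 3L, decoyEffect = 5,
                      crossHybFraction = 0.1, crossHybComboShift = 3,
                      compendiumSize = 60L,
                      armSpec = list(control = c(NR = 7L),
                                     triple = c(CR = 10L, DR = 6L, SR = 5L)),
                      baselineVolume = 250, growthRate = 0.12,
                      crDecay = 0.2, drDecay = 0.15, drPlateau = 0.35,
                      srDecay = log(2) / 12, srNadirDay = 12,
                      srRegrow = 0.08, detectionFloor = 5,
                      endpointVolume = 1500, treatmentStartDay = 9,
                      studyEnd = 60, measureEvery = 3,
                      growthNoiseSd = 0.1) {
  cfg <- as.list(environment())
  counts <- c(nGenesHuman, nGenesMouse, nPerCondition, compendiumSize)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (nPlanted < 0 || nDecoys < 0) stop("planted counts must be >= 0")
  if (crossHybFraction < 0 || crossHybFraction > 1)
    stop("crossHybFraction must be in [0, 1]")
  if (drPlateau <= 0 || drPlateau >= 1)
    stop("drPlateau must be in (0, 1)")
  if (!all(is.finite(c(plantedEffect, decoyEffect, noiseSd, baselineMean))))
    stop("effect sizes must be finite")
  if (any(probesPerGene < 1)) stop("probesPerGene must be >= 1")
  if (noiseSd < 0 || growthNoiseSd < 0) stop("noise sds must be >= 0")
  if (nPlanted + nDecoys > nGenesHuman)
    stop("more planted + decoy ligands than human genes")
  if (nPlanted + nDecoys > nGenesMouse)
    stop("not enough mouse genes to host cognate receptors")
  structure(cfg, class = "SimConfig")
}

#' Simulate a dual-species xenograft expression dataset
#'
#' Generative model per probe: gene baseline + probe offset + per-arm gene
#' effect + independent normal noise on the log2 scale. Planted ligands
#' get the effect in the combo arm only; decoys in one monotherapy arm;
#' cross-hybridizing probes (never on planted, decoy or receptor genes)
#' carry a spurious combo shift and make up the blacklist. Designated
#' receptor genes (one per planted/decoy ligand) and planted/decoy genes
#' get baselines in the clearly-expressed range, as real hits would.
#'
#' @param config a [simConfig()].
#' @return list with `se` (probe-level `SummarizedExperiment`),
#'   `blacklist` (probe ids) and `truth` (planted ligand set, decoy table,
#'   ligand -> receptor map, stroma-expressed receptor set, blacklist).
#' @export
simulateXenoExpression <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(config$seed, {
    humanGenes <- sprintf("HGN%04d", seq_len(config$nGenesHuman))
    mouseGenes <- sprintf("MGN%04d", seq_len(config$nGenesMouse))
    planted <- sample(humanGenes, config$nPlanted)
    decoys <- sample(setdiff(humanGenes, planted), config$nDecoys)
    receptors <- sample(mouseGenes, config$nPlanted + config$nDecoys)
    receptorOf <- stats::setNames(receptors, c(planted, decoys))
    decoyArm <- rep(c("brafi", "anti_vegfa"), length.out = config$nDecoys)

    genes <- c(humanGenes, mouseGenes)
    species <- rep(c("human", "mouse"),
                   c(config$nGenesHuman, config$nGenesMouse))
    baseline <- stats::rnorm(length(genes), config$baselineMean,
                             config$baselineSd)
    names(baseline) <- genes
    ## planted ligands, decoys and their receptors must sit clearly in the
    ## expressed range (the guarantee that every planted ligand has a
    ## stroma-expressed cognate receptor): baselines 2+ units above the
    ## population centre, probe offsets non-negative.
    special <- c(planted, decoys, receptors)
    baseline[special] <- config$baselineMean + 2 +
      abs(stats::rnorm(length(special), 0, config$baselineSd / 2))

    effect <- matrix(0, nrow = length(genes), ncol = 4,
                     dimnames = list(genes, .CONDITIONS))
    effect[planted, "combo"] <- config$plantedEffect
    for (i in seq_along(decoys))
      effect[decoys[i], decoyArm[i]] <- config$decoyEffect

    nProbes <- sample(config$probesPerGene, length(genes), replace = TRUE)
    gidx <- rep(seq_along(genes), nProbes)
    probeIds <- sprintf("P%05d", seq_along(gidx))
    offset <- stats::rnorm(length(gidx), 0, config$probeOffsetSd)
    offset[genes[gidx] %in% special] <- abs(offset[genes[gidx] %in% special])

    eligible <- which(!(genes[gidx] %in% special))
    nXh <- floor(config$crossHybFraction * length(gidx))
    crossHyb <- sort(sample(eligible, min(nXh, length(eligible))))
    isXh <- seq_along(gidx) %in% crossHyb

    cond <- rep(.CONDITIONS, each = config$nPerCondition)
    sampleIds <- paste(cond, rep(seq_len(config$nPerCondition), times = 4),
                       sep = "_")
    mu <- baseline[gidx] + offset
    mat <- matrix(0, nrow = length(gidx), ncol = length(cond),
                  dimnames = list(probeIds, sampleIds))
    for (j in seq_along(cond)) {
      mat[, j] <- mu + effect[cbind(gidx, match(cond[j], .CONDITIONS))] +
        ifelse(isXh & cond[j] == "combo", config$crossHybComboShift, 0) +
        stats::rnorm(length(gidx), 0, config$noiseSd)
    }
    annotation <- data.frame(probe_id = probeIds,
                             species = species[gidx],
                             gene = genes[gidx],
                             cross_hyb = as.integer(isXh),
                             stringsAsFactors = FALSE)
    samples <- data.frame(sample_id = sampleIds, condition = cond,
                          replicate = rep(seq_len(config$nPerCondition),
                                          times = 4),
                          stringsAsFactors = FALSE)
    se <- makeXenoExperiment(mat, annotation, samples, level = "probe")
    truth <- list(planted = sort(planted),
                  decoys = data.frame(gene = decoys, condition = decoyArm,
                                      stringsAsFactors = FALSE),
                  receptorOf = receptorOf,
                  stromaReceptors = sort(receptors),
                  blacklist = probeIds[isXh])
    list(se = se, blacklist = probeIds[isXh], truth = truth)
  })
}

#' Simulate a ligand-receptor compendium hosting the planted signal
#'
#' Every planted (and decoy) ligand is paired with its designated
#' stroma-expressed receptor; the remaining interactions are fillers over
#' symbols absent from the expression data, so they can never produce a
#' candidate. Pairs are split across two source tables (tags `iuphar` and
#' `dlrp`) and merged, with one planted pair present in both sources to
#' exercise provenance union.
#'
#' @param config a [simConfig()].
#' @param truth the `truth` element of [simulateXenoExpression()].
#' @return An [LRCompendium-class] of `config$compendiumSize` interactions.
#' @export
simulateCompendium <- function(config, truth) {
  stopifnot(inherits(config, "SimConfig"))
  nPlanted <- length(truth$receptorOf)
  if (config$compendiumSize < nPlanted)
    stop("compendiumSize too small to host the planted pairs")
  .withSeed(config$seed + 1L, {
    nFill <- config$compendiumSize - nPlanted
    lig <- c(names(truth$receptorOf), sprintf("FILLERL%03d", seq_len(nFill)))
    rec <- c(unname(truth$receptorOf), sprintf("FILLERR%03d", seq_len(nFill)))
    src <- rep(c("iuphar", "dlrp"), length.out = length(lig))
    t1 <- data.frame(ligand = lig[src == "iuphar"],
                     receptor = rec[src == "iuphar"], source = "iuphar",
                     stringsAsFactors = FALSE)
    t2 <- data.frame(ligand = lig[src == "dlrp"],
                     receptor = rec[src == "dlrp"], source = "dlrp",
                     stringsAsFactors = FALSE)
    if (length(lig))  # first planted pair carried by both resources
      t2 <- rbind(data.frame(ligand = lig[1], receptor = rec[1],
                             source = "dlrp", stringsAsFactors = FALSE), t2)
    mergeSources(list(t1, t2))
  })
}

## True (noise-free) volume of one mouse at day t, given class dynamics.
.trueVolume <- function(t, class, v0, cfg) {
  s <- cfg$treatmentStartDay
  if (t < s) return(v0 * exp(-cfg$growthRate * (s - t)))
  dt <- t - s
  switch(class,
         NR = v0 * exp(cfg$growthRate * dt),
         CR = v0 * exp(-cfg$crDecay * dt),
         DR = cfg$drPlateau * v0 +
           (1 - cfg$drPlateau) * v0 * exp(-cfg$drDecay * dt),
         SR = if (dt <= cfg$srNadirDay) {
           v0 * exp(-cfg$srDecay * dt)
         } else {
           v0 * exp(-cfg$srDecay * cfg$srNadirDay) *
             exp(cfg$srRegrow * (dt - cfg$srNadirDay))
         })
}

#' Simulate caliper growth cohorts with planted response classes
#'
#' Tumors grow exponentially to ~`baselineVolume` at treatment start, then
#' follow class-specific dynamics: CR decays below the detection floor
#' (recorded 0), DR decays to a plateau below baseline, SR decays to a
#' nadir then regrows past baseline, NR (and control) keep growing.
#' Observed volumes get multiplicative lognormal noise and are
#' back-converted to caliper length/width with a fixed 2:1 aspect ratio
#' (width = length / 2), making the inversion unique. Measurements stop
#' once a mouse crosses the volume surrogate endpoint, which also defines
#' its survival record (censored at study end otherwise).
#'
#' @param config a [simConfig()].
#' @return list with `growth` (mouse_id, arm, day, length_mm, width_mm,
#'   volume), `survival` (mouse_id, arm, time_days, event) and `truth`
#'   (mouse_id, arm, class, progression_day).
#' @export
simulateGrowthCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .withSeed(config$seed + 2L, {
    days <- seq(0, config$studyEnd, by = config$measureEvery)
    growth <- list()
    surv <- list()
    truth <- list()
    for (arm in names(config$armSpec)) {
      spec <- config$armSpec[[arm]]
      if (!all(names(spec) %in% c("CR", "DR", "SR", "NR")))
        stop("planted classes must be among CR, DR, SR, NR")
      classes <- rep(names(spec), spec)
      for (i in seq_along(classes)) {
        id <- sprintf("%s_%02d", arm, i)
        cls <- classes[i]
        v0 <- config$baselineVolume *
          exp(stats::rnorm(1, 0, config$growthNoiseSd))
        vTrue <- vapply(days, .trueVolume, 0, class = cls, v0 = v0,
                        cfg = config)
        vObs <- vTrue * exp(stats::rnorm(length(days), 0,
                                         config$growthNoiseSd))
        vObs[vObs < config$detectionFloor] <- 0
        crossed <- which(vObs >= config$endpointVolume)
        lastIdx <- if (length(crossed)) crossed[1] else length(days)
        keep <- seq_len(lastIdx)
        len <- (8 * vObs[keep])^(1 / 3)
        growth[[id]] <- data.frame(mouse_id = id, arm = arm,
                                   day = days[keep], length_mm = len,
                                   width_mm = len / 2,
                                   volume = vObs[keep],
                                   stringsAsFactors = FALSE)
        surv[[id]] <- data.frame(mouse_id = id, arm = arm,
                                 time_days = days[lastIdx],
                                 event = as.integer(length(crossed) > 0),
                                 stringsAsFactors = FALSE)
        truth[[id]] <- data.frame(mouse_id = id, arm = arm, class = cls,
                                  progression_day = if (length(crossed))
                                    days[crossed[1]] else NA_real_,
                                  stringsAsFactors = FALSE)
      }
    }
    g <- do.call(rbind, growth)
    rownames(g) <- NULL
    s <- do.call(rbind, surv)
    rownames(s) <- NULL
    tr <- do.call(rbind, truth)
    rownames(tr) <- NULL
    list(growth = g, survival = s, truth = tr)
  })
}

#' Write simulated inputs in the pipeline's file dialects
#'
#' Writes whatever the supplied simulation objects contain: expression
#' TSVs (`expression.tsv`, `annotation.tsv`, `samples.tsv`,
#' `blacklist.txt`, `truth_ligands.tsv`), a `compendium.tsv`, and growth
#' CSVs (`growth.csv`, `survival.csv`, `truth_growth.csv`).
#'
#' @param dir output directory (created if absent).
#' @param expression result of [simulateXenoExpression()], or `NULL`.
#' @param compendium an [LRCompendium-class], or `NULL`.
#' @param growth result of [simulateGrowthCohort()], or `NULL`.
#' @return Invisibly, `dir`.
#' @export
writeSimulatedInputs <- function(dir, expression = NULL, compendium = NULL,
                                 growth = NULL) {
  .ensureDir(dir)
  if (!is.null(expression)) {
    writeExpression(expression$se,
                    file.path(dir, "expression.tsv"),
                    file.path(dir, "annotation.tsv"),
                    file.path(dir, "samples.tsv"))
    writeLines(c("# cross-hybridizing probes", expression$blacklist),
               file.path(dir, "blacklist.txt"))
    tr <- expression$truth
    utils::write.table(
      data.frame(gene = c(tr$planted, tr$decoys$gene),
                 role = rep(c("combo_specific", "decoy"),
                            c(length(tr$planted), nrow(tr$decoys))),
                 condition = c(rep("combo", length(tr$planted)),
                               tr$decoys$condition),
                 receptor = unname(tr$receptorOf[c(tr$planted,
                                                   tr$decoys$gene)])),
      file.path(dir, "truth_ligands.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(compendium))
    writeCompendium(compendium, file.path(dir, "compendium.tsv"))
  if (!is.null(growth)) {
    utils::write.csv(growth$growth[, c("mouse_id", "arm", "day",
                                       "length_mm", "width_mm")],
                     file.path(dir, "growth.csv"), row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(growth$survival, file.path(dir, "survival.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(growth$truth, file.path(dir, "truth_growth.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
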