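## Fixture builders shared across test files. Everything is generated in
## code; no binary fixtures.

## Small deterministic replicate jitter so within-group variance is
## nonzero but negligible against planted effects.
.jit <- c(-0.1, 0, 0.1)

## Standard 12-sample sheet: 4 conditions x 3 replicates.
toySampleSheet <- function(n = 3) {
  conds <- pipelineConditions()
  data.frame(sample_id = paste(rep(conds, each = n), seq_len(n), sep = "_"),
             condition = rep(conds, each = n),
             replicate = rep(seq_len(n), times = length(conds)),
             stringsAsFactors = FALSE)
}

## Probe matrix from per-gene condition means: `means` is a named list
## gene -> numeric(4) of condition means (control, brafi, anti_vegfa,
## combo); each gene gets one probe plus `extraProbes` lower-mean probes.
toyMatrix <- function(means, samples = toySampleSheet(),
                      extraProbes = integer(length(means))) {
  rows <- list()
  ids <- character()
  for (k in seq_along(means)) {
    g <- names(means)[k]
    mu <- rep(means[[k]], each = 3) + rep(.jit, times = 4)
    rows[[length(rows) + 1L]] <- mu
    ids <- c(ids, paste0(g, "_p1"))
    for (e in seq_len(extraProbes[k])) {
      rows[[length(rows) + 1L]] <- mu - e
      ids <- c(ids, paste0(g, "_p", e + 1L))
    }
  }
  mat <- do.call(rbind, rows)
  dimnames(mat) <- list(ids, samples$sample_id)
  mat
}

toyAnnotation <- function(mat, species, genes) {
  data.frame(probe_id = rownames(mat),
             species = species, gene = genes,
             cross_hyb = 0L, stringsAsFactors = FALSE)
}

## A complete tiny crosstalk scenario with a known answer:
##   LIGA  human ligand, up only in combo          -> the true hit
##   LIGB  human ligand, up in brafi and combo     -> excluded (monotherapy)
##   LIGC  human ligand, up only in combo, but its receptor is silent
##   RECA  mouse receptor, expressed, unmodulated
##   RECB  mouse receptor, below the expression floor
toyScenario <- function() {
  means <- list(LIGA = c(5, 5, 5, 10),
                LIGB = c(5, 9, 5, 9),
                LIGC = c(5, 5, 5, 10),
                RECA = c(8, 8, 8, 8),
                RECB = c(2, 2, 2, 2))
  samples <- toySampleSheet()
  mat <- toyMatrix(means, samples, extraProbes = c(1L, 0L, 0L, 0L, 0L))
  genes <- sub("_p[0-9]+$", "", rownames(mat))
  species <- ifelse(genes %in% c("RECA", "RECB"), "mouse", "human")
  se <- makeXenoExperiment(mat, toyAnnotation(mat, species, genes), samples)
  comp <- mergeSources(list(data.frame(
    ligand = c("LIGA", "LIGB", "LIGC"),
    receptor = c("RECA", "RECA", "RECB"),
    source = "toy")))
  list(se = se, compendium = comp)
}

## Random probe-level SE for oracle comparisons.
randomProbeSE <- function(nProbes = 50, nGenes = 12, seed = 1) {
  set.seed(seed)
  samples <- toySampleSheet()
  genes <- sprintf("G%03d", sample(nGenes, nProbes, replace = TRUE))
  species <- sample(c("human", "mouse"), nProbes, replace = TRUE)
  mat <- matrix(rnorm(nProbes * nrow(samples), 7, 2), nrow = nProbes,
                dimnames = list(sprintf("P%03d", seq_len(nProbes)),
                                samples$sample_id))
  annot <- data.frame(probe_id = rownames(mat), species = species,
                      gene = genes, cross_hyb = 0L,
                      stringsAsFactors = FALSE)
  makeXenoExperiment(mat, annot, samples)
}

## Independent Benjamini-Hochberg step-up oracle (hand formula).
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

## Independent log-rank oracle: explicit observed-minus-expected table
## over pooled distinct event times.
logrankOracle <- function(timeA, eventA, timeB, eventB) {
  time <- c(timeA, timeB)
  event <- c(eventA, eventB)
  grp <- rep(c(1, 2), c(length(timeA), length(timeB)))
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    atRisk <- time >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}
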