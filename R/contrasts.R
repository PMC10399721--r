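## Two-group differential-expression engine on log2 values.
##
## Zero-variance conventions (documented, shared by the scalar and the
## vectorised paths): when the standard error is exactly zero the test is
## degenerate — p = 1 if the group means are equal (no evidence of change),
## p = 0 if they differ (the difference is exact).

.tStat <- function(m1, m2, v1, v2, n1, n2, variance) {
  lr <- m1 - m2
  if (variance == "pooled") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    a <- v1 / n1
    b <- v2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  p <- ifelse(se == 0, ifelse(lr == 0, 1, 0),
              2 * stats::pt(-abs(lr / se), df))
  list(log2ratio = lr, p_raw = unname(p))
}

#' Two-group contrast on log2 expression values
#'
#' Computes the log2 ratio (mean treated minus mean control) and a
#' two-sided t-test p-value, with pooled (Student) variance by default or
#' Welch on request.
#'
#' @param treated,control numeric vectors of log2 values, each of length
#'   at least 2.
#' @param variance `"pooled"` (default) or `"welch"`.
#' @return Named list with `log2ratio` and `p_raw`.
#' @export
#' @examples
#' twoGroupContrast(c(2.8, 3.0, 3.2), c(0.8, 1.0, 1.2))
twoGroupContrast <- function(treated, control,
                             variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  if (length(treated) < 2L || length(control) < 2L)
    stop("each group needs at least 2 values")
  if (anyNA(treated) || anyNA(control)) stop("missing values not allowed")
  .tStat(mean(treated), mean(control), stats::var(treated),
         stats::var(control), length(treated), length(control), variance)
}

## Vectorised per-row contrast of one condition against control.
.rowContrast <- function(x, cols1, cols2, variance) {
  n1 <- length(cols1)
  n2 <- length(cols2)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 replicates")
  x1 <- x[, cols1, drop = FALSE]
  x2 <- x[, cols2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  st <- .tStat(m1, m2, v1, v2, n1, n2, variance)
  data.frame(log2ratio = st$log2ratio, p_raw = st$p_raw,
             row.names = rownames(x))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; values are returned in input
#' order, are elementwise at least the raw values and are capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
bhAdjust <- function(p) {
  .checkProb(p)
  stats::p.adjust(p, method = "BH")
}

#' Per-gene contrast table across treated conditions
#'
#' Runs the two-group engine for every row against the control arm, one
#' treated condition at a time, and BH-adjusts within each species x
#' condition family (mirroring one supplementary table per species and
#' contrast).
#'
#' @param se probe- or gene-level `SummarizedExperiment`.
#' @param variance `"pooled"` or `"welch"`.
#' @param conditions treated conditions to contrast (default all three).
#' @return data.frame with columns `gene`, `species`, `condition`,
#'   `log2ratio`, `p_raw`, `p_bh`.
#' @export
contrastTable <- function(se, variance = c("pooled", "welch"),
                          conditions = c("brafi", "anti_vegfa", "combo")) {
  variance <- match.arg(variance)
  stopifnot(all(conditions %in% .TREATED))
  cond <- as.character(colData(se)$condition)
  ctrl <- which(cond == "control")
  if (!length(ctrl)) stop("no control samples present")
  x <- assay(se)
  rd <- rowData(se)
  out <- vector("list", length(conditions))
  for (k in seq_along(conditions)) {
    cc <- conditions[k]
    trt <- which(cond == cc)
    if (!length(trt)) stop(sprintf("no samples for condition '%s'", cc))
    st <- .rowContrast(x, trt, ctrl, variance)
    df <- data.frame(gene = as.character(rd$gene),
                     species = as.character(rd$species),
                     condition = cc,
                     log2ratio = st$log2ratio,
                     p_raw = st$p_raw,
                     p_bh = NA_real_,
                     row.names = NULL)
    for (sp in unique(df$species)) {
      i <- df$species == sp
      df$p_bh[i] <- bhAdjust(df$p_raw[i])
    }
    out[[k]] <- df
  }
  do.call(rbind, out)
}

#' Per-probe raw p-values for the significance prefilter
#'
#' @param se probe-level `SummarizedExperiment`.
#' @param variance `"pooled"` or `"welch"`.
#' @return Numeric matrix, probes x treated conditions, of raw p-values.
#' @export
probePvalues <- function(se, variance = c("pooled", "welch")) {
  variance <- match.arg(variance)
  cond <- as.character(colData(se)$condition)
  ctrl <- which(cond == "control")
  if (!length(ctrl)) stop("no control samples present")
  x <- assay(se)
  p <- vapply(.TREATED, function(cc) {
    .rowContrast(x, which(cond == cc), ctrl, variance)$p_raw
  }, numeric(nrow(x)))
  p <- matrix(p, nrow = nrow(x),
              dimnames = list(rownames(x), .TREATED))
  p
}

#' Ligands regulated only in one target condition
#'
#' A ligand is condition-specific iff its p-value is below `alpha` in the
#' target condition and at or above `alpha` in both other treated
#' conditions. `pMode` selects raw or BH-adjusted p-values; raw matches the
#' probe-prefilter threshold style, BH is the genome-scale setting used for
#' planted-signal recovery.
#'
#' @param contrasts data.frame from [contrastTable()].
#' @param ligands character vector of (human) candidate ligand symbols.
#' @param alpha significance threshold.
#' @param pMode `"raw"` or `"bh"`.
#' @param target target condition (default `"combo"`).
#' @param species compartment whose genes are tested (default `"human"`).
#' @return Character vector of condition-specific ligands, in `ligands`
#'   order.
#' @export
conditionSpecificLigands <- function(contrasts, ligands, alpha = 0.05,
                                     pMode = c("raw", "bh"),
                                     target = "combo", species = "human") {
  pMode <- match.arg(pMode)
  target <- match.arg(target, .TREATED)
  pcol <- if (pMode == "raw") "p_raw" else "p_bh"
  sub <- contrasts[contrasts$species == species &
                     contrasts$gene %in% ligands, , drop = FALSE]
  keep <- logical(length(ligands))
  others <- setdiff(.TREATED, target)
  for (i in seq_along(ligands)) {
    rows <- sub[sub$gene == ligands[i], , drop = FALSE]
    if (!all(.TREATED %in% rows$condition))
      stop(sprintf("ligand '%s' lacks a result for every treated condition",
                   ligands[i]))
    p <- rows[[pcol]][match(.TREATED, rows$condition)]
    names(p) <- .TREATED
    keep[i] <- p[[target]] < alpha && all(p[others] >= alpha)
  }
  ligands[keep]
}
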