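#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData rowData<- colData<-
#' @importFrom S4Vectors metadata metadata<-
NULL

#' Build a dual-species expression container
#'
#' Wraps a log2 intensity matrix, its probe annotation and a sample sheet
#' into a `SummarizedExperiment` (assay `"log2"`) tagged with its
#' quantification level (`"probe"` or `"gene"`). Columns are reordered to
#' sample-sheet order; all values must be finite.
#'
#' @param mat numeric matrix of log2 intensities, rownames = probe ids (or
#'   gene ids at gene level), colnames = sample ids.
#' @param annotation data.frame with columns `probe_id`, `species`, `gene`
#'   and optionally `cross_hyb` (0/1), one row per row of `mat`.
#' @param samples data.frame with columns `sample_id`, `condition`
#'   (one of `r paste(pipelineConditions(), collapse = ", ")`), `replicate`.
#' @param level `"probe"` or `"gene"`.
#' @return A `SummarizedExperiment`.
#' @export
makeXenoExperiment <- function(mat, annotation, samples, level = "probe") {
  level <- match.arg(level, c("probe", "gene"))
  mat <- as.matrix(mat)
  if (!is.numeric(mat) || anyNA(mat) || any(!is.finite(mat)))
    stop("expression values must all be finite numbers")
  if (anyDuplicated(rownames(mat))) stop("row ids must be unique")
  if (anyDuplicated(samples$sample_id)) stop("sample_ids must be unique")
  missing <- setdiff(colnames(mat), samples$sample_id)
  if (length(missing))
    stop(sprintf("sample(s) in matrix missing from sample sheet: %s",
                 paste(missing, collapse = ", ")))
  absent <- setdiff(samples$sample_id, colnames(mat))
  if (length(absent))
    stop(sprintf("sample(s) in sheet missing from matrix: %s",
                 paste(absent, collapse = ", ")))
  mat <- mat[, samples$sample_id, drop = FALSE]
  if (!all(samples$condition %in% .CONDITIONS))
    stop(sprintf("conditions must be among: %s",
                 paste(.CONDITIONS, collapse = ", ")))
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  m <- match(rownames(mat), annotation$probe_id)
  if (anyNA(m)) stop("every matrix row needs an annotation row")
  rd <- DataFrame(probe_id = annotation$probe_id[m],
                  species = annotation$species[m],
                  gene = annotation$gene[m])
  rd$cross_hyb <- if ("cross_hyb" %in% names(annotation)) {
    as.logical(annotation$cross_hyb[m])
  } else FALSE
  if (!all(rd$species %in% c("human", "mouse")))
    stop("species must be 'human' or 'mouse'")
  cd <- DataFrame(sample_id = samples$sample_id,
                  condition = factor(samples$condition, levels = .CONDITIONS),
                  replicate = samples$replicate,
                  row.names = samples$sample_id)
  se <- SummarizedExperiment(assays = list(log2 = mat),
                             rowData = rd, colData = cd)
  metadata(se)$level <- level
  se
}

#' Quantification level of an expression container
#'
#' @param se a `SummarizedExperiment` built by this package.
#' @return `"probe"` or `"gene"`.
#' @export
exprLevel <- function(se) {
  lv <- metadata(se)$level
  if (is.null(lv)) "probe" else lv
}

#' Load probe-level expression data from TSV files
#'
#' Joins an expression matrix to its probe annotation and sample sheet.
#' Probes without an annotation row are dropped (count reported via
#' `message()`); probes annotated to several genes (`;`-separated) are
#' duplicated into one row per gene so the per-gene collapse rule applies.
#'
#' File dialects (tab-separated, header required):
#' \itemize{
#'   \item expression: first column `probe_id`, remaining columns sample
#'     ids, log2 values;
#'   \item annotation: `probe_id`, `species`, `gene`, optional `cross_hyb`;
#'   \item sample sheet: `sample_id`, `condition`, `replicate`.
#' }
#'
#' @param exprFile,annotFile,sampleFile file paths.
#' @return A probe-level `SummarizedExperiment`.
#' @export
loadExpression <- function(exprFile, annotFile, sampleFile) {
  raw <- utils::read.delim(exprFile, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(raw)[1] != "probe_id")
    stop("expression file must start with a 'probe_id' column")
  ids <- as.character(raw[[1]])
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric expression value at probe '%s', sample '%s'",
                   ids[i], names(vals)[j]))
    }
    vals[[j]] <- v
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  annot <- utils::read.delim(annotFile, stringsAsFactors = FALSE)
  samples <- utils::read.delim(sampleFile, stringsAsFactors = FALSE)
  keep <- rownames(mat) %in% annot$probe_id
  if (any(!keep)) {
    message(sprintf("dropped %d unannotated probe(s)", sum(!keep)))
    mat <- mat[keep, , drop = FALSE]
  }
  ## expand multi-gene probes into one row per gene
  m <- match(rownames(mat), annot$probe_id)
  genes <- strsplit(as.character(annot$gene[m]), ";", fixed = TRUE)
  nper <- lengths(genes)
  if (any(nper > 1L)) {
    message(sprintf("duplicated %d multi-gene probe(s) into per-gene rows",
                    sum(nper > 1L)))
    idx <- rep(seq_len(nrow(mat)), nper)
    newIds <- ifelse(rep(nper, nper) > 1L,
                     paste0(rownames(mat)[idx], "|", unlist(genes)),
                     rownames(mat)[idx])
    annot <- data.frame(probe_id = newIds,
                        species = annot$species[m][idx],
                        gene = unlist(genes),
                        cross_hyb = if ("cross_hyb" %in% names(annot))
                          annot$cross_hyb[m][idx] else 0L,
                        stringsAsFactors = FALSE)
    mat <- mat[idx, , drop = FALSE]
    rownames(mat) <- newIds
  } else {
    annot <- data.frame(probe_id = rownames(mat),
                        species = annot$species[m],
                        gene = unlist(genes),
                        cross_hyb = if ("cross_hyb" %in% names(annot))
                          annot$cross_hyb[m] else 0L,
                        stringsAsFactors = FALSE)
  }
  bad <- is.na(annot$gene) | !nzchar(annot$gene)
  if (any(bad)) {
    message(sprintf("dropped %d probe(s) without a gene symbol", sum(bad)))
    mat <- mat[!bad, , drop = FALSE]
    annot <- annot[!bad, , drop = FALSE]
  }
  makeXenoExperiment(mat, annot, samples, level = "probe")
}

#' Write an expression container back to the TSV dialect
#'
#' @param se a `SummarizedExperiment`.
#' @param exprFile,annotFile,sampleFile output paths (any may be `NULL`
#'   to skip).
#' @return Invisibly, the paths written.
#' @export
writeExpression <- function(se, exprFile = NULL, annotFile = NULL,
                            sampleFile = NULL) {
  if (!is.null(exprFile)) {
    ## %.17g keeps the round trip bit-identical for doubles
    vals <- apply(assay(se), 2, function(x) sprintf("%.17g", x))
    vals <- matrix(vals, nrow = nrow(se))
    df <- data.frame(probe_id = rownames(se), vals, check.names = FALSE)
    names(df)[-1] <- colnames(se)
    utils::write.table(df, exprFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(annotFile)) {
    rd <- as.data.frame(rowData(se))
    rd$cross_hyb <- as.integer(rd$cross_hyb)
    utils::write.table(rd, annotFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(sampleFile)) {
    cd <- as.data.frame(colData(se))
    utils::write.table(cd, sampleFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(exprFile, annotFile, sampleFile))
}

#' Read a probe blacklist
#'
#' Plain text, one probe id per line, `#` comments and blank lines allowed.
#'
#' @param path file path.
#' @return Character vector of probe ids.
#' @export
readBlacklist <- function(path) {
  x <- trimws(readLines(path))
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Probe significance prefilter
#'
#' A probe is retained iff its raw p-value is strictly below `alpha` in at
#' least one treated-vs-control contrast ("at least one experimental
#' condition with p below the threshold"); a probe exactly at `alpha` in
#' every contrast is dropped.
#'
#' @param p numeric matrix of raw p-values, probes x treated conditions.
#' @param alpha significance threshold (default 0.05).
#' @return Named logical vector of retention flags (names = rownames of
#'   `p`).
#' @export
significancePrefilter <- function(p, alpha = 0.05) {
  p <- as.matrix(p)
  .checkProb(p)
  keep <- apply(p, 1L, function(x) any(x < alpha))
  names(keep) <- rownames(p)
  keep
}

#' Remove cross-hybridizing probes
#'
#' Drops rows whose probe id is on the blacklist; all other rows and values
#' are untouched. Blacklist ids absent from the matrix are ignored (count
#' reported via `message()`).
#'
#' @param se probe-level `SummarizedExperiment`.
#' @param blacklist character vector of probe ids.
#' @return The filtered `SummarizedExperiment`.
#' @export
removeCrossHybridizing <- function(se, blacklist) {
  if (exprLevel(se) != "probe")
    stop("cross-hybridizing removal applies to probe-level data")
  blacklist <- unique(as.character(blacklist))
  unseen <- setdiff(blacklist, rownames(se))
  if (length(unseen))
    message(sprintf("%d blacklist id(s) not present in the matrix",
                    length(unseen)))
  se[!(rownames(se) %in% blacklist), ]
}

#' Collapse probes to genes by largest mean expression
#'
#' For each (species, gene), keeps the single probe with the largest mean
#' expression across all samples; values are copied unchanged from that
#' probe. Ties are broken by lexicographically smallest probe id. Row names
#' of the result are `species:gene`.
#'
#' @param se probe-level `SummarizedExperiment` with annotated genes.
#' @return Gene-level `SummarizedExperiment`.
#' @export
collapseToGenes <- function(se) {
  if (exprLevel(se) != "probe") stop("input must be probe level")
  rd <- rowData(se)
  if (any(is.na(rd$gene) | !nzchar(rd$gene)))
    stop("every probe must be annotated with a gene before collapse")
  if (nrow(se) == 0L) {
    out <- se
    metadata(out)$level <- "gene"
    return(out)
  }
  mu <- rowMeans(assay(se))
  ord <- order(rd$species, rd$gene, -mu, rd$probe_id, method = "radix")
  firstOfGroup <- !duplicated(paste(rd$species, rd$gene, sep = "\r")[ord])
  pick <- ord[firstOfGroup]
  out <- se[pick, ]
  rownames(out) <- paste(rowData(out)$species, rowData(out)$gene, sep = ":")
  metadata(out)$level <- "gene"
  out
}

#' Call genes expressed
#'
#' A gene is called expressed iff its mean log2 intensity within at least
#' one condition in `scope` is at or above `floor`. The default floor
#' (`"auto"`) is the per-species median of gene-level mean intensities — a
#' relative, platform-independent cutoff; `scope` defaults to all four
#' conditions.
#'
#' @param se gene-level `SummarizedExperiment`.
#' @param floor numeric log2 intensity, or `"auto"`.
#' @param scope character vector of conditions to scan (non-empty).
#' @return `DataFrame` with one row per gene: `species`, `gene`,
#'   `mean_intensity`, `max_condition_mean`, `floor`, `expressed`.
#' @export
expressionCall <- function(se, floor = "auto", scope = pipelineConditions()) {
  if (exprLevel(se) != "gene") stop("expression calls require gene level")
  if (length(scope) == 0L) stop("scope must name at least one condition")
  if (!all(scope %in% .CONDITIONS))
    stop("scope conditions must be among the pipeline conditions")
  cond <- as.character(colData(se)$condition)
  x <- assay(se)
  condMeans <- vapply(scope, function(cc) {
    cols <- which(cond == cc)
    if (!length(cols)) return(rep(-Inf, nrow(x)))
    rowMeans(x[, cols, drop = FALSE])
  }, numeric(nrow(x)))
  condMeans <- matrix(condMeans, nrow = nrow(x))
  maxCond <- if (nrow(x)) apply(condMeans, 1L, max) else numeric()
  overall <- if (nrow(x)) rowMeans(x) else numeric()
  rd <- rowData(se)
  if (identical(floor, "auto")) {
    fl <- rep(NA_real_, nrow(x))
    for (sp in unique(rd$species)) {
      i <- rd$species == sp
      fl[i] <- stats::median(overall[i])
    }
  } else {
    stopifnot(is.numeric(floor), length(floor) == 1L)
    fl <- rep(as.numeric(floor), nrow(x))
  }
  DataFrame(species = rd$species, gene = rd$gene,
            mean_intensity = overall, max_condition_mean = maxCond,
            floor = fl, expressed = maxCond >= fl,
            row.names = rownames(se))
}

#' Expressed gene symbols of one species
#'
#' @param call `DataFrame` from [expressionCall()].
#' @param species `"human"` or `"mouse"`.
#' @return Character vector of expressed gene symbols.
#' @export
expressedGenes <- function(call, species) {
  species <- match.arg(species, c("human", "mouse"))
  as.character(call$gene[call$species == species & call$expressed])
}
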