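#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
NULL

#' SymbolMap: cross-species gene-symbol harmonization table
#'
#' Maps raw, species-qualified gene symbols onto canonical species-agnostic
#' symbols. Resolution is total: an explicit `(raw, species)` entry wins,
#' otherwise the raw symbol is uppercased (the usual human/mouse symbol-case
#' convention, e.g. mouse `Csf2` and human `CSF2` both map to `CSF2`).
#' Canonical symbols are required to be uppercase so the mapping is
#' idempotent.
#'
#' @slot entries data.frame with columns `raw`, `species`, `canonical`.
#' @seealso [normalizeSymbol()], [readSymbolMap()]
#' @export
setClass("SymbolMap", representation(entries = "data.frame"))

setValidity("SymbolMap", function(object) {
  e <- object@entries
  msgs <- character()
  need <- c("raw", "species", "canonical")
  if (!all(need %in% names(e))) {
    return(sprintf("entries must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(e)) {
    if (any(!nzchar(e$raw)) || any(!nzchar(e$canonical)))
      msgs <- c(msgs, "raw and canonical symbols must be non-empty")
    if (!all(e$species %in% c("human", "mouse")))
      msgs <- c(msgs, "species must be 'human' or 'mouse'")
    if (anyDuplicated(paste(e$raw, e$species)))
      msgs <- c(msgs, "duplicate (raw, species) entries")
    if (any(e$canonical != toupper(e$canonical)))
      msgs <- c(msgs, "canonical symbols must be uppercase (idempotence)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SymbolMap
#'
#' @param entries data.frame with columns `raw`, `species`, `canonical`;
#'   defaults to an empty table (pure uppercase rule).
#' @return A [SymbolMap-class] object.
#' @export
#' @examples
#' m <- SymbolMap(data.frame(raw = "Csf2ra", species = "mouse",
#'                           canonical = "CSF2RA"))
#' normalizeSymbol("Csf2ra", "mouse", m)
SymbolMap <- function(entries = data.frame(raw = character(),
                                           species = character(),
                                           canonical = character())) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  new("SymbolMap", entries = entries)
}

#' LRCompendium: directional ligand-receptor interaction compendium
#'
#' A deduplicated, ordered collection of directional ligand -> receptor gene
#' pairs with source provenance, in the spirit of compendia assembled from
#' IUPHAR and DLRP. Direction matters: A->B and B->A are distinct
#' interactions, because the analysis asks specifically for tumor-derived
#' ligands binding stroma-expressed receptors. Both query indices are
#' derived from (and validated against) the interaction table.
#'
#' @slot interactions `DataFrame` with columns `ligand`, `receptor` and a
#'   `CharacterList` column `sources`; one row per unique (ligand, receptor)
#'   pair, in first-occurrence order.
#' @slot ligandIndex named list: ligand -> character vector of receptors.
#' @slot receptorIndex named list: receptor -> character vector of ligands.
#' @seealso [mergeSources()], [receptorsOf()], [readCompendium()]
#' @export
setClass("LRCompendium",
         representation(interactions = "DataFrame",
                        ligandIndex = "list",
                        receptorIndex = "list"))

.buildLigandIndex <- function(ligand, receptor) {
  lapply(split(receptor, factor(ligand, levels = unique(ligand))),
         function(r) sort(unique(r)))
}

setValidity("LRCompendium", function(object) {
  it <- object@interactions
  msgs <- character()
  need <- c("ligand", "receptor", "sources")
  if (!all(need %in% colnames(it)))
    return(sprintf("interactions must have columns %s",
                   paste(need, collapse = ", ")))
  if (nrow(it)) {
    if (any(!nzchar(it$ligand)) || any(!nzchar(it$receptor)))
      msgs <- c(msgs, "ligand and receptor symbols must be non-empty")
    if (anyDuplicated(paste(it$ligand, it$receptor)))
      msgs <- c(msgs, "duplicate (ligand, receptor) pair")
    if (any(lengths(it$sources) == 0L))
      msgs <- c(msgs, "every interaction needs at least one source tag")
  }
  li <- .buildLigandIndex(it$ligand, it$receptor)
  ri <- .buildLigandIndex(it$receptor, it$ligand)
  if (!identical(object@ligandIndex, li))
    msgs <- c(msgs, "ligandIndex is not derivable from the interaction list")
  if (!identical(object@receptorIndex, ri))
    msgs <- c(msgs, "receptorIndex is not derivable from the interaction list")
  if (length(msgs)) msgs else TRUE
})

#' CrosstalkReport: result container for the crosstalk pipeline
#'
#' Produced by [runCrosstalk()]. Holds the candidate tumor-ligand /
#' stroma-receptor table, the headline counts, the ranked list of ligands
#' regulated only under combination therapy, and the full per-gene contrast
#' statistics used to derive them.
#'
#' @slot candidates `DataFrame`: one row per candidate ligand with its
#'   stroma-expressed receptors (`CharacterList`), per-condition
#'   significance flags and combination-arm log2 ratio.
#' @slot comboSpecific character: ligands significant only in the
#'   combination arm, ranked by descending combo log2 ratio.
#' @slot nLigands,nReceptors integer: candidate ligand count and distinct
#'   receptor count.
#' @slot contrasts data.frame of per-gene contrast statistics
#'   (gene, species, condition, log2ratio, p_raw, p_bh).
#' @slot params list of the analysis parameters used.
#' @export
setClass("CrosstalkReport",
         representation(candidates = "DataFrame",
                        comboSpecific = "character",
                        nLigands = "integer",
                        nReceptors = "integer",
                        contrasts = "data.frame",
                        params = "list"))

setValidity("CrosstalkReport", function(object) {
  msgs <- character()
  if (!all(object@comboSpecific %in% object@candidates$ligand))
    msgs <- c(msgs, "combo-specific ligands must be a subset of candidates")
  if (length(msgs)) msgs else TRUE
})
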