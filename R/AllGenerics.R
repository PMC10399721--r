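#' Interaction table of a compendium
#'
#' @param x an [LRCompendium-class].
#' @return `DataFrame` of interactions (`ligand`, `receptor`, `sources`).
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' Receptors of a ligand
#'
#' @param x an [LRCompendium-class].
#' @param ligand canonical ligand symbol (length 1).
#' @return Sorted character vector of receptor symbols; empty for an
#'   unknown ligand.
#' @export
setGeneric("receptorsOf", function(x, ligand) standardGeneric("receptorsOf"))

#' Ligands of a receptor
#'
#' @param x an [LRCompendium-class].
#' @param receptor canonical receptor symbol (length 1).
#' @return Sorted character vector of ligand symbols; empty for an unknown
#'   receptor.
#' @export
setGeneric("ligandsOf", function(x, receptor) standardGeneric("ligandsOf"))

#' Candidate crosstalk table of a report
#'
#' @param x a [CrosstalkReport-class].
#' @return `DataFrame` of candidate ligands with receptor sets, significance
#'   flags and combo log2 ratios.
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))

#' Combination-therapy-specific ligands of a report
#'
#' @param x a [CrosstalkReport-class].
#' @return Character vector, ranked by descending combination-arm log2
#'   ratio; the first element is the headline ligand.
#' @export
setGeneric("comboSpecificLigands",
           function(x) standardGeneric("comboSpecificLigands"))

#' Per-gene contrast statistics of a report
#'
#' @param x a [CrosstalkReport-class].
#' @return data.frame with columns gene, species, condition, log2ratio,
#'   p_raw, p_bh.
#' @export
setGeneric("contrastResults", function(x) standardGeneric("contrastResults"))

#' Headline crosstalk counts
#'
#' @param x a [CrosstalkReport-class].
#' @return Named integer vector: candidate `ligands`, distinct `receptors`,
#'   and `combo_specific` ligand count.
#' @export
setGeneric("crosstalkCounts", function(x) standardGeneric("crosstalkCounts"))
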