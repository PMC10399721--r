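#' Normalize a gene symbol to its canonical cross-species form
#'
#' Resolution is total and deterministic: an explicit `(raw, species)`
#' entry in `map` wins; otherwise the raw symbol is uppercased. Mapping a
#' canonical symbol returns itself.
#'
#' @param raw character vector of raw gene symbols (non-empty strings).
#' @param species `"human"` or `"mouse"` (scalar or vector matching `raw`).
#' @param map a [SymbolMap-class]; defaults to the pure uppercase rule.
#' @return Character vector of canonical symbols.
#' @export
#' @examples
#' normalizeSymbol("Csf2", "mouse")   # "CSF2"
#' normalizeSymbol("CSF2", "human")   # idempotent
normalizeSymbol <- function(raw, species, map = SymbolMap()) {
  stopifnot(is(map, "SymbolMap"))
  if (length(raw) == 0L) return(character())
  if (!is.character(raw) || anyNA(raw) || any(!nzchar(raw)))
    stop("gene symbols must be non-empty strings")
  species <- rep_len(species, length(raw))
  if (!all(species %in% c("human", "mouse")))
    stop("species must be 'human' or 'mouse'")
  out <- toupper(raw)
  e <- map@entries
  if (nrow(e)) {
    key <- paste(raw, species, sep = "\r")
    hit <- match(key, paste(e$raw, e$species, sep = "\r"))
    out[!is.na(hit)] <- e$canonical[hit[!is.na(hit)]]
  }
  out
}

#' Read a symbol-harmonization table
#'
#' TSV dialect: header row with columns `raw`, `species`, `canonical`.
#'
#' @param path file path.
#' @return A [SymbolMap-class].
#' @export
readSymbolMap <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  SymbolMap(e[, c("raw", "species", "canonical")])
}

.newCompendium <- function(ligand, receptor, sources) {
  it <- DataFrame(ligand = as.character(ligand),
                  receptor = as.character(receptor),
                  sources = as(sources, "CharacterList"))
  new("LRCompendium",
      interactions = it,
      ligandIndex = .buildLigandIndex(it$ligand, it$receptor),
      receptorIndex = .buildLigandIndex(it$receptor, it$ligand))
}

#' Assemble a ligand-receptor compendium from source tables
#'
#' Merges one or more raw interaction tables (e.g. exports of IUPHAR-style
#' and DLRP-style resources) into a deduplicated directional compendium.
#' Symbols are harmonized through `map` (ligands as tumor/`ligandSpecies`
#' symbols, receptors as stroma/`receptorSpecies` symbols); duplicate
#' (ligand, receptor) pairs are collapsed into a single interaction whose
#' source set is the union of the contributing tags; interaction order is
#' first occurrence. Rows with a missing ligand or receptor are rejected
#' with a warning, not an error.
#'
#' @param tables list of data.frames with columns `ligand`, `receptor`,
#'   `source`.
#' @param map a [SymbolMap-class] used for harmonization.
#' @param ligandSpecies,receptorSpecies species under which ligand and
#'   receptor symbols are resolved (defaults: human ligands, mouse
#'   receptors, the xenograft orientation).
#' @return An [LRCompendium-class].
#' @export
#' @examples
#' a <- data.frame(ligand = "CSF2", receptor = c("CSF2RA", "CSF2RB"),
#'                 source = "iuphar")
#' b <- data.frame(ligand = "CSF2", receptor = "CSF2RA", source = "dlrp")
#' mergeSources(list(a, b))
mergeSources <- function(tables, map = SymbolMap(),
                         ligandSpecies = "human", receptorSpecies = "mouse") {
  stopifnot(is.list(tables))
  lig <- rec <- src <- character()
  for (tb in tables) {
    tb <- as.data.frame(tb, stringsAsFactors = FALSE)
    if (!all(c("ligand", "receptor", "source") %in% names(tb)))
      stop("each source table needs columns ligand, receptor, source")
    bad <- is.na(tb$ligand) | !nzchar(trimws(as.character(tb$ligand))) |
      is.na(tb$receptor) | !nzchar(trimws(as.character(tb$receptor)))
    if (any(bad)) {
      warning(sprintf("rejected %d row(s) with missing ligand or receptor",
                      sum(bad)))
      tb <- tb[!bad, , drop = FALSE]
    }
    if (!nrow(tb)) next
    lig <- c(lig, normalizeSymbol(as.character(tb$ligand), ligandSpecies, map))
    rec <- c(rec, normalizeSymbol(as.character(tb$receptor), receptorSpecies,
                                  map))
    src <- c(src, as.character(tb$source))
  }
  if (!length(lig)) {
    return(.newCompendium(character(), character(), CharacterList()))
  }
  key <- paste(lig, rec, sep = "\r")
  first <- !duplicated(key)
  srcSets <- lapply(split(src, factor(key, levels = key[first])),
                    function(s) sort(unique(s)))
  .newCompendium(lig[first], rec[first], srcSets)
}

#' Read a compendium TSV
#'
#' TSV dialect: header row with columns `ligand`, `receptor`, `source`; one
#' interaction per line. Duplicate pairs across lines are merged.
#'
#' @param path file path.
#' @inheritParams mergeSources
#' @return An [LRCompendium-class].
#' @export
readCompendium <- function(path, map = SymbolMap(),
                           ligandSpecies = "human",
                           receptorSpecies = "mouse") {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  mergeSources(list(tb), map, ligandSpecies, receptorSpecies)
}

#' Write a compendium TSV
#'
#' @param x an [LRCompendium-class].
#' @param path output file; multi-source interactions join tags with `;`.
#' @return Invisibly, `path`.
#' @export
writeCompendium <- function(x, path) {
  stopifnot(is(x, "LRCompendium"))
  it <- x@interactions
  df <- data.frame(ligand = it$ligand, receptor = it$receptor,
                   source = vapply(it$sources, paste, "", collapse = ";"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn interactions interaction table of the compendium
#' @export
setMethod("interactions", "LRCompendium", function(x) x@interactions)

#' @describeIn receptorsOf receptors paired with `ligand`
#' @export
setMethod("receptorsOf", "LRCompendium", function(x, ligand) {
  stopifnot(length(ligand) == 1L)
  r <- x@ligandIndex[[ligand]]
  if (is.null(r)) character() else r
})

#' @describeIn ligandsOf ligands paired with `receptor`
#' @export
setMethod("ligandsOf", "LRCompendium", function(x, receptor) {
  stopifnot(length(receptor) == 1L)
  l <- x@receptorIndex[[receptor]]
  if (is.null(l)) character() else l
})

#' @describeIn LRCompendium number of interactions
#' @export
setMethod("length", "LRCompendium", function(x) nrow(x@interactions))

setMethod("show", "LRCompendium", function(object) {
  it <- object@interactions
  cat(sprintf("LRCompendium with %d directional interaction(s): %d ligand(s), %d receptor(s)\n",
              nrow(it), length(unique(it$ligand)),
              length(unique(it$receptor))))
  if (nrow(it)) {
    n <- min(5L, nrow(it))
    for (i in seq_len(n)) {
      cat(sprintf("  %s -> %s [%s]\n", it$ligand[i], it$receptor[i],
                  paste(it$sources[[i]], collapse = ",")))
    }
    if (nrow(it) > n) cat(sprintf("  ... and %d more\n", nrow(it) - n))
  }
})
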