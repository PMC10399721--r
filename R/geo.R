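#' Parse a GEO series-matrix file (offline)
#'
#' Minimal importer for the series-matrix text format distributed by the
#' Gene Expression Omnibus, supporting the optional real-data input mode
#' (e.g. the A375 xenograft series GSE69754, downloaded separately by the
#' user). Parse-only: no network access. Metadata lines start with `!`;
#' the expression table sits between `!series_matrix_table_begin` and
#' `!series_matrix_table_end`, with quoted sample accessions as column
#' headers.
#'
#' To analyze such a series with [runCrosstalk()], pair the returned
#' matrix with a user-supplied probe annotation (probe -> species ->
#' gene), a cross-hybridization blacklist and a sample sheet mapping the
#' GEO samples onto the four arm labels, then build the container with
#' [makeXenoExperiment()].
#'
#' @param path path to an uncompressed series-matrix file.
#' @return list with `matrix` (numeric, probes x samples) and `samples`
#'   (data.frame with `accession` and `title` when present).
#' @export
readSeriesMatrix <- function(path) {
  lines <- readLines(path)
  unquote <- function(x) gsub('^"|"$', "", x)
  grab <- function(tag) {
    hit <- grep(paste0("^!", tag, "\t"), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    unquote(strsplit(hit[1], "\t", fixed = TRUE)[[1]][-1])
  }
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L)
    stop("no series-matrix table found")
  tbl <- lines[(begin + 1L):(end - 1L)]
  header <- unquote(strsplit(tbl[1], "\t", fixed = TRUE)[[1]])
  rows <- strsplit(tbl[-1], "\t", fixed = TRUE)
  ids <- unquote(vapply(rows, `[`, "", 1L))
  mat <- matrix(NA_real_, nrow = length(rows), ncol = length(header) - 1L,
                dimnames = list(ids, header[-1]))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][-1]))
    mat[i, ] <- v
  }
  accession <- colnames(mat)
  title <- grab("Sample_title")
  samples <- data.frame(accession = accession,
                        title = if (is.null(title)) NA_character_ else title,
                        stringsAsFactors = FALSE)
  list(matrix = mat, samples = samples)
}
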