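## Internal helpers shared across the package.

## Treatment-arm vocabulary used throughout: an untreated control, two
## monotherapies (BRAF inhibitor, anti-VEGFA antibody) and their combination.
.CONDITIONS <- c("control", "brafi", "anti_vegfa", "combo")
.TREATED <- c("brafi", "anti_vegfa", "combo")

#' Arm labels used by the pipeline
#'
#' @return Character vector of the four condition labels in canonical order
#'   (`control`, `brafi`, `anti_vegfa`, `combo`).
#' @export
#' @examples
#' pipelineConditions()
pipelineConditions <- function() .CONDITIONS

#' Round half away from zero
#'
#' Percentages in arm summaries are rendered with half-away-from-zero
#' rounding (so 0.5 rounds to 1, -0.5 to -1), unlike base `round()`'s
#' round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' roundHalfUp(0.5)        # 1
#' roundHalfUp(1/7 * 100, 1)  # 14.3
roundHalfUp <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1L)
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## Run a pipeline stage; any error is re-signalled with the stage name
## attached so a user can tell which step of runCrosstalk() failed.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.checkProb <- function(p, what = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(sprintf("%s values must be numeric in [0, 1]", what))
  }
  invisible(p)
}

## Plain-text run manifest: inputs, parameter values, files written.
## Deliberately timestamp-free so identical runs produce identical bytes.
.writeManifest <- function(dir, section) {
  lines <- c(sprintf("package\txenocrosstalk %s",
                     as.character(utils::packageVersion("xenocrosstalk"))))
  for (nm in names(section)) {
    val <- section[[nm]]
    lines <- c(lines, sprintf("%s\t%s", nm, paste(format(val), collapse = ",")))
  }
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(file.path(dir, "manifest.txt"))
}

.ensureDir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  invisible(dir)
}

## Seeded evaluation that restores the caller's RNG state afterwards:
## generators are pure functions of (config, seed).
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
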