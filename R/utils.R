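## Internal helpers: seeded RNG scoping and validation errors.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generation never leaks
#' into (or depends on) the caller's random stream.
#'
#' @param seed integer seed, or NA/NULL to use the current stream unchanged.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopValidation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ieegnoise_validation_error", "error")))
}

stopFormat <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ieegnoise_format_error", "error")))
}

stopVersion <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ieegnoise_version_error", "error")))
}

stopShape <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("ieegnoise_shape_error", "error")))
}

#' Truncate to two decimals
#'
#' Reporting convention for recall/PPV/F1: values are truncated (floored),
#' not rounded, to two decimal places; e.g. 0.5688 reports as 0.56.  A tiny
#' epsilon guards against floating-point values such as 0.96999999...
#'
#' @param x numeric vector in \[0, 1\].
#' @return numeric vector truncated to two decimals.
#' @export
#' @examples
#' truncate2(c(0.5688, 0.9672, 0.815))
truncate2 <- function(x) floor(x * 100 + 1e-9) / 100

#' Canonical segment class labels
#'
#' The five gold-standard classes in canonical order: physiological iEEG,
#' pathological iEEG (spike with superimposed HFO), 50 Hz and 60 Hz
#' power-line noise, and broadband non-cerebral artifact (muscle, movement,
#' machine).
#'
#' @return character vector of the five canonical labels.
#' @export
classLabels <- function() {
  c("physiological", "pathological", "line_noise_50", "line_noise_60",
    "artifact")
}

checkLabels <- function(labels) {
  bad <- setdiff(unique(labels[!is.na(labels)]), classLabels())
  if (length(bad))
    stopValidation("unknown class label(s): ", paste(bad, collapse = ", "))
  invisible(labels)
}
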