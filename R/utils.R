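## Internal utilities shared across modules.

#' Evaluate an expression with a fixed RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so no function in this package leaks global random state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Canonicalise a taxon name
#'
#' Strips leading/trailing whitespace and replaces internal spaces with
#' underscores, the `Genus_species` convention used throughout.
#'
#' @param x Character vector of names.
#' @return Character vector of canonical names.
#' @export
#' @examples
#' canonicalName("  Bos taurus ")
canonicalName <- function(x) {
  x <- gsub("^\\s+|\\s+$", "", x)
  gsub("\\s+", "_", x)
}

#' Split a taxon label into base name and polyphyly marker
#'
#' Labels may carry a `%d` suffix marking one of several placements of a
#' polyphyletic taxon within a source tree (e.g. `Bos%1`, `Bos%2`).
#'
#' @param x Character vector of labels.
#' @return For `baseName`, the label without any marker; for
#'   `polyphylyMarker`, the integer marker index or `NA` when absent.
#' @export
#' @examples
#' baseName(c("Bos%1", "Ovis_aries"))
#' polyphylyMarker(c("Bos%1", "Ovis_aries"))
baseName <- function(x) sub("%[0-9]+$", "", x)

#' @rdname baseName
#' @export
polyphylyMarker <- function(x) {
  m <- regmatches(x, regexpr("%[0-9]+$", x))
  out <- rep(NA_integer_, length(x))
  hit <- grepl("%[0-9]+$", x)
  out[hit] <- as.integer(sub("%", "", regmatches(x, regexpr("%[0-9]+$", x))))
  out
}

## Validate a taxon label: non-empty base name, positive marker if present.
validTaxonLabel <- function(x) {
  nzchar(baseName(x)) & (is.na(polyphylyMarker(x)) | polyphylyMarker(x) >= 1L)
}

## UTC timestamp string used for history entries.
historyTimestamp <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

## Deterministic timestamp used by the synthetic-data generator so that
## identical seeds yield byte-identical files.
epochTimestamp <- function() "1970-01-01T00:00:00"

`%||%` <- function(a, b) if (is.null(a)) b else a
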