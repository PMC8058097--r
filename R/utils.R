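#' @keywords internal
"_PACKAGE"

# Canonical chromosome labels: autosomes 1..22 plus the sex chromosomes.
.chrom_levels <- c(as.character(1:22), "X", "Y")
.autosomes <- as.character(1:22)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Abort with a classed condition
#'
#' All validation failures in the package raise conditions inheriting from
#' `oncoage_error`, so callers can distinguish schema/validation problems
#' from programming errors.
#' @noRd
oa_stop <- function(msg, class = "oncoage_error", ...) {
  stop(structure(
    class = c(class, "oncoage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Normalise chromosome labels ("chr1" -> "1"), validate against the
#' canonical vocabulary.
#' @noRd
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  bad <- !(x %in% .chrom_levels)
  if (any(bad)) {
    oa_stop(sprintf("invalid chromosome label(s): %s",
                    paste(unique(x[bad]), collapse = ", ")),
            class = "oncoage_validation_error")
  }
  x
}

#' Segment length under the 1-based inclusive convention
#' @noRd
seg_len <- function(start, end) end - start + 1

#' Check that required columns are present, error naming the missing ones
#' @noRd
require_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    oa_stop(sprintf("%s is missing required column(s): %s", what,
                    paste(missing, collapse = ", ")),
            class = "oncoage_schema_error")
  }
  invisible(df)
}

#' Missing-value marker normalisation: "", "NA", "na", "[Not Available]"
#' style placeholders become NA on read.
#' @noRd
normalize_missing <- function(x) {
  if (!is.character(x)) return(x)
  x[trimws(x) %in% c("", "NA", "na", "N/A", "[Not Available]")] <- NA_character_
  x
}
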