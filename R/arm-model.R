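#' Chromosome arm models
#'
#' An arm model records, for every chromosome, its total length, the
#' centromere interval and the derived p/q arm extents, plus an acrocentric
#' flag. Coordinates are 1-based inclusive. The p arm spans
#' `[1, cen_start - 1]` and the q arm `[cen_end + 1, length]`; acrocentric
#' chromosomes (13, 14, 15, 21, 22 in the human genome) are treated as
#' having no usable p arm, matching GISTIC broad output which reports only
#' their q arm.
#'
#' @param table data.frame with columns `chromosome`, `length`,
#'   `cen_start`, `cen_end`, `acrocentric`.
#' @return An object of class `arm_model`: the validated table with derived
#'   columns `p_start`, `p_end`, `q_start`, `q_end` (`NA` p extent for
#'   acrocentric chromosomes).
#' @export
arm_model <- function(table) {
  require_columns(table, c("chromosome", "length", "cen_start", "cen_end",
                           "acrocentric"), "arm model")
  table$chromosome <- normalize_chrom(table$chromosome)
  if (anyDuplicated(table$chromosome)) {
    oa_stop("duplicate chromosome in arm model",
            class = "oncoage_validation_error")
  }
  with(table, {
    if (any(cen_start <= 1 | cen_end >= length | cen_end < cen_start)) {
      oa_stop("centromere interval must lie strictly inside the chromosome",
              class = "oncoage_validation_error")
    }
  })
  table$p_start <- ifelse(table$acrocentric, NA_real_, 1)
  table$p_end <- ifelse(table$acrocentric, NA_real_, table$cen_start - 1)
  table$q_start <- table$cen_end + 1
  table$q_end <- table$length
  rownames(table) <- table$chromosome
  class(table) <- c("arm_model", "data.frame")
  table
}

#' @describeIn arm_model hg19 arm model shipped with the package (UCSC
#'   chromosome lengths and centromere gap intervals).
#' @export
hg19_arm_model <- function() {
  path <- system.file("extdata", "hg19_arms.tsv", package = "oncoage")
  tab <- utils::read.delim(path, colClasses = c(
    chromosome = "character", length = "numeric", cen_start = "numeric",
    cen_end = "numeric", acrocentric = "logical"))
  arm_model(tab)
}

#' @describeIn arm_model tiny three-chromosome genome (chromosomes 1, 2 and
#'   the acrocentric 13) used throughout the test suite; 1 Mb chromosomes
#'   with a 100 kb centromere.
#' @export
toy_arm_model <- function() {
  arm_model(data.frame(
    chromosome = c("1", "2", "13"),
    length = c(1e6, 8e5, 6e5),
    cen_start = c(450001, 350001, 100001),
    cen_end = c(550000, 450000, 200000),
    acrocentric = c(FALSE, FALSE, TRUE)
  ))
}

#' Valid GISTIC-style arm labels for an arm model
#'
#' @param model an `arm_model`.
#' @return character vector like `c("1p", "1q", ..., "13q")`; acrocentric
#'   chromosomes contribute only their q label.
#' @export
arm_labels <- function(model) {
  stopifnot(inherits(model, "arm_model"))
  unlist(lapply(seq_len(nrow(model)), function(i) {
    chrom <- model$chromosome[i]
    if (model$acrocentric[i]) paste0(chrom, "q")
    else paste0(chrom, c("p", "q"))
  }), use.names = FALSE)
}

#' Split an arm label such as "17p" into chromosome and arm
#' @noRd
parse_arm_label <- function(labels, model) {
  ok <- grepl("^(chr)?([0-9]{1,2}|X|Y)[pq]$", labels)
  if (any(!ok)) {
    oa_stop(sprintf("malformed arm label(s): %s",
                    paste(unique(labels[!ok]), collapse = ", ")),
            class = "oncoage_validation_error")
  }
  chrom <- normalize_chrom(sub("[pq]$", "", labels))
  arm <- substring(labels, nchar(labels))
  valid <- paste0(chrom, arm) %in% arm_labels(model)
  if (any(!valid)) {
    oa_stop(sprintf("arm label(s) not in arm model: %s",
                    paste(unique(paste0(chrom, arm)[!valid]), collapse = ", ")),
            class = "oncoage_validation_error")
  }
  data.frame(chromosome = chrom, arm = arm, stringsAsFactors = FALSE)
}
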