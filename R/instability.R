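#' Genomic-instability metrics from allele-specific segments
#'
#' The genomic-instability (GI) score of a tumour is the percentage of its
#' measured autosomal genome whose allele-specific copy state deviates
#' from the ground state: 1+1 (major+minor) for tumours that have not
#' undergone whole-genome duplication (WGD), 2+2 for WGD tumours. Percent
#' genomic LOH is the percentage of measured autosomal length held by
#' segments retaining exactly one parental allele (`n_minor = 0`,
#' `n_major >= 1`); homozygous deletions (0+0) are not LOH. Sex
#' chromosomes are excluded from all denominators; denominators are the
#' measured (profiled) length, so unprofiled gaps do not count.
#'
#' @name instability
NULL

.autosomal_segments <- function(profile, caller) {
  seg <- profile$segments
  seg <- seg[seg$chromosome %in% .autosomes, , drop = FALSE]
  if (nrow(seg) == 0)
    oa_stop(sprintf("%s: sample '%s' has no autosomal segments",
                    caller, profile$sample_id),
            class = "oncoage_validation_error")
  seg
}

#' Length-weighted mean total copy number over autosomes
#'
#' @param profile a [segment_profile].
#' @return ploidy (copies).
#' @export
tumour_ploidy <- function(profile) {
  seg <- .autosomal_segments(profile, "tumour_ploidy")
  len <- seg_len(seg$start, seg$end)
  sum(len * (seg$n_major + seg$n_minor)) / sum(len)
}

#' @describeIn instability percent of measured autosomal length not in the
#'   ground state (1+1 non-WGD, 2+2 WGD).
#' @param profile a [segment_profile].
#' @param wgd logical; resolved WGD status of the tumour.
#' @export
gi_score <- function(profile, wgd) {
  if (is.na(wgd)) oa_stop("gi_score: wgd flag must be resolved")
  seg <- .autosomal_segments(profile, "gi_score")
  ground <- if (wgd) 2L else 1L
  len <- seg_len(seg$start, seg$end)
  off <- seg$n_major != ground | seg$n_minor != ground
  100 * sum(len[off]) / sum(len)
}

#' @describeIn instability percent of measured autosomal length in LOH
#'   (exactly one parental allele: `n_minor = 0`, `n_major >= 1`).
#' @export
percent_loh <- function(profile) {
  seg <- .autosomal_segments(profile, "percent_loh")
  len <- seg_len(seg$start, seg$end)
  loh <- seg$n_minor == 0 & seg$n_major >= 1
  100 * sum(len[loh]) / sum(len)
}

#' Call whole-genome duplication from ploidy and LOH fraction
#'
#' The WGD decision boundary is linear in the (LOH fraction, ploidy)
#' plane: a tumour is called WGD when
#' `ploidy > tau0 - tau1 * loh_fraction`. The defaults (`tau0 = 2.9`,
#' `tau1 = 2`) follow the published convention for calling WGD from
#' allele-specific copy-number releases; both are configurable.
#'
#' @param ploidy mean copy number, `> 0`.
#' @param loh_fraction fraction of the genome in LOH, in `[0, 1]`.
#' @param tau0,tau1 boundary parameters.
#' @return logical vector.
#' @export
call_wgd <- function(ploidy, loh_fraction, tau0 = 2.9, tau1 = 2) {
  if (any(ploidy <= 0) || any(loh_fraction < 0 | loh_fraction > 1))
    oa_stop("call_wgd: ploidy must be > 0 and loh_fraction in [0, 1]",
            class = "oncoage_validation_error")
  ploidy > tau0 - tau1 * loh_fraction
}

#' Per-sample instability summary
#'
#' For each profile: derives ploidy when absent (length-weighted mean over
#' autosomes), computes the LOH fraction, resolves WGD (supplied flag if
#' present, otherwise [call_wgd]), then the GI score under the resolved
#' ground state.
#'
#' @param profiles list of [segment_profile] objects.
#' @param tau0,tau1 WGD boundary parameters passed to [call_wgd].
#' @return data.frame with columns `sample`, `ploidy`, `gi_score`,
#'   `percent_loh`, `loh_fraction`, `wgd`.
#' @export
instability_summary <- function(profiles, tau0 = 2.9, tau1 = 2) {
  rows <- lapply(profiles, function(p) {
    ploidy <- if (is.na(p$ploidy)) tumour_ploidy(p) else p$ploidy
    loh <- percent_loh(p) / 100
    wgd <- if (is.na(p$wgd)) call_wgd(ploidy, loh, tau0, tau1) else p$wgd
    data.frame(sample = p$sample_id, ploidy = ploidy,
               gi_score = gi_score(p, wgd), percent_loh = 100 * loh,
               loh_fraction = loh, wgd = wgd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
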