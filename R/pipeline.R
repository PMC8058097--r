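#' Pipeline configuration
#'
#' One configuration object drives [run_pipeline]. Inputs come either
#' from a simulation scenario (no files needed) or from file paths in
#' the formats of the package readers.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed for any simulated inputs.
#' @param scenario scenario preset name for simulated inputs (see
#'   [load_scenario]); ignored when `input` paths are given.
#' @param input optional named list of file paths: `segments`, `maf`,
#'   `broad`, `clinical`, `expression`, `methylation`, `probe_map`.
#' @param analyses character subset of
#'   `c("instability", "scna", "mutations", "expr_meth")`.
#' @param adj_cutoff BH-adjusted significance cutoff.
#' @param hypermutation_cutoff non-silent burden above which a tumour is
#'   hypermutated.
#' @param gene_min_frequency mutation-matrix frequency floor.
#' @param expressed_fraction expressed-gene fraction floor.
#' @param max_missing covariate missingness bar.
#' @param wgd_tau0,wgd_tau1 WGD boundary parameters.
#' @param n_samples cohort size for simulated inputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            scenario = "endometrial-like", input = NULL,
                            analyses = c("instability", "scna",
                                         "mutations", "expr_meth"),
                            adj_cutoff = 0.05,
                            hypermutation_cutoff = 1000,
                            gene_min_frequency = 0.05,
                            expressed_fraction = 0.5,
                            max_missing = 0.10,
                            wgd_tau0 = 2.9, wgd_tau1 = 2,
                            n_samples = 200) {
  cfg <- as.list(environment())
  if (adj_cutoff <= 0 || adj_cutoff >= 1)
    oa_stop("adj_cutoff must lie in (0, 1)",
            class = "oncoage_validation_error")
  if (hypermutation_cutoff <= 0 || gene_min_frequency <= 0 ||
      expressed_fraction <= 0 || max_missing <= 0)
    oa_stop("thresholds must be positive",
            class = "oncoage_validation_error")
  if (!is.null(input)) {
    missing_files <- unlist(input)[!file.exists(unlist(input))]
    if (length(missing_files))
      oa_stop(sprintf("input path(s) not found: %s",
                      paste(missing_files, collapse = ", ")),
              class = "oncoage_validation_error")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

# lightweight provenance fingerprint of a configuration
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

#' Run the staged age-association pipeline
#'
#' Executes the toggled analysis tracks (instability, SCNA, mutations,
#' expression/methylation) on simulated or file inputs, writing one TSV
#' per result with a provenance metadata header and logging per-stage
#' sample counts and exclusions. Outputs are pure functions of
#' (inputs, configuration, seed).
#'
#' @param config a [pipeline_config].
#' @param arm_model an [arm_model]; defaults to the toy genome for
#'   simulated inputs and hg19 otherwise.
#' @param quiet suppress log messages.
#' @return (invisibly) a named list of in-memory results.
#' @export
run_pipeline <- function(config, arm_model = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log_msg <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(tool = paste0("oncoage ",
                             as.character(utils::packageVersion("oncoage"))),
               config = config_hash(config), seed = config$seed)
  emit <- function(df, name, family = NA) {
    write_tsv(df, file.path(config$out_dir, paste0(name, ".tsv")),
              metadata = c(meta, list(bh_family = family)))
  }
  simulated <- is.null(config$input)
  if (simulated) {
    arm_model <- arm_model %||% toy_arm_model()
    params <- load_scenario(config$scenario, seed = config$seed,
                            n_samples = config$n_samples)
    cohort <- simulate_cohort(params, arm_model)
    clinical <- cohort$clinical
  } else {
    arm_model <- arm_model %||% hg19_arm_model()
    clinical <- read_clinical(config$input$clinical)
  }
  if (!"cancer_type" %in% names(clinical)) clinical$cancer_type <- "all"
  results <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      oa_stop(sprintf("pipeline stage '%s' failed: %s", name,
                      conditionMessage(e)),
              class = "oncoage_stage_error")
    })
  }

  if ("instability" %in% config$analyses) {
    results$instability <- run_stage("instability", {
      profiles <- if (simulated) cohort$profiles
                  else read_segments(config$input$segments, arm_model)
      summ <- instability_summary(profiles, config$wgd_tau0, config$wgd_tau1)
      log_msg("instability: %d samples, %d WGD", nrow(summ), sum(summ$wgd))
      emit(summ, "instability")
      d <- merge(clinical, summ, by.x = "sample_id", by.y = "sample")
      assoc <- rbind(
        screen_then_adjust(d, "gi_score", "continuous",
                           adj_cutoff = config$adj_cutoff),
        screen_then_adjust(d, "percent_loh", "continuous",
                           adj_cutoff = config$adj_cutoff),
        screen_then_adjust(transform(d, wgd = as.integer(wgd)), "wgd",
                           "binary", adj_cutoff = config$adj_cutoff))
      emit(assoc, "instability_associations", family = "cohorts")
      list(summary = summ, associations = assoc)
    })
  }

  if ("scna" %in% config$analyses) {
    results$scna <- run_stage("scna", {
      if (simulated) {
        broad <- cohort$gistic$broad
        focal <- filter_focal_regions(cohort$gistic$focal, arm_model)
      } else {
        broad <- read_gistic_broad(config$input$broad, arm_model)
        focal <- NULL
      }
      cohorts <- data.frame(sample = clinical$sample_id,
                            cancer_type = clinical$cancer_type)
      scores <- scna_scores(broad, focal, cohorts, arm_model)
      log_msg("scna: %d samples scored", nrow(scores))
      emit(scores, "scna_scores")
      d <- merge(clinical,
                 scores[, setdiff(names(scores), "cancer_type")],
                 by.x = "sample_id", by.y = "sample")
      assoc <- screen_then_adjust(d, "overall", "continuous",
                                  adj_cutoff = config$adj_cutoff)
      emit(assoc, "scna_associations", family = "cohorts")
      list(scores = scores, associations = assoc)
    })
  }

  if ("mutations" %in% config$analyses) {
    results$mutations <- run_stage("mutations", {
      if (simulated) {
        maf <- cohort$mutations$mutations
        flags <- cohort$mutations$flags
        msi <- setNames(flags$msi_high, flags$sample)
      } else {
        maf <- read_maf_minimal(config$input$maf)
        msi <- NULL
      }
      summ <- mutation_summary(maf, samples = clinical$sample_id,
                               msi_high = msi)
      emit(summ, "mutation_summary")
      d <- merge(clinical, summ, by.x = "sample_id", by.y = "sample")
      enrich <- hypermutation_enrichment(d$hypermutated,
                                         age_group_split(d$age))
      keep <- d$burden < config$hypermutation_cutoff &
        !(d$msi_high %in% TRUE)
      log_msg("mutations: %d samples, %d excluded (hypermutated/MSI-H)",
              nrow(d), sum(!keep))
      gm <- gene_mutation_matrix(filter_nonsilent(maf),
                                 d$sample_id[keep],
                                 config$gene_min_frequency)
      assoc <- screen_then_adjust(d, "log_burden", "continuous",
                                  adj_cutoff = config$adj_cutoff)
      emit(assoc, "burden_associations", family = "cohorts")
      list(summary = summ, enrichment = enrich, gene_matrix = gm,
           associations = assoc)
    })
  }

  if ("expr_meth" %in% config$analyses) {
    results$expr_meth <- run_stage("expr_meth", {
      if (simulated) {
        expr <- cohort$omics$expression
        meth <- cohort$omics$methylation
        pmap <- cohort$omics$probe_map
      } else {
        expr <- read_matrix(config$input$expression, "expression")
        meth <- read_matrix(config$input$methylation, "methylation")
        pmap <- utils::read.delim(config$input$probe_map,
                                  stringsAsFactors = FALSE)
      }
      expr <- filter_expressed(expr, config$expressed_fraction)
      mapped <- map_probes(meth, pmap, expr)
      covs <- covariate_select(clinical,
                               c("gender", "race", "stage", "grade",
                                 "smoking", "alcohol", "purity"),
                               config$max_missing)
      er <- age_feature_regression(log2_expr(expr), clinical, covs,
                                   flag_cutoff = config$adj_cutoff)
      mr <- age_feature_regression(mapped$meth, clinical, covs,
                                   flag_cutoff = config$adj_cutoff)
      log_msg("expr_meth: %d genes, %d age-DEGs, %d age-DMGs",
              nrow(er), sum(er$flag), sum(mr$flag))
      emit(er, "age_degs", family = "expression features")
      emit(mr, "age_dmgs", family = "methylation features")
      overlap <- classify_overlap(er, mr)
      groups <- correlation_groups(expr, mapped$meth, er, mr)
      conc <- coefficient_concordance(er, mr)
      make_ranked_list(er, file.path(config$out_dir, "ranked_expression.rnk"))
      make_ranked_list(mr, file.path(config$out_dir, "ranked_methylation.rnk"))
      list(expr_results = er, meth_results = mr, overlap = overlap,
           groups = groups, concordance = conc, probe_map = mapped$map)
    })
  }
  invisible(results)
}
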