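#' Synthetic cohort simulation parameters
#'
#' Bundles every knob of the synthetic tumour-cohort generator. The
#' defaults describe an "endometrial-like" study condition: genomic
#' instability, LOH, WGD probability and mutation burden all rise with
#' age, the C>T substitution share increases with age, hypermutators are
#' strongly enriched among young patients (rates 0.34 young vs 0.11 old),
#' and expression of planted age genes is negatively coupled to their
#' methylation.
#'
#' @param n_samples cohort size.
#' @param seed integer seed; every generator derives its RNG state from
#'   it, so identical parameters give bit-identical cohorts.
#' @param age_range inclusive integer age range (years).
#' @param cancer_type cohort label.
#' @param gi_baseline,gi_slope,gi_noise non-ground genome fraction:
#'   `f = gi_baseline + gi_slope/100 * age + N(0, gi_noise)`, clamped to
#'   `[0, 1]`; `gi_slope` is in percent of genome per year.
#' @param loh_baseline,loh_slope,loh_noise LOH genome fraction (subset of
#'   the non-ground fraction), linear in age, clamped.
#' @param wgd_intercept,wgd_logit_slope WGD probability
#'   `plogis(wgd_intercept + wgd_logit_slope * age)`.
#' @param burden_intercept,burden_log_slope non-silent burden
#'   `Poisson(exp(burden_intercept + burden_log_slope * age))`.
#' @param ct_baseline,ct_fraction_slope C>T share of SNVs, linear in age,
#'   clamped to `[0.05, 0.9]`; the other five classes share the rest
#'   equally.
#' @param silent_rate Silent variants added per non-silent variant
#'   (exercises the non-silent filter).
#' @param n_driver_genes,driver_intercept,driver_or_per_year per-gene
#'   driver carriage `plogis(driver_intercept + log(driver_or_per_year) *
#'   age)`.
#' @param hypermutator_rate_young,hypermutator_rate_old hypermutator
#'   probability per age group (young: age <= 50).
#' @param n_genes,n_age_genes,n_meth_only,n_expr_only gene universe:
#'   `n_age_genes` methylation-coupled age genes, plus blocks whose age
#'   signal sits only in methylation or only in expression, remainder
#'   null.
#' @param meth_age_slope,meth_noise methylation beta of signal genes:
#'   `clamp01(mu_g + meth_age_slope * age + N(0, meth_noise))`.
#' @param coupling log2-expression change per unit beta for coupled genes
#'   (negative: methylation suppresses expression).
#' @param expr_age_slope,expr_noise direct age slope (log2 units/year)
#'   for expression-only genes, and the log2 noise SD for all genes.
#' @param arm_gain_intercept,arm_gain_or_per_year carriage model of the
#'   designated gained arm in the broad table.
#' @param designated_arm arm label carrying the planted gain.
#' @param background_arm_rate probability that any other arm carries an
#'   age-independent event.
#' @param focal_rate expected background focal lesions per sample.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_samples = 200, seed = 1, age_range = c(30, 85),
                       cancer_type = "SYN",
                       gi_baseline = 0.05, gi_slope = 0.3, gi_noise = 0.03,
                       loh_baseline = 0.01, loh_slope = 0.001,
                       loh_noise = 0.02,
                       wgd_intercept = -2, wgd_logit_slope = 0.03,
                       burden_intercept = 3.3, burden_log_slope = 0.01,
                       ct_baseline = 0.15, ct_fraction_slope = 0.003,
                       silent_rate = 0.3,
                       n_driver_genes = 10, driver_intercept = -2,
                       driver_or_per_year = 1.02,
                       hypermutator_rate_young = 0.34,
                       hypermutator_rate_old = 0.11,
                       n_genes = 200, n_age_genes = 30,
                       n_meth_only = 10, n_expr_only = 10,
                       meth_age_slope = 0.003, meth_noise = 0.05,
                       coupling = -4,
                       expr_age_slope = 0.02, expr_noise = 0.3,
                       arm_gain_intercept = -2.2,
                       arm_gain_or_per_year = 1.03,
                       designated_arm = "1q",
                       background_arm_rate = 0.15, focal_rate = 2) {
  p <- as.list(environment())
  rates <- c(hypermutator_rate_young, hypermutator_rate_old)
  if (any(rates < 0 | rates > 1))
    oa_stop("hypermutator rates must be probabilities",
            class = "oncoage_parameter_error")
  if (n_age_genes + n_meth_only + n_expr_only > n_genes)
    oa_stop("planted gene blocks exceed n_genes",
            class = "oncoage_parameter_error")
  if (any(c(gi_noise, loh_noise, meth_noise, expr_noise) <= 0))
    oa_stop("noise scales must be positive",
            class = "oncoage_parameter_error")
  for (a in age_range) {
    f <- gi_baseline + gi_slope / 100 * a
    if (f < 0 || f > 1)
      oa_stop("gi baseline/slope put the non-ground fraction outside [0, 1]",
              class = "oncoage_parameter_error")
  }
  class(p) <- "sim_params"
  p
}

#' Load a scenario preset
#'
#' Presets are YAML parameter overrides shipped with the package:
#' `"endometrial-like"` (the defaults), `"null"` (all planted effects
#' zero, equal hypermutator rates) and `"glioma-like"` (driver mutation
#' odds decreasing with age).
#'
#' @param name preset name.
#' @param ... further overrides passed to [sim_params].
#' @return `sim_params` list.
#' @export
load_scenario <- function(name = c("endometrial-like", "null", "glioma-like"),
                          ...) {
  name <- match.arg(name)
  path <- system.file("extdata", "scenarios",
                      paste0(gsub("-", "_", name), ".yaml"),
                      package = "oncoage")
  overrides <- yaml::read_yaml(path) %||% list()
  dots <- list(...)
  overrides[names(dots)] <- dots
  do.call(sim_params, overrides)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Simulate a clinical table
#'
#' Ages are uniform integers on the configured range; gender, race,
#' stage, grade, smoking and alcohol are drawn from fixed multinomials
#' with realistic missingness (alcohol deliberately exceeds the 10%
#' missingness bar so covariate selection has something to drop); purity
#' is Beta(5, 2).
#'
#' @param params a [sim_params] list.
#' @return [clinical_table] with `n_samples` rows.
#' @export
simulate_clinical <- function(params) {
  set.seed(params$seed)
  n <- params$n_samples
  if (n == 0) {
    return(clinical_table(data.frame(sample_id = character(),
                                     age = numeric(),
                                     stringsAsFactors = FALSE)))
  }
  draw <- function(levels, probs, miss = 0) {
    x <- sample(levels, n, replace = TRUE, prob = probs)
    if (miss > 0) x[stats::runif(n) < miss] <- NA
    x
  }
  tab <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age = sample(seq(params$age_range[1], params$age_range[2]), n,
                 replace = TRUE),
    cancer_type = params$cancer_type,
    gender = draw(c("female", "male"), c(0.6, 0.4)),
    race = draw(c("white", "black", "asian", "other"),
                c(0.7, 0.15, 0.1, 0.05), miss = 0.05),
    stage = draw(c("I", "II", "III", "IV"), c(0.4, 0.3, 0.2, 0.1),
                 miss = 0.03),
    grade = draw(c("G1", "G2", "G3"), c(0.3, 0.4, 0.3), miss = 0.03),
    smoking = draw(c("never", "former", "current"), c(0.5, 0.3, 0.2),
                   miss = 0.03),
    alcohol = draw(c("no", "yes"), c(0.6, 0.4), miss = 0.15),
    purity = stats::rbeta(n, 5, 2),
    stringsAsFactors = FALSE
  )
  clinical_table(tab)
}

#' Simulate allele-specific segment profiles
#'
#' Per sample: WGD is Bernoulli with log-odds linear in age; a planted
#' fraction of the autosomal genome (linear in age plus noise, clamped)
#' is assigned non-ground allele states, a planted sub-fraction of it
#' carries LOH (`n_minor = 0`). Within each autosome the layout is
#' LOH block, then other non-ground block, then ground state, so the
#' realised planted fractions are recovered exactly by the instability
#' metrics.
#'
#' @param clinical [clinical_table] from [simulate_clinical].
#' @param params a [sim_params] list.
#' @param arm_model an [arm_model] (the toy model keeps tests fast).
#' @return named list of [segment_profile] objects; each carries a
#'   `planted` attribute with the realised non-ground and LOH fractions.
#' @export
simulate_segments <- function(clinical, params, arm_model = toy_arm_model()) {
  set.seed(params$seed + 1L)
  autos <- arm_model[arm_model$chromosome %in% .autosomes, , drop = FALSE]
  total_len <- sum(autos$length)
  profiles <- lapply(seq_len(nrow(clinical)), function(i) {
    age <- clinical$age[i]
    wgd <- stats::runif(1) <
      stats::plogis(params$wgd_intercept + params$wgd_logit_slope * age)
    f <- clamp01(params$gi_baseline + params$gi_slope / 100 * age +
                 stats::rnorm(1, 0, params$gi_noise))
    l <- clamp01(params$loh_baseline + params$loh_slope * age +
                 stats::rnorm(1, 0, params$loh_noise))
    l <- min(l, f)
    ground <- if (wgd) c(2L, 2L) else c(1L, 1L)
    loh_state <- if (wgd) c(2L, 0L) else c(1L, 0L)
    other_state <- if (wgd) c(3L, 2L) else c(2L, 1L)
    # per chromosome: [LOH][other non-ground][ground], built from vectors
    L <- autos$length
    n_loh <- round(l * L)
    n_oth <- round(f * L) - n_loh
    n_gr <- L - n_loh - n_oth
    lens <- c(rbind(n_loh, n_oth, n_gr))
    chrom <- rep(autos$chromosome, each = 3)
    maj <- rep(c(loh_state[1], other_state[1], ground[1]), nrow(autos))
    mino <- rep(c(loh_state[2], other_state[2], ground[2]), nrow(autos))
    ends <- unlist(lapply(split(lens, rep(seq_len(nrow(autos)), each = 3)),
                          cumsum), use.names = FALSE)
    starts <- ends - lens + 1
    keep <- lens >= 1
    segs <- data.frame(chromosome = chrom[keep], start = starts[keep],
                       end = ends[keep], n_major = maj[keep],
                       n_minor = mino[keep], stringsAsFactors = FALSE)
    p <- segment_profile(clinical$sample_id[i], segs,
                         purity = clinical$purity[i], wgd = wgd)
    len <- seg_len(p$segments$start, p$segments$end)
    off <- p$segments$n_major != ground[1] | p$segments$n_minor != ground[2]
    loh <- p$segments$n_minor == 0 & p$segments$n_major >= 1
    attr(p, "planted") <- c(f = sum(len[off]) / sum(len),
                            loh = sum(len[loh]) / sum(len))
    p
  })
  names(profiles) <- clinical$sample_id
  profiles
}

#' Simulate a MAF-style mutation table with planted age effects
#'
#' Non-hypermutator burden is Poisson with log-mean linear in age;
#' hypermutators (age-group-specific rates) receive a burden above 1000
#' and an MSI-H or POLE flag. SNV substitution classes are multinomial
#' with a C>T share increasing with age (records are randomly emitted in
#' purine-reference form to exercise strand collapsing); Silent records
#' are added on top of the non-silent burden. Driver-gene carriage is
#' Bernoulli with per-gene log-odds linear in age.
#'
#' @param clinical [clinical_table].
#' @param params a [sim_params] list.
#' @param gene_list background gene symbols for burden variants.
#' @return list: `mutations` ([mutation_table]), `flags` (data.frame
#'   `sample`, `hypermutator`, `msi_high`, `pole_mut`, `pold1_mut`),
#'   `driver_genes` (character vector of planted driver symbols).
#' @export
simulate_mutations <- function(clinical, params,
                               gene_list = sprintf("BG%03d", 1:50)) {
  if (length(gene_list) == 0)
    oa_stop("simulate_mutations: empty gene list",
            class = "oncoage_parameter_error")
  set.seed(params$seed + 2L)
  n <- nrow(clinical)
  age <- clinical$age
  young <- age <= 50
  hyper_rate <- ifelse(young, params$hypermutator_rate_young,
                       params$hypermutator_rate_old)
  hyper <- stats::runif(n) < hyper_rate
  burden <- stats::rpois(n, exp(params$burden_intercept +
                                params$burden_log_slope * age))
  burden[hyper] <- 1001L + stats::rpois(sum(hyper), 500)
  msi <- hyper & stats::runif(n) < 0.6
  pole <- hyper & !msi
  pold1 <- hyper & !msi & !pole
  pold1 <- pold1 | (stats::runif(n) < 0.01)
  drivers <- sprintf("DRV%02d", seq_len(params$n_driver_genes))

  make_records <- function(i) {
    b <- burden[i]
    n_sil <- stats::rpois(1, params$silent_rate * b)
    total <- b + n_sil
    if (total == 0) return(NULL)
    p_ct <- min(0.9, max(0.05, params$ct_baseline +
                         params$ct_fraction_slope * age[i]))
    cls <- sample(.substitution_classes, total, replace = TRUE,
                  prob = c(rep((1 - p_ct) / 5, 2), p_ct, rep((1 - p_ct) / 5, 3)))
    ref <- substr(cls, 1, 1)
    alt <- substr(cls, 3, 3)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    flip <- stats::runif(total) < 0.5
    ref[flip] <- comp[ref[flip]]
    alt[flip] <- comp[alt[flip]]
    vc <- c(sample(c("Missense_Mutation", "Nonsense_Mutation", "Splice_Site",
                     "Frame_Shift_Del", "In_Frame_Ins"), b, replace = TRUE,
                   prob = c(0.7, 0.12, 0.08, 0.06, 0.04)),
            rep("Silent", n_sil))
    data.frame(sample_id = clinical$sample_id[i],
               gene = sample(gene_list, total, replace = TRUE),
               variant_classification = vc,
               reference_allele = ref, alt_allele = alt,
               stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, lapply(seq_len(n), make_records))
  # planted driver carriage, one missense record per carried gene
  driver_rows <- do.call(rbind, lapply(drivers, function(g) {
    carried <- stats::runif(n) < stats::plogis(
      params$driver_intercept + log(params$driver_or_per_year) * age)
    if (!any(carried)) return(NULL)
    data.frame(sample_id = clinical$sample_id[carried], gene = g,
               variant_classification = "Missense_Mutation",
               reference_allele = "C", alt_allele = "T",
               stringsAsFactors = FALSE)
  }))
  records <- rbind(records, driver_rows)
  list(
    mutations = mutation_table(records),
    flags = data.frame(sample = clinical$sample_id, hypermutator = hyper,
                       msi_high = msi, pole_mut = pole, pold1_mut = pold1,
                       stringsAsFactors = FALSE),
    driver_genes = drivers
  )
}

#' Simulate coupled expression and methylation matrices
#'
#' Age genes get a methylation beta rising (or falling) with age and a
#' log2 expression equal to a gene baseline plus `coupling * beta` plus
#' noise; methylation-only and expression-only blocks carry their age
#' signal in a single layer; remaining genes are noise in both. Each gene
#' receives 1-3 methylation probes of which exactly one carries the
#' gene's signal, the decoys being noise-only.
#'
#' @param clinical [clinical_table].
#' @param params a [sim_params] list.
#' @return list: `expression` (gene x sample RSEM [omics_matrix]),
#'   `methylation` (probe x sample beta [omics_matrix]), `probe_map`
#'   (data.frame `probe`, `gene`, `signal`), `truth` (data.frame `gene`,
#'   `type` in coupled/meth_only/expr_only/null).
#' @export
simulate_expr_meth <- function(clinical, params) {
  set.seed(params$seed + 3L)
  n <- nrow(clinical)
  age <- clinical$age
  ng <- params$n_genes
  types <- rep("null", ng)
  types[seq_len(params$n_age_genes)] <- "coupled"
  types[params$n_age_genes + seq_len(params$n_meth_only)] <- "meth_only"
  types[params$n_age_genes + params$n_meth_only +
        seq_len(params$n_expr_only)] <- "expr_only"
  genes <- sprintf("GENE%04d", seq_len(ng))

  beta <- matrix(NA_real_, ng, n, dimnames = list(genes, clinical$sample_id))
  log2e <- matrix(NA_real_, ng, n, dimnames = list(genes, clinical$sample_id))
  mu_b <- stats::runif(ng, 0.2, 0.5)
  nu_e <- stats::runif(ng, 6, 10)
  for (g in seq_len(ng)) {
    eps_b <- stats::rnorm(n, 0, params$meth_noise)
    eps_e <- stats::rnorm(n, 0, params$expr_noise)
    b <- switch(types[g],
      coupled = ,
      meth_only = clamp01(mu_b[g] + params$meth_age_slope * age + eps_b),
      clamp01(mu_b[g] + eps_b))
    e <- switch(types[g],
      coupled = nu_e[g] + params$coupling * b + eps_e,
      expr_only = nu_e[g] + params$expr_age_slope * age + eps_e,
      nu_e[g] + eps_e)
    beta[g, ] <- b
    log2e[g, ] <- pmax(0, e)
  }
  expression <- omics_matrix(2^log2e - 1, "expression")

  n_probes <- sample(1:3, ng, replace = TRUE)
  probe_rows <- list()
  map_rows <- list()
  probe_i <- 0L
  for (g in seq_len(ng)) {
    signal_slot <- sample.int(n_probes[g], 1)
    for (k in seq_len(n_probes[g])) {
      probe_i <- probe_i + 1L
      id <- sprintf("cg%06d", probe_i)
      vals <- if (k == signal_slot) beta[g, ]
              else clamp01(stats::runif(1, 0.2, 0.7) +
                           stats::rnorm(n, 0, params$meth_noise))
      probe_rows[[probe_i]] <- vals
      map_rows[[probe_i]] <- data.frame(probe = id, gene = genes[g],
                                        signal = k == signal_slot,
                                        stringsAsFactors = FALSE)
    }
  }
  meth <- do.call(rbind, probe_rows)
  map <- do.call(rbind, map_rows)
  rownames(meth) <- map$probe
  colnames(meth) <- clinical$sample_id
  list(expression = expression,
       methylation = omics_matrix(meth, "methylation"),
       probe_map = map,
       truth = data.frame(gene = genes, type = types,
                          stringsAsFactors = FALSE))
}

#' Simulate GISTIC-like broad and focal event tables
#'
#' The designated arm carries a gain whose odds rise with age; other arms
#' carry age-independent background events. Background focal lesions are
#' placed uniformly inside arms, away from centromere/telomere windows;
#' one designated focal region carries an age-dependent gain.
#'
#' @param clinical [clinical_table].
#' @param params a [sim_params] list.
#' @param arm_model an [arm_model].
#' @return list: `broad` (long per-arm table as from
#'   [read_gistic_broad]), `focal` (data.frame `sample`, `chromosome`,
#'   `start`, `end`, `region`, `log2_ratio`).
#' @export
simulate_gistic_events <- function(clinical, params,
                                   arm_model = toy_arm_model()) {
  set.seed(params$seed + 4L)
  n <- nrow(clinical)
  age <- clinical$age
  labels <- arm_labels(arm_model)
  if (!params$designated_arm %in% labels)
    oa_stop("designated_arm not in arm model",
            class = "oncoage_parameter_error")
  broad <- do.call(rbind, lapply(labels, function(lb) {
    if (lb == params$designated_arm) {
      carried <- stats::runif(n) < stats::plogis(
        params$arm_gain_intercept + log(params$arm_gain_or_per_year) * age)
      log2r <- ifelse(carried, 0.5, 0)
    } else {
      ev <- stats::runif(n) < params$background_arm_rate
      log2r <- ifelse(ev, sample(c(0.5, -0.5), n, replace = TRUE), 0)
    }
    data.frame(sample = clinical$sample_id, arm = lb,
               chromosome = sub("[pq]$", "", lb), log2_ratio = log2r,
               stringsAsFactors = FALSE)
  }))
  # background focal lesions, placed mid-arm
  focal <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, params$focal_rate)
    if (k == 0) return(NULL)
    rows <- lapply(seq_len(k), function(j) {
      ci <- sample.int(nrow(arm_model), 1)
      q0 <- arm_model$q_start[ci]
      q1 <- arm_model$q_end[ci]
      w <- min(round(stats::runif(1, 1e3, 2e4)), floor((q1 - q0) / 4))
      s <- round(stats::runif(1, q0 + 2e4, q1 - 2e4 - w))
      data.frame(sample = clinical$sample_id[i],
                 chromosome = arm_model$chromosome[ci],
                 start = s, end = s + w,
                 region = sprintf("bg_%s", arm_model$chromosome[ci]),
                 log2_ratio = sample(c(1.2, 0.5, -0.5, -1.2), 1),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  list(broad = broad, focal = focal)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running every generator off one parameter set.
#'
#' @param params a [sim_params] list.
#' @param arm_model an [arm_model].
#' @return list with `clinical`, `profiles`, `mutations` (list), `omics`
#'   (list), `gistic` (list), `params`.
#' @export
simulate_cohort <- function(params = sim_params(),
                            arm_model = toy_arm_model()) {
  clinical <- simulate_clinical(params)
  list(
    clinical = clinical,
    profiles = simulate_segments(clinical, params, arm_model),
    mutations = simulate_mutations(clinical, params),
    omics = simulate_expr_meth(clinical, params),
    gistic = simulate_gistic_events(clinical, params, arm_model),
    params = params
  )
}
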