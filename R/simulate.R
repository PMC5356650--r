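#' Configuration for the synthetic study generator
#'
#' One object holds every knob of the simulated study: a latent per-sample
#' pathway activity drives (a) the expression of a signature gene program in
#' the direction opposite to the inhibitor-induced change, (b) the survival
#' hazard, and (c) drug log-IC50. The defaults describe the standard
#' simulated cohort used throughout the package's tests: 2000 genes with a
#' 100-gene up and a 100-gene down pathway program, 200 samples, unit
#' activity and noise standard deviations, and a log-hazard of 0.8 per unit
#' activity.
#'
#' @param n_genes total genes.
#' @param n_signature_up,n_signature_dn sizes of the pathway-program gene
#'   sets. "Up" genes rise with pathway activity (and are therefore
#'   suppressed by the inhibitor); "down" genes do the opposite.
#' @param n_samples cohort size.
#' @param activity_sd sd of the latent activity (activity ~ Normal(0, sd)).
#' @param effect_size expression shift (log2 units) per unit activity on
#'   signature genes; also the treated-vs-control shift in the drug
#'   experiment.
#' @param noise_sd sd of the Gaussian expression noise (log2 units).
#' @param hazard_coef log-hazard increase per unit activity.
#' @param baseline_hazard baseline exponential event rate (per study time
#'   unit).
#' @param censor_rate fraction of samples independently censored, in [0, 1).
#' @param ic50_coef shift of log-IC50 per unit activity for the planted
#'   drug.
#' @param burden_coef log-odds increase of the high-burden label per unit
#'   activity.
#' @param confounder_sd sd of an optional second latent variable added to a
#'   random gene block and exported as a clinical covariate; 0 disables it.
#' @param seed root seed; every sub-generator derives its stream from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_signature_up = 100,
                       n_signature_dn = 100, n_samples = 200,
                       activity_sd = 1, effect_size = 1, noise_sd = 1,
                       hazard_coef = 0.8, baseline_hazard = 0.1,
                       censor_rate = 0.2, ic50_coef = 1, burden_coef = 1.5,
                       confounder_sd = 0, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_signature_up = as.integer(n_signature_up),
              n_signature_dn = as.integer(n_signature_dn),
              n_samples = as.integer(n_samples),
              activity_sd = activity_sd, effect_size = effect_size,
              noise_sd = noise_sd, hazard_coef = hazard_coef,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              ic50_coef = ic50_coef, burden_coef = burden_coef,
              confounder_sd = confounder_sd, seed = as.integer(seed))
  if (cfg$n_signature_up + cfg$n_signature_dn > cfg$n_genes)
    stop("signature gene sets exceed n_genes")
  if (cfg$activity_sd <= 0 || cfg$noise_sd <= 0)
    stop("activity_sd and noise_sd must be positive")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1)
    stop("censor_rate must lie in [0, 1)")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  class(cfg) <- "sim_config"
  cfg
}

.sim_gene_ids <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

.sim_gene_sets <- function(cfg) {
  ids <- .sim_gene_ids(cfg)
  list(up = ids[seq_len(cfg$n_signature_up)],
       dn = ids[cfg$n_signature_up + seq_len(cfg$n_signature_dn)],
       ids = ids)
}

#' Simulate a replicated inhibitor treatment experiment
#'
#' Control replicates are baseline plus Gaussian noise; treated replicates
#' additionally shift the pathway-program genes by `effect_size`, with the
#' inhibitor suppressing the program: pathway-up genes go down under
#' treatment and pathway-down genes go up. With `effect_size = 0` treated
#' and control differ only by noise.
#'
#' @param config a [sim_config()].
#' @param n_replicates number of treated/control pairs (default 3).
#' @param concentration,conc_unit labels recorded on each pair.
#' @param baseline_mean mean baseline log2 expression (default 8).
#' @return List of [expression_pair()] replicates.
#' @export
simulate_drug_experiment <- function(config, n_replicates = 3,
                                     concentration = 10, conc_unit = "uM",
                                     baseline_mean = 8) {
  stopifnot(inherits(config, "sim_config"), n_replicates >= 1)
  gs <- .sim_gene_sets(config)
  shift <- numeric(config$n_genes)
  shift[gs$ids %in% gs$up] <- -config$effect_size
  shift[gs$ids %in% gs$dn] <- +config$effect_size
  with_seed(config$seed + 101L, {
    baseline <- stats::rnorm(config$n_genes, baseline_mean, 1)
    lapply(seq_len(n_replicates), function(r) {
      control <- baseline + stats::rnorm(config$n_genes, 0, config$noise_sd)
      treated <- control + shift +
        stats::rnorm(config$n_genes, 0, config$noise_sd)
      expression_pair(gs$ids, treated, control,
                      drug_name = "pathway_inhibitor",
                      cell_line = "simcell",
                      concentration = concentration, conc_unit = conc_unit)
    })
  })
}

#' Simulate an expression cohort with known latent pathway activity
#'
#' Each sample draws a latent activity from Normal(0, `activity_sd`);
#' expression of pathway-up genes is `+effect_size * activity` and of
#' pathway-down genes `-effect_size * activity`, plus Gaussian noise on all
#' genes. High activity therefore pushes expression opposite to the
#' inhibitor-induced profile, so the DRS against the inhibitor signature is
#' expected to anti-correlate with activity.
#'
#' @param config a [sim_config()].
#' @return List: `expr` (genes x samples matrix) and `truth` (class
#'   `sim_truth`: `activity`, `confounder` (or NULL), `signature_up_genes`,
#'   `signature_dn_genes`, `config`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gs <- .sim_gene_sets(config)
  sample_ids <- sprintf("s%03d", seq_len(config$n_samples))
  with_seed(config$seed + 202L, {
    activity <- stats::rnorm(config$n_samples, 0, config$activity_sd)
    expr <- matrix(stats::rnorm(config$n_genes * config$n_samples, 0,
                                config$noise_sd),
                   nrow = config$n_genes,
                   dimnames = list(gs$ids, sample_ids))
    up_rows <- gs$ids %in% gs$up
    dn_rows <- gs$ids %in% gs$dn
    expr[up_rows, ] <- expr[up_rows, ] +
      config$effect_size * rep(activity, each = sum(up_rows))
    expr[dn_rows, ] <- expr[dn_rows, ] -
      config$effect_size * rep(activity, each = sum(dn_rows))
    confounder <- NULL
    if (config$confounder_sd > 0) {
      confounder <- stats::rnorm(config$n_samples, 0, config$confounder_sd)
      free <- which(!(up_rows | dn_rows))
      block <- free[seq_len(min(100L, length(free)))]
      expr[block, ] <- expr[block, ] +
        rep(confounder, each = length(block))
    }
    truth <- structure(
      list(activity = stats::setNames(activity, sample_ids),
           confounder = if (is.null(confounder)) NULL else
             stats::setNames(confounder, sample_ids),
           signature_up_genes = gs$up, signature_dn_genes = gs$dn,
           config = config),
      class = "sim_truth")
    list(expr = expr, truth = truth)
  })
}

#' Simulate clinical outcomes and drug-response tables from latent activity
#'
#' Survival times are exponential with rate
#' `baseline_hazard * exp(hazard_coef * activity)`; a fraction `censor_rate`
#' of samples is censored independently at a uniform fraction of their event
#' time. A binary residual-burden label is drawn with
#' `P(high) = plogis(burden_coef * activity)`. The drug-response table
#' contains one planted drug whose log-IC50 is `ic50_coef * activity` plus
#' noise, and `n_null_drugs` pure-noise drugs.
#'
#' @param truth a `sim_truth` from [simulate_cohort()].
#' @param n_null_drugs number of no-signal drugs in the IC50 table.
#' @return List: `clinical` (`data.frame` with `sample_id`, `time`, `event`,
#'   `burden` (`"low"`/`"high"`), optional `confounder`) and `ic50` (numeric
#'   matrix, samples x drugs; column `planted_drug` plus `null_drug_*`).
#' @export
simulate_outcomes <- function(truth, n_null_drugs = 19) {
  stopifnot(inherits(truth, "sim_truth"))
  cfg <- truth$config
  a <- truth$activity
  n <- length(a)
  with_seed(cfg$seed + 303L, {
    rate <- cfg$baseline_hazard * exp(cfg$hazard_coef * a)
    ev_time <- stats::rexp(n, rate)
    censored <- stats::runif(n) < cfg$censor_rate
    time <- ifelse(censored, stats::runif(n) * ev_time, ev_time)
    event <- as.integer(!censored)
    burden <- ifelse(stats::runif(n) <
                       stats::plogis(cfg$burden_coef * a), "high", "low")
    clinical <- data.frame(sample_id = names(a), time = time, event = event,
                           burden = burden, stringsAsFactors = FALSE)
    if (!is.null(truth$confounder))
      clinical$confounder <- unname(truth$confounder)
    ic50 <- matrix(stats::rnorm(n * (n_null_drugs + 1), 0, cfg$noise_sd),
                   nrow = n,
                   dimnames = list(names(a),
                                   c("planted_drug",
                                     sprintf("null_drug_%02d",
                                             seq_len(n_null_drugs)))))
    ic50[, "planted_drug"] <- ic50[, "planted_drug"] + cfg$ic50_coef * a
    list(clinical = clinical, ic50 = ic50)
  })
}

#' Run the whole synthetic study in one call
#'
#' Convenience wrapper: simulates the drug experiment, builds and averages
#' the replicate profiles, simulates the cohort and outcomes, and scores the
#' cohort.
#'
#' @param config a [sim_config()].
#' @param n_perm permutations for DRS normalization.
#' @param n_replicates treated/control replicate pairs.
#' @param n_null_drugs no-signal drugs in the IC50 table.
#' @return List: `profile`, `expr`, `truth`, `clinical`, `ic50`, `drs`
#'   (the [score_cohort()] table).
#' @export
simulate_study <- function(config, n_perm = 200, n_replicates = 3,
                           n_null_drugs = 19) {
  pairs <- simulate_drug_experiment(config, n_replicates = n_replicates)
  profile <- average_replicates(lapply(pairs, build_profile))
  cohort <- simulate_cohort(config)
  outcomes <- simulate_outcomes(cohort$truth, n_null_drugs = n_null_drugs)
  drs <- score_cohort(cohort$expr, profile, n_perm = n_perm,
                      seed = config$seed)
  list(profile = profile, expr = cohort$expr, truth = cohort$truth,
       clinical = outcomes$clinical, ic50 = outcomes$ic50, drs = drs)
}
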