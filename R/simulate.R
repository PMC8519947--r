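#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the PASS pipeline
#' assumes: negative-binomial counts with library-size variation, a small
#' number of "driver" pathways whose member genes are upregulated in
#' responders (more strongly on treatment than before it), RECIST labels
#' consistent with the 180-day progression rule, and exponential
#' progression/survival times tied to response.
#'
#' @param n_genes Number of genes in the simulated transcriptome.
#' @param n_pathways Number of simulated gene sets.
#' @param set_size Length-2 integer range of gene-set sizes.
#' @param overlap Fraction of each set's genes drawn from genes already used
#'   by earlier sets (0 = disjoint where capacity allows).
#' @param n_patients Number of patients.
#' @param r_frac Responder fraction, strictly between 0 and 1.
#' @param timepoints `"both"`, `"PRE"`, or `"ON"` biopsies per patient.
#' @param n_driver Number of driver pathways carrying the response signal.
#' @param delta_pre,delta_on Log2 fold change added to driver-pathway genes
#'   in responder samples at the PRE / ON timepoint.
#' @param base_mean Mean and sd of the per-gene baseline log2 expression.
#' @param dispersion Negative-binomial dispersion phi (Var = mu + phi*mu^2).
#' @param libsize_sd Standard deviation of log-normal library-size factors.
#' @param patient_sd Standard deviation of the patient-level log2 offset
#'   shared by a patient's paired biopsies.
#' @param pathway_sd Standard deviation of the per-sample pathway-activity
#'   offset: every gene's home pathway (the first set containing it) gets
#'   an independent N(0, pathway_sd) log2 offset in each sample, so member
#'   genes fluctuate jointly. This is what gives single-sample enrichment
#'   scores realistic sample-to-sample variability; without it, rank-based
#'   pathway scores average away all gene-level noise and any systematic
#'   effect separates the classes almost perfectly.
#' @param hazard_r Progression hazard (per day) for responders.
#' @param hazard_ratio Nonresponder-to-responder hazard ratio.
#' @param censor_rate Expected fraction of censored observations, in [0,1).
#' @param seed Integer seed fixing all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1200, n_pathways = 50, set_size = c(20, 60),
                       overlap = 0.1, n_patients = 100, r_frac = 0.4,
                       timepoints = c("both", "PRE", "ON"), n_driver = 3,
                       delta_pre = 0.5, delta_on = 1.5,
                       base_mean = c(5, 2), dispersion = 0.2,
                       libsize_sd = 0.3, patient_sd = 0.2, pathway_sd = 0.5,
                       hazard_r = log(2) / 500, hazard_ratio = 3,
                       censor_rate = 0.2, seed = 1L) {
  timepoints <- match.arg(timepoints)
  stopifnot(r_frac > 0, r_frac < 1, dispersion > 0,
            delta_on >= 0, n_driver <= n_pathways,
            set_size[2] <= n_genes, censor_rate >= 0, censor_rate < 1,
            hazard_r > 0, hazard_ratio > 0)
  structure(list(
    n_genes = n_genes, n_pathways = n_pathways, set_size = set_size,
    overlap = overlap, n_patients = n_patients, r_frac = r_frac,
    timepoints = timepoints, n_driver = n_driver, delta_pre = delta_pre,
    delta_on = delta_on, base_mean = base_mean, dispersion = dispersion,
    libsize_sd = libsize_sd, patient_sd = patient_sd,
    pathway_sd = pathway_sd, hazard_r = hazard_r,
    hazard_ratio = hazard_ratio, censor_rate = censor_rate,
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a gene-set collection and gene lengths
#'
#' Sets are drawn with sizes uniform in the configured range. A fraction
#' `overlap` of each set is sampled from genes already used by earlier sets
#' (when any exist); the remainder comes from unused genes while capacity
#' lasts. Gene lengths are uniform integers in 200-20000 bp.
#'
#' @param config A [sim_config()].
#' @return List with `sets` (named list of gene vectors) and `lengths`
#'   (named integer vector).
#' @export
simulate_genesets <- function(config) {
  set.seed(config$seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  lengths <- stats::setNames(sample(200:20000, config$n_genes, replace = TRUE),
                             genes)
  if (config$overlap >= 1) stop("overlap fraction must be < 1", call. = FALSE)
  used <- character(0)
  unused <- genes
  sets <- vector("list", config$n_pathways)
  for (k in seq_len(config$n_pathways)) {
    m <- if (config$set_size[1] == config$set_size[2]) config$set_size[1] else
      sample(config$set_size[1]:config$set_size[2], 1)
    n_old <- min(round(config$overlap * m), length(used))
    old <- if (n_old > 0) sample(used, n_old) else character(0)
    n_new <- m - n_old
    if (length(unused) >= n_new) {
      new <- if (n_new > 0) sample(unused, n_new) else character(0)
    } else {
      # capacity exhausted: top up from already-used genes
      new <- c(unused, sample(setdiff(used, old), n_new - length(unused)))
    }
    members <- c(old, new)
    sets[[k]] <- sort(members)
    used <- union(used, members)
    unused <- setdiff(unused, members)
  }
  names(sets) <- sprintf("PATHWAY_%03d", seq_len(config$n_pathways))
  list(sets = sets, lengths = lengths)
}

# Uniform censoring horizon giving the requested expected censor fraction
# for exponential event times with the given per-subject hazards.
.censor_horizon <- function(hazards, censor_rate) {
  if (censor_rate <= 0) return(Inf)
  # P(censored | lambda, u) = (1/(lambda u)) (1 - e^{-lambda u}) for C ~ U(0,u)
  frac <- function(u) mean((1 / (hazards * u)) * (1 - exp(-hazards * u)))
  stats::uniroot(function(u) frac(u) - censor_rate,
                 lower = 1e-6, upper = 1e8, tol = 1e-10)$root
}

#' Simulate censored survival times for two response arms
#'
#' Event times are exponential with arm-specific hazards; censoring times
#' are uniform on a horizon chosen so the expected censored fraction equals
#' `censor_rate` (independent, non-informative).
#'
#' @param n Subjects per arm.
#' @param hazard_r,hazard_nr Event hazards for responders / nonresponders.
#' @param censor_rate Expected censored fraction in [0, 1).
#' @param seed Integer seed.
#' @return Data frame with `group` (`R`/`NR`), `time`, `event`.
#' @export
simulate_survival <- function(n, hazard_r, hazard_nr, censor_rate = 0,
                              seed = 1L) {
  stopifnot(hazard_r > 0, hazard_nr > 0, censor_rate >= 0, censor_rate < 1)
  set.seed(as.integer(seed))
  hazards <- rep(c(hazard_r, hazard_nr), each = n)
  t_event <- stats::rexp(2 * n, rate = hazards)
  if (censor_rate > 0) {
    u <- .censor_horizon(hazards, censor_rate)
    t_cens <- stats::runif(2 * n, 0, u)
  } else {
    t_cens <- rep(Inf, 2 * n)
  }
  data.frame(group = rep(c("R", "NR"), each = n),
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Simulate a full anti-PD1 cohort
#'
#' Produces a count matrix, an annotated sample table, and the generative
#' truth. Counts are negative binomial with mean
#' `s_j * 2^(mu_i + patient offset + delta_i(sample))`, where `delta` is the
#' configured driver effect for driver-pathway genes in responder samples at
#' the matching timepoint and zero otherwise. PFS/OS are exponential with
#' the configured responder hazard ratio; RECIST codes are assigned so that
#' [classify_response()] on (recist, observed PFS) reproduces the true
#' response label.
#'
#' @param config A [sim_config()].
#' @param genesets Optional pre-simulated output of [simulate_genesets()];
#'   generated from `config` when `NULL`.
#' @return List with `counts`, `samples`, `sets`, `lengths`, `truth`.
#' @export
simulate_cohort <- function(config, genesets = NULL) {
  if (is.null(genesets)) genesets <- simulate_genesets(config)
  sets <- genesets$sets
  set.seed(config$seed + 10007L)

  genes <- sprintf("g%05d", seq_len(config$n_genes))
  np <- config$n_patients
  patients <- sprintf("p%03d", seq_len(np))
  n_r <- round(config$r_frac * np)
  response <- rep("NR", np)
  response[sample(np, n_r)] <- "R"

  tps <- switch(config$timepoints, both = c("PRE", "ON"),
                PRE = "PRE", ON = "ON")
  samp <- expand.grid(patient_id = patients, timepoint = tps,
                      stringsAsFactors = FALSE)
  samp <- samp[order(samp$patient_id, samp$timepoint != "PRE"), ]
  samp$sample_id <- paste(samp$patient_id, samp$timepoint, sep = "_")
  samp$response <- response[match(samp$patient_id, patients)]
  ns <- nrow(samp)

  # generative means
  mu0 <- stats::rnorm(config$n_genes, config$base_mean[1], config$base_mean[2])
  names(mu0) <- genes
  pat_off <- stats::setNames(stats::rnorm(np, 0, config$patient_sd), patients)
  libsize <- exp(stats::rnorm(ns, 0, config$libsize_sd))

  drivers <- names(sets)[seq_len(config$n_driver)]
  driver_genes <- unique(unlist(sets[drivers], use.names = FALSE))
  lfc_pre <- lfc_on <- stats::setNames(numeric(config$n_genes), genes)
  lfc_pre[driver_genes] <- config$delta_pre
  lfc_on[driver_genes] <- config$delta_on

  delta <- matrix(0, config$n_genes, ns, dimnames = list(genes, samp$sample_id))
  is_r <- samp$response == "R"
  delta[, is_r & samp$timepoint == "PRE"] <- lfc_pre
  delta[, is_r & samp$timepoint == "ON"] <- lfc_on

  log2mu <- mu0 + delta + rep(pat_off[samp$patient_id], each = config$n_genes)

  # per-sample pathway-activity fluctuation: each gene inherits the offset
  # of its home pathway (first set containing it) in every sample
  if (config$pathway_sd > 0) {
    module <- rep(NA_integer_, config$n_genes)
    names(module) <- genes
    for (k in rev(seq_along(sets))) module[sets[[k]]] <- k
    act <- matrix(stats::rnorm(length(sets) * ns, 0, config$pathway_sd),
                  length(sets), ns)
    in_mod <- !is.na(module)
    log2mu[in_mod, ] <- log2mu[in_mod, , drop = FALSE] +
      act[module[in_mod], , drop = FALSE]
  }
  mu <- sweep(2^log2mu, 2, libsize, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                  size = 1 / config$dispersion),
                   nrow = config$n_genes,
                   dimnames = list(genes, samp$sample_id))

  # survival at patient level
  hr_pat <- ifelse(response == "R", config$hazard_r,
                   config$hazard_r * config$hazard_ratio)
  pfs_event_t <- stats::rexp(np, rate = hr_pat)
  os_event_t <- stats::rexp(np, rate = hr_pat / 2)
  if (config$censor_rate > 0) {
    u_pfs <- .censor_horizon(hr_pat, config$censor_rate)
    u_os <- .censor_horizon(hr_pat / 2, config$censor_rate)
    c_pfs <- stats::runif(np, 0, u_pfs)
    c_os <- stats::runif(np, 0, u_os)
  } else {
    c_pfs <- c_os <- rep(Inf, np)
  }
  pfs <- pmin(pfs_event_t, c_pfs); pfs_ev <- as.integer(pfs_event_t <= c_pfs)
  os <- pmin(os_event_t, c_os); os_ev <- as.integer(os_event_t <= c_os)

  # RECIST consistent with true response under the 180-day rule on observed PFS
  recist <- character(np)
  for (i in seq_len(np)) {
    if (response[i] == "R") {
      recist[i] <- if (pfs[i] > 180)
        sample(c("CR", "PR", "SD"), 1, prob = c(0.2, 0.5, 0.3))
      else sample(c("CR", "PR"), 1, prob = c(0.3, 0.7))
    } else {
      recist[i] <- if (pfs[i] <= 180)
        sample(c("PD", "SD"), 1, prob = c(0.7, 0.3))
      else "PD"
    }
  }

  idx <- match(samp$patient_id, patients)
  samples <- data.frame(
    sample_id = samp$sample_id, patient_id = samp$patient_id,
    cohort = "synthetic", timepoint = samp$timepoint,
    recist = recist[idx],
    pfs_days = pfs[idx], pfs_event = pfs_ev[idx],
    os_days = os[idx], os_event = os_ev[idx],
    response = samp$response, stringsAsFactors = FALSE)
  samples <- validate_sample_table(samples)

  truth <- list(driver_pathways = drivers, driver_genes = driver_genes,
                lfc_pre = lfc_pre, lfc_on = lfc_on,
                response = stats::setNames(response, patients),
                libsize = stats::setNames(libsize, samp$sample_id),
                hazard_r = config$hazard_r,
                hazard_ratio = config$hazard_ratio)

  list(counts = expression_matrix(counts, "counts"), samples = samples,
       sets = sets, lengths = genesets$lengths, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Writes `counts.tsv`, `samples.tsv`, `sets.gmt`, `lengths.tsv` and
#' `truth.json` under `dir`.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(cohort$counts, file.path(dir, "counts.tsv"))
  write_sample_table(cohort$samples, file.path(dir, "samples.tsv"))
  write_gmt(cohort$sets, file.path(dir, "sets.gmt"))
  write_gene_lengths(cohort$lengths, file.path(dir, "lengths.tsv"))
  truth <- cohort$truth
  truth$lfc_pre <- NULL; truth$lfc_on <- NULL; truth$libsize <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
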