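#' Scenario configuration for the synthetic EHR generator
#'
#' Builds the full set of generator knobs with defaults encoding the
#' study conditions the package is calibrated against: a roughly 50/50
#' split between phenotypic IM/PM and NM/UM, 15% concomitant CYP2D6
#' inhibitor exposure, a 1.8% comparison-arm event rate and a true
#' marginal odds ratio of 1.19 carried by the phenoconverted phenotype.
#'
#' Three presets are shipped:
#' \describe{
#'   \item{`"headline"`}{the calibrated primary-analysis scenario; mild
#'     confounding through depression, anxiety, benzodiazepine use, back
#'     pain and age, with per-arm covariate shifts matching the observed
#'     cohort characteristics.}
#'   \item{`"inhibitor_effect"`}{the effect (true marginal OR 1.49) is
#'     carried by inhibitor exposure rather than by phenotype, for the
#'     inhibitor-only analysis restricted to genotypic NMs.}
#'   \item{`"confounded"`}{same structure with strong, one-directional
#'     confounding; used to demonstrate that the crude OR is biased while
#'     the IP-weighted OR recovers the truth.}
#' }
#'
#' @param name Preset name.
#' @param ... Named overrides, merged recursively over the preset (e.g.
#'   `outcome = list(target_or = 2)`).
#' @return A scenario list.
#' @export
#' @examples
#' sc <- pain_ed_scenario("headline", inhibitor = list(p = 0.2))
#' sc$inhibitor$p
pain_ed_scenario <- function(name = c("headline", "inhibitor_effect",
                                      "confounded"), ...) {
  name <- match.arg(name)
  sc <- list(
    name = name,
    epoch = "2014-01-01",
    study_days = 3287,                # 2014-01-01 .. 2022-12-31
    allele_freqs = c(
      "*1" = 0.36, "*2" = 0.18, "*35" = 0.02,
      "*41" = 0.08, "*17" = 0.05, "*9" = 0.02, "*29" = 0.01,
      "*10" = 0.05,
      "*4" = 0.15, "*5" = 0.03, "*3" = 0.02, "*6" = 0.01,
      "*8" = 0.005, "*7" = 0.003, "*11" = 0.001, "*15" = 0.001,
      "*1x2" = 0.006, "*2x2" = 0.004
    ),
    caller = list(
      tools = c("aldy", "cyrius", "pypgx", "stellarpgx"),
      error = c(0.03, 0.03, 0.03, 0.03),
      no_call = c(0.05, 0.05, 0.05, 0.05)
    ),
    inhibitor = list(p = 0.15, strong_share = 0.6, qualifying = 0.9,
                     split_refill = 0.3),
    opioid = list(
      drug_mix = c(hydrocodone = 0.45, tramadol = 0.25,
                   oxycodone = 0.22, codeine = 0.08),
      supply_choices = c(15, 30, 45, 60, 90),
      supply_probs = c(0.20, 0.35, 0.20, 0.15, 0.10),
      n_rx_probs = c(0.5, 0.3, 0.2),
      gap_choices = c(0, 1, 3, 7, 10, 13, 14, 16, 21, 30),
      gap_probs = c(0.15, 0.10, 0.10, 0.15, 0.10, 0.05,
                    0.05, 0.10, 0.10, 0.10)
    ),
    short_supply_rate = 0.02,
    cancer_rate = 0.02,
    demographics = list(female = 0.665,
                        race = c(White = 0.557, Black = 0.189,
                                 Other = 0.254),
                        mme_meanlog = 2.9, mme_sdlog = 1.1,
                        prior_ed_rate = 0.31),
    prevalence = c(
      pain_joint = 0.267, pain_ra = 0.244, pain_headache = 0.096,
      pain_neuropathic = 0.130, pain_fibromyalgia = 0.016,
      pain_injury = 0.260, cm_psychosis = 0.041, cm_oud = 0.012,
      cm_diabetes = 0.152, cm_kidney = 0.057, cm_liver = 0.053,
      med_pain = 0.544, med_antipsychotic = 0.153,
      med_cns_stimulant = 0.018, med_muscle_relaxant = 0.214
    ),
    confounders = list(
      binary = list(
        cm_depression = c(0.130, 0.209),
        cm_anxiety = c(0.113, 0.164),
        med_benzo = c(0.301, 0.340),
        pain_back = c(0.129, 0.157)
      ),
      age = c(mean0 = 50.6, mean1 = 51.8, sd = 15.4)
    ),
    outcome = list(
      p0 = 0.018,
      target_or = 1.19,
      effect_on = "phenotype",      # or "inhibitor"
      age_center = 51.2,
      delta = c(cm_depression = 0.35, cm_anxiety = 0.30,
                med_benzo = 0.20, pain_back = 0.30,
                age_decade = -0.40),
      noise_ed_rate = 0.02
    )
  )
  if (name == "inhibitor_effect") {
    sc$outcome$target_or <- 1.49
    sc$outcome$effect_on <- "inhibitor"
  }
  if (name == "confounded") {
    sc$confounders <- list(
      binary = list(
        cm_depression = c(0.10, 0.35),
        cm_anxiety = c(0.08, 0.30),
        med_benzo = c(0.25, 0.45),
        pain_back = c(0.10, 0.30)
      ),
      age = c(mean0 = 49, mean1 = 54, sd = 15)
    )
    sc$outcome$delta <- c(cm_depression = 0.8, cm_anxiety = 0.6,
                          med_benzo = 0.4, pain_back = 0.5,
                          age_decade = 0.3)
  }
  overrides <- list(...)
  if (length(overrides)) sc <- modify_list_deep(sc, overrides)
  sc
}

# sample() treats a length-1 numeric first argument as 1:x; guard against
# that for degenerate scenario settings (e.g. a single gap value)
sample_vec <- function(x, n, prob = NULL) {
  if (length(x) == 1) rep(x, n) else sample(x, n, TRUE, prob)
}

# latent person-level simulation: genotype, inhibitor exposure, exposure
# class, covariates, calibrated counterfactual outcome probabilities and
# the realized outcome. Assumes the RNG seed has been set by the caller.
sim_latent <- function(n, sc) {
  cfg <- pgx_defaults()
  af <- sc$allele_freqs
  if (abs(sum(af) - 1) > 1e-8) stop("allele frequencies must sum to 1")

  pid <- sprintf("P%07d", seq_len(n))
  alleles <- names(af)
  a1 <- sample(alleles, n, TRUE, af)
  a2 <- sample(alleles, n, TRUE, af)
  diplotype <- canonical_diplotype(paste0(a1, "/", a2))
  gscore <- allele_activity_or_na(a1, cfg$allele_activity) +
    allele_activity_or_na(a2, cfg$allele_activity)
  gpheno <- phenotype_from_score(gscore, cfg$phenotype_cuts)

  inh <- stats::rbinom(n, 1, sc$inhibitor$p)
  strength <- ifelse(stats::runif(n) < sc$inhibitor$strong_share,
                     "strong", "moderate")
  strength[inh == 0] <- "not-applicable"
  qualifying <- as.integer(inh == 1 &
                             stats::runif(n) < sc$inhibitor$qualifying)
  level <- ifelse(qualifying == 1, strength, "none")
  pc <- phenoconvert(gscore, level, cfg)
  ppheno <- pc$phenotype

  exposed <- if (identical(sc$outcome$effect_on, "inhibitor")) {
    inh
  } else {
    as.integer(ppheno %in% c("IM", "PM"))
  }

  # covariates; the configured confounders shift with the exposure arm
  co <- sc$confounders
  age <- stats::rnorm(n, ifelse(exposed == 1, co$age[["mean1"]],
                                co$age[["mean0"]]), co$age[["sd"]])
  age <- round(pmin(pmax(age, 14), 95), 1)
  X <- data.frame(person_id = pid, age = age, stringsAsFactors = FALSE)
  X$sex <- ifelse(stats::runif(n) < sc$demographics$female,
                  "female", "male")
  X$race_ethnicity <- sample(names(sc$demographics$race), n, TRUE,
                             sc$demographics$race)
  for (nm in names(co$binary)) {
    p <- ifelse(exposed == 1, co$binary[[nm]][2], co$binary[[nm]][1])
    X[[nm]] <- stats::rbinom(n, 1, p)
  }
  for (nm in names(sc$prevalence)) {
    X[[nm]] <- stats::rbinom(n, 1, sc$prevalence[[nm]])
  }
  X$mme_per_day <- round(stats::rlnorm(n, sc$demographics$mme_meanlog,
                                       sc$demographics$mme_sdlog), 1)
  X$prior_ed_visits <- stats::rpois(n, sc$demographics$prior_ed_rate)

  short <- stats::rbinom(n, 1, sc$short_supply_rate)
  cancer <- stats::rbinom(n, 1, sc$cancer_rate)
  eligible <- age >= 18 & short == 0 & cancer == 0

  # linear predictor of the outcome confounders
  delta <- sc$outcome$delta
  xb <- rep(0, n)
  for (nm in names(delta)) {
    xb <- xb + delta[[nm]] * if (nm == "age_decade") {
      (X$age - sc$outcome$age_center) / 10
    } else {
      X[[nm]]
    }
  }

  # calibrate the intercept to the comparison-arm event rate, then the
  # exposure coefficient to the target marginal OR by counterfactual
  # standardization over the eligible population
  p0t <- sc$outcome$p0
  alpha <- stats::uniroot(function(a) {
    mean(stats::plogis(a + xb[eligible & exposed == 0])) - p0t
  }, c(-20, 5), tol = 1e-12)$root
  xe <- xb[eligible]
  marg_or <- function(b) {
    p1 <- mean(stats::plogis(alpha + b + xe))
    p0 <- mean(stats::plogis(alpha + xe))
    (p1 / (1 - p1)) / (p0 / (1 - p0))
  }
  target <- sc$outcome$target_or
  beta <- tryCatch(
    stats::uniroot(function(b) marg_or(b) - target,
                   c(-6, 6), tol = 1e-12)$root,
    error = function(e) stop("calibration error: target marginal OR ",
                             target, " is unattainable", call. = FALSE))

  p0v <- stats::plogis(alpha + xb)
  p1v <- stats::plogis(alpha + beta + xb)
  y <- stats::rbinom(n, 1, ifelse(exposed == 1, p1v, p0v))

  per <- cbind(
    data.frame(allele_1 = a1, allele_2 = a2, diplotype = diplotype,
               genotype_score = gscore, genotype_phenotype = gpheno,
               inhibitor = inh, inhibitor_strength = strength,
               qualifying = qualifying, inhibitor_level = level,
               phenotype_pheno = ppheno, exposed = exposed,
               short_supply = short, cancer = cancer, eligible = eligible,
               p_untreated = p0v, p_treated = p1v, outcome = y,
               stringsAsFactors = FALSE),
    X[, setdiff(names(X), "person_id")]
  )
  per <- cbind(person_id = pid, per, stringsAsFactors = FALSE)
  list(per = per, alpha = alpha, beta = beta,
       marginal_or = marg_or(beta))
}

#' Simulate an analysis-ready cohort frame (latent fast path)
#'
#' Draws the person-level ground truth of a scenario — exposure class,
#' the 24 baseline covariates and the calibrated binary outcome — without
#' emitting prescription/encounter records, for fast estimator validation
#' (e.g. confidence-interval coverage studies). The true marginal OR,
#' obtained by counterfactual standardization over the simulated
#' population, equals the scenario's `outcome$target_or` by construction.
#'
#' @param n Number of persons.
#' @param scenario A [pain_ed_scenario()] list.
#' @param seed Integer seed (required; the generator is fully
#'   deterministic given `n`, `scenario`, `seed`).
#' @return data.frame of eligible persons with `person_id`, the
#'   [covariate_cols()] columns, `exposed` and `outcome`; attribute
#'   `"truth"` holds `alpha`, `beta` and `marginal_or`.
#' @export
simulate_cohort_frame <- function(n, scenario = pain_ed_scenario(), seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  lat <- sim_latent(n, scenario)
  per <- lat$per[lat$per$eligible, , drop = FALSE]
  out <- per[, c("person_id", covariate_cols(), "exposed", "outcome")]
  rownames(out) <- NULL
  attr(out, "truth") <- list(alpha = lat$alpha, beta = lat$beta,
                             marginal_or = lat$marginal_or,
                             scenario = scenario$name)
  out
}

#' Simulate a synthetic EHR dataset with known ground truth
#'
#' Generates the four person-level raw tables the pipeline consumes —
#' multi-caller genotype reports, prescription records, coded encounters
#' and demographics — together with the generating ground truth. The
#' latent structure is drawn first (diplotypes under Hardy-Weinberg,
#' inhibitor exposure, phenoconverted phenotype, covariates, and a
#' calibrated outcome; see [simulate_cohort_frame()]); records are then
#' emitted to realize it: each of four pseudo-callers reports the true
#' diplotype, a perturbed one, or a no-call; opioid refills straddle the
#' 14-day stitching boundary; inhibitor courses overlap the opioid
#' follow-up window for at least 3 days (qualifying) or at most 2 days
#' (sub-threshold); covariate flags become baseline-window encounter and
#' prescription rows; and outcome events become pain-coded ED encounters
#' inside follow-up.
#'
#' @inheritParams simulate_cohort_frame
#' @return A list of class `"pain_ed_sim"` with elements `calls`, `rx`,
#'   `encounters`, `demographics`, `truth` (person-level ground truth with
#'   attributes `alpha`, `beta`, `marginal_or`), `study_end` and
#'   `scenario`.
#' @export
#' @examples
#' sim <- simulate_pain_ed(500, pain_ed_scenario(), seed = 1)
#' head(sim$truth$exposed)
simulate_pain_ed <- function(n, scenario = pain_ed_scenario(), seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  sc <- scenario
  lat <- sim_latent(n, sc)
  per <- lat$per
  epoch <- as.Date(sc$epoch)
  study_end <- epoch + sc$study_days - 1
  pid <- per$person_id
  cfg <- pgx_defaults()

  ## ---- caller reports -------------------------------------------------
  tools <- sc$caller$tools
  alleles <- names(sc$allele_freqs)
  calls <- vector("list", length(tools))
  for (t in seq_along(tools)) {
    u <- stats::runif(n)
    nocall <- u < sc$caller$no_call[t]
    err <- !nocall & u < sc$caller$no_call[t] + sc$caller$error[t]
    b1 <- per$allele_1
    b2 <- per$allele_2
    m <- which(err)
    if (length(m)) {
      slot2 <- stats::runif(length(m)) < 0.5
      repl <- sample(alleles, length(m), TRUE)
      cur <- ifelse(slot2, b2[m], b1[m])
      same <- repl == cur
      repl[same] <- alleles[match(cur[same], alleles) %% length(alleles) + 1]
      b1[m[!slot2]] <- repl[!slot2]
      b2[m[slot2]] <- repl[slot2]
    }
    swap <- stats::runif(n) < 0.5
    dip <- ifelse(swap, paste0(b2, "/", b1), paste0(b1, "/", b2))
    dip[nocall] <- NA_character_
    calls[[t]] <- data.frame(person_id = pid, caller_id = tools[t],
                             diplotype = dip, stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  calls <- calls[order(calls$person_id, calls$caller_id), ]
  rownames(calls) <- NULL

  ## ---- opioid prescriptions ------------------------------------------
  op <- sc$opioid
  drug <- sample(names(op$drug_mix), n, TRUE, op$drug_mix)
  s <- sample(181:(sc$study_days - 187), n, TRUE)   # leave washout + follow-up room
  d1 <- ifelse(per$short_supply == 1, 5,
               sample_vec(op$supply_choices, n, op$supply_probs))
  n_rx <- ifelse(per$short_supply == 1, 1L,
                 sample(seq_along(op$n_rx_probs), n, TRUE, op$n_rx_probs))
  gap2 <- sample_vec(op$gap_choices, n, op$gap_probs)
  gap3 <- sample_vec(op$gap_choices, n, op$gap_probs)
  d2 <- sample_vec(op$supply_choices, n, op$supply_probs)
  d3 <- sample_vec(op$supply_choices, n, op$supply_probs)
  has2 <- n_rx >= 2
  has3 <- n_rx >= 3
  end1 <- s + d1 - 1
  start2 <- end1 + gap2 + 1
  end2 <- start2 + d2 - 1
  start3 <- end2 + gap3 + 1
  end3 <- start3 + d3 - 1
  gap_lim <- cfg$days$opioid_gap
  ep1_end <- end1
  in2 <- has2 & gap2 <= gap_lim
  ep1_end[in2] <- end2[in2]
  in3 <- in2 & has3 & gap3 <= gap_lim
  ep1_end[in3] <- end3[in3]

  index <- s + cfg$days$index_offset
  fu_end <- pmin(index + cfg$days$followup, ep1_end)
  fu_len <- fu_end - index + 1

  rx_op <- rbind(
    data.frame(person_id = pid, drug = drug, start = s, quantity = 4 * d1),
    data.frame(person_id = pid[has2], drug = drug[has2],
               start = start2[has2], quantity = 4 * d2[has2]),
    data.frame(person_id = pid[has3], drug = drug[has3],
               start = start3[has3], quantity = 4 * d3[has3])
  )
  rx_op$drug_class <- "opioid"
  rx_op$inhibitor_strength <- "not-applicable"

  ## ---- inhibitor prescriptions ---------------------------------------
  qi <- which(per$qualifying == 1)
  si <- which(per$inhibitor == 1 & per$qualifying == 0)
  inh_drug <- function(strength, m) {
    ifelse(strength == "strong",
           sample(cfg$drug_lists$strong_inhibitors, m, TRUE),
           sample(cfg$drug_lists$moderate_inhibitors, m, TRUE))
  }
  rx_inh <- NULL
  if (length(qi)) {
    m <- length(qi)
    dur <- sample(c(30, 60, 90), m, TRUE)
    width <- pmax(fu_len[qi] + 17, 1)
    istart <- index[qi] - 20 + floor(stats::runif(m) * width)
    drg <- inh_drug(per$inhibitor_strength[qi], m)
    split <- stats::runif(m) < sc$inhibitor$split_refill
    da <- ifelse(split, pmax(floor(dur / 2), 1), dur)
    ga <- sample(0:3, m, TRUE)
    r1 <- data.frame(person_id = pid[qi], drug = drg, start = istart,
                     quantity = 4 * da)
    r2 <- data.frame(person_id = pid[qi][split], drug = drg[split],
                     start = (istart + da)[split] + ga[split],
                     quantity = 4 * (dur - da)[split])
    rx_inh <- rbind(r1, r2)
    rx_inh$inhibitor_strength <-
      c(per$inhibitor_strength[qi], per$inhibitor_strength[qi][split])
  }
  if (length(si)) {
    m <- length(si)
    dur <- sample(c(30, 60), m, TRUE)
    iend <- index[si] + sample(0:1, m, TRUE)
    r <- data.frame(person_id = pid[si],
                    drug = inh_drug(per$inhibitor_strength[si], m),
                    start = iend - dur + 1, quantity = 4 * dur)
    r$inhibitor_strength <- per$inhibitor_strength[si]
    rx_inh <- rbind(rx_inh, r)
  }
  if (!is.null(rx_inh)) rx_inh$drug_class <- "inhibitor"

  ## ---- baseline medication rows for the medication-history flags -----
  rx_med <- NULL
  for (flag in names(cfg$covariate_meds)) {
    w <- which(per[[flag]] == 1)
    if (!length(w)) next
    r <- data.frame(
      person_id = pid[w],
      drug = sample(cfg$covariate_meds[[flag]], length(w), TRUE),
      start = index[w] - 4 - floor(stats::runif(length(w)) *
                                     (cfg$days$baseline - 4)),
      quantity = 30
    )
    r$inhibitor_strength <- "not-applicable"
    r$drug_class <- "other"
    rx_med <- rbind(rx_med, r)
  }

  rx <- rbind(rx_op, rx_inh, rx_med)
  rx <- data.frame(person_id = rx$person_id, drug = rx$drug,
                   drug_class = rx$drug_class,
                   inhibitor_strength = rx$inhibitor_strength,
                   start_date = epoch + rx$start, quantity = rx$quantity,
                   stringsAsFactors = FALSE)
  rx <- rx[order(rx$person_id, rx$drug, rx$start_date), ]
  rownames(rx) <- NULL

  ## ---- encounters -----------------------------------------------------
  enc <- list()
  base_date <- function(w) {
    index[w] - 1 - floor(stats::runif(length(w)) * cfg$days$baseline)
  }
  for (flag in names(cfg$code_sets$diagnosis_flags)) {
    w <- which(per[[flag]] == 1)
    if (!length(w)) next
    enc[[flag]] <- data.frame(person_id = pid[w], day = base_date(w),
                              setting = "other",
                              code = cfg$code_sets$diagnosis_flags[[flag]])
  }
  w <- which(per$cancer == 1)
  if (length(w)) {
    enc[["cancer"]] <- data.frame(person_id = pid[w], day = base_date(w),
                                  setting = "other",
                                  code = sample(cfg$code_sets$cancer,
                                                length(w), TRUE))
  }
  k <- per$prior_ed_visits
  if (any(k > 0)) {
    w <- rep(seq_len(n), k)
    enc[["prior_ed"]] <- data.frame(person_id = pid[w], day = base_date(w),
                                    setting = "ED", code = "V-GEN")
  }
  w <- which(per$outcome == 1)
  if (length(w)) {
    enc[["event"]] <- data.frame(
      person_id = pid[w],
      day = index[w] + floor(stats::runif(length(w)) * fu_len[w]),
      setting = "ED",
      code = sample(cfg$code_sets$pain_ed, length(w), TRUE))
  }
  w <- which(stats::rbinom(n, 1, sc$outcome$noise_ed_rate) == 1)
  if (length(w)) {
    enc[["noise"]] <- data.frame(
      person_id = pid[w],
      day = index[w] + floor(stats::runif(length(w)) * fu_len[w]),
      setting = "ED", code = "V-GEN")
  }
  enc <- do.call(rbind, enc)
  encounters <- data.frame(person_id = enc$person_id,
                           date = epoch + enc$day,
                           setting = enc$setting, code = enc$code,
                           stringsAsFactors = FALSE)
  encounters <- encounters[order(encounters$person_id, encounters$date), ]
  rownames(encounters) <- NULL

  demographics <- data.frame(
    person_id = pid, age = per$age, sex = per$sex,
    race_ethnicity = per$race_ethnicity, mme_per_day = per$mme_per_day,
    stringsAsFactors = FALSE
  )

  truth <- per
  truth$opioid_drug <- drug
  truth$opioid_start <- epoch + s
  truth$index_date <- epoch + index
  truth$followup_end <- epoch + fu_end
  attr(truth, "alpha") <- lat$alpha
  attr(truth, "beta") <- lat$beta
  attr(truth, "marginal_or") <- lat$marginal_or

  structure(list(calls = calls, rx = rx, encounters = encounters,
                 demographics = demographics, truth = truth,
                 study_end = study_end, scenario = sc),
            class = "pain_ed_sim")
}

#' @export
print.pain_ed_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic pain-ED dataset ('%s' scenario): %d persons\n",
    x$scenario$name, nrow(x$truth)))
  cat(sprintf("  exposed fraction %.3f; event rate %.4f; true marginal OR %.4f\n",
              mean(x$truth$exposed), mean(x$truth$outcome),
              attr(x$truth, "marginal_or")))
  cat(sprintf("  tables: calls %d, rx %d, encounters %d rows\n",
              nrow(x$calls), nrow(x$rx), nrow(x$encounters)))
  invisible(x)
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Convenience wrapper: consensus phenotyping, cohort construction and the
#' requested IPTW analysis on the raw tables of a [simulate_pain_ed()]
#' object.
#'
#' @param sim A `"pain_ed_sim"` object.
#' @param analysis,subgroup Passed to [analyze_cohort()].
#' @param config Configuration list.
#' @param ... Passed to [iptw_fit()] via [analyze_cohort()].
#' @return A list with `phenotypes`, `cohort` and `fit` (an
#'   `"iptw_fit"`).
#' @export
run_pipeline <- function(sim, analysis = "A", subgroup = "all",
                         config = pgx_defaults(), ...) {
  ph <- pgx_phenotypes(sim$calls, config)
  cohort <- build_cohort(sim$rx, sim$encounters, sim$demographics, ph,
                         config, study_end = sim$study_end)
  fit <- analyze_cohort(cohort, analysis, subgroup, ...)
  list(phenotypes = ph, cohort = cohort, fit = fit)
}
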