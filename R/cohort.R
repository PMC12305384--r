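#' Names of the 24 baseline covariates
#'
#' Demographics (age, sex, race/ethnicity), seven pain-diagnosis flags,
#' seven comorbidity flags, five medication-history flags plus the opioid
#' dose covariate (morphine milligram equivalents per day, carried through
#' as a number), and the count of prior ED visits.
#'
#' @return Character vector of length 24.
#' @export
covariate_cols <- function() {
  c("age", "sex", "race_ethnicity",
    "pain_back", "pain_joint", "pain_ra", "pain_headache",
    "pain_neuropathic", "pain_fibromyalgia", "pain_injury",
    "cm_depression", "cm_psychosis", "cm_anxiety", "cm_oud",
    "cm_diabetes", "cm_kidney", "cm_liver",
    "med_pain", "med_benzo", "med_antipsychotic", "med_cns_stimulant",
    "med_muscle_relaxant",
    "mme_per_day", "prior_ed_visits")
}

#' Apply cohort inclusion and exclusion rules
#'
#' Starting from each person's first stitched opioid episode, retains
#' adults (age >= 18 at index) with a qualifying opioid episode of at least
#' `days$min_supply` days' imputed supply and a determinate consensus
#' genotype, and removes persons with a cancer-coded encounter in the
#' `days$baseline` days before the index date (index = opioid start +
#' `days$index_offset`). Persons missing from the demographics or phenotype
#' tables are dropped as missing-data exclusions. A step-by-step attrition
#' log is attached.
#'
#' @param first_eps One opioid episode per person, as returned by the
#'   internal first-episode selection (columns `person_id`, `drug`,
#'   `start_date`, `end_date`).
#' @param phenotypes Output of [pgx_phenotypes()].
#' @param demographics data.frame with `person_id`, `age`, `sex`,
#'   `race_ethnicity`, `mme_per_day`.
#' @param encounters data.frame with `person_id`, `date`, `setting`,
#'   `code`.
#' @param config Configuration list.
#' @return data.frame of eligible persons with `person_id`, `opioid_drug`,
#'   `opioid_start`, `opioid_end`, `index_date`, `followup_end`,
#'   `genotype_score`, `genotype_phenotype`; attribute `"attrition"` holds
#'   the filter-by-filter counts.
#' @export
apply_inclusion_exclusion <- function(first_eps, phenotypes, demographics,
                                      encounters, config = pgx_defaults()) {
  d <- config$days
  ep <- first_eps
  ep$index_date <- ep$start_date + d$index_offset
  ep$followup_end <- pmin(ep$index_date + d$followup, ep$end_date)

  att <- data.frame(stage = "persons with an opioid exposure",
                    n = nrow(ep), stringsAsFactors = FALSE)
  step <- function(keep, label) {
    ep <<- ep[keep, , drop = FALSE]
    att <<- rbind(att, data.frame(stage = label, n = nrow(ep)))
  }

  di <- match(as.character(ep$person_id),
              as.character(demographics$person_id))
  pi <- match(as.character(ep$person_id),
              as.character(phenotypes$person_id))
  present <- !is.na(di) & !is.na(pi)
  ep$age <- demographics$age[di]
  ep$genotype_score <- phenotypes$genotype_score[pi]
  ep$genotype_phenotype <- phenotypes$genotype_phenotype[pi]
  step(present & !is.na(ep$age),
       "demographic and genotype records available")

  supply <- as.numeric(ep$end_date) - as.numeric(ep$start_date) + 1
  step(supply >= d$min_supply,
       sprintf("opioid episode of >= %d days' supply", d$min_supply))
  step(ep$age >= 18, "aged >= 18 years at index")
  step(ep$genotype_phenotype != "Indeterminate",
       "determinate consensus CYP2D6 genotype")

  cancer <- encounters$code %in% config$code_sets$cancer
  if (any(cancer)) {
    ce <- encounters[cancer, , drop = FALSE]
    i <- match(as.character(ce$person_id), as.character(ep$person_id))
    keep_rows <- !is.na(i)
    i <- i[keep_rows]
    dt <- as.numeric(ce$date[keep_rows])
    in_window <- dt >= as.numeric(ep$index_date[i]) - d$baseline &
      dt <= as.numeric(ep$index_date[i]) - 1
    has_cancer <- tabulate(i[in_window], nbins = nrow(ep)) > 0
  } else {
    has_cancer <- rep(FALSE, nrow(ep))
  }
  step(!has_cancer,
       sprintf("no cancer diagnosis in the %d days before index",
               d$baseline))

  out <- data.frame(
    person_id = ep$person_id,
    opioid_drug = ep$drug,
    opioid_start = ep$start_date,
    opioid_end = ep$end_date,
    index_date = ep$index_date,
    followup_end = ep$followup_end,
    age = ep$age,
    genotype_score = ep$genotype_score,
    genotype_phenotype = ep$genotype_phenotype,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "attrition") <- att
  out
}

#' Ascertain the pain-related ED visit outcome
#'
#' The outcome is 1 when any emergency-department encounter carrying a
#' pain-related diagnosis code falls inside the person's follow-up window
#' `[index_date, followup_end]` (both inclusive); the date of the first
#' such visit is recorded.
#'
#' @param cohort data.frame with `person_id`, `index_date`, `followup_end`.
#' @param encounters data.frame with `person_id`, `date`, `setting`,
#'   `code`.
#' @param pain_codes Character vector of pain-related diagnosis codes.
#' @return `cohort` with added columns `outcome` (0/1) and `outcome_date`.
#' @export
ascertain_outcome <- function(cohort, encounters,
                              pain_codes = pgx_defaults()$code_sets$pain_ed) {
  required_cols(encounters, c("person_id", "date", "setting", "code"),
                "encounters")
  hit <- encounters$setting == "ED" & encounters$code %in% pain_codes
  cohort$outcome <- 0L
  cohort$outcome_date <- cohort$index_date[NA_integer_]
  if (any(hit)) {
    he <- encounters[hit, , drop = FALSE]
    i <- match(as.character(he$person_id), as.character(cohort$person_id))
    ok <- !is.na(i)
    i <- i[ok]
    dt <- as.numeric(he$date[ok])
    inside <- dt >= as.numeric(cohort$index_date[i]) &
      dt <= as.numeric(cohort$followup_end[i])
    i <- i[inside]; dts <- he$date[ok][inside]
    if (length(i)) {
      first <- tapply(as.numeric(dts), factor(i, seq_len(nrow(cohort))), min)
      got <- which(!is.na(first))
      cohort$outcome[got] <- 1L
      cohort$outcome_date[got] <- cohort$index_date[got] -
        as.numeric(cohort$index_date[got]) + first[got]
    }
  }
  cohort
}

#' Assemble the 24 baseline covariates
#'
#' Builds the covariate vector for each cohort person from demographics,
#' baseline-window encounters and baseline-window prescriptions. The
#' baseline window is the `days$baseline` days before the index date,
#' `[index - 180 d, index - 1 d]` by default. Diagnosis flags come from
#' encounter codes (see `code_sets$diagnosis_flags`), medication-history
#' flags from prescription drug names (see `covariate_meds`); the pain
#' medication flag additionally counts opioid prescriptions that started
#' before the index opioid exposure. `prior_ed_visits` counts all ED
#' encounters in the baseline window; `mme_per_day` is carried through
#' from demographics.
#'
#' @param cohort data.frame with `person_id`, `index_date`, `opioid_start`.
#' @param encounters,rx,demographics Source tables.
#' @param config Configuration list.
#' @return `cohort` with the [covariate_cols()] columns added.
#' @export
assemble_covariates <- function(cohort, encounters, rx, demographics,
                                config = pgx_defaults()) {
  d <- config$days
  n <- nrow(cohort)
  pid <- as.character(cohort$person_id)
  lo <- as.numeric(cohort$index_date) - d$baseline
  hi <- as.numeric(cohort$index_date) - 1

  di <- match(pid, as.character(demographics$person_id))
  cohort$age <- demographics$age[di]
  cohort$sex <- as.character(demographics$sex[di])
  cohort$race_ethnicity <- as.character(demographics$race_ethnicity[di])
  cohort$mme_per_day <- demographics$mme_per_day[di]

  # encounters in each person's baseline window
  ei <- match(as.character(encounters$person_id), pid)
  eok <- !is.na(ei)
  edt <- as.numeric(encounters$date)
  in_base <- eok & edt >= lo[pmax(ei, 1L)] & edt <= hi[pmax(ei, 1L)]
  ef <- factor(ei[in_base], seq_len(n))
  for (flag in names(config$code_sets$diagnosis_flags)) {
    codes <- config$code_sets$diagnosis_flags[[flag]]
    m <- encounters$code[in_base] %in% codes
    cohort[[flag]] <- as.integer(tabulate(ef[m], nbins = n) > 0)
  }
  cohort$prior_ed_visits <-
    tabulate(ef[encounters$setting[in_base] == "ED"], nbins = n)

  # prescriptions in the baseline window
  ri <- match(as.character(rx$person_id), pid)
  rok <- !is.na(ri)
  rdt <- as.numeric(rx$start_date)
  r_in <- rok & rdt >= lo[pmax(ri, 1L)] & rdt <= hi[pmax(ri, 1L)]
  rf <- factor(ri[r_in], seq_len(n))
  drug <- tolower(as.character(rx$drug))
  for (flag in names(config$covariate_meds)) {
    m <- drug[r_in] %in% config$covariate_meds[[flag]]
    cohort[[flag]] <- as.integer(tabulate(rf[m], nbins = n) > 0)
  }
  # prior opioid use also counts toward the pain-medication flag, but the
  # index opioid exposure itself (starting at index - index_offset) does not
  cls <- if ("drug_class" %in% names(rx)) as.character(rx$drug_class) else
    rep("other", nrow(rx))
  prior_op <- r_in & cls == "opioid" &
    rdt < as.numeric(cohort$opioid_start)[pmax(ri, 1L)]
  cohort$med_pain <- as.integer(cohort$med_pain |
                                  tabulate(rf[prior_op[r_in]], nbins = n) > 0)
  cohort
}

#' Assign phenoconverted phenotypes and analysis groups
#'
#' Derives each person's phenoconverted phenotype from the genotype
#' activity score and the concomitant inhibitor level, then labels the
#' three analyses: (A) the primary contrast of phenotypic IM/PM versus
#' phenotypic NM/UM over the whole cohort; (B) inhibitor exposure versus
#' inhibitor-free, restricted to genotypic NMs; and (C) genotypic IM/PM
#' versus genotypic NM/UM, restricted to inhibitor-free persons. The drug
#' subgroup splits hydrocodone/tramadol/codeine (`"htc"`) from oxycodone.
#'
#' @param cohort data.frame with `genotype_score`, `genotype_phenotype`,
#'   `inhibitor_level`, `inh_free`, `opioid_drug`.
#' @param config Configuration list.
#' @return `cohort` with added columns `adjusted_score`,
#'   `phenotype_pheno` (`"pUM"`..., the phenoconverted category),
#'   `a_exposed`, `in_b`, `b_exposed`, `in_c`, `c_exposed`, `subgroup`.
#' @export
assign_groups <- function(cohort, config = pgx_defaults()) {
  pc <- phenoconvert(cohort$genotype_score, cohort$inhibitor_level, config)
  cohort$adjusted_score <- pc$adjusted_activity_score
  cohort$phenotype_pheno <- ifelse(pc$phenotype == "Indeterminate",
                                   "Indeterminate",
                                   paste0("p", pc$phenotype))
  cohort$a_exposed <- as.integer(cohort$phenotype_pheno %in% c("pIM", "pPM"))
  cohort$in_b <- cohort$genotype_phenotype == "NM"
  cohort$b_exposed <- as.integer(!cohort$inh_free)
  cohort$in_c <- cohort$inh_free
  cohort$c_exposed <- as.integer(cohort$genotype_phenotype %in% c("IM", "PM"))
  cohort$subgroup <- ifelse(cohort$opioid_drug == "oxycodone",
                            "oxycodone", "htc")
  cohort
}

#' Build the analysis cohort from raw tables
#'
#' End-to-end cohort assembly: stitches prescriptions into exposure
#' episodes, selects each person's first opioid episode, applies the
#' inclusion/exclusion rules with an attrition log, determines concomitant
#' inhibitor exposure over the follow-up window and the inhibitor-free
#' status (no inhibitor episode within the washout-through-study-end
#' interval), ascertains the pain-related ED visit outcome, assembles the
#' 24 baseline covariates and assigns analysis groups.
#'
#' @param rx Prescription table: `person_id`, `drug`, `drug_class`,
#'   `inhibitor_strength`, `start_date`, `quantity`.
#' @param encounters Encounter table: `person_id`, `date`, `setting`,
#'   `code`.
#' @param demographics Demographics: `person_id`, `age`, `sex`,
#'   `race_ethnicity`, `mme_per_day`.
#' @param phenotypes Output of [pgx_phenotypes()], one row per person.
#' @param config Configuration list, see [pgx_defaults()].
#' @param study_end End of the study period; defaults to the latest
#'   episode end date in `rx`.
#' @return The analysis-ready cohort data.frame (one row per person) with
#'   attribute `"attrition"`.
#' @export
build_cohort <- function(rx, encounters, demographics, phenotypes,
                         config = pgx_defaults(), study_end = NULL) {
  episodes <- drug_exposures(rx, config)
  op <- episodes[episodes$drug_class == "opioid", , drop = FALSE]
  if (!nrow(op)) stop("no opioid exposure episodes found")
  inh <- episodes[episodes$drug_class == "inhibitor", , drop = FALSE]
  if (is.null(study_end)) study_end <- max(episodes$end_date)

  first_eps <- first_opioid_episodes(op)
  cohort <- apply_inclusion_exclusion(first_eps, phenotypes, demographics,
                                      encounters, config)
  att <- attr(cohort, "attrition")

  # concomitant inhibitor level over the follow-up window
  win <- data.frame(person_id = cohort$person_id,
                    win_start = cohort$index_date,
                    win_end = cohort$followup_end)
  conc <- concomitancy_by_person(win, inh, config$days$min_overlap)
  cohort$inhibitor_level <- conc$inhibitor_level
  cohort$overlap_days <- conc$overlap_days

  # inhibitor-free status: washout before opioid start through study end
  free <- rep(TRUE, nrow(cohort))
  if (nrow(inh)) {
    i <- match(as.character(inh$person_id), as.character(cohort$person_id))
    ok <- !is.na(i)
    lo <- as.numeric(cohort$opioid_start) - config$days$washout
    touches <- ok & as.numeric(inh$end_date) >= lo[pmax(i, 1L)] &
      as.numeric(inh$start_date) <= as.numeric(study_end)
    free <- tabulate(i[touches], nbins = nrow(cohort)) == 0
  }
  cohort$inh_free <- free

  cohort <- ascertain_outcome(cohort, encounters,
                              config$code_sets$pain_ed)
  cohort <- assemble_covariates(cohort, encounters, rx, demographics,
                                config)
  cohort <- assign_groups(cohort, config)
  attr(cohort, "attrition") <- att
  cohort
}
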