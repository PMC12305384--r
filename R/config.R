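#' Default analysis configuration
#'
#' Returns the full set of shipped defaults used across the pipeline: the
#' CYP2D6 allele activity table, phenotype cut-points, inhibitor factors,
#' drug lists, diagnosis/medication code sets and the day-count conventions
#' (stitching gaps, washout, index offset, follow-up length).
#'
#' The activity values and phenotype boundaries follow the CPIC activity
#' score convention: fully functional alleles (*1, *2, *35) score 1,
#' reduced-function alleles *9/*17/*29/*41 score 0.5 and *10 scores 0.25,
#' nonfunctional alleles (*3 through *8, *11, *15) score 0. A diplotype's
#' activity score is the sum over its two alleles (a gene duplication
#' "xN" multiplies the base allele value by N). Phenotypes: score > 2.25
#' ultrarapid (UM); 1.25 to 2.25 inclusive normal (NM); strictly between 0
#' and 1.25 intermediate (IM); exactly 0 poor (PM). A concomitant strong
#' CYP2D6 inhibitor multiplies the score by 0, a moderate inhibitor by 0.5.
#'
#' Every element can be overridden through [pgx_config()].
#'
#' @return A named list with components `allele_activity`,
#'   `phenotype_cuts`, `inhibitor_factors`, `consensus`, `drug_lists`,
#'   `covariate_meds`, `code_sets` and `days` (day-count conventions).
#' @export
#' @examples
#' cfg <- pgx_defaults()
#' cfg$allele_activity[["*41"]]
pgx_defaults <- function() {
  list(
    allele_activity = c(
      "*1" = 1, "*2" = 1, "*35" = 1,
      "*9" = 0.5, "*17" = 0.5, "*29" = 0.5, "*41" = 0.5,
      "*10" = 0.25,
      "*3" = 0, "*4" = 0, "*5" = 0, "*6" = 0, "*7" = 0, "*8" = 0,
      "*11" = 0, "*15" = 0
    ),
    # [lower NM bound, upper NM bound]; UM strictly above, IM strictly
    # inside (0, lower), PM exactly 0
    phenotype_cuts = c(nm_low = 1.25, nm_high = 2.25),
    inhibitor_factors = c(none = 1, moderate = 0.5, strong = 0),
    consensus = list(
      min_tools = 2,          # a consensus needs >= this many agreeing calls
      majority = "called"     # strict majority of tools that made a call
    ),
    drug_lists = list(
      opioids = c("codeine", "hydrocodone", "oxycodone", "tramadol"),
      strong_inhibitors = c("bupropion", "fluoxetine", "paroxetine",
                            "terbinafine", "quinidine"),
      moderate_inhibitors = c("abiraterone", "cinacalcet", "mirabegron",
                              "duloxetine", "lorcaserin", "rolapitant")
    ),
    # medication-history covariates: drug names counted for each flag
    covariate_meds = list(
      med_pain = c("ibuprofen", "naproxen", "acetaminophen", "gabapentin"),
      med_benzo = c("alprazolam", "diazepam", "lorazepam", "zolpidem"),
      med_antipsychotic = c("quetiapine", "olanzapine", "risperidone"),
      med_cns_stimulant = c("methylphenidate", "amphetamine", "modafinil"),
      med_muscle_relaxant = c("cyclobenzaprine", "methocarbamol",
                              "baclofen", "tizanidine")
    ),
    code_sets = list(
      # illustrative defaults; real deployments supply their own code lists
      pain_ed = c("PAIN-ACUTE", "PAIN-BACK", "PAIN-ABD", "PAIN-HEAD",
                  "PAIN-MSK"),
      cancer = c("CA-PRIMARY", "CA-SECONDARY"),
      diagnosis_flags = list(
        pain_back = "DX-BACKPAIN",
        pain_joint = "DX-JOINTPAIN",
        pain_ra = "DX-RA",
        pain_headache = "DX-HEADACHE",
        pain_neuropathic = "DX-NEUROPATHY",
        pain_fibromyalgia = "DX-FIBROMYALGIA",
        pain_injury = "DX-INJURY",
        cm_depression = "DX-DEPRESSION",
        cm_psychosis = "DX-PSYCHOSIS",
        cm_anxiety = "DX-ANXIETY",
        cm_oud = "DX-OUD",
        cm_diabetes = "DX-DIABETES",
        cm_kidney = "DX-KIDNEYFAIL",
        cm_liver = "DX-LIVER"
      )
    ),
    days = list(
      tablets_per_day = 4,     # imputed daily consumption
      opioid_gap = 13,         # merge opioid refills when gap <= 13 d (< 14 d)
      inhibitor_gap = 3,       # merge inhibitor refills when gap <= 3 d
      min_overlap = 3,         # concomitancy needs >= 3 overlapping days
      washout = 180,           # inhibitor-free look-back before opioid start
      index_offset = 3,        # index date = opioid start + 3 d
      followup = 60,           # follow-up cap after index
      min_supply = 7,          # qualifying opioid episode length (days)
      baseline = 180           # covariate/cancer look-back before index
    )
  )
}

#' Load a configuration, optionally overriding defaults from YAML
#'
#' Reads a YAML document and merges it (recursively, by name) over
#' [pgx_defaults()], so a file only needs to state the values it changes,
#' e.g. an updated allele activity table or site-specific code lists.
#'
#' @param file Path to a YAML file, or `NULL` for pure defaults.
#' @return A configuration list with the same shape as [pgx_defaults()].
#' @export
pgx_config <- function(file = NULL) {
  cfg <- pgx_defaults()
  if (is.null(file)) return(cfg)
  user <- yaml::read_yaml(file)
  modify_list_deep(cfg, user)
}

modify_list_deep <- function(base, new) {
  stopifnot(is.list(base), is.list(new))
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else if (is.numeric(base[[nm]]) && !is.null(names(base[[nm]])) &&
               is.list(new[[nm]])) {
      # named numeric vectors come back from YAML as named lists
      v <- unlist(new[[nm]])
      base[[nm]][names(v)] <- v
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}
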