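# A small hand-built EHR: seven persons exercising every inclusion,
# exclusion, outcome and grouping rule. Days are offsets from the origin.
origin <- as.Date("2020-01-01")
day <- function(d) origin + d

tiny_ehr <- function() {
  agree <- function(p, dip) data.frame(person_id = p,
                                       caller_id = c("a", "b", "c", "d"),
                                       diplotype = dip)
  calls <- rbind(
    agree("p1", "*1/*1"),                       # NM, score 2
    agree("p2", "*1/*1"),
    agree("p3", "*1/*1"),
    data.frame(person_id = "p4", caller_id = c("a", "b", "c", "d"),
               diplotype = c("*1/*1", "*1/*1", "*1/*4", "*4/*1")),  # 2-2
    agree("p5", "*1/*1"),
    agree("p6", "*4/*4"),                       # PM, score 0
    agree("p7", "*1/*2")                        # NM, score 2
  )
  # every person: one opioid, 30-day supply starting day 100
  # (p3: 6-day supply only)
  rx <- rbind(
    make_rx(c("p1", "p2"), "hydrocodone", 100, 120),
    make_rx("p3", "hydrocodone", 100, 24),
    make_rx(c("p4", "p5", "p6", "p7"), "hydrocodone", 100, 120),
    make_rx("p1", "fluoxetine", 105, 120, drug_class = "inhibitor",
            inhibitor_strength = "strong"),
    make_rx("p7", "ibuprofen", 50, 60, drug_class = "other")
  )
  # index = day 103; follow-up = day 103..129; baseline window -77..102
  enc <- data.frame(
    person_id = c("p1", "p5", "p6", "p6", "p6", "p7", "p7", "p7"),
    date = day(c(110,
                 103 - 180,      # cancer exactly 180 d before index: excluded
                 103 - 181,      # cancer 181 d before: retained
                 108,            # pain code but not in the ED
                 130,            # pain ED visit 1 day past follow-up end
                 129,            # pain ED visit exactly at follow-up end
                 73,             # depression at index - 30: flag set
                 108)),          # depression after index: no flag
    setting = c("ED", "other", "other", "other", "ED", "ED", "other", "other"),
    code = c("PAIN-ACUTE", "CA-PRIMARY", "CA-PRIMARY", "PAIN-BACK",
             "PAIN-ACUTE", "PAIN-ACUTE", "DX-DEPRESSION", "DX-DEPRESSION"),
    stringsAsFactors = FALSE
  )
  demo <- data.frame(
    person_id = paste0("p", 1:7),
    age = c(40, 17, 40, 40, 40, 40, 40),
    sex = "female", race_ethnicity = "White", mme_per_day = 30,
    stringsAsFactors = FALSE
  )
  list(calls = calls, rx = rx, encounters = enc, demographics = demo)
}

build_tiny <- function() {
  e <- tiny_ehr()
  ph <- pgx_phenotypes(e$calls)
  build_cohort(e$rx, e$encounters, e$demographics, ph,
               study_end = day(400))
}

test_that("inclusion and exclusion rules fire at the printed boundaries", {
  co <- build_tiny()
  expect_setequal(co$person_id, c("p1", "p6", "p7"))
  att <- attr(co, "attrition")
  expect_equal(att$n[1], 7)
  expect_true(all(diff(att$n) <= 0))
  # p3 fails the 7-day supply rule; a 7-day supply is retained
  e <- tiny_ehr()
  e$rx$quantity[e$rx$person_id == "p3" & e$rx$drug_class == "opioid"] <- 28
  co2 <- build_cohort(e$rx, e$encounters, e$demographics,
                      pgx_phenotypes(e$calls), study_end = day(400))
  expect_true("p3" %in% co2$person_id)
  # an 18th birthday at index is included
  e$demographics$age[e$demographics$person_id == "p2"] <- 18
  co3 <- build_cohort(e$rx, e$encounters, e$demographics,
                      pgx_phenotypes(e$calls), study_end = day(400))
  expect_true("p2" %in% co3$person_id)
})

test_that("index and follow-up windows follow the study design", {
  co <- build_tiny()
  p1 <- co[co$person_id == "p1", ]
  expect_equal(p1$index_date, day(103))
  expect_equal(p1$followup_end, day(129))   # opioid ends before index + 60
  # a 90-day supply is capped at index + 60
  e <- tiny_ehr()
  e$rx$quantity[e$rx$person_id == "p6" & e$rx$drug_class == "opioid"] <- 360
  co2 <- build_cohort(e$rx, e$encounters, e$demographics,
                      pgx_phenotypes(e$calls), study_end = day(400))
  expect_equal(co2$followup_end[co2$person_id == "p6"], day(163))
})

test_that("outcome is the first pain-coded ED visit inside follow-up", {
  co <- build_tiny()
  expect_equal(co$outcome[co$person_id == "p1"], 1L)
  expect_equal(co$outcome_date[co$person_id == "p1"], day(110))
  # p6's pain code was not in the ED and its ED visit was past follow-up
  expect_equal(co$outcome[co$person_id == "p6"], 0L)
  # p7's visit at exactly followup_end counts ...
  expect_equal(co$outcome[co$person_id == "p7"], 1L)
  # ... and flips to 0 when pushed one day past the window
  e <- tiny_ehr()
  e$encounters$date[6] <- day(130)
  co2 <- build_cohort(e$rx, e$encounters, e$demographics,
                      pgx_phenotypes(e$calls), study_end = day(400))
  expect_equal(co2$outcome[co2$person_id == "p7"], 0L)
})

test_that("baseline covariates are assembled from the 180-day window", {
  co <- build_tiny()
  p7 <- co[co$person_id == "p7", ]
  expect_equal(p7$cm_depression, 1L)   # dx at index - 30
  expect_equal(p7$med_pain, 1L)        # ibuprofen in the window
  p6 <- co[co$person_id == "p6", ]
  expect_equal(p6$cm_depression, 0L)   # dx only after index
  expect_true(all(p6[, c("pain_back", "cm_anxiety", "med_benzo")] == 0))
  expect_equal(p6$prior_ed_visits, 0)
  expect_equal(p7$age, 40)
  expect_equal(p7$mme_per_day, 30)
  expect_true(all(covariate_cols() %in% names(co)))
})

test_that("prior opioid prescriptions count toward the pain-medication flag", {
  cohort <- data.frame(person_id = "x1", index_date = day(103),
                       opioid_start = day(100))
  demo <- data.frame(person_id = "x1", age = 50, sex = "male",
                     race_ethnicity = "Other", mme_per_day = 10)
  enc <- data.frame(person_id = character(), date = day(integer()),
                    setting = character(), code = character())
  # an opioid starting before the index exposure sets the flag
  rx1 <- make_rx("x1", c("oxycodone", "hydrocodone"), c(20, 100), c(40, 120))
  out <- assemble_covariates(cohort, enc, rx1, demo)
  expect_equal(out$med_pain, 1L)
  # the index opioid prescription itself does not
  rx2 <- make_rx("x1", "hydrocodone", 100, 120)
  expect_equal(assemble_covariates(cohort, enc, rx2, demo)$med_pain, 0L)
})

test_that("analysis groups follow phenotype and inhibitor status", {
  co <- build_tiny()
  p1 <- co[co$person_id == "p1", ]   # genotypic NM + strong inhibitor
  expect_equal(p1$phenotype_pheno, "pPM")
  expect_equal(p1$inhibitor_level, "strong")
  expect_equal(p1$a_exposed, 1L)
  expect_true(p1$in_b); expect_equal(p1$b_exposed, 1L)
  expect_false(p1$in_c)
  p6 <- co[co$person_id == "p6", ]   # genotypic PM, no inhibitor
  expect_equal(p6$phenotype_pheno, "pPM")
  expect_equal(p6$a_exposed, 1L)
  expect_false(p6$in_b)
  expect_true(p6$in_c); expect_equal(p6$c_exposed, 1L)
  p7 <- co[co$person_id == "p7", ]   # genotypic NM, no inhibitor
  expect_equal(p7$phenotype_pheno, "pNM")
  expect_equal(p7$a_exposed, 0L)
  expect_true(p7$in_b); expect_equal(p7$b_exposed, 0L)
  expect_true(p7$in_c); expect_equal(p7$c_exposed, 0L)
  expect_equal(unique(co$subgroup), "htc")
})

test_that("a sub-threshold inhibitor overlap phenoconverts nobody", {
  e <- tiny_ehr()
  # shift p1's inhibitor so it overlaps follow-up by 2 days only
  i <- which(e$rx$drug == "fluoxetine")
  e$rx$start_date[i] <- day(75)     # 30-day supply: days 75..104
  co <- build_cohort(e$rx, e$encounters, e$demographics,
                     pgx_phenotypes(e$calls), study_end = day(400))
  p1 <- co[co$person_id == "p1", ]
  expect_equal(p1$inhibitor_level, "none")
  expect_equal(p1$phenotype_pheno, "pNM")
  expect_equal(p1$a_exposed, 0L)
  # but the person is still not inhibitor-free, hence B-exposed, not in C
  expect_equal(p1$b_exposed, 1L)
  expect_false(p1$in_c)
})

test_that("every cohort person sits in exactly one arm of the primary analysis", {
  sim <- simulate_pain_ed(1500, pain_ed_scenario(), seed = 3)
  ph <- pgx_phenotypes(sim$calls)
  co <- build_cohort(sim$rx, sim$encounters, sim$demographics, ph,
                     study_end = sim$study_end)
  expect_true(all(co$a_exposed %in% c(0L, 1L)))
  expect_equal(sum(co$a_exposed == 1) + sum(co$a_exposed == 0), nrow(co))
  # B and C restrictions: B-exposed persons are never in C
  expect_true(all(!co$in_c[co$in_b & co$b_exposed == 1]))
  att <- attr(co, "attrition")
  expect_true(all(diff(att$n) <= 0))
})
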