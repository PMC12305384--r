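#' @keywords internal
#' Parse star-allele labels into base name and copy multiplier.
#' Accepts "*<digits>" with an optional "x<digits>" duplication suffix.
#' Returns a data.frame(base, num, copies); unparseable input gives NA rows.
parse_star_allele <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^\\*([0-9]+)(x([0-9]+))?$", x))
  base <- vapply(m, function(g) if (length(g)) paste0("*", g[2]) else NA_character_, "")
  num <- vapply(m, function(g) if (length(g)) as.numeric(g[2]) else NA_real_, 0)
  copies <- vapply(m, function(g) {
    if (!length(g)) return(NA_real_)
    if (nzchar(g[4])) as.numeric(g[4]) else 1
  }, 0)
  copies[!is.na(copies) & copies < 1] <- NA_real_
  data.frame(base = base, num = num, copies = copies,
             stringsAsFactors = FALSE)
}

#' Activity value of a single star allele
#'
#' Looks an allele up in the activity table and multiplies by its gene copy
#' number, so a duplication such as `"*1x2"` scores twice the `"*1"` value.
#'
#' @param allele Character vector of star-allele labels, e.g. `"*41"`,
#'   `"*1x2"`.
#' @param allele_table Named numeric vector mapping allele name to activity
#'   value; defaults to the shipped CPIC-style table in [pgx_defaults()].
#' @return Numeric vector of activity values.
#' @seealso [diplotype_activity_score()], [phenotype_from_score()]
#' @export
#' @examples
#' allele_activity(c("*2", "*10", "*1x2"))
allele_activity <- function(allele,
                            allele_table = pgx_defaults()$allele_activity) {
  p <- parse_star_allele(allele)
  bad <- is.na(p$base)
  if (any(bad)) {
    stop("malformed star-allele label: ",
         paste(unique(allele[bad]), collapse = ", "))
  }
  unknown <- !(p$base %in% names(allele_table))
  if (any(unknown)) {
    stop("allele not in activity table: ",
         paste(unique(p$base[unknown]), collapse = ", "))
  }
  unname(allele_table[p$base] * p$copies)
}

# vectorised lookup that yields NA (instead of an error) for unknown or
# malformed alleles; used for table-level processing where unresolvable
# alleles become Indeterminate persons
allele_activity_or_na <- function(allele, allele_table) {
  p <- parse_star_allele(allele)
  val <- allele_table[p$base]          # NA for unknown
  unname(as.numeric(val) * p$copies)
}

#' Activity score of a diplotype
#'
#' The activity score is the sum of the values assigned to each of the two
#' alleles of a diplotype.
#'
#' @param diplotype Character vector like `"*1/*4"`, or a length-2 character
#'   vector of alleles when `length(diplotype) == 2` and no `/` is present.
#' @inheritParams allele_activity
#' @return Numeric vector of diplotype activity scores.
#' @export
#' @examples
#' diplotype_activity_score("*1/*10")  # 1.25
diplotype_activity_score <- function(diplotype,
                                     allele_table = pgx_defaults()$allele_activity) {
  if (length(diplotype) == 2 && !any(grepl("/", diplotype, fixed = TRUE))) {
    diplotype <- paste(diplotype, collapse = "/")
  }
  parts <- strsplit(as.character(diplotype), "/", fixed = TRUE)
  n <- lengths(parts)
  if (any(n != 2)) stop("a diplotype must contain exactly two alleles")
  a1 <- vapply(parts, `[`, "", 1)
  a2 <- vapply(parts, `[`, "", 2)
  allele_activity(a1, allele_table) + allele_activity(a2, allele_table)
}

#' Map an activity score to a metabolizer phenotype
#'
#' Categories: `UM` for scores strictly above the upper normal bound
#' (default 2.25), `NM` for scores in \[1.25, 2.25\], `IM` for scores
#' strictly between 0 and 1.25, and `PM` for a score of exactly 0. Both
#' boundary scores classify as `NM`.
#'
#' @param score Nonnegative numeric vector of activity scores; `NA` gives
#'   `NA`.
#' @param cuts Length-2 named vector `c(nm_low=, nm_high=)`.
#' @return Character vector in `c("UM","NM","IM","PM")`.
#' @export
#' @examples
#' phenotype_from_score(c(0, 0.5, 1.25, 2.25, 3))
phenotype_from_score <- function(score, cuts = pgx_defaults()$phenotype_cuts) {
  score <- as.numeric(score)
  if (any(score < 0, na.rm = TRUE)) stop("activity score must be nonnegative")
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score > cuts[["nm_high"]]] <- "UM"
  out[!is.na(score) & score >= cuts[["nm_low"]] & score <= cuts[["nm_high"]]] <- "NM"
  out[!is.na(score) & score > 0 & score < cuts[["nm_low"]]] <- "IM"
  out[!is.na(score) & score == 0] <- "PM"
  out
}

#' Inhibitor-mediated phenoconversion
#'
#' Adjusts a genotype-based activity score for a concomitant CYP2D6
#' inhibitor: adjusted score = inhibitor factor x genotype score, with
#' factor 1 for no inhibitor, 0.5 for a moderate inhibitor and 0 for a
#' strong inhibitor. The phenotype is then re-derived from the adjusted
#' score, so e.g. a normal metabolizer (score 2.0) on a strong inhibitor
#' becomes a phenotypic poor metabolizer.
#'
#' @param genotype_score Nonnegative numeric vector of genotype-based
#'   activity scores (`NA` allowed; propagates).
#' @param level Character vector in `c("none","moderate","strong")`,
#'   recycled against `genotype_score`.
#' @param config Configuration list, see [pgx_defaults()].
#' @return A data.frame with columns `genotype_activity_score`,
#'   `inhibitor_factor`, `adjusted_activity_score` and `phenotype`
#'   (`"Indeterminate"` where the genotype score is `NA`).
#' @export
#' @examples
#' phenoconvert(2, c("none", "moderate", "strong"))
phenoconvert <- function(genotype_score, level = "none",
                         config = pgx_defaults()) {
  factors <- config$inhibitor_factors
  level <- as.character(level)
  if (!all(level %in% names(factors))) {
    stop("inhibitor level must be one of: ",
         paste(names(factors), collapse = ", "))
  }
  n <- max(length(genotype_score), length(level))
  genotype_score <- rep_len(as.numeric(genotype_score), n)
  level <- rep_len(level, n)
  if (any(genotype_score < 0, na.rm = TRUE)) {
    stop("activity score must be nonnegative")
  }
  f <- unname(factors[level])
  adj <- f * genotype_score
  ph <- phenotype_from_score(adj, config$phenotype_cuts)
  ph[is.na(ph)] <- "Indeterminate"
  data.frame(
    genotype_activity_score = genotype_score,
    inhibitor_factor = f,
    adjusted_activity_score = adj,
    phenotype = ph,
    stringsAsFactors = FALSE
  )
}

#' Canonicalize diplotype strings
#'
#' Orders the two alleles of a diplotype by numeric allele id (then by copy
#' multiplier), so `"*4/*1"` and `"*1/*4"` compare equal. Strings that are
#' missing, `"NA"`, or not of the form `"*a/*b"` return `NA` (treated as
#' no-calls).
#'
#' @param x Character vector of diplotype strings.
#' @return Character vector of canonical diplotypes, `NA` for no-calls.
#' @export
#' @examples
#' canonical_diplotype(c("*4/*1", "*1/*4", "NA"))
canonical_diplotype <- function(x) {
  x <- as.character(x)
  out <- rep(NA_character_, length(x))
  idx <- which(!is.na(x) & x != "" & toupper(x) != "NA")
  if (!length(idx)) return(out)
  parts <- strsplit(x[idx], "/", fixed = TRUE)
  two <- lengths(parts) == 2
  idx <- idx[two]
  parts <- parts[two]
  if (!length(idx)) return(out)
  a1 <- parse_star_allele(vapply(parts, `[`, "", 1))
  a2 <- parse_star_allele(vapply(parts, `[`, "", 2))
  valid <- !is.na(a1$base) & !is.na(a2$base)
  swap <- valid & (a2$num < a1$num |
                     (a2$num == a1$num & a2$copies < a1$copies))
  fmt <- function(p) ifelse(p$copies > 1,
                            paste0(p$base, "x", format(p$copies, trim = TRUE)),
                            p$base)
  s1 <- ifelse(swap, fmt(a2), fmt(a1))
  s2 <- ifelse(swap, fmt(a1), fmt(a2))
  out[idx[valid]] <- paste0(s1[valid], "/", s2[valid])
  out
}

#' Consensus diplotype across genotype callers
#'
#' Combines the reports of several star-allele calling tools for one person
#' into a consensus call: the canonical diplotype that is reported by at
#' least `min_tools` callers *and* forms a strict majority of the tools
#' that produced a call. When no diplotype meets both conditions the call
#' is indeterminate (`NA`). With `majority = "all"` the strict majority is
#' instead taken over all tools run, counting no-calls against agreement.
#'
#' @param reports A data.frame with columns `caller_id` and `diplotype`
#'   (`NA` or `"NA"` marks a no-call), or a character vector of diplotype
#'   strings (optionally named by caller).
#' @param min_tools Minimum number of agreeing callers (default 2).
#' @param majority `"called"` (default) or `"all"`.
#' @return The canonical consensus diplotype, or `NA_character_`.
#' @export
#' @examples
#' consensus_diplotype(c(A = "*1/*4", B = "*4/*1", C = NA, D = NA))
consensus_diplotype <- function(reports, min_tools = 2,
                                majority = c("called", "all")) {
  majority <- match.arg(majority)
  if (is.data.frame(reports)) {
    ids <- reports$caller_id
    calls <- reports$diplotype
  } else {
    ids <- names(reports)
    calls <- reports
  }
  if (!is.null(ids) && anyDuplicated(ids)) {
    stop("duplicate caller_id in reports: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  cc <- canonical_diplotype(calls)
  called <- cc[!is.na(cc)]
  if (!length(called)) return(NA_character_)
  tab <- table(called)
  denom <- if (majority == "called") length(called) else length(cc)
  best <- max(tab)
  if (best >= min_tools && best > denom / 2) {
    names(tab)[which.max(tab)]
  } else {
    NA_character_
  }
}

#' Person-level consensus genotypes and phenotypes from a caller table
#'
#' Vectorised, table-level driver for [consensus_diplotype()]: takes the
#' long table of per-caller reports (one row per person x caller), forms
#' each person's consensus diplotype, scores it and assigns the
#' genotype-based metabolizer phenotype. Persons whose consensus cannot be
#' resolved, or whose consensus contains an allele absent from the activity
#' table, are reported as `"Indeterminate"` with `NA` score.
#'
#' @param calls data.frame with columns `person_id`, `caller_id`,
#'   `diplotype`.
#' @param config Configuration list, see [pgx_defaults()].
#' @return data.frame with one row per person: `person_id`, `diplotype`
#'   (consensus, `NA` if indeterminate), `n_called`, `n_agree`,
#'   `genotype_score`, `genotype_phenotype`.
#' @export
pgx_phenotypes <- function(calls, config = pgx_defaults()) {
  required_cols(calls, c("person_id", "caller_id", "diplotype"), "calls")
  pid <- as.character(calls$person_id)
  dupkey <- paste0(pid, "\r", calls$caller_id)
  if (anyDuplicated(dupkey)) {
    stop("duplicate caller_id within person: ",
         paste(utils::head(unique(pid[duplicated(dupkey)]), 5), collapse = ", "))
  }
  cc <- canonical_diplotype(calls$diplotype)
  persons <- sort(unique(pid))
  pf <- factor(pid, levels = persons)
  n_tools <- tabulate(pf, nbins = length(persons))

  ok <- !is.na(cc)
  n_called <- tabulate(pf[ok], nbins = length(persons))

  # count votes per (person, diplotype) via run-length encoding
  best_dip <- rep(NA_character_, length(persons))
  best_cnt <- integer(length(persons))
  if (any(ok)) {
    key_p <- pid[ok]
    key_d <- cc[ok]
    o <- order(key_p, key_d, method = "radix")
    key <- paste0(key_p[o], "\r", key_d[o])
    r <- rle(key)
    gp <- sub("\r.*$", "", r$values)
    gd <- sub("^.*\r", "", r$values)
    # per person, keep the diplotype with the most votes
    oo <- order(gp, -r$lengths, method = "radix")
    first <- !duplicated(gp[oo])
    i <- match(gp[oo][first], persons)
    best_dip[i] <- gd[oo][first]
    best_cnt[i] <- r$lengths[oo][first]
  }

  min_tools <- config$consensus$min_tools
  denom <- if (identical(config$consensus$majority, "all")) n_tools else n_called
  has_consensus <- best_cnt >= min_tools & best_cnt > denom / 2
  consensus <- ifelse(has_consensus, best_dip, NA_character_)

  score <- rep(NA_real_, length(persons))
  idx <- which(!is.na(consensus))
  if (length(idx)) {
    parts <- strsplit(consensus[idx], "/", fixed = TRUE)
    v1 <- allele_activity_or_na(vapply(parts, `[`, "", 1),
                                config$allele_activity)
    v2 <- allele_activity_or_na(vapply(parts, `[`, "", 2),
                                config$allele_activity)
    score[idx] <- v1 + v2
  }
  pheno <- phenotype_from_score(score, config$phenotype_cuts)
  pheno[is.na(pheno)] <- "Indeterminate"

  data.frame(
    person_id = persons,
    diplotype = consensus,
    n_called = n_called,
    n_agree = ifelse(has_consensus, best_cnt, NA_integer_),
    genotype_score = score,
    genotype_phenotype = pheno,
    stringsAsFactors = FALSE
  )
}

required_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}
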