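#' Impute a prescription's end date from its dispensed quantity
#'
#' Prescription instructions are frequently missing in EHR dispensing data;
#' following the most common directions for the drugs studied here (4
#' tablets a day), the days' supply is `ceiling(quantity / tablets_per_day)`
#' and the covered interval includes the start day, so the end date is
#' `start_date + ceiling(quantity / tablets_per_day) - 1`.
#'
#' @param start_date Date (or integer day) vector of prescription starts.
#' @param quantity Positive integer vector of tablets dispensed.
#' @param tablets_per_day Assumed daily consumption (default 4).
#' @return Vector of end dates, same class as `start_date`.
#' @export
#' @examples
#' impute_end_date(as.Date("2020-01-01"), 28)  # 2020-01-07
impute_end_date <- function(start_date, quantity, tablets_per_day = 4) {
  quantity <- as.numeric(quantity)
  if (any(is.na(quantity)) || any(quantity < 1)) {
    stop("quantity must be a positive integer")
  }
  start_date + (ceiling(quantity / tablets_per_day) - 1)
}

#' Stitch one person's prescriptions of one drug into exposure episodes
#'
#' Merges consecutive prescriptions of the same medication into a single
#' exposure episode when the gap between one prescription's imputed end
#' date and the next one's start date (exclusive of both endpoints) is at
#' most `max_gap_days`. Opioid refills merge across gaps of fewer than 14
#' days (`max_gap_days = 13`); CYP2D6-inhibitor refills merge only across
#' gaps of at most 3 days. An episode runs from its earliest start to the
#' latest imputed end among its constituent prescriptions.
#'
#' @param records data.frame of prescriptions for a single person and drug
#'   with columns `person_id`, `drug`, `start_date`, `quantity` (and
#'   optionally `drug_class`, `inhibitor_strength`).
#' @param max_gap_days Largest gap (in full uncovered days) that still
#'   merges two prescriptions.
#' @param tablets_per_day Passed to [impute_end_date()].
#' @return data.frame of episodes: `person_id`, `drug`, `start_date`,
#'   `end_date`, `source_count` (plus `drug_class`/`inhibitor_strength`
#'   when present in the input).
#' @seealso [drug_exposures()] for the whole-table driver.
#' @export
stitch_episodes <- function(records, max_gap_days,
                            tablets_per_day = 4) {
  required_cols(records, c("person_id", "drug", "start_date", "quantity"),
                "records")
  if (length(unique(records$drug)) > 1) {
    stop("stitch_episodes() takes records of a single drug; got: ",
         paste(unique(records$drug), collapse = ", "))
  }
  if (length(unique(records$person_id)) > 1) {
    stop("stitch_episodes() takes records of a single person")
  }
  records$.gap <- max_gap_days
  drug_exposures(records, tablets_per_day = tablets_per_day)
}

#' Build drug-exposure episodes from a prescription table
#'
#' Vectorised stitching over all persons and drugs at once. The merge gap
#' is taken per drug class: `days$opioid_gap` for opioids (and `other`
#' drugs), `days$inhibitor_gap` for CYP2D6 inhibitors; a `.gap` column in
#' the input overrides both.
#'
#' @param rx data.frame with columns `person_id`, `drug`, `start_date`,
#'   `quantity`, optionally `drug_class` (`"opioid"`, `"inhibitor"`,
#'   `"other"`) and `inhibitor_strength`.
#' @param config Configuration list, see [pgx_defaults()].
#' @param tablets_per_day Assumed daily consumption; defaults to the
#'   configured value.
#' @return data.frame of exposure episodes, ordered by person, drug and
#'   start date, with columns `person_id`, `drug`, `drug_class`,
#'   `inhibitor_strength`, `start_date`, `end_date`, `source_count`.
#' @export
drug_exposures <- function(rx, config = pgx_defaults(),
                           tablets_per_day = config$days$tablets_per_day) {
  required_cols(rx, c("person_id", "drug", "start_date", "quantity"), "rx")
  n <- nrow(rx)
  if (!n) {
    return(data.frame(person_id = character(), drug = character(),
                      drug_class = character(),
                      inhibitor_strength = character(),
                      start_date = rx$start_date[0], end_date = rx$start_date[0],
                      source_count = integer(), stringsAsFactors = FALSE))
  }
  cls <- if ("drug_class" %in% names(rx)) as.character(rx$drug_class) else
    rep("other", n)
  strength <- if ("inhibitor_strength" %in% names(rx))
    as.character(rx$inhibitor_strength) else rep("not-applicable", n)
  gap <- if (".gap" %in% names(rx)) rx$.gap else
    ifelse(cls == "inhibitor", config$days$inhibitor_gap,
           config$days$opioid_gap)

  start <- as.numeric(rx$start_date)
  end <- as.numeric(impute_end_date(rx$start_date, rx$quantity,
                                    tablets_per_day))
  pid <- as.character(rx$person_id)
  drug <- as.character(rx$drug)

  o <- order(pid, drug, start, end, method = "radix")
  pid <- pid[o]; drug <- drug[o]; start <- start[o]; end <- end[o]
  cls <- cls[o]; strength <- strength[o]; gap <- gap[o]

  g <- paste0(pid, "\r", drug)
  first <- g != c("", g[-length(g)])
  # running max of imputed ends within each person-drug group
  cm <- stats::ave(end, cumsum(first), FUN = cummax)
  prev_end <- c(NA_real_, cm[-length(cm)])
  gap_days <- start - prev_end - 1
  new_ep <- first | gap_days > gap
  ep <- cumsum(new_ep)

  last <- !duplicated(ep, fromLast = TRUE)
  out <- data.frame(
    person_id = pid[new_ep],
    drug = drug[new_ep],
    drug_class = cls[new_ep],
    inhibitor_strength = strength[new_ep],
    start_date = rx$start_date[o][new_ep],
    end_date = rx$start_date[o][last] - start[last] + cm[last],
    source_count = tabulate(ep),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Concomitant opioid-inhibitor exposure level
#'
#' Determines the inhibitor level acting on an opioid exposure from the
#' inclusive-date overlap between inhibitor episodes and an assessment
#' window (by default the opioid episode itself; the cohort builder passes
#' the follow-up window). An inhibitor counts only when it overlaps the
#' window for at least `min_overlap` consecutive days; when both a strong
#' and a moderate inhibitor qualify, the strong one wins (the minimum
#' inhibitor factor applies).
#'
#' @param opioid One opioid episode (a one-row data.frame or list with
#'   `start_date`, `end_date`).
#' @param inhibitors data.frame of inhibitor episodes with `start_date`,
#'   `end_date`, `inhibitor_strength` (`"strong"`/`"moderate"`).
#' @param window Optional length-2 vector overriding the assessment window.
#' @param min_overlap Minimum qualifying overlap in days (default 3).
#' @return A list with `overlap_days` (the largest overlap observed at the
#'   resolved level, or overall when no inhibitor qualifies) and `level`
#'   (`"none"`, `"moderate"` or `"strong"`).
#' @export
#' @examples
#' op <- data.frame(start_date = 0, end_date = 30)
#' inh <- data.frame(start_date = 10, end_date = 12,
#'                   inhibitor_strength = "strong")
#' concomitant_level(op, inh)
concomitant_level <- function(opioid, inhibitors, window = NULL,
                              min_overlap = 3) {
  if (is.null(window)) {
    window <- c(opioid$start_date[1], opioid$end_date[1])
  }
  if (is.null(inhibitors) || !nrow(inhibitors)) {
    return(list(overlap_days = 0L, level = "none"))
  }
  ov <- pmax(0, as.numeric(pmin(inhibitors$end_date, window[2])) -
                  as.numeric(pmax(inhibitors$start_date, window[1])) + 1)
  qual <- ov >= min_overlap
  strength <- as.character(inhibitors$inhibitor_strength)
  if (any(qual & strength == "strong")) {
    list(overlap_days = as.integer(max(ov[qual & strength == "strong"])),
         level = "strong")
  } else if (any(qual & strength == "moderate")) {
    list(overlap_days = as.integer(max(ov[qual & strength == "moderate"])),
         level = "moderate")
  } else {
    list(overlap_days = as.integer(max(c(0, ov))), level = "none")
  }
}

# vectorised concomitancy: one row per person in `windows`
# (person_id, win_start, win_end); returns level + max qualifying overlap
concomitancy_by_person <- function(windows, inh_episodes, min_overlap = 3) {
  lev <- rep("none", nrow(windows))
  ovd <- integer(nrow(windows))
  if (!is.null(inh_episodes) && nrow(inh_episodes)) {
    i <- match(as.character(inh_episodes$person_id),
               as.character(windows$person_id))
    keep <- !is.na(i)
    if (any(keep)) {
      inh <- inh_episodes[keep, , drop = FALSE]
      i <- i[keep]
      ov <- pmax(0, pmin(as.numeric(inh$end_date), as.numeric(windows$win_end[i])) -
                     pmax(as.numeric(inh$start_date), as.numeric(windows$win_start[i])) + 1)
      qual <- ov >= min_overlap
      f <- factor(i, levels = seq_len(nrow(windows)))
      n_strong <- tabulate(f[qual & inh$inhibitor_strength == "strong"],
                           nbins = nrow(windows))
      n_mod <- tabulate(f[qual & inh$inhibitor_strength == "moderate"],
                        nbins = nrow(windows))
      lev[n_mod > 0] <- "moderate"
      lev[n_strong > 0] <- "strong"
      mx <- rep(0, nrow(windows))
      if (any(qual)) {
        agg <- tapply(ov[qual], f[qual], max)
        mx[as.integer(names(agg))] <- agg
      }
      ovd <- as.integer(mx)
    }
  }
  data.frame(person_id = windows$person_id, inhibitor_level = lev,
             overlap_days = ovd, stringsAsFactors = FALSE)
}

#' Is a person free of CYP2D6 inhibitor exposure?
#'
#' A person is inhibitor-free when no inhibitor episode intersects the
#' interval from `washout` days before the opioid start (inclusive) through
#' the end of the study period.
#'
#' @param opioid_start Opioid episode start date.
#' @param study_end End of the study period.
#' @param inhibitor_episodes data.frame of the person's stitched inhibitor
#'   episodes (`start_date`, `end_date`); `NULL` or empty means free.
#' @param washout Look-back length in days (default 180, inclusive).
#' @return Logical scalar.
#' @export
inhibitor_free <- function(opioid_start, study_end, inhibitor_episodes,
                           washout = 180) {
  if (is.null(inhibitor_episodes) || !nrow(inhibitor_episodes)) return(TRUE)
  lo <- as.numeric(opioid_start) - washout
  hi <- as.numeric(study_end)
  !any(as.numeric(inhibitor_episodes$end_date) >= lo &
         as.numeric(inhibitor_episodes$start_date) <= hi)
}

#' Select a person's first opioid exposure episode
#'
#' Returns the episode with the earliest start date; same-day ties are
#' broken alphabetically by drug name and recorded in the `"tie"`
#' attribute.
#'
#' @param episodes data.frame of one person's opioid episodes.
#' @return The selected one-row data.frame, with attribute `tie = TRUE`
#'   when the start date was tied across drugs.
#' @export
select_first_opioid <- function(episodes) {
  if (is.null(episodes) || !nrow(episodes)) {
    stop("no opioid episode to select from")
  }
  o <- order(as.numeric(episodes$start_date), episodes$drug)
  sel <- episodes[o[1], , drop = FALSE]
  tie <- nrow(episodes) > 1 &&
    sum(as.numeric(episodes$start_date) ==
          as.numeric(sel$start_date)) > 1
  attr(sel, "tie") <- tie
  sel
}

# vectorised first-episode selection across persons; returns one row per
# person plus a "ties" attribute naming persons whose selection was
# tie-broken alphabetically
first_opioid_episodes <- function(episodes) {
  stopifnot(nrow(episodes) > 0)
  o <- order(as.character(episodes$person_id),
             as.numeric(episodes$start_date), episodes$drug,
             method = "radix")
  e <- episodes[o, , drop = FALSE]
  firsts <- !duplicated(e$person_id)
  sel <- e[firsts, , drop = FALSE]
  # a tie exists when the first two episodes of a person share a start date
  nxt <- which(firsts) + 1L
  has_next <- nxt <= nrow(e) & !firsts[pmin(nxt, nrow(e))]
  tie <- has_next &
    as.numeric(e$start_date[pmin(nxt, nrow(e))]) == as.numeric(sel$start_date)
  attr(sel, "ties") <- sel$person_id[tie]
  rownames(sel) <- NULL
  sel
}
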