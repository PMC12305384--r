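# Independent brute-force oracles used to cross-check the implementation.

# Interval union with gap closure on a day grid: cover each prescription's
# imputed days, fill uncovered runs of length <= gap that sit between
# covered days, then read off maximal covered runs.
brute_stitch <- function(starts, quantities, gap, tablets_per_day = 4) {
  ends <- starts + ceiling(quantities / tablets_per_day) - 1
  lo <- min(starts)
  hi <- max(ends)
  covered <- rep(FALSE, hi - lo + 1)
  for (i in seq_along(starts)) {
    covered[(starts[i] - lo + 1):(ends[i] - lo + 1)] <- TRUE
  }
  r <- rle(covered)
  pos <- cumsum(c(1, r$lengths))
  for (j in seq_along(r$values)) {
    if (!r$values[j] && j > 1 && j < length(r$values) &&
        r$lengths[j] <= gap) {
      covered[pos[j]:(pos[j + 1] - 1)] <- TRUE
    }
  }
  r <- rle(covered)
  pos <- cumsum(c(1, r$lengths))
  idx <- which(r$values)
  data.frame(start = lo + pos[idx] - 1,
             end = lo + pos[idx] + r$lengths[idx] - 2)
}

# Majority-vote consensus counter, written independently of the package:
# normalizes each diplotype by sorting its alleles as plain labels after
# numeric-id parsing, then counts.
brute_consensus <- function(calls, min_tools = 2) {
  norm1 <- function(d) {
    if (is.na(d)) return(NA_character_)
    al <- strsplit(d, "/", fixed = TRUE)[[1]]
    key <- vapply(al, function(a) {
      num <- as.numeric(sub("^\\*([0-9]+).*$", "\\1", a))
      mult <- if (grepl("x", a)) as.numeric(sub("^.*x", "", a)) else 1
      num * 1000 + mult
    }, 0)
    paste(al[order(key)], collapse = "/")
  }
  cc <- vapply(calls, norm1, "")
  cc <- cc[!is.na(cc)]
  if (length(cc) == 0) return(NA_character_)
  counts <- sort(table(cc), decreasing = TRUE)
  if (counts[1] >= min_tools && counts[1] > length(cc) / 2) {
    names(counts)[1]
  } else {
    NA_character_
  }
}

# quick constructor for prescription frames
make_rx <- function(person_id, drug, start, quantity,
                    drug_class = "opioid",
                    inhibitor_strength = "not-applicable",
                    origin = as.Date("2020-01-01")) {
  data.frame(person_id = person_id, drug = drug, drug_class = drug_class,
             inhibitor_strength = inhibitor_strength,
             start_date = origin + start, quantity = quantity,
             stringsAsFactors = FALSE)
}
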