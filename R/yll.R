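#' Classify an ICD-10 code into the analysis cause groups
#'
#' Non-accidental deaths are chapters A00-R99; within those, I00-I99 is
#' cardiovascular and J00-J99 respiratory. External and other chapters
#' (S, T, U, V-Y, Z) fall outside the non-accidental group.
#'
#' @param icd10 character vector of codes (letter + two digits, optional
#'   subcode, e.g. `"I21.0"`).
#' @return character vector in `c("cardiovascular", "respiratory",
#'   "non_accidental", "other")`; cardiovascular and respiratory codes are
#'   also counted as non-accidental downstream.
#' @export
classify_cause <- function(icd10) {
  ok <- grepl("^[A-Z][0-9]{2}(\\.[0-9A-Z]+)?$", icd10)
  if (!all(ok))
    stop("malformed ICD-10 code(s): ",
         paste(utils::head(icd10[!ok], 5L), collapse = ", "), call. = FALSE)
  letter <- substr(icd10, 1L, 1L)
  out <- rep("other", length(icd10))
  out[letter >= "A" & letter <= "R"] <- "non_accidental"
  out[letter == "I"] <- "cardiovascular"
  out[letter == "J"] <- "respiratory"
  out
}

lookup_year <- function(year, available) {
  if (year %in% available) return(year)
  earlier <- available[available < year]
  if (!length(earlier))
    stop(sprintf("no life table for year %d or earlier", year),
         call. = FALSE)
  max(earlier)
}

#' Years of life lost for a single death
#'
#' Looks up the expected remaining life years at the decedent's completed
#' age and sex in the period life table for the year of death. If the death
#' year is not covered, the latest earlier available table is used (e.g. the
#' 2016 table for deaths in 2017). Ages above the table maximum are clamped
#' to the terminal open age group.
#'
#' @param death a list/row with `date` (Date), `age` (completed years >= 0),
#'   `sex` (`"male"`/`"female"`).
#' @param tables a life table data frame `(year, sex, age, ex)` (see
#'   [read_life_table()], [make_life_table()]).
#' @return expected remaining life years (> 0).
#' @export
yll_for_death <- function(death, tables) {
  if (!nrow(tables)) stop("empty life table", call. = FALSE)
  if (is.na(death$age) || death$age < 0)
    stop("age must be a non-negative number of completed years",
         call. = FALSE)
  if (!death$sex %in% tables$sex)
    stop(sprintf("sex '%s' not present in life table", death$sex),
         call. = FALSE)
  yr <- lookup_year(as.POSIXlt(as.Date(death$date))$year + 1900L,
                    sort(unique(tables$year)))
  sub <- tables[tables$year == yr & tables$sex == death$sex, ]
  age <- min(death$age, max(sub$age))
  hit <- sub$ex[sub$age == age]
  if (!length(hit))
    stop(sprintf("no life-table row for year %d, sex %s, age %d",
                 yr, death$sex, age), call. = FALSE)
  hit[1L]
}

# Vectorized life-table lookup used by the aggregator.
yll_lookup <- function(dates, ages, sexes, tables) {
  yrs <- as.POSIXlt(as.Date(dates))$year + 1900L
  avail <- sort(unique(tables$year))
  yrs <- vapply(yrs, lookup_year, integer(1), available = avail)
  max_age <- max(tables$age)
  ages <- pmin(as.integer(ages), max_age)
  if (any(ages < 0)) stop("negative age in death records", call. = FALSE)
  key <- paste(tables$year, tables$sex, tables$age, sep = "|")
  ix <- match(paste(yrs, sexes, ages, sep = "|"), key)
  if (anyNA(ix))
    stop("death records not covered by life table (sex or age missing)",
         call. = FALSE)
  tables$ex[ix]
}

#' Aggregate death records to a daily stratified YLL series
#'
#' Sums per-death YLL over qualifying deaths each calendar day. Strata
#' follow the standard analysis layout: `all`, `male`, `female` (all
#' non-accidental deaths), the age-65 split (`nonacc_lt65`, `nonacc_ge65`,
#' with age 65 assigned to the older group), the sex-by-age cells
#' (`male_ge65`, `female_ge65`) and the cause-specific elderly strata
#' (`resp_ge65`, `cv_ge65`). External-cause deaths (outside A00-R99) are
#' excluded from every stratum, mirroring registry analyses restricted to
#' non-accidental mortality. Days with no deaths are zero.
#'
#' @param deaths data frame with `date`, `age`, `sex`, `icd10`.
#' @param tables life table data frame `(year, sex, age, ex)`.
#' @param calendar `Date` vector of consecutive days covering all deaths.
#' @return data frame: `date` plus the stratum columns, one row per
#'   calendar day.
#' @export
aggregate_daily_yll <- function(deaths, tables, calendar) {
  calendar <- as.Date(calendar)
  strata <- c("all", "male", "female", "nonacc_lt65", "nonacc_ge65",
              "male_ge65", "female_ge65", "resp_ge65", "cv_ge65")
  out <- data.frame(date = calendar)
  for (s in strata) out[[s]] <- 0
  if (!nrow(deaths)) return(out)
  d <- as.Date(deaths$date)
  outside <- !(d %in% calendar)
  if (any(outside))
    stop("death record(s) outside the calendar: ",
         paste(format(utils::head(d[outside], 5L)), collapse = ", "),
         call. = FALSE)
  cause <- classify_cause(deaths$icd10)
  keep <- cause != "other"
  if (!any(keep)) return(out)
  d <- d[keep]; cause <- cause[keep]
  age <- deaths$age[keep]; sex <- deaths$sex[keep]
  yll <- yll_lookup(d, age, sex, tables)
  day <- match(d, calendar)
  add <- function(col, mask) {
    if (any(mask)) {
      sums <- tapply(yll[mask], day[mask], sum)
      out[[col]][as.integer(names(sums))] <<-
        out[[col]][as.integer(names(sums))] + as.numeric(sums)
    }
  }
  ge65 <- age >= 65
  add("all", rep(TRUE, length(yll)))
  add("male", sex == "male")
  add("female", sex == "female")
  add("nonacc_lt65", !ge65)
  add("nonacc_ge65", ge65)
  add("male_ge65", ge65 & sex == "male")
  add("female_ge65", ge65 & sex == "female")
  add("resp_ge65", ge65 & cause == "respiratory")
  add("cv_ge65", ge65 & cause == "cardiovascular")
  out
}
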