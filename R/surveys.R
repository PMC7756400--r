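#' Data-availability classes
#'
#' The six accessibility classes used to label survey metadata, ordered from
#' most to least open.  `availability_rank` gives that ordering for the
#' most-open-first attribution of multiply-covered cells.
#'
#' @export
availability_classes <- c(
  "publicly_available", "partly_publicly_available", "available_upon_request",
  "not_publicly_available", "incomplete_metadata", "unavailable_metadata")

#' @rdname availability_classes
#' @param availability Character vector of class labels.
#' @return Integer rank, 1 = most open.
#' @export
availability_rank <- function(availability) {
  r <- match(availability, availability_classes)
  if (anyNA(r))
    stop_trawlcover(
      sprintf("unknown availability class: %s",
              paste(unique(availability[is.na(r)]), collapse = ", ")),
      "validation_error")
  r
}

#' Survey metadata table
#'
#' @param survey_id Character vector of survey identifiers.
#' @param availability One of the six [availability_classes] per survey.
#' @param years_sampled List of integer vectors of sampled years.
#' @param gear Gear label (otter trawl for all surveys retained by the
#'   inclusion filter).
#' @return A data.frame of class `survey_meta`.
#' @export
survey_meta <- function(survey_id, availability, years_sampled,
                        gear = "otter_trawl") {
  availability_rank(availability)  # validates
  df <- data.frame(survey_id = survey_id, availability = availability,
                   gear = gear, stringsAsFactors = FALSE)
  df$years_sampled <- lapply(years_sampled, function(y) sort(unique(as.integer(y))))
  class(df) <- c("survey_meta", "data.frame")
  df
}

#' Survey inclusion filter
#'
#' Partitions surveys into included and excluded with per-survey reasons.  A
#' survey is included iff it (a) sampled at least `min_years` distinct years
#' within `window`, (b) sampled at least one year in or after `recent_year`,
#' and (c) is not a near-shore survey (median haul distance to coast below
#' `min_coast_nm` nautical miles, tested only when the field is present).
#'
#' @param meta A [survey_meta] table.
#' @param hauls Haul data.frame (linked by `survey_id`); optional
#'   `distance_to_coast_nm` drives the near-shore flag.
#' @param window Study window, inclusive years.
#' @param recent_year Minimum "still ongoing" year.
#' @param min_years Minimum distinct sampled years in the window.
#' @param min_coast_nm Near-shore threshold, nautical miles.
#' @return List with `included` (survey ids), `excluded` (data.frame of
#'   `survey_id`, `reason`).
#' @export
filter_surveys <- function(meta, hauls, window = c(2001, 2019),
                           recent_year = 2015, min_years = 4,
                           min_coast_nm = 3) {
  unknown <- setdiff(unique(hauls$survey_id), meta$survey_id)
  if (length(unknown))
    stop_trawlcover(
      sprintf("hauls reference unknown survey_id: %s",
              paste(unknown, collapse = ", ")),
      "linkage_error")
  reasons <- character(0); excluded <- character(0)
  included <- character(0)
  for (i in seq_len(nrow(meta))) {
    sid <- meta$survey_id[i]
    yrs <- meta$years_sampled[[i]]
    yrs_in <- yrs[yrs >= window[1] & yrs <= window[2]]
    reason <- NULL
    if (length(yrs_in) < min_years) {
      reason <- "min_years"
    } else if (!any(yrs_in >= recent_year)) {
      reason <- "recent_year"
    } else if ("distance_to_coast_nm" %in% names(hauls)) {
      d <- hauls$distance_to_coast_nm[hauls$survey_id == sid]
      d <- d[!is.na(d)]
      if (length(d) && stats::median(d) < min_coast_nm)
        reason <- "near_shore"
    }
    if (is.null(reason)) included <- c(included, sid)
    else { excluded <- c(excluded, sid); reasons <- c(reasons, reason) }
  }
  list(included = included,
       excluded = data.frame(survey_id = excluded, reason = reasons,
                             stringsAsFactors = FALSE))
}
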