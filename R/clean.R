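# Cleaning rules for raw long-format visit records: drop records with a
# missing time point or a non-numeric/out-of-range value, average
# duplicated time points per subject, merge synonymous variable headings,
# and back-calculate derivable instrument scores. No other imputation is
# performed.

.as_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("subject_id", "variable", "day", "value") %in%
                  names(records)))
  records
}

#' Drop invalid visit records
#'
#' Removes records with a missing time point, a value that does not parse
#' as a number, or (when `valid_ranges` is supplied) a value outside the
#' variable's plausible physical range. Rejections are counted by reason,
#' not raised.
#'
#' @param records Data frame with `subject_id`, `variable`, `day`,
#'   `value` (value may be character).
#' @param valid_ranges Optional named list `variable -> c(lo, hi)`.
#' @return List with `records` (clean, numeric `value`) and `log`
#'   (data frame of rejection counts by reason).
#' @export
drop_invalid_records <- function(records, valid_ranges = NULL) {
  records <- .as_records(records)
  missing_time <- is.na(records$day)
  value_num <- suppressWarnings(as.numeric(records$value))
  non_numeric <- !missing_time & is.na(value_num)
  out_of_range <- rep(FALSE, nrow(records))
  if (!is.null(valid_ranges)) {
    for (v in names(valid_ranges)) {
      r <- valid_ranges[[v]]
      idx <- records$variable == v & !is.na(value_num)
      out_of_range[idx] <- value_num[idx] < r[1L] | value_num[idx] > r[2L]
    }
  }
  out_of_range <- out_of_range & !missing_time & !non_numeric
  keep <- !(missing_time | non_numeric | out_of_range)
  clean <- records[keep, , drop = FALSE]
  clean$value <- value_num[keep]
  rownames(clean) <- NULL
  list(records = clean,
       log = data.frame(
         reason = c("missing_time", "non_numeric", "out_of_range"),
         n = c(sum(missing_time), sum(non_numeric), sum(out_of_range))))
}

#' Average duplicated time points
#'
#' When a subject has several records for the same variable at the same
#' day, they are replaced by their arithmetic mean.
#'
#' @param records Clean numeric records.
#' @return Records with one row per (subject, variable, day).
#' @export
collapse_duplicates <- function(records) {
  records <- .as_records(records)
  if (!nrow(records)) return(records)
  agg <- aggregate(value ~ subject_id + variable + day, data = records,
                   FUN = mean)
  agg <- agg[order(agg$subject_id, agg$variable, agg$day), ,
             drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("subject_id", "variable", "day", "value")]
}

#' Merge synonymous variable headings
#'
#' Rewrites synonymous variable names to their canonical name. Synonymous
#' columns are expected to be mutually exclusive across subjects; if both
#' names carry values for the same (subject, day), they are treated as
#' duplicated time points and averaged, with a warning.
#'
#' @param records Clean numeric records.
#' @param synonym_map Named list: canonical name -> character vector of
#'   synonymous headings. No heading may map to two canonical names.
#' @return Records with canonical variable names (duplicates averaged).
#' @export
merge_synonyms <- function(records, synonym_map) {
  records <- .as_records(records)
  all_syn <- unlist(synonym_map, use.names = FALSE)
  if (anyDuplicated(all_syn))
    stop("synonym map conflict: a heading maps to two canonical names",
         call. = FALSE)
  for (canon in names(synonym_map)) {
    hit <- records$variable %in% synonym_map[[canon]]
    records$variable[hit] <- canon
  }
  key <- paste(records$subject_id, records$variable, records$day,
               sep = "\r")
  if (anyDuplicated(key)) {
    warning("overlapping synonym values at the same day; averaging",
            call. = FALSE)
    records <- collapse_duplicates(records)
  }
  records
}

#' Back-calculate derivable instrument scores
#'
#' For a summed instrument (ALSFRS-R: 12 items, total = item sum): when
#' the total is missing at a visit but all items are present, the total
#' is filled in as the item sum; when the total is present and exactly
#' one item is missing, that item is filled in as total minus the sum of
#' the others. Anything else is left unchanged — no imputation. A
#' back-calculated item outside its valid range leaves the record
#' unchanged with a warning.
#'
#' @param records Clean numeric records.
#' @param total Variable name of the total score.
#' @param items Character vector of the item variable names.
#' @param item_range Valid item score range.
#' @return Records with derivable cells filled in.
#' @export
backcalculate_score <- function(records, total = "alsfrs_total",
                                items = paste0("alsfrs_q", 1:12),
                                item_range = c(0, 4)) {
  records <- .as_records(records)
  inst <- records$variable %in% c(total, items)
  if (!any(inst)) return(records)
  sub <- records[inst, , drop = FALSE]
  added <- list()
  for (g in split(sub, paste(sub$subject_id, sub$day, sep = "\r"))) {
    have_items <- g$variable[g$variable %in% items]
    has_total <- total %in% g$variable
    if (!has_total && length(unique(have_items)) == length(items)) {
      added[[length(added) + 1L]] <- data.frame(
        subject_id = g$subject_id[1L], variable = total, day = g$day[1L],
        value = sum(g$value[g$variable %in% items]),
        stringsAsFactors = FALSE)
    } else if (has_total &&
               length(setdiff(items, have_items)) == 1L) {
      miss <- setdiff(items, have_items)
      val <- g$value[g$variable == total] -
        sum(g$value[g$variable %in% items])
      if (val < item_range[1L] || val > item_range[2L]) {
        warning("back-calculated ", miss, " outside [",
                item_range[1L], ", ", item_range[2L],
                "]; record left unchanged", call. = FALSE)
      } else {
        added[[length(added) + 1L]] <- data.frame(
          subject_id = g$subject_id[1L], variable = miss,
          day = g$day[1L], value = val, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(added))
    records <- rbind(records, do.call(rbind, added))
  records <- records[order(records$subject_id, records$variable,
                           records$day), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Back-calculate vital-capacity percent-of-normal
#'
#' For spirometry variables recorded both as a raw volume and as percent
#' of the predicted normal, fills whichever of the pair is missing at a
#' visit from the other using a per-subject predicted-normal volume:
#' `percent = 100 * raw / normal`. Visits where both or neither are
#' present are left unchanged.
#'
#' @param records Clean numeric records.
#' @param raw_var,pct_var Variable names of the raw and percent forms.
#' @param normal Named numeric vector: subject_id -> predicted normal
#'   volume (same units as `raw_var`).
#' @return Records with derivable cells filled in.
#' @export
backcalculate_capacity <- function(records, raw_var = "fvc",
                                   pct_var = "fvc_percent", normal) {
  records <- .as_records(records)
  sub <- records[records$variable %in% c(raw_var, pct_var) &
                   records$subject_id %in% names(normal), , drop = FALSE]
  added <- list()
  for (g in split(sub, paste(sub$subject_id, sub$day, sep = "\r"))) {
    nrm <- normal[[g$subject_id[1L]]]
    has_raw <- raw_var %in% g$variable
    has_pct <- pct_var %in% g$variable
    if (has_raw && !has_pct) {
      added[[length(added) + 1L]] <- data.frame(
        subject_id = g$subject_id[1L], variable = pct_var,
        day = g$day[1L],
        value = 100 * g$value[g$variable == raw_var][1L] / nrm,
        stringsAsFactors = FALSE)
    } else if (has_pct && !has_raw) {
      added[[length(added) + 1L]] <- data.frame(
        subject_id = g$subject_id[1L], variable = raw_var,
        day = g$day[1L],
        value = g$value[g$variable == pct_var][1L] * nrm / 100,
        stringsAsFactors = FALSE)
    }
  }
  if (length(added)) records <- rbind(records, do.call(rbind, added))
  rownames(records) <- NULL
  records
}

#' Full cleaning chain
#'
#' [drop_invalid_records()], [merge_synonyms()] (if a map is given),
#' [collapse_duplicates()], then [backcalculate_score()]. The chain is
#' idempotent.
#'
#' @inheritParams drop_invalid_records
#' @inheritParams merge_synonyms
#' @inheritParams backcalculate_score
#' @return List with `records` and the rejection `log`.
#' @export
clean_records <- function(records, valid_ranges = NULL,
                          synonym_map = NULL, total = "alsfrs_total",
                          items = paste0("alsfrs_q", 1:12),
                          item_range = c(0, 4)) {
  step <- drop_invalid_records(records, valid_ranges)
  out <- step$records
  if (!is.null(synonym_map))
    out <- suppressWarnings(merge_synonyms(out, synonym_map))
  out <- collapse_duplicates(out)
  out <- backcalculate_score(out, total, items, item_range)
  list(records = out, log = step$log)
}
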