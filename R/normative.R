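# Cohort stratification and normative reference tables.
#
# Cohort cells follow the study's stratification: five age bins
# (<30.5, 30.5-40.5, 40.5-50.5, 50.5-60.5, >60.5 years), two sexes and
# three height bins.  The published height bins "<165, 166-175, >175"
# leave 165-166 cm unassigned; we repair them to the half-open partition
# (<=165, (165, 175], >175] so that every height maps to exactly one
# bin.  Age bins are left-closed at the .5 cuts (30.5 years falls into
# 30.5-40.5).

AGE_BREAKS <- c(-Inf, 30.5, 40.5, 50.5, 60.5, Inf)
AGE_LABELS <- c("<30.5", "30.5-40.5", "40.5-50.5", "50.5-60.5", ">60.5")
HEIGHT_BREAKS <- c(-Inf, 165, 175, Inf)
HEIGHT_LABELS <- c("<=165", "165-175", ">175")

#' Assign a subject to a cohort cell
#'
#' @param age age in years (> 0)
#' @param sex `"F"` or `"M"`
#' @param height_cm height in cm (> 0)
#' @return data.frame with `age_bin`, `sex`, `height_bin` (one row per
#'   subject); 30 distinct cells are possible
#' @export
assign_cohort <- function(age, sex, height_cm) {
  if (anyNA(age) || anyNA(sex) || anyNA(height_cm)) {
    stop("missing covariate (age, sex or height)")
  }
  stopifnot(all(age > 0), all(height_cm > 0), all(sex %in% c("F", "M")))
  data.frame(
    age_bin = as.character(cut(age, AGE_BREAKS, AGE_LABELS, right = FALSE)),
    sex = as.character(sex),
    height_bin = as.character(cut(height_cm, HEIGHT_BREAKS, HEIGHT_LABELS,
                                  right = TRUE)),
    stringsAsFactors = FALSE)
}

#' Build a normative reference table
#'
#' Summarises morphometry records per cohort cell, spine segment and
#' metric: subject count, mean, SD and the 5/25/50/75/95 percentiles
#' (linear interpolation between order statistics).  Percentiles are
#' reported only for cells with at least `min_n_percentile` subjects.
#' Empty cells are simply absent from the table.
#'
#' @param records morphometry rows as produced by [measure_subject()]
#'   (rbind over subjects); must contain `subject_id`, `segment`,
#'   `metric`, `value`
#' @param covariates data.frame with `subject_id`, `age`, `sex`,
#'   `height_cm`; one row per subject, no duplicates
#' @param metrics metrics to tabulate
#' @param min_n_percentile minimum cell size for percentile reporting
#' @return data.frame of class `reference_table`; raw per-cell values are
#'   kept in attribute `"values"` for empirical percentile ranking
#' @export
build_reference_table <- function(records, covariates,
                                  metrics = c("disc_volume", "canal_area"),
                                  min_n_percentile = 5) {
  if (anyDuplicated(covariates$subject_id)) {
    stop("duplicate subject ids in covariates")
  }
  rec <- records[records$metric %in% metrics, , drop = FALSE]
  missing_ids <- setdiff(rec$subject_id, covariates$subject_id)
  if (length(missing_ids)) {
    stop("no covariates for subjects: ", paste(missing_ids, collapse = ", "))
  }
  key <- assign_cohort(
    covariates$age[match(rec$subject_id, covariates$subject_id)],
    covariates$sex[match(rec$subject_id, covariates$subject_id)],
    covariates$height_cm[match(rec$subject_id, covariates$subject_id)])
  rec <- cbind(rec, key)

  cell_id <- interaction(rec$age_bin, rec$sex, rec$height_bin, rec$segment,
                         rec$metric, drop = TRUE, lex.order = TRUE)
  groups <- split(rec, cell_id)
  # sort for order-independence of the output
  groups <- groups[order(names(groups))]
  rows <- lapply(groups, function(g) {
    v <- sort(g$value)
    qs <- if (length(v) >= min_n_percentile) {
      stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7,
                      names = FALSE)
    } else rep(NA_real_, 5)
    data.frame(age_bin = g$age_bin[1], sex = g$sex[1],
               height_bin = g$height_bin[1], segment = g$segment[1],
               metric = g$metric[1], units = g$units[1],
               n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               p5 = qs[1], p25 = qs[2], p50 = qs[3], p75 = qs[4],
               p95 = qs[5])
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "values") <- lapply(groups, function(g) sort(g$value))
  class(out) <- c("reference_table", "data.frame")
  out
}

cell_key <- function(age_bin, sex, height_bin, segment, metric) {
  paste(age_bin, sex, height_bin, segment, metric, sep = ".")
}

#' Compare a subject against the reference table
#'
#' For every (segment, metric) in the subject's record, reports the
#' cohort size, the subject value, its empirical percentile rank
#' (mid-rank convention for ties) and its z-score within the subject's
#' cohort cell.  Metrics whose cell is absent from the table are marked
#' `no_reference`.
#'
#' @param record one subject's morphometry ([measure_subject()] output)
#' @param age,sex,height_cm the subject's covariates
#' @param table a [build_reference_table()] result
#' @param metrics metrics to compare
#' @return data.frame with one row per (segment, metric); serialise with
#'   [jsonlite::toJSON()] if needed
#' @export
compare_subject <- function(record, age, sex, height_cm, table,
                            metrics = c("disc_volume", "canal_area")) {
  stopifnot(inherits(table, "reference_table"))
  key <- assign_cohort(age, sex, height_cm)
  values <- attr(table, "values")
  rec <- record[record$metric %in% metrics, , drop = FALSE]
  rows <- lapply(seq_len(nrow(rec)), function(i) {
    k <- cell_key(key$age_bin, key$sex, key$height_bin,
                  rec$segment[i], rec$metric[i])
    v <- values[[k]]
    x <- rec$value[i]
    if (is.null(v) || length(v) == 0) {
      return(data.frame(segment = rec$segment[i], metric = rec$metric[i],
                        value = x, cohort_n = 0L, percentile = NA_real_,
                        z = NA_real_, status = "no_reference"))
    }
    pct <- 100 * (sum(v < x) + 0.5 * sum(v == x)) / length(v)
    mu <- mean(v)
    sg <- if (length(v) > 1) stats::sd(v) else NA_real_
    data.frame(segment = rec$segment[i], metric = rec$metric[i], value = x,
               cohort_n = length(v), percentile = pct,
               z = if (!is.na(sg) && sg > 0) (x - mu) / sg else NA_real_,
               status = "ok")
  })
  do.call(rbind, rows)
}
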