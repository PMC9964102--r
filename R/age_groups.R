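#' Define the age-group partition
#'
#' Cut points `c(c1, ..., ck)` define the half-open groups
#' `(-Inf, c1)`, `[c1, c2)`, ..., `[ck, Inf)`, so every age maps to exactly
#' one group. Default labels follow the conventional reading with
#' integer-recorded ages: cuts `c(50, 60, 70)` give "under 50", "50 to 59",
#' "60 to 69", "70 plus".
#'
#' @param cut_points strictly increasing ages in years.
#' @param labels optional display names, length `length(cut_points) + 1`.
#' @return An object of class `age_groups`.
#' @export
#' @examples
#' age_groups()               # the default four-group partition
#' age_groups(c(40, 65))      # three groups
age_groups <- function(cut_points = c(50, 60, 70), labels = NULL) {
  stopifnot(is.numeric(cut_points), length(cut_points) >= 1L,
            !anyNA(cut_points))
  if (is.unsorted(cut_points, strictly = TRUE))
    stop("cut_points must be strictly increasing")
  k <- length(cut_points)
  if (is.null(labels)) {
    labels <- character(k + 1L)
    labels[1L] <- paste("under", cut_points[1L])
    if (k > 1L) {
      for (i in seq_len(k - 1L)) {
        labels[i + 1L] <- paste(cut_points[i], "to", cut_points[i + 1L] - 1)
      }
    }
    labels[k + 1L] <- paste(cut_points[k], "plus")
  }
  stopifnot(length(labels) == k + 1L, !anyDuplicated(labels))
  structure(list(cut_points = cut_points, labels = labels),
            class = "age_groups")
}

#' @export
print.age_groups <- function(x, ...) {
  cat("<age groups>", paste(x$labels, collapse = " | "), "\n")
  invisible(x)
}

#' Assign each age to its group
#'
#' @param age numeric vector of ages in years.
#' @param groups an [age_groups()] object.
#' @return A factor with the group labels as levels (all levels kept even if
#'   empty).
#' @export
assign_age_group <- function(age, groups = age_groups()) {
  idx <- findInterval(age, groups$cut_points) + 1L
  factor(groups$labels[idx], levels = groups$labels)
}

#' Split a cohort into per-age-group sub-cohorts
#'
#' Every record is assigned to exactly one group; the union of the
#' sub-cohorts equals the input. Empty groups appear as zero-row
#' data frames so downstream code sees the full partition.
#'
#' @param cohort cohort `data.frame` with an `age` column.
#' @param groups an [age_groups()] object.
#' @return A named list of sub-cohorts, one per group, in age order.
#' @export
split_by_age <- function(cohort, groups = age_groups()) {
  split(cohort, assign_age_group(cohort$age, groups))
}

#' Age coordinate representing a group on the proportionality plot
#'
#' Bounded groups use the midpoint under integer-age semantics: the group
#' `[lo, hi)` covers recorded ages `lo` to `hi - 1`, so its midpoint is
#' `(lo + hi - 1)/2` — e.g., 54.5 for "50 to 59". Open-ended groups (the
#' youngest and oldest) have no midpoint; their coordinate is the median
#' observed age in the group, or an explicit override.
#'
#' @param groups an [age_groups()] object.
#' @param label one of `groups$labels`.
#' @param ages observed ages of records in the group (used for open-ended
#'   groups when no override is given).
#' @param override fixed coordinate in years, taking precedence over `ages`.
#' @return The age coordinate in years.
#' @export
#' @examples
#' age_group_midpoint(age_groups(), "50 to 59")   # 54.5
age_group_midpoint <- function(groups, label, ages = NULL, override = NULL) {
  i <- match(label, groups$labels)
  if (is.na(i)) stop(sprintf("unknown age group label: %s", label))
  if (!is.null(override)) {
    stopifnot(is.numeric(override), length(override) == 1L)
    return(as.numeric(override))
  }
  k <- length(groups$cut_points)
  if (i > 1L && i <= k) {
    lo <- groups$cut_points[i - 1L]
    hi <- groups$cut_points[i]
    return((lo + hi - 1) / 2)
  }
  ages <- ages[!is.na(ages)]
  if (!length(ages)) {
    stop(sprintf(
      "group '%s' is open-ended: supply observed ages or an override", label))
  }
  stats::median(ages)
}
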