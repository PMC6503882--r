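# Containers for per-animal lifespan data and survival-curve point tables,
# plus their CSV dialects.

#' Lifespan cohort
#'
#' Per-animal follow-up data for one group: lifespan in days, an event flag
#' (1 = died naturally, 0 = right-censored), and the set of tumor-type labels
#' found at postmortem examination (possibly empty). The initial cohort size
#' `N0` equals the number of records: every animal is followed to death or
#' censoring.
#'
#' @param lifespan_days Positive ages at death/censoring, in days.
#' @param event Integer 0/1 vector (1 = death observed); defaults to all 1.
#' @param tumor_labels Optional list of character vectors, one per animal,
#'   naming the tumor types found postmortem (empty vector = tumor-free).
#'   `NULL` means the cohort carries no tumor annotation at all.
#' @param group Group label.
#' @param animal_id Optional ids; generated if missing.
#' @return An object of class `cohort`.
#' @export
cohort <- function(lifespan_days, event = rep(1L, length(lifespan_days)),
                   tumor_labels = NULL, group = "cohort", animal_id = NULL) {
  if (length(lifespan_days) == 0L) stop("empty cohort", call. = FALSE)
  if (!is.numeric(lifespan_days) || any(!is.finite(lifespan_days)) ||
      any(lifespan_days <= 0)) {
    stop("'lifespan_days' must be positive and finite", call. = FALSE)
  }
  event <- as.integer(event)
  if (length(event) != length(lifespan_days) || any(!event %in% c(0L, 1L))) {
    stop("'event' must be a 0/1 vector matching 'lifespan_days'", call. = FALSE)
  }
  has_tumors <- !is.null(tumor_labels)
  if (has_tumors) {
    if (!is.list(tumor_labels) || length(tumor_labels) != length(lifespan_days)) {
      stop("'tumor_labels' must be a list with one entry per animal",
           call. = FALSE)
    }
    tumor_labels <- lapply(tumor_labels, as.character)
  } else {
    tumor_labels <- rep(list(character(0)), length(lifespan_days))
  }
  if (is.null(animal_id)) {
    animal_id <- sprintf("%s_%03d", gsub("\\s+", "_", group[1L]),
                         seq_along(lifespan_days))
  }
  structure(list(group = as.character(group[1L]),
                 animal_id = as.character(animal_id),
                 lifespan_days = as.numeric(lifespan_days),
                 event = event,
                 tumor_labels = tumor_labels,
                 has_tumor_annotation = has_tumors,
                 n0 = length(lifespan_days)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort '", x$group, "': N0 = ", x$n0, ", deaths = ", sum(x$event),
      ", censored = ", sum(1L - x$event), "\n", sep = "")
  if (x$has_tumor_annotation) {
    cat("  tumor-bearing animals:",
        sum(lengths(x$tumor_labels) > 0), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  data.frame(animal_id = x$animal_id,
             group = x$group,
             lifespan_days = x$lifespan_days,
             event = x$event,
             tumor_labels = vapply(x$tumor_labels, paste, "", collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Read / write cohort CSV files
#'
#' The cohort CSV dialect has a one-line header and columns `animal_id`,
#' `group`, `lifespan_days`, `event` (1 = death, 0 = censored) and
#' `tumor_labels` (semicolon-separated, empty allowed).
#'
#' @param path File path.
#' @return `read_cohort_csv()` returns a single `cohort` when the file holds
#'   one group, otherwise a named list of cohorts.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "lifespan_days", "event", "tumor_labels")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$tumor_labels <- as.character(df$tumor_labels)  # all-empty column reads as NA
  df$tumor_labels[is.na(df$tumor_labels)] <- ""
  one <- function(d) {
    cohort(d$lifespan_days, event = d$event,
           tumor_labels = lapply(strsplit(d$tumor_labels, ";", fixed = TRUE),
                                 function(v) v[nzchar(v)]),
           group = d$group[1L], animal_id = d$animal_id)
  }
  groups <- unique(df$group)
  if (length(groups) == 1L) return(one(df))
  stats::setNames(lapply(groups, function(g) one(df[df$group == g, , drop = FALSE])),
                  groups)
}

#' @rdname read_cohort_csv
#' @param x A `cohort`.
#' @export
write_cohort_csv <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Survival-curve point table
#'
#' A survival curve as (age, survivors) points — either the empirical step
#' function of a followed cohort or points digitized from a published figure.
#' Ages must be strictly increasing and survivor counts non-increasing and
#' never above `N0`.
#'
#' @param age_days Ages in days (>= 0, strictly increasing).
#' @param survivors Number (or fraction) surviving at each age, non-increasing.
#' @param n0 Initial cohort size; defaults to the largest survivor count.
#' @return An object of class `survival_curve`.
#' @export
survival_curve <- function(age_days, survivors, n0 = max(survivors)) {
  if (length(age_days) != length(survivors) || length(age_days) < 2L) {
    stop("need matching 'age_days' and 'survivors' with >= 2 points",
         call. = FALSE)
  }
  if (any(!is.finite(age_days)) || any(age_days < 0) ||
      any(diff(age_days) <= 0)) {
    stop("'age_days' must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (any(!is.finite(survivors)) || any(survivors < 0) ||
      any(diff(survivors) > 0) || any(survivors > n0)) {
    stop("'survivors' must be non-increasing, non-negative and <= n0",
         call. = FALSE)
  }
  structure(list(age_days = as.numeric(age_days),
                 survivors = as.numeric(survivors),
                 n0 = as.numeric(n0)),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("Survival curve: ", length(x$age_days), " points, N0 = ", x$n0,
      ", ages ", format(min(x$age_days), digits = 4), "-",
      format(max(x$age_days), digits = 4), " days\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.survival_curve <- function(x, ...) {
  data.frame(age_days = x$age_days, survivors = x$survivors)
}

#' Empirical survival curve of a cohort
#'
#' Step-function points (age, number still alive just after that age) of an
#' uncensored cohort, prepended with the point (0, N0).
#'
#' @param x A `cohort`.
#' @return A [survival_curve()].
#' @export
as_survival_curve <- function(x) {
  stopifnot(inherits(x, "cohort"))
  ages <- sort(unique(x$lifespan_days))
  deaths <- vapply(ages, function(a) sum(x$lifespan_days <= a), 0)
  survival_curve(c(0, ages), c(x$n0, x$n0 - deaths), n0 = x$n0)
}

#' Read / write survival-curve CSV files (columns `age_days`, `survivors`)
#'
#' @param path File path.
#' @param n0 Initial size; defaults to the largest survivor count in the file.
#' @export
read_curve_csv <- function(path, n0 = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age_days", "survivors") %in% names(df))) {
    stop("curve CSV must have columns age_days, survivors", call. = FALSE)
  }
  survival_curve(df$age_days, df$survivors,
                 n0 = if (is.null(n0)) max(df$survivors) else n0)
}

#' @rdname read_curve_csv
#' @param x A `survival_curve`.
#' @export
write_curve_csv <- function(x, path) {
  stopifnot(inherits(x, "survival_curve"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write organ-panel CSV files
#'
#' Cross-sectional sacrifice data with columns `animal_id`, `group`,
#' `age_months`, `body_weight_g`, `thymus_weight_mg`, `spleen_weight_mg`,
#' `log2_thymulin_titer`.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_organ_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "age_months", "body_weight_g",
            "thymus_weight_mg", "spleen_weight_mg", "log2_thymulin_titer")
  if (!all(need %in% names(df))) {
    stop("organ-panel CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_organ_panel_csv
#' @param x Organ-panel data.frame.
#' @export
write_organ_panel_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
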