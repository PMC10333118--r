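#' @importFrom rlang .data
#' @importFrom stats optim optimize rnorm runif rlnorm rbinom sd var cor dist setNames
NULL

# Canonical column sets for the four interchange CSVs.
.fs_cols <- list(
  outcomes   = c("reserve_id", "year", "cumulative_loss_ha"),
  covariates = c("reserve_id", "pop_density", "road_length", "precipitation",
                 "elevation", "slope", "aspect", "agb_baseline", "ppp", "age",
                 "travel_time", "area_ha", "group"),
  treatments = c("reserve_id", "intervention_year"),
  carbon     = c("reserve_id", "agb_c_density", "bgb_c_density", "agb_c_se",
                 "bgb_c_se", "forest_cover_2010", "forest_cover_interv")
)

# Numeric covariates used as matching predictors (all but the group label).
.fs_predictor_covariates <- setdiff(.fs_cols$covariates, c("reserve_id", "group"))

#' Assemble a study dataset from its component tables
#'
#' Bundles the outcome panel (cumulative forest loss per reserve and year),
#' the reserve-level covariate table, the treatment assignment table and an
#' optional carbon table into a validated `study_dataset` object, the common
#' currency of all downstream estimation functions.
#'
#' @param outcomes Tibble with columns `reserve_id`, `year`,
#'   `cumulative_loss_ha` (hectares lost since the first panel year;
#'   non-decreasing within reserve).
#' @param covariates Tibble with one row per reserve: `reserve_id`,
#'   `pop_density` (persons/km2), `road_length` (km), `precipitation` (mm/yr),
#'   `elevation` (m), `slope` (deg), `aspect` (deg), `agb_baseline` (Mg/ha),
#'   `ppp` (US$), `age` (yr), `travel_time` (min), `area_ha`, `group`
#'   (landscape-grouping label).
#' @param treatments Tibble with `reserve_id` and `intervention_year`
#'   (`NA` for donor reserves).
#' @param carbon Optional tibble with per-reserve carbon densities
#'   (tC/ha, reference year 2010), their standard errors and forest cover in
#'   2010 and at the intervention year.
#' @return A `study_dataset`: list with elements `outcomes`, `covariates`,
#'   `treatments`, `carbon`, `groups` (named list mapping group label to
#'   reserve ids) and `years` (panel year range).
#' @export
study_dataset <- function(outcomes, covariates, treatments, carbon = NULL) {
  outcomes   <- tibble::as_tibble(outcomes)
  covariates <- tibble::as_tibble(covariates)
  treatments <- tibble::as_tibble(treatments)
  if (!is.null(carbon)) carbon <- tibble::as_tibble(carbon)
  if (!"excluded_reason" %in% names(treatments)) {
    treatments$excluded_reason <- NA_character_
  }
  treatments$intervention_year <- as.integer(treatments$intervention_year)
  outcomes$year <- as.integer(outcomes$year)
  outcomes <- dplyr::arrange(outcomes, .data$reserve_id, .data$year)
  covariates <- dplyr::arrange(covariates, .data$reserve_id)
  treatments <- dplyr::arrange(treatments, .data$reserve_id)
  groups <- split(covariates$reserve_id, covariates$group)
  x <- structure(
    list(outcomes = outcomes, covariates = covariates,
         treatments = treatments, carbon = carbon, groups = groups,
         years = range(outcomes$year)),
    class = "study_dataset"
  )
  validate_study(x)
  x
}

#' Validate a study dataset
#'
#' Checks every structural invariant: required columns, a common contiguous
#' year range shared by all reserves, non-decreasing non-negative cumulative
#' loss, positive areas, consistency of reserve-id sets across tables, and
#' intervention years strictly inside the panel.
#'
#' @param study A `study_dataset`.
#' @return `study`, invisibly, if valid; otherwise an error naming the
#'   offending reserve/column.
#' @export
validate_study <- function(study) {
  stopifnot(inherits(study, "study_dataset"))
  out <- study$outcomes
  for (tab in c("outcomes", "covariates", "treatments")) {
    miss <- setdiff(.fs_cols[[tab]], names(study[[tab]]))
    if (length(miss) > 0) {
      stop(sprintf("format error: %s is missing column(s): %s",
                   tab, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(study$carbon)) {
    miss <- setdiff(.fs_cols$carbon, names(study$carbon))
    if (length(miss) > 0) {
      stop(sprintf("format error: carbon is missing column(s): %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }

  yr <- sort(unique(out$year))
  if (!identical(yr, seq(min(yr), max(yr)))) {
    stop("validation error: panel years are not a contiguous integer range",
         call. = FALSE)
  }
  by_res <- split(out, out$reserve_id)
  for (id in names(by_res)) {
    d <- by_res[[id]]
    if (!identical(sort(d$year), yr)) {
      stop(sprintf("validation error: reserve %s does not cover the common year range %d-%d",
                   id, min(yr), max(yr)), call. = FALSE)
    }
    d <- d[order(d$year), ]
    if (d$cumulative_loss_ha[1] < 0) {
      stop(sprintf("validation error: reserve %s has negative loss at first year", id),
           call. = FALSE)
    }
    dec <- which(diff(d$cumulative_loss_ha) < 0)
    if (length(dec) > 0) {
      stop(sprintf("validation error: cumulative_loss_ha decreases for reserve %s at year %d",
                   id, d$year[dec[1] + 1]), call. = FALSE)
    }
  }

  ids_out <- unique(out$reserve_id)
  ids_cov <- study$covariates$reserve_id
  if (anyDuplicated(ids_cov) > 0) {
    stop("validation error: duplicate reserve_id in covariates", call. = FALSE)
  }
  orphans <- setdiff(ids_out, ids_cov)
  if (length(orphans) > 0) {
    stop(sprintf("consistency error: reserve(s) in outcomes but not covariates: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  orphans <- setdiff(study$treatments$reserve_id, ids_out)
  if (length(orphans) > 0) {
    stop(sprintf("consistency error: reserve(s) in treatments but not outcomes: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  if (any(study$covariates$area_ha <= 0)) {
    stop("validation error: area_ha must be > 0", call. = FALSE)
  }
  if (any(study$covariates$age < 0)) {
    stop("validation error: age must be >= 0", call. = FALSE)
  }

  ty <- study$treatments$intervention_year
  bad <- !is.na(ty) & (ty <= min(yr) | ty > max(yr))
  if (any(bad)) {
    stop(sprintf("validation error: intervention_year outside the panel for reserve(s): %s",
                 paste(study$treatments$reserve_id[bad], collapse = ", ")),
         call. = FALSE)
  }
  if (!is.null(study$carbon)) {
    cb <- study$carbon
    if (any(cb$agb_c_density < 0 | cb$bgb_c_density < 0 |
            cb$agb_c_se < 0 | cb$bgb_c_se < 0)) {
      stop("validation error: carbon densities and SEs must be >= 0", call. = FALSE)
    }
    if (any(cb$forest_cover_2010 <= 0 | cb$forest_cover_interv <= 0)) {
      stop("validation error: forest covers must be > 0", call. = FALSE)
    }
  }
  invisible(study)
}

#' @export
print.study_dataset <- function(x, ...) {
  n_res <- length(unique(x$outcomes$reserve_id))
  n_tr <- sum(!is.na(x$treatments$intervention_year) &
                is.na(x$treatments$excluded_reason))
  cat(sprintf("<study_dataset> %d reserves (%d treated), panel %d-%d, %d group(s)\n",
              n_res, n_tr, x$years[1], x$years[2], length(x$groups)))
  invisible(x)
}

#' Load a study from CSV files
#'
#' Reads the four interchange CSVs (outcomes, covariates, treatments and
#' optionally carbon) and returns a validated [study_dataset()]. Files are
#' UTF-8 with a header row and `.` decimal separator.
#'
#' @param outcome_path,covariate_path,treatment_path,carbon_path File paths;
#'   `carbon_path` may be `NULL`.
#' @param strict If `TRUE` (default), unknown columns are a format error;
#'   set `FALSE` to ignore extras.
#' @return A validated `study_dataset`.
#' @export
load_study <- function(outcome_path, covariate_path, treatment_path,
                       carbon_path = NULL, strict = TRUE) {
  read_one <- function(path, tab) {
    if (!file.exists(path)) {
      stop(sprintf("input file not found: %s", path), call. = FALSE)
    }
    d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    extra <- setdiff(names(d), c(.fs_cols[[tab]], "excluded_reason"))
    if (strict && length(extra) > 0) {
      stop(sprintf("format error: %s has unknown column(s): %s",
                   tab, paste(extra, collapse = ", ")), call. = FALSE)
    }
    miss <- setdiff(.fs_cols[[tab]], names(d))
    if (length(miss) > 0) {
      stop(sprintf("format error: %s is missing column(s): %s",
                   tab, paste(miss, collapse = ", ")), call. = FALSE)
    }
    d
  }
  outcomes <- read_one(outcome_path, "outcomes")
  covariates <- read_one(covariate_path, "covariates")
  treatments <- read_one(treatment_path, "treatments")
  carbon <- if (!is.null(carbon_path)) read_one(carbon_path, "carbon")
  study_dataset(outcomes, covariates, treatments, carbon)
}

#' Write a study to CSV files
#'
#' Inverse of [load_study()]: writes the component tables of a study into a
#' directory using the canonical file names (`outcomes.csv`, `covariates.csv`,
#' `treatments.csv`, `carbon.csv`). Round-trips numeric content to full
#' precision.
#'
#' @param study A `study_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  validate_study(study)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(study$outcomes, file.path(dir, "outcomes.csv"))
  readr::write_csv(study$covariates, file.path(dir, "covariates.csv"))
  readr::write_csv(study$treatments, file.path(dir, "treatments.csv"))
  if (!is.null(study$carbon)) {
    readr::write_csv(study$carbon, file.path(dir, "carbon.csv"))
  }
  invisible(dir)
}

#' Restrict treated reserves to an intervention-year window
#'
#' Treated reserves whose intervention year falls outside
#' `[min_year, max_year]` are demoted to excluded — they keep their treatment
#' record with an `excluded_reason` and are never added to the donor pool.
#' The study window 2007-2015 guarantees both an adequate pre-intervention
#' training period and an adequate post-intervention evaluation period.
#'
#' @param study A `study_dataset`.
#' @param min_year,max_year Inclusive window bounds.
#' @return The filtered `study_dataset`.
#' @export
filter_treatment_window <- function(study, min_year = 2007, max_year = 2015) {
  stopifnot(min_year <= max_year)
  validate_study(study)
  tr <- study$treatments
  out_of_window <- !is.na(tr$intervention_year) &
    (tr$intervention_year < min_year | tr$intervention_year > max_year)
  tr$excluded_reason[out_of_window] <-
    sprintf("intervention_year outside [%d, %d]", min_year, max_year)
  study$treatments <- tr
  n_exc <- sum(out_of_window)
  if (n_exc > 0) {
    message(sprintf("filter_treatment_window: excluded %d treated reserve(s)", n_exc))
  }
  if (length(treated_ids(study)) == 0) {
    warning("no treated reserves remain after window filtering", call. = FALSE)
  }
  study
}

#' Reserve id accessors
#'
#' `treated_ids()` returns reserves with a non-missing intervention year and
#' no exclusion reason; `donor_ids()` returns never-treated reserves
#' (excluded treated reserves are *not* donors), optionally restricted to one
#' landscape group.
#'
#' @param study A `study_dataset`.
#' @param group Optional group label to restrict to.
#' @return Character vector of reserve ids, sorted.
#' @export
treated_ids <- function(study) {
  tr <- study$treatments
  sort(tr$reserve_id[!is.na(tr$intervention_year) & is.na(tr$excluded_reason)])
}

#' @rdname treated_ids
#' @export
donor_ids <- function(study, group = NULL) {
  tr <- study$treatments
  donors <- tr$reserve_id[is.na(tr$intervention_year)]
  if (!is.null(group)) {
    donors <- intersect(donors, study$groups[[group]])
  }
  sort(donors)
}

#' @rdname treated_ids
#' @export
reserve_group <- function(study, reserve_id) {
  study$covariates$group[match(reserve_id, study$covariates$reserve_id)]
}

#' @rdname treated_ids
#' @export
intervention_year_of <- function(study, reserve_id) {
  study$treatments$intervention_year[
    match(reserve_id, study$treatments$reserve_id)]
}

# Outcome series (named by year) for one reserve.
outcome_series <- function(study, reserve_id) {
  d <- study$outcomes[study$outcomes$reserve_id == reserve_id, ]
  d <- d[order(d$year), ]
  setNames(d$cumulative_loss_ha, d$year)
}

# Year x unit outcome matrix for a set of reserves (columns sorted by id).
outcome_matrix <- function(study, ids) {
  ids <- sort(ids)
  m <- vapply(ids, function(id) outcome_series(study, id),
              numeric(diff(study$years) + 1))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(ids))
  colnames(m) <- ids
  rownames(m) <- seq(study$years[1], study$years[2])
  m
}

# Truncate the panel at `last_year` (used by the anticipation backdate).
truncate_panel <- function(study, last_year) {
  stopifnot(last_year > study$years[1])
  study$outcomes <- study$outcomes[study$outcomes$year <= last_year, ]
  study$years <- range(study$outcomes$year)
  # intervention years beyond the truncated panel become irrelevant here;
  # drop them so validation passes on the sub-study
  ty <- study$treatments$intervention_year
  study$treatments$intervention_year[!is.na(ty) & ty > last_year] <- NA_integer_
  validate_study(study)
  study
}
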