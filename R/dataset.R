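#' @keywords internal
.dataset_columns <- c("ID", "TIME", "AMT", "DUR", "ROUTE", "DV",
                      "OBS_TYPE", "BL", "ADA", "BLQ", "EARLY", "BW", "SEX")

#' Read a monkey-study dataset
#'
#' Reads the package's NONMEM-flavoured wide CSV dialect: one row per dose
#' event or observation, partitioned by the presence of `AMT`. Mandatory
#' columns are `ID, TIME, AMT, DUR, ROUTE, DV, OBS_TYPE, BL, ADA, BLQ,
#' EARLY, BW, SEX`; missing values are coded `"."`. `OBS_TYPE` multiplexes
#' PK concentrations (ug/mL) and NK/B/T cell counts (cells/uL); `BL`
#' carries the individual mean baseline for PD rows; `ADA`, `BLQ` and
#' `EARLY` are 0/1 flags (anti-drug-antibody affected, below the
#' quantification limit, and PD sample within 8 h of a dose). Times are in
#' days.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `monkey_dataset`, ordered as on file.
#' @seealso [write_dataset()], [split_subjects()], [exclude_flagged()]
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = ".",
                        colClasses = "character")
  missing_cols <- setdiff(.dataset_columns, names(df))
  if (length(missing_cols))
    stop("dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[.dataset_columns]
  num <- c("TIME", "AMT", "DUR", "DV", "BL", "BW")
  for (nm in num) df[[nm]] <- as.numeric(df[[nm]])
  for (nm in c("ADA", "BLQ", "EARLY")) df[[nm]] <- as.integer(df[[nm]])
  if (any(is.na(df$TIME)) || any(df$TIME < 0))
    stop("dataset validation: TIME must be present and non-negative",
         call. = FALSE)
  obs <- is.na(df$AMT)
  if (any(df$DV[obs] < 0, na.rm = TRUE))
    stop("dataset validation: observed values must be >= 0", call. = FALSE)
  pd <- obs & df$OBS_TYPE %in% c("NK", "B", "T")
  if (any(pd & is.na(df$BL)))
    stop("dataset validation: PD rows require a baseline (BL)",
         call. = FALSE)
  if (any(obs & df$BLQ == 1 & df$OBS_TYPE != "PK", na.rm = TRUE))
    stop("dataset validation: BLQ flag is only defined for PK rows",
         call. = FALSE)
  class(df) <- c("monkey_dataset", "data.frame")
  df
}

#' Write a monkey-study dataset
#'
#' Writes the canonical form of the CSV dialect read by [read_dataset()]:
#' fixed column order, no quoting, missing values as `"."`. Reading a file
#' written by this function and writing it again reproduces the file
#' byte-identically.
#'
#' @param ds dataset `data.frame` (needs the mandatory columns).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  missing_cols <- setdiff(.dataset_columns, names(ds))
  if (length(missing_cols))
    stop("dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- ds[.dataset_columns]
  for (nm in names(out)) out[[nm]] <- as.character(out[[nm]])
  utils::write.table(out, path, sep = ",", quote = FALSE, na = ".",
                     row.names = FALSE)
  invisible(path)
}

#' Split a dataset into per-subject dose events and observations
#'
#' @param ds a `monkey_dataset`.
#' @return Named list (one element per subject id, in order of first
#'   appearance) of lists with elements `doses` (a [dose_events()]-style
#'   table), `obs` (observation rows), `bw` and `sex`.
#' @export
split_subjects <- function(ds) {
  ids <- unique(ds$ID)
  out <- lapply(ids, function(id) {
    sub <- ds[ds$ID == id, , drop = FALSE]
    ev <- sub[!is.na(sub$AMT), , drop = FALSE]
    doses <- data.frame(time = ev$TIME, amount = ev$AMT,
                        route = ev$ROUTE, duration = ev$DUR,
                        stringsAsFactors = FALSE)
    list(doses = doses,
         obs = sub[is.na(sub$AMT), , drop = FALSE],
         bw = sub$BW[1], sex = sub$SEX[1])
  })
  names(out) <- ids
  out
}

#' Express a cell count relative to its individual baseline
#'
#' Returns `100 * count / baseline` so that, e.g., a value of 33 means the
#' sample held one third of the baseline cell count.
#'
#' @param count cell count (cells/uL); vectorised.
#' @param baseline individual baseline count (cells/uL), must be > 0.
#' @return Percent of baseline.
#' @examples
#' relative_to_baseline(685, 685)    # 100
#' relative_to_baseline(685/3, 685)  # 33.3
#' @export
relative_to_baseline <- function(count, baseline) {
  if (any(baseline <= 0))
    stop("relative_to_baseline: baseline must be > 0", call. = FALSE)
  100 * count / baseline
}

#' Filter flagged observations from a dataset
#'
#' Drops observation rows carrying the selected flags, mirroring the data
#' cleaning used for model development: anti-drug-antibody affected PK
#' samples, PK samples below the quantification limit, and PD samples
#' drawn within 8 hours of a dose (nonspecific transient depletion). Dose
#' rows are always retained. Retained and excluded rows partition the
#' input.
#'
#' @param ds a `monkey_dataset`.
#' @param drop_ada,drop_blq,drop_early_pd logical switches per flag.
#' @return List with `retained`, `excluded` and `counts` (named integer
#'   vector `ada`, `blq`, `early`, `total`; a row with several flags is
#'   counted under each but once in `total`).
#' @export
exclude_flagged <- function(ds, drop_ada = TRUE, drop_blq = TRUE,
                            drop_early_pd = TRUE) {
  obs <- is.na(ds$AMT)
  f_ada <- drop_ada & obs & !is.na(ds$ADA) & ds$ADA == 1
  f_blq <- drop_blq & obs & !is.na(ds$BLQ) & ds$BLQ == 1
  f_early <- drop_early_pd & obs & !is.na(ds$EARLY) & ds$EARLY == 1 &
    ds$OBS_TYPE %in% c("NK", "B", "T")
  drop <- f_ada | f_blq | f_early
  list(retained = ds[!drop, , drop = FALSE],
       excluded = ds[drop, , drop = FALSE],
       counts = c(ada = sum(f_ada), blq = sum(f_blq),
                  early = sum(f_early), total = sum(drop)))
}
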