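# Data model and delimited-text IO for mating-group experiments.
#
# A dataset bundles four tables:
#   roster    one row per fly: id, vial, sex, size_class, marker, role
#   events    one row per copulation: vial, day, seq, male_id, female_id
#   offspring one row per female x laying day: marker-split offspring counts
#   design    one row per vial: experiment, social, treatment, focal_size

ROSTER_COLS    <- c("id", "vial", "sex", "size_class", "marker", "role")
EVENT_COLS     <- c("vial", "day", "seq", "male_id", "female_id")
OFFSPRING_COLS <- c("vial", "female_id", "lay_day", "count_wildtype", "count_spa")
DESIGN_COLS    <- c("vial", "experiment", "social", "treatment", "focal_size")

SEXES    <- c("male", "female")
SIZES    <- c("large", "small")
MARKERS  <- c("wildtype", "spa")
ROLES    <- c("focal_male", "rival_male", "female")
SOCIALS  <- c("Hom", "Het")
EXPERIMENTS <- c("F", "M", "FM")

#' Assemble and validate a mating-group dataset
#'
#' Bundles the roster, mating-event log, offspring counts and per-vial design
#' labels into a single validated object. Tables are coerced to canonical
#' column order and sorted deterministically (roster by vial then id, events
#' by vial, day, seq; offspring by vial, female, laying day) so that a
#' write/read round trip reproduces the object exactly.
#'
#' @param roster data frame with columns `id`, `vial`, `sex` (`male`/`female`),
#'   `size_class` (`large`/`small`, shorthand for low/high larval density),
#'   `marker` (`wildtype`/`spa`) and `role` (`focal_male`/`rival_male`/`female`).
#' @param events data frame with columns `vial`, `day` (1-based session day),
#'   `seq` (temporal rank of the copulation within the vial-day), `male_id`,
#'   `female_id`.
#' @param offspring data frame with columns `vial`, `female_id`, `lay_day`
#'   (eggs laid in the 20-h interval after that day's session),
#'   `count_wildtype` (sired by the focal male) and `count_spa`.
#' @param design optional data frame with columns `vial`, `experiment`
#'   (`F`/`M`/`FM`), `social` (`Hom`/`Het`), `treatment` and `focal_size`.
#'   When `NULL`, size-composition labels are derived from the roster and
#'   `experiment`/`treatment` are left `NA`.
#' @param days number of daily interaction sessions (default 4).
#' @param validate run the full invariant check (default `TRUE`).
#'
#' @return An object of class `mating_dataset`.
#' @seealso [read_dataset()], [write_dataset()], [validate_dataset()]
#' @export
#' @examples
#' d <- simulate_experiment("F", n_het = 2, n_hom = 1, seed = 1)
#' d
mating_dataset <- function(roster, events, offspring, design = NULL,
                           days = 4L, validate = TRUE) {
  roster    <- as.data.frame(roster)
  events    <- as.data.frame(events)
  offspring <- as.data.frame(offspring)

  check_columns(roster, ROSTER_COLS, "roster")
  check_columns(events, EVENT_COLS, "events")
  check_columns(offspring, OFFSPRING_COLS, "offspring")

  roster    <- roster[ROSTER_COLS]
  events    <- events[EVENT_COLS]
  offspring <- offspring[OFFSPRING_COLS]

  for (col in c("day", "seq")) events[[col]] <- as.integer(events[[col]])
  for (col in c("lay_day", "count_wildtype", "count_spa"))
    offspring[[col]] <- as.integer(offspring[[col]])

  if (is.null(design)) {
    design <- derive_design(roster)
  } else {
    design <- as.data.frame(design)
    check_columns(design, DESIGN_COLS, "design")
    design <- design[DESIGN_COLS]
  }

  roster    <- sort_by_cols(roster, c("vial", "id"))
  events    <- sort_by_cols(events, c("vial", "day", "seq"))
  offspring <- sort_by_cols(offspring, c("vial", "female_id", "lay_day"))
  design    <- sort_by_cols(design, "vial")

  x <- structure(
    list(roster = roster, events = events, offspring = offspring,
         design = design),
    days = as.integer(days),
    class = "mating_dataset"
  )
  if (validate) validate_dataset(x)
  x
}

sort_by_cols <- function(df, cols) {
  o <- do.call(order, unname(df[cols]))
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

check_columns <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    mq_error("mq_missing_column",
             sprintf("%s table is missing column(s): %s",
                     table, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

check_domain <- function(x, domain, what, table) {
  bad <- setdiff(unique(x[!is.na(x)]), domain)
  if (length(bad)) {
    mq_error("mq_bad_value",
             sprintf("%s/%s contains invalid value(s): %s (allowed: %s)",
                     table, what, paste(bad, collapse = ", "),
                     paste(domain, collapse = ", ")))
  }
}

#' Validate a mating-group dataset
#'
#' Checks every structural invariant of the data model: column domains,
#' 4-male / 4-female vial composition with exactly one wild-type focal male,
#' marker--role consistency, day ranges, uniqueness of the within-day
#' copulation order, referential integrity of every event and offspring row,
#' and non-negative offspring counts. Each violation raises an error with a
#' distinct condition class (see `R/errors.R`).
#'
#' @param x a `mating_dataset`.
#' @return `x`, invisibly, if all checks pass.
#' @export
validate_dataset <- function(x) {
  stopifnot(inherits(x, "mating_dataset"))
  days <- attr(x, "days")
  roster <- x$roster; events <- x$events; offspring <- x$offspring

  check_domain(roster$sex, SEXES, "sex", "roster")
  check_domain(roster$size_class, SIZES, "size_class", "roster")
  check_domain(roster$marker, MARKERS, "marker", "roster")
  check_domain(roster$role, ROLES, "role", "roster")
  check_domain(x$design$social, SOCIALS, "social", "design")
  check_domain(x$design$experiment, EXPERIMENTS, "experiment", "design")

  if (anyDuplicated(roster$id)) {
    mq_error("mq_bad_value", "roster ids must be unique across the dataset")
  }
  bad_sex_role <- (roster$role == "female") != (roster$sex == "female")
  if (any(bad_sex_role)) {
    mq_error("mq_bad_value", "roster role inconsistent with sex")
  }
  bad_marker <- (roster$role == "focal_male" & roster$marker != "wildtype") |
    (roster$role != "focal_male" & roster$marker != "spa")
  if (any(bad_marker)) {
    mq_error("mq_marker_mismatch",
             sprintf("marker/role mismatch for id(s): %s",
                     paste(roster$id[bad_marker], collapse = ", ")))
  }

  for (v in unique(roster$vial)) {
    rv <- roster[roster$vial == v, ]
    if (sum(rv$sex == "male") != 4L || sum(rv$sex == "female") != 4L) {
      mq_error("mq_vial_composition",
               sprintf("vial %s must have 4 males and 4 females", v))
    }
    nf <- sum(rv$role == "focal_male")
    if (nf != 1L) {
      mq_error("mq_focal_count",
               sprintf("vial %s has %d focal males (expected exactly 1)", v, nf))
    }
  }

  if (nrow(events)) {
    if (any(is.na(events$day)) || any(events$day < 1L | events$day > days)) {
      mq_error("mq_bad_day",
               sprintf("event day outside 1..%d", days))
    }
    if (any(is.na(events$seq)) || any(events$seq < 1L)) {
      mq_error("mq_bad_value", "event seq must be a positive integer")
    }
    key <- paste(events$vial, events$day, events$seq, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- events[duplicated(key), , drop = FALSE][1, ]
      mq_error("mq_duplicate_seq",
               sprintf("duplicate copulation rank: vial %s day %d seq %d",
                       dup$vial, dup$day, dup$seq))
    }
    male_key   <- paste(roster$vial[roster$sex == "male"],
                        roster$id[roster$sex == "male"])
    female_key <- paste(roster$vial[roster$sex == "female"],
                        roster$id[roster$sex == "female"])
    bad_m <- !(paste(events$vial, events$male_id) %in% male_key)
    bad_f <- !(paste(events$vial, events$female_id) %in% female_key)
    if (any(bad_m | bad_f)) {
      i <- which(bad_m | bad_f)[1]
      mq_error("mq_unknown_id",
               sprintf("event references unknown or wrong-sex id in vial %s (%s x %s)",
                       events$vial[i], events$male_id[i], events$female_id[i]))
    }
  } else {
    mq_warn("mq_empty_events", "dataset contains zero mating events")
  }

  if (nrow(offspring)) {
    if (any(is.na(offspring$lay_day)) ||
        any(offspring$lay_day < 1L | offspring$lay_day > days)) {
      mq_error("mq_bad_day", sprintf("offspring lay_day outside 1..%d", days))
    }
    if (any(offspring$count_wildtype < 0L | offspring$count_spa < 0L,
            na.rm = FALSE)) {
      mq_error("mq_negative_count", "offspring counts must be non-negative")
    }
    female_key <- paste(roster$vial[roster$sex == "female"],
                        roster$id[roster$sex == "female"])
    bad <- !(paste(offspring$vial, offspring$female_id) %in% female_key)
    if (any(bad)) {
      i <- which(bad)[1]
      mq_error("mq_unknown_id",
               sprintf("offspring row references unknown female %s in vial %s",
                       offspring$female_id[i], offspring$vial[i]))
    }
  }

  missing_design <- setdiff(unique(roster$vial), x$design$vial)
  if (length(missing_design)) {
    mq_error("mq_unknown_vial",
             sprintf("design table missing vial(s): %s",
                     paste(missing_design, collapse = ", ")))
  }

  invisible(x)
}

#' Derive per-vial design labels from the roster
#'
#' Reads off each vial's focal-male size and whether the male and female
#' size compositions are homogeneous or mixed. The experiment code (which
#' sex was manipulated across the whole design) cannot be inferred from a
#' single vial, so `experiment` and `treatment` are returned as `NA`; supply
#' a design table to [mating_dataset()] when these labels matter.
#'
#' @param roster a roster data frame.
#' @return data frame with one row per vial.
#' @export
derive_design <- function(roster) {
  vials <- sort(unique(roster$vial))
  if (!length(vials)) {
    return(data.frame(vial = character(), experiment = character(),
                      social = character(), treatment = character(),
                      focal_size = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(vials, function(v) {
    rv <- roster[roster$vial == v, ]
    msz <- unique(rv$size_class[rv$sex == "male"])
    fsz <- unique(rv$size_class[rv$sex == "female"])
    mixed <- length(msz) > 1L || length(fsz) > 1L
    data.frame(vial = v,
               experiment = NA_character_,
               social = if (mixed) "Het" else "Hom",
               treatment = NA_character_,
               focal_size = rv$size_class[rv$role == "focal_male"][1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.mating_dataset <- function(x, ...) {
  cat("mating_dataset:",
      length(unique(x$roster$vial)), "vial(s),",
      nrow(x$events), "mating event(s),",
      nrow(x$offspring), "offspring batch(es)\n")
  exps <- unique(stats::na.omit(x$design$experiment))
  if (length(exps)) cat("experiments:", paste(exps, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method base::all.equal
all.equal.mating_dataset <- function(target, current, ...) {
  all.equal(unclass(target)[c("roster", "events", "offspring", "design")],
            unclass(current)[c("roster", "events", "offspring", "design")], ...)
}

dataset_paths <- function(dir) {
  c(roster = file.path(dir, "roster.csv"),
    events = file.path(dir, "events.csv"),
    offspring = file.path(dir, "offspring.csv"),
    design = file.path(dir, "design.csv"))
}

#' Read a mating-group dataset from CSV files
#'
#' Reads the four UTF-8 CSV tables written by [write_dataset()] (or prepared
#' by hand to the same schemas), cross-links them and validates every
#' invariant. `design.csv` is optional; labels are derived from the roster
#' when it is absent.
#'
#' @param dir directory containing `roster.csv`, `events.csv`,
#'   `offspring.csv` and optionally `design.csv`; ignored when the three
#'   explicit paths are given.
#' @param roster,events,offspring,design explicit file paths overriding `dir`.
#' @param days number of daily sessions (default 4).
#' @return a validated `mating_dataset`.
#' @export
read_dataset <- function(dir = NULL, roster = NULL, events = NULL,
                         offspring = NULL, design = NULL, days = 4L) {
  if (!is.null(dir)) {
    p <- dataset_paths(dir)
    if (is.null(roster)) roster <- p[["roster"]]
    if (is.null(events)) events <- p[["events"]]
    if (is.null(offspring)) offspring <- p[["offspring"]]
    if (is.null(design) && file.exists(p[["design"]])) design <- p[["design"]]
  }
  for (f in c(roster, events, offspring)) {
    if (!file.exists(f)) {
      mq_error("mq_missing_column", sprintf("input file not found: %s", f))
    }
  }
  rd <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                    colClasses = "character")
  }
  roster_df <- rd(roster)
  events_df <- rd(events)
  offspring_df <- rd(offspring)
  design_df <- if (!is.null(design)) rd(design) else NULL
  d <- mating_dataset(roster_df, events_df, offspring_df, design_df,
                      days = days)
  message(sprintf("read dataset: %d roster rows, %d events, %d offspring batches",
                  nrow(d$roster), nrow(d$events), nrow(d$offspring)))
  d
}

#' Write a mating-group dataset to CSV files
#'
#' Writes `roster.csv`, `events.csv`, `offspring.csv` and `design.csv` (UTF-8,
#' header row) into `dir`. Rows are emitted in the dataset's canonical sort
#' order and columns in the documented schema order, so repeated writes of
#' the same dataset are byte-identical and `read_dataset(write_dataset(d))`
#' reproduces `d` exactly.
#'
#' @param x a `mating_dataset`.
#' @param dir output directory (created if needed).
#' @return the vector of file paths, invisibly.
#' @export
write_dataset <- function(x, dir) {
  stopifnot(inherits(x, "mating_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- dataset_paths(dir)
  wr <- function(df, path) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  }
  wr(x$roster, p[["roster"]])
  wr(x$events, p[["events"]])
  wr(x$offspring, p[["offspring"]])
  wr(x$design, p[["design"]])
  invisible(p)
}

#' Read an arbitrarily named delimited table into a documented schema
#'
#' Thin column-mapping adapter for externally deposited tables whose column
#' names differ from the package schemas (for example a repository download).
#' The caller supplies the mapping from schema names to source names; no
#' source layout is assumed.
#'
#' @param path delimited text file.
#' @param mapping named character vector: `c(schema_col = "source_col", ...)`.
#' @param sep field separator (default `","`).
#' @return data frame with the schema columns.
#' @export
#' @examples
#' \dontrun{
#' roster <- read_mapped_table("deposited.csv",
#'   c(id = "FlyID", vial = "Vial", sex = "Sex",
#'     size_class = "Size", marker = "EyePhenotype", role = "Role"))
#' }
read_mapped_table <- function(path, mapping, sep = ",") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  missing <- setdiff(unname(mapping), names(df))
  if (length(missing)) {
    mq_error("mq_missing_column",
             sprintf("source table lacks mapped column(s): %s",
                     paste(missing, collapse = ", ")))
  }
  out <- df[unname(mapping)]
  names(out) <- names(mapping)
  out
}
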