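#' @keywords internal
"_PACKAGE"

#' Developmental stages of the two-sex life table
#'
#' Fixed stage ladder: egg, larva, pupa, then the adult stage split by sex.
#' Larval instars are not resolved.
#'
#' @export
STAGES <- c("egg", "larva", "pupa", "female", "male")

.PREADULT <- c("egg", "larva", "pupa")

#' Construct an insect cohort from individual life-history records
#'
#' A cohort holds one row per insect followed from the egg stage (age 0 is
#' the day of oviposition) through daily census to death, plus a long-format
#' table of daily egg counts for females. Durations are whole days; the
#' duration recorded for the stage an individual died in is the number of
#' days it actually survived in that stage. Individuals that died before
#' adulthood have `sex = "undetermined"`, `adult_longevity_d = 0` and `NA`
#' durations for stages never entered.
#'
#' @param records data.frame with columns `id`, `treatment`, `egg_d`,
#'   `larva_d`, `pupa_d`, `sex` (`"female"`, `"male"` or `"undetermined"`),
#'   `death_stage` (`"egg"`, `"larva"`, `"pupa"` or `"adult"`) and
#'   `adult_longevity_d`.
#' @param fecundity data.frame with columns `id`, `adult_day` (1 = day of
#'   emergence) and `eggs`; one row per laying day per female. May have zero
#'   rows.
#' @return An object of class `"cohort"`: a list with elements `records`,
#'   `fecundity`, `n` (initial cohort size), `treatment` and
#'   `census_interval` (fixed at 1 day).
#' @export
cohort <- function(records, fecundity = empty_fecundity()) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  fecundity <- as.data.frame(fecundity, stringsAsFactors = FALSE)
  obj <- structure(
    list(
      records = records,
      fecundity = fecundity,
      n = nrow(records),
      treatment = if (nrow(records)) records$treatment[1] else NA_character_,
      census_interval = 1L
    ),
    class = "cohort"
  )
  validate_cohort(obj)
  obj
}

#' An empty fecundity table
#' @return zero-row data.frame with columns `id`, `adult_day`, `eggs`.
#' @export
empty_fecundity <- function() {
  data.frame(id = character(), adult_day = integer(), eggs = integer(),
             stringsAsFactors = FALSE)
}

.REC_COLS <- c("id", "treatment", "egg_d", "larva_d", "pupa_d",
               "sex", "death_stage", "adult_longevity_d")
.FEC_COLS <- c("id", "adult_day", "eggs")

#' Validate a cohort object
#'
#' Checks the structural invariants of the data model: unique ids, a single
#' treatment label, whole-day durations, the sex/fate consistency rules
#' (preadult deaths are unsexed; only adult females carry fecundity), and
#' that every laying day falls within the female's adult lifespan.
#'
#' @param x a `cohort`.
#' @return `x`, invisibly; stops with an informative error otherwise.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  fec <- x$fecundity
  if (!all(.REC_COLS %in% names(rec)))
    stop("missing required cohort column(s): ",
         paste(setdiff(.REC_COLS, names(rec)), collapse = ", "))
  if (!all(.FEC_COLS %in% names(fec)))
    stop("missing required fecundity column(s): ",
         paste(setdiff(.FEC_COLS, names(fec)), collapse = ", "))
  if (nrow(rec) < 1) stop("cohort must contain at least one record")
  if (anyDuplicated(rec$id)) stop("duplicate id in cohort records")
  if (length(unique(rec$treatment)) != 1)
    stop("all records in a cohort must share one treatment label")
  if (!all(rec$sex %in% c("female", "male", "undetermined")))
    stop("sex must be one of female, male, undetermined")
  if (!all(rec$death_stage %in% c(.PREADULT, "adult")))
    stop("death_stage must be one of egg, larva, pupa, adult")

  dur_ok <- function(d) all(is.na(d) | (d >= 1 & d == round(d)))
  if (!dur_ok(rec$egg_d) || !dur_ok(rec$larva_d) || !dur_ok(rec$pupa_d))
    stop("stage durations must be whole days >= 1 (daily census)")
  if (any(is.na(rec$adult_longevity_d)) ||
      any(rec$adult_longevity_d < 0 | rec$adult_longevity_d != round(rec$adult_longevity_d)))
    stop("adult_longevity_d must be a whole number of days >= 0")

  pre <- rec$death_stage %in% .PREADULT
  if (any(pre & rec$sex != "undetermined"))
    stop("sex must be undetermined for preadult deaths")
  if (any(!pre & rec$sex == "undetermined"))
    stop("adults must be sexed female or male")
  if (any(pre & rec$adult_longevity_d != 0))
    stop("adult_longevity_d must be 0 for individuals that never emerged")
  if (any(!pre & rec$adult_longevity_d < 1))
    stop("adults must have adult_longevity_d >= 1")

  # stage reached implies duration present; stage never entered implies NA
  need <- function(stage) {
    reached <- match(rec$death_stage, c(.PREADULT, "adult")) >= match(stage, .PREADULT)
    col <- rec[[paste0(stage, "_d")]]
    if (any(reached & is.na(col)))
      stop("missing ", stage, " duration for individual(s) that reached the ", stage, " stage")
    if (any(!reached & !is.na(col)))
      stop(stage, " duration present for individual(s) that died before the ", stage, " stage")
  }
  need("egg"); need("larva"); need("pupa")

  if (nrow(fec)) {
    if (!all(fec$id %in% rec$id)) stop("fecundity rows with unmatched id")
    if (any(fec$eggs < 0 | fec$eggs != round(fec$eggs)))
      stop("egg counts must be non-negative integers")
    if (any(fec$adult_day < 1 | fec$adult_day != round(fec$adult_day)))
      stop("adult_day must be a whole number >= 1")
    if (anyDuplicated(fec[c("id", "adult_day")]))
      stop("duplicate (id, adult_day) in fecundity table")
    m <- match(fec$id, rec$id)
    if (any(rec$sex[m] != "female" | rec$death_stage[m] != "adult"))
      stop("fecundity recorded for a male or a non-emerger")
    if (any(fec$adult_day > rec$adult_longevity_d[m]))
      stop("fecundity day index beyond adult longevity")
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  rec <- x$records
  cat("Age-stage two-sex cohort: n =", x$n,
      " treatment =", x$treatment, "\n")
  cat("  emerged adults:", sum(rec$death_stage == "adult"),
      "(", sum(rec$sex == "female"), "female /",
      sum(rec$sex == "male"), "male )\n")
  cat("  total eggs laid:", sum(x$fecundity$eggs), "\n")
  invisible(x)
}

.read_csv_strict <- function(path, cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = NULL, check.names = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "))
  if (any(vapply(df, function(col) any(col == "NA"), logical(1))))
    stop("explicit 'NA' tokens are not accepted; use an empty field (", path, ")")
  df[cols]
}

.to_int <- function(x, what) {
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  if (any(!is.na(x) & is.na(out))) stop("non-numeric value in ", what)
  if (any(!is.na(out) & out < 0)) stop("negative value in ", what)
  out
}

#' Read a cohort from CSV files
#'
#' The cohort file has the header
#' `id,treatment,egg_d,larva_d,pupa_d,sex,death_stage,adult_longevity_d`;
#' the fecundity file has `id,adult_day,eggs` (one row per laying day).
#' Empty fields denote missing values (stages never entered); the literal
#' token `NA` is rejected.
#'
#' @param path path to the cohort CSV.
#' @param fecundity_path path to the fecundity CSV.
#' @return a [cohort] object.
#' @export
read_cohort <- function(path, fecundity_path) {
  rec <- .read_csv_strict(path, .REC_COLS)
  fec <- .read_csv_strict(fecundity_path, .FEC_COLS)
  rec$egg_d <- .to_int(rec$egg_d, "egg_d")
  rec$larva_d <- .to_int(rec$larva_d, "larva_d")
  rec$pupa_d <- .to_int(rec$pupa_d, "pupa_d")
  rec$adult_longevity_d <- .to_int(rec$adult_longevity_d, "adult_longevity_d")
  if (nrow(fec)) {
    fec$adult_day <- .to_int(fec$adult_day, "adult_day")
    fec$eggs <- .to_int(fec$eggs, "eggs")
  } else {
    fec <- empty_fecundity()
  }
  cohort(rec, fec)
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x))` reproduces an
#' identical cohort (bit-exact field equality). Missing durations are
#' written as empty fields.
#'
#' @param x a `cohort`.
#' @param path,fecundity_path output file paths.
#' @return `x`, invisibly.
#' @export
write_cohort <- function(x, path, fecundity_path) {
  validate_cohort(x)
  utils::write.csv(x$records[.REC_COLS], path, row.names = FALSE, na = "",
                   quote = FALSE)
  utils::write.csv(x$fecundity[.FEC_COLS], fecundity_path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(x)
}

#' Individual lifespans in days
#'
#' Days alive counted under the daily-census convention: an individual with
#' egg 3 + larva 7 + pupa 6 + adult 14 days was alive on age-days 0..29 and
#' has lifespan 30. Deaths mid-stage count only the days survived in the
#' fatal stage.
#'
#' @param x a `cohort`.
#' @return named integer vector of lifespans (days), one per record.
#' @export
lifespan <- function(x) {
  stopifnot(inherits(x, "cohort"))
  rec <- x$records
  out <- rowSums(cbind(rec$egg_d, rec$larva_d, rec$pupa_d,
                       rec$adult_longevity_d), na.rm = TRUE)
  stats::setNames(as.integer(out), rec$id)
}

# Per-individual stage occupancy by age-day: list of integer vectors with
# stage index 1..5 (egg, larva, pupa, female, male) for each day alive.
.stage_seqs <- function(x) {
  rec <- x$records
  Map(function(e, l, p, a, sx) {
    seq_ <- rep.int(1L, e)
    if (!is.na(l)) seq_ <- c(seq_, rep.int(2L, l))
    if (!is.na(p)) seq_ <- c(seq_, rep.int(3L, p))
    if (a > 0) seq_ <- c(seq_, rep.int(if (sx == "female") 4L else 5L, a))
    seq_
  }, rec$egg_d, rec$larva_d, rec$pupa_d, rec$adult_longevity_d, rec$sex)
}

# age-day (0-based) on which each fecundity row's eggs were laid
.laying_age <- function(x) {
  rec <- x$records
  fec <- x$fecundity
  if (!nrow(fec)) return(integer())
  m <- match(fec$id, rec$id)
  preadult <- rec$egg_d[m] + rec$larva_d[m] + rec$pupa_d[m]
  as.integer(preadult + fec$adult_day - 1L)
}
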