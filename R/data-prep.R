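#' Read a calving-record file
#'
#' Reads the comma-delimited record dialect (one header row; columns
#' \code{calf_id}, \code{sire_id}, \code{dam_id}, \code{mgs_id},
#' \code{herd_id}, \code{calving_year}, \code{calving_month}, \code{parity},
#' \code{calf_sex}, \code{ce_score}, \code{livability}, \code{sire_breed},
#' \code{dam_breed}, \code{dam_birth_year}) and validates every enum,
#' reporting the first offending line.
#'
#' @param path file path.
#' @return data.frame of raw calving records.
#' @export
readCalvingRecords <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("calf_id", "sire_id", "dam_id", "mgs_id", "herd_id",
            "calving_year", "calving_month", "parity", "calf_sex",
            "ce_score", "livability", "sire_breed", "dam_breed",
            "dam_birth_year")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parse error: missing column(s) ", paste(miss, collapse = ", "))
  for (col in c("calf_id", "sire_id", "dam_id", "mgs_id", "herd_id"))
    x[[col]] <- as.character(x[[col]])
  bad <- function(ok, what) {
    if (!all(ok))
      stop(sprintf("parse error at line %d: invalid %s",
                   which(!ok)[1] + 1L, what))
  }
  bad(x$livability %in% 1:3, "livability (must be 1-3)")
  bad(x$ce_score %in% 1:5, "ce_score (must be 1-5)")
  bad(x$calving_month %in% 1:12, "calving_month (must be 1-12)")
  bad(x$calf_sex %in% c("M", "F"), "calf_sex (must be M/F)")
  bad(is.finite(x$parity) & x$parity >= 1, "parity (must be >= 1)")
  x
}

#' Read a pedigree file
#'
#' @param path file with columns bull_id, sire_id, mgs_id, birth_year;
#'   unknown ancestors coded 0.
#' @return a \linkS4class{SireMgsPedigree}.
#' @export
readPedigree <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(bull_id = "character", sire_id = "character",
                               mgs_id = "character"))
  SireMgsPedigree(x)
}

#' Read simulation truth files
#'
#' @param dir directory holding \code{truth_bulls.csv},
#'   \code{truth_herd_years.csv}, \code{truth_records.csv}.
#' @return list of the three truth tables.
#' @export
readTruth <- function(dir) {
  list(bulls = read.csv(file.path(dir, "truth_bulls.csv"),
                        stringsAsFactors = FALSE),
       herd_years = read.csv(file.path(dir, "truth_herd_years.csv"),
                             stringsAsFactors = FALSE),
       records = read.csv(file.path(dir, "truth_records.csv"),
                          stringsAsFactors = FALSE))
}

#' Assign October/May year-season labels
#'
#' Two seasons per year: season A starts in May, season B in October.
#' Months May-September belong to season A of the calving year, October-
#' December to season B of the calving year, and January-April to season B
#' of the previous year (the October-anchored season spans the year
#' boundary).
#'
#' @param calving_year integer year(s).
#' @param calving_month integer month(s), 1-12.
#' @return character labels like \code{"2010-A"}.
#' @export
assignYearSeason <- function(calving_year, calving_month) {
  if (any(!(calving_month %in% 1:12)))
    stop("invalid input: calving_month must be in 1-12")
  ifelse(calving_month >= 5 & calving_month <= 9,
         paste0(calving_year, "-A"),
         ifelse(calving_month >= 10,
                paste0(calving_year, "-B"),
                paste0(calving_year - 1L, "-B")))
}

#' Apply the national edit rules to raw calving records
#'
#' Rules, in this fixed order:
#' \enumerate{
#'   \item keep records whose dam birth year lies in the extraction window;
#'   \item keep purebred records (service-sire breed equals dam breed);
#'   \item recode the 3-point livability to binary stillbirth
#'     (\code{sb} = 2 for livability 2 or 3, else 1);
#'   \item collapse third and later parities into parity class 3;
#'   \item drop records with unknown MGS;
#'   \item drop herds that never reported a stillbirth (guards against
#'     herds reporting only live calves);
#'   \item assign year-season and herd-year labels, then drop herd-year
#'     contemporary groups with fewer than \code{minGroupSize} records.
#' }
#'
#' @param records raw records (see \code{\link{readCalvingRecords}}).
#' @param damBirthYears inclusive dam-birth-year window, default 1995-2018.
#' @param minGroupSize minimum herd-year contemporary-group size, default 5.
#' @return an \linkS4class{EditedCalvings} with a per-rule edit log.
#' @export
applyEdits <- function(records, damBirthYears = c(1995L, 2018L),
                       minGroupSize = 5L) {
  log <- integer()
  n0 <- nrow(records)

  keep <- records$dam_birth_year >= damBirthYears[1] &
          records$dam_birth_year <= damBirthYears[2]
  log["dam_birth_year_window"] <- sum(!keep)
  r <- records[keep, , drop = FALSE]

  keep <- r$sire_breed == r$dam_breed
  log["not_purebred"] <- sum(!keep)
  r <- r[keep, , drop = FALSE]

  r$sb <- ifelse(r$livability %in% c(2L, 3L), 2L, 1L)
  r$parity_class <- pmin(as.integer(r$parity), 3L)

  keep <- !.isUnknownId(r$mgs_id)
  log["unknown_mgs"] <- sum(!keep)
  r <- r[keep, , drop = FALSE]

  r$year_season <- if (nrow(r)) assignYearSeason(r$calving_year,
                                                 r$calving_month)
                   else character()
  r$herd_year <- if (nrow(r)) paste(r$herd_id, r$calving_year, sep = "-")
                 else character()

  # rules 6 and 7 interact: dropping an undersized herd-year group can strip
  # a herd's only stillbirth, so the pair is iterated to a fixed point (the
  # post-conditions must hold jointly on the final data)
  log["herd_without_stillbirth"] <- 0L
  log["small_herd_year_group"] <- 0L
  repeat {
    herdsWithSB <- unique(r$herd_id[r$sb == 2L])
    keep <- r$herd_id %in% herdsWithSB
    log["herd_without_stillbirth"] <- log["herd_without_stillbirth"] +
      sum(!keep)
    r <- r[keep, , drop = FALSE]

    sizes <- table(r$herd_year)
    keep <- r$herd_year %in% names(sizes)[sizes >= minGroupSize]
    log["small_herd_year_group"] <- log["small_herd_year_group"] +
      sum(!keep)
    r <- r[keep, , drop = FALSE]
    if (all(keep)) break
  }

  log["retained"] <- nrow(r)
  stopifnot(sum(log) == n0)
  attr(log, "min_group_size") <- as.integer(minGroupSize)
  rownames(r) <- NULL
  new("EditedCalvings", records = r, editLog = log)
}

#' Record counts and stillbirth percentage by parity class and calf sex
#'
#' @param dataset an \linkS4class{EditedCalvings}.
#' @return data.frame with \code{parity_class}, \code{calf_sex}, \code{n}
#'   and \code{pct_sb} (100 x stillbirths / n); empty cells are absent.
#' @export
summarizeByParitySex <- function(dataset) {
  r <- calvingRecords(dataset)
  if (!nrow(r)) stop("dataset is empty")
  agg <- aggregate(cbind(n = rep(1L, nrow(r)), sb2 = r$sb == 2L),
                   by = list(parity_class = r$parity_class,
                             calf_sex = r$calf_sex), FUN = sum)
  agg$pct_sb <- 100 * agg$sb2 / agg$n
  agg <- agg[order(agg$parity_class, agg$calf_sex),
             c("parity_class", "calf_sex", "n", "pct_sb")]
  rownames(agg) <- NULL
  agg
}

#' Overall stillbirth rate from a cell summary
#'
#' The record-count-weighted mean of per-cell stillbirth percentages, equal
#' to 100 x total stillbirths / total records when the cells are exact.
#'
#' @param table data.frame with columns \code{n} and \code{pct_sb}.
#' @return overall percentage of stillbirth.
#' @export
overallStillbirthRate <- function(table) {
  if (!nrow(table)) stop("empty summary table")
  if (sum(table$n) == 0) stop("undefined rate: zero total records")
  weighted.mean(table$pct_sb, table$n)
}

#' Stillbirth percentage by calving-ease score
#'
#' @param dataset an \linkS4class{EditedCalvings}.
#' @return data.frame with \code{ce_score}, \code{n}, \code{pct_sb};
#'   unobserved scores are absent.
#' @export
stillbirthByCalvingEase <- function(dataset) {
  r <- calvingRecords(dataset)
  if (!nrow(r)) stop("dataset is empty")
  agg <- aggregate(cbind(n = rep(1L, nrow(r)), sb2 = r$sb == 2L),
                   by = list(ce_score = r$ce_score), FUN = sum)
  agg$pct_sb <- 100 * agg$sb2 / agg$n
  agg[order(agg$ce_score), c("ce_score", "n", "pct_sb")]
}

#' Bundled breed-level parity-sex stillbirth summary
#'
#' Published record counts (N) and stillbirth percentages by parity class
#' and calf sex for the five US dairy breeds evaluated here (Ayrshire,
#' Guernsey, Milking Shorthorn, Brown Swiss, Jersey), shipped as a small
#' delimited reference table. Useful as input to
#' \code{\link{overallStillbirthRate}} and for cross-checking summary
#' arithmetic.
#'
#' @return data.frame with \code{breed}, \code{parity_class},
#'   \code{calf_sex}, \code{n}, \code{pct_sb}.
#' @export
referenceBreedSummary <- function() {
  read.csv(system.file("extdata", "breed_parity_sex_summary.csv",
                       package = "stillbirthSMGS"),
           stringsAsFactors = FALSE)
}
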