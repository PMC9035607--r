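#' @title S4 classes for the S-MGS stillbirth evaluation
#' @name stillbirthSMGS-classes
#' @description
#' Central containers: \linkS4class{SireMgsPedigree} (bull ancestry),
#' \linkS4class{RelationshipInverse} (sparse A-inverse),
#' \linkS4class{EditedCalvings} (records after the national edit rules),
#' \linkS4class{SmgsDesign} (incidence structure of the threshold model),
#' \linkS4class{SmgsFit} (retained Gibbs draws), and
#' \linkS4class{GeneticParameters} (direct/maternal posterior summaries).
NULL

UNKNOWN_ID <- "0"

.isUnknownId <- function(x) is.na(x) | x == "" | x == UNKNOWN_ID

#' Sire-MGS pedigree of bulls
#'
#' An ordered pedigree of bulls, each with an optional sire-of-bull and
#' maternal-grandsire-of-bull and a birth year. Ancestors must precede
#' descendants; unknown ancestors are coded \code{"0"}. The pedigree defines
#' the additive relationship matrix A of the evaluation model.
#'
#' @slot entries data.frame with columns \code{bull_id}, \code{sire_id},
#'   \code{mgs_id}, \code{birth_year}.
#' @slot roles character vector parallel to \code{entries} classifying bulls
#'   as \code{"sire"}, \code{"mgs"}, \code{"both"} or \code{"ancestor"};
#'   may be empty for pedigrees read from files.
#' @exportClass SireMgsPedigree
setClass("SireMgsPedigree",
  representation(entries = "data.frame", roles = "character"),
  prototype(entries = data.frame(bull_id = character(), sire_id = character(),
                                 mgs_id = character(),
                                 birth_year = integer()),
            roles = character()))

setValidity("SireMgsPedigree", function(object) {
  e <- object@entries
  need <- c("bull_id", "sire_id", "mgs_id", "birth_year")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(e$bull_id)) return("duplicated bull_id")
  if (length(object@roles) && length(object@roles) != nrow(e))
    return("roles must be empty or match the number of bulls")
  pos <- seq_len(nrow(e))
  names(pos) <- e$bull_id
  for (col in c("sire_id", "mgs_id")) {
    anc <- e[[col]]
    known <- which(!.isUnknownId(anc))
    if (length(known)) {
      if (any(!(anc[known] %in% e$bull_id)))
        return(sprintf("%s references a bull absent from the pedigree", col))
      if (any(pos[anc[known]] >= known))
        return("ancestors must precede descendants")
    }
  }
  TRUE
})

#' Construct a SireMgsPedigree
#'
#' @param entries data.frame with columns \code{bull_id}, \code{sire_id},
#'   \code{mgs_id}, \code{birth_year}; ancestors before descendants.
#' @param roles optional role labels (see \linkS4class{SireMgsPedigree}).
#' @return A \linkS4class{SireMgsPedigree}.
#' @export
SireMgsPedigree <- function(entries, roles = character()) {
  entries$bull_id <- as.character(entries$bull_id)
  entries$sire_id <- as.character(entries$sire_id)
  entries$mgs_id <- as.character(entries$mgs_id)
  entries$birth_year <- as.integer(entries$birth_year)
  new("SireMgsPedigree", entries = entries, roles = roles)
}

#' Sparse inverse of the additive relationship matrix
#'
#' @slot matrix symmetric sparse A-inverse over the bull index.
#' @slot indexMap named integer vector, bull_id to row of \code{matrix}.
#' @exportClass RelationshipInverse
setClass("RelationshipInverse",
  representation(matrix = "Matrix", indexMap = "integer"))

setValidity("RelationshipInverse", function(object) {
  m <- object@matrix
  if (nrow(m) != ncol(m)) return("A-inverse must be square")
  if (length(object@indexMap) != nrow(m))
    return("indexMap length must match matrix dimension")
  if (any(Matrix::diag(m) < 1 - 1e-12))
    return("A-inverse diagonal must be >= 1")
  TRUE
})

#' Calving records after the national edit rules
#'
#' @slot records data.frame of retained records carrying, in addition to the
#'   raw columns, \code{sb} (1 = alive, 2 = stillborn), \code{parity_class}
#'   (1, 2, 3 = third-and-later), \code{year_season} and \code{herd_year}.
#' @slot editLog named integer vector: records removed per edit rule, plus
#'   \code{retained}.
#' @exportClass EditedCalvings
setClass("EditedCalvings",
  representation(records = "data.frame", editLog = "integer"))

setValidity("EditedCalvings", function(object) {
  r <- object@records
  if (nrow(r) == 0) return(TRUE)
  if (!all(r$sb %in% 1:2)) return("sb must be 1 or 2")
  if (!all(r$parity_class %in% 1:3)) return("parity_class must be 1, 2 or 3")
  if (any(.isUnknownId(r$mgs_id))) return("unknown MGS must have been removed")
  byHerd <- tapply(r$sb == 2, r$herd_id, any)
  if (!all(byHerd)) return("every retained herd must report a stillbirth")
  if (any(table(r$herd_year) < attr(object@editLog, "min_group_size") %||% 1))
    return("herd-year groups below the minimum size were retained")
  TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Design structure of the S-MGS threshold model
#'
#' Incidence maps for the fixed effects (intercept, year-season, parity-sex,
#' sire and MGS birth-year groups, and the two parity-sex-by-birth-year
#' interactions), the random herd-year effect, and the sire/MGS bull indices,
#' together with full-rank constraints (first level of each fixed factor and
#' interaction cells on a constrained margin are clamped at zero).
#'
#' @slot y integer stillbirth code per record (1/2).
#' @slot factorIndex named list of 1-based level indices per record.
#' @slot factorLevels named list of level labels.
#' @slot estimable named list of logicals per level (FALSE = clamped at 0).
#' @slot hyFactor name of the herd-year factor.
#' @slot sire,mgs 1-based bull index (into the pedigree) per record.
#' @slot pedigree the \linkS4class{SireMgsPedigree} backing A.
#' @slot bullSBLevel,bullMBLevel per-bull index into the sire (MGS)
#'   birth-year-group factor levels (NA when the group is unrepresented).
#' @exportClass SmgsDesign
setClass("SmgsDesign",
  representation(y = "integer", factorIndex = "list", factorLevels = "list",
                 estimable = "list", hyFactor = "character",
                 sire = "integer", mgs = "integer",
                 pedigree = "SireMgsPedigree",
                 bullSBLevel = "integer", bullMBLevel = "integer"))

setValidity("SmgsDesign", function(object) {
  n <- length(object@y)
  if (!all(object@y %in% 1:2)) return("y must be 1/2 stillbirth codes")
  for (f in names(object@factorIndex)) {
    idx <- object@factorIndex[[f]]
    if (length(idx) != n) return(sprintf("factor %s has wrong length", f))
    nl <- length(object@factorLevels[[f]])
    if (any(idx < 1L | idx > nl))
      return(sprintf("factor %s has out-of-range level indices", f))
    if (length(object@estimable[[f]]) != nl)
      return(sprintf("estimable mask for %s has wrong length", f))
  }
  nb <- nrow(object@pedigree@entries)
  if (any(object@sire < 1L | object@sire > nb)) return("sire index out of range")
  if (any(object@mgs < 1L | object@mgs > nb)) return("mgs index out of range")
  TRUE
})

#' Posterior draws from the S-MGS threshold model
#'
#' @slot variances data.frame of retained draws with columns
#'   \code{sigma_s2}, \code{sigma_mgs2}, \code{sigma_s_mgs}, \code{sigma_hy2}.
#' @slot solutions matrix (draws x equations) of location solutions; columns
#'   follow \code{effectTable}.
#' @slot effectTable data.frame mapping solution columns to (factor, level).
#' @slot design the \linkS4class{SmgsDesign} that was fitted.
#' @slot ainverse the \linkS4class{RelationshipInverse} used.
#' @slot config list echo of the MCMC configuration.
#' @exportClass SmgsFit
setClass("SmgsFit",
  representation(variances = "data.frame", solutions = "matrix",
                 effectTable = "data.frame", design = "SmgsDesign",
                 ainverse = "RelationshipInverse", config = "list"))

setValidity("SmgsFit", function(object) {
  if (nrow(object@variances) != nrow(object@solutions))
    return("variance and solution draws out of step")
  if (ncol(object@solutions) != nrow(object@effectTable))
    return("effectTable must describe every solution column")
  cfg <- object@config
  expect <- floor((cfg$n_iter - cfg$burn_in) / cfg$thin) +
    as.integer((cfg$n_iter - cfg$burn_in) %% cfg$thin > 0)
  if (nrow(object@variances) != expect)
    return("retained sample count inconsistent with n_iter/burn_in/thin")
  TRUE
})

#' Direct and maternal genetic parameters
#'
#' Posterior summaries (mean and 95% HPD) of the direct variance, maternal
#' variance, direct-maternal covariance and correlation, heritabilities and
#' underlying-scale phenotypic variance, obtained by transforming each
#' retained draw and summarizing afterwards.
#'
#' @slot summary data.frame: parameter, mean, hpd_low, hpd_high.
#' @slot draws data.frame of per-draw transformed values.
#' @slot nExcluded number of draws excluded from the correlation summary
#'   because the implied maternal variance was non-positive.
#' @exportClass GeneticParameters
setClass("GeneticParameters",
  representation(summary = "data.frame", draws = "data.frame",
                 nExcluded = "integer"))

setMethod("show", "SireMgsPedigree", function(object) {
  e <- object@entries
  cat("SireMgsPedigree with", nrow(e), "bulls\n")
  if (nrow(e)) {
    cat("  founders:", sum(.isUnknownId(e$sire_id) & .isUnknownId(e$mgs_id)),
        "  birth years:", min(e$birth_year), "-", max(e$birth_year), "\n")
  }
})

setMethod("show", "EditedCalvings", function(object) {
  cat("EditedCalvings with", nrow(object@records), "records\n")
  if (nrow(object@records)) {
    cat(sprintf("  stillbirth rate: %.2f%%\n",
                100 * mean(object@records$sb == 2)))
    cat("  herds:", length(unique(object@records$herd_id)),
        " herd-years:", length(unique(object@records$herd_year)), "\n")
  }
  cat("  edit log:", paste(names(object@editLog), object@editLog,
                           sep = "=", collapse = ", "), "\n")
})

setMethod("show", "RelationshipInverse", function(object) {
  cat("RelationshipInverse over", nrow(object@matrix), "bulls,",
      length(object@matrix@x), "stored entries\n")
})

setMethod("show", "SmgsDesign", function(object) {
  cat("SmgsDesign:", length(object@y), "records,",
      nrow(object@pedigree@entries), "bulls\n")
  for (f in names(object@factorLevels))
    cat(sprintf("  %-6s %4d levels (%d estimable)\n", f,
                length(object@factorLevels[[f]]), sum(object@estimable[[f]])))
})

setMethod("show", "SmgsFit", function(object) {
  cat("SmgsFit:", nrow(object@variances), "retained draws,",
      ncol(object@solutions), "equations\n")
  m <- colMeans(object@variances)
  cat(sprintf("  posterior means: sigma_s2=%.4f sigma_mgs2=%.4f sigma_s_mgs=%.4f sigma_hy2=%.4f\n",
              m["sigma_s2"], m["sigma_mgs2"], m["sigma_s_mgs"],
              m["sigma_hy2"]))
})

setMethod("show", "GeneticParameters", function(object) {
  cat("GeneticParameters (posterior mean [95% HPD]):\n")
  s <- object@summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-22s %8.4f [%8.4f, %8.4f]\n", s$parameter[i], s$mean[i],
                s$hpd_low[i], s$hpd_high[i]))
  if (object@nExcluded > 0)
    cat("  draws excluded from correlation summary:", object@nExcluded, "\n")
})
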