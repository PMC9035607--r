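#' Number of bulls in a pedigree
#' @param x a \linkS4class{SireMgsPedigree}.
#' @return integer count of bulls.
#' @export
setGeneric("nBulls", function(x) standardGeneric("nBulls"))

#' @rdname nBulls
#' @export
setMethod("nBulls", "SireMgsPedigree", function(x) nrow(x@entries))

#' Bull identifiers, in pedigree order
#' @param x a \linkS4class{SireMgsPedigree}.
#' @return character vector of bull ids.
#' @export
setGeneric("bullIds", function(x) standardGeneric("bullIds"))

#' @rdname bullIds
#' @export
setMethod("bullIds", "SireMgsPedigree", function(x) x@entries$bull_id)

#' Pedigree entries as a data.frame
#' @param x a \linkS4class{SireMgsPedigree}.
#' @return data.frame with bull_id, sire_id, mgs_id, birth_year.
#' @export
setGeneric("pedigreeEntries", function(x) standardGeneric("pedigreeEntries"))

#' @rdname pedigreeEntries
#' @export
setMethod("pedigreeEntries", "SireMgsPedigree", function(x) x@entries)

#' Edited calving records
#' @param x an \linkS4class{EditedCalvings}.
#' @return data.frame of retained records.
#' @export
setGeneric("calvingRecords", function(x) standardGeneric("calvingRecords"))

#' @rdname calvingRecords
#' @export
setMethod("calvingRecords", "EditedCalvings", function(x) x@records)

#' Edit log of removals per rule
#' @param x an \linkS4class{EditedCalvings}.
#' @return named integer vector: removals per rule and records retained.
#' @export
setGeneric("editLog", function(x) standardGeneric("editLog"))

#' @rdname editLog
#' @export
setMethod("editLog", "EditedCalvings", function(x) x@editLog)

#' Sparse A-inverse matrix
#' @param x a \linkS4class{RelationshipInverse}.
#' @return sparse symmetric Matrix.
#' @export
setGeneric("aInverseMatrix", function(x) standardGeneric("aInverseMatrix"))

#' @rdname aInverseMatrix
#' @export
setMethod("aInverseMatrix", "RelationshipInverse", function(x) x@matrix)

#' Retained variance-component draws
#' @param x an \linkS4class{SmgsFit}.
#' @return data.frame with sigma_s2, sigma_mgs2, sigma_s_mgs, sigma_hy2.
#' @export
setGeneric("varianceSamples", function(x) standardGeneric("varianceSamples"))

#' @rdname varianceSamples
#' @export
setMethod("varianceSamples", "SmgsFit", function(x) x@variances)

#' Posterior-mean location solutions
#' @param x an \linkS4class{SmgsFit}.
#' @param factor optional factor name (e.g. \code{"sire"}, \code{"YS"});
#'   when given, a named vector of that factor's level solutions.
#' @return named numeric vector of posterior means.
#' @export
setGeneric("solutionMeans",
           function(x, factor = NULL) standardGeneric("solutionMeans"))

#' @rdname solutionMeans
#' @export
setMethod("solutionMeans", "SmgsFit", function(x, factor = NULL) {
  m <- colMeans(x@solutions)
  if (is.null(factor)) {
    names(m) <- paste(x@effectTable$factor, x@effectTable$level, sep = ":")
    return(m)
  }
  sel <- x@effectTable$factor == factor
  if (!any(sel)) stop("unknown factor: ", factor)
  setNames(m[sel], x@effectTable$level[sel])
})
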