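#' Underlying-scale bull solutions
#'
#' For each bull and role, the underlying solution is the posterior-mean
#' random-effect solution plus the posterior-mean fixed birth-year-group
#' solution of the bull's cohort (zero for cohorts without records in that
#' role). Differences between bulls are invariant to the group anchoring;
#' the genetic-base conversion fixes the scale downstream.
#'
#' @param fit an \linkS4class{SmgsFit}.
#' @param role \code{"sire"} (direct pathway) or \code{"mgs"} (maternal).
#' @return data.frame: bull_id, birth_year, epsilon, n_records.
#' @export
underlyingSolutions <- function(fit, role = c("sire", "mgs")) {
  role <- match.arg(role)
  design <- fit@design
  e <- pedigreeEntries(design@pedigree)
  if (anyNA(e$birth_year))
    stop("assignment error: bull without a birth year")
  sol <- solutionMeans(fit, role)
  grpFactor <- if (role == "sire") "sB" else "mB"
  grpLevel <- if (role == "sire") design@bullSBLevel else design@bullMBLevel
  grpSol <- solutionMeans(fit, grpFactor)
  grp <- ifelse(is.na(grpLevel), 0, grpSol[grpLevel])
  idx <- if (role == "sire") design@sire else design@mgs
  nrec <- tabulate(idx, nbins = nrow(e))
  data.frame(bull_id = e$bull_id, birth_year = e$birth_year,
             epsilon = unname(sol + grp), n_records = nrec)
}

#' Convert underlying solutions to observed-scale stillbirth PTA
#'
#' Anchors the observed scale to a genetic base: with F the standard normal
#' distribution function, the threshold-plus-constant is the mean over base
#' bulls of F^{-1}(1 - base rate) + epsilon*, and each bull's PTA is
#' 100 x (1 - F(-epsilon + that anchor)). The mean PTA over base bulls then
#' reproduces the base percentage, and the conversion is strictly
#' increasing in epsilon.
#'
#' @param epsilons data.frame from \code{\link{underlyingSolutions}}.
#' @param baseYears inclusive birth-year range of the genetic base
#'   (sires 2011-2015 and MGS 2006-2010 are the conventional choices).
#' @param basePct phenotypic base: the record-weighted stillbirth percentage
#'   in heifers over the base birth years (in percent, strictly inside
#'   (0, 100)).
#' @return data.frame: bull_id, birth_year, epsilon, pta_pct, n_records.
#' @export
observedScalePTA <- function(epsilons, baseYears, basePct) {
  if (basePct <= 0 || basePct >= 100)
    stop("infinite-threshold error: base percentage must be inside (0, 100)")
  inBase <- epsilons$birth_year >= baseYears[1] &
            epsilons$birth_year <= baseYears[2]
  if (!any(inBase))
    stop("no bull falls in the configured base window ",
         baseYears[1], "-", baseYears[2])
  anchor <- mean(qnorm(1 - basePct / 100) + epsilons$epsilon[inBase])
  out <- epsilons
  out$pta_pct <- 100 * (1 - pnorm(-epsilons$epsilon + anchor))
  out
}

#' Record-weighted heifer stillbirth percentage for a base window
#'
#' The phenotypic base: stillbirth percentage among first-parity records
#' whose sire (or MGS) was born inside the base window, weighted by record
#' counts.
#'
#' @param dataset an \linkS4class{EditedCalvings}.
#' @param pedigree the matching \linkS4class{SireMgsPedigree}.
#' @param role \code{"sire"} or \code{"mgs"}.
#' @param baseYears inclusive bull-birth-year range.
#' @return percentage of stillbirth.
#' @export
phenotypicBasePct <- function(dataset, pedigree, role = c("sire", "mgs"),
                              baseYears) {
  role <- match.arg(role)
  r <- calvingRecords(dataset)
  e <- pedigreeEntries(pedigree)
  by <- setNames(e$birth_year, e$bull_id)
  ids <- if (role == "sire") r$sire_id else r$mgs_id
  sel <- r$parity_class == 1L & by[ids] >= baseYears[1] &
         by[ids] <= baseYears[2]
  if (!any(sel, na.rm = TRUE))
    stop("no heifer records with ", role, " born in ", baseYears[1], "-",
         baseYears[2])
  100 * mean(r$sb[which(sel)] == 2L)
}

#' Mixed-model-equation diagonals for bull effects
#'
#' The diagonal of the coefficient-matrix row for a bull's effect in the
#' given role: its record count plus its A-inverse diagonal times the
#' matching element of the inverse of G0.
#'
#' @param fit an \linkS4class{SmgsFit}.
#' @param role \code{"sire"} or \code{"mgs"}.
#' @param g0 2x2 sire-MGS covariance at which to evaluate (defaults to the
#'   posterior means of the fit).
#' @return named numeric vector of diagonals, one per bull.
#' @export
mmeDiagonals <- function(fit, role = c("sire", "mgs"), g0 = NULL) {
  role <- match.arg(role)
  if (is.null(g0)) {
    v <- colMeans(varianceSamples(fit))
    g0 <- matrix(c(v["sigma_s2"], v["sigma_s_mgs"], v["sigma_s_mgs"],
                   v["sigma_mgs2"]), 2)
  }
  g0inv <- solve(g0)
  k <- if (role == "sire") 1 else 2
  design <- fit@design
  idx <- if (role == "sire") design@sire else design@mgs
  nb <- nBulls(design@pedigree)
  n <- tabulate(idx, nbins = nb)
  d <- n + Matrix::diag(aInverseMatrix(fit@ainverse)) * g0inv[k, k]
  setNames(as.numeric(d), bullIds(design@pedigree))
}

#' Approximate reliability from mixed-model-equation diagonals
#'
#' reliability = 1 - (1 / diagonal) / genetic variance, floored at 0. Uses
#' only diagonal information, ignoring relationships among bulls and the
#' distribution of records over other effects, which can inflate the values
#' relative to exact prediction-error-variance reliabilities.
#'
#' @param d positive MME diagonal(s), e.g. from \code{\link{mmeDiagonals}}.
#' @param sigmaA2 genetic variance on the underlying scale (the sire
#'   variance for service-sire reliabilities, the MGS variance for MGS
#'   reliabilities).
#' @return reliabilities in [0, 1).
#' @export
reliabilityApprox <- function(d, sigmaA2) {
  if (any(d <= 0) || sigmaA2 <= 0)
    stop("invalid input: diagonals and genetic variance must be positive")
  pmax(0, 1 - (1 / d) / sigmaA2)
}

.linearTrend <- function(year, y) {
  if (length(year) < 3) stop("trend error: need at least 3 years")
  fit <- lm(y ~ year)
  sm <- suppressWarnings(summary(fit))   # exact lines trip a perfect-fit note
  cf <- sm$coefficients
  slope <- unname(cf["year", "Estimate"])
  # degenerate (zero-residual) fits: an exact line has p = 0 unless flat
  p <- if (sm$sigma < 1e-10) as.numeric(abs(slope) < 1e-10)
       else unname(cf["year", "Pr(>|t|)"])
  if (is.nan(p)) p <- 1
  structure(list(slope = slope,
                 intercept = unname(cf["(Intercept)", "Estimate"]),
                 p_value = p,
                 yearly_means = data.frame(year = year, mean = y),
                 smoothed = NULL),
            class = "TrendEstimate")
}

#' @export
print.TrendEstimate <- function(x, ...) {
  cat(sprintf("TrendEstimate: slope %.4f per year (p = %.4g), %d years\n",
              x$slope, x$p_value, nrow(x$yearly_means)))
  invisible(x)
}

#' Phenotypic trend of heifer stillbirth over sire birth years
#'
#' Ordinary least squares of the yearly mean heifer (first-parity)
#' stillbirth percentage on sire birth year, with a two-sided t test of
#' zero slope.
#'
#' @param dataset an \linkS4class{EditedCalvings}.
#' @param pedigree the matching \linkS4class{SireMgsPedigree}.
#' @return a \code{TrendEstimate} (slope, intercept, p_value, yearly_means).
#' @export
phenotypicTrend <- function(dataset, pedigree) {
  r <- calvingRecords(dataset)
  e <- pedigreeEntries(pedigree)
  by <- setNames(e$birth_year, e$bull_id)
  h <- r[r$parity_class == 1L, , drop = FALSE]
  yr <- by[h$sire_id]
  agg <- aggregate(cbind(pct = 100 * (h$sb == 2L)), by = list(year = yr),
                   FUN = mean)
  .linearTrend(agg$year, agg$pct)
}

#' Genetic trend of PTA over bull birth years
#'
#' Ordinary least squares of the yearly mean PTA (service-sire or daughter
#' stillbirth percentage) on bull birth year.
#'
#' @param pta data.frame from \code{\link{observedScalePTA}} (needs
#'   \code{birth_year} and \code{pta_pct}); bulls without records can be
#'   excluded by the caller.
#' @return a \code{TrendEstimate}.
#' @export
geneticTrend <- function(pta) {
  agg <- aggregate(cbind(mean_pta = pta$pta_pct),
                   by = list(year = pta$birth_year), FUN = mean)
  out <- .linearTrend(agg$year, agg$mean_pta)
  names(out$yearly_means) <- c("year", "mean")
  out
}

#' Cubic smoothing-spline smoother for trend series
#'
#' Smooths a yearly series with a cubic smoothing spline whose roughness
#' penalty is chosen by generalized cross-validation (or fixed via
#' \code{spar}). For plotting only; slope tests always use the linear
#' regressions.
#'
#' @param year numeric x values (at least 5 distinct).
#' @param value numeric series.
#' @param spar optional fixed smoothing parameter (larger = smoother).
#' @return data.frame with \code{year} and \code{smoothed}.
#' @export
splineSmooth <- function(year, value, spar = NULL) {
  if (length(unique(year)) < 5)
    stop("smoothing error: need at least 5 distinct points")
  fit <- if (is.null(spar)) smooth.spline(year, value, cv = FALSE)
         else smooth.spline(year, value, spar = spar)
  data.frame(year = year, smoothed = predict(fit, year)$y)
}
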