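#' MCMC configuration for the S-MGS threshold model
#'
#' Chain sizes default to a desk-scale run (20,000 iterations, 5,000
#' burn-in, thinning 10); the national-scale schedule (500,000 / 100,000 /
#' 100) is available by argument. Priors are weakly informative: an
#' inverse-Wishart for the 2x2 sire-MGS covariance with \code{prior_df}
#' degrees of freedom and scale \code{prior_df * g0_start}, and a scaled
#' inverse-chi-square with \code{prior_df} and scale \code{hy_var_start}
#' for the herd-year variance. Start values play the role of the national-
#' evaluation initial values.
#'
#' @param n_iter total Gibbs iterations.
#' @param burn_in iterations discarded before retention.
#' @param thin retain every \code{thin}-th post-burn-in draw.
#' @param seed RNG seed (drives every draw; same seed, same chain).
#' @param g0_start 2x2 positive-definite start for (sire, MGS) covariance.
#' @param hy_var_start starting herd-year variance.
#' @param prior_df inverse-Wishart / inverse-chi-square degrees of freedom.
#' @param fixed_prior_var prior variance of each fixed-effect level (very
#'   diffuse; keeps the posterior proper under any incidence pattern).
#' @return classed list (\code{MCMCConfig}).
#' @export
mcmcConfig <- function(n_iter = 20000L, burn_in = 5000L, thin = 10L,
                       seed = 1L,
                       g0_start = matrix(c(0.02, 0.002, 0.002, 0.01), 2),
                       hy_var_start = 0.05, prior_df = 4,
                       fixed_prior_var = 1e6) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  g0_start <- as.matrix(g0_start)
  if (any(eigen(g0_start, symmetric = TRUE,
                only.values = TRUE)$values <= 0))
    stop("g0_start must be positive definite")
  cfg <- list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
              thin = as.integer(thin), seed = as.integer(seed),
              g0_start = g0_start, hy_var_start = hy_var_start,
              prior_df = prior_df,
              prior_scale_g0 = prior_df * g0_start,
              prior_scale_hy = hy_var_start,
              fixed_prior_var = fixed_prior_var)
  class(cfg) <- "MCMCConfig"
  cfg
}

# pool sparse birth years into 5-year blocks; years with at least minBulls
# bulls keep their own group
.birthYearGroups <- function(birthYears, minBulls = 5L) {
  tab <- table(birthYears)
  own <- as.integer(names(tab)[tab >= minBulls])
  ifelse(birthYears %in% own, as.character(birthYears),
         paste0(5L * (birthYears %/% 5L), "s"))
}

#' Build the design structure of the threshold model
#'
#' Maps every edited record to one level of each model term: intercept,
#' year-season (YS), parity-sex (PS, 3 parity classes x 2 sexes), sire and
#' MGS birth-year groups (sB, mB; single birth years, with sparse years
#' pooled into 5-year blocks), the two parity-sex-by-birth-year interactions
#' (sPSB, mPSB), the random herd-year (hy), and the sire/MGS bull indices
#' into the pedigree. Full-rank constraints: the first level of each
#' non-intercept fixed factor is clamped at 0, and interaction cells whose
#' parity-sex or birth-year margin is that factor's first level are clamped
#' to the margins' span; the liability threshold is fixed at 0 with the
#' intercept carried explicitly.
#'
#' @param dataset an \linkS4class{EditedCalvings}.
#' @param pedigree a \linkS4class{SireMgsPedigree} containing every sire and
#'   MGS referenced by the records.
#' @param yearGroupMinBulls pooling threshold for birth-year groups.
#' @return an \linkS4class{SmgsDesign}.
#' @export
buildDesign <- function(dataset, pedigree, yearGroupMinBulls = 5L) {
  r <- calvingRecords(dataset)
  if (!nrow(r)) stop("dataset is empty")
  e <- pedigreeEntries(pedigree)
  pos <- setNames(seq_len(nrow(e)), e$bull_id)
  sire <- pos[r$sire_id]
  mgs <- pos[r$mgs_id]
  if (anyNA(sire))
    stop("linkage error: record sire(s) absent from pedigree: ",
         paste(head(unique(r$sire_id[is.na(sire)])), collapse = ", "))
  if (anyNA(mgs))
    stop("linkage error: record MGS absent from pedigree: ",
         paste(head(unique(r$mgs_id[is.na(mgs)])), collapse = ", "))

  bullGroup <- .birthYearGroups(e$birth_year, yearGroupMinBulls)
  ps <- paste0("p", r$parity_class, r$calf_sex)
  sB <- bullGroup[sire]
  mB <- bullGroup[mgs]
  sPSB <- paste(ps, sB, sep = "|")
  mPSB <- paste(ps, mB, sep = "|")

  mkFactor <- function(x) {
    lev <- sort(unique(x))
    list(idx = match(x, lev), lev = lev)
  }
  fYS <- mkFactor(r$year_season)
  fPS <- mkFactor(ps)
  fsB <- mkFactor(sB)
  fmB <- mkFactor(mB)
  fsP <- mkFactor(sPSB)
  fmP <- mkFactor(mPSB)
  fhy <- mkFactor(r$herd_year)

  dropFirst <- function(f) c(FALSE, rep(TRUE, length(f$lev) - 1L))
  dropMargins <- function(f, psFirst, bFirst) {
    parts <- strsplit(f$lev, "|", fixed = TRUE)
    !(vapply(parts, `[`, "", 1L) == psFirst |
      vapply(parts, `[`, "", 2L) == bFirst)
  }

  factorIndex <- list(intercept = rep(1L, nrow(r)), YS = fYS$idx,
                      PS = fPS$idx, sB = fsB$idx, mB = fmB$idx,
                      sPSB = fsP$idx, mPSB = fmP$idx, hy = fhy$idx)
  factorLevels <- list(intercept = "(Intercept)", YS = fYS$lev,
                       PS = fPS$lev, sB = fsB$lev, mB = fmB$lev,
                       sPSB = fsP$lev, mPSB = fmP$lev, hy = fhy$lev)
  estimable <- list(intercept = TRUE, YS = dropFirst(fYS),
                    PS = dropFirst(fPS), sB = dropFirst(fsB),
                    mB = dropFirst(fmB),
                    sPSB = dropMargins(fsP, fPS$lev[1], fsB$lev[1]),
                    mPSB = dropMargins(fmP, fPS$lev[1], fmB$lev[1]),
                    hy = rep(TRUE, length(fhy$lev)))
  estimable <- .dropRankDeficient(factorIndex, factorLevels, estimable,
                                  skip = "hy")

  new("SmgsDesign", y = as.integer(r$sb), factorIndex = factorIndex,
      factorLevels = factorLevels, estimable = estimable, hyFactor = "hy",
      sire = unname(sire), mgs = unname(mgs), pedigree = pedigree,
      bullSBLevel = match(bullGroup, fsB$lev),
      bullMBLevel = match(bullGroup, fmB$lev))
}

# margin drops leave residual aliasing when interaction cells are sparsely
# populated (a parity-sex level seen with only one birth-year group, say);
# detect redundant fixed-effect columns by pivoted QR of the incidence
# cross-product and clamp them too
.dropRankDeficient <- function(factorIndex, factorLevels, estimable, skip) {
  n <- length(factorIndex[[1]])
  cols <- list()
  key <- list()
  for (f in names(factorIndex)) {
    if (f %in% skip) next
    for (j in which(estimable[[f]])) {
      cols[[length(cols) + 1L]] <-
        Matrix::sparseVector(x = 1, i = which(factorIndex[[f]] == j),
                             length = n)
      key[[length(key) + 1L]] <- c(f, j)
    }
  }
  p <- length(cols)
  if (p < 2) return(estimable)
  X <- Matrix::sparseMatrix(
    i = unlist(lapply(cols, function(v) v@i)),
    j = rep(seq_len(p), vapply(cols, function(v) length(v@i), 1L)),
    x = 1, dims = c(n, p))
  XtX <- as.matrix(Matrix::crossprod(X))
  q <- qr(XtX, tol = 1e-9)
  if (q$rank < p) {
    for (k in q$pivot[seq.int(q$rank + 1L, p)]) {
      f <- key[[k]][1]
      estimable[[f]][as.integer(key[[k]][2])] <- FALSE
    }
  }
  estimable
}

# full (general) CSC arrays of the symmetric A-inverse
.ainvArrays <- function(ainverse) {
  m <- as(as(aInverseMatrix(ainverse), "generalMatrix"), "CsparseMatrix")
  list(p = m@p, i = m@i, x = m@x)
}

.effectTable <- function(design) {
  rows <- lapply(names(design@factorLevels), function(f)
    data.frame(factor = f, level = design@factorLevels[[f]]))
  bulls <- bullIds(design@pedigree)
  rows <- c(rows, list(data.frame(factor = "sire", level = bulls),
                       data.frame(factor = "mgs", level = bulls)))
  out <- do.call(rbind, rows)
  out$col <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fit the S-MGS threshold model by Gibbs sampling
#'
#' Data-augmented Gibbs sampling: each record's liability is drawn from a
#' unit-variance normal truncated at the (fixed, zero) threshold on the side
#' given by its stillbirth code; location effects are drawn single-site
#' from their full conditionals, with each bull's (sire, MGS) pair updated
#' jointly as a 2-vector to respect the G0 x A correlation; the herd-year
#' variance is drawn from its scaled inverse-chi-square full conditional and
#' the 2x2 sire-MGS covariance from its inverse-Wishart full conditional
#' using the bull-effect quadratic form with the A-inverse. The residual
#' variance is never updated (fixed at 1 for identification).
#'
#' @param design an \linkS4class{SmgsDesign}.
#' @param ainverse a \linkS4class{RelationshipInverse} over the design's
#'   pedigree.
#' @param config an \code{\link{mcmcConfig}}.
#' @return an \linkS4class{SmgsFit}.
#' @export
runGibbs <- function(design, ainverse, config = mcmcConfig()) {
  stopifnot(is(design, "SmgsDesign"), is(ainverse, "RelationshipInverse"),
            inherits(config, "MCMCConfig"))
  nb <- nBulls(design@pedigree)
  if (nrow(aInverseMatrix(ainverse)) != nb)
    stop("A-inverse dimension does not match the design's pedigree")
  arr <- .ainvArrays(ainverse)
  nf <- length(design@factorIndex)
  hyPos <- match(design@hyFactor, names(design@factorIndex))
  lambdaFix <- rep(1 / config$fixed_prior_var, nf)
  set.seed(config$seed)
  res <- gibbs_smgs_cpp(
    sb = design@y, yGauss = numeric(), augment = TRUE,
    fidx = unname(design@factorIndex),
    nlev = vapply(design@factorLevels, length, 1L),
    estim = unname(design@estimable), lambdaFix = lambdaFix,
    hyFactor = hyPos, sire = design@sire, mgs = design@mgs, nbull = nb,
    Ap = arr$p, Ai = arr$i, Ax = arr$x,
    g0Start = config$g0_start, hyVarStart = config$hy_var_start,
    nu0G = config$prior_df, V0 = config$prior_scale_g0,
    nu0hy = config$prior_df, S0hy = config$prior_scale_hy,
    niter = config$n_iter, burnin = config$burn_in, thin = config$thin,
    updateVar = TRUE, noise = TRUE)
  v <- as.data.frame(res$variances)
  names(v) <- c("sigma_s2", "sigma_mgs2", "sigma_s_mgs", "sigma_hy2")
  new("SmgsFit", variances = v, solutions = res$solutions,
      effectTable = .effectTable(design), design = design,
      ainverse = ainverse, config = unclass(config))
}

#' Deterministic mixed-model-equation solve by Gauss-Seidel sweeps
#'
#' Runs the sampler's update sweeps with the stochastic terms switched off
#' and the liabilities fixed at a supplied working response, so that the
#' iterates converge to the solution of the mixed-model equations at the
#' given variance components. Used to verify that the sampler's full
#' conditionals are centred on the correct system, and handy as a cheap
#' BLUP solver.
#'
#' @param design an \linkS4class{SmgsDesign}.
#' @param ainverse matching \linkS4class{RelationshipInverse}.
#' @param liabilities numeric working response per record.
#' @param g0 2x2 sire-MGS covariance to condition on.
#' @param hyVar herd-year variance to condition on.
#' @param nSweeps Gauss-Seidel sweeps.
#' @param fixedPriorVar diffuse prior variance on fixed-effect levels.
#' @return named numeric vector of solutions (factor:level names).
#' @export
solveLocations <- function(design, ainverse, liabilities, g0, hyVar,
                           nSweeps = 500L, fixedPriorVar = 1e6) {
  stopifnot(length(liabilities) == length(design@y))
  nb <- nBulls(design@pedigree)
  arr <- .ainvArrays(ainverse)
  nf <- length(design@factorIndex)
  hyPos <- match(design@hyFactor, names(design@factorIndex))
  res <- gibbs_smgs_cpp(
    sb = integer(), yGauss = as.numeric(liabilities), augment = FALSE,
    fidx = unname(design@factorIndex),
    nlev = vapply(design@factorLevels, length, 1L),
    estim = unname(design@estimable),
    lambdaFix = rep(1 / fixedPriorVar, nf),
    hyFactor = hyPos, sire = design@sire, mgs = design@mgs, nbull = nb,
    Ap = arr$p, Ai = arr$i, Ax = arr$x,
    g0Start = as.matrix(g0), hyVarStart = hyVar,
    nu0G = 4, V0 = as.matrix(g0), nu0hy = 4, S0hy = hyVar,
    niter = as.integer(nSweeps), burnin = as.integer(nSweeps) - 1L,
    thin = 1L, updateVar = FALSE, noise = FALSE)
  et <- .effectTable(design)
  setNames(as.numeric(res$finalSolution), paste(et$factor, et$level,
                                                sep = ":"))
}

#' Draws from the truncated unit-variance liability distribution
#'
#' The elementary data-augmentation draw of the sampler, exposed for
#' verification: a normal with the given mean and variance 1 truncated to
#' (0, Inf) where \code{positive} is TRUE and to (-Inf, 0] otherwise.
#'
#' @param eta numeric vector of means.
#' @param positive logical vector (recycled) selecting the truncation side.
#' @return numeric vector of draws, one per element of \code{eta}.
#' @export
truncLiabilityDraws <- function(eta, positive) {
  positive <- rep_len(as.logical(positive), length(eta))
  trunc_liability_cpp(as.numeric(eta), positive)
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first \code{firstFrac} of a chain with the mean
#' of the last \code{lastFrac} using spectral-density variance estimates,
#' returning the standard z score.
#'
#' @param chain numeric vector of draws (length >= 50).
#' @param firstFrac,lastFrac window fractions (defaults 0.1 and 0.5).
#' @return z score.
#' @export
gewekeZ <- function(chain, firstFrac = 0.1, lastFrac = 0.5) {
  if (length(chain) < 50) stop("diagnostic error: chain shorter than 50")
  if (sd(chain) == 0) stop("diagnostic error: zero-variance chain")
  unname(coda::geweke.diag(coda::mcmc(chain), frac1 = firstFrac,
                           frac2 = lastFrac)$z)
}

#' Convergence diagnostics for every variance component of a fit
#'
#' @param fit an \linkS4class{SmgsFit}.
#' @return data.frame with parameter, Geweke z and effective sample size.
#' @export
mcmcDiagnostics <- function(fit) {
  v <- varianceSamples(fit)
  data.frame(parameter = names(v),
             geweke_z = vapply(v, gewekeZ, 1.0),
             ess = vapply(v, function(x)
               unname(coda::effectiveSize(coda::mcmc(x))), 1.0),
             row.names = NULL)
}
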