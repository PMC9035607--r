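#' Simulation configuration for synthetic calving data
#'
#' Defines the generative model behind the synthetic records: correlated
#' sire and maternal-grandsire (MGS) genetic effects drawn down a bull
#' pedigree with covariance \code{g0_true} per the additive relationship
#' rules, normal herd-year effects, fixed liability shifts per year-season
#' and parity-sex cell, a unit residual, and a single liability threshold.
#' The residual variance is identically 1 and is not configurable: with a
#' binary outcome and one threshold, the liability scale is only identified
#' up to the residual standard deviation.
#'
#' Defaults emulate a mid-size US Jersey-like population: the parity mix and
#' the parity-specific probability of a female calf (skewed towards heifer
#' females by sexed-semen use) follow national parity-sex record
#' distributions, and \code{g0_true} uses liability-scale sire/MGS
#' (co)variances typical of stillbirth.
#'
#' @param n_sires,n_mgs number of bulls serving as service sires and as MGS.
#' @param allow_overlap may a bull appear in both roles (identifies the
#'   sire-MGS covariance); \code{overlap_fraction} of the smaller pool is
#'   shared when TRUE.
#' @param overlap_fraction fraction of min(n_sires, n_mgs) used in both roles.
#' @param n_herds number of herds.
#' @param years inclusive calving-year range.
#' @param mean_records_per_herd_year Poisson mean of records per herd-year.
#' @param parity_distribution probabilities of parity classes 1, 2, 3+.
#' @param sex_ratio_by_parity probability of a female calf per parity class.
#' @param g0_true 2x2 matrix (sire variance, sire-MGS covariance; covariance,
#'   MGS variance) on the underlying scale.
#' @param herd_year_variance underlying-scale herd-year variance.
#' @param threshold liability cutpoint T; default places the marginal
#'   stillbirth incidence near \code{target_incidence}.
#' @param target_incidence used only to derive the default threshold.
#' @param fixed_effects_true list with \code{year_season} (named liability
#'   shifts, default none) and \code{parity_sex} (length-6 vector over
#'   parity class x sex cells p1M, p1F, p2M, p2F, p3M, p3F).
#' @param pedigree_depth generations of bull ancestry above the active bulls.
#' @param sire_birth_years,mgs_birth_years,overlap_birth_years birth-year
#'   pools for sire-only, MGS-only and dual-role bulls.
#' @param prob_unknown_mgs fraction of records whose MGS id is masked as
#'   unknown (the true MGS effect still enters the liability).
#' @param prob_crossbred fraction of records given a non-matching dam breed.
#' @param prob_die48h fraction of stillbirths recorded as score 3
#'   (died within 48 h) rather than 2 (born dead).
#' @param prob_old_dam fraction of records given an out-of-window dam birth
#'   year, to exercise the extraction-window edit.
#' @param seed RNG seed.
#' @return a classed list of validated settings (\code{SimulationConfig}).
#' @export
simConfig <- function(n_sires = 300L, n_mgs = 300L, allow_overlap = TRUE,
                      overlap_fraction = 0.4, n_herds = 140L,
                      years = 2010:2018, mean_records_per_herd_year = 20,
                      parity_distribution = c(0.366, 0.265, 0.369),
                      sex_ratio_by_parity = c(0.75, 0.64, 0.59),
                      g0_true = matrix(c(0.016, 0.005, 0.005, 0.014), 2),
                      herd_year_variance = 0.05,
                      threshold = NULL, target_incidence = 0.05,
                      fixed_effects_true = list(
                        year_season = numeric(),
                        parity_sex = c(p1M = 0.10, p1F = 0.05, p2M = -0.03,
                                       p2F = -0.06, p3M = -0.02, p3F = -0.04)),
                      pedigree_depth = 2L,
                      sire_birth_years = 2008:2016,
                      mgs_birth_years = 2002:2010,
                      overlap_birth_years = 2006:2012,
                      prob_unknown_mgs = 0.03, prob_crossbred = 0.02,
                      prob_die48h = 0.3, prob_old_dam = 0.01, seed = 1L) {
  if (n_sires < 1L || n_mgs < 1L)
    stop("invalid config: n_sires and n_mgs must be >= 1")
  g0_true <- as.matrix(g0_true)
  if (!isTRUE(all.equal(g0_true, t(g0_true))) ||
      any(eigen(g0_true, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    stop("invalid config: g0_true must be symmetric positive semi-definite")
  if (herd_year_variance < 0)
    stop("invalid config: herd_year_variance must be >= 0")
  if (abs(sum(parity_distribution) - 1) > 1e-8 ||
      any(parity_distribution < 0))
    stop("invalid config: parity_distribution must be probabilities summing to 1")
  if (any(sex_ratio_by_parity < 0 | sex_ratio_by_parity > 1))
    stop("invalid config: sex ratios must be in [0, 1]")
  if (is.null(threshold))
    threshold <- qnorm(1 - target_incidence) *
      sqrt(1 + herd_year_variance + g0_true[1, 1] + g0_true[2, 2])
  cfg <- list(n_sires = as.integer(n_sires), n_mgs = as.integer(n_mgs),
              allow_overlap = allow_overlap,
              overlap_fraction = overlap_fraction,
              n_herds = as.integer(n_herds), years = as.integer(years),
              mean_records_per_herd_year = mean_records_per_herd_year,
              parity_distribution = parity_distribution,
              sex_ratio_by_parity = sex_ratio_by_parity,
              g0_true = g0_true, herd_year_variance = herd_year_variance,
              threshold = threshold,
              fixed_effects_true = fixed_effects_true,
              pedigree_depth = as.integer(pedigree_depth),
              sire_birth_years = as.integer(sire_birth_years),
              mgs_birth_years = as.integer(mgs_birth_years),
              overlap_birth_years = as.integer(overlap_birth_years),
              prob_unknown_mgs = prob_unknown_mgs,
              prob_crossbred = prob_crossbred,
              prob_die48h = prob_die48h, prob_old_dam = prob_old_dam,
              seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

# square root of a PSD 2x2 (eigen-based; tolerates zero matrices)
.sqrtPSD <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(m)) %*% t(e$vectors)
}

#' Generate a bull pedigree
#'
#' Builds \code{pedigree_depth} ancestor generations above the active sire
#' and MGS pools. Founders (the oldest generation) have unknown parents;
#' every other bull's sire and MGS are sampled from the generation above
#' with probability 0.8 of being known. Birth years of active bulls are
#' drawn from the role-specific pools so that the default genetic-base
#' windows (sires 2011-2015, MGS 2006-2010) are populated.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \linkS4class{SireMgsPedigree} with role labels.
#' @export
generatePedigree <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  nOver <- if (config$allow_overlap)
    as.integer(round(config$overlap_fraction *
                     min(config$n_sires, config$n_mgs))) else 0L
  nS <- config$n_sires - nOver
  nM <- config$n_mgs - nOver
  roles <- c(rep("mgs", nM), rep("both", nOver), rep("sire", nS))
  years <- c(sample(config$mgs_birth_years, nM, replace = TRUE),
             sample(config$overlap_birth_years, nOver, replace = TRUE),
             sample(config$sire_birth_years, nS, replace = TRUE))
  nActive <- length(roles)

  gens <- list()
  depth <- config$pedigree_depth
  if (depth > 0) {
    for (g in seq_len(depth)) {
      ng <- max(2L, ceiling(nActive / 2^g))
      gens[[g]] <- list(n = ng,
                        years = sample(min(config$mgs_birth_years) - 6L * g +
                                       (-2:2), ng, replace = TRUE))
    }
  }

  id <- function(prefix, i) sprintf("%s%04d", prefix, i)
  rows <- list()
  # oldest generation first so the ordering is topological
  for (g in rev(seq_len(depth))) {
    up <- if (g < depth) sapply(seq_len(gens[[g + 1L]]$n),
                                function(i) id(sprintf("A%d_", g + 1L), i))
          else character()
    for (i in seq_len(gens[[g]]$n)) {
      sire <- mgsb <- UNKNOWN_ID
      if (length(up)) {
        if (runif(1) < 0.8) sire <- sample(up, 1)
        if (runif(1) < 0.8) mgsb <- sample(up, 1)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(bull_id = id(sprintf("A%d_", g), i), sire_id = sire,
                   mgs_id = mgsb, birth_year = gens[[g]]$years[i],
                   role = "ancestor")
    }
  }
  up <- if (depth > 0) sapply(seq_len(gens[[1L]]$n),
                              function(i) id("A1_", i)) else character()
  ordA <- order(years)   # older active bulls first
  for (k in seq_len(nActive)) {
    i <- ordA[k]
    sire <- mgsb <- UNKNOWN_ID
    if (length(up)) {
      if (runif(1) < 0.8) sire <- sample(up, 1)
      if (runif(1) < 0.8) mgsb <- sample(up, 1)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(bull_id = id("B", i), sire_id = sire, mgs_id = mgsb,
                 birth_year = years[i], role = roles[i])
  }
  e <- do.call(rbind, rows)
  SireMgsPedigree(e[, 1:4], roles = e$role)
}

# draw (s, m) pairs down the pedigree: founders ~ N(0, G0); descendants by
# u = 1/2 u_sire + 1/4 u_mgs + phi with Mendelian-sampling variance d * G0,
# d = 11/16, 3/4, 15/16 or 1 as sire/MGS are known -- the exact inverse of
# the A-inverse rules used by the estimator.
.simulateBullEffects <- function(pedigree, g0) {
  e <- pedigree@entries
  n <- nrow(e)
  u <- matrix(0, n, 2)
  pos <- setNames(seq_len(n), e$bull_id)
  root <- .sqrtPSD(g0)
  for (i in seq_len(n)) {
    sKnown <- !.isUnknownId(e$sire_id[i])
    mKnown <- !.isUnknownId(e$mgs_id[i])
    mu <- c(0, 0)
    d <- 1
    if (sKnown) mu <- mu + 0.5 * u[pos[e$sire_id[i]], ]
    if (mKnown) mu <- mu + 0.25 * u[pos[e$mgs_id[i]], ]
    if (sKnown && mKnown) d <- 11 / 16
    else if (sKnown) d <- 3 / 4
    else if (mKnown) d <- 15 / 16
    u[i, ] <- mu + sqrt(d) * as.vector(root %*% rnorm(2))
  }
  u
}

#' Simulate calving records from the threshold-liability model
#'
#' Each record's latent liability is the sum of a year-season shift, a
#' parity-sex shift, a herd-year effect, the service sire's direct effect,
#' the MGS's maternal effect and a standard-normal residual. Livability is
#' scored 2 (born dead) when the liability exceeds the threshold, with a
#' configurable fraction relabelled 3 (died within 48 h); calving ease is a
#' monotone 5-bin discretization of the same liability. A fraction of MGS
#' ids is masked as unknown and a fraction of dam breeds set to a different
#' code so that the edit rules have work to do.
#'
#' @param config a \code{\link{simConfig}}.
#' @param pedigree a \linkS4class{SireMgsPedigree} from
#'   \code{\link{generatePedigree}} (role labels required).
#' @return list with \code{records} (data.frame in the record-file dialect)
#'   and \code{truth} (list of \code{bulls}, \code{herd_years},
#'   \code{records} component tables; liabilities re-add exactly from their
#'   components).
#' @export
simulateCalvingRecords <- function(config, pedigree) {
  stopifnot(inherits(config, "SimulationConfig"),
            is(pedigree, "SireMgsPedigree"))
  if (!length(pedigree@roles))
    stop("pedigree must carry role labels (use generatePedigree)")
  g0 <- config$g0_true
  if (any(eigen(g0, symmetric = TRUE, only.values = TRUE)$values < -1e-12))
    stop("invalid config: g0_true must be positive semi-definite")
  set.seed(config$seed + 1L)

  e <- pedigree@entries
  u <- .simulateBullEffects(pedigree, g0)
  sirePool <- which(pedigree@roles %in% c("sire", "both"))
  mgsPool <- which(pedigree@roles %in% c("mgs", "both"))
  if (!length(sirePool) || !length(mgsPool))
    stop("pedigree has no active sire or MGS pool")

  hySd <- sqrt(config$herd_year_variance)
  ysShift <- config$fixed_effects_true$year_season
  psShift <- config$fixed_effects_true$parity_sex
  psName <- function(p, s) paste0("p", p, s)

  out <- vector("list", config$n_herds * length(config$years))
  hyRows <- out
  k <- 0L
  calf <- 0L
  for (h in seq_len(config$n_herds)) {
    for (y in config$years) {
      nr <- rpois(1, config$mean_records_per_herd_year)
      hy <- rnorm(1, 0, hySd)
      k <- k + 1L
      hyRows[[k]] <- data.frame(herd_id = sprintf("H%03d", h),
                                calving_year = y, hy_effect = hy)
      if (nr == 0) next
      par <- sample(1:3, nr, replace = TRUE,
                    prob = config$parity_distribution)
      sex <- ifelse(runif(nr) < config$sex_ratio_by_parity[par], "F", "M")
      si <- sample(sirePool, nr, replace = TRUE)
      mi <- sample(mgsPool, nr, replace = TRUE)
      month <- sample(1:12, nr, replace = TRUE)
      ysLab <- assignYearSeason(rep(y, nr), month)
      ys <- ifelse(ysLab %in% names(ysShift), ysShift[ysLab], 0)
      ps <- psShift[psName(par, sex)]
      res <- rnorm(nr)
      liab <- ys + ps + hy + u[si, 1] + u[mi, 2] + res
      sb2 <- liab > config$threshold
      liv <- ifelse(sb2, ifelse(runif(nr) < config$prob_die48h, 3L, 2L), 1L)
      cuts <- config$threshold + c(-1.5, -0.75, -0.25, 0.5)
      ce <- findInterval(liab, cuts) + 1L
      parityRaw <- ifelse(par == 3L, par + sample(0:2, nr, replace = TRUE),
                          par)
      damBirth <- ifelse(runif(nr) < config$prob_old_dam, 1990L,
                         y - parityRaw - 1L)
      mgsId <- ifelse(runif(nr) < config$prob_unknown_mgs, UNKNOWN_ID,
                      e$bull_id[mi])
      damBreed <- ifelse(runif(nr) < config$prob_crossbred, "HO", "JE")
      ids <- sprintf("C%06d", calf + seq_len(nr))
      calf <- calf + nr
      out[[k]] <- data.frame(
        calf_id = ids, sire_id = e$bull_id[si],
        dam_id = sprintf("D%06d", seq_len(nr) + calf), mgs_id = mgsId,
        herd_id = sprintf("H%03d", h), calving_year = y,
        calving_month = month, parity = parityRaw, calf_sex = sex,
        ce_score = ce, livability = liv, sire_breed = "JE",
        dam_breed = damBreed, dam_birth_year = damBirth,
        ys_effect = ys, ps_effect = ps, hy_effect = hy,
        sire_effect = u[si, 1], mgs_effect = u[mi, 2], residual = res,
        liability = liab, true_mgs_id = e$bull_id[mi])
    }
  }
  rec <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(rec) <- NULL
  truthCols <- c("calf_id", "ys_effect", "ps_effect", "hy_effect",
                 "sire_effect", "mgs_effect", "residual", "liability",
                 "true_mgs_id")
  truth <- list(
    bulls = data.frame(bull_id = e$bull_id, birth_year = e$birth_year,
                       role = pedigree@roles, s_effect = u[, 1],
                       m_effect = u[, 2]),
    herd_years = do.call(rbind, hyRows[seq_len(k)]),
    records = rec[, truthCols])
  list(records = rec[, setdiff(names(rec), setdiff(truthCols, "calf_id"))],
       truth = truth)
}

#' Write a simulated dataset as delimited-text fixture files
#'
#' Writes \code{records.csv}, \code{pedigree.csv} and three truth files
#' (\code{truth_bulls.csv}, \code{truth_herd_years.csv},
#' \code{truth_records.csv}) to \code{dir}. Unknown ancestors are encoded as
#' the literal \code{0}. The files round-trip losslessly through
#' \code{\link{readCalvingRecords}}, \code{\link{readPedigree}} and
#' \code{\link{readTruth}}.
#'
#' @param records record data.frame from \code{\link{simulateCalvingRecords}}.
#' @param pedigree a \linkS4class{SireMgsPedigree}.
#' @param truth truth list from \code{\link{simulateCalvingRecords}}, or NULL.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeFixture <- function(records, pedigree, truth = NULL, dir) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir)
  paths <- c(records = file.path(dir, "records.csv"),
             pedigree = file.path(dir, "pedigree.csv"))
  write.csv(records, paths["records"], row.names = FALSE, quote = FALSE)
  write.csv(pedigreeEntries(pedigree), paths["pedigree"], row.names = FALSE,
            quote = FALSE)
  if (!is.null(truth)) {
    paths <- c(paths, truth_bulls = file.path(dir, "truth_bulls.csv"),
               truth_herd_years = file.path(dir, "truth_herd_years.csv"),
               truth_records = file.path(dir, "truth_records.csv"))
    write.csv(truth$bulls, paths["truth_bulls"], row.names = FALSE,
              quote = FALSE)
    write.csv(truth$herd_years, paths["truth_herd_years"],
              row.names = FALSE, quote = FALSE)
    write.csv(truth$records, paths["truth_records"], row.names = FALSE,
              quote = FALSE)
  }
  invisible(paths)
}
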