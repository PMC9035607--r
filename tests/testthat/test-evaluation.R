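# builds a minimal fitted object with hand-set posterior solutions so the
# PTA arithmetic can be checked against hand sums
makeToyFit <- function(sireSol = c(S1 = 0.2, S2 = -0.1),
                       mgsSol = c(G1 = 0.05, G2 = 0), sBSol = 0.1,
                       mBSol = 0.02) {
  r <- rbind(makeRecords(n = 4, sire = c("S1", "S1", "S2", "S2"),
                         mgs = c("G1", "G2", "G1", "G2"),
                         livability = c(2, 1, 1, 1)),
             makeRecords(n = 2, sire = "S1", mgs = "G1", livability = 1))
  ped <- SireMgsPedigree(data.frame(
    bull_id = c("G1", "G2", "S1", "S2"), sire_id = "0", mgs_id = "0",
    birth_year = c(2007, 2008, 2012, 2013)))
  des <- buildDesign(applyEdits(r), ped, yearGroupMinBulls = 5L)
  et <- stillbirthSMGS:::.effectTable(des)
  sol <- matrix(0, 120, nrow(et))
  put <- function(fac, lev, val) {
    sol[, et$factor == fac & et$level == lev] <<- val
  }
  put("sire", "S1", sireSol["S1"]); put("sire", "S2", sireSol["S2"])
  put("mgs", "G1", mgsSol["G1"]); put("mgs", "G2", mgsSol["G2"])
  for (lev in des@factorLevels$sB) put("sB", lev, sBSol)
  for (lev in des@factorLevels$mB) put("mB", lev, mBSol)
  v <- data.frame(sigma_s2 = rep(0.016, 120), sigma_mgs2 = 0.014,
                  sigma_s_mgs = 0.005, sigma_hy2 = 0.05)
  cfg <- unclass(mcmcConfig(n_iter = 240, burn_in = 0, thin = 2))
  new("SmgsFit", variances = v, solutions = sol, effectTable = et,
      design = des, ainverse = buildAInverse(ped), config = cfg)
}

test_that("underlying solutions add the birth-year group to the bull solution", {
  fit <- makeToyFit()
  eps <- underlyingSolutions(fit, "sire")
  expect_equal(eps$epsilon[eps$bull_id == "S1"], 0.2 + 0.1)
  expect_equal(eps$epsilon[eps$bull_id == "S2"], -0.1 + 0.1)
  epm <- underlyingSolutions(fit, "mgs")
  expect_equal(epm$epsilon[epm$bull_id == "G1"], 0.05 + 0.02)
  # zero group solution leaves the random solution untouched
  fit0 <- makeToyFit(sBSol = 0)
  eps0 <- underlyingSolutions(fit0, "sire")
  expect_equal(eps0$epsilon[eps0$bull_id == "S1"], 0.2)
  # a common group shift cancels in differences
  d1 <- diff(eps$epsilon[eps$bull_id %in% c("S1", "S2")])
  d0 <- diff(eps0$epsilon[eps0$bull_id %in% c("S1", "S2")])
  expect_equal(d1, d0)
})

test_that("observed-scale conversion anchors the base exactly", {
  # single base bull with epsilon = epsilon*: PTA equals the base rate
  eps <- data.frame(bull_id = "S1", birth_year = 2012, epsilon = 0.37,
                    n_records = 10)
  pta <- observedScalePTA(eps, c(2011, 2015), basePct = 5)
  expect_equal(pta$pta_pct, 5)
  # closed-form case: 0.1 above the base mean at a 5% base
  single <- observedScalePTA(
    data.frame(bull_id = c("base", "x"), birth_year = c(2012, 1999),
               epsilon = c(0, 0.1), n_records = 5), c(2011, 2015), 5)
  expect_equal(single$pta_pct[1], 5)
  expect_equal(single$pta_pct[2], 100 * (1 - pnorm(qnorm(0.95) - 0.1)))
  expect_equal(round(single$pta_pct[2], 2), 6.12)
})

test_that("the base-mean bull reproduces the base rate within 0.01 points", {
  # the anchoring averages on the liability scale (inside the distribution
  # function), so the bull sitting at the base-mean epsilon must convert to
  # exactly the base percentage
  set.seed(20)
  eps <- data.frame(bull_id = sprintf("B%02d", 1:40),
                    birth_year = rep(2011:2015, 8),
                    epsilon = rnorm(40, 0, 0.1), n_records = 5)
  probe <- rbind(eps, data.frame(bull_id = "MEAN", birth_year = 1990,
                                 epsilon = mean(eps$epsilon), n_records = 0))
  for (basePct in c(2, 5, 11)) {
    pta <- observedScalePTA(probe, c(2011, 2015), basePct)
    expect_lt(abs(pta$pta_pct[pta$bull_id == "MEAN"] - basePct), 0.01)
  }
})

test_that("observed-scale PTA is strictly increasing and shift-invariant", {
  eps <- data.frame(bull_id = sprintf("B%02d", 1:30),
                    birth_year = rep(2011:2015, 6),
                    epsilon = seq(-0.4, 0.4, length.out = 30), n_records = 5)
  pta <- observedScalePTA(eps, c(2011, 2015), 5)
  expect_true(all(diff(pta$pta_pct) > 0))
  expect_true(all(pta$pta_pct > 0 & pta$pta_pct < 100))
  shifted <- eps
  shifted$epsilon <- eps$epsilon + 0.7
  pta2 <- observedScalePTA(shifted, c(2011, 2015), 5)
  expect_equal(pta$pta_pct, pta2$pta_pct, tolerance = 1e-12)
  # extreme merit drives PTA towards the boundary
  lowmerit <- eps
  lowmerit$epsilon[1] <- -30
  expect_lt(observedScalePTA(lowmerit, c(2011, 2015), 5)$pta_pct[1], 1e-12)
})

test_that("conversion fails loudly on impossible bases", {
  eps <- data.frame(bull_id = "B1", birth_year = 2012, epsilon = 0,
                    n_records = 1)
  expect_error(observedScalePTA(eps, c(2011, 2015), 0), "infinite-threshold")
  expect_error(observedScalePTA(eps, c(2011, 2015), 100),
               "infinite-threshold")
  expect_error(observedScalePTA(eps, c(1990, 1995), 5), "base window")
})

test_that("reliabilities follow the diagonal formula and its limits", {
  expect_equal(reliabilityApprox(1 / 0.02, 0.02), 0)
  expect_equal(reliabilityApprox(1e12, 0.02), 1, tolerance = 1e-9)
  expect_equal(reliabilityApprox(c(60, 110), 0.02),
               1 - (1 / c(60, 110)) / 0.02)
  expect_error(reliabilityApprox(-1, 0.02), "invalid input")
  expect_error(reliabilityApprox(10, 0), "invalid input")
  # a bull with no information floors at zero rather than going negative
  expect_equal(reliabilityApprox(1 / 0.02 * 0.5, 0.02), 0)
})

test_that("diagonal reliabilities match the dense PEV oracle without relationships", {
  # relationship-free toy: founders only, sire effects only (MGS pool
  # disjoint), one fixed mean absorbed by a huge record class
  sigma_a2 <- 0.05
  nprog <- c(2, 5, 10, 40, 100)
  ped <- SireMgsPedigree(data.frame(
    bull_id = c(sprintf("S%d", 1:5), "G1"), sire_id = "0", mgs_id = "0",
    birth_year = c(rep(2012, 5), 2005)))
  recs <- do.call(rbind, lapply(1:5, function(i)
    makeRecords(n = nprog[i], sire = sprintf("S%d", i), mgs = "G1",
                livability = c(2, rep(1, nprog[i] - 1)))))
  des <- buildDesign(applyEdits(recs, minGroupSize = 1), ped)
  g0 <- diag(c(sigma_a2, sigma_a2))
  # dense MME: prediction-error variance = inverse diagonal of the full C
  liab <- rnorm(length(des@y))
  oracle <- denseMME(des, buildAInverse(ped), liab, g0, hyVar = 1e6)
  Cinv <- solve(oracle$C[oracle$estimable, oracle$estimable])
  et <- stillbirthSMGS:::.effectTable(des)[oracle$estimable, ]
  sIdx <- which(et$factor == "sire" & et$level %in% sprintf("S%d", 1:5))
  pev <- diag(Cinv)[sIdx]
  relExact <- 1 - pev / sigma_a2
  d <- nprog + 1 / sigma_a2   # diagonal of each sire equation
  relApprox <- reliabilityApprox(d, sigma_a2)
  # the diagonal shortcut can only inflate: fixed-effect absorption makes
  # the exact prediction-error variance larger than the diagonal suggests
  expect_true(all(relApprox >= relExact - 1e-12))
  # more progeny, more reliability
  expect_true(all(diff(relApprox) > 0))
})

test_that("mmeDiagonals combines record counts with the A-inverse diagonal", {
  fit <- makeToyFit()
  g0 <- matrix(c(0.016, 0.005, 0.005, 0.014), 2)
  d <- mmeDiagonals(fit, "sire", g0)
  g0inv <- solve(g0)
  expect_equal(unname(d["S1"]), 4 + g0inv[1, 1])   # founder: a^ii = 1
  expect_equal(unname(d["S2"]), 2 + g0inv[1, 1])
  dm <- mmeDiagonals(fit, "mgs", g0)
  expect_equal(unname(dm["G2"]), 2 + g0inv[2, 2])
})

test_that("linear trends recover exact lines and flag flat series", {
  years <- 2000:2010
  tr <- stillbirthSMGS:::.linearTrend(years, rep(4.2, 11))
  expect_equal(tr$slope, 0)
  expect_equal(tr$p_value, 1)
  tr2 <- stillbirthSMGS:::.linearTrend(years, 2 - 0.1 * (years - 2000))
  expect_equal(tr2$slope, -0.1, tolerance = 1e-12)
  expect_equal(tr2$p_value, 0)
  expect_error(stillbirthSMGS:::.linearTrend(2000:2001, c(1, 2)),
               "at least 3 years")
})

test_that("genetic trends are exact on linear PTA and flat on constant PTA", {
  pta <- data.frame(birth_year = rep(2000:2008, each = 3),
                    pta_pct = rep(5, 27))
  expect_equal(geneticTrend(pta)$slope, 0)
  pta$pta_pct <- 3 + 0.25 * (pta$birth_year - 2000)
  tr <- geneticTrend(pta)
  expect_equal(tr$slope, 0.25, tolerance = 1e-12)
})

test_that("an injected phenotypic trend is recovered within sampling error", {
  # liability drifts with sire birth year through year-season shifts
  years <- 2008:2017
  shift <- setNames(rep(-0.03 * (years - min(years)), each = 2),
                    as.vector(outer(years, c("A", "B"),
                                    function(y, s) paste0(y, "-", s))))
  cfg <- simConfig(n_sires = 60, n_mgs = 60, n_herds = 60, years = years,
                   mean_records_per_herd_year = 15,
                   fixed_effects_true = list(year_season = shift,
                     parity_sex = c(p1M = 0, p1F = 0, p2M = 0, p2F = 0,
                                    p3M = 0, p3F = 0)),
                   seed = 90)
  ped <- generatePedigree(cfg)
  sim <- simulateCalvingRecords(cfg, ped)
  r <- sim$records
  yearly <- aggregate(cbind(pct = 100 * (r$livability > 1)),
                      by = list(year = r$calving_year), FUN = mean)
  tr <- stillbirthSMGS:::.linearTrend(yearly$year, yearly$pct)
  # -0.03 liability/yr near the 5% threshold is about -0.3 %SB/yr
  expect_lt(tr$slope, 0)
  expect_lt(tr$p_value, 0.05)
})

test_that("spline smoothing preserves lines, flattens noise, denoises signal", {
  years <- 2000:2019
  line <- 1 + 0.2 * (years - 2000)
  sm <- splineSmooth(years, line)
  expect_lt(max(abs(sm$smoothed - line)), 1e-6)
  set.seed(33)
  noise <- rnorm(20)
  heavy <- splineSmooth(years, noise, spar = 2)
  expect_lt(max(abs(heavy$smoothed - mean(noise))), 0.25)
  signal <- sin((years - 2000) / 3)
  obs <- signal + rnorm(20, 0, 0.25)
  sm2 <- splineSmooth(years, obs)
  expect_lt(mean((sm2$smoothed - signal)^2), mean((obs - signal)^2))
  expect_error(splineSmooth(2000:2003, rnorm(4)), "at least 5")
})
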