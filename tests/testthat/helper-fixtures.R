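# In-code fixtures shared across the suite.

# minimal raw record data.frame; defaults give one clean herd
makeRecords <- function(n = 6, herd = "H1", year = 2012, month = 6,
                        parity = 1, sex = "M", livability = 1,
                        ce = 1, sire = "S1", mgs = "G1",
                        sire_breed = "JE", dam_breed = "JE",
                        dam_birth_year = 2008) {
  data.frame(calf_id = sprintf("C%s_%03d", herd, seq_len(n)),
             sire_id = rep_len(sire, n), dam_id = sprintf("D%03d", seq_len(n)),
             mgs_id = rep_len(mgs, n), herd_id = rep_len(herd, n),
             calving_year = rep_len(year, n),
             calving_month = rep_len(month, n),
             parity = rep_len(parity, n), calf_sex = rep_len(sex, n),
             ce_score = rep_len(ce, n), livability = rep_len(livability, n),
             sire_breed = rep_len(sire_breed, n),
             dam_breed = rep_len(dam_breed, n),
             dam_birth_year = rep_len(dam_birth_year, n),
             stringsAsFactors = FALSE)
}

# random sire-MGS pedigree with founders first (always topological)
randomPedigree <- function(n, pFounder = 0.3, years = 2000:2016,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("B%04d", seq_len(n))
  sire <- mgs <- rep("0", n)
  for (i in seq_len(n)) {
    if (i > 1 && runif(1) > pFounder) {
      sire[i] <- ids[sample.int(i - 1L, 1)]
      if (runif(1) > 0.3) mgs[i] <- ids[sample.int(i - 1L, 1)]
    }
  }
  SireMgsPedigree(data.frame(bull_id = ids, sire_id = sire, mgs_id = mgs,
                             birth_year = sort(sample(years, n,
                                                      replace = TRUE))))
}

# small simulated dataset + design + A-inverse, reused by fit-level tests
smallSimulation <- function(seed = 42, n_sires = 80, n_mgs = 80,
                            n_herds = 50, years = 2010:2016,
                            mean_rec = 12, g0 = matrix(c(0.05, 0.015,
                                                         0.015, 0.04), 2),
                            hyvar = 0.05) {
  cfg <- simConfig(n_sires = n_sires, n_mgs = n_mgs, n_herds = n_herds,
                   years = years, mean_records_per_herd_year = mean_rec,
                   g0_true = g0, herd_year_variance = hyvar, seed = seed)
  ped <- generatePedigree(cfg)
  sim <- simulateCalvingRecords(cfg, ped)
  ed <- applyEdits(sim$records)
  list(cfg = cfg, ped = ped, sim = sim, edited = ed,
       design = buildDesign(ed, ped), ainv = buildAInverse(ped))
}

# dense mixed-model-equation system matching an SmgsDesign (test oracle)
denseMME <- function(design, ainv, liabilities, g0, hyVar,
                     fixedPriorVar = 1e6) {
  n <- length(design@y)
  nb <- nBulls(design@pedigree)
  blocks <- list()
  lambda <- numeric(0)
  for (f in names(design@factorIndex)) {
    nl <- length(design@factorLevels[[f]])
    X <- matrix(0, n, nl)
    X[cbind(seq_len(n), design@factorIndex[[f]])] <- 1
    blocks[[f]] <- X
    lam <- if (f == design@hyFactor) 1 / hyVar else 1 / fixedPriorVar
    lambda <- c(lambda, rep(lam, nl))
  }
  Zs <- matrix(0, n, nb); Zs[cbind(seq_len(n), design@sire)] <- 1
  Zm <- matrix(0, n, nb); Zm[cbind(seq_len(n), design@mgs)] <- 1
  W <- cbind(do.call(cbind, blocks), Zs, Zm)
  est <- c(unlist(design@estimable), rep(TRUE, 2 * nb))
  A <- as.matrix(aInverseMatrix(ainv))
  Gprec <- kronecker(solve(g0), A)   # (s-block, m-block) ordering
  C <- crossprod(W) + diag(c(lambda, rep(0, 2 * nb)))
  C[(length(lambda) + 1):nrow(C), (length(lambda) + 1):ncol(C)] <-
    C[(length(lambda) + 1):nrow(C), (length(lambda) + 1):ncol(C)] + Gprec
  rhs <- crossprod(W, liabilities)
  # clamp non-estimable equations at zero
  sol <- rep(0, ncol(W))
  sol[est] <- solve(C[est, est], rhs[est])
  list(solution = sol, C = C, estimable = est)
}
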