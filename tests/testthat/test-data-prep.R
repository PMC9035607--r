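test_that("year-season labels follow the October/May anchors", {
  expect_equal(assignYearSeason(2010, 5), "2010-A")
  expect_equal(assignYearSeason(2010, 9), "2010-A")
  expect_equal(assignYearSeason(2010, 10), "2010-B")
  expect_equal(assignYearSeason(2010, 12), "2010-B")
  # the October season spans the year boundary
  expect_equal(assignYearSeason(2011, 2), "2010-B")
  expect_equal(assignYearSeason(2011, 4), "2010-B")
  expect_error(assignYearSeason(2010, 13), "invalid input")
  expect_error(assignYearSeason(2010, 0), "invalid input")
})

test_that("livability recoding keeps score-3 records as stillbirths", {
  r <- makeRecords(n = 6, livability = c(1, 1, 1, 1, 1, 3))
  ed <- applyEdits(r)
  expect_equal(nrow(calvingRecords(ed)), 6L)
  expect_equal(calvingRecords(ed)$sb, c(1L, 1L, 1L, 1L, 1L, 2L))
})

test_that("herds reporting only live calves are removed whole", {
  r <- rbind(makeRecords(n = 6, herd = "H1", livability = c(2, 1, 1, 1, 1, 1)),
             makeRecords(n = 5, herd = "H2", livability = 1))
  ed <- applyEdits(r)
  expect_equal(sort(unique(calvingRecords(ed)$herd_id)), "H1")
  expect_equal(unname(editLog(ed)["herd_without_stillbirth"]), 5L)
})

test_that("undersized herd-year contemporary groups are removed last", {
  # H3 has a stillbirth, 6 records in 2012 but only 4 in 2013: the 2013
  # group goes, the 2012 group stays
  r <- rbind(makeRecords(n = 6, herd = "H3", year = 2012,
                         livability = c(2, 1, 1, 1, 1, 1)),
             makeRecords(n = 4, herd = "H3", year = 2013, livability = 1))
  ed <- applyEdits(r)
  expect_equal(nrow(calvingRecords(ed)), 6L)
  expect_equal(unname(editLog(ed)["small_herd_year_group"]), 4L)
  expect_true(all(calvingRecords(ed)$calving_year == 2012))
})

test_that("dam-birth-year window and purebred filters run first", {
  r <- makeRecords(n = 7, livability = c(2, 1, 1, 1, 1, 1, 1))
  r$dam_birth_year[2] <- 1990
  r$dam_breed[3] <- "HO"
  ed <- applyEdits(r)
  lg <- editLog(ed)
  expect_equal(unname(lg["dam_birth_year_window"]), 1L)
  expect_equal(unname(lg["not_purebred"]), 1L)
  expect_equal(unname(lg["retained"]), 5L)
  expect_equal(sum(lg), nrow(r))
})

test_that("third and later parities collapse into class 3", {
  r <- makeRecords(n = 6, parity = c(1, 2, 3, 4, 7, 2),
                   livability = c(2, 1, 1, 1, 1, 1))
  ed <- applyEdits(r)
  expect_equal(calvingRecords(ed)$parity_class, c(1L, 2L, 3L, 3L, 3L, 2L))
})

test_that("records with unknown MGS are eliminated", {
  r <- makeRecords(n = 6, livability = c(2, 1, 1, 1, 1, 1))
  r$mgs_id[4] <- "0"
  ed <- applyEdits(r)
  expect_equal(unname(editLog(ed)["unknown_mgs"]), 1L)
  expect_false(any(calvingRecords(ed)$mgs_id == "0"))
})

test_that("editing is idempotent and its log is exhaustive", {
  sim <- smallSimulation(seed = 13, n_sires = 30, n_mgs = 30, n_herds = 12,
                         years = 2011:2014)
  ed1 <- applyEdits(sim$sim$records)
  r1 <- calvingRecords(ed1)
  ed2 <- applyEdits(r1[, names(sim$sim$records)])
  expect_equal(calvingRecords(ed2)[, names(r1)], r1)
  expect_equal(sum(editLog(ed1)), nrow(sim$sim$records))
})

test_that("edit post-conditions hold on randomized fixtures", {
  for (seed in c(101, 202, 303)) {
    sim <- smallSimulation(seed = seed, n_sires = 25, n_mgs = 25,
                           n_herds = 10, years = 2011:2014, mean_rec = 8)
    r <- calvingRecords(sim$edited)
    expect_true(all(tapply(r$sb == 2, r$herd_id, any)))
    expect_true(all(table(r$herd_year) >= 5))
    expect_false(any(r$mgs_id == "0"))
  }
})

test_that("parity-sex summary counts and percentages are exact", {
  # mirror of a published first-parity male cell: 379 records, 39 dead
  r <- makeRecords(n = 379, parity = 1, sex = "M",
                   livability = c(rep(2, 39), rep(1, 340)))
  ed <- applyEdits(r)
  tab <- summarizeByParitySex(ed)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n, 379L)
  expect_equal(round(tab$pct_sb, 2), 10.29)
})

test_that("single-record and all-alive cells behave at the boundaries", {
  r <- rbind(makeRecords(n = 1, herd = "H1", parity = 1, sex = "F",
                         livability = 2),
             makeRecords(n = 5, herd = "H1", parity = 2, sex = "M",
                         livability = 1))
  ed <- applyEdits(r, minGroupSize = 1)
  tab <- summarizeByParitySex(ed)
  expect_equal(tab$pct_sb[tab$parity_class == 1 & tab$calf_sex == "F"], 100)
  expect_equal(tab$pct_sb[tab$parity_class == 2 & tab$calf_sex == "M"], 0)
  expect_equal(nrow(tab), 2L)   # empty cells absent
})

test_that("the overall rate equals both weighted-cell and raw-count forms", {
  sim <- smallSimulation(seed = 77, n_sires = 30, n_mgs = 30, n_herds = 10,
                         years = 2011:2014)
  ed <- sim$edited
  tab <- summarizeByParitySex(ed)
  r <- calvingRecords(ed)
  expect_equal(overallStillbirthRate(tab), 100 * mean(r$sb == 2))
  expect_equal(overallStillbirthRate(tab[1, , drop = FALSE]), tab$pct_sb[1])
  expect_error(overallStillbirthRate(tab[0, ]), "empty")
})

test_that("stillbirth rises monotonically with calving-ease score", {
  sim <- smallSimulation(seed = 55, n_sires = 40, n_mgs = 40, n_herds = 30,
                         years = 2010:2016, mean_rec = 15)
  tab <- stillbirthByCalvingEase(sim$edited)
  expect_true(all(diff(tab$pct_sb) >= 0))
  expect_true(all(tab$ce_score %in% 1:5))
})

test_that("malformed record files raise parse errors naming the line", {
  r <- makeRecords(n = 3)
  r$livability[2] <- 7
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(r, f, row.names = FALSE)
  expect_error(readCalvingRecords(f), "line 3.*livability")
  r <- makeRecords(n = 3)
  r$calf_sex[1] <- "X"
  write.csv(r, f, row.names = FALSE)
  expect_error(readCalvingRecords(f), "line 2.*calf_sex")
  write.csv(r[, -1], f, row.names = FALSE)
  expect_error(readCalvingRecords(f), "missing column")
})

test_that("the bundled breed summary reproduces the published totals", {
  tab <- referenceBreedSummary()
  expect_equal(nrow(tab), 30L)
  expect_equal(sum(tab$n[tab$breed == "BS"]), 80394L)
  expect_equal(sum(tab$n[tab$breed == "JE"]), 485604L)
})
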