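test_that("bundled fixture loads with the expected shape", {
  co <- rorschachFixture()
  expect_s4_class(co, "RorschachCohort")
  expect_length(subjectIds(co), 19)
  expect_length(variableNames(co), 45)
  g <- as.character(cohortGroups(co))
  expect_equal(sum(g == "AD"), 8)
  expect_equal(sum(g == "INPH"), 11)
  expect_equal(variableNames(co)[1], "Numero Risposte")
  expect_equal(variableNames(co)[45], "Sensazione")
  expect_true(all(cohortCounts(co) >= 0))
})

test_that("two printed subjects are exact duplicates of each other", {
  m <- cohortCounts(rorschachFixture())
  expect_identical(unname(m["INPH 7 pr", ]), unname(m["INPH 9 pr", ]))
})

test_that("constructor validity rejects malformed cohorts", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  expect_s4_class(RorschachCohort(m, group = c("AD", "INPH")),
                  "RorschachCohort")
  expect_error(RorschachCohort(m, group = c("AD", "foo")), "group")
  mneg <- m; mneg[1, 1] <- -1
  expect_error(RorschachCohort(mneg, group = c("AD", "INPH")),
               "non-negative")
  mfrac <- m; mfrac[1, 1] <- 0.5
  expect_error(RorschachCohort(mfrac, group = c("AD", "INPH")), "integral")
  mdup <- m; rownames(mdup) <- c("s1", "s1")
  expect_error(RorschachCohort(mdup, group = c("AD", "INPH")), "unique")
})

test_that("readCohort rejects interior holes and bad cells with context", {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeLines(c("subject_id,group,A,B,C",
               "s1,AD,1,,2",
               "s2,INPH,1,2,3"), f)
  expect_error(readCohort(f), "subject 's1', variable 'B'")
  writeLines(c("subject_id,group,A,B",
               "s1,AD,1,-2",
               "s2,INPH,1,2"), f)
  expect_error(readCohort(f), "subject 's1', variable 'B'")
  expect_error(readCohort(tempfile()), "cannot read")
})

test_that("readCohort fills missing trailing cells with 0 and warns", {
  # the published 47-variable listing of the same table drops the final cell
  # of one duplicated row; reproduce that defect from the fixture in code
  src <- readLines(system.file("extdata", "rorschach_cohort.csv",
                               package = "RorschachMap"), encoding = "UTF-8")
  i <- grep("^\"?INPH 7 pr", src)
  expect_length(i, 1)
  src[i] <- sub(",[0-9]+$", ",", src[i])
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeLines(src, f, useBytes = TRUE)
  expect_warning(co <- readCohort(f), "INPH 7 pr")
  expect_identical(cohortCounts(co), cohortCounts(rorschachFixture()))
})

test_that("writeCohort/readCohort round-trips the fixture cell for cell", {
  co <- rorschachFixture()
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeCohort(co, f)
  co2 <- readCohort(f)
  expect_identical(cohortCounts(co2), cohortCounts(co))
  expect_identical(as.character(cohortGroups(co2)),
                   as.character(cohortGroups(co)))
})

test_that("describeCohort matches the independent reference stats", {
  d <- describeCohort(rorschachFixture())
  ref <- referenceStats()
  for (v in names(ref)) {
    row <- d[d$variable == v, ]
    expect_equal(round(row$mean, 2), ref[[v]][1], info = v)
    expect_equal(round(row$sd, 2), ref[[v]][2], info = v)
    expect_equal(row$min, ref[[v]][3], info = v)
    expect_equal(row$max, ref[[v]][4], info = v)
  }
})

test_that("population sd is the sample sd shrunk by sqrt((n-1)/n)", {
  co <- rorschachFixture()
  ds <- describeCohort(co, sdType = "sample")
  dp <- describeCohort(co, sdType = "population")
  expect_equal(dp$sd, ds$sd * sqrt(18 / 19))
})

test_that("protocol rules flag exactly one determinant-sum violation", {
  pv <- validateProtocol(rorschachFixture())
  viol <- violationTable(pv)
  expect_equal(nrow(viol), 1)
  expect_equal(viol$subject_id, "INPH 8 pr")
  expect_equal(viol$rule, "Det")
  expect_equal(viol$expected, 11L)
  expect_equal(viol$observed, 10L)
})

test_that("scaleCohort maps to [0, 1] and inverseScale recovers counts", {
  co <- scaleCohort(rorschachFixture())
  sm <- scaledMatrix(co)
  expect_true(all(sm >= 0 & sm <= 1))
  nonconst <- apply(cohortCounts(co), 2, function(x) max(x) > min(x))
  expect_equal(unname(apply(sm[, nonconst], 2, max)),
               rep(1, sum(nonconst)))
  back <- inverseScale(co)
  expect_equal(back, cohortCounts(co), tolerance = 1e-12)
})

test_that("constant variables scale to zero everywhere", {
  m <- cbind(A = c(1, 3, 5), B = c(2, 2, 2))
  rownames(m) <- paste("s", 1:3)
  co <- scaleCohort(RorschachCohort(m, group = c("AD", "AD", "INPH")))
  expect_equal(unname(scaledMatrix(co)[, "B"]), c(0, 0, 0))
})

test_that("appendGroupIndicators builds the 47-variable table", {
  co <- appendGroupIndicators(rorschachFixture())
  expect_length(variableNames(co), 47)
  m <- cohortCounts(co)
  expect_equal(unname(m["Demenza 1", c("INPH", "DEMENZA")]), c(0, 1))
  expect_equal(unname(m["INPH 1 pr", c("INPH", "DEMENZA")]), c(1, 0))
  expect_equal(sum(m[, "INPH"]), 11)
  expect_equal(sum(m[, "DEMENZA"]), 8)
  expect_error(appendGroupIndicators(co), "already present")
  one <- RorschachCohort(matrix(1:4, 2, 2,
                                dimnames = list(c("a", "b"), c("x", "y"))),
                         group = c("AD", "AD"))
  expect_error(appendGroupIndicators(one), "both groups")
})

test_that("variableDictionary maps descriptive names onto fixture columns", {
  dict <- variableDictionary()
  expect_true(all(dict %in% variableNames(rorschachFixture())))
  expect_equal(unname(dict["Popular"]), "BAN")
  expect_equal(unname(dict["Refuse"]), "Rifiuti")
})
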