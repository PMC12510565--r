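test_that("city-day grading follows the half-open breakpoint intervals", {
  bp <- breakpointTable()
  expect_equal(as.character(classifyCityDay(c(50, 80, 120, 200, 300), bp)),
               c("CLEAN", "MILD", "MODERATE", "HEAVY", "SERIOUS"))
  # boundary values belong to the lower grade
  expect_equal(as.character(classifyCityDay(c(75, 115, 150, 250), bp)),
               c("CLEAN", "MILD", "MODERATE", "HEAVY"))
  expect_error(classifyCityDay(-1, bp), ">= 0")
  expect_error(breakpointTable(mild = 80, moderate = 80),
               "strictly increasing")
})

test_that("daily means average available hours and flag short days", {
  pm <- matrix(c(rep(50, 24), rep(0, 12), rep(100, 12)), 1, 48)
  p <- HourlyPanel(list(PM25 = pm), hoursFrom("2023-01-01", 48), "A")
  dm <- dailyMean(p)
  expect_equal(dm$mean, c(50, 50))
  expect_true(all(dm$valid))
  pm2 <- pm
  pm2[1, 25:38] <- NA                       # 10 valid hours on day 2
  p2 <- HourlyPanel(list(PM25 = pm2), hoursFrom("2023-01-01", 48), "A")
  dm2 <- dailyMean(p2)
  expect_equal(dm2$valid, c(TRUE, FALSE))
  expect_equal(dm2$nHours[2], 10)
})

test_that("contiguous clusters are the connected polluted components", {
  A <- pathAdjacency(4, c("A", "B", "C", "D"))
  A["C", "D"] <- A["D", "C"] <- 0L          # D isolated
  lv <- cityLevels(A = "MILD", B = "MILD", C = "MILD", D = "MODERATE")
  cl <- contiguousClusters(lv, A)
  expect_equal(sort(vapply(cl, paste, "", collapse = "")),
               c("ABC", "D"))
  expect_equal(contiguousClusters(cityLevels(A = "CLEAN", B = "CLEAN",
                                             C = "CLEAN", D = "CLEAN"), A),
               list())
  expect_error(contiguousClusters(cityLevels(Z = "MILD"), A),
               "missing from adjacency")
})

test_that("the worked regional classification rules hold", {
  A <- pathAdjacency(8)
  mk <- function(...) {
    lv <- rep("CLEAN", 8)
    names(lv) <- LETTERS[1:8]
    args <- list(...)
    for (nm in names(args)) lv[nm] <- args[[nm]]
    factor(lv, levels = c("CLEAN", "MILD", "MODERATE", "HEAVY", "SERIOUS"),
           ordered = TRUE)
  }
  # 5 contiguous mild cities -> mild regional
  lv <- mk(A = "MILD", B = "MILD", C = "MILD", D = "MILD", E = "MILD")
  expect_equal(as.character(classifyRegionDay(lv, A)$eventLevel),
               "MILD_REGIONAL")
  # 5 contiguous heavy cities -> severe regional
  lv <- mk(A = "HEAVY", B = "HEAVY", C = "HEAVY", D = "HEAVY", E = "HEAVY")
  expect_equal(as.character(classifyRegionDay(lv, A)$eventLevel),
               "SEVERE_REGIONAL")
  # 6 contiguous moderate, none heavy -> moderate regional
  lv <- mk(A = "MODERATE", B = "MODERATE", C = "MODERATE", D = "MODERATE",
           E = "MODERATE", F = "MODERATE")
  expect_equal(as.character(classifyRegionDay(lv, A)$eventLevel),
               "MODERATE_REGIONAL")
  # only 4 polluted cities -> gate fails -> none
  lv <- mk(A = "SERIOUS", B = "SERIOUS", C = "SERIOUS", D = "SERIOUS")
  expect_equal(as.character(classifyRegionDay(lv, A)$eventLevel), "NONE")
  # 5 contiguous mild + 1 heavy elsewhere in the region -> moderate
  lv <- mk(A = "MILD", B = "MILD", C = "MILD", D = "MILD", E = "MILD",
           H = "HEAVY")
  expect_equal(as.character(classifyRegionDay(lv, A)$eventLevel),
               "MODERATE_REGIONAL")
})

test_that("decision tree is total, mutually exclusive and matches a brute-force oracle", {
  set.seed(33)
  A6 <- pathAdjacency(6)
  lvs <- c("CLEAN", "MILD", "MODERATE", "HEAVY", "SERIOUS")
  # exhaustive over all 5^6 gradings on a 6-city path graph
  grids <- expand.grid(rep(list(lvs), 6), stringsAsFactors = FALSE)
  out <- character(nrow(grids))
  for (i in seq_len(nrow(grids))) {
    lv <- factor(unlist(grids[i, ]), levels = lvs, ordered = TRUE)
    names(lv) <- LETTERS[1:6]
    out[i] <- as.character(classifyRegionDay(lv, A6)$eventLevel)
  }
  expect_true(all(out %in% c("NONE", "MILD_REGIONAL", "MODERATE_REGIONAL",
                             "SEVERE_REGIONAL")))
  # oracle agreement on a random subsample (brute-force re-implementation)
  sub <- sample(nrow(grids), 400)
  for (i in sub) {
    lv <- factor(unlist(grids[i, ]), levels = lvs, ordered = TRUE)
    names(lv) <- LETTERS[1:6]
    expect_identical(as.character(classifyRegionDay(lv, A6)$eventLevel),
                     bruteRegionDay(lv, A6))
  }
})

test_that("raising one city's grade never lowers the regional level", {
  set.seed(12)
  A6 <- pathAdjacency(6)
  lvs <- c("CLEAN", "MILD", "MODERATE", "HEAVY", "SERIOUS")
  rank <- function(ev) match(ev, c("NONE", "MILD_REGIONAL",
                                   "MODERATE_REGIONAL", "SEVERE_REGIONAL"))
  for (rep in 1:300) {
    lv <- sample(lvs, 6, replace = TRUE,
                 prob = c(0.35, 0.25, 0.2, 0.12, 0.08))
    names(lv) <- LETTERS[1:6]
    base <- bruteRegionDay(factor(lv, levels = lvs, ordered = TRUE), A6)
    ci <- sample(6, 1)
    k <- match(lv[ci], lvs)
    if (k == 5) next
    lv2 <- lv
    lv2[ci] <- lvs[k + 1]
    up <- as.character(classifyRegionDay(
      factor(lv2, levels = lvs, ordered = TRUE), A6)$eventLevel)
    expect_gte(rank(up), rank(base))
  }
})

test_that("relabeling cities together with the adjacency leaves events unchanged", {
  set.seed(77)
  A <- chengduAdjacency()
  lvs <- c("CLEAN", "MILD", "MODERATE", "HEAVY", "SERIOUS")
  for (rep in 1:25) {
    lv <- setNames(sample(lvs, 16, replace = TRUE), rownames(A))
    perm <- sample(16)
    A2 <- A[perm, perm]
    lv2 <- lv[perm]
    e1 <- classifyRegionDay(factor(lv, levels = lvs, ordered = TRUE), A)
    e2 <- classifyRegionDay(factor(lv2, levels = lvs, ordered = TRUE), A2)
    expect_identical(as.character(e1$eventLevel),
                     as.character(e2$eventLevel))
  }
})

test_that("event tallies split by season and sum to the annual count", {
  ev <- data.frame(
    date = as.Date(c("2023-01-05", "2023-04-10", "2023-07-01",
                     "2023-10-12", "2023-12-25", "2023-12-26")),
    eventLevel = c("MILD_REGIONAL", "MILD_REGIONAL", "NONE",
                   "MODERATE_REGIONAL", "SEVERE_REGIONAL",
                   "MODERATE_REGIONAL"))
  tly <- countEvents(ev, 2023)
  expect_equal(tly$Year, c(2, 2, 1))
  expect_equal(tly$Winter, c(1, 1, 1))
  expect_equal(tly$Spring, c(1, 0, 0))
  expect_equal(tly$Autumn, c(0, 1, 0))
  expect_equal(rowSums(tly[, c("Spring", "Summer", "Autumn", "Winter")]),
               tly$Year)
})

test_that("the synthetic fixture produces all three regional event classes", {
  p <- makeFixture16City(nDays = 40, seed = 2023)
  ev <- classifyRegion(p)
  tab <- table(factor(as.character(ev$eventLevel),
                      levels = c("NONE", "MILD_REGIONAL",
                                 "MODERATE_REGIONAL", "SEVERE_REGIONAL")))
  expect_gt(tab[["MILD_REGIONAL"]], 0)
  expect_gt(tab[["MODERATE_REGIONAL"]], 0)
  expect_gt(tab[["SEVERE_REGIONAL"]], 0)
})
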