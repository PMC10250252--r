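# GSS: rubric validation, assessment constraints, aggregation conventions.

test_that("rubric validation enforces the 100-point budget and unique ids", {
  ok <- gssRubric(data.frame(id = c("a", "b", "c"),
                             description = c("x", "y", "z"),
                             max_points = c(60, 30, 10)))
  expect_s3_class(ok, "GssRubric")
  expect_error(gssRubric(data.frame(id = c("a", "b", "c"),
                                    description = "d",
                                    max_points = c(60, 30, 20))),
               "sum to exactly 100")
  expect_error(gssRubric(data.frame()), "non-empty")
  expect_error(gssRubric(data.frame(id = c("a", "a"), description = "d",
                                    max_points = c(50, 50))),
               "unique")
  expect_error(gssRubric(data.frame(id = c("a", "b"), description = "d",
                                    max_points = c(100, 0))),
               "> 0")
})

test_that("the shipped example rubric is valid and flags its catheter criterion", {
  r <- defaultGssRubric()
  expect_identical(sum(r$criteria$max_points), 100)
  expect_true(any(r$criteria$catheter))
})

test_that("assessments respect per-criterion bounds", {
  r <- defaultGssRubric()
  pts <- c(main_vessel = 40, collaterals = 20, catheter = 18, artifacts = 9)
  a <- gssAssessment("c1", pts, r)
  expect_identical(a$total, 87)
  bad <- pts; bad[["catheter"]] <- 25
  expect_error(gssAssessment("c1", bad, r), "\\[0, max\\]")
  # NA only allowed on catheter criteria of unscorable cases
  na_pts <- pts; na_pts[["catheter"]] <- NA
  expect_error(gssAssessment("c1", na_pts, r), "catheter")
  ok <- gssAssessment("c1", na_pts, r, catheter_scorable = FALSE)
  expect_identical(ok$total, 69)
})

test_that("summaries use the documented quantile convention", {
  r <- defaultGssRubric()
  mk <- function(id, total) {
    # distribute a target total over the criteria
    pts <- c(main_vessel = min(45, total), collaterals = 0, catheter = 0,
             artifacts = 0)
    rest <- total - pts[["main_vessel"]]
    pts[["collaterals"]] <- min(25, rest); rest <- rest - pts[["collaterals"]]
    pts[["catheter"]] <- min(20, rest); rest <- rest - pts[["catheter"]]
    pts[["artifacts"]] <- rest
    gssAssessment(id, pts, r)
  }
  s <- summarizeGss(lapply(c(92, 88, 96), function(t) mk(t, t)), r)
  expect_identical(s$median, 92)
  s2 <- summarizeGss(lapply(c(87, 92, 96), function(t) mk(t, t)), r)
  expect_identical(c(s2$q25, s2$q75), c(87, 96))
  # single assessment: median and both IQR bounds equal its total
  s1 <- summarizeGss(list(mk("x", 90)), r)
  expect_identical(c(s1$median, s1$q25, s1$q75), c(90, 90, 90))
})

test_that("aggregation matches the sorted-list quantile oracle", {
  r <- defaultGssRubric()
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(1:200, 1)
    totals <- sample(0:100, n, replace = TRUE)
    mk <- function(id, total) gssAssessment(id, c(
      main_vessel = min(45, total),
      collaterals = min(25, max(0, total - 45)),
      catheter = min(20, max(0, total - 70)),
      artifacts = max(0, total - 90)), r)
    as_list <- lapply(seq_len(n), function(i) mk(i, totals[i]))
    s <- summarizeGss(as_list, r)
    expect_equal(s$median, oracleQ6(totals, 0.5))
    expect_equal(s$q25, oracleQ6(totals, 0.25))
    expect_equal(s$q75, oracleQ6(totals, 0.75))
    # permutation invariance
    s_shuf <- summarizeGss(sample(as_list), r)
    expect_equal(s[c("median", "q25", "q75")],
                 s_shuf[c("median", "q25", "q75")])
  }
})

test_that("catheter-unscorable cases are excluded from totals but kept for other criteria", {
  r <- defaultGssRubric()
  full <- gssAssessment("a", c(main_vessel = 45, collaterals = 25,
                               catheter = 20, artifacts = 10), r)
  colli <- gssAssessment("b", c(main_vessel = 10, collaterals = 5,
                                catheter = NA, artifacts = 0), r,
                         catheter_scorable = FALSE)
  s <- summarizeGss(list(full, colli), r)
  expect_identical(s$n_scored, 1L)
  expect_identical(s$n_excluded, 1L)
  expect_identical(s$median, 100)  # totals over scorable cases only
  pc <- s$per_criterion
  expect_identical(pc$n[pc$id == "catheter"], 1L)
  expect_identical(pc$n[pc$id == "main_vessel"], 2L)
  expect_equal(pc$median[pc$id == "main_vessel"], 27.5)
})

test_that("degenerate inputs raise empty-input errors", {
  r <- defaultGssRubric()
  expect_error(summarizeGss(list(), r), "empty-input")
  colli <- gssAssessment("b", c(main_vessel = 10, collaterals = 5,
                                catheter = NA, artifacts = 0), r,
                         catheter_scorable = FALSE)
  expect_error(summarizeGss(list(colli), r), "empty-input")
})
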