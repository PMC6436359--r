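test_that("item table matches the published instrument structure", {
  items <- scas_items()
  expect_equal(nrow(items), 12L)
  expect_equal(as.integer(table(items$phase)[c("oral", "pharyngeal",
                                               "penetration_aspiration")]),
               c(4L, 3L, 5L))
  expect_equal(sort(items$weight[items$phase == "oral"]), c(1, 1, 2, 2))
  expect_equal(sort(items$weight[items$phase == "pharyngeal"]), c(2, 10, 10))
  expect_equal(sort(items$weight[items$phase == "penetration_aspiration"]),
               c(10, 15, 15, 20, 30))
  expect_equal(items$max_total, 3 * items$weight)
})

test_that("offering and assessment scoring reproduce hand-computed sums", {
  g <- zero_grid()
  expect_equal(score_offering(g, "liquid"), 0)
  s0 <- score_assessment(g)
  expect_equal(unlist(s0, use.names = FALSE), c(0, 0, 0, 0))

  g1 <- all_ones_grid()
  expect_equal(score_offering(g1, "paste"), 118)  # 1+1+2+2+2+10+10+10+15+15+20+30
  s1 <- score_assessment(g1)
  expect_equal(s1$oral, 18)
  expect_equal(s1$pharyngeal, 66)
  expect_equal(s1$penetration_aspiration, 270)
  expect_equal(s1$total, 354)

  g2 <- zero_grid()
  g2["choking", "liquid"] <- 1L
  expect_equal(score_offering(g2, "liquid"), 20)

  g3 <- zero_grid()
  g3["cough", ] <- 1L
  s3 <- score_assessment(g3)
  expect_equal(unlist(s3, use.names = FALSE), c(0, 0, 45, 45))
})

test_that("scoring is additive over offerings and monotone in flags", {
  set.seed(101)
  for (rep in 1:25) {
    g <- matrix(rbinom(36, 1, 0.4), 12, 3,
                dimnames = dimnames(zero_grid()))
    s <- score_assessment(g)
    per_off <- sum(vapply(c("liquid", "paste", "solid"),
                          function(o) score_offering(g, o), numeric(1)))
    expect_equal(s$total, per_off)
    expect_equal(s$total, s$oral + s$pharyngeal + s$penetration_aspiration)
    # flipping any 0 to 1 never decreases any subscore
    zeros <- which(g == 0)
    if (length(zeros)) {
      g2 <- g
      g2[sample(zeros, 1)] <- 1L
      s2 <- score_assessment(g2)
      expect_true(all(unlist(s2) >= unlist(s)))
    }
  }
})

test_that("grid validation reports unknown items, bad flags and missing cells", {
  g <- all_ones_grid()
  rownames(g)[1] <- "nonexistent_sign"
  expect_error(score_assessment(g), "nonexistent_sign",
               class = "scaspd_validation_error")

  g2 <- all_ones_grid()
  g2[3, 2] <- 7L
  expect_error(score_assessment(g2), "0 or 1",
               class = "scaspd_validation_error")

  long <- expand.grid(item_id = scas_items()$item_id,
                      offering_id = c("liquid", "paste", "solid"),
                      stringsAsFactors = FALSE)
  long$observed <- 1L
  incomplete <- long[-c(1, 14), ]
  err <- tryCatch(observation_grid(incomplete), error = identity)
  expect_s3_class(err, "scaspd_validation_error")
  expect_match(conditionMessage(err), "lip_closure, liquid")
})

test_that("item aliases resolve to canonical identifiers", {
  expect_equal(normalize_item_id("prehension_of_food"), "lip_closure")
  expect_equal(normalize_item_id("respiratory_impairment"), "breathing")
  expect_error(normalize_item_id("no_such_item"), "no_such_item",
               class = "scaspd_validation_error")
})

test_that("severity classification honours inclusive upper bounds", {
  rev <- scas_scheme("revised")
  pre <- scas_scheme("preliminary")
  expect_equal(as.character(classify_severity(0, rev)), "normal")
  expect_equal(as.character(classify_severity(3, rev)), "normal")
  expect_equal(as.character(classify_severity(19, rev)), "functional")
  expect_equal(as.character(classify_severity(36, rev)), "moderate_severe")
  expect_equal(as.character(classify_severity(60, pre)), "moderate")
  expect_equal(as.character(classify_severity(61, pre)), "severe")
  expect_error(classify_severity(-1, rev), class = "scaspd_validation_error")
  expect_error(classify_severity(355, rev), class = "scaspd_validation_error")
})

test_that("every integer score gets exactly one non-decreasing band", {
  for (scheme in list(scas_scheme("revised"), scas_scheme("preliminary"))) {
    lab <- classify_severity(0:354, scheme)
    expect_false(anyNA(lab))
    expect_true(all(diff(as.integer(lab)) >= 0))
    expect_setequal(levels(lab), scheme$levels)
  }
})

test_that("custom schemes must tile the score range", {
  expect_error(severity_scheme("bad", c("a", "b"), c(10, 300)),
               class = "scaspd_validation_error")
  expect_error(severity_scheme("bad", c("a", "b"), c(100, 50)),
               class = "scaspd_validation_error")
  ok <- severity_scheme("halves", c("low", "high"), c(100, 354))
  expect_equal(as.character(classify_severity(c(100, 101), ok)),
               c("low", "high"))
})

test_that("dichotomization is an inclusive ordinal threshold", {
  expect_equal(dichotomize("normal", "mild"), 0L)
  expect_equal(dichotomize("severe", "mild"), 1L)
  expect_equal(dichotomize("functional", "functional"), 1L)
  expect_equal(dichotomize(c("normal", "mild", "moderate"), "mild"),
               c(0L, 1L, 1L))
  expect_error(dichotomize("normal", "moderate_severe"),
               class = "scaspd_validation_error")
})

test_that("imputing an offering scores it at the maximum and marks the record", {
  r <- assessment_record("p1", zero_grid())
  r <- impute_offering(r, "solid")
  expect_equal(r$imputed_offerings, "solid")
  expect_equal(score_offering(r, "solid"), 118)
  expect_equal(score_assessment(r)$total, 118)
})

test_that("the shipped instrument configuration round-trips", {
  path <- system.file("extdata", "scas_instrument.json", package = "scaspd")
  skip_if(path == "", "installed config not found")
  cfg <- read_instrument(path)
  expect_equal(cfg$items$weight, scas_items()$weight)
  expect_equal(cfg$schemes$revised$upper, scas_scheme("revised")$upper)
  # alternative weightings are honoured by the scoring functions
  alt <- cfg$items
  alt$weight <- rep(1, 12)
  alt$max_total <- 3 * alt$weight
  expect_equal(score_assessment(all_ones_grid(), items = alt)$total, 36)
})
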