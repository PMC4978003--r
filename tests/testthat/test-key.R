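test_that("the shipped discriminant functions evaluate exactly", {
  d2 <- discriminant_D2()
  zero <- c(SL = 0, MW = 0)
  expect_equal(evaluate_discriminant(d2, zero), -15.038, tolerance = 1e-12)
  # hand arithmetic: 0.0847*482 - 0.0625*361 - 15.038
  s <- evaluate_discriminant(d2, c(SL = 482, MW = 361))
  expect_equal(s, 0.0847 * 482 - 0.0625 * 361 - 15.038, tolerance = 1e-9)
  expect_equal(s, 3.2249, tolerance = 1e-9)
  fl <- d2$class_scores[d2$class_scores$class == "flavus", ]
  expect_true(s >= fl$min && s <= fl$max)

  d4 <- discriminant_D4()
  expect_equal(evaluate_discriminant(
    d4, c(PoOC = 0, CW = 0, PEW = 0, PEL = 0)), 8.3829, tolerance = 1e-12)
  expect_equal(evaluate_discriminant(
    d4, c(PoOC = 320, CW = 700, PEW = 150, PEL = 350)),
    0.0511 * 320 - 0.0486 * 700 - 0.0702 * 150 + 0.0435 * 350 + 8.3829,
    tolerance = 1e-9)
  expect_error(evaluate_discriminant(d2, c(SL = 480)), "MW")
})

test_that("discriminant scores are affine in the traits", {
  d4 <- discriminant_D4()
  tr <- c(PoOC = 320, CW = 700, PEW = 150, PEL = 350)
  s1 <- evaluate_discriminant(d4, tr)
  for (a in c(0.25, 2, 13)) {
    sa <- evaluate_discriminant(d4, a * tr)
    expect_equal(sa - d4$constant, a * (s1 - d4$constant), tolerance = 1e-9)
  }
})

test_that("the CW/PoOC couplet splits at 1.85 with a strict inequality", {
  side <- function(cw, pooc) ratio_check_cw_pooc(c(CW = cw, PoOC = pooc))
  expect_equal(as.character(side(960, 500)), "madecassus-side")    # 1.92
  expect_equal(as.character(side(865, 500)), "flavus/nitidus-side") # 1.73
  expect_message(s <- side(925, 500), "borderline|threshold")       # exactly 1.85
  expect_equal(as.character(s), "flavus/nitidus-side")
  expect_equal(attr(side(960, 500), "ratio"), 1.92)
})

test_that("the dichotomous key follows its couplets", {
  rec <- c(CW = 865, PoOC = 500, SL = 482, MW = 361)  # CW/PoOC = 1.73

  expect_equal(key_classify(rec, hump = TRUE)$label, "gibber")
  expect_equal(key_classify(rec, hump = FALSE, color = "dark")$label,
               "madecassus")
  d <- key_classify(c(CW = 960, PoOC = 500, SL = 482, MW = 361),
                    hump = FALSE, color = "yellow-light")
  expect_equal(d$label, "madecassus")
  expect_match(d$evidence, "CW/PoOC")

  # cryptic pair resolved by D2: SL = 482, MW = 361 gives +3.22 -> flavus
  d2 <- key_classify(rec, hump = FALSE, color = "yellow-light")
  expect_equal(d2$label, "flavus")
  expect_match(d2$evidence, "D2")
  # nitidus-like measurements
  d3 <- key_classify(c(CW = 600, PoOC = 350, SL = 367, MW = 298),
                     hump = FALSE, color = "yellow-light")
  expect_equal(d3$label, "nitidus")

  # elevation is reported but never decides
  d4 <- key_classify(rec, hump = FALSE, color = "yellow-light",
                     elevation = 100)
  expect_equal(d4$label, "flavus")
  expect_true(any(grepl("never decisive", d4$trace)))

  expect_error(key_classify(rec, hump = NA), "hump")
})

test_that("gibber is only ever keyed out via the hump", {
  set.seed(6)
  for (i in 1:25) {
    rec <- c(CW = runif(1, 500, 1000), PoOC = runif(1, 300, 600),
             SL = runif(1, 300, 600), MW = runif(1, 250, 500))
    d <- suppressWarnings(
      key_classify(rec, hump = FALSE,
                   color = sample(c("dark", "yellow-light"), 1)))
    expect_false(d$label == "gibber")
    expect_true(d$label %in% c("flavus", "madecassus", "nitidus"))
  }
})

test_that("forward selection finds the informative trait set", {
  # two classes differing only in SL
  set.seed(7)
  df <- make_specimen_df(24, n_nests = 24, seed = 7)
  df$SL <- df$SL + rep(c(0, 60), each = 12)
  ds <- morph_dataset(df)
  lab <- rep(c("A", "B"), each = 12)
  fn <- extract_reduced_function(ds, lab, classes = c("A", "B"),
                                 max_traits = 1)
  expect_equal(names(fn$coefficients), "SL")
  expect_equal(attr(fn, "loocv_error"), 0)
  # sign convention: first class has the positive score mean
  expect_gt(fn$class_scores$mean[fn$class_scores$class == "A"],
            fn$class_scores$mean[fn$class_scores$class == "B"])
  # pooled grand mean centred at zero
  sc <- evaluate_discriminant(fn, ds)
  expect_equal(mean(sc), 0, tolerance = 1e-9)
})

test_that("larger trait budgets never classify worse", {
  set.seed(8)
  specs <- madecassus_group_specs()[c("flavus", "nitidus")]
  specs$flavus$n_nests <- 20L; specs$flavus$n_workers <- 30L
  specs$nitidus$n_nests <- 20L; specs$nitidus$n_workers <- 30L
  ds <- generate_dataset(specs, seed = 9)
  err_of <- function(mt) {
    fn <- suppressWarnings(
      extract_reduced_function(ds, ds$species, c("flavus", "nitidus"),
                               max_traits = mt,
                               traits = c("SL", "MW", "ML", "PEW")))
    attr(fn, "loocv_error")
  }
  errs <- vapply(c(1, 2, 4), err_of, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("a two-trait function separates the synthetic cryptic pair", {
  specs <- madecassus_group_specs()[c("flavus", "nitidus")]
  ds <- generate_dataset(specs, seed = 10)
  fn <- suppressWarnings(
    extract_reduced_function(ds, ds$species, c("flavus", "nitidus"),
                             max_traits = 2))
  expect_lte(attr(fn, "loocv_error"), 0.05)
  # scores are in pooled within-class sd units: classes sit either side of 0
  cs <- fn$class_scores
  expect_gt(cs$mean[cs$class == "flavus"], 0)
  expect_lt(cs$mean[cs$class == "nitidus"], 0)
})
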