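test_that("the packaged registry carries all sixteen published algorithms", {
  nm <- chu9d_algorithms()
  expect_length(nm, 16L)
  expect_setequal(
    nm,
    as.vector(outer(c("AU", "UK"),
                    as.vector(outer(c("OLS", "CLAD", "MM", "GLM"),
                                    c("model1", "model2"), paste, sep = "/")),
                    paste, sep = "/")))
  mm <- chu9d_algorithm("AU/MM/model2")
  expect_equal(mm$intercept, 0.222655)
  expect_equal(mm$gammas[["ks_i2"]], 0.023085)
  expect_setequal(names(mm$gammas),
                  c("ks_i1", "ks_i2", "ks_i3", "ks_i4", "ks_i9", "ks_i10"))

  glm1 <- chu9d_algorithm("AU/GLM/model1")
  expect_equal(glm1$beta1, 0.092650)
  expect_null(glm1$beta2)            # squared term not part of the logit fit
  expect_identical(glm1$link, "logit")

  uk <- chu9d_algorithm("UK/OLS/model1")
  expect_equal(uk$beta1, 0.032434)
  expect_equal(uk$beta2, -0.000249)

  expect_error(chu9d_algorithm("AU/MM/model3"), "AU/MM/model2")
})

test_that("published extrema are reproduced from the printed coefficients", {
  rec <- all_items_row(5)
  expect_equal(round(predict_chu9d(rec, chu9d_algorithm("AU/MM/model2"))$raw, 4),
               1.0555)
  expect_equal(round(predict_chu9d(rec, chu9d_algorithm("AU/OLS/model2"))$raw, 4),
               1.0342)
  expect_equal(round(predict_chu9d(rec, chu9d_algorithm("AU/GLM/model2"))$raw, 4),
               0.9483)
  # index form, hand arithmetic: -0.435412 + 0.043515*50 - 0.000334*2500
  p <- predict_chu9d(data.frame(ks_index = 50), chu9d_algorithm("AU/OLS/model1"))
  expect_equal(p$raw, 0.905338, tolerance = 1e-12)
})

test_that("identity-link predictions are affine in each item", {
  spec <- chu9d_algorithm("AU/MM/model2")
  base <- all_items_row(3)
  p0 <- predict_chu9d(base, spec, truncate = FALSE)$raw
  for (it in names(spec$gammas)) {
    up <- base
    up[[it]] <- 4
    p1 <- predict_chu9d(up, spec, truncate = FALSE)$raw
    expect_equal(p1 - p0, spec$gammas[[it]], tolerance = 1e-12)
  }
})

test_that("logit-link predictions lie in (0,1) and invert the linear predictor", {
  # linear predictor 0 maps to utility 0.5
  spec0 <- mapping_spec("item_linear", intercept = -0.9,
                        gammas = c(ks_i1 = 0.3), link = "logit",
                        estimator = "GLM")
  expect_equal(predict_chu9d(data.frame(ks_i1 = 3), spec0)$raw, 0.5)
  glm2 <- chu9d_algorithm("AU/GLM/model2")
  for (lev in 1:5) {
    p <- predict_chu9d(all_items_row(lev), glm2)$raw
    expect_true(p > 0 && p < 1)
  }
})

test_that("truncation caps at one and never worsens pointwise error for y <= 1", {
  spec <- chu9d_algorithm("AU/MM/model2")
  set.seed(7)
  df <- as.data.frame(matrix(sample(1:5, 200, TRUE), 20, 10,
                             dimnames = list(NULL, item_names)))
  pr <- predict_chu9d(df, spec)
  expect_true(all(pr$truncated <= 1))
  expect_true(all(pr$truncated <= pr$raw))
  y <- stats::runif(20, 0.33, 1)
  expect_true(all(abs(pr$truncated - y) <= abs(pr$raw - y) + 1e-15))
  # batch containing the all-fives record exceeds 1 raw, capped truncated
  s <- summary(predict_chu9d(rbind(df, all_items_row(5)), spec))
  expect_equal(round(s["raw", "max"], 4), 1.0555)  # all-fives record dominates
  expect_equal(s["truncated", "max"], 1)
})

test_that("batch prediction summaries behave on singletons and duplicates", {
  spec <- chu9d_algorithm("AU/OLS/model2")
  one <- all_items_row(4)
  s <- summary(predict_chu9d(one, spec))
  expect_equal(s["raw", "mean"], s["raw", "min"])
  expect_equal(s["raw", "mean"], s["raw", "max"])
  two <- rbind(one, one)
  pr <- predict_chu9d(two, spec)
  expect_identical(pr$raw[1], pr$raw[2])
  expect_error(predict_chu9d(one[0, ], spec), "no records")
})

test_that("prediction demands the predictors the algorithm names", {
  expect_error(predict_chu9d(all_items_row(3), chu9d_algorithm("AU/OLS/model1")),
               "ks_index")
  expect_error(predict_chu9d(data.frame(ks_i1 = 3), chu9d_algorithm("AU/MM/model2")),
               "ks_i2")
})

test_that("spec serialisation round-trips coefficients exactly", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  for (nm in c("AU/MM/model2", "UK/GLM/model1", "AU/CLAD/model1")) {
    spec <- chu9d_algorithm(nm)
    write_mapping_spec(spec, tmp)
    back <- read_mapping_spec(tmp)
    expect_identical(back$intercept, spec$intercept)
    expect_identical(back$gammas, spec$gammas)
    expect_identical(back$beta1, spec$beta1)
    expect_identical(back$beta2, spec$beta2)
    expect_identical(back$form, spec$form)
    expect_identical(back$link, spec$link)
  }
})

test_that("spec construction enforces the form and link invariants", {
  expect_error(mapping_spec("item_linear", intercept = 0.2,
                            gammas = c(ks_i1 = 0.1), link = "logit",
                            estimator = "MM"),
               "logit link")
  expect_error(mapping_spec("item_linear", intercept = 0.2,
                            gammas = c(bogus = 0.1)), "item labels")
  expect_error(mapping_spec("index_quadratic", intercept = 0.2), "beta1")
})
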