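# independent re-statement of the spectral LAI model used as an oracle
oracle_model1 <- function(i) {
  terms <- cbind(17.37 * i$N * i$N_v,
                 0.85 * i$NDVI * i$Tr,
                 -0.52 * i$Tr,
                 -8.51 * i$N_vc^2,
                 -14.96 * i$NDVI^2)
  5.85 + rowSums(terms)
}

random_inputs <- function(n, seed) {
  set.seed(seed)
  data.frame(N = runif(n, 0, 1), NDVI = runif(n, 0, 1),
             Tr = runif(n, 0, 50), N_v = runif(n, 0, 1),
             N_vc = runif(n, 0, 1),
             Volume_v = runif(n, 0, 1), Volume_vc = runif(n, 0, 1),
             Area_v = runif(n, 0, 1), Area_vc = runif(n, 0, 1),
             SArea_v = runif(n, 0, 2), SArea_vc = runif(n, 0, 2))
}

test_that("normalization divides structural metrics by cell area only", {
  cs <- data.frame(N = 0.4, NDVI = 0.7, Tr = 31, N_v = 0.5, N_vc = 0.5,
                   Volume_v = 8, Volume_vc = 7.92, Area_v = 4,
                   Area_vc = 3.6, SArea_v = 5, SArea_vc = 4)
  inp <- normalize_inputs(cs, 12.96)
  expect_equal(inp$Volume_vc, 7.92 / 12.96, tolerance = 1e-12)  # 0.6111 m
  expect_equal(inp$Area_vc, 3.6 / 12.96, tolerance = 1e-12)     # 0.2778
  expect_equal(inp$Tr, 31)
  expect_equal(inp$N, 0.4)
  expect_error(normalize_inputs(cs, 0), "positive")

  zero <- cs; zero[] <- 0; zero$Tr <- 0
  expect_true(all(unlist(normalize_inputs(zero, 12.96)) == 0))
})

test_that("the spectral model matches an independent expression oracle", {
  inp <- random_inputs(1000, seed = 8)
  expect_equal(lai_model1(inp), oracle_model1(inp), tolerance = 1e-12)

  # printed worked values
  zero <- random_inputs(1, 1); zero[] <- 0
  expect_equal(lai_model1(zero), 5.85)
  e2 <- zero; e2$NDVI <- 1
  expect_equal(lai_model1(e2), 5.85 - 14.96)
  expect_equal(lai_model(e2, lai_model_spec(1, clamp_nonnegative = TRUE)), 0)
  e3 <- zero; e3$Tr <- 10
  expect_equal(lai_model1(e3), 5.85 - 5.2, tolerance = 1e-12)
})

test_that("structural and combined models honour their documented parses", {
  zero <- random_inputs(1, 2); zero[] <- 0
  expect_equal(lai_model2(zero), 0.47)

  # Area_vc = 0 kills every non-constant term of model 2
  i2 <- random_inputs(5, 3); i2$Area_vc <- 0
  expect_equal(lai_model2(i2), rep(0.47, 5))

  # direct evaluation oracle for the documented parse
  i3 <- data.frame(Area_vc = 0.3, Area_v = 0.4, Volume_v = 0.2)
  expect_equal(lai_model2(i3),
               0.47 + 2.39 * 0.3 - 2.29 * 0.3 * 0.4^0.41 * 43.07^(-0.2),
               tolerance = 1e-12)

  i4 <- random_inputs(1, 4)
  expect_equal(lai_model3(i4),
               2.69 * i4$N * i4$Volume_vc + 0.11 * i4$Tr * i4$Area_v -
                 0.67 * i4$Area_v / i4$N_vc -
                 0.38 * 1.54^i4$Tr * i4$N^2 * i4$NDVI^2 /
                 (6.92 * i4$N_vc^4 * i4$Volume_vc),
               tolerance = 1e-12)

  # undefined rational terms flag as missing, never error
  i5 <- random_inputs(1, 5); i5$Volume_vc <- 0
  expect_true(is.na(lai_model3(i5)))
  i6 <- random_inputs(1, 6); i6$N_vc <- 0
  expect_true(is.na(lai_model3(i6)))
})

test_that("model evaluation is pure", {
  inp <- random_inputs(50, 10)
  a <- lai_model1(inp); b <- lai_model1(inp)
  expect_identical(a, b)
  expect_identical(lai_model3(inp), lai_model3(inp))
})

test_that("OLS refit recovers known coefficients", {
  inp <- random_inputs(200, 12)
  truth <- c(0.5, 2.0, -1.2, 0.8)
  y <- truth[1] + truth[2] * inp$Volume_vc + truth[3] * inp$Area_v +
    truth[4] * inp$N
  fit0 <- refit_linear(inp, y, c("Volume_vc", "Area_v", "N"))
  expect_equal(unname(fit0$coefficients), truth, tolerance = 1e-10)
  expect_equal(fit0$r_squared, 1, tolerance = 1e-10)

  # noisy recovery within 3 standard errors
  set.seed(13)
  yn <- y + rnorm(200, 0, 0.3)
  fit <- refit_linear(inp, yn, c("Volume_vc", "Area_v", "N"))
  expect_true(all(abs(fit$coefficients - truth) <= 3 * fit$std_errors))

  # duplicated column -> rank error naming the culprit
  inp$dup <- inp$Volume_vc
  expect_error(refit_linear(inp, yn, c("Volume_vc", "dup", "N")),
               "collinear.*dup")
})
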