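# Feature tables built directly (not via the simulator) so model-fitting
# behaviour is isolated from signal synthesis.
two_class_features <- function(n = 10, gap = 10, seed = 1) {
  set.seed(seed)
  shared <- function() rnorm(2 * n, 0, 0.1)
  tibble::tibble(
    soil = rep(c("a", "b"), each = n),
    sx = rep(c(0, gap), each = n) + rnorm(2 * n, 0, 0.1),
    sy = shared(), mean = shared(), std = shared(),
    variance = shared(), kurtosis = shared()
  )
}

test_that("a class split on one feature gets a dominant weight and perfect training accuracy", {
  feats <- two_class_features()
  model <- fit_soil_model(feats, seed = 1)
  expect_gt(abs(model$weights[["sx"]]), 0.9)
  expect_equal(detection_rate(feats, model), 1.0)
  expect_true(model$separable)

  # Independent check of the optimum direction: no random unit direction
  # separates better than (a tolerance above) the fitted one.
  X <- scale(as.matrix(feats[c("sx", "sy", "mean", "std", "variance", "kurtosis")]))
  y <- factor(feats$soil)
  obj <- function(w) {
    L <- drop(X %*% (w / sqrt(sum(w^2))))
    mu <- tapply(L, y, mean)
    s <- tapply(L, y, sd)
    abs(mu[1] - mu[2]) / (s[1] + s[2] + 1e-6)
  }
  set.seed(2)
  grid_best <- max(apply(matrix(rnorm(6 * 4000), ncol = 6), 1, obj))
  expect_gte(model$objective, 0.95 * grid_best)
})

test_that("identical class distributions are flagged non-separable", {
  set.seed(3)
  feats <- tibble::tibble(
    soil = rep(c("a", "b"), each = 25),
    sx = rnorm(50), sy = rnorm(50), mean = rnorm(50),
    std = rnorm(50), variance = rnorm(50), kurtosis = rnorm(50)
  )
  model <- fit_soil_model(feats, seed = 3)
  expect_false(model$separable)
  expect_lt(model$objective, 1)
})

test_that("fitting is reproducible given a seed and validates its inputs", {
  feats <- two_class_features(seed = 4)
  m1 <- fit_soil_model(feats, seed = 9)
  m2 <- fit_soil_model(feats, seed = 9)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$thresholds, m2$thresholds)

  expect_error(
    fit_soil_model(dplyr::filter(feats, soil == "a")),
    class = "solegait_error_fit"
  )
  expect_error(
    fit_soil_model(feats[c(1:10, 11, 12), ]),
    class = "solegait_error_fit"
  )
})

test_that("the level is a weighted sum of standardized features", {
  feats <- two_class_features(seed = 5)
  model <- fit_soil_model(feats, seed = 5)

  # all-zero weights give level 0 everywhere
  m0 <- model
  m0$weights[] <- 0
  expect_equal(differentiation_level(feats, m0), rep(0, nrow(feats)))

  # a one-hot weight on sx reproduces the scaled feature
  m1 <- model
  m1$weights[] <- 0
  m1$weights[["sx"]] <- 1
  expect_equal(
    differentiation_level(feats, m1),
    (feats$sx - model$center[["sx"]]) / model$scale[["sx"]]
  )

  # features at the scaling midpoint give level 0 under any weights
  mid <- tibble::as_tibble(as.list(model$center))
  expect_equal(differentiation_level(mid, model), 0)
})

test_that("the level is invariant to affine rescaling of raw features", {
  feats <- two_class_features(seed = 6)
  rescaled <- dplyr::mutate(feats,
    sx = 100 * sx + 7, sy = 0.01 * sy - 2, std = 3 * std
  )
  m1 <- fit_soil_model(feats, seed = 2)
  m2 <- fit_soil_model(rescaled, seed = 2)
  expect_equal(
    abs(differentiation_level(feats, m1)),
    abs(differentiation_level(rescaled, m2)),
    tolerance = 1e-6
  )
})

test_that("classification uses level intervals with ties to the lower class", {
  feats <- two_class_features(seed = 7)
  model <- fit_soil_model(feats, seed = 7)

  # a feature vector at a class training mean classifies to that class
  means_a <- dplyr::summarise(
    dplyr::filter(feats, soil == "a"),
    dplyr::across(c(sx, sy, mean, std, variance, kurtosis), mean)
  )
  got <- classify_soil(means_a, model)
  expect_equal(got$pred_class, "a")
  expect_false(got$outlier)

  # a handcrafted model with an exactly representable threshold: a level
  # exactly at the threshold goes to the lower-level class
  m <- model
  m$weights[] <- 0
  m$weights[["sx"]] <- 1
  m$center[] <- 0
  m$scale[] <- 1
  m$thresholds <- 0.5
  m$classes <- c("lo", "hi")
  probe <- means_a
  probe$sx <- 0.5
  expect_equal(classify_soil(probe, m)$level, 0.5)
  expect_equal(classify_soil(probe, m)$pred_class, "lo")
  probe$sx <- 0.6
  expect_equal(classify_soil(probe, m)$pred_class, "hi")
})

test_that("centroids outside the exclusion rectangle are outliers but still classified", {
  feats <- two_class_features(seed = 8)
  model <- fit_soil_model(feats, seed = 8, exclusion = c(50, 8e-4))
  probe <- feats[1, ]
  probe$sx <- 60 # beyond x_max = 50
  probe$sy <- 0
  got <- classify_soil(probe, model)
  expect_true(got$outlier)
  expect_true(got$pred_class %in% model$classes)

  inside <- feats[1, ]
  inside$sx <- 10
  inside$sy <- 4e-4
  expect_false(classify_soil(inside, model)$outlier)
})

test_that("detection rate is the fraction of correct non-outlier strikes", {
  feats <- two_class_features(seed = 10)
  model <- fit_soil_model(feats, seed = 10)
  expect_equal(detection_rate(feats, model), 1.0)
  expect_error(detection_rate(feats[0, ], model), class = "solegait_error_parameter")

  # permuted labels against 6 balanced classes agree about 1/6 of the time
  set.seed(12)
  n <- 600
  feats6 <- tibble::tibble(
    soil = sample(rep(letters[1:6], each = n / 6)),
    sx = rep(seq(0, 50, length.out = 6), each = n / 6) + rnorm(n, 0, 0.01),
    sy = rnorm(n, 1, 0.01), mean = rnorm(n, 0, 0.01), std = rnorm(n, 1, 0.01),
    variance = rnorm(n, 1, 0.01), kurtosis = rnorm(n, 3, 0.01)
  )
  m6 <- fit_soil_model(feats6, seed = 12, n_restarts = 5)
  expect_equal(detection_rate(feats6, m6), 1 / 6, tolerance = 0.35)
})

test_that("soil models round-trip through yaml and json", {
  feats <- two_class_features(seed = 13)
  model <- fit_soil_model(feats, seed = 13)
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_soil_model(model, path)
    back <- read_soil_model(path)
    expect_equal(back$weights, model$weights)
    expect_equal(back$thresholds, model$thresholds)
    expect_equal(back$classes, model$classes)
    expect_equal(
      differentiation_level(feats, back),
      differentiation_level(feats, model)
    )
  }
})
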