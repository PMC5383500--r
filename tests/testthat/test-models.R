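test_that("predictor standardization matches sample-sd z-scores", {
  out <- standardizePredictors(matrix(c(1, 2, 3), 3, 1,
                                      dimnames = list(NULL, "x")))
  expect_equal(unname(out$Z[, 1]), c(-1, 0, 1))
  # idempotent on an already standardized column
  again <- standardizePredictors(out$Z)
  expect_equal(again$Z, out$Z, tolerance = 1e-12)
  # constant column flagged and zeroed, not dropped
  cst <- standardizePredictors(cbind(x = c(1, 2, 3), flat = c(2, 2, 2)))
  expect_true(cst$constants$constant[["flat"]])
  expect_equal(unname(cst$Z[, "flat"]), rep(0, 3))
})

test_that("logistic fits match an independent IRLS oracle", {
  set.seed(71)
  for (rep in 1:3) {
    n <- 150
    X <- matrix(runif(2 * n), n, 2, dimnames = list(NULL, c("d1", "d2")))
    Z <- scale(X)
    eta <- 0.5 - 1.5 * Z[, 1] + 0.8 * Z[, 2]
    y <- rbinom(n, 1, plogis(eta))
    design <- data.frame(species = sprintf("s%03d", 1:n), response = y,
                         d1 = X[, 1], d2 = X[, 2])
    attr(design, "neighborhood") <- resolveNeighborhood(1.0, 50)
    m <- fitEnvModel(design, scheme = "none")
    oracle <- irlsLogistic(scale(X), y)
    expect_equal(unname(coefTable(m)[, "estimate"]), unname(oracle),
                 tolerance = 1e-5)
    expect_true(isConverged(m))
  }
})

test_that("permuted responses yield small, nonsignificant coefficients", {
  set.seed(72)
  n <- 400
  X <- matrix(runif(2 * n), n, 2, dimnames = list(NULL, c("d1", "d2")))
  y <- sample(rep(0:1, each = n / 2))
  design <- data.frame(species = sprintf("s%03d", 1:n), response = y,
                       d1 = X[, 1], d2 = X[, 2])
  m <- fitEnvModel(design, scheme = "none")
  ct <- coefTable(m)
  expect_true(all(abs(ct[-1, "z"]) < 4))
})

test_that("an intercept-only fit recovers the pool fraction", {
  design <- data.frame(species = sprintf("s%02d", 1:20),
                       response = rep(c(1L, 0L), c(6, 14)))
  m <- fitEnvModel(design, scheme = "none")
  expect_equal(plogis(coefTable(m)["(Intercept)", "estimate"]), 0.3,
               tolerance = 1e-8)
})

test_that("AICc follows the closed form and its AIC limit", {
  expect_equal(computeAICc(-10, 3, 20), 27.5)
  set.seed(73)
  for (i in 1:50) {
    ll <- runif(1, -500, -1); k <- sample(1:10, 1); n <- sample(15:500, 1)
    expect_equal(computeAICc(ll, k, n),
                 -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  }
  expect_equal(computeAICc(-10, 3, 1e9), -2 * -10 + 2 * 3, tolerance = 1e-6)
  expect_warning(bad <- computeAICc(-10, 3, 4), "AICc undefined")
  expect_identical(bad, Inf)
})

test_that("interaction columns are z-scored products of z-scored mains", {
  set.seed(74)
  n <- 200
  X <- matrix(runif(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  Z <- scale(X)
  prods <- cbind(Z[, 1] * Z[, 2], Z[, 1] * Z[, 3], Z[, 2] * Z[, 3])
  Zp <- scale(prods)
  eta <- -0.5 + Z %*% c(-1, 0.5, 0) + Zp %*% c(0.8, 0, 0)
  y <- rbinom(n, 1, plogis(eta))
  design <- data.frame(species = seq_len(n), response = y, a = X[, 1],
                       b = X[, 2], c = X[, 3])
  m <- fitEnvModel(design, scheme = "all_pairwise")
  expect_setequal(m@interactions, c("a:b", "a:c", "b:c"))
  oracle <- irlsLogistic(cbind(Z, Zp), y)
  expect_equal(unname(coefTable(m)[, "estimate"]), unname(oracle),
               tolerance = 1e-5)
})

test_that("ordinal x ordinal interactions are excluded on request", {
  kinds <- c(a = "continuous", b = "ordinal", c = "ordinal")
  terms <- funneigh:::.interactionTerms(c("a", "b", "c"), "all_pairwise",
                                        kind = kinds,
                                        excludeOrdinalPairs = TRUE)
  expect_setequal(terms, c("a:b", "a:c"))
})

test_that("backward elimination never raises AICc and hits the fixed point", {
  set.seed(75)
  n <- 300
  X <- matrix(runif(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  Z <- scale(X)
  y <- rbinom(n, 1, plogis(-0.3 - 1.2 * Z[, 1] + 0.9 * Z[, 2]))
  design <- data.frame(species = seq_len(n), response = y,
                       a = X[, 1], b = X[, 2])
  full <- fitEnvModel(design, scheme = "all_pairwise")
  pars <- backwardEliminate(full, design)
  # pure-noise interaction: dropping it should lower AICc here
  expect_lte(aicc(pars), aicc(full))
  # a model already at its optimum is returned unchanged
  again <- backwardEliminate(pars, design)
  expect_identical(again@interactions, pars@interactions)
  expect_equal(aicc(again), aicc(pars))
})

test_that("greedy elimination tracks the exhaustive-search optimum", {
  set.seed(76)
  n <- 250
  X <- matrix(runif(4 * n), n, 4, dimnames = list(NULL, c("a", "b", "c",
                                                          "d")))
  Z <- scale(X)
  y <- rbinom(n, 1, plogis(-0.2 - Z[, 1] + 0.7 * Z[, 2] +
                             0.9 * scale(Z[, 1] * Z[, 2])))
  design <- data.frame(species = seq_len(n), response = y, a = X[, 1],
                       b = X[, 2], c = X[, 3], d = X[, 4])
  full <- fitEnvModel(design, scheme = "all_pairwise")
  expect_length(full@interactions, 6)
  greedy <- backwardEliminate(full, design)
  # compare against exhaustive search over a 4-interaction subset
  small <- fitEnvModel(design, scheme = "none",
                       interactions = full@interactions[1:4])
  exh <- backwardEliminate(small, design, exhaustive = TRUE)
  grd <- backwardEliminate(small, design)
  expect_lte(aicc(greedy), aicc(full))
  expect_lte(aicc(exh), aicc(small))
  expect_lte(aicc(exh), aicc(grd) + 1e-9)
})

test_that("diagnostics flag runaway estimates and flat predictors", {
  # near-constant predictor separating the classes: huge estimate, p near 1
  n <- 40
  design <- data.frame(species = seq_len(n),
                       response = rep(c(0L, 1L), each = n / 2),
                       d1 = 0.5 + c(rep(0, n / 2), rep(1e-7, n / 2)),
                       d2 = runif(n))
  m <- fitEnvModel(design, scheme = "none")
  flags <- diagnoseModel(m, design)
  expect_true("runaway estimate" %in% flags)
  expect_true("insufficient distance variation" %in% flags)

  # well-conditioned fit carries no flags
  set.seed(77)
  ok <- data.frame(species = 1:200, response = rbinom(200, 1, 0.4),
                   d1 = runif(200), d2 = runif(200))
  m2 <- fitEnvModel(ok, scheme = "none")
  expect_length(diagnoseModel(m2, ok), 0)

  # constant predictor is flagged at fit time
  cst <- data.frame(species = 1:100,
                    response = rbinom(100, 1, 0.5),
                    d1 = runif(100), flat = 0.2)
  m3 <- fitEnvModel(cst, scheme = "none")
  expect_true("constant predictor column" %in% diagnoseModel(m3, cst))
})

test_that("environmental predictions follow the inverse-logit closed forms", {
  m <- toyModel("environmental", c("d1", "d2"), beta0 = 0.4, beta = c(-2, 1))
  nd <- data.frame(species = c("x", "y"), d1 = c(0, 1), d2 = c(0, 0.5))
  p <- predictEnv(m, nd)
  expect_equal(unname(p["x"]), plogis(0.4))
  expect_equal(unname(p["y"]), plogis(0.4 - 2 + 0.5))
  # beta0 = 0, x = 0 -> 0.5
  m0 <- toyModel("environmental", "d1", beta0 = 0, beta = -2)
  expect_equal(unname(predictEnv(m0, data.frame(species = "x", d1 = 0))),
               0.5)
  expect_true(all(p > 0 & p < 1))
})

test_that("prediction is identical from raw or pre-standardized inputs", {
  set.seed(78)
  n <- 120
  design <- data.frame(species = sprintf("s%03d", 1:n),
                       response = rbinom(n, 1, 0.5),
                       d1 = runif(n, 0.2, 0.8), d2 = runif(n, 0.1, 0.4))
  m <- fitEnvModel(design, scheme = "all_pairwise")
  p1 <- predictEnv(m, design)
  # standardize by hand with the stored constants, then predict through a
  # model whose constants are the identity
  cst <- m@constants
  zd <- design
  for (t in c("d1", "d2"))
    zd[[t]] <- (design[[t]] - cst$mains$center[[t]]) / cst$mains$scale[[t]]
  m2 <- m
  m2@constants$mains$center[] <- 0
  m2@constants$mains$scale[] <- 1
  p2 <- predictEnv(m2, zd)
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("biotic fits with identical plots collapse to plain logistic", {
  set.seed(79)
  n <- 60
  base <- data.frame(species = sprintf("s%02d", 1:n),
                     response = rbinom(n, 1, 0.4),
                     d1 = runif(n), d2 = runif(n))
  design <- rbind(cbind(base, plot = "p1"), cbind(base, plot = "p2"),
                  cbind(base, plot = "p3"))
  m <- fitBioticModel(design, scheme = "none")
  expect_true("zero RE variance" %in% m@degeneracyReasons)
  expect_equal(m@reVariance, 0)
  ref <- glm(response ~ scale(d1) + scale(d2), data = design,
             family = binomial())
  expect_equal(unname(coefTable(m)[, "estimate"]), unname(coef(ref)),
               tolerance = 1e-4)
  # with zero RE variance, per-plot predictions equal the fixed-effect one
  pb <- predictBiotic(m, design)
  byPlot <- split(pb$perPlot$p, pb$perPlot$plot)
  expect_equal(byPlot$p1, byPlot$p2, tolerance = 1e-12)
})

test_that("biotic mixed models estimate plot intercepts when plots differ", {
  set.seed(80)
  nSpecies <- 40; nPlots <- 8
  plotEff <- rnorm(nPlots, 0, 1.5)
  design <- do.call(rbind, lapply(seq_len(nPlots), function(p) {
    d1 <- runif(nSpecies); d2 <- runif(nSpecies)
    eta <- -0.5 + plotEff[p] - 2 * scale(d1)[, 1] + 0.5 * scale(d2)[, 1]
    data.frame(species = sprintf("s%02d", 1:nSpecies),
               plot = paste0("p", p),
               response = rbinom(nSpecies, 1, plogis(eta)),
               d1 = d1, d2 = d2)
  }))
  m <- fitBioticModel(design, scheme = "none")
  expect_gt(m@reVariance, 0)
  expect_length(m@plotIntercepts, nPlots)
  expect_lt(coefTable(m)["d1", "estimate"], 0)
  # plot-level and population-level predictions differ
  pPlot <- predictBiotic(m, design, rePrediction = "plot")$average
  pPop <- predictBiotic(m, design, rePrediction = "population")$average
  expect_false(isTRUE(all.equal(pPlot, pPop)))
})

test_that("biotic prediction averages per-plot probabilities", {
  m <- toyModel("biotic", "d1", beta0 = 0, beta = 1,
                plotIntercepts = c(p1 = 0, p2 = 0))
  nd <- data.frame(species = "x", plot = c("p1", "p2"),
                   d1 = qlogis(c(0.2, 0.6)))
  out <- predictBiotic(m, nd)
  expect_equal(unname(out$average["x"]), 0.4)
  # identical plots: the average equals any single-plot probability
  nd2 <- data.frame(species = "x", plot = c("p1", "p2"), d1 = qlogis(0.35))
  expect_equal(unname(predictBiotic(m, nd2)$average["x"]), 0.35)
})

test_that("model export round-trips through JSON", {
  set.seed(81)
  design <- data.frame(species = 1:80, response = rbinom(80, 1, 0.5),
                       d1 = runif(80))
  m <- fitEnvModel(design, scheme = "none")
  path <- withr::local_tempfile(fileext = ".json")
  writeModelJson(m, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$filter, "environmental")
  expect_equal(obj$aicc, aicc(m), tolerance = 1e-9)
  expect_length(obj$coefficients$estimate, 2)
  expect_equal(unlist(obj$coefficients$term), c("(Intercept)", "d1"))
})
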