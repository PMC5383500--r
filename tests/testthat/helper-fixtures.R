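# Shared fixtures and independent oracles.

# Random standardized trait table: each trait spans [0, 1] exactly so the
# table is valid as-is.
randomTraitTable <- function(nSpecies, nTraits, seed) {
  set.seed(seed)
  tm <- matrix(runif(nSpecies * nTraits), nSpecies, nTraits)
  tm <- apply(tm, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  dimnames(tm) <- list(sprintf("sp%03d", seq_len(nSpecies)),
                       paste0("t", seq_len(nTraits)))
  kinds <- setNames(rep("continuous", nTraits), colnames(tm))
  new("TraitTable", traits = tm, traitKind = kinds,
      transformLog = setNames(rep(FALSE, nTraits), colnames(tm)),
      standardized = TRUE,
      ranges = matrix(rep(c(0, 1), nTraits), 2,
                      dimnames = list(c("min", "max"), colnames(tm))),
      referenceSpecies = rownames(tm))
}

# Pool assignment declaring the given species pool members (first
# nObserved of them observed) within a regional list.
makePool <- function(regional, pool, observed, focalSite = "f") {
  level <- setNames(rep("environmentally_excluded", length(regional)),
                    regional)
  level[pool] <- "dark_diversity"
  level[observed] <- "observed"
  new("PoolAssignment", species = regional,
      level = factor(level, levels = c("environmentally_excluded",
                                       "dark_diversity", "observed")),
      inHabitatPool = regional %in% pool,
      focalSite = focalSite, minSites = 2L)
}

# Independently coded iteratively reweighted least squares for logistic
# regression (the oracle the glm-based fits are checked against).
irlsLogistic <- function(X, y, tol = 1e-12, maxit = 200) {
  X <- cbind(1, X)
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    betaNew <- solve(crossprod(X, X * W), crossprod(X, W * z))
    if (max(abs(betaNew - beta)) < tol) {
      beta <- drop(betaNew)
      break
    }
    beta <- drop(betaNew)
  }
  beta
}

# Brute-force neighborhood distance: sort all distances, average the k
# smallest.
bruteNeighborhood <- function(d, k) mean(sort(d)[seq_len(k)])

# A tiny deterministic filter model with known coefficients, for closed-form
# prediction checks. Constants are identity (center 0, scale 1).
toyModel <- function(filter, mains, beta0, beta,
                     plotIntercepts = numeric(0)) {
  ct <- matrix(NA_real_, length(mains) + 1, 4,
               dimnames = list(c("(Intercept)", mains),
                               c("estimate", "se", "z", "p")))
  ct[, "estimate"] <- c(beta0, beta)
  new("FilterModel", filter = filter,
      neighborhood = resolveNeighborhood(1.0, 10L),
      scheme = "none", mains = mains, interactions = character(0),
      coefTable = ct,
      constants = list(mains = list(center = setNames(rep(0, length(mains)),
                                                      mains),
                                    scale = setNames(rep(1, length(mains)),
                                                     mains),
                                    constant = setNames(
                                      rep(FALSE, length(mains)), mains)),
                       inters = NULL),
      logLik = 0, n = 10L, nParams = length(beta) + 1L, aicc = 0,
      reVariance = if (filter == "biotic") 0.5 else NA_real_,
      plotIntercepts = plotIntercepts,
      converged = TRUE, degenerate = FALSE,
      degeneracyReasons = character(0))
}

# CSV fixture writer for reader tests.
writeFixtureCsvs <- function(dir,
                             traits = data.frame(
                               species_id = c("a", "b", "c"),
                               height = c(10, 20, 30),
                               sla = c(5, 10, 20)),
                             occurrences = data.frame(
                               site_id = c("f", "f", "s1", "s1"),
                               species_id = c("a", "b", "a", "c")),
                             community = data.frame(
                               plot_id = c("p1", "p1", "p2"),
                               site_id = "f",
                               species_id = c("a", "b", "a"),
                               count = c(3L, 1L, 2L)),
                             colonists = data.frame(
                               species_id = "z", site_id = "f",
                               plot_id = c("p1", "p2"),
                               seeds_added = 15L,
                               plants_year3 = c(3L, 6L)),
                             regional = data.frame(
                               species_id = c("a", "b", "c", "d"))) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in c("traits", "occurrences", "community", "colonists",
               "regional")) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".csv"))
    write.csv(get(nm), paths[[nm]], row.names = FALSE)
  }
  paths
}
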