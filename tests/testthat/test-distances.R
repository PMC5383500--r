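test_that("Gower dissimilarity is the mean absolute trait difference", {
  expect_equal(gowerDistance(c(0.2, 0.5, 0.9), c(0.2, 0.7, 0.5)), 0.2)
  expect_equal(gowerDistance(c(0.3, 0.1), c(0.3, 0.1)), 0)
  expect_equal(gowerDistance(0, 1), 1)
  # brute-force oracle over random pairs
  set.seed(1)
  for (i in 1:50) {
    a <- runif(5); b <- runif(5)
    expect_equal(gowerDistance(a, b), sum(abs(a - b)) / 5,
                 tolerance = 1e-12)
  }
  expect_error(gowerDistance(NA, 1), "no shared complete traits")
})

test_that("distance tensors are symmetric, bounded, zero on the diagonal", {
  tt <- randomTraitTable(20, 4, seed = 7)
  dt <- traitDistances(tt)
  for (m in c(dt@perTrait, list(dt@multivariate))) {
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 20))
  }
  # triangle inequality on random triples of the multivariate matrix
  set.seed(8)
  m <- dt@multivariate
  for (i in 1:200) {
    ijk <- sample(20, 3)
    expect_lte(m[ijk[1], ijk[3]],
               m[ijk[1], ijk[2]] + m[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("neighborhood sizes resolve with round-up and the NN special case", {
  expect_equal(neighborhoodK(resolveNeighborhood(0.3, 87)), 27)
  expect_equal(neighborhoodK(resolveNeighborhood(1.0, 228)), 228)
  expect_equal(neighborhoodK(resolveNeighborhood("NN", 228)), 1)
  expect_equal(neighborhoodK(resolveNeighborhood(0.2, 5)), 1)
  expect_equal(neighborhoodK(resolveNeighborhood(0.1, 1)), 1)
  expect_error(resolveNeighborhood(0.25, 87), "proportion")
  expect_error(resolveNeighborhood(0, 87), "proportion")
  expect_error(resolveNeighborhood(1.1, 87), "proportion")
})

test_that("neighborhood distance equals the sort-and-average oracle", {
  expect_equal(neighborhoodDistance(c(a = 0.05, b = 0.10, c = 0.30,
                                      d = 0.55), 2), 0.075)
  set.seed(11)
  for (i in 1:20) {
    d <- setNames(runif(15), sprintf("s%02d", 1:15))
    for (k in 1:15)
      expect_equal(neighborhoodDistance(d, k), bruteNeighborhood(d, k),
                   tolerance = 1e-12)
    expect_equal(neighborhoodDistance(d, 1), min(d))
    expect_equal(neighborhoodDistance(d, 15), mean(d))
  }
  expect_error(neighborhoodDistance(numeric(0), 1), "empty")
  expect_error(neighborhoodDistance(c(a = 1), 2), "between")
})

test_that("neighborhood distance is non-decreasing in k (NN <= ... <= MP)", {
  set.seed(13)
  for (i in 1:100) {
    d <- runif(sample(3:40, 1))
    v <- vapply(seq_along(d), function(k) neighborhoodDistance(d, k),
                numeric(1))
    expect_true(all(diff(v) >= -1e-12))
    expect_equal(v[1], min(d))
    expect_equal(v[length(d)], mean(d))
  }
})

test_that("environmental design rows match per-species recomputation", {
  tt <- randomTraitTable(40, 3, seed = 21)
  ids <- speciesIds(tt)
  poolSp <- ids[1:15]
  pool <- makePool(ids, poolSp, observed = poolSp[1:5])
  tm <- traitMatrix(tt)
  for (size in list("NN", 0.3, 1.0)) {
    des <- envPredictorMatrix(pool, tt, size)
    spec <- attr(des, "neighborhood")
    expect_equal(spec@n, 15L)
    for (i in seq_len(nrow(des))) {
      sp <- des$species[i]
      expect_equal(des$response[i], as.integer(sp %in% poolSp))
      for (tr in colnames(tm)) {
        d <- abs(tm[sp, tr] - tm[setdiff(poolSp, sp), tr])
        keff <- min(spec@k, length(d))
        expect_equal(des[[tr]][i], bruteNeighborhood(d, keff),
                     tolerance = 1e-12, label = paste(size, sp, tr))
      }
    }
  }
})

test_that("a pool member identical to its neighbors has zero distances", {
  tm <- rbind(matrix(0.5, 5, 2), matrix(runif(20), 10, 2))
  tm <- apply(tm, 2, function(v) (v - min(v)) / (max(v) - min(v)))
  dimnames(tm) <- list(sprintf("s%02d", 1:15), c("t1", "t2"))
  tt <- new("TraitTable", traits = tm,
            traitKind = setNames(rep("continuous", 2), colnames(tm)),
            transformLog = setNames(rep(FALSE, 2), colnames(tm)),
            standardized = TRUE,
            ranges = matrix(rep(c(0, 1), 2), 2,
                            dimnames = list(c("min", "max"), colnames(tm))),
            referenceSpecies = rownames(tm))
  clones <- rownames(tm)[tm[, 1] == tm[1, 1] & tm[, 2] == tm[1, 2]]
  pool <- makePool(rownames(tm), clones, observed = clones[1])
  des <- envPredictorMatrix(pool, tt, 0.3)  # k = 2 of 5, all clones
  row <- des[des$species == clones[1], ]
  expect_equal(row$t1, 0)
  expect_equal(row$t2, 0)
  expect_equal(row$response, 1L)
})

test_that("centering constants are flat averages excluding self-pairs", {
  # two distances -> their mean
  tm <- matrix(c(0.0, 0.1, 0.3), 3, 1,
               dimnames = list(c("obs", "p1", "p2"), "t1"))
  tt <- new("TraitTable", traits = tm,
            traitKind = c(t1 = "continuous"),
            transformLog = c(t1 = FALSE), standardized = TRUE,
            ranges = matrix(c(0, 1), 2, dimnames = list(c("min", "max"),
                                                        "t1")),
            referenceSpecies = rownames(tm))
  pool <- makePool(rownames(tm), c("obs", "p1", "p2"), observed = "obs")
  community <- data.frame(plot_id = "p", site_id = "f",
                          species_id = "obs", count = 1L)
  ctr <- computeCenter(pool, tt, community)
  expect_equal(unname(ctr["t1"]), mean(c(0.1, 0.3)))

  # random fixture equals an independent flat-average oracle
  tt2 <- randomTraitTable(20, 2, seed = 31)
  ids <- speciesIds(tt2)
  pool2 <- makePool(ids, ids[1:10], observed = ids[1:4])
  comm2 <- data.frame(plot_id = rep(c("p1", "p2"), each = 4),
                      site_id = "f",
                      species_id = ids[c(1:4, 3:6)], count = 1L)
  ctr2 <- computeCenter(pool2, tt2, comm2)
  tm2 <- traitMatrix(tt2)
  obs <- unique(comm2$species_id)
  for (tr in colnames(tm2)) {
    acc <- c()
    for (p in ids[1:10]) for (o in obs)
      if (p != o) acc <- c(acc, abs(tm2[p, tr] - tm2[o, tr]))
    expect_equal(unname(ctr2[tr]), mean(acc), tolerance = 1e-12)
  }
})

test_that("centered weighted distances follow the worked examples", {
  # counts 3 and 1 (weights .75/.25), distances .2/.6, center .3, k = 2
  expect_equal(centeredWeightedDistance(c(a = 0.2, b = 0.6), c(a = 3, b = 1),
                                        center = 0.3, k = 2), 0)
  # single observed species: value = d - center
  expect_equal(centeredWeightedDistance(c(a = 0.45), c(a = 7),
                                        center = 0.3, k = 1), 0.15)
  # equal abundances, k = all: mean of centered distances
  d <- c(a = 0.1, b = 0.5, c = 0.6)
  expect_equal(centeredWeightedDistance(d, c(a = 2, b = 2, c = 2),
                                        center = 0.4, k = 3),
               mean(d - 0.4))
  # self-exclusion renormalizes the remaining weights
  expect_equal(centeredWeightedDistance(c(a = 0, b = 0.6), c(a = 5, b = 1),
                                        center = 0.3, k = 1, target = "a"),
               0.3)
})

test_that("weighted distances are invariant to rescaling all counts", {
  set.seed(41)
  d <- setNames(runif(8), letters[1:8])
  counts <- setNames(sample(1:20, 8, replace = TRUE), letters[1:8])
  for (k in c(1, 3, 8)) {
    v1 <- centeredWeightedDistance(d, counts, center = 0.4, k = k)
    v2 <- centeredWeightedDistance(d, counts * 17, center = 0.4, k = k)
    expect_equal(v1, v2, tolerance = 1e-12)
  }
})

test_that("biotic design rows match per-row recomputation", {
  tt <- randomTraitTable(25, 2, seed = 51)
  ids <- speciesIds(tt)
  poolSp <- ids[1:12]
  set.seed(52)
  community <- do.call(rbind, lapply(1:4, function(p) {
    sp <- sample(poolSp[1:6], 4)
    data.frame(plot_id = paste0("p", p), site_id = "f", species_id = sp,
               count = sample(1:9, 4, replace = TRUE))
  }))
  pool <- makePool(ids, poolSp, observed = unique(community$species_id))
  ctr <- computeCenter(pool, tt, community)
  tm <- traitMatrix(tt)
  for (size in list("NN", 0.3, 1.0)) {
    des <- bioticPredictorMatrix(pool, tt, community, size, center = ctr)
    for (i in seq_len(nrow(des))) {
      sp <- des$species[i]
      pl <- community[community$plot_id == des$plot[i], ]
      obs <- setdiff(pl$species_id, sp)
      nref <- length(obs)
      k <- if (identical(size, "NN")) 1 else ceiling(size * nref - 1e-9)
      for (tr in colnames(tm)) {
        dv <- setNames(abs(tm[sp, tr] - tm[pl$species_id, tr]),
                       pl$species_id)
        cw <- centeredWeightedDistance(dv, setNames(pl$count, pl$species_id),
                                       center = ctr[[tr]],
                                       k = max(1, min(k, nref)), target = sp)
        expect_equal(des[[tr]][i], cw, tolerance = 1e-12,
                     label = paste(size, sp, des$plot[i], tr))
      }
      expect_equal(des$response[i], as.integer(sp %in% pl$species_id))
    }
  }
})

test_that("precomputed distance matrices act as a single trait", {
  tt <- randomTraitTable(12, 2, seed = 61)
  ids <- speciesIds(tt)
  m <- as.matrix(dist(traitMatrix(tt))) / sqrt(2)
  dimnames(m) <- list(ids, ids)
  pool <- makePool(ids, ids[1:6], observed = ids[1:2])
  des <- envPredictorMatrix(pool, tt, 1.0, precomputed = list(phylo = m))
  expect_true("phylo" %in% names(des))
  # mean pairwise distance to the pool, self-excluded
  i <- which(des$species == ids[1])
  expect_equal(des$phylo[i], mean(m[ids[1], ids[2:6]]), tolerance = 1e-12)
})
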