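#' @include distances.R
NULL

.sampleSd <- function(x) stats::sd(x)

#' Z-score a predictor matrix
#'
#' Columns are centered and scaled to unit sample standard deviation
#' (n - 1 denominator). Constant columns are flagged and zeroed (retained so
#' that term bookkeeping stays aligned); when `constants` are supplied the
#' stored transformation is applied instead (used at prediction time).
#'
#' @param X numeric matrix.
#' @param constants optional list with `center`, `scale`, `constant` from a
#'   previous call.
#' @return list with the standardized matrix `Z` and the constants.
#' @export
standardizePredictors <- function(X, constants = NULL) {
  X <- as.matrix(X)
  if (is.null(constants)) {
    center <- colMeans(X)
    scale <- apply(X, 2, .sampleSd)
    constant <- !is.finite(scale) | scale < 1e-12
    scale[constant] <- 1
    constants <- list(center = center, scale = scale, constant = constant)
  }
  Z <- sweep(sweep(X, 2, constants$center, "-"), 2, constants$scale, "/")
  Z[, constants$constant] <- 0
  list(Z = Z, constants = constants)
}

# Interaction terms for a scheme. Pairwise interactions among ordinal traits
# can be excluded (they often lack distance variation at small neighborhood
# sizes and prevent convergence).
.interactionTerms <- function(mains, scheme, kind = NULL,
                              excludeOrdinalPairs = FALSE) {
  if (scheme == "none" || length(mains) < 2) return(character(0))
  pairs <- utils::combn(mains, 2)
  keep <- rep(TRUE, ncol(pairs))
  if (excludeOrdinalPairs && !is.null(kind))
    keep <- !(kind[pairs[1, ]] == "ordinal" & kind[pairs[2, ]] == "ordinal")
  apply(pairs[, keep, drop = FALSE], 2, paste, collapse = ":")
}

# Standardized design with interaction columns. Interactions are products of
# z-scored mains, themselves z-scored. Returns matrix Z (display term names),
# constants, and constant-column flags.
.buildDesign <- function(df, mains, inters, constants = NULL) {
  sm <- standardizePredictors(as.matrix(df[mains]),
                              constants = constants$mains)
  Z <- sm$Z
  interConst <- NULL
  if (length(inters)) {
    parts <- strsplit(inters, ":", fixed = TRUE)
    raw <- vapply(parts, function(p) sm$Z[, p[1]] * sm$Z[, p[2]],
                  numeric(nrow(sm$Z)))
    raw <- matrix(raw, nrow = nrow(sm$Z),
                  dimnames = list(NULL, inters))
    si <- standardizePredictors(raw, constants = constants$inters)
    Z <- cbind(Z, si$Z)
    interConst <- si$constants
  }
  colnames(Z) <- c(mains, inters)
  list(Z = Z,
       constants = list(mains = sm$constants, inters = interConst),
       constantCols = c(sm$constants$constant,
                        if (length(inters)) interConst$constant))
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1). Reduces to AIC as n grows.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return AICc; +Inf with a warning when n <= k + 1.
#' @examples
#' computeAICc(-10, 3, 20)  # 27.5
#' @export
computeAICc <- function(loglik, k, n) {
  if (n <= k + 1) {
    warning("n <= k + 1; AICc undefined, returning Inf")
    return(Inf)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Fit one filter model (environmental: logistic; biotic: binomial mixed with
# plot random intercept). design must have a response column, the predictor
# columns, and for biotic fits a plot column.
.fitFilter <- function(design, filter, neighborhood, scheme, mains, inters) {
  bd <- .buildDesign(design, mains, inters)
  terms <- c(mains, inters)
  internal <- if (length(terms)) paste0("x", seq_along(terms))
              else character(0)
  dat <- as.data.frame(bd$Z)
  names(dat) <- internal
  dat$response <- design$response
  reasons <- character(0)
  if (any(bd$constantCols))
    reasons <- c(reasons, "constant predictor column")
  warns <- character(0)
  handler <- function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  reVar <- NA_real_
  plotInt <- numeric(0)
  converged <- FALSE
  fitGlm <- function(d) {
    withCallingHandlers(
      stats::glm(response ~ ., data = d, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      warning = handler)
  }
  if (filter == "environmental") {
    fit <- fitGlm(dat)
    converged <- isTRUE(fit$converged)
    sm <- summary(fit)$coefficients
    beta <- stats::coef(fit)
    ll <- as.numeric(stats::logLik(fit))
    nPar <- sum(!is.na(beta))
  } else {
    dat$plot <- factor(design$plot)
    if (nlevels(dat$plot) < 2)
      stop("biotic model needs at least 2 plots")
    form <- stats::as.formula(paste(
      "response ~", paste(internal, collapse = " + "), "+ (1 | plot)"))
    fit <- tryCatch(
      withCallingHandlers(
        suppressMessages(
          lme4::glmer(form, data = dat, family = stats::binomial())),
        warning = handler),
      error = function(e) e)
    fellBack <- FALSE
    if (!inherits(fit, "error")) {
      reVar <- as.numeric(lme4::VarCorr(fit)$plot[1])
      if (reVar < 1e-8) fellBack <- TRUE
    }
    if (inherits(fit, "error") || fellBack) {
      # zero (or failed) random-intercept variance: plain logistic fallback
      fit <- fitGlm(dat[setdiff(names(dat), "plot")])
      reVar <- 0
      plotInt <- stats::setNames(rep(0, nlevels(dat$plot)),
                                 levels(dat$plot))
      reasons <- c(reasons, "zero RE variance")
      converged <- isTRUE(fit$converged)
      sm <- summary(fit)$coefficients
      beta <- stats::coef(fit)
      ll <- as.numeric(stats::logLik(fit))
      nPar <- sum(!is.na(beta))
    } else {
      converged <- length(fit@optinfo$conv$lme4) == 0 &&
        fit@optinfo$conv$opt == 0
      sm <- summary(fit)$coefficients
      beta <- lme4::fixef(fit)
      ll <- as.numeric(stats::logLik(fit))
      nPar <- length(beta) + 1L
      b <- lme4::ranef(fit)$plot
      plotInt <- stats::setNames(b[["(Intercept)"]], rownames(b))
    }
  }
  if (any(grepl("fitted probabilities numerically 0 or 1", warns)) &&
      max(abs(beta), na.rm = TRUE) > 10) {
    reasons <- c(reasons, "separation")
    converged <- FALSE
  }
  coefTab <- matrix(NA_real_, length(terms) + 1, 4,
                    dimnames = list(c("(Intercept)", terms),
                                    c("estimate", "se", "z", "p")))
  full <- c("(Intercept)", internal)
  present <- intersect(rownames(sm), full)
  coefTab[match(present, full), ] <- sm[present, , drop = FALSE]
  coefTab[match(names(beta), full), "estimate"] <- as.numeric(beta)
  n <- nrow(dat)
  ai <- if (converged) computeAICc(ll, nPar, n) else Inf
  new("FilterModel",
      filter = filter, neighborhood = neighborhood, scheme = scheme,
      mains = mains, interactions = inters,
      coefTable = coefTab, constants = bd$constants,
      logLik = ll, n = as.integer(n), nParams = as.integer(nPar), aicc = ai,
      reVariance = reVar, plotIntercepts = plotInt,
      converged = converged, degenerate = length(reasons) > 0,
      degeneracyReasons = unique(reasons))
}

#' Fit the environmental-filtering logistic model
#'
#' Logistic regression of habitat-pool membership (pool members are
#' successes, environmentally excluded species failures) on per-trait
#' functional neighborhood distances, with optional pairwise trait
#' interactions. Predictors are z-scored; interactions among ordinal traits
#' are excluded by default (they often have too little distance variation at
#' small neighborhood sizes to allow convergence).
#'
#' @param design output of [envPredictorMatrix()].
#' @param scheme "none", "all_pairwise" or "parsimonious" (the latter is the
#'   all-pairwise fit followed by [backwardEliminate()]).
#' @param kind optional named character of trait kinds (for the ordinal
#'   exclusion rule).
#' @param excludeOrdinalPairs drop ordinal x ordinal interactions (default
#'   TRUE).
#' @param interactions explicit interaction terms overriding the scheme.
#' @return a [FilterModel-class].
#' @export
fitEnvModel <- function(design, scheme = c("none", "all_pairwise",
                                           "parsimonious"),
                        kind = NULL, excludeOrdinalPairs = TRUE,
                        interactions = NULL) {
  scheme <- match.arg(scheme)
  mains <- setdiff(names(design), c("species", "response", "plot"))
  if (length(unique(design$response)) < 2)
    stop("both pool members and excluded species are required")
  nb <- attr(design, "neighborhood")
  if (is.null(nb)) nb <- resolveNeighborhood(1.0, sum(design$response == 1))
  inters <- if (!is.null(interactions)) interactions else
    .interactionTerms(mains, if (scheme == "parsimonious") "all_pairwise"
                      else scheme,
                      kind = kind, excludeOrdinalPairs = excludeOrdinalPairs)
  fit <- .fitFilter(design, "environmental", nb,
                    if (scheme == "parsimonious") "all_pairwise" else scheme,
                    mains, inters)
  if (scheme == "parsimonious") fit <- backwardEliminate(fit, design)
  fit
}

#' Fit the biotic-filtering binomial mixed model
#'
#' Binomial mixed model over habitat-pool species x plots: presence in the
#' observed plot community as response, centered abundance-weighted
#' neighborhood distances per trait as fixed effects, and plot identity as a
#' random intercept (Laplace approximation via lme4). When the estimated
#' random-intercept variance collapses to zero the model is refit as a plain
#' logistic regression and flagged ("zero RE variance") but remains usable.
#'
#' @param design output of [bioticPredictorMatrix()].
#' @inheritParams fitEnvModel
#' @return a [FilterModel-class].
#' @export
fitBioticModel <- function(design, scheme = c("none", "all_pairwise",
                                              "parsimonious"),
                           kind = NULL, excludeOrdinalPairs = FALSE,
                           interactions = NULL) {
  scheme <- match.arg(scheme)
  mains <- setdiff(names(design), c("species", "response", "plot"))
  if (length(unique(design$response)) < 2)
    stop("both presences and absences are required")
  nb <- attr(design, "neighborhood")
  if (is.null(nb))
    nb <- resolveNeighborhood(1.0, length(unique(design$species)))
  inters <- if (!is.null(interactions)) interactions else
    .interactionTerms(mains, if (scheme == "parsimonious") "all_pairwise"
                      else scheme,
                      kind = kind, excludeOrdinalPairs = excludeOrdinalPairs)
  fit <- .fitFilter(design, "biotic", nb,
                    if (scheme == "parsimonious") "all_pairwise" else scheme,
                    mains, inters)
  if (scheme == "parsimonious") fit <- backwardEliminate(fit, design)
  fit
}

#' Greedy backward elimination of interaction terms by AICc
#'
#' Starting from a fitted model, repeatedly drops the single interaction term
#' whose removal most lowers the AICc, stopping when no removal lowers it.
#' Main effects are never dropped. With `exhaustive = TRUE` (possible for up
#' to 6 interaction terms) all interaction subsets are scored instead.
#'
#' @param model a [FilterModel-class] fitted with interactions.
#' @param design the design the model was fitted to.
#' @param exhaustive search all interaction subsets instead of greedily.
#' @return the most parsimonious [FilterModel-class] (scheme "parsimonious").
#' @export
backwardEliminate <- function(model, design, exhaustive = FALSE) {
  refit <- function(inters) .fitFilter(design, model@filter,
                                       model@neighborhood, "parsimonious",
                                       model@mains, inters)
  best <- model
  if (exhaustive) {
    if (length(model@interactions) > 6)
      stop("exhaustive search supported for at most 6 interaction terms")
    subsets <- unlist(lapply(0:length(model@interactions), function(m)
      utils::combn(model@interactions, m, simplify = FALSE)), recursive = FALSE)
    for (s in subsets) {
      cand <- refit(s)
      if (cand@aicc < best@aicc) best <- cand
    }
  } else {
    repeat {
      if (!length(best@interactions)) break
      cands <- lapply(seq_along(best@interactions), function(i)
        refit(best@interactions[-i]))
      ai <- vapply(cands, function(m) m@aicc, numeric(1))
      if (min(ai) >= best@aicc) break
      best <- cands[[which.min(ai)]]
    }
  }
  best@scheme <- "parsimonious"
  best
}

#' Degeneracy diagnostics for a fitted filter model
#'
#' Flags (a) runaway estimates: any standardized coefficient with
#' |estimate| > 10 and p > .95 (a symptom of too little distance variation,
#' typical of nearest-neighbor fits); (b) insufficient distance variation:
#' any raw predictor whose sd / mean(|x|) falls below 0.01; (c) separation
#' and constant-column flags recorded at fit time.
#'
#' @param model a [FilterModel-class].
#' @param design the raw design the model was fitted to (for flag b);
#'   optional.
#' @return character vector of flags (empty when well-conditioned).
#' @export
diagnoseModel <- function(model, design = NULL) {
  flags <- character(0)
  ct <- model@coefTable
  est <- ct[-1, "estimate"]
  p <- ct[-1, "p"]
  if (any(!is.na(est) & !is.na(p) & abs(est) > 10 & p > 0.95))
    flags <- c(flags, "runaway estimate")
  if (!is.null(design)) {
    for (t in model@mains) {
      x <- design[[t]]
      m <- mean(abs(x))
      if (m > 0 && .sampleSd(x) / m < 0.01)
        flags <- c(flags, "insufficient distance variation")
    }
  }
  unique(c(flags, model@degeneracyReasons))
}

.clampProb <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

# Linear predictor from raw (unstandardized) predictor columns using the
# model's stored constants. NA (aliased) coefficients contribute zero.
.linearPredictor <- function(model, newdata) {
  bd <- .buildDesign(newdata, model@mains, model@interactions,
                     constants = model@constants)
  beta <- model@coefTable[, "estimate"]
  beta[is.na(beta)] <- 0
  drop(beta[1] + bd$Z %*% beta[-1])
}

#' Predict environmental-filter passage for new species
#'
#' Applies the fitted environmental model to new species (e.g. added
#' colonists). Predictors must have been computed with the model's own
#' neighborhood specification ([envPredictorMatrix()] with the same `size`);
#' the stored standardization constants are applied internally.
#'
#' @param model an environmental [FilterModel-class].
#' @param newdata design rows with the model's raw predictor columns.
#' @return named numeric vector of probabilities in (0, 1).
#' @export
predictEnv <- function(model, newdata) {
  stopifnot(model@filter == "environmental")
  p <- .clampProb(stats::plogis(.linearPredictor(model, newdata)))
  stats::setNames(p, newdata$species)
}

#' Predict biotic-filter passage for a colonist
#'
#' Computes a per-plot establishment probability (the colonist treated as
#' absent from every plot) and their arithmetic mean. By default the
#' estimated plot-specific random intercepts are used (plots are known
#' units); `rePrediction = "population"` sets them to zero.
#'
#' @param model a biotic [FilterModel-class].
#' @param newdata design rows (one per species x plot) with a `plot` column
#'   and the model's raw predictor columns.
#' @param rePrediction "plot" or "population".
#' @return list with `perPlot` (data.frame species, plot, p) and `average`
#'   (named numeric, mean probability per species).
#' @export
predictBiotic <- function(model, newdata,
                          rePrediction = c("plot", "population")) {
  stopifnot(model@filter == "biotic")
  rePrediction <- match.arg(rePrediction)
  eta <- .linearPredictor(model, newdata)
  if (rePrediction == "plot" && length(model@plotIntercepts)) {
    b <- model@plotIntercepts[as.character(newdata$plot)]
    b[is.na(b)] <- 0
    eta <- eta + b
  }
  perPlot <- data.frame(species = newdata$species,
                        plot = newdata$plot,
                        p = .clampProb(stats::plogis(eta)),
                        stringsAsFactors = FALSE)
  avg <- tapply(perPlot$p, perPlot$species, mean)
  list(perPlot = perPlot,
       average = stats::setNames(as.numeric(avg), names(avg)))
}

#' @rdname accessors
#' @export
setMethod("coefTable", "FilterModel", function(object, ...)
  object@coefTable)

#' @rdname accessors
#' @export
setMethod("aicc", "FilterModel", function(object, ...) object@aicc)

#' @rdname accessors
#' @export
setMethod("isConverged", "FilterModel", function(object, ...)
  object@converged)

#' @rdname accessors
#' @export
setMethod("isDegenerate", "FilterModel", function(object, ...)
  object@degenerate)

#' @rdname accessors
#' @export
setMethod("modelTerms", "FilterModel", function(object, ...)
  c(object@mains, object@interactions))

setMethod("show", "FilterModel", function(object) {
  cat(sprintf("FilterModel (%s), neighborhood %s, scheme %s\n",
              object@filter, object@neighborhood@label, object@scheme))
  cat(sprintf("  n = %d, params = %d, logLik = %.3f, AICc = %.3f\n",
              object@n, object@nParams, object@logLik, object@aicc))
  if (!is.na(object@reVariance))
    cat(sprintf("  plot random-intercept variance = %.4f\n",
                object@reVariance))
  cat("  converged:", object@converged,
      if (object@degenerate)
        paste0(" | flags: ", paste(object@degeneracyReasons, collapse = ", "))
      else "", "\n")
  print(round(object@coefTable, 3))
})

#' Export a fitted model as structured text (JSON)
#'
#' @param model a [FilterModel-class].
#' @param path file to write; when NULL the JSON string is returned.
#' @return the path (invisibly) or the JSON string.
#' @export
writeModelJson <- function(model, path = NULL) {
  obj <- list(
    filter = model@filter,
    neighborhood = list(label = model@neighborhood@label,
                        p = model@neighborhood@p,
                        k = model@neighborhood@k, n = model@neighborhood@n),
    scheme = model@scheme,
    terms = list(mains = model@mains, interactions = model@interactions),
    coefficients = c(list(term = rownames(model@coefTable)),
                     as.list(as.data.frame(model@coefTable))),
    constants = model@constants,
    logLik = model@logLik, n = model@n, nParams = model@nParams,
    aicc = model@aicc, reVariance = model@reVariance,
    plotIntercepts = as.list(model@plotIntercepts),
    converged = model@converged, degenerate = model@degenerate,
    reasons = model@degeneracyReasons)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
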