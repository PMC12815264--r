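# Environmental modelling of per-sample HGT prevalence: redundancy
# filtering, correlation-distance clustering of variables, random forest
# with shuffle-null permutation-importance significance, ICE curves and
# Friedman-Popescu H-statistics.

#' Drop redundant environmental variables
#'
#' Greedy filter in the listed column order: a variable is dropped when its
#' absolute Spearman correlation with an already-retained variable reaches
#' \code{rhoThreshold}; the retained representative is recorded.
#'
#' @param env data.frame of numeric variables (>= 2 columns).
#' @param rhoThreshold redundancy cut-off (default 0.95, inclusive).
#' @return list with \code{retained} (variable names) and \code{dropped}
#'   (data.frame: variable, representative, rho).
#' @export
dedupeEnv <- function(env, rhoThreshold = 0.95) {
    vars <- names(env)
    if (length(vars) < 2L) stop("need at least 2 variables")
    retained <- character()
    dropped <- list()
    for (v in vars) {
        rho <- vapply(retained, function(r)
            suppressWarnings(cor(env[[v]], env[[r]], method = "spearman")),
            numeric(1))
        hit <- which(abs(rho) >= rhoThreshold - 1e-12)
        if (length(hit)) {
            dropped[[length(dropped) + 1L]] <-
                data.frame(variable = v, representative = retained[hit[1L]],
                           rho = rho[hit[1L]], stringsAsFactors = FALSE)
        } else {
            retained <- c(retained, v)
        }
    }
    list(retained = retained,
         dropped = if (length(dropped)) do.call(rbind, dropped) else
             data.frame(variable = character(),
                        representative = character(), rho = numeric()))
}

#' Hierarchical clustering of environmental variables
#'
#' Pairwise distance |1 - Spearman's rho| (note anticorrelated pairs land
#' near distance 2) with average-linkage (UPGMA) clustering. Deterministic
#' and invariant to column order up to relabeling.
#'
#' @param env data.frame of numeric variables (>= 3 columns).
#' @return an \code{hclust} object over the variables.
#' @export
envDistanceCluster <- function(env) {
    if (ncol(env) < 3L) stop("need at least 3 variables")
    constant <- names(env)[vapply(env, function(x) var(x) == 0, logical(1))]
    if (length(constant))
        stop("constant variable(s) with undefined correlations: ",
             paste(constant, collapse = ", "))
    rho <- cor(env, method = "spearman")
    d <- as.dist(abs(1 - rho))
    hclust(d, method = "average")
}

#' Random-forest regression of HGT prevalence on environment
#'
#' Regression forest with permutation variable importance (mean out-of-bag
#' error increase when a variable is shuffled) and out-of-bag R^2.
#' Deterministic for a fixed seed (single-threaded).
#'
#' @param env data.frame of predictor variables.
#' @param response numeric response (per-sample HGT prevalence).
#' @param nTrees number of trees (default 10000).
#' @param mtry variables tried per split; default floor(sqrt(p)), i.e. 3 for
#'   12 predictors.
#' @param seed integer RNG seed.
#' @return list with \code{model} (the \code{ranger} fit), \code{oob_r2},
#'   \code{importance} (named vector) and \code{mtry}.
#' @export
fitRf <- function(env, response, nTrees = 10000L, mtry = NULL, seed = 1L) {
    if (!ncol(env)) stop("no predictors")
    if (length(response) < 30L) stop("need at least 30 samples")
    if (is.null(mtry)) mtry <- max(1L, as.integer(floor(sqrt(ncol(env)))))
    mtry <- as.integer(mtry)
    dat <- data.frame(.y = response, env, check.names = FALSE)
    fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                          num.trees = nTrees, mtry = mtry,
                          importance = "permutation", seed = seed,
                          num.threads = 1L)
    list(model = fit, oob_r2 = fit$r.squared,
         importance = fit$variable.importance, mtry = mtry)
}

#' Shuffle-null significance of random-forest variable importance
#'
#' Refits the forest \code{nReplicates} times with the response permuted,
#' building a per-variable null distribution of permutation importance. The
#' p-value is (count of null >= observed + 1) / (nReplicates + 1) by default
#' (the add-one convention avoids zero p-values; \code{plusOne = FALSE}
#' yields the plain proportion). BH correction is applied across variables.
#' Null forests may use fewer trees than the observed fit
#' (\code{nullTrees}).
#'
#' @inheritParams fitRf
#' @param nReplicates number of response permutations (>= 100 advised).
#' @param nullTrees trees per null forest (default 500).
#' @param alpha BH significance level.
#' @param plusOne logical; use the add-one p-value convention.
#' @return data.frame: \code{variable}, \code{observed_importance},
#'   \code{null_q50}, \code{null_q95}, \code{p}, \code{q},
#'   \code{significant}, \code{direction} (sign of Spearman correlation with
#'   the response, annotation only).
#' @export
importanceNullTest <- function(env, response, nTrees = 10000L,
                               nullTrees = 500L, nReplicates = 1000L,
                               mtry = NULL, seed = 1L, alpha = 0.05,
                               plusOne = TRUE) {
    if (nReplicates < 100L)
        warning("fewer than 100 replicates: p-value resolution is coarse")
    obs <- fitRf(env, response, nTrees = nTrees, mtry = mtry, seed = seed)
    set.seed(seed)
    repSeeds <- sample.int(.Machine$integer.max - 1L, nReplicates)
    nullImp <- matrix(NA_real_, nReplicates, ncol(env),
                      dimnames = list(NULL, names(env)))
    for (r in seq_len(nReplicates)) {
        set.seed(repSeeds[r])
        yPerm <- sample(response)
        f <- fitRf(env, yPerm, nTrees = nullTrees, mtry = mtry,
                   seed = repSeeds[r])
        nullImp[r, ] <- f$importance[names(env)]
    }
    geObs <- vapply(names(env), function(v)
        sum(nullImp[, v] >= obs$importance[[v]]), numeric(1))
    p <- if (plusOne) (geObs + 1) / (nReplicates + 1) else
        geObs / nReplicates
    q <- p.adjust(p, method = "BH")
    dirRho <- vapply(names(env), function(v)
        suppressWarnings(cor(env[[v]], response, method = "spearman")),
        numeric(1))
    data.frame(variable = names(env),
               observed_importance = unname(obs$importance[names(env)]),
               null_q50 = apply(nullImp, 2L, median),
               null_q95 = apply(nullImp, 2L, quantile, probs = 0.95),
               p = unname(p), q = unname(q), significant = unname(q < alpha),
               direction = ifelse(dirRho >= 0, "positive", "negative"),
               stringsAsFactors = FALSE, row.names = NULL)
}

.rfPredict <- function(model, data)
    predict(model, data = data, num.threads = 1L)$predictions

#' Individual Conditional Expectation curves
#'
#' For every sample, the model prediction as one variable sweeps a grid with
#' all other variables held at their observed values. The mean ICE curve
#' equals the partial-dependence curve.
#'
#' @param fit a \code{\link{fitRf}} result (or bare \code{ranger} model).
#' @param env the training predictor data.frame.
#' @param variable variable to sweep.
#' @param grid numeric grid; default 25 equally spaced points over the
#'   observed range. Values outside the observed range are allowed but
#'   flagged as extrapolation.
#' @return list with \code{grid}, \code{curves} (samples x grid matrix),
#'   \code{pd} (mean curve) and \code{extrapolated} (logical per grid
#'   point).
#' @export
iceCurves <- function(fit, env, variable, grid = NULL) {
    model <- if (is.list(fit) && !is.null(fit$model)) fit$model else fit
    if (!variable %in% names(env)) stop("unknown variable: ", variable)
    x <- env[[variable]]
    if (is.null(grid))
        grid <- seq(min(x), max(x), length.out = 25L)
    extrap <- grid < min(x) | grid > max(x)
    if (any(extrap))
        warning("grid extends beyond the training range of ", variable)
    n <- nrow(env)
    big <- env[rep(seq_len(n), times = length(grid)), , drop = FALSE]
    big[[variable]] <- rep(grid, each = n)
    pred <- .rfPredict(model, big)
    curves <- matrix(pred, nrow = n, ncol = length(grid),
                     dimnames = list(rownames(env), NULL))
    list(grid = grid, curves = curves, pd = colMeans(curves),
         extrapolated = extrap)
}

# Partial-dependence values of the model at each sample's own coordinates
# for the given variable set: PD_S(x_iS) = mean_l f(x_l with S := x_iS).
.pdAtSamples <- function(model, env, vars) {
    n <- nrow(env)
    big <- env[rep(seq_len(n), times = n), , drop = FALSE]  # l fast, i slow
    for (v in vars)
        big[[v]] <- rep(env[[v]], each = n)
    pred <- .rfPredict(model, big)
    colMeans(matrix(pred, nrow = n, ncol = n))
}

#' Friedman-Popescu H-statistic for a variable pair
#'
#' The share of the joint partial-dependence effect of two variables that
#' their interaction explains:
#' H^2 = sum_i [PD_jk(x_i) - PD_j(x_i) - PD_k(x_i)]^2 / sum_i PD_jk(x_i)^2,
#' with all partial-dependence functions mean-centered over the samples.
#' Near 0 for additive models, symmetric in j and k; undefined (NA) when the
#' joint partial dependence is identically zero after centering.
#'
#' @param fit a \code{\link{fitRf}} result (or bare \code{ranger} model).
#' @param env the training predictor data.frame.
#' @param varJ,varK variable names in the model.
#' @return H^2 in [0, 1] (clipped), or NA.
#' @export
hStatistic <- function(fit, env, varJ, varK) {
    model <- if (is.list(fit) && !is.null(fit$model)) fit$model else fit
    if (!all(c(varJ, varK) %in% names(env)))
        stop("both variables must be model predictors")
    pdJ <- .pdAtSamples(model, env, varJ)
    pdK <- .pdAtSamples(model, env, varK)
    pdJK <- .pdAtSamples(model, env, c(varJ, varK))
    pdJ <- pdJ - mean(pdJ)
    pdK <- pdK - mean(pdK)
    pdJK <- pdJK - mean(pdJK)
    denom <- sum(pdJK^2)
    if (denom == 0) return(NA_real_)
    min(1, sum((pdJK - pdJ - pdK)^2) / denom)
}
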