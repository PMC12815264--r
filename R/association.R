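# Genome-pair association modelling: feature table construction, ordered
# quantile normalization, logistic regression of HGT on co-occurrence and
# ecology, variance inflation, AIC comparison and the collider-bias
# demonstration.

#' Ordered quantile (rank-based normal) transformation
#'
#' Maps a continuous vector through its ranks onto standard normal quantiles:
#' value with rank r (average ranks for ties) among n observations becomes
#' qnorm((r - 0.5) / n). Monotone, rank-preserving and idempotent in rank;
#' after transformation one unit corresponds to one standard deviation.
#'
#' @param x numeric vector with at least 3 distinct finite values; NAs are
#'   propagated.
#' @return transformed vector of the same length.
#' @export
orderNorm <- function(x) {
    ok <- is.finite(x)
    if (sum(ok) < 3L) stop("orderNorm needs at least 3 finite values")
    if (length(unique(x[ok])) < 2L)
        stop("orderNorm undefined for a constant vector")
    n <- sum(ok)
    r <- rank(x[ok], ties.method = "average")
    out <- rep(NA_real_, length(x))
    out[ok] <- qnorm((r - 0.5) / n)
    out
}

#' Per-genome environmental medians over occupied samples
#'
#' For each genome, the median of each environmental variable across the
#' samples in which the genome is present.
#'
#' @param se a presence-called \linkS4class{SampleExperiment} whose colData
#'   carries the environmental variables.
#' @param vars variable names (default: all numeric colData columns).
#' @return genomes-by-variables numeric matrix (NA for genomes present
#'   nowhere).
#' @export
genomeEnvMedians <- function(se, vars = NULL) {
    pm <- .presence(se)
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    if (is.null(vars))
        vars <- names(cd)[vapply(cd, is.numeric, logical(1))]
    out <- matrix(NA_real_, nrow(pm), length(vars),
                  dimnames = list(rownames(pm), vars))
    for (g in rownames(pm)) {
        sel <- pm[g, ]
        if (!sum(sel)) next
        out[g, ] <- vapply(vars, function(v) median(cd[[v]][sel]),
                           numeric(1))
    }
    out
}

#' Build the genome-pair feature table for the focal regression
#'
#' One row per unordered pair of prevalence-surviving genomes differing at
#' the genus level or above. The binary response \code{hgt} is whether at
#' least one event links the pair; \code{cooccur} is the pair's
#' significant-co-occurrence flag; \code{phylo_dist} the patristic distance;
#' \code{env_diff_<v>} the absolute difference of the two genomes' median
#' environmental values (medians over each genome's occupied samples);
#' \code{fraction_class} compares the genomes' size-fraction classes
#' (both_free_living / both_combined_fl_pa / the mixed-or-unclassified
#' reference). Continuous columns get orderNorm-transformed copies suffixed
#' \code{_t}.
#'
#' @param events cluster-RBH event table (\code{\link{callRbhHgt}}).
#' @param coocResults \code{\link{hypergeomCooccurrence}} output; its genome
#'   universe defines the pairs.
#' @param patristic patristic distance matrix covering all genomes.
#' @param envMedians \code{\link{genomeEnvMedians}} output, or NULL to skip
#'   environmental differences.
#' @param fractionClasses \code{\link{classifySizeFraction}} output, or NULL.
#' @param taxonomy genome taxonomy data.frame.
#' @return data.frame, one row per retained pair.
#' @export
buildPairTable <- function(events, coocResults, patristic,
                           envMedians = NULL, fractionClasses = NULL,
                           taxonomy = NULL) {
    if (is.null(taxonomy)) stop("taxonomy is required")
    ids <- sort(unique(c(coocResults$genome_a, coocResults$genome_b)))
    missingPat <- setdiff(ids, rownames(patristic))
    if (length(missingPat))
        stop("genome missing patristic distance: ",
             paste(missingPat, collapse = ", "))
    if (!is.null(envMedians)) {
        missingEnv <- setdiff(ids, rownames(envMedians))
        if (length(missingEnv))
            stop("genome missing environmental data: ",
                 paste(missingEnv, collapse = ", "))
    }
    pkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
    sig <- setNames(coocResults$significant,
                    pkey(coocResults$genome_a, coocResults$genome_b))
    hgtKeys <- if (nrow(events))
        unique(pkey(events$genome_a, events$genome_b)) else character()
    fcls <- if (is.null(fractionClasses)) NULL else
        setNames(fractionClasses$class, fractionClasses$genome_id)

    pr <- t(combn(ids, 2L))
    lev <- apply(pr, 1L, function(p)
        divergenceLevel(taxonomy, p[1L], p[2L]))
    keep <- lev != "within_genus"
    pr <- pr[keep, , drop = FALSE]
    key <- pkey(pr[, 1L], pr[, 2L])

    tab <- data.frame(genome_a = pr[, 1L], genome_b = pr[, 2L],
                      hgt = key %in% hgtKeys,
                      cooccur = unname(sig[key]),
                      phylo_dist = patristic[pr],
                      divergence_level = lev[keep],
                      stringsAsFactors = FALSE)
    if (!is.null(envMedians)) {
        for (v in colnames(envMedians))
            tab[[paste0("env_diff_", v)]] <-
                abs(envMedians[pr[, 1L], v] - envMedians[pr[, 2L], v])
    }
    if (!is.null(fcls)) {
        ca <- fcls[pr[, 1L]]; cb <- fcls[pr[, 2L]]
        cls <- ifelse(ca == "free_living" & cb == "free_living",
                      "both_free_living",
                      ifelse(ca == "combined_fl_pa" & cb == "combined_fl_pa",
                             "both_combined_fl_pa", "mixed_or_unclassified"))
        tab$fraction_class <- factor(cls,
                                     levels = c("mixed_or_unclassified",
                                                "both_free_living",
                                                "both_combined_fl_pa"))
    }
    cont <- c("phylo_dist", grep("^env_diff_", names(tab), value = TRUE))
    for (v in cont)
        tab[[paste0(v, "_t")]] <- orderNorm(tab[[v]])
    rownames(tab) <- NULL
    tab
}

#' Fit a logistic regression and package the result
#'
#' Maximum-likelihood logit fit (iteratively reweighted least squares, with
#' deviance convergence tolerance 1e-8) of a binary response on the named
#' predictors. Coefficients are reported with standard errors from the
#' Fisher information, Wald 95\% confidence intervals (estimate +/- 1.96 SE)
#' and Wald z p-values. Quasi-complete separation is flagged with a warning
#' but coefficients are still reported.
#'
#' @param table data.frame of features (\code{\link{buildPairTable}}).
#' @param predictors character vector of column names.
#' @param response name of the binary response column (default "hgt").
#' @return a \linkS4class{ModelFit}.
#' @export
fitLogistic <- function(table, predictors, response = "hgt") {
    y <- table[[response]]
    if (length(unique(y[!is.na(y)])) < 2L)
        stop("response must have both classes")
    fml <- stats::as.formula(paste(response, "~",
                                   paste(predictors, collapse = " + ")))
    sep <- FALSE
    fit <- withCallingHandlers(
        glm(fml, family = binomial(), data = table,
            control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w))) {
                sep <<- TRUE
                invokeRestart("muffleWarning")
            }
        })
    if (!fit$converged) stop("logistic fit did not converge")
    if (any(fit$fitted.values < 1e-8 | fit$fitted.values > 1 - 1e-8))
        sep <- TRUE
    if (sep)
        warning("quasi-complete separation detected; ",
                "coefficients reported with caution")
    sm <- summary(fit)$coefficients
    co <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                     ci_lower = sm[, 1L] - 1.96 * sm[, 2L],
                     ci_upper = sm[, 1L] + 1.96 * sm[, 2L],
                     z = sm[, 3L], p = sm[, 4L],
                     stringsAsFactors = FALSE, row.names = NULL)
    new("ModelFit", coefficients = co, logLik = as.numeric(logLik(fit)),
        aic = AIC(fit), nRows = as.integer(stats::nobs(fit)),
        separation = sep, model = fit)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on the remaining
#' predictors; factor terms get the generalized VIF
#' (det-based, per term). Exact collinearity is reported as Inf.
#'
#' @param table data.frame of predictors.
#' @param predictors character vector of column names (>= 2 terms).
#' @return named numeric vector of (G)VIFs per term.
#' @export
vif <- function(table, predictors) {
    if (length(predictors) < 2L) stop("need at least 2 predictors")
    fml <- stats::as.formula(paste("~", paste(predictors, collapse = " + ")))
    X <- model.matrix(fml, data = table)
    assign <- attr(X, "assign")
    X <- X[, assign != 0L, drop = FALSE]
    assign <- assign[assign != 0L]
    R <- cor(X)
    detR <- det(R)
    out <- setNames(numeric(length(predictors)), predictors)
    for (t in seq_along(predictors)) {
        sel <- assign == t
        if (detR <= .Machine$double.eps) {
            out[t] <- Inf
            next
        }
        g <- det(R[sel, sel, drop = FALSE]) *
            det(R[!sel, !sel, drop = FALSE]) / detR
        out[t] <- if (is.finite(g) && g > 0) g else Inf
    }
    out
}

#' Rank fitted models by AIC
#'
#' @param fits named list of \linkS4class{ModelFit} objects fitted to the
#'   same rows.
#' @return data.frame sorted by ascending AIC with \code{delta_aic} relative
#'   to the best model.
#' @export
compareModels <- function(fits) {
    n <- vapply(fits, function(f) f@nRows, integer(1))
    if (length(unique(n)) != 1L)
        stop("models were fitted on differing row counts")
    out <- data.frame(model = names(fits),
                      aic = vapply(fits, modelAIC, numeric(1)),
                      logLik = vapply(fits, modelLogLik, numeric(1)),
                      k = vapply(fits, function(f) nrow(f@coefficients),
                                 integer(1)),
                      stringsAsFactors = FALSE, row.names = NULL)
    out <- out[order(out$aic), ]
    out$delta_aic <- out$aic - out$aic[1L]
    rownames(out) <- NULL
    out
}

#' Odds fold change implied by a log-odds coefficient
#'
#' exp(beta) gives the multiplicative change in the odds of HGT per unit of
#' the (transformed) predictor; for negative coefficients the reciprocal is
#' also reported as a fold decrease.
#'
#' @param beta finite log-odds coefficient.
#' @return list with \code{fold} = exp(beta) and, when beta < 0,
#'   \code{fold_decrease} = exp(-beta).
#' @export
oddsFromCoefficient <- function(beta) {
    if (!is.finite(beta)) stop("beta must be finite")
    out <- list(fold = exp(beta))
    if (beta < 0) out$fold_decrease <- exp(-beta)
    out
}

#' Collider-bias simulation for the distance/co-occurrence pattern
#'
#' Simulates genome pairs in which phylogenetic distance and co-occurrence
#' are generated independently, with HGT probability increasing with
#' co-occurrence and decreasing with distance. Conditioning on HGT (a common
#' effect of both) then induces a spurious difference: among HGT-positive
#' pairs, the non-co-occurring stratum shows lower mean distance -- the
#' qualitative pattern seen in real data, reproduced with no mechanistic
#' link between distance and co-occurrence.
#'
#' @param nPairs number of simulated pairs.
#' @param effectCooccur,effectPhylo log-odds effects on HGT (both nonzero;
#'   defaults are the fitted focal-model coefficients 2.26 and -1.66).
#' @param intercept baseline log-odds of HGT.
#' @param pCooccur marginal co-occurrence probability.
#' @param seed integer RNG seed.
#' @return list with \code{summary} (mean distance by HGT x co-occurrence
#'   stratum), \code{hgt_cooc_gap} = mean(dist | HGT, cooc) -
#'   mean(dist | HGT, !cooc), and \code{marginal_gap} (the same contrast
#'   ignoring HGT, expected ~0).
#' @export
colliderSimulation <- function(nPairs = 1e5, effectCooccur = 2.26,
                               effectPhylo = -1.66, intercept = -2,
                               pCooccur = 0.3, seed = 7L) {
    set.seed(seed)
    dist <- abs(rnorm(nPairs))
    cooc <- runif(nPairs) < pCooccur
    pHgt <- plogis(intercept + effectCooccur * cooc + effectPhylo * dist)
    hgt <- runif(nPairs) < pHgt
    df <- data.frame(dist = dist, cooc = cooc, hgt = hgt)
    summ <- aggregate(dist ~ hgt + cooc, data = df, FUN = mean)
    m <- function(h, co) mean(dist[hgt == h & cooc == co])
    list(summary = summ,
         hgt_cooc_gap = m(TRUE, TRUE) - m(TRUE, FALSE),
         marginal_gap = mean(dist[cooc]) - mean(dist[!cooc]))
}

#' Simulate a genome-pair table from a known logistic model
#'
#' Generates pair rows with independent co-occurrence flags and phylogenetic
#' distances, and draws the HGT response from a logistic model with the
#' planted coefficients. Used for parameter-recovery checks of
#' \code{\link{fitLogistic}}: across seeded replicates the fitted signs
#' should match the planted signs.
#'
#' @param nPairs number of rows.
#' @param betaCooccur,betaPhylo planted log-odds effects.
#' @param intercept baseline log-odds.
#' @param pCooccur marginal co-occurrence probability.
#' @param seed integer RNG seed.
#' @return data.frame with \code{hgt}, \code{cooccur}, \code{phylo_dist} and
#'   the orderNorm-transformed \code{phylo_dist_t}.
#' @export
simulateAssociationTable <- function(nPairs = 1000L, betaCooccur = 2.26,
                                     betaPhylo = -1.66, intercept = -2,
                                     pCooccur = 0.3, seed = 1L) {
    set.seed(seed)
    cooc <- runif(nPairs) < pCooccur
    dist <- abs(rnorm(nPairs))
    distT <- orderNorm(dist)
    p <- plogis(intercept + betaCooccur * cooc + betaPhylo * distT)
    data.frame(hgt = runif(nPairs) < p, cooccur = cooc, phylo_dist = dist,
               phylo_dist_t = distT)
}
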