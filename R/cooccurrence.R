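# Presence calling from breadth of coverage, prevalence filtering, pairwise
# co-occurrence statistics (hypergeometric test, simple overlap,
# compositional proportionality), size-fraction classification and
# per-sample feature prevalence.

#' Call genome presence from breadth of coverage
#'
#' A genome is present in a sample when its breadth of coverage is at least
#' \code{presenceThreshold} (inclusive, default 30\%). RPKM values of absent
#' genomes are set to zero in the returned object; the input object is left
#' untouched.
#'
#' @param se a \linkS4class{SampleExperiment} with \code{breadth} and
#'   \code{rpkm} assays.
#' @param presenceThreshold breadth cut-off in [0, 1].
#' @return the \code{SampleExperiment} with a logical \code{present} assay
#'   and post-zeroing \code{rpkm}.
#' @export
callPresence <- function(se, presenceThreshold = 0.30) {
    b <- SummarizedExperiment::assay(se, "breadth")
    r <- SummarizedExperiment::assay(se, "rpkm")
    present <- b >= presenceThreshold
    r[!present] <- 0
    SummarizedExperiment::assay(se, "rpkm") <- r
    SummarizedExperiment::assay(se, "present") <- present
    S4Vectors::metadata(se)$presence_threshold <- presenceThreshold
    validObject(se)
    se
}

.presence <- function(se) {
    if (!"present" %in% SummarizedExperiment::assayNames(se))
        stop("call callPresence() first")
    SummarizedExperiment::assay(se, "present")
}

#' Prevalence filter
#'
#' \code{filterPrevalence} reports which genomes are present in at least
#' \code{minSamples} samples and which samples contain zero present genomes;
#' \code{applyPrevalenceFilter} subsets the experiment to the retained
#' genomes and drops the empty samples. Filtering is idempotent: applying it
#' twice equals applying it once.
#'
#' @param se a presence-called \linkS4class{SampleExperiment}.
#' @param minSamples minimum number of samples a genome must be present in
#'   (default 10, inclusive).
#' @return \code{filterPrevalence}: list with \code{retained} genome ids and
#'   \code{empty_samples}. \code{applyPrevalenceFilter}: the subsetted
#'   \code{SampleExperiment}.
#' @export
filterPrevalence <- function(se, minSamples = 10L) {
    p <- .presence(se)
    list(retained = rownames(p)[rowSums(p) >= minSamples],
         empty_samples = colnames(p)[colSums(p) == 0L])
}

#' @rdname filterPrevalence
#' @export
applyPrevalenceFilter <- function(se, minSamples = 10L) {
    f <- filterPrevalence(se, minSamples)
    se[f$retained, setdiff(colnames(se), f$empty_samples)]
}

#' Hypergeometric co-occurrence tests for genome pairs
#'
#' For genomes A and B present in \code{k_a} and \code{k_b} of N samples with
#' \code{obs} joint samples, the upper-tail p-value is P[X >= obs] for X ~
#' Hypergeometric(N, k_a, k_b) (the observed table included, the standard
#' exact-test convention). The effect size is the co-occurrence ratio
#' obs / expected with expected = k_a k_b / N. Benjamini-Hochberg correction
#' is applied jointly over all tested pairs; a pair is significantly
#' co-occurring when q < \code{alpha} and ratio > 1.
#'
#' @param se a presence-called \linkS4class{SampleExperiment}; samples with
#'   zero present genomes are excluded first.
#' @param pairs optional 2-column matrix/data.frame of genome id pairs;
#'   default all unordered pairs.
#' @param alpha BH significance level (default 0.05).
#' @return data.frame with one row per pair: \code{genome_a},
#'   \code{genome_b}, \code{n_samples}, \code{k_a}, \code{k_b}, \code{obs},
#'   \code{expected}, \code{ratio}, \code{p}, \code{q}, \code{significant}.
#' @export
hypergeomCooccurrence <- function(se, pairs = NULL, alpha = 0.05) {
    pm <- .presence(se)
    pm <- pm[, colSums(pm) > 0L, drop = FALSE]
    N <- ncol(pm)
    if (N == 0L) stop("no samples with any present genome")
    if (nrow(pm) < 2L) stop("need at least 2 genomes")
    if (is.null(pairs)) {
        pairs <- t(combn(rownames(pm), 2L))
    } else {
        pairs <- as.matrix(pairs)
    }
    ka <- rowSums(pm)[pairs[, 1L]]
    kb <- rowSums(pm)[pairs[, 2L]]
    storage.mode(pm) <- "integer"
    obs <- vapply(seq_len(nrow(pairs)), function(i)
        sum(pm[pairs[i, 1L], ] & pm[pairs[i, 2L], ]), integer(1))
    expected <- ka * kb / N
    ratio <- ifelse(expected > 0, obs / expected, NA_real_)
    p <- phyper(obs - 1L, ka, N - ka, kb, lower.tail = FALSE)
    q <- p.adjust(p, method = "BH")
    data.frame(genome_a = pairs[, 1L], genome_b = pairs[, 2L],
               n_samples = N, k_a = as.integer(ka), k_b = as.integer(kb),
               obs = obs, expected = expected, ratio = ratio, p = p, q = q,
               significant = q < alpha & ratio > 1,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Simple co-occurrence overlap
#'
#' The shared-sample fraction
#' |S_A intersect S_B| / min(|S_A|, |S_B|), where S_X is the set of samples
#' containing genome X. A genome found everywhere trivially overlaps every
#' other genome at 1.0, which is why the hypergeometric ratio is the focal
#' statistic.
#'
#' @param se a presence-called \linkS4class{SampleExperiment}.
#' @param genomeA,genomeB genome ids, both present somewhere.
#' @return a fraction in [0, 1]; symmetric in its arguments.
#' @export
simpleOverlap <- function(se, genomeA, genomeB) {
    pm <- .presence(se)
    a <- pm[genomeA, ]; b <- pm[genomeB, ]
    if (!sum(a) || !sum(b))
        stop("simple overlap undefined for a genome with zero presence")
    sum(a & b) / min(sum(a), sum(b))
}

#' Proportionality (rho) between genome abundance profiles
#'
#' Compositional co-abundance: per sample, RPKM values are shifted by
#' \code{pseudocount}, closed to proportions and transformed with the
#' centered log-ratio; then
#' rho(i, j) = 1 - var(clr_i - clr_j) / (var(clr_i) + var(clr_j)).
#' Values lie in [-1, 1] with 1 on the diagonal. Genomes whose clr profile
#' has zero variance get NA against all partners.
#'
#' @param rpkm genome-by-sample non-negative matrix (or a
#'   \linkS4class{SampleExperiment}, whose post-zeroing rpkm assay is used).
#' @param pseudocount positive shift applied before closure (default 1 RPKM
#'   unit).
#' @return symmetric genome-by-genome matrix.
#' @export
proportionalityRho <- function(rpkm, pseudocount = 1) {
    if (is(rpkm, "SummarizedExperiment"))
        rpkm <- SummarizedExperiment::assay(rpkm, "rpkm")
    if (pseudocount <= 0) stop("pseudocount must be positive")
    if (any(rpkm < 0)) stop("rpkm must be non-negative")
    x <- log(rpkm + pseudocount)
    # closure then clr: subtracting the per-sample log geometric mean makes
    # the closure constant cancel
    clr <- sweep(x, 2L, colMeans(x))
    v <- apply(clr, 1L, var)
    n <- nrow(clr)
    out <- matrix(NA_real_, n, n, dimnames = list(rownames(rpkm),
                                                  rownames(rpkm)))
    ok <- which(v > 0)
    for (i in ok) {
        for (j in ok) {
            if (j < i) next
            out[i, j] <- out[j, i] <-
                1 - var(clr[i, ] - clr[j, ]) / (v[i] + v[j])
        }
    }
    diag(out) <- 1
    out
}

#' Classify genomes by sample size fraction
#'
#' A genome is associated with a size-fraction group (free-living or the
#' combined free-living + particle-attached fraction) when strictly more than
#' \code{supportThreshold} of the samples containing it belong to that group
#' (samples with other labels count in the denominator) AND its median RPKM
#' across the samples containing it is highest in that group. Everything else
#' is unclassified.
#'
#' @param se a presence-called \linkS4class{SampleExperiment} whose colData
#'   has a \code{fraction} column with levels \code{free_living},
#'   \code{combined_fl_pa}, \code{other}.
#' @param supportThreshold strict support cut-off (default 0.75).
#' @return data.frame: \code{genome_id}, \code{class}, \code{support},
#'   median RPKM per group.
#' @export
classifySizeFraction <- function(se, supportThreshold = 0.75) {
    pm <- .presence(se)
    rpkm <- SummarizedExperiment::assay(se, "rpkm")
    fraction <- SummarizedExperiment::colData(se)$fraction
    if (is.null(fraction)) stop("colData(se)$fraction is required")
    groups <- c("free_living", "combined_fl_pa")
    res <- lapply(rownames(pm), function(g) {
        inSamp <- pm[g, ]
        n <- sum(inSamp)
        med <- vapply(groups, function(fr) {
            sel <- inSamp & fraction == fr
            if (!sum(sel)) NA_real_ else median(rpkm[g, sel])
        }, numeric(1))
        if (n == 0L)
            return(data.frame(genome_id = g, class = "unclassified",
                              support = NA_real_,
                              median_rpkm_free_living = med[1L],
                              median_rpkm_combined_fl_pa = med[2L],
                              stringsAsFactors = FALSE))
        support <- vapply(groups, function(fr)
            sum(inSamp & fraction == fr) / n, numeric(1))
        win <- groups[which.max(support)]
        cls <- "unclassified"
        if (support[win] > supportThreshold) {
            others <- med[setdiff(groups, win)]
            if (!is.na(med[win]) &&
                (all(is.na(others)) || med[win] >= max(others, na.rm = TRUE)))
                cls <- win
        }
        data.frame(genome_id = g, class = cls, support = support[win],
                   median_rpkm_free_living = med[1L],
                   median_rpkm_combined_fl_pa = med[2L],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Per-sample prevalence of a genome feature
#'
#' For each sample, the fraction of present genomes whose feature flag is
#' TRUE (e.g. "has at least one putative HGT event"). Samples with zero
#' present genomes return NA.
#'
#' @param se a presence-called \linkS4class{SampleExperiment}.
#' @param flags named logical vector covering all genomes of \code{se}.
#' @return named numeric vector over samples.
#' @export
featurePrevalence <- function(se, flags) {
    pm <- .presence(se)
    if (!all(rownames(pm) %in% names(flags)))
        stop("flags must cover all genomes")
    fl <- flags[rownames(pm)]
    nPresent <- colSums(pm)
    nFlag <- colSums(pm & fl)
    ifelse(nPresent > 0L, nFlag / nPresent, NA_real_)
}

#' Paired test of feature prevalence between matched size fractions
#'
#' Two-sided paired Wilcoxon signed-rank test on per-sample prevalence values
#' from matched small and large size-fraction metagenomes, with the fold
#' change summarized as mean(large) / mean(small). When every paired
#' difference is zero the p-value is 1 by convention.
#'
#' @param prevalenceSmall,prevalenceLarge per-sample values on the same
#'   biological samples in the same order (n >= 6).
#' @return list with \code{fold_change}, \code{p}, \code{n}.
#' @export
pairedFractionTest <- function(prevalenceSmall, prevalenceLarge) {
    ok <- complete.cases(prevalenceSmall, prevalenceLarge)
    s <- prevalenceSmall[ok]; l <- prevalenceLarge[ok]
    if (length(s) < 6L) stop("need at least 6 matched samples")
    if (all(l - s == 0)) {
        p <- 1
    } else {
        p <- suppressWarnings(wilcox.test(l, s, paired = TRUE)$p.value)
    }
    list(fold_change = mean(l) / mean(s), p = p, n = length(s))
}

#' @rdname pairedFractionTest
#' @param small,large data.frames (samples x features) of per-sample
#'   prevalence for several features on matched samples.
#' @return \code{pairedFeatureTests}: data.frame with one row per feature
#'   (\code{feature}, \code{fold_change}, \code{p}, BH \code{q}).
#' @export
pairedFeatureTests <- function(small, large) {
    stopifnot(identical(colnames(small), colnames(large)))
    rows <- lapply(colnames(small), function(f) {
        r <- pairedFractionTest(small[[f]], large[[f]])
        data.frame(feature = f, fold_change = r$fold_change, p = r$p,
                   n = r$n, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    out
}
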