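# Functional enrichment: majority-rule COG assignment of gene clusters,
# Fisher tests of HGT involvement per COG category (optionally stratified by
# identity bin and divergence level), and gene-level MGE fold enrichments.

EXCLUDED_COG <- c("A", "B", "Y", "Z")  # eukaryotic-specific categories

#' Majority-rule COG category per gene cluster
#'
#' Each cluster inherits the most frequent single-letter COG category among
#' its annotated members. Ties and clusters with no annotated member are left
#' unassigned; the rare eukaryotic-specific categories A, B, Y and Z are
#' excluded from voting and assignment.
#'
#' @param clusters cluster membership table (\code{\link{clusterGenes}}).
#' @param annotations data.frame with \code{gene_id} and \code{cog_category}
#'   (a string of zero or more category letters); defaults to the columns
#'   already present in \code{clusters}.
#' @return named character vector cluster_id -> category ("" = unassigned).
#' @export
assignClusterCog <- function(clusters, annotations = NULL) {
    if (is.null(annotations))
        annotations <- clusters[, c("gene_id", "cog_category")]
    cog <- setNames(annotations$cog_category, annotations$gene_id)
    vapply(split(clusters$gene_id, clusters$cluster_id), function(g) {
        letters <- unlist(strsplit(cog[g], ""))
        letters <- letters[!is.na(letters) & !(letters %in% EXCLUDED_COG)]
        if (!length(letters)) return("")
        tb <- sort(table(letters), decreasing = TRUE)
        if (length(tb) > 1L && tb[1L] == tb[2L]) return("")  # tie
        names(tb)[1L]
    }, character(1))
}

.crossOddsRatio <- function(a, b, c, d, haldane = FALSE) {
    if (haldane) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
    (a * d) / (b * c)
}

#' COG category enrichment among HGT-involved clusters
#'
#' For each COG category, a two-sided Fisher's exact test on the 2x2 table of
#' (cluster in category) x (cluster in at least one HGT relationship),
#' against the universe of all COG-assigned clusters. The odds ratio is the
#' sample cross-product ratio ad/bc. Benjamini-Hochberg correction is applied
#' across categories within the stratum.
#'
#' @param clusterCog named vector from \code{\link{assignClusterCog}}.
#' @param hgtClusterIds cluster ids with >= 1 HGT relationship in this
#'   stratum.
#' @param stratum label recorded in the output (default "all").
#' @param alpha BH significance level.
#' @return data.frame: \code{stratum}, \code{category}, counts \code{a}
#'   (in-category HGT), \code{b} (in-category non-HGT), \code{c}
#'   (other-category HGT), \code{d} (other-category non-HGT),
#'   \code{odds_ratio}, \code{p}, \code{q}, \code{direction},
#'   \code{significant}.
#' @export
cogEnrichment <- function(clusterCog, hgtClusterIds, stratum = "all",
                          alpha = 0.05) {
    universe <- names(clusterCog)[nzchar(clusterCog)]
    if (!length(universe)) stop("empty universe: no COG-assigned clusters")
    cats <- sort(unique(clusterCog[universe]))
    if (length(cats) < 2L) stop("need at least 2 categories")
    isHgt <- universe %in% hgtClusterIds
    rows <- lapply(cats, function(cc) {
        inCat <- clusterCog[universe] == cc
        a <- sum(inCat & isHgt); b <- sum(inCat & !isHgt)
        c <- sum(!inCat & isHgt); d <- sum(!inCat & !isHgt)
        or <- .crossOddsRatio(a, b, c, d)
        p <- fisher.test(matrix(c(a, b, c, d), 2L))$p.value
        data.frame(stratum = stratum, category = cc, a = a, b = b, c = c,
                   d = d, odds_ratio = or, p = p,
                   direction = ifelse(is.nan(or) | or >= 1, "enriched",
                                      "depleted"),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q <- p.adjust(out$p, method = "BH")
    out$significant <- out$q < alpha
    rownames(out) <- NULL
    out
}

#' Stratified COG enrichment over identity bins and divergence levels
#'
#' Runs \code{\link{cogEnrichment}} once over all events and once per
#' (identity bin x divergence level) stratum with at least one HGT cluster.
#' BH families are the categories within each stratum.
#'
#' @param clusters cluster membership table.
#' @param events cluster-RBH event table with \code{cluster_id},
#'   \code{identity_bin} and \code{divergence_level}.
#' @param alpha BH significance level.
#' @return combined enrichment data.frame across strata.
#' @export
cogEnrichmentStratified <- function(clusters, events, alpha = 0.05) {
    clusterCog <- assignClusterCog(clusters)
    out <- list(cogEnrichment(clusterCog, unique(events$cluster_id),
                              stratum = "all", alpha = alpha))
    if (nrow(events)) {
        strata <- unique(events[, c("identity_bin", "divergence_level")])
        for (i in seq_len(nrow(strata))) {
            sel <- events$identity_bin == strata$identity_bin[i] &
                events$divergence_level == strata$divergence_level[i]
            lab <- paste(strata$identity_bin[i], strata$divergence_level[i],
                         sep = ":")
            out[[length(out) + 1L]] <-
                cogEnrichment(clusterCog, unique(events$cluster_id[sel]),
                              stratum = lab, alpha = alpha)
        }
    }
    do.call(rbind, out)
}

#' Gene-level mobile-genetic-element fold enrichment
#'
#' Two-sided Fisher's exact test of one MGE flag against HGT involvement over
#' all genes, with the fold reported as the cross-product odds ratio ad/bc.
#' When a margin is zero the Haldane-Anscombe 0.5 correction is applied and
#' flagged. For depleted flags (odds ratio < 1) the reciprocal is also
#' reported as a fold depletion.
#'
#' @param genes gene table with the MGE flag columns.
#' @param hgtGeneIds gene ids involved in >= 1 HGT event.
#' @param mgeFlagName one of \code{promge_hit}, \code{plasmid_contig},
#'   \code{virus_contig}, \code{provirus_contig}.
#' @return list: \code{fold} (odds ratio), \code{p}, \code{table} (a, b, c,
#'   d), \code{corrected} (Haldane applied), and \code{fold_depletion} when
#'   fold < 1.
#' @export
mgeFoldEnrichment <- function(genes, hgtGeneIds, mgeFlagName) {
    if (!mgeFlagName %in% names(genes))
        stop("unknown MGE flag: ", mgeFlagName)
    flag <- genes[[mgeFlagName]]
    hgt <- genes$gene_id %in% hgtGeneIds
    a <- sum(flag & hgt); b <- sum(flag & !hgt)
    c <- sum(!flag & hgt); d <- sum(!flag & !hgt)
    corrected <- (b * c == 0) || (a * d == 0)
    or <- .crossOddsRatio(a, b, c, d, haldane = corrected)
    p <- fisher.test(matrix(c(a, b, c, d), 2L))$p.value
    out <- list(fold = or, p = p,
                table = c(a = a, b = b, c = c, d = d),
                corrected = corrected)
    if (is.finite(or) && or < 1) out$fold_depletion <- 1 / or
    out
}
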