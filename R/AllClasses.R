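#' @import methods
#' @importFrom stats median phyper p.adjust fisher.test wilcox.test qnorm rnorm
#'   runif rbinom glm binomial coef vcov logLik AIC lm var cor sd predict
#'   as.dist hclust quantile plogis setNames complete.cases model.matrix
#'   rlnorm cov ks.test aggregate
#' @importFrom utils read.delim write.table combn head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @useDynLib hgtcooc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                    "species")

MGE_FLAGS <- c("promge_hit", "plasmid_contig", "virus_contig",
               "provirus_contig")

#' GenomeSet: a collection of genomes with genes, taxonomy and phylogeny
#'
#' The central container for a set of prokaryotic genomes under comparison.
#' Holds per-genome taxonomy (seven GTDB-style ranks) and quality metrics,
#' per-contig lengths, per-gene coordinates and nucleotide sequences with
#' functional annotations (COG category, mobile-genetic-element flags), the
#' genome phylogeny as an \code{ape} \code{phylo} object, the patristic
#' distance matrix between genomes, and -- for simulated sets -- the planted
#' ground truth used by parameter-recovery tests.
#'
#' Gene coordinates are internally 0-based half-open; on disk (GFF3) they are
#' 1-based inclusive.
#'
#' @slot genomeTable data.frame with columns \code{genome_id}, the seven rank
#'   columns, \code{completeness}, \code{contamination}.
#' @slot contigTable data.frame with columns \code{contig_id},
#'   \code{genome_id}, \code{length}.
#' @slot geneTable data.frame with columns \code{gene_id}, \code{genome_id},
#'   \code{contig_id}, \code{start}, \code{end}, \code{strand}, \code{seq},
#'   \code{cog_category} and the four MGE flag columns.
#' @slot tree an \code{ape::phylo} with tip labels equal to genome ids.
#' @slot patristic symmetric numeric matrix of patristic distances.
#' @slot truth list of planted-truth tables (possibly empty for real data).
#' @export
setClass("GenomeSet",
         representation(genomeTable = "data.frame",
                        contigTable = "data.frame",
                        geneTable = "data.frame",
                        tree = "ANY",
                        patristic = "matrix",
                        truth = "list"))

setValidity("GenomeSet", function(object) {
    gt <- object@genomeTable
    ct <- object@contigTable
    ge <- object@geneTable
    msgs <- character()
    need <- c("genome_id", TAXONOMY_RANKS, "completeness", "contamination")
    if (!all(need %in% names(gt)))
        msgs <- c(msgs, "genomeTable missing required columns")
    else {
        if (any(gt$completeness <= 0 | gt$completeness > 100))
            msgs <- c(msgs, "completeness must be in (0, 100]")
        if (any(gt$contamination < 0 | gt$contamination >= 100))
            msgs <- c(msgs, "contamination must be in [0, 100)")
        if (anyDuplicated(gt$genome_id))
            msgs <- c(msgs, "duplicated genome_id")
    }
    if (nrow(ct) && any(ct$length <= 0))
        msgs <- c(msgs, "contig lengths must be positive")
    if (nrow(ge)) {
        if (any(ge$end <= ge$start))
            msgs <- c(msgs, "gene end must exceed start")
        if (any(nchar(ge$seq) != ge$end - ge$start))
            msgs <- c(msgs, "gene sequence length must equal end - start")
        clen <- setNames(ct$length, ct$contig_id)
        if (any(ge$end > clen[ge$contig_id]))
            msgs <- c(msgs, "gene extends beyond its contig")
        probe <- ge$seq[seq_len(min(nrow(ge), 50L))]
        if (any(grepl("[^ACGT]", probe)))
            msgs <- c(msgs, "gene sequences must be over {A,C,G,T}")
    }
    if (length(dim(object@patristic)) == 2L && nrow(object@patristic)) {
        pm <- object@patristic
        if (!isTRUE(all.equal(pm, t(pm), tolerance = 1e-8)))
            msgs <- c(msgs, "patristic matrix must be symmetric")
        if (any(abs(diag(pm)) > 1e-12))
            msgs <- c(msgs, "patristic diagonal must be zero")
    }
    if (length(msgs)) msgs else TRUE
})

#' SampleExperiment: genome-by-sample coverage with sample metadata
#'
#' A \linkS4class{SummarizedExperiment} whose rows are genomes and whose
#' columns are metagenomic samples. Carries the \code{breadth} (fraction of a
#' genome covered by at least one read, in [0,1]) and \code{rpkm} assays, plus
#' -- after \code{\link{callPresence}} -- a logical \code{present} assay.
#' \code{colData} holds the per-sample size-fraction label and environmental
#' variables.
#'
#' @export
setClass("SampleExperiment",
         contains = "SummarizedExperiment")

setValidity("SampleExperiment", function(object) {
    an <- SummarizedExperiment::assayNames(object)
    msgs <- character()
    if (!all(c("breadth", "rpkm") %in% an))
        return("assays 'breadth' and 'rpkm' are required")
    b <- SummarizedExperiment::assay(object, "breadth")
    r <- SummarizedExperiment::assay(object, "rpkm")
    if (any(b < 0 | b > 1)) msgs <- c(msgs, "breadth must lie in [0, 1]")
    if (any(r < 0)) msgs <- c(msgs, "rpkm must be non-negative")
    if ("present" %in% an) {
        p <- SummarizedExperiment::assay(object, "present")
        if (!is.logical(p)) msgs <- c(msgs, "'present' assay must be logical")
    }
    if (length(msgs)) msgs else TRUE
})

#' ModelFit: a fitted logistic regression with bookkeeping
#'
#' Wraps a maximum-likelihood logit fit: per-coefficient estimates (log-odds),
#' standard errors, Wald 95\% confidence intervals (estimate +/- 1.96 SE) and
#' p-values, along with the log-likelihood, AIC and row count.
#'
#' @slot coefficients data.frame with columns \code{term}, \code{estimate},
#'   \code{se}, \code{ci_lower}, \code{ci_upper}, \code{z}, \code{p}.
#' @slot logLik numeric log-likelihood at the optimum.
#' @slot aic numeric; equals 2k - 2 logLik for k estimated parameters.
#' @slot nRows integer number of rows used.
#' @slot separation logical; TRUE when quasi-complete separation was detected.
#' @slot model the underlying \code{glm} object (for prediction).
#' @export
setClass("ModelFit",
         representation(coefficients = "data.frame", logLik = "numeric",
                        aic = "numeric", nRows = "integer",
                        separation = "logical", model = "ANY"))

setValidity("ModelFit", function(object) {
    k <- nrow(object@coefficients)
    if (abs(object@aic - (2 * k - 2 * object@logLik)) > 1e-6)
        return("aic must equal 2k - 2 logLik")
    TRUE
})
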