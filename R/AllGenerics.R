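#' @rdname GenomeSet-accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("genomeTable", function(x) standardGeneric("genomeTable"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("contigTable", function(x) standardGeneric("contigTable"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("geneTable", function(x) standardGeneric("geneTable"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("phylogeny", function(x) standardGeneric("phylogeny"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("patristicDist", function(x) standardGeneric("patristicDist"))

#' @rdname GenomeSet-accessors
#' @export
setGeneric("plantedTruth", function(x) standardGeneric("plantedTruth"))

#' Accessors for GenomeSet components
#'
#' @param x a \linkS4class{GenomeSet}.
#' @return \code{genomeIds}: character vector of genome identifiers.
#'   \code{genomeTable}, \code{contigTable}, \code{geneTable},
#'   \code{taxonomyTable}: the corresponding data.frames. \code{phylogeny}:
#'   the \code{ape::phylo} tree. \code{patristicDist}: the symmetric patristic
#'   distance matrix. \code{plantedTruth}: the list of planted-truth tables
#'   (empty for non-simulated sets).
#' @name GenomeSet-accessors
NULL

setMethod("genomeIds", "GenomeSet", function(x) x@genomeTable$genome_id)
setMethod("genomeTable", "GenomeSet", function(x) x@genomeTable)
setMethod("contigTable", "GenomeSet", function(x) x@contigTable)
setMethod("geneTable", "GenomeSet", function(x) x@geneTable)
setMethod("taxonomyTable", "GenomeSet", function(x)
    x@genomeTable[, c("genome_id", TAXONOMY_RANKS)])
setMethod("phylogeny", "GenomeSet", function(x) x@tree)
setMethod("patristicDist", "GenomeSet", function(x) x@patristic)
setMethod("plantedTruth", "GenomeSet", function(x) x@truth)

setMethod("show", "GenomeSet", function(object) {
    cat("GenomeSet with", nrow(object@genomeTable), "genomes,",
        nrow(object@contigTable), "contigs,",
        nrow(object@geneTable), "genes\n")
    if (length(object@truth))
        cat("  planted truth:", paste(names(object@truth), collapse = ", "),
            "\n")
})

setMethod("show", "ModelFit", function(object) {
    cat("Logistic ModelFit on", object@nRows, "rows; logLik =",
        format(object@logLik, digits = 6), "; AIC =",
        format(object@aic, digits = 6), "\n")
    if (object@separation)
        cat("  warning: quasi-complete separation detected\n")
    print(object@coefficients, digits = 4, row.names = FALSE)
})

#' @rdname ModelFit-accessors
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))

#' @rdname ModelFit-accessors
#' @export
setGeneric("modelAIC", function(x) standardGeneric("modelAIC"))

#' @rdname ModelFit-accessors
#' @export
setGeneric("modelLogLik", function(x) standardGeneric("modelLogLik"))

#' Accessors for ModelFit components
#'
#' @param x a \linkS4class{ModelFit}.
#' @return \code{modelCoefficients}: data.frame of estimates, standard errors,
#'   Wald confidence intervals and p-values. \code{modelAIC},
#'   \code{modelLogLik}: scalars.
#' @name ModelFit-accessors
NULL

setMethod("modelCoefficients", "ModelFit", function(x) x@coefficients)
setMethod("modelAIC", "ModelFit", function(x) x@aic)
setMethod("modelLogLik", "ModelFit", function(x) x@logLik)
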