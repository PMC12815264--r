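# On-disk fixture format: per-genome FASTA (gene sequences) + GFF3, taxonomy
# and annotation TSVs, newick tree, breadth/RPKM/environment tables and
# planted-truth tables. All plain text; numerics are written with enough
# digits to round-trip doubles exactly.

.fmtNum <- function(x) {
    out <- vapply(x, function(v) {
        if (is.na(v)) "NA" else sprintf("%.17g", v)
    }, character(1))
    out
}

.writeTsv <- function(df, path) {
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- .fmtNum(out[[j]])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readTsv <- function(path, numeric = character()) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    for (v in intersect(numeric, names(df)))
        df[[v]] <- as.numeric(df[[v]])
    df
}

#' Write a simulated fixture to disk
#'
#' Emits per-genome FASTA (gene nucleotide sequences, headers
#' \code{genome|contig|gene}) and GFF3 (1-based inclusive coordinates,
#' \code{ID=} attributes), the taxonomy TSV, the newick tree with branch
#' lengths, the patristic matrix, breadth/RPKM matrices (samples x genomes),
#' the per-sample environment and fraction tables, gene functional
#' annotations, and the planted-truth tables. \code{\link{readFixture}}
#' reproduces the in-memory objects exactly.
#'
#' @param gs a \linkS4class{GenomeSet}.
#' @param se a \linkS4class{SampleExperiment} (optional).
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeFixture <- function(gs, se = NULL, dir) {
    if (!dir.exists(dir) &&
        !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create directory: ", dir)
    gdir <- file.path(dir, "genomes")
    dir.create(gdir, showWarnings = FALSE)
    ge <- geneTable(gs)
    ct <- contigTable(gs)
    for (g in genomeIds(gs)) {
        rows <- ge[ge$genome_id == g, , drop = FALSE]
        seqs <- Biostrings::DNAStringSet(rows$seq)
        names(seqs) <- paste(rows$genome_id, rows$contig_id, rows$gene_id,
                             sep = "|")
        Biostrings::writeXStringSet(seqs, file.path(gdir,
                                                    paste0(g, ".fasta")))
        gff <- c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d",
                         ct$contig_id[ct$genome_id == g],
                         ct$length[ct$genome_id == g]),
                 sprintf("%s\thgtcooc\tgene\t%d\t%d\t.\t%s\t.\tID=%s;family=%d",
                         rows$contig_id, rows$start + 1L, rows$end,
                         rows$strand, rows$gene_id, rows$family))
        writeLines(gff, file.path(gdir, paste0(g, ".gff")))
    }
    .writeTsv(genomeTable(gs), file.path(dir, "taxonomy.tsv"))
    ape::write.tree(phylogeny(gs), file.path(dir, "tree.nwk"))
    pm <- patristicDist(gs)
    .writeTsv(data.frame(genome_id = rownames(pm), pm, check.names = FALSE),
              file.path(dir, "patristic.tsv"))
    .writeTsv(ge[, c("gene_id", "cog_category", MGE_FLAGS)],
              file.path(dir, "annotations.tsv"))
    tr <- plantedTruth(gs)
    if (!is.null(tr$hgt_events))
        .writeTsv(tr$hgt_events, file.path(dir, "truth_events.tsv"))
    if (!is.null(tr$cooccurring_pairs))
        .writeTsv(tr$cooccurring_pairs,
                  file.path(dir, "truth_cooccurring_pairs.tsv"))
    if (!is.null(tr$env_effect))
        jsonlite::write_json(tr$env_effect,
                             file.path(dir, "truth_env_effect.json"),
                             auto_unbox = TRUE, digits = NA)
    if (!is.null(se)) {
        b <- t(SummarizedExperiment::assay(se, "breadth"))
        r <- t(SummarizedExperiment::assay(se, "rpkm"))
        .writeTsv(data.frame(sample_id = rownames(b), b,
                             check.names = FALSE),
                  file.path(dir, "breadth.tsv"))
        .writeTsv(data.frame(sample_id = rownames(r), r,
                             check.names = FALSE),
                  file.path(dir, "rpkm.tsv"))
        cd <- as.data.frame(SummarizedExperiment::colData(se))
        envCols <- setdiff(names(cd), "fraction")
        .writeTsv(data.frame(sample_id = rownames(cd),
                             cd[, envCols, drop = FALSE],
                             check.names = FALSE),
                  file.path(dir, "env.tsv"))
        if ("fraction" %in% names(cd))
            .writeTsv(data.frame(sample_id = rownames(cd),
                                 fraction = cd$fraction),
                      file.path(dir, "samples.tsv"))
    }
    invisible(dir)
}

#' Read a fixture directory back into memory
#'
#' @param dir a directory written by \code{\link{writeFixture}}.
#' @return list with \code{genomes} (\linkS4class{GenomeSet}) and
#'   \code{samples} (\linkS4class{SampleExperiment} or NULL).
#' @export
readFixture <- function(dir) {
    gt <- .readTsv(file.path(dir, "taxonomy.tsv"),
                   numeric = c("completeness", "contamination"))
    tree <- ape::read.tree(file.path(dir, "tree.nwk"))
    pmRaw <- .readTsv(file.path(dir, "patristic.tsv"),
                      numeric = setdiff(
                          names(read.delim(file.path(dir, "patristic.tsv"),
                                           nrows = 1L)), "genome_id"))
    pm <- as.matrix(pmRaw[, -1L, drop = FALSE])
    rownames(pm) <- pmRaw$genome_id
    colnames(pm) <- colnames(pm)

    geneRows <- list(); contigRows <- list()
    for (g in gt$genome_id) {
        fa <- Biostrings::readDNAStringSet(
            file.path(dir, "genomes", paste0(g, ".fasta")))
        hdr <- do.call(rbind, strsplit(names(fa), "|", fixed = TRUE))
        gffLines <- readLines(file.path(dir, "genomes", paste0(g, ".gff")))
        sr <- gffLines[startsWith(gffLines, "##sequence-region")]
        srf <- do.call(rbind, strsplit(sr, " "))
        contigRows[[g]] <- data.frame(contig_id = srf[, 2L], genome_id = g,
                                      length = as.integer(srf[, 4L]),
                                      stringsAsFactors = FALSE)
        feat <- gffLines[!startsWith(gffLines, "#")]
        ff <- do.call(rbind, strsplit(feat, "\t"))
        attrs <- ff[, 9L]
        gid <- sub("^ID=([^;]+).*$", "\\1", attrs)
        fam <- as.integer(sub("^.*family=([0-9]+).*$", "\\1", attrs))
        geneRows[[g]] <- data.frame(
            gene_id = gid, genome_id = g, contig_id = ff[, 1L],
            start = as.integer(ff[, 4L]) - 1L, end = as.integer(ff[, 5L]),
            strand = ff[, 7L],
            seq = as.character(fa)[match(gid, hdr[, 3L])],
            family = fam, stringsAsFactors = FALSE)
    }
    ge <- do.call(rbind, geneRows)
    ann <- .readTsv(file.path(dir, "annotations.tsv"))
    for (fl in MGE_FLAGS) ann[[fl]] <- as.logical(ann[[fl]])
    ann$cog_category[is.na(ann$cog_category)] <- ""
    m <- match(ge$gene_id, ann$gene_id)
    ge$cog_category <- ann$cog_category[m]
    for (fl in MGE_FLAGS) ge[[fl]] <- ann[[fl]][m]
    ge <- ge[, c("gene_id", "genome_id", "contig_id", "start", "end",
                 "strand", "seq", "cog_category", "family", MGE_FLAGS)]
    rownames(ge) <- NULL
    ctAll <- do.call(rbind, contigRows)
    rownames(ctAll) <- NULL

    truth <- list()
    evPath <- file.path(dir, "truth_events.tsv")
    if (file.exists(evPath))
        truth$hgt_events <- .readTsv(evPath,
                                     numeric = c("target_identity",
                                                 "realized_identity"))
    cpPath <- file.path(dir, "truth_cooccurring_pairs.tsv")
    if (file.exists(cpPath)) truth$cooccurring_pairs <- .readTsv(cpPath)
    eePath <- file.path(dir, "truth_env_effect.json")
    if (file.exists(eePath)) truth$env_effect <- jsonlite::read_json(eePath)

    gs <- new("GenomeSet", genomeTable = gt, contigTable = ctAll,
              geneTable = ge, tree = tree, patristic = pm, truth = truth)
    validObject(gs)

    se <- NULL
    bPath <- file.path(dir, "breadth.tsv")
    if (file.exists(bPath)) {
        readMat <- function(path) {
            df <- read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
            m <- as.matrix(df[, -1L, drop = FALSE])
            storage.mode(m) <- "double"
            rownames(m) <- df$sample_id
            t(m)
        }
        b <- readMat(bPath)
        r <- readMat(file.path(dir, "rpkm.tsv"))
        env <- .readTsv(file.path(dir, "env.tsv"))
        envNum <- env[, setdiff(names(env), "sample_id"), drop = FALSE]
        envNum[] <- lapply(envNum, as.numeric)
        rownames(envNum) <- env$sample_id
        frPath <- file.path(dir, "samples.tsv")
        fraction <- if (file.exists(frPath))
            .readTsv(frPath)$fraction else NULL
        se <- SampleExperiment(b, r, env = envNum, fraction = fraction)
    }
    list(genomes = gs, samples = se)
}
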