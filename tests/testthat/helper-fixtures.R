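# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

# The default 50-genome study fixture (seeds pinned inside simulateFixture).
defaultFixture <- function() {
    if (is.null(.fixtureCache$fx))
        .fixtureCache$fx <- simulateFixture(seed = 42)
    .fixtureCache$fx
}

# Cluster-RBH detection on the default fixture.
defaultDetection <- function() {
    if (is.null(.fixtureCache$det))
        .fixtureCache$det <- detectHgt(defaultFixture()$genomes)
    .fixtureCache$det
}

# A small fixture for cheap end-to-end paths.
smallFixture <- function() {
    if (is.null(.fixtureCache$small))
        .fixtureCache$small <- simulateFixture(nGenomes = 16L,
                                               genesPerGenome = 30L,
                                               geneLength = 500L,
                                               nRecent = 5L, nOlder = 3L,
                                               nSamples = 40L, seed = 7L)
    .fixtureCache$small
}

# Build a toy GenomeSet from explicit gene sequences: one contig per genome
# unless contig ids are given; genes laid head-to-tail.
makeToyGenomeSet <- function(genes, taxonomy) {
    genes$strand <- "+"
    if (is.null(genes$contig_id))
        genes$contig_id <- paste0(genes$genome_id, "_c1")
    rows <- split(seq_len(nrow(genes)), genes$contig_id)
    genes$start <- NA_integer_; genes$end <- NA_integer_
    ct <- lapply(names(rows), function(cid) {
        idx <- rows[[cid]]
        len <- nchar(genes$seq[idx])
        off <- cumsum(c(0L, len[-length(len)]))
        genes$start[idx] <<- off
        genes$end[idx] <<- off + len
        data.frame(contig_id = cid, genome_id = genes$genome_id[idx[1L]],
                   length = sum(len), stringsAsFactors = FALSE)
    })
    for (fl in c("promge_hit", "plasmid_contig", "virus_contig",
                 "provirus_contig"))
        if (is.null(genes[[fl]])) genes[[fl]] <- FALSE
    if (is.null(genes$cog_category)) genes$cog_category <- ""
    if (is.null(genes$family)) genes$family <- seq_len(nrow(genes))
    ids <- unique(genes$genome_id)
    gt <- data.frame(genome_id = ids,
                     taxonomy[match(ids, taxonomy$genome_id),
                              c("domain", "phylum", "class", "order",
                                "family", "genus", "species")],
                     completeness = 95, contamination = 1,
                     stringsAsFactors = FALSE)
    n <- length(ids)
    pm <- matrix(1, n, n, dimnames = list(ids, ids)); diag(pm) <- 0
    new("GenomeSet", genomeTable = gt,
        contigTable = do.call(rbind, ct),
        geneTable = genes, tree = NULL, patristic = pm, truth = list())
}

# A 7-rank taxonomy row.
taxRow <- function(genome_id, d = "d1", p = "p1", k = "c1", o = "o1",
                   f = "f1", g = "g1", s = "s1") {
    data.frame(genome_id = genome_id, domain = d, phylum = p, class = k,
               order = o, family = f, genus = g, species = s,
               stringsAsFactors = FALSE)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# Mutate a sequence to an exact number of mismatches.
mutateSeq <- function(seq, nMut) {
    v <- strsplit(seq, "")[[1L]]
    pos <- sample(length(v), nMut)
    v[pos] <- vapply(v[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    paste(v, collapse = "")
}

# Minimal presence-called SampleExperiment from a logical matrix.
presenceSE <- function(present, rpkm = NULL, fraction = NULL, env = NULL) {
    breadth <- ifelse(present, 0.8, 0)
    if (is.null(rpkm)) rpkm <- ifelse(present, 1, 0)
    se <- SampleExperiment(breadth, rpkm, env = env, fraction = fraction)
    callPresence(se)
}
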