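# Generator: taxonomy/tree concordance, substitution-model calibration,
# planted events and serialization round trips.

test_that("two-leaf tree gives the prescribed patristic distance", {
    spec <- taxonomySpec(branching = c(domain = 1L, phylum = 1L, class = 1L,
                                       order = 1L, family = 1L, genus = 1L,
                                       species = 2L))
    gs <- generateTaxonomyTree(spec, nGenomes = 2L, seed = 1L)
    pm <- patristicDist(gs)
    expect_identical(dim(pm), c(2L, 2L))
    expect_equal(diag(pm), c(G001 = 0, G002 = 0))
    expect_equal(pm[1L, 2L], spec$divergence[["species"]])
    # newick round-trips: sum of the two terminal branch lengths equals d
    tr <- phylogeny(gs)
    expect_equal(sum(tr$edge.length), pm[1L, 2L])
})

test_that("patristic matrix equals an independent path-sum over the newick", {
    gs <- generateTaxonomyTree(nGenomes = 50L, seed = 1L)
    tr <- phylogeny(gs)
    oracle <- ape::cophenetic.phylo(tr)
    ids <- genomeIds(gs)
    expect_equal(patristicDist(gs)[ids, ids], oracle[ids, ids],
                 tolerance = 1e-8)
})

test_that("taxonomy labels are concordant with tree distances", {
    gs <- generateTaxonomyTree(nGenomes = 50L, seed = 3L)
    pm <- patristicDist(gs)
    tax <- taxonomyTable(gs)
    ids <- genomeIds(gs)
    pr <- t(combn(ids, 2L))
    lev <- apply(pr, 1L, function(p) divergenceLevel(tax, p[1L], p[2L]))
    d <- pm[pr]
    ord <- c("within_genus", "genus", "family", "order", "class", "phylum",
             "domain")
    present <- ord[ord %in% lev]
    byLev <- split(d, factor(lev, levels = present))
    # strictly increasing: max at each level < min at the next level up
    for (i in seq_len(length(present) - 1L))
        expect_lt(max(byLev[[i]]), min(byLev[[i + 1L]]))
})

test_that("tree generation rejects oversized requests and bad specs", {
    spec <- taxonomySpec(branching = c(domain = 1L, phylum = 1L, class = 1L,
                                       order = 1L, family = 1L, genus = 1L,
                                       species = 2L))
    expect_error(generateTaxonomyTree(spec, nGenomes = 3L), "exceeds")
    expect_error(taxonomySpec(divergence = c(species = 0.3, genus = 0.2,
                                             family = 0.45, order = 0.6,
                                             class = 0.8, phylum = 1,
                                             domain = 1.3)),
                 "strictly increase")
})

test_that("ortholog identity decays with distance as the model predicts", {
    fx <- defaultFixture()
    gs <- fx$genomes
    ge <- geneTable(gs)
    tax <- taxonomyTable(gs)
    pm <- patristicDist(gs)
    planted <- plantedTruth(gs)$hgt_events
    touched <- unique(c(planted$gene_id_recipient, planted$gene_id_donor))
    ge <- ge[!ge$gene_id %in% touched & !grepl("hgt", ge$gene_id), ]
    ids <- genomeIds(gs)
    set.seed(11)
    # sample cross-genus ortholog pairs and compare identity to the exact
    # expectation under the branch-wise substitution model (Jukes-Cantor
    # composition), and check calibration below the detection threshold
    idsPairs <- t(combn(ids, 2L))
    lev <- apply(idsPairs, 1L, function(p)
        divergenceLevel(tax, p[1L], p[2L]))
    cross <- idsPairs[lev != "within_genus", , drop = FALSE]
    pick <- cross[sample(nrow(cross), 40L), , drop = FALSE]
    obs <- c(); expd <- c(); dist <- c()
    for (i in seq_len(nrow(pick))) {
        a <- ge[ge$genome_id == pick[i, 1L], ]
        b <- ge[ge$genome_id == pick[i, 2L], ]
        fams <- intersect(a$family, b$family)[1:5]
        for (f in fams) {
            obs <- c(obs, pairwiseIdentity(a$seq[a$family == f],
                                           b$seq[b$family == f]))
            d <- pm[pick[i, 1L], pick[i, 2L]]
            dist <- c(dist, d)
            expd <- c(expd, 1 - 0.75 * (1 - exp(-4 * d / 3)))
        }
    }
    expect_gte(length(obs), 100L)
    # no cross-genus ortholog reaches the 95% detection threshold
    expect_lt(max(obs), 0.95)
    # mean within 3 standard errors of the model expectation
    se3 <- 3 * sd(obs - expd) / sqrt(length(obs))
    expect_lt(abs(mean(obs - expd)), se3 + 0.002)
    # monotone decay: mean identity at genus-level pairs > domain-level
    expect_gt(mean(obs[dist == min(dist)]), mean(obs[dist == max(dist)]))
})

test_that("gene geometry invariants hold", {
    gs <- defaultFixture()$genomes
    ge <- geneTable(gs)
    expect_true(all(ge$end - ge$start == nchar(ge$seq)))
    clen <- setNames(contigTable(gs)$length, contigTable(gs)$contig_id)
    expect_true(all(ge$end <= clen[ge$contig_id]))
    expect_false(any(grepl("[^ACGT]", ge$seq[sample(nrow(ge), 200L)])))
})

test_that("planted events hit their identity targets with binomial noise", {
    gs <- defaultFixture()$genomes
    tr <- plantedTruth(gs)$hgt_events
    core <- tr[tr$type %in% c("recent", "older"), ]
    expect_identical(nrow(core), 40L)
    # truth completeness: one row per planted event, unique families
    expect_false(anyDuplicated(core$family) > 0)
    ge <- geneTable(gs)
    for (i in seq_len(nrow(core))) {
        e <- core[i, ]
        dSeq <- ge$seq[ge$gene_id == e$gene_id_donor]
        rSeq <- ge$seq[ge$gene_id == e$gene_id_recipient]
        # realized identity recorded in truth equals the Hamming identity
        expect_equal(pairwiseIdentity(dSeq, rSeq), e$realized_identity)
    }
    expect_true(all(core$realized_identity[core$type == "recent"] >= 0.99))
    old <- core$realized_identity[core$type == "older"]
    expect_true(all(old < 0.99))
    # binomial noise around targets: |realized - target| within 4 sd
    len <- 1000
    dev <- abs(core$realized_identity - core$target_identity)
    bound <- 4 * sqrt(core$target_identity * (1 - core$target_identity) /
                          len) + 1e-9
    expect_true(all(dev <= bound))
    # all recipients differ from donors at genus level or above
    tax <- taxonomyTable(gs)
    levs <- mapply(function(a, b) divergenceLevel(tax, a, b),
                   core$donor_genome, core$recipient_genome)
    expect_false(any(levs == "within_genus"))
    # negative controls flagged non-detectable
    ctrl <- tr[tr$type %in% c("short_contig_control",
                              "short_region_control"), ]
    expect_identical(nrow(ctrl), 2L)
    expect_false(any(ctrl$detectable))
    # short-contig control sits on a contig below the filter
    ct <- contigTable(gs)
    sc <- ctrl[ctrl$type == "short_contig_control", ]
    expect_lt(ct$length[ct$contig_id == sc$recipient_contig], 5000L)
})

test_that("sampled occupancy responds to the planted niche structure", {
    fx <- defaultFixture()
    se <- callPresence(fx$samples)
    pm <- SummarizedExperiment::assay(se, "present")
    expect_true(all(SummarizedExperiment::assay(se, "breadth") >= 0 &
                        SummarizedExperiment::assay(se, "breadth") <= 1))
    expect_true(all(SummarizedExperiment::assay(se, "rpkm") >= 0))
    # niche-sharing pairs overlap more than random pairs on average
    truth <- S4Vectors::metadata(fx$samples)$truth
    cp <- truth$cooccurring_pairs
    jacc <- function(a, b) sum(pm[a, ] & pm[b, ]) /
        max(1L, min(sum(pm[a, ]), sum(pm[b, ])))
    shared <- mapply(jacc, cp$genome_a, cp$genome_b)
    set.seed(5)
    ids <- rownames(pm)
    rnd <- replicate(200L, {
        p <- sample(ids, 2L)
        jacc(p[1L], p[2L])
    })
    expect_gt(mean(shared), mean(rnd))
})

test_that("degenerate niche and missing niche models warn", {
    gs <- smallFixture()$genomes
    expect_warning(generateSamples(gs, nSamples = 25L, niche = NULL,
                                   hgtEnvEffect = NULL, seed = 1L),
                   "powerless")
})

test_that("fixture round-trips through disk bit-exactly", {
    fx <- smallFixture()
    dir <- file.path(tempdir(), "fixture-roundtrip")
    writeFixture(fx$genomes, fx$samples, dir)
    back <- readFixture(dir)
    gs0 <- fx$genomes; gs1 <- back$genomes
    cols <- c("gene_id", "genome_id", "contig_id", "start", "end", "strand",
              "seq", "cog_category", "family", "promge_hit",
              "plasmid_contig", "virus_contig", "provirus_contig")
    ge0 <- geneTable(gs0)[, cols]
    ge1 <- geneTable(gs1)[, cols]
    ord0 <- order(ge0$genome_id, ge0$family)
    ord1 <- order(ge1$genome_id, ge1$family)
    expect_identical(`rownames<-`(ge0[ord0, ], NULL),
                     `rownames<-`(ge1[ord1, ], NULL))
    ct0 <- contigTable(gs0); ct1 <- contigTable(gs1)
    expect_identical(`rownames<-`(ct0[order(ct0$contig_id), ], NULL),
                     `rownames<-`(ct1[order(ct1$contig_id), ], NULL))
    expect_identical(genomeTable(gs0), genomeTable(gs1))
    expect_identical(patristicDist(gs0), patristicDist(gs1))
    expect_identical(plantedTruth(gs0)$hgt_events,
                     plantedTruth(gs1)$hgt_events)
    # newick re-parse yields the same patristic structure as the original
    expect_equal(ape::cophenetic.phylo(phylogeny(gs1))[genomeIds(gs0),
                                                       genomeIds(gs0)],
                 patristicDist(gs0), tolerance = 1e-8)
    # sample matrices identical
    expect_identical(
        SummarizedExperiment::assay(fx$samples, "breadth"),
        SummarizedExperiment::assay(back$samples, "breadth"))
    expect_identical(
        SummarizedExperiment::assay(fx$samples, "rpkm"),
        SummarizedExperiment::assay(back$samples, "rpkm"))
    cd0 <- as.data.frame(SummarizedExperiment::colData(fx$samples))
    cd1 <- as.data.frame(SummarizedExperiment::colData(back$samples))
    expect_equal(cd0[, sort(names(cd0))], cd1[, sort(names(cd0))],
                 tolerance = 0)
    # GFF3 on disk is 1-based inclusive
    g1 <- genomeIds(gs0)[1L]
    gff <- readLines(file.path(dir, "genomes", paste0(g1, ".gff")))
    feat <- strsplit(gff[!startsWith(gff, "#")][1L], "\t")[[1L]]
    ge <- geneTable(gs0)
    row <- ge[ge$genome_id == g1 & ge$contig_id == feat[1L] &
                  ge$gene_id == sub("^ID=([^;]+).*", "\\1", feat[9L]), ]
    expect_identical(as.integer(feat[4L]), row$start + 1L)
    expect_identical(as.integer(feat[5L]), row$end)
})
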