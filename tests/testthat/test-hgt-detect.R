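# HGT detection: identity kernels, greedy clustering vs an all-pairs oracle,
# cross-genus RBH calling, seed-and-extend segments and region events.

test_that("pairwise identity matches Hamming and edit-distance oracles", {
    set.seed(21)
    a <- randomSeq(100L)
    expect_identical(pairwiseIdentity(a, a), 1)
    b <- mutateSeq(a, 1L)
    expect_equal(pairwiseIdentity(a, b), 0.99)
    expect_error(pairwiseIdentity("", a), "empty")
    # unequal lengths: 1 - editDistance / max(len), vs utils::adist
    for (i in 1:30) {
        x <- randomSeq(60L)
        y <- randomSeq(sample(40:60, 1L))
        expect_equal(pairwiseIdentity(x, y),
                     1 - drop(utils::adist(x, y)) / max(nchar(x), nchar(y)))
        expect_identical(pairwiseIdentity(x, y), pairwiseIdentity(y, x))
    }
})

test_that("greedy clustering agrees with a brute-force oracle", {
    set.seed(22)
    base <- replicate(8L, randomSeq(300L))
    seqs <- c(base,
              vapply(base[1:5], function(s) mutateSeq(s, 5L), character(1)),
              vapply(base[1:3], function(s) mutateSeq(s, 40L), character(1)),
              replicate(14L, randomSeq(sample(260:300, 1L))))
    genes <- data.frame(gene_id = sprintf("g%02d", seq_along(seqs)),
                        seq = unname(seqs), stringsAsFactors = FALSE)
    got <- clusterGenes(genes, 0.95, 0.95)

    # oracle: same ordering and tie rules, every gene checked against every
    # existing representative in insertion order
    ord <- order(-nchar(genes$seq), genes$gene_id)
    oseq <- genes$seq[ord]
    reps <- integer(0); cl <- integer(length(oseq))
    for (i in seq_along(oseq)) {
        assigned <- FALSE
        for (r in seq_along(reps)) {
            s1 <- oseq[i]; s2 <- oseq[reps[r]]
            lr <- min(nchar(s1), nchar(s2)) / max(nchar(s1), nchar(s2))
            if (lr < 0.95) next
            if (pairwiseIdentity(s1, s2) >= 0.95 - 1e-12) {
                cl[i] <- r; assigned <- TRUE; break
            }
        }
        if (!assigned) { reps <- c(reps, i); cl[i] <- length(reps) }
    }
    expect_identical(got$cluster_id, sprintf("CL%05d", cl))
    # trivial cases
    two <- data.frame(gene_id = c("a", "b"), seq = c(base[1L], base[1L]))
    expect_identical(unique(clusterGenes(two)$cluster_id), "CL00001")
    far <- data.frame(gene_id = c("a", "b"),
                      seq = c(base[1L], mutateSeq(base[1L], 30L)))
    expect_identical(length(unique(clusterGenes(far)$cluster_id)), 2L)
})

test_that("RBH calling is cross-genus only, reciprocal, and filtered", {
    set.seed(23)
    tax <- rbind(taxRow("GA", g = "g1", s = "s1"),
                 taxRow("GB", g = "g1", s = "s2"),     # same genus as GA
                 taxRow("GC", f = "f2", g = "g9", s = "s9"))  # other family
    g <- randomSeq(1000L)
    genes <- data.frame(
        gene_id = c("GA_x", "GB_x", "GC_x"),
        genome_id = c("GA", "GB", "GC"),
        seq = c(g, mutateSeq(g, 2L), g),
        stringsAsFactors = FALSE)
    gs <- makeToyGenomeSet(genes, tax)
    # pad contigs above the length filter with extra unrelated genes
    pad <- data.frame(gene_id = paste0(c("GA", "GB", "GC"), "_pad"),
                      genome_id = c("GA", "GB", "GC"),
                      seq = replicate(3L, randomSeq(5000L)),
                      stringsAsFactors = FALSE)
    gs <- makeToyGenomeSet(rbind(genes, pad), tax)
    cl <- clusterGenes(geneTable(gs))
    ev <- callRbhHgt(cl, taxonomyTable(gs), contigTable(gs))
    # GA-GB is within genus: no event despite identical genes; GA-GC and
    # GB-GC are cross-family
    expect_false(any(ev$genome_a == "GA" & ev$genome_b == "GB"))
    gaGc <- ev[ev$genome_a == "GA" & ev$genome_b == "GC", ]
    expect_identical(nrow(gaGc), 1L)
    expect_identical(gaGc$identity, 1)
    expect_identical(gaGc$identity_bin, "ge99")
    expect_identical(gaGc$divergence_level, "family")
    expect_error(callRbhHgt(cl, tax[tax$genome_id != "GC", ],
                            contigTable(gs)), "GC")
})

test_that("events on short contigs are removed after calling", {
    gs <- defaultFixture()$genomes
    det <- defaultDetection()
    tr <- plantedTruth(gs)$hgt_events
    sc <- tr[tr$type == "short_contig_control", ]
    # the planted copy is perfect, so only the contig filter removes it
    expect_false(sc$gene_id_recipient %in%
                     c(det$events$gene_a, det$events$gene_b))
})

test_that("identity bins are consistent with identity", {
    ev <- defaultDetection()$events
    expect_identical(ev$identity_bin == "ge99", ev$identity >= 0.99)
    expect_true(all(ev$identity >= 0.95))
})

test_that("event tables are deterministic and symmetric in input order", {
    gs <- smallFixture()$genomes
    d1 <- detectHgt(gs)
    d2 <- detectHgt(gs)
    expect_identical(d1$events, d2$events)
    # shuffling gene rows leaves the event set unchanged
    ge <- geneTable(gs)
    set.seed(31)
    gs2 <- gs
    gs2@geneTable <- ge[sample(nrow(ge)), ]
    d3 <- detectHgt(gs2)
    expect_identical(d1$events, d3$events)
})

test_that("segment finding recovers exact and near-exact regions", {
    set.seed(24)
    tax <- rbind(taxRow("GA"), taxRow("GB", f = "f2", g = "g2", s = "s2"))
    shared <- randomSeq(2000L)
    genes <- data.frame(gene_id = c("GA_g1", "GB_g1"),
                        genome_id = c("GA", "GB"),
                        seq = c(shared, shared), stringsAsFactors = FALSE)
    gs <- makeToyGenomeSet(genes, tax)
    seg <- findIdentitySegments(gs, "GA", "GB")
    expect_identical(nrow(seg), 1L)
    expect_identical(seg$length, 2000L)
    expect_identical(seg$identity, 1)
    expect_identical(seg$score, 2000)

    # planted 600 bp region at ~0.99 identity inside divergent backgrounds
    region <- randomSeq(600L)
    a <- paste0(randomSeq(1500L), region, randomSeq(1500L))
    b <- paste0(randomSeq(800L), mutateSeq(region, 6L), randomSeq(1200L))
    gs2 <- makeToyGenomeSet(
        data.frame(gene_id = c("GA_g1", "GB_g1"),
                   genome_id = c("GA", "GB"), seq = c(a, b),
                   stringsAsFactors = FALSE), tax)
    seg2 <- findIdentitySegments(gs2, "GA", "GB")
    expect_identical(nrow(seg2), 1L)
    ovl <- min(seg2$end_a, 1500L + 600L) - max(seg2$start_a, 1500L)
    expect_gte(ovl / 600, 0.9)
    expect_gte(seg2$identity, 0.95)

    # 400 bp perfect region: below the length minimum, no segment
    c400 <- randomSeq(400L)
    a3 <- paste0(randomSeq(1000L), c400, randomSeq(1000L))
    b3 <- paste0(randomSeq(500L), c400, randomSeq(1500L))
    gs3 <- makeToyGenomeSet(
        data.frame(gene_id = c("GA_g1", "GB_g1"),
                   genome_id = c("GA", "GB"), seq = c(a3, b3),
                   stringsAsFactors = FALSE), tax)
    expect_identical(nrow(findIdentitySegments(gs3, "GA", "GB")), 0L)

    # k larger than every contig: empty result with a warning
    gsS <- makeToyGenomeSet(
        data.frame(gene_id = c("GA_g1", "GB_g1"),
                   genome_id = c("GA", "GB"),
                   seq = c(randomSeq(20L), randomSeq(20L)),
                   stringsAsFactors = FALSE), tax)
    expect_warning(s <- findIdentitySegments(gsS, "GA", "GB"), "contig")
    expect_identical(nrow(s), 0L)
})

test_that("region events intersect genes and resolve overlaps by score", {
    set.seed(25)
    tax <- rbind(taxRow("GA"), taxRow("GB", f = "f2", g = "g2", s = "s2"),
                 taxRow("GD", g = "g1", s = "s3"))
    # two adjacent 3 kb genes in GA share their junction-spanning 2 kb with
    # a single GB gene
    gene1 <- randomSeq(3000L)
    gene2 <- randomSeq(3000L)
    shared <- paste0(substr(gene1, 2001L, 3000L), substr(gene2, 1L, 1000L))
    genes <- data.frame(
        gene_id = c("GA_g1", "GA_g2", "GB_g1", "GB_g2"),
        genome_id = c("GA", "GA", "GB", "GB"),
        seq = c(gene1, gene2, shared, randomSeq(4000L)),
        stringsAsFactors = FALSE)
    gs <- makeToyGenomeSet(genes, tax)
    seg <- findIdentitySegments(gs, "GA", "GB")
    ev <- callRegionHgt(seg, gs)
    gaGenes <- ev$gene_id[ev$gene_genome == "GA"]
    expect_setequal(gaGenes, c("GA_g1", "GA_g2"))  # one segment, two genes

    # same-genus pair yields zero events regardless of segments
    segD <- seg
    segD$genome_b <- "GD"
    segD$contig_b <- "GD_c1"
    gsD <- makeToyGenomeSet(
        rbind(genes, data.frame(gene_id = "GD_g1", genome_id = "GD",
                                seq = shared, stringsAsFactors = FALSE)),
        tax)
    sameGenus <- findIdentitySegments(gsD, "GA", "GD")
    expect_identical(nrow(callRegionHgt(sameGenus, gsD)), 0L)

    # unknown contig reference errors
    segBad <- seg
    segBad$contig_a <- "nope"
    expect_error(callRegionHgt(segBad, gs), "unknown contig")
})

test_that("overlapping segments keep only the highest-scoring hit", {
    tax <- rbind(taxRow("GA"), taxRow("GB", f = "f2", g = "g2", s = "s2"))
    set.seed(26)
    gs <- makeToyGenomeSet(
        data.frame(gene_id = c("GA_g1", "GB_g1"),
                   genome_id = c("GA", "GB"),
                   seq = c(randomSeq(6000L), randomSeq(6000L)),
                   stringsAsFactors = FALSE), tax)
    segs <- data.frame(
        genome_a = "GA", contig_a = "GA_c1",
        start_a = c(100L, 400L), end_a = c(1000L, 900L),
        genome_b = "GB", contig_b = "GB_c1",
        start_b = c(100L, 400L), end_b = c(1000L, 900L),
        length = c(900L, 500L), identity = c(1, 1), score = c(900, 500),
        stringsAsFactors = FALSE)
    ev <- callRegionHgt(segs, gs)
    expect_true(all(ev$seg_start %in% c(100L)))
    expect_false(any(ev$seg_start == 400L))
})

test_that("divergence levels walk the taxonomy correctly", {
    a <- c("d1", "p1", "c1", "o1", "f1", "g1", "s1")
    expect_identical(divergenceLevelFromLabels(a, replace(a, 7, "s2")),
                     "within_genus")
    expect_identical(divergenceLevelFromLabels(a, a), "within_genus")
    expect_identical(
        divergenceLevelFromLabels(a, c("d1", "p1", "c1", "o1", "f2", "g2",
                                       "s2")), "family")
    expect_identical(
        divergenceLevelFromLabels(a, c("d2", "p2", "c2", "o2", "f2", "g2",
                                       "s2")), "domain")
    expect_error(divergenceLevelFromLabels(a, c(a[-7], NA)), "missing")
})

test_that("per-level event rates normalize by genome-pair counts", {
    tax <- rbind(taxRow("G1", f = "f1", g = "g1", s = "s1"),
                 taxRow("G2", f = "f1", g = "g2", s = "s2"),
                 taxRow("G3", f = "f2", g = "g3", s = "s3"),
                 taxRow("G4", f = "f2", g = "g4", s = "s4"))
    # genus-level pairs: (G1,G2), (G3,G4); family-level: 4 cross pairs
    ev <- data.frame(divergence_level = c("genus", "family", "family"))
    out <- eventsPerLevel(ev, tax)
    expect_identical(out$n_genome_pairs[out$level == "genus"], 2L)
    expect_identical(out$n_genome_pairs[out$level == "family"], 4L)
    expect_equal(out$rate[out$level == "genus"], 0.5)
    expect_equal(out$rate[out$level == "family"], 0.5)
    expect_true(is.na(out$rate[out$level == "domain"]))
    none <- eventsPerLevel(ev[0, , drop = FALSE], tax)
    expect_true(all(none$n_events == 0L))
})

test_that("planted divergence-level profile carries into called events", {
    gs <- defaultFixture()$genomes
    ev <- defaultDetection()$events
    tab <- eventsPerLevel(ev, taxonomyTable(gs))
    tr <- plantedTruth(gs)$hgt_events
    tr <- tr[tr$detectable, ]
    planted <- table(factor(tr$divergence_level, levels = tab$level))
    expect_equal(as.integer(planted), tab$n_events)
})
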