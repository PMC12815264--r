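# Synthetic data generation: taxonomy-consistent phylogenies, vertically
# diverged gene families, planted HGT events, niche-driven sample occupancy
# and environmental covariates, all with recorded ground truth.

BASES <- c("A", "C", "G", "T")

#' Specification of a synthetic seven-rank taxonomy
#'
#' Defines how many child lineages each taxon spawns at every rank and how
#' much sequence divergence (expected substitutions per site along the tree
#' path) separates two genomes whose lowest differing rank is a given level.
#' Divergence must increase strictly from species-level splits to domain-level
#' splits, so taxonomy and tree distances stay concordant.
#'
#' Defaults place within-genus (species-level) splits at 0.12
#' substitutions/site -- far enough that even congeneric orthologs fall below
#' the 95\% identity detection threshold, which calibrates the vertical
#' background of the simulation (every >= 95\% cross-genus match is a planted
#' event).
#'
#' @param branching named integer vector, children per parent at each rank
#'   (domain = number of domains).
#' @param divergence named numeric vector, patristic distance between genome
#'   pairs whose divergence level is the named rank; strictly increasing from
#'   species to domain.
#' @return a list of class \code{taxonomySpec}.
#' @export
taxonomySpec <- function(branching = c(domain = 2L, phylum = 2L, class = 1L,
                                       order = 2L, family = 2L, genus = 2L,
                                       species = 2L),
                         divergence = c(species = 0.12, genus = 0.30,
                                        family = 0.45, order = 0.60,
                                        class = 0.80, phylum = 1.00,
                                        domain = 1.30)) {
    stopifnot(identical(sort(names(branching)), sort(TAXONOMY_RANKS)),
              identical(sort(names(divergence)), sort(TAXONOMY_RANKS)))
    branching <- branching[TAXONOMY_RANKS]
    divergence <- divergence[TAXONOMY_RANKS]
    if (any(branching < 1L)) stop("branching counts must be >= 1")
    dd <- divergence[rev(TAXONOMY_RANKS)]  # species ... domain
    if (any(diff(dd) <= 0))
        stop("divergence must strictly increase from species to domain splits")
    structure(list(branching = branching, divergence = divergence),
              class = "taxonomySpec")
}

# Height of the internal node at which two lineages differing at `rank`
# coalesce: half the prescribed patristic distance.
.rankHeights <- function(spec) spec$divergence / 2

#' Generate a taxonomy-consistent genome phylogeny
#'
#' Builds an ultrametric species tree following the branching plan of a
#' \code{\link{taxonomySpec}}, samples \code{nGenomes} leaves (one genome per
#' species), and returns a \linkS4class{GenomeSet} skeleton carrying the
#' taxonomy table, the pruned \code{phylo} tree with branch lengths, and the
#' patristic distance matrix. Two genomes sharing a genus are always closer in
#' the tree than any cross-family pair, by construction.
#'
#' @param spec a \code{\link{taxonomySpec}}.
#' @param nGenomes number of genomes (leaves) to sample; must not exceed the
#'   number of species the spec can produce.
#' @param seed integer RNG seed.
#' @return a \linkS4class{GenomeSet} with empty contig and gene tables.
#' @export
generateTaxonomyTree <- function(spec = taxonomySpec(), nGenomes = 50L,
                                 seed = 1L) {
    if (nGenomes < 2L) stop("nGenomes must be >= 2")
    nSpecies <- prod(spec$branching)
    if (nGenomes > nSpecies)
        stop("nGenomes (", nGenomes, ") exceeds the ", nSpecies,
             " species this taxonomySpec can produce")
    set.seed(seed)

    br <- spec$branching
    # enumerate full lineages: matrix species x 7 of child indices
    grids <- lapply(TAXONOMY_RANKS, function(r) seq_len(br[[r]]))
    names(grids) <- TAXONOMY_RANKS
    lin <- expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE)[, TAXONOMY_RANKS]
    keep <- sort(sample.int(nSpecies, nGenomes))
    lin <- lin[keep, , drop = FALSE]

    # unique label per taxon = cumulative path through the hierarchy
    width <- c(domain = 1L, phylum = 2L, class = 2L, order = 2L, family = 2L,
               genus = 3L, species = 3L)
    prefix <- c(domain = "d", phylum = "p", class = "c", order = "o",
                family = "f", genus = "g", species = "s")
    labels <- as.data.frame(lin)
    path <- rep("", nrow(lin))
    for (r in TAXONOMY_RANKS) {
        path <- paste0(path, ".", lin[[r]])
        key <- factor(path, levels = unique(path))
        labels[[r]] <- sprintf("%s%0*d", prefix[[r]], width[[r]],
                               as.integer(key))
    }
    genomeIdsV <- sprintf("G%03d", seq_len(nGenomes))

    heights <- .rankHeights(spec)  # node heights per divergence level
    newick <- .buildNewick(labels, genomeIdsV, heights)
    tree <- ape::read.tree(text = newick)

    # patristic distances follow directly from the divergence levels
    pm <- matrix(0, nGenomes, nGenomes,
                 dimnames = list(genomeIdsV, genomeIdsV))
    for (i in seq_len(nGenomes - 1L)) {
        for (j in seq(i + 1L, nGenomes)) {
            lev <- divergenceLevelFromLabels(unlist(labels[i, ]),
                                             unlist(labels[j, ]))
            d <- if (lev == "within_genus")
                spec$divergence[["species"]] else spec$divergence[[lev]]
            pm[i, j] <- pm[j, i] <- d
        }
    }

    gt <- data.frame(genome_id = genomeIdsV, labels,
                     completeness = round(runif(nGenomes, 80, 100), 2),
                     contamination = round(runif(nGenomes, 0, 4), 2),
                     stringsAsFactors = FALSE)
    rownames(gt) <- NULL
    new("GenomeSet", genomeTable = gt,
        contigTable = data.frame(contig_id = character(),
                                 genome_id = character(),
                                 length = integer()),
        geneTable = data.frame(),
        tree = tree, patristic = pm,
        truth = list(spec = spec, seed = seed))
}

# Recursively assemble a newick string over the retained lineages.
# `labels` rows are leaves in a fixed order; grouping at successive ranks
# defines internal nodes; unary nodes are collapsed.
.buildNewick <- function(labels, leafNames, heights) {
    rec <- function(rows, rankIdx, parentHeight) {
        if (length(rows) == 1L)
            return(sprintf("%s:%.10g", leafNames[rows], parentHeight))
        rank <- TAXONOMY_RANKS[rankIdx]
        groups <- split(rows, factor(labels[[rank]][rows],
                                     levels = unique(labels[[rank]][rows])))
        if (length(groups) == 1L)
            return(rec(rows, rankIdx + 1L, parentHeight))
        # children of this node differ at `rank`: height = divergence[rank]/2
        h <- unname(heights[[rank]])
        kids <- vapply(groups, function(g) rec(g, rankIdx + 1L, h),
                       character(1))
        sprintf("(%s):%.10g", paste(kids, collapse = ","), parentHeight - h)
    }
    rootRows <- seq_len(nrow(labels))
    # root corresponds to the domain-level split; if only one domain is
    # retained the recursion collapses it automatically
    hRoot <- unname(heights[["domain"]])
    inner <- rec(rootRows, 1L, hRoot)
    # strip the dangling root branch length
    paste0(sub(":[0-9.eE+-]+$", "", inner), ";")
}

# Mutate an integer-coded sequence (0..3) along a branch of length bl:
# each site substitutes with probability 1 - exp(-rate * bl), uniformly to
# one of the three alternative bases.
.mutateSeq <- function(x, bl, rate) {
    if (bl <= 0) return(x)
    m <- 1 - exp(-rate * bl)
    hit <- which(runif(length(x)) < m)
    if (length(hit))
        x[hit] <- (x[hit] + sample.int(3L, length(hit), replace = TRUE)) %% 4L
    x
}

#' Evolve gene families down the genome phylogeny
#'
#' Simulates \code{genesPerGenome} single-copy gene families: each family gets
#' a random root sequence which is evolved down the tree under a
#' Jukes-Cantor-like model (per branch of length b, every site substitutes
#' independently with probability 1 - exp(-rate * b), uniformly to one of the
#' three alternative bases; no indels). Expected ortholog identity therefore
#' decays with patristic distance d as 1 - (3/4)(1 - exp(-4 rate d / 3)), and
#' with the default taxonomy spec cross-genus orthologs sit near 74\%
#' identity -- far below the 95\% HGT detection threshold.
#'
#' Each genome's genes are then laid out head-to-tail on 1--5 contigs
#' (uniform), all on the + strand; a contig's sequence is the concatenation of
#' its genes. Gene families also receive COG category labels (a fraction left
#' unannotated) recorded in the gene table.
#'
#' @param gs a \linkS4class{GenomeSet} skeleton from
#'   \code{\link{generateTaxonomyTree}}.
#' @param genesPerGenome,geneLength family count and length (bp,
#'   >= 100).
#' @param rate substitution rate scaling per unit branch length.
#' @param annotatedFrac fraction of families given a COG category.
#' @param cogPool candidate COG category letters for family annotation.
#' @param seed integer RNG seed.
#' @return the \code{GenomeSet} with contig and gene tables filled in.
#' @export
evolveGenes <- function(gs, genesPerGenome = 100L, geneLength = 1000L,
                        rate = 1, annotatedFrac = 0.8,
                        cogPool = c("C", "E", "F", "G", "H", "I", "J", "K",
                                    "L", "M", "N", "O", "P", "Q", "T", "U",
                                    "V"), seed = 2L) {
    if (geneLength < 100L) stop("geneLength must be >= 100")
    set.seed(seed)
    tree <- phylogeny(gs)
    ids <- genomeIds(gs)
    nTip <- length(tree$tip.label)
    nNode <- nTip + tree$Nnode
    edges <- tree$edge
    bl <- tree$edge.length
    ord <- reorderPreorder(tree)

    root <- nTip + 1L
    leafSeqs <- vector("list", genesPerGenome)
    for (f in seq_len(genesPerGenome)) {
        seqs <- vector("list", nNode)
        seqs[[root]] <- sample(0:3, geneLength, replace = TRUE)
        for (e in ord) {
            p <- edges[e, 1L]; ch <- edges[e, 2L]
            seqs[[ch]] <- .mutateSeq(seqs[[p]], bl[e], rate)
        }
        leafSeqs[[f]] <- seqs[seq_len(nTip)]
    }
    tipIndex <- match(ids, tree$tip.label)

    # COG categories per family (prokaryote-style letters; A/B/Y/Z rare
    # eukaryotic categories deliberately absent from the default pool)
    famCog <- sample(cogPool, genesPerGenome, replace = TRUE)
    famCog[runif(genesPerGenome) > annotatedFrac] <- ""

    geneRows <- vector("list", length(ids))
    contigRows <- vector("list", length(ids))
    for (gi in seq_along(ids)) {
        g <- ids[gi]
        # gene order is independently shuffled per genome: gene order is not
        # conserved between distant genomes, so matching diagonals between
        # genome pairs are confined to single gene pairs
        famOrder <- sample.int(genesPerGenome)
        nContig <- sample.int(5L, 1L)
        # split the gene list into nContig contiguous runs
        cuts <- sort(sample.int(genesPerGenome - 1L,
                                min(nContig - 1L, genesPerGenome - 1L)))
        contigOf <- findInterval(seq_len(genesPerGenome) - 1L, cuts) + 1L
        seqChar <- vapply(famOrder, function(f)
            paste(BASES[leafSeqs[[f]][[tipIndex[gi]]] + 1L], collapse = ""),
            character(1))
        off <- integer(genesPerGenome)
        pos <- integer(max(contigOf))
        for (i in seq_len(genesPerGenome)) {
            ct <- contigOf[i]
            off[i] <- pos[ct]
            pos[ct] <- pos[ct] + geneLength
        }
        contigIdsV <- sprintf("%s_c%d", g, seq_len(max(contigOf)))
        contigRows[[gi]] <- data.frame(contig_id = contigIdsV, genome_id = g,
                                       length = pos[seq_len(max(contigOf))],
                                       stringsAsFactors = FALSE)
        geneRows[[gi]] <- data.frame(
            gene_id = sprintf("%s_f%03d", g, famOrder),
            genome_id = g,
            contig_id = contigIdsV[contigOf],
            start = off, end = off + geneLength, strand = "+",
            seq = seqChar, cog_category = famCog[famOrder],
            family = famOrder,
            promge_hit = FALSE, plasmid_contig = FALSE, virus_contig = FALSE,
            provirus_contig = FALSE, stringsAsFactors = FALSE)
    }
    gs@contigTable <- do.call(rbind, contigRows)
    gs@geneTable <- do.call(rbind, geneRows)
    rownames(gs@contigTable) <- rownames(gs@geneTable) <- NULL
    gs@truth$gene_params <- list(genesPerGenome = genesPerGenome,
                                 geneLength = geneLength, rate = rate)
    validObject(gs)
    gs
}

# Preorder over edges of a phylo (parents visited before children).
reorderPreorder <- function(tree) {
    nTip <- length(tree$tip.label)
    root <- nTip + 1L
    childEdges <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
    out <- integer(0)
    stack <- as.character(root)
    while (length(stack)) {
        node <- stack[[1L]]; stack <- stack[-1L]
        es <- childEdges[[node]]
        if (is.null(es)) next
        out <- c(out, es)
        stack <- c(as.character(tree$edge[es, 2L]), stack)
    }
    out
}

# Exact expected ortholog identity under the branch-wise substitution model
# for total path length d: substitution matrices (1-m)I + m(J-I)/3 compose
# into the Jukes-Cantor form in the continuous limit.
expectedIdentity <- function(d, rate = 1) 1 - 0.75 * (1 - exp(-4 * rate * d / 3))

#' Assign genomes to niche groups with shared environmental responses
#'
#' Partitions genomes into groups; each group responds logistically to one or
#' two environmental variables with shared slopes, so genomes within a group
#' co-occur above chance across samples. Within-group pairs are the planted
#' co-occurring pairs recorded in the truth.
#'
#' @param gs a \linkS4class{GenomeSet}.
#' @param nGroups number of niche groups.
#' @param envVars names of candidate driver variables.
#' @param slopeRange absolute slope range for the logistic response.
#' @param seed integer RNG seed.
#' @return a list with \code{assignment} (genome -> group), \code{groups}
#'   (per-group drivers and slopes) and \code{cooccurring_pairs}.
#' @export
nicheModel <- function(gs, nGroups = 8L,
                       envVars = c("temperature", "nitrate", "oxygen"),
                       slopeRange = c(1.2, 2.0), seed = 3L) {
    set.seed(seed)
    ids <- genomeIds(gs)
    grp <- sample(rep_len(seq_len(nGroups), length(ids)))
    groups <- lapply(seq_len(nGroups), function(k) {
        v <- sample(envVars, sample(1:2, 1L))
        b <- runif(length(v), slopeRange[1], slopeRange[2]) *
            sample(c(-1, 1), length(v), replace = TRUE)
        list(vars = v, slopes = b)
    })
    pairs <- do.call(rbind, lapply(seq_len(nGroups), function(k) {
        m <- ids[grp == k]
        if (length(m) < 2L) return(NULL)
        t(combn(m, 2L))
    }))
    list(assignment = setNames(grp, ids), groups = groups,
         cooccurring_pairs = data.frame(genome_a = pairs[, 1L],
                                        genome_b = pairs[, 2L],
                                        stringsAsFactors = FALSE))
}

#' Plant horizontal gene transfer events into a simulated genome set
#'
#' Copies gene sequences between cross-genus genome pairs. "Recent" events are
#' copied at a target identity drawn from [0.99, 1]; "older" events are
#' mutated to a target drawn from [0.955, 0.985] (binomial site sampling, so
#' realized identity carries binomial noise and is recorded in the truth).
#' The transferred copy overwrites the recipient's own ortholog of the donated
#' family, so each planted event yields exactly one >= 95\% cross-genus gene
#' pair against a vertical background far below threshold.
#'
#' Pair sampling can be biased toward planted co-occurring pairs
#' (\code{cooccurWeight}) and toward phylogenetically close pairs
#' (\code{distanceDecay}), which plants the positive co-occurrence and
#' negative distance associations the downstream regression should recover.
#'
#' Two negative controls can be added: an event whose recipient gene is
#' rehoused on a 4000 bp contig (removable by the < 5000 bp contig filter) and
#' a 400 bp perfect sub-gene region (below the 500 bp segment minimum).
#'
#' @param gs a \linkS4class{GenomeSet} with genes evolved.
#' @param nRecent,nOlder planted event counts for the >= 99\% and 95--99\%
#'   identity bins.
#' @param niche optional \code{\link{nicheModel}} output used for pair bias.
#' @param cooccurWeight multiplicative sampling weight for niche-sharing
#'   pairs.
#' @param distanceDecay exponential decay of pair weight with patristic
#'   distance.
#' @param cogBias optional COG category; when set, donated families are drawn
#'   only from that category (plants a functional enrichment).
#' @param addControls logical; plant the two filter negative controls.
#' @param seed integer RNG seed.
#' @return the \code{GenomeSet} with modified genes and a
#'   \code{truth$hgt_events} table.
#' @export
plantHgtEvents <- function(gs, nRecent = 28L, nOlder = 12L, niche = NULL,
                           cooccurWeight = 8, distanceDecay = 1.5,
                           cogBias = NULL, addControls = TRUE, seed = 4L) {
    set.seed(seed)
    ids <- genomeIds(gs)
    tax <- taxonomyTable(gs)
    ge <- geneTable(gs)
    pm <- patristicDist(gs)
    nEv <- nRecent + nOlder

    pr <- t(combn(ids, 2L))
    lev <- apply(pr, 1L, function(p) divergenceLevel(tax, p[1L], p[2L]))
    eligible <- pr[lev != "within_genus", , drop = FALSE]
    if (!nrow(eligible)) stop("no eligible cross-genus genome pair to plant into")
    w <- exp(-distanceDecay * pm[eligible])
    if (!is.null(niche)) {
        key <- function(a, b) paste(pmin(a, b), pmax(a, b))
        cp <- niche$cooccurring_pairs
        shared <- key(eligible[, 1L], eligible[, 2L]) %in%
            key(cp$genome_a, cp$genome_b)
        w <- w * ifelse(shared, cooccurWeight, 1)
    }

    fams <- sort(unique(ge$family))
    if (!is.null(cogBias)) {
        famCog <- ge$cog_category[match(fams, ge$family)]
        fams <- fams[famCog == cogBias]
        if (length(fams) < nEv + 2L * addControls)
            stop("not enough families in COG category ", cogBias)
    }
    famPick <- sample(fams, nEv + 2L * addControls)

    # recent targets sit well inside the >= 99% bin so binomial mutation
    # noise rarely demotes a recent event into the 95-99% bin; the planted
    # recent share (default 28/40 = 70%) then carries through to the called
    # events, matching the recent-dominated mix the detector should see
    drawTarget <- function(recent) {
        if (recent) runif(1, 0.995, 1) else runif(1, 0.955, 0.985)
    }

    events <- vector("list", nEv)
    for (i in seq_len(nEv)) {
        pi <- sample.int(nrow(eligible), 1L, prob = w)
        donor <- eligible[pi, 1L]; recip <- eligible[pi, 2L]
        if (runif(1) < 0.5) { tmp <- donor; donor <- recip; recip <- tmp }
        fam <- famPick[i]
        recent <- i <= nRecent
        target <- drawTarget(recent)
        dRow <- which(ge$genome_id == donor & ge$family == fam)
        rRow <- which(ge$genome_id == recip & ge$family == fam)
        seq <- ge$seq[dRow]
        len <- nchar(seq)
        nMut <- rbinom(1L, len, 1 - target)
        if (nMut > 0) {
            pos <- sample.int(len, nMut)
            v <- strsplit(seq, "")[[1L]]
            v[pos] <- vapply(v[pos], function(b)
                sample(setdiff(BASES, b), 1L), character(1))
            seq <- paste(v, collapse = "")
        }
        realized <- 1 - nMut / len
        newId <- sprintf("%s_hgt%02d", recip, i)
        ge$seq[rRow] <- seq
        ge$gene_id[rRow] <- newId
        levp <- divergenceLevel(tax, donor, recip)
        events[[i]] <- data.frame(
            donor_genome = donor, recipient_genome = recip, family = fam,
            gene_id_donor = ge$gene_id[dRow], gene_id_recipient = newId,
            target_identity = target, realized_identity = realized,
            identity_bin = if (realized >= 0.99) "ge99" else "95to99",
            divergence_level = levp,
            recipient_contig = ge$contig_id[rRow],
            type = if (recent) "recent" else "older",
            detectable = realized >= 0.95, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, events)
    gs@geneTable <- ge

    if (addControls) {
        ctrl <- .plantControls(gs, eligible, famPick[nEv + 1:2], tax)
        gs <- ctrl$gs
        truth <- rbind(truth, ctrl$truth)
    }
    gs@truth$hgt_events <- truth
    gs@truth$plant_params <- list(nRecent = nRecent, nOlder = nOlder,
                                  cooccurWeight = cooccurWeight,
                                  distanceDecay = distanceDecay,
                                  cogBias = cogBias)
    validObject(gs)
    gs
}

# Negative controls: (1) a perfect-copy event whose recipient gene is moved
# onto a carved-out 4000 bp contig; (2) a 400 bp perfect sub-gene region.
.plantControls <- function(gs, eligible, fams, tax) {
    ge <- gs@geneTable
    ct <- gs@contigTable

    # --- short-contig control -------------------------------------------------
    fam1 <- fams[1L]
    pi <- sample.int(nrow(eligible), 1L)
    donor <- eligible[pi, 1L]; recip <- eligible[pi, 2L]
    dRow <- which(ge$genome_id == donor & ge$family == fam1)
    rRow <- which(ge$genome_id == recip & ge$family == fam1)
    geneLen <- ge$end[rRow] - ge$start[rRow]
    newId <- sprintf("%s_hgtSC", recip)
    ge$seq[rRow] <- ge$seq[dRow]
    ge$gene_id[rRow] <- newId
    # carve a 4-gene (4000 bp) contig containing the planted gene
    host <- ge$contig_id[rRow]
    onHost <- which(ge$contig_id == host)
    onHost <- onHost[order(ge$start[onHost])]
    k <- match(rRow, onHost)
    take <- onHost[seq(max(1L, k - 3L), length.out = min(4L, length(onHost)))]
    if (!(rRow %in% take)) take <- onHost[seq_len(min(4L, length(onHost)))]
    rest <- setdiff(onHost, take)
    shortId <- sprintf("%s_cS", recip)
    ge$contig_id[take] <- shortId
    ge$start[take] <- seq(0L, by = geneLen, length.out = length(take))
    ge$end[take] <- ge$start[take] + geneLen
    newCt <- data.frame(contig_id = shortId, genome_id = recip,
                        length = length(take) * geneLen,
                        stringsAsFactors = FALSE)
    if (length(rest)) {
        ge$start[rest] <- seq(0L, by = geneLen, length.out = length(rest))
        ge$end[rest] <- ge$start[rest] + geneLen
        ct$length[ct$contig_id == host] <- length(rest) * geneLen
        ct <- rbind(ct, newCt)
    } else {
        ct$contig_id[ct$contig_id == host] <- shortId
        ct$length[ct$contig_id == shortId] <- newCt$length
    }
    t1 <- data.frame(donor_genome = donor, recipient_genome = recip,
                     family = fam1, gene_id_donor = ge$gene_id[dRow],
                     gene_id_recipient = newId, target_identity = 1,
                     realized_identity = 1, identity_bin = "ge99",
                     divergence_level = divergenceLevel(tax, donor, recip),
                     recipient_contig = shortId,
                     type = "short_contig_control", detectable = FALSE,
                     stringsAsFactors = FALSE)

    # --- short-region control (400 bp perfect sub-gene copy) -----------------
    fam2 <- fams[2L]
    pi <- sample.int(nrow(eligible), 1L)
    donor2 <- eligible[pi, 1L]; recip2 <- eligible[pi, 2L]
    dRow2 <- which(ge$genome_id == donor2 & ge$family == fam2)
    rRow2 <- which(ge$genome_id == recip2 & ge$family == fam2)
    len2 <- nchar(ge$seq[rRow2])
    regLen <- 400L
    offset <- sample.int(len2 - regLen, 1L)
    donorSlice <- substr(ge$seq[dRow2], offset, offset + regLen - 1L)
    s <- ge$seq[rRow2]
    substr(s, offset, offset + regLen - 1L) <- donorSlice
    ge$seq[rRow2] <- s
    t2 <- data.frame(donor_genome = donor2, recipient_genome = recip2,
                     family = fam2, gene_id_donor = ge$gene_id[dRow2],
                     gene_id_recipient = ge$gene_id[rRow2],
                     target_identity = 1, realized_identity = NA_real_,
                     identity_bin = "ge99",
                     divergence_level = divergenceLevel(tax, donor2, recip2),
                     recipient_contig = ge$contig_id[rRow2],
                     type = "short_region_control", detectable = FALSE,
                     stringsAsFactors = FALSE)

    gs@geneTable <- ge
    gs@contigTable <- ct
    list(gs = gs, truth = rbind(t1, t2))
}

#' Simulate metagenomic sample occupancy, abundance and environment
#'
#' Draws \code{nSamples} samples with 12 oceanographic covariates, then places
#' genomes in samples according to a logistic niche model: each genome's
#' occupancy probability responds to its niche group's driver variables (see
#' \code{\link{nicheModel}}), genomes carrying planted HGT additionally
#' respond to \code{hgtEnvEffect$variable} (planting the
#' environment-to-HGT-prevalence association), and designated size-fraction
#' specialists occur almost exclusively in samples of their fraction with
#' their highest median RPKM there. Present genomes get breadth >= 0.3 and
#' log-normal RPKM; absent genomes get sub-threshold breadth.
#'
#' @param gs a \linkS4class{GenomeSet} (after HGT planting, so the
#'   environmental link can target HGT-involved genomes).
#' @param nSamples number of samples (>= 20).
#' @param niche a \code{\link{nicheModel}} result, or NULL for independent
#'   occupancy (co-occurrence tests become powerless; a warning is issued).
#' @param hgtEnvEffect list(variable, slope) or NULL; the planted link from
#'   environment to HGT prevalence.
#' @param fractionProps sample size-fraction proportions
#'   (free_living / combined_fl_pa / other).
#' @param nSpecialists named counts of fraction-specialist genomes.
#' @param baseOccupancy intercept range (logit scale) for genome occupancy.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SampleExperiment}; planted truth (co-occurring
#'   pairs, environmental effect, specialists) is stored in its
#'   \code{metadata()$truth}.
#' @export
generateSamples <- function(gs, nSamples = 200L, niche = NULL,
                            hgtEnvEffect = list(variable = "chlorophyll_a",
                                                slope = 2),
                            fractionProps = c(free_living = 0.70,
                                              combined_fl_pa = 0.25,
                                              other = 0.05),
                            nSpecialists = c(free_living = 6L,
                                             combined_fl_pa = 4L),
                            baseOccupancy = c(-1.2, 0.2), seed = 5L) {
    if (nSamples < 20L) stop("nSamples must be >= 20")
    set.seed(seed)
    ids <- genomeIds(gs)
    nG <- length(ids)
    sampleIds <- sprintf("S%03d", seq_len(nSamples))

    env <- .simulateEnv(nSamples)
    rownames(env) <- sampleIds
    envZ <- scale(env)

    fraction <- sample(names(fractionProps), nSamples, replace = TRUE,
                       prob = fractionProps)

    logit <- matrix(runif(nG, baseOccupancy[1], baseOccupancy[2]), nG,
                    nSamples)
    if (is.null(niche)) {
        warning("no niche model supplied: occupancy is independent and ",
                "co-occurrence tests on this fixture are powerless")
    } else {
        grp <- niche$assignment[ids]
        for (k in seq_along(niche$groups)) {
            rows <- which(grp == k)
            if (!length(rows)) next
            gk <- niche$groups[[k]]
            eff <- as.numeric(envZ[, gk$vars, drop = FALSE] %*% gk$slopes)
            logit[rows, ] <- logit[rows, ] + rep(eff, each = length(rows))
        }
    }
    hgtGenomes <- character()
    if (!is.null(gs@truth$hgt_events)) {
        tr <- gs@truth$hgt_events
        tr <- tr[tr$type %in% c("recent", "older"), ]
        hgtGenomes <- unique(c(tr$donor_genome, tr$recipient_genome))
    }
    if (!is.null(hgtEnvEffect) && length(hgtGenomes)) {
        rows <- match(hgtGenomes, ids)
        eff <- hgtEnvEffect$slope * envZ[, hgtEnvEffect$variable]
        logit[rows, ] <- logit[rows, ] + rep(eff, each = length(rows))
    }

    # fraction specialists: niche-flat occupancy, heavily penalized outside
    # their fraction so they satisfy the strict >75% support rule
    specialists <- list()
    pool <- ids
    for (fr in names(nSpecialists)) {
        pick <- sample(pool, nSpecialists[[fr]])
        pool <- setdiff(pool, pick)
        specialists[[fr]] <- pick
        rows <- match(pick, ids)
        logit[rows, ] <- runif(length(rows), 0, 0.5)
        logit[rows, fraction != fr] <- -6
    }

    present <- matrix(runif(nG * nSamples) < plogis(logit), nG, nSamples)
    if (all(rowMeans(present) > 0.95))
        warning("degenerate niche model: all genomes ubiquitous")

    breadth <- matrix(0, nG, nSamples)
    nPres <- sum(present)
    breadth[present] <- 0.3 + 0.7 * stats::rbeta(nPres, 2, 2)
    absentIdx <- which(!present)
    leak <- absentIdx[runif(length(absentIdx)) < 0.25]
    breadth[leak] <- runif(length(leak), 0, 0.295)

    muG <- rnorm(nG, 1.5, 0.5)
    rpkm <- matrix(0, nG, nSamples)
    bonus <- matrix(0, nG, nSamples)
    for (fr in names(specialists))
        bonus[match(specialists[[fr]], ids), fraction == fr] <- 0.8
    rpkm[present] <- rlnorm(nPres, (muG[row(present)] + bonus)[present], 0.6)
    rpkm[leak] <- runif(length(leak), 0, 0.5)

    dimnames(breadth) <- dimnames(rpkm) <- list(ids, sampleIds)
    se <- SampleExperiment(breadth, rpkm, env = env, fraction = fraction)
    S4Vectors::metadata(se)$truth <- list(
        cooccurring_pairs = if (is.null(niche)) NULL else
            niche$cooccurring_pairs,
        niche = niche,
        env_effect = hgtEnvEffect,
        hgt_genomes = hgtGenomes,
        specialists = specialists,
        seed = seed)
    se
}

# 12 oceanographic covariates on plausible scales; depth/PAR strongly
# anticorrelated, several others moderately structured, none redundant at
# |rho| >= 0.95.
.simulateEnv <- function(n) {
    z <- matrix(rnorm(n * 6L), n, 6L)
    depth <- exp(2 + 1.2 * z[, 1L])
    par <- 100 * plogis(-1.6 * z[, 1L] + 0.5 * z[, 2L])
    temperature <- 14 + 7 * (-0.5 * z[, 1L] + 0.8 * z[, 3L])
    salinity <- 35 + 0.8 * (0.4 * z[, 3L] + 0.9 * z[, 4L])
    nitrate <- pmax(0, 8 + 6 * (0.6 * z[, 1L] - 0.5 * z[, 3L] +
                                    0.6 * z[, 5L]))
    oxygen <- 220 + 40 * (-0.5 * z[, 1L] + 0.3 * z[, 3L] + 0.7 * z[, 6L])
    chl <- exp(-1 + 0.9 * (-0.7 * z[, 1L] + 0.7 * rnorm(n)))
    fcdom <- exp(0.4 * z[, 5L] + 0.4 * rnorm(n))
    bbp470 <- exp(-6 + 0.5 * chl / stats::sd(chl) + 0.5 * rnorm(n))
    latitude <- runif(n, -70, 70)
    longitude <- runif(n, -180, 180)
    potdens <- 1026 + 1.5 * (0.6 * z[, 4L] - 0.4 * temperature /
                                 stats::sd(temperature) + 0.5 * rnorm(n))
    data.frame(depth = depth, temperature = temperature, salinity = salinity,
               nitrate = nitrate, oxygen = oxygen, chlorophyll_a = chl,
               par = par, fcdom = fcdom, bbp470 = bbp470,
               latitude = latitude, longitude = longitude,
               potential_density = potdens)
}

#' Construct a SampleExperiment from breadth and RPKM matrices
#'
#' @param breadth,rpkm genome-by-sample numeric matrices with matching
#'   dimnames; breadth in [0,1], rpkm non-negative.
#' @param env optional per-sample data.frame of environmental variables.
#' @param fraction optional per-sample size-fraction labels.
#' @return a \linkS4class{SampleExperiment}.
#' @export
SampleExperiment <- function(breadth, rpkm, env = NULL, fraction = NULL) {
    stopifnot(identical(dim(breadth), dim(rpkm)))
    cd <- S4Vectors::DataFrame(row.names = colnames(breadth))
    if (!is.null(fraction)) cd$fraction <- fraction
    if (!is.null(env)) cd <- cbind(cd, S4Vectors::DataFrame(env))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(breadth = breadth, rpkm = rpkm), colData = cd)
    new("SampleExperiment", se)
}

#' Independent-occupancy presence fixture (null model)
#'
#' Generates a \linkS4class{SampleExperiment} in which every genome occupies
#' every sample independently with probability \code{occupancy}. Used to
#' calibrate the type-I error of co-occurrence tests: with no planted niche
#' structure, hypergeometric p-values should be (conservatively) uniform.
#'
#' @param nGenomes,nSamples dimensions.
#' @param occupancy per-cell presence probability.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SampleExperiment}.
#' @export
simulateNullPresence <- function(nGenomes = 46L, nSamples = 200L,
                                 occupancy = 0.3, seed = 6L) {
    set.seed(seed)
    ids <- sprintf("G%03d", seq_len(nGenomes))
    sampleIds <- sprintf("S%03d", seq_len(nSamples))
    present <- matrix(runif(nGenomes * nSamples) < occupancy, nGenomes,
                      nSamples, dimnames = list(ids, sampleIds))
    breadth <- ifelse(present, 0.8, 0)
    rpkm <- ifelse(present, 1, 0)
    callPresence(SampleExperiment(breadth, rpkm))
}

#' Simulate a complete study fixture
#'
#' Orchestrates the full generator: taxonomy and tree, vertically evolved
#' gene families, niche groups, planted HGT events (with filter negative
#' controls), planted mobile-genetic-element annotations, and the
#' sample/abundance/environment tables. All planted truth is recorded in the
#' \code{GenomeSet} truth slot and the \code{SampleExperiment} metadata.
#'
#' @param nGenomes,genesPerGenome,geneLength genome set dimensions.
#' @param nRecent,nOlder planted HGT counts per identity bin (defaults keep
#'   roughly 70\% of events in the >= 99\% bin).
#' @param nSamples number of metagenomic samples.
#' @param cogBias optional COG category that receives all planted transfers.
#' @param addControls plant filter negative controls.
#' @param seed master seed; stage seeds are derived from it.
#' @return list with \code{genomes} (\linkS4class{GenomeSet}) and
#'   \code{samples} (\linkS4class{SampleExperiment}).
#' @export
simulateFixture <- function(nGenomes = 50L, genesPerGenome = 100L,
                            geneLength = 1000L, nRecent = 28L, nOlder = 12L,
                            nSamples = 200L, cogBias = NULL,
                            addControls = TRUE, seed = 42L) {
    seeds <- seed + 0:4
    gs <- generateTaxonomyTree(nGenomes = nGenomes, seed = seeds[1L])
    gs <- evolveGenes(gs, genesPerGenome = genesPerGenome,
                      geneLength = geneLength, seed = seeds[2L])
    nm <- nicheModel(gs, seed = seeds[3L])
    gs <- plantHgtEvents(gs, nRecent = nRecent, nOlder = nOlder, niche = nm,
                         cogBias = cogBias, addControls = addControls,
                         seed = seeds[4L])
    gs <- plantMgeFlags(gs, seed = seeds[4L] + 1000L)
    # specialist counts scale with the genome set (12% / 8%, the default
    # 6 + 4 at 50 genomes) so small fixtures keep enough generalist genomes
    nSpec <- c(free_living = max(2L, round(0.12 * nGenomes)),
               combined_fl_pa = max(2L, round(0.08 * nGenomes)))
    se <- generateSamples(gs, nSamples = nSamples, niche = nm,
                          nSpecialists = nSpec, seed = seeds[5L])
    gs@truth$cooccurring_pairs <- nm$cooccurring_pairs
    gs@truth$env_effect <- S4Vectors::metadata(se)$truth$env_effect
    list(genomes = gs, samples = se)
}

#' Plant mobile-genetic-element annotations with an HGT association
#'
#' Assigns the four MGE flags to genes with baseline rates, elevated (proMGE,
#' plasmid, virus) or depleted (provirus) among genes involved in planted HGT
#' events, mirroring the enrichment structure the MGE tests should recover.
#'
#' @param gs a \linkS4class{GenomeSet} after \code{\link{plantHgtEvents}}.
#' @param baseRates,hgtRates named per-flag Bernoulli rates for background and
#'   HGT-involved genes.
#' @param seed integer RNG seed.
#' @return the updated \code{GenomeSet}.
#' @export
plantMgeFlags <- function(gs,
                          baseRates = c(promge_hit = 0.02,
                                        plasmid_contig = 0.010,
                                        virus_contig = 0.010,
                                        provirus_contig = 0.030),
                          hgtRates = c(promge_hit = 0.15,
                                       plasmid_contig = 0.08,
                                       virus_contig = 0.04,
                                       provirus_contig = 0.002),
                          seed = 7L) {
    set.seed(seed)
    ge <- gs@geneTable
    tr <- gs@truth$hgt_events
    hgtGenes <- if (is.null(tr)) character() else
        unique(c(tr$gene_id_donor[tr$type %in% c("recent", "older")],
                 tr$gene_id_recipient[tr$type %in% c("recent", "older")]))
    isHgt <- ge$gene_id %in% hgtGenes
    for (fl in MGE_FLAGS) {
        rate <- ifelse(isHgt, hgtRates[[fl]], baseRates[[fl]])
        ge[[fl]] <- runif(nrow(ge)) < rate
    }
    gs@geneTable <- ge
    gs@truth$mge_rates <- list(base = baseRates, hgt = hgtRates)
    gs
}
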