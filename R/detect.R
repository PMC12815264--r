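# HGT detection: full-length gene clustering with cross-genus reciprocal best
# hits (focal path) and ungapped seed-and-extend identity segments (region
# path), plus divergence-level binning of the resulting events.

DIVERGENCE_LEVELS <- c("genus", "family", "order", "class", "phylum",
                       "domain")

#' Lowest shared ancestry between two taxonomies
#'
#' Returns the highest taxonomic rank at which two seven-rank lineages differ
#' (walking from domain down to species). Pairs that share their genus label
#' (differing at species only, or identical) return \code{"within_genus"} and
#' are excluded from HGT event calling, since high identity between such
#' genomes is expected from vertical inheritance.
#'
#' @param labA,labB character vectors of the seven rank labels, ordered
#'   domain to species.
#' @return one of \code{"domain"}, \code{"phylum"}, \code{"class"},
#'   \code{"order"}, \code{"family"}, \code{"genus"}, \code{"within_genus"}.
#' @export
divergenceLevelFromLabels <- function(labA, labB) {
    labA <- as.character(labA); labB <- as.character(labB)
    if (length(labA) != 7L || length(labB) != 7L)
        stop("taxonomies must have 7 rank labels")
    if (anyNA(labA) || anyNA(labB) || any(!nzchar(c(labA, labB))))
        stop("missing rank label")
    diffAt <- which(labA != labB)
    if (!length(diffAt) || min(diffAt) == 7L) return("within_genus")
    TAXONOMY_RANKS[min(diffAt)]
}

#' @rdname divergenceLevelFromLabels
#' @param taxonomy data.frame with \code{genome_id} and the seven rank
#'   columns.
#' @param genomeA,genomeB genome identifiers present in \code{taxonomy}.
#' @export
divergenceLevel <- function(taxonomy, genomeA, genomeB) {
    ia <- match(genomeA, taxonomy$genome_id)
    ib <- match(genomeB, taxonomy$genome_id)
    if (is.na(ia)) stop("genome missing from taxonomy: ", genomeA)
    if (is.na(ib)) stop("genome missing from taxonomy: ", genomeB)
    divergenceLevelFromLabels(unlist(taxonomy[ia, TAXONOMY_RANKS]),
                              unlist(taxonomy[ib, TAXONOMY_RANKS]))
}

#' Pairwise nucleotide identity
#'
#' For equal-length sequences identity is 1 - Hamming/length; for unequal
#' lengths it falls back to 1 - editDistance/max(length). Symmetric in its
#' arguments.
#'
#' @param seqA,seqB non-empty nucleotide strings.
#' @return a fraction in [0, 1].
#' @export
pairwiseIdentity <- function(seqA, seqB) {
    if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence")
    .seqIdentity(seqA, seqB)
}

#' Greedy incremental gene clustering
#'
#' Clusters genes at \code{idThreshold} identity with a length-difference
#' cut-off, in the style of full-length nucleotide clustering tools: genes are
#' processed in descending length (ties broken by lexicographic gene id) and
#' each gene joins the first existing cluster whose representative it matches
#' at identity >= \code{idThreshold} with min(len)/max(len) >=
#' \code{coverage}; otherwise it founds a new cluster with itself as
#' representative. Under the ungapped identity model used here the mutual
#' aligned coverage of a qualifying pair equals its length ratio, so the
#' length cut-off enforces both.
#'
#' @param genes data.frame with columns \code{gene_id} and \code{seq}
#'   (e.g. \code{geneTable(gs)}).
#' @param idThreshold,coverage clustering thresholds (defaults 0.95 / 0.95).
#' @return the input rows (plus \code{length}) with \code{cluster_id} and
#'   logical \code{is_representative} columns, one row per gene.
#' @export
clusterGenes <- function(genes, idThreshold = 0.95, coverage = 0.95) {
    if (!nrow(genes)) stop("at least one gene required")
    genes$length <- nchar(genes$seq)
    ord <- order(-genes$length, genes$gene_id)
    genes <- genes[ord, , drop = FALSE]
    cl <- .greedyCluster(genes$seq, idThreshold, coverage)
    genes$cluster_id <- sprintf("CL%05d", cl)
    genes$is_representative <- !duplicated(cl)
    rownames(genes) <- NULL
    genes
}

.identityBin <- function(identity) ifelse(identity >= 0.99, "ge99", "95to99")

#' Call HGT events from clusters by cross-genus reciprocal best hits
#'
#' Within each multi-genome cluster, a gene pair (a in genome A, b in genome
#' B) is called a putative HGT event when A and B differ at the genus level or
#' above, a's closest match (highest identity, ties by lexicographic gene id)
#' among B's cluster members is b and vice versa (reciprocity), and their
#' identity is >= \code{minIdentity}. At most one event is kept per (cluster,
#' genome pair) -- the highest-identity reciprocal pair. Events whose genes
#' sit on contigs shorter than \code{minContig} bp are removed afterwards, in
#' that order.
#'
#' @param clusters output of \code{\link{clusterGenes}} (must retain
#'   \code{genome_id} and \code{contig_id} columns).
#' @param taxonomy data.frame of genome taxonomies
#'   (\code{taxonomyTable(gs)}).
#' @param contigs data.frame with \code{contig_id} and \code{length}.
#' @param minContig minimum contig length in bp (default 5000).
#' @param minIdentity minimum event identity (default 0.95).
#' @return data.frame of events: \code{genome_a}, \code{genome_b} (sorted
#'   within pair), \code{gene_a}, \code{gene_b}, \code{identity},
#'   \code{identity_bin}, \code{divergence_level}, \code{cluster_id},
#'   \code{method}.
#' @export
callRbhHgt <- function(clusters, taxonomy, contigs, minContig = 5000L,
                       minIdentity = 0.95) {
    missing <- setdiff(unique(clusters$genome_id), taxonomy$genome_id)
    if (length(missing))
        stop("genome missing from taxonomy: ",
             paste(missing, collapse = ", "))
    events <- list()
    for (cid in unique(clusters$cluster_id)) {
        mem <- clusters[clusters$cluster_id == cid, , drop = FALSE]
        gsIn <- unique(mem$genome_id)
        if (nrow(mem) < 2L || length(gsIn) < 2L) next
        n <- nrow(mem)
        idm <- matrix(1, n, n)
        for (i in seq_len(n - 1L))
            for (j in seq(i + 1L, n))
                idm[i, j] <- idm[j, i] <-
                    pairwiseIdentity(mem$seq[i], mem$seq[j])
        for (pi in seq_len(length(gsIn) - 1L)) {
            for (pj in seq(pi + 1L, length(gsIn))) {
                A <- gsIn[pi]; B <- gsIn[pj]
                lev <- divergenceLevel(taxonomy, A, B)
                if (lev == "within_genus") next
                ia <- which(mem$genome_id == A)
                ib <- which(mem$genome_id == B)
                best <- NULL
                for (i in ia) {
                    # a's closest match among B's members
                    o <- ib[order(-idm[i, ib], mem$gene_id[ib])]
                    j <- o[1L]
                    # reciprocity: b's closest match among A's members is a
                    oa <- ia[order(-idm[j, ia], mem$gene_id[ia])]
                    if (oa[1L] != i) next
                    id <- idm[i, j]
                    if (id < minIdentity - 1e-12) next
                    cand <- list(i = i, j = j, id = id)
                    if (is.null(best) || cand$id > best$id ||
                        (cand$id == best$id &&
                         mem$gene_id[cand$i] < mem$gene_id[best$i]))
                        best <- cand
                }
                if (is.null(best)) next
                ga <- mem[best$i, ]; gb <- mem[best$j, ]
                if (gb$genome_id < ga$genome_id) { tmp <- ga; ga <- gb; gb <- tmp }
                events[[length(events) + 1L]] <- data.frame(
                    genome_a = ga$genome_id, genome_b = gb$genome_id,
                    gene_a = ga$gene_id, gene_b = gb$gene_id,
                    contig_a = ga$contig_id, contig_b = gb$contig_id,
                    identity = best$id,
                    identity_bin = .identityBin(best$id),
                    divergence_level = lev, cluster_id = cid,
                    method = "cluster_rbh", stringsAsFactors = FALSE)
            }
        }
    }
    ev <- if (length(events)) do.call(rbind, events) else
        data.frame(genome_a = character(), genome_b = character(),
                   gene_a = character(), gene_b = character(),
                   contig_a = character(), contig_b = character(),
                   identity = numeric(), identity_bin = character(),
                   divergence_level = character(), cluster_id = character(),
                   method = character(), stringsAsFactors = FALSE)
    # contig-length filter applies after event calling
    if (nrow(ev)) {
        clen <- setNames(contigs$length, contigs$contig_id)
        keep <- clen[ev$contig_a] >= minContig & clen[ev$contig_b] >= minContig
        ev <- ev[keep, , drop = FALSE]
    }
    ev <- ev[order(ev$cluster_id, ev$genome_a, ev$genome_b), , drop = FALSE]
    rownames(ev) <- NULL
    ev
}

# Contig sequences of one genome: genes concatenated in coordinate order.
contigSequences <- function(gs, genome) {
    ge <- geneTable(gs)
    ge <- ge[ge$genome_id == genome, , drop = FALSE]
    vapply(split(ge, ge$contig_id), function(d)
        paste(d$seq[order(d$start)], collapse = ""), character(1))
}

#' Find high-identity ungapped segments between two genomes
#'
#' Exact shared k-mers seed ungapped extensions in both directions; extension
#' stops when the running score (matches - mismatches) falls \code{xdrop}
#' below its maximum, and each side is trimmed back to its maximum-scoring
#' endpoint. Seeds falling inside an already-extended diagonal interval are
#' skipped, which merges the extensions of overlapping seeds. Reported
#' segments are >= \code{minLen} bp at identity >= \code{minId};
#' deterministic for fixed inputs.
#'
#' @param gs a \linkS4class{GenomeSet}.
#' @param genomeA,genomeB genome identifiers.
#' @param minLen,minId segment thresholds (500 bp, 0.95).
#' @param k seed length (31).
#' @param xdrop X-drop score tolerance (20).
#' @param contigs optional precomputed list(a =, b =) of named contig
#'   sequence vectors (avoids recomputation in all-pairs sweeps).
#' @return data.frame of segment matches with per-side contig, 0-based
#'   half-open coordinates, \code{length}, \code{identity} and \code{score}.
#' @export
findIdentitySegments <- function(gs, genomeA, genomeB, minLen = 500L,
                                 minId = 0.95, k = 31L, xdrop = 20L,
                                 contigs = NULL) {
    if (is.null(contigs)) {
        sa <- contigSequences(gs, genomeA)
        sb <- contigSequences(gs, genomeB)
    } else {
        sa <- contigs$a
        sb <- contigs$b
    }
    if (all(nchar(sa) < k) || all(nchar(sb) < k)) {
        warning("k = ", k, " exceeds every contig length; no segments")
        return(data.frame(genome_a = character(), contig_a = character(),
                          start_a = integer(), end_a = integer(),
                          genome_b = character(), contig_b = character(),
                          start_b = integer(), end_b = integer(),
                          length = integer(), identity = numeric(),
                          score = numeric(), stringsAsFactors = FALSE))
    }
    raw <- .findSegments(unname(sa), unname(sb), as.integer(k),
                         as.integer(minLen), minId, as.integer(xdrop))
    out <- data.frame(genome_a = rep(genomeA, nrow(raw)),
                      contig_a = names(sa)[raw$contig_a],
                      start_a = raw$start_a, end_a = raw$end_a,
                      genome_b = rep(genomeB, nrow(raw)),
                      contig_b = names(sb)[raw$contig_b],
                      start_b = raw$start_b, end_b = raw$end_b,
                      length = raw$length, identity = raw$identity,
                      score = raw$score, stringsAsFactors = FALSE)
    out <- out[order(out$contig_a, out$start_a, out$contig_b, out$start_b), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Call region-path HGT events by intersecting segments with genes
#'
#' For one genome pair's segment matches: overlapping segments are resolved by
#' keeping the highest-scoring one (ties broken by longer length, then
#' lexicographic coordinates), then genes of either genome overlapping a
#' retained segment by >= 1 bp become region-method events. The
#' cross-genus-or-above restriction and the \code{minContig} filter apply as
#' in \code{\link{callRbhHgt}}.
#'
#' @param segments output of \code{\link{findIdentitySegments}} for one
#'   genome pair.
#' @param gs the \linkS4class{GenomeSet} providing gene annotations,
#'   taxonomy and contig lengths.
#' @param minContig minimum contig length in bp.
#' @return data.frame of events: genome pair, intersected \code{gene_id} and
#'   its genome, segment coordinates, \code{identity}, \code{identity_bin},
#'   \code{divergence_level}, \code{method}.
#' @export
callRegionHgt <- function(segments, gs, minContig = 5000L) {
    empty <- data.frame(genome_a = character(), genome_b = character(),
                        gene_id = character(), gene_genome = character(),
                        contig = character(), seg_start = integer(),
                        seg_end = integer(), identity = numeric(),
                        identity_bin = character(),
                        divergence_level = character(), method = character(),
                        stringsAsFactors = FALSE)
    if (!nrow(segments)) return(empty)
    tax <- taxonomyTable(gs)
    ct <- contigTable(gs)
    ge <- geneTable(gs)
    unknown <- setdiff(unique(c(segments$contig_a, segments$contig_b)),
                       ct$contig_id)
    if (length(unknown))
        stop("segment references unknown contig: ",
             paste(unknown, collapse = ", "))
    A <- segments$genome_a[1L]; B <- segments$genome_b[1L]
    lev <- divergenceLevel(tax, A, B)
    if (lev == "within_genus") return(empty)

    # overlap resolution: highest score wins; ties -> longer, then coords
    o <- order(-segments$score, -segments$length, segments$contig_a,
               segments$start_a, segments$contig_b, segments$start_b)
    segments <- segments[o, , drop = FALSE]
    kept <- logical(0)
    keptRows <- list()
    overlaps <- function(s, t)
        (s$contig_a == t$contig_a && s$start_a < t$end_a &&
             t$start_a < s$end_a) ||
        (s$contig_b == t$contig_b && s$start_b < t$end_b &&
             t$start_b < s$end_b)
    for (i in seq_len(nrow(segments))) {
        s <- segments[i, ]
        clash <- any(vapply(keptRows, function(t) overlaps(s, t), logical(1)))
        if (!clash) keptRows[[length(keptRows) + 1L]] <- s
    }
    segments <- do.call(rbind, keptRows)

    clen <- setNames(ct$length, ct$contig_id)
    out <- list()
    for (i in seq_len(nrow(segments))) {
        s <- segments[i, ]
        if (clen[s$contig_a] < minContig || clen[s$contig_b] < minContig)
            next
        for (side in c("a", "b")) {
            contig <- s[[paste0("contig_", side)]]
            st <- s[[paste0("start_", side)]]
            en <- s[[paste0("end_", side)]]
            hits <- ge[ge$contig_id == contig & ge$start < en & ge$end > st, ,
                       drop = FALSE]
            if (!nrow(hits)) next
            out[[length(out) + 1L]] <- data.frame(
                genome_a = min(A, B), genome_b = max(A, B),
                gene_id = hits$gene_id, gene_genome = hits$genome_id,
                contig = contig, seg_start = st, seg_end = en,
                identity = s$identity,
                identity_bin = .identityBin(s$identity),
                divergence_level = lev, method = "region",
                stringsAsFactors = FALSE)
        }
    }
    ev <- if (length(out)) do.call(rbind, out) else empty
    rownames(ev) <- NULL
    ev
}

#' Tabulate HGT events by taxonomic divergence level
#'
#' Counts events at each divergence level and normalizes by the number of
#' genome pairs whose divergence level is that rank, giving a per-comparison
#' transfer rate that is comparable across levels.
#'
#' @param events event data.frame with a \code{divergence_level} column.
#' @param taxonomy genome taxonomy data.frame (all genomes under
#'   comparison, not only those with events).
#' @return data.frame: \code{level}, \code{n_events}, \code{n_genome_pairs},
#'   \code{rate} (NA where a level has zero pairs).
#' @export
eventsPerLevel <- function(events, taxonomy) {
    ids <- taxonomy$genome_id
    levPairs <- setNames(integer(length(DIVERGENCE_LEVELS)),
                         DIVERGENCE_LEVELS)
    if (length(ids) >= 2L) {
        pr <- t(combn(ids, 2L))
        lv <- apply(pr, 1L, function(p)
            divergenceLevel(taxonomy, p[1L], p[2L]))
        tb <- table(factor(lv, levels = DIVERGENCE_LEVELS))
        levPairs[names(tb)] <- as.integer(tb)
    }
    nEv <- table(factor(events$divergence_level, levels = DIVERGENCE_LEVELS))
    out <- data.frame(level = DIVERGENCE_LEVELS,
                      n_events = as.integer(nEv),
                      n_genome_pairs = as.integer(levPairs),
                      stringsAsFactors = FALSE)
    out$rate <- ifelse(out$n_genome_pairs > 0,
                       out$n_events / out$n_genome_pairs, NA_real_)
    out
}

#' Run the focal cluster-RBH HGT detection on a GenomeSet
#'
#' Convenience wrapper: clusters all genes, then calls cross-genus reciprocal
#' best hit events.
#'
#' @param gs a \linkS4class{GenomeSet}.
#' @param idThreshold,coverage clustering thresholds.
#' @param minContig,minIdentity event-calling thresholds.
#' @return list with \code{clusters} (membership table) and \code{events}.
#' @export
detectHgt <- function(gs, idThreshold = 0.95, coverage = 0.95,
                      minContig = 5000L, minIdentity = 0.95) {
    cl <- clusterGenes(geneTable(gs), idThreshold, coverage)
    ev <- callRbhHgt(cl, taxonomyTable(gs), contigTable(gs),
                     minContig = minContig, minIdentity = minIdentity)
    list(clusters = cl, events = ev)
}

#' Region-path HGT events for all cross-genus genome pairs
#'
#' Runs \code{\link{findIdentitySegments}} and \code{\link{callRegionHgt}}
#' over every unordered genome pair differing at the genus level or above.
#'
#' @inheritParams findIdentitySegments
#' @param minContig minimum contig length in bp.
#' @return list with \code{segments} (all retained matches) and
#'   \code{events} (region-method events).
#' @export
detectRegionHgt <- function(gs, minLen = 500L, minId = 0.95, k = 31L,
                            xdrop = 20L, minContig = 5000L) {
    ids <- genomeIds(gs)
    tax <- taxonomyTable(gs)
    contigCache <- lapply(setNames(ids, ids), contigSequences, gs = gs)
    segs <- list(); evs <- list()
    for (i in seq_len(length(ids) - 1L)) {
        for (j in seq(i + 1L, length(ids))) {
            if (divergenceLevel(tax, ids[i], ids[j]) == "within_genus") next
            s <- findIdentitySegments(gs, ids[i], ids[j], minLen = minLen,
                                      minId = minId, k = k, xdrop = xdrop,
                                      contigs = list(
                                          a = contigCache[[ids[i]]],
                                          b = contigCache[[ids[j]]]))
            if (!nrow(s)) next
            segs[[length(segs) + 1L]] <- s
            e <- callRegionHgt(s, gs, minContig = minContig)
            if (nrow(e)) evs[[length(evs) + 1L]] <- e
        }
    }
    list(segments = if (length(segs)) do.call(rbind, segs) else NULL,
         events = if (length(evs)) do.call(rbind, evs) else NULL)
}
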