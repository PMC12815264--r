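# End-to-end orchestration: validated run configuration, staged execution
# with a JSON manifest, and deterministic reruns.

.defaultConfig <- function() {
    list(
        seed = 42L,
        out = "hgtcooc_run",
        simulate = list(n_genomes = 50L, genes_per_genome = 100L,
                        gene_length = 1000L, n_recent = 28L, n_older = 12L,
                        n_samples = 200L),
        thresholds = list(identity = 0.95, recent_identity = 0.99,
                          region_min_len = 500L, min_contig = 5000L,
                          breadth = 0.30, prevalence = 10L, support = 0.75,
                          bh_alpha = 0.05, env_rho = 0.95),
        env_rf = list(n_trees = 2000L, null_trees = 200L,
                      n_replicates = 200L),
        stages = list(simulate = TRUE, detect = TRUE, region = FALSE,
                      cooccur = TRUE, associate = TRUE, enrich = TRUE,
                      env_rf = TRUE))
}

#' Build and validate a pipeline run configuration
#'
#' Merges user settings over the defaults; unknown keys are rejected and
#' thresholds are checked against their documented ranges.
#'
#' @param ... named settings, or a single list (e.g. from
#'   \code{yaml::read_yaml}); nested lists merge per key.
#' @return validated config list (class \code{runConfig}).
#' @export
runConfig <- function(...) {
    user <- list(...)
    if (length(user) == 1L && is.null(names(user)) && is.list(user[[1L]]))
        user <- user[[1L]]
    def <- .defaultConfig()
    merge <- function(base, upd, path = "") {
        bad <- setdiff(names(upd), names(base))
        if (length(bad))
            stop("unknown config key: ", paste0(path, bad, collapse = ", "))
        for (k in names(upd)) {
            base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]]))
                merge(base[[k]], upd[[k]], paste0(path, k, "$")) else
                    upd[[k]]
        }
        base
    }
    cfg <- merge(def, user)
    th <- cfg$thresholds
    stopifnot(th$identity >= 0.5, th$identity <= 1,
              th$recent_identity >= th$identity, th$recent_identity <= 1,
              th$region_min_len > 0, th$min_contig >= 0,
              th$breadth >= 0, th$breadth <= 1, th$prevalence >= 1,
              th$support > 0, th$support < 1,
              th$bh_alpha > 0, th$bh_alpha < 1,
              th$env_rho > 0, th$env_rho <= 1)
    class(cfg) <- "runConfig"
    cfg
}

.configHash <- function(cfg) {
    analytic <- cfg[setdiff(names(cfg), "out")]
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(jsonlite::toJSON(analytic, auto_unbox = TRUE, digits = NA),
               tmp)
    unname(tools::md5sum(tmp))
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in dependency order (simulate -> detect ->
#' cooccur -> associate -> enrich -> env_rf), writes stage outputs as TSV
#' into the run directory and records a JSON manifest (config hash, seed,
#' row counts per output). Reruns with the same config are deterministic.
#'
#' @param config a \code{\link{runConfig}}.
#' @param quiet suppress stage timing messages.
#' @return list of in-memory stage results, invisibly; files in
#'   \code{config$out}.
#' @export
runPipeline <- function(config = runConfig(), quiet = FALSE) {
    stopifnot(inherits(config, "runConfig"))
    dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
    th <- config$thresholds
    manifest <- list(config_hash = .configHash(config), seed = config$seed,
                     package_version = as.character(
                         utils::packageVersion("hgtcooc")),
                     stages = list())
    res <- list()
    note <- function(stage, t0, rows) {
        if (!quiet)
            message(sprintf("[%s] done in %.1fs", stage,
                            as.numeric(Sys.time()) - t0))
        manifest$stages[[stage]] <<- list(completed = TRUE, rows = rows)
    }
    out <- function(df, name) {
        .writeTsv(df, file.path(config$out, paste0(name, ".tsv")))
        nrow(df)
    }

    if (isTRUE(config$stages$simulate)) {
        t0 <- as.numeric(Sys.time())
        sim <- config$simulate
        fx <- simulateFixture(nGenomes = sim$n_genomes,
                              genesPerGenome = sim$genes_per_genome,
                              geneLength = sim$gene_length,
                              nRecent = sim$n_recent, nOlder = sim$n_older,
                              nSamples = sim$n_samples, seed = config$seed)
        res$genomes <- fx$genomes
        res$samples <- fx$samples
        note("simulate", t0, nrow(geneTable(fx$genomes)))
    }

    if (isTRUE(config$stages$detect)) {
        t0 <- as.numeric(Sys.time())
        det <- detectHgt(res$genomes, idThreshold = th$identity,
                         minContig = th$min_contig,
                         minIdentity = th$identity)
        res$clusters <- det$clusters
        res$events <- det$events
        n <- out(det$events, "events")
        out(det$clusters[, c("gene_id", "genome_id", "cluster_id",
                             "is_representative")], "clusters")
        out(eventsPerLevel(det$events, taxonomyTable(res$genomes)),
            "events_per_level")
        note("detect", t0, n)
    }

    if (isTRUE(config$stages$region)) {
        t0 <- as.numeric(Sys.time())
        reg <- detectRegionHgt(res$genomes, minLen = th$region_min_len,
                               minId = th$identity,
                               minContig = th$min_contig)
        res$region_events <- reg$events
        n <- if (is.null(reg$events)) 0L else out(reg$events,
                                                  "region_events")
        note("region", t0, n)
    }

    if (isTRUE(config$stages$cooccur)) {
        t0 <- as.numeric(Sys.time())
        se <- callPresence(res$samples, presenceThreshold = th$breadth)
        se <- applyPrevalenceFilter(se, minSamples = th$prevalence)
        res$presence <- se
        res$cooc <- hypergeomCooccurrence(se, alpha = th$bh_alpha)
        res$fraction_classes <- classifySizeFraction(
            se, supportThreshold = th$support)
        n <- out(res$cooc, "cooccurrence")
        out(res$fraction_classes, "fraction_classes")
        note("cooccur", t0, n)
    }

    if (isTRUE(config$stages$associate)) {
        t0 <- as.numeric(Sys.time())
        em <- genomeEnvMedians(res$presence)
        tab <- buildPairTable(res$events, res$cooc,
                              patristicDist(res$genomes), envMedians = em,
                              fractionClasses = res$fraction_classes,
                              taxonomy = taxonomyTable(res$genomes))
        res$pair_table <- tab
        preds <- c("cooccur", "phylo_dist_t",
                   grep("^env_diff_.*_t$", names(tab), value = TRUE),
                   "fraction_class")
        res$fit <- fitLogistic(tab, preds)
        n <- out(tab, "pair_table")
        out(modelCoefficients(res$fit), "model_coefficients")
        note("associate", t0, n)
    }

    if (isTRUE(config$stages$enrich)) {
        t0 <- as.numeric(Sys.time())
        enr <- cogEnrichmentStratified(res$clusters, res$events,
                                       alpha = th$bh_alpha)
        res$enrichment <- enr
        hgtGenes <- unique(c(res$events$gene_a, res$events$gene_b))
        mge <- do.call(rbind, lapply(MGE_FLAGS, function(fl) {
            r <- mgeFoldEnrichment(geneTable(res$genomes), hgtGenes, fl)
            data.frame(flag = fl, fold = r$fold, p = r$p,
                       corrected = r$corrected, stringsAsFactors = FALSE)
        }))
        res$mge <- mge
        n <- out(enr, "enrichment")
        out(mge, "mge_enrichment")
        note("enrich", t0, n)
    }

    if (isTRUE(config$stages$env_rf)) {
        t0 <- as.numeric(Sys.time())
        se <- res$presence
        tr <- plantedTruth(res$genomes)$hgt_events
        hgtGenomes <- unique(c(tr$donor_genome, tr$recipient_genome))
        flags <- setNames(rownames(se) %in% hgtGenomes, rownames(se))
        prev <- featurePrevalence(se, flags)
        cd <- as.data.frame(SummarizedExperiment::colData(se))
        env <- cd[, setdiff(names(cd), "fraction"), drop = FALSE]
        keepS <- !is.na(prev)
        env <- env[keepS, , drop = FALSE]
        dd <- dedupeEnv(env, rhoThreshold = th$env_rho)
        env <- env[, dd$retained, drop = FALSE]
        er <- config$env_rf
        imp <- importanceNullTest(env, prev[keepS], nTrees = er$n_trees,
                                  nullTrees = er$null_trees,
                                  nReplicates = er$n_replicates,
                                  seed = config$seed,
                                  alpha = th$bh_alpha)
        res$env_importance <- imp
        res$hgt_prevalence <- prev
        n <- out(imp, "env_importance")
        note("env_rf", t0, n)
    }

    jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(res)
}
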