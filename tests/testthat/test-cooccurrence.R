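# Presence calling, prevalence filtering, co-occurrence statistics,
# size-fraction classification and feature prevalence.

test_that("presence is called at the inclusive breadth threshold", {
    b <- matrix(c(0.30, 0.299, 0, 1), 2L, 2L,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
    r <- matrix(c(2, 5, 3, 4), 2L, 2L, dimnames = dimnames(b))
    se <- SampleExperiment(b, r)
    out <- callPresence(se)
    pm <- SummarizedExperiment::assay(out, "present")
    expect_identical(pm, matrix(c(TRUE, FALSE, FALSE, TRUE), 2L, 2L,
                                dimnames = dimnames(b)))
    rz <- SummarizedExperiment::assay(out, "rpkm")
    expect_identical(rz[2L, 1L], 0)   # absent cell zeroed
    expect_identical(rz[1L, 1L], 2)   # present cell untouched
    # input object untouched
    expect_false("present" %in% SummarizedExperiment::assayNames(se))
    expect_identical(SummarizedExperiment::assay(se, "rpkm"), r)
})

test_that("prevalence filter keeps >= 10 samples and is idempotent", {
    set.seed(41)
    present <- matrix(runif(60 * 40) < 0.25, 60L, 40L,
                      dimnames = list(sprintf("g%02d", 1:60),
                                      sprintf("s%02d", 1:40)))
    present[1L, ] <- c(rep(TRUE, 10L), rep(FALSE, 30L))   # exactly 10
    present[2L, ] <- c(rep(TRUE, 9L), rep(FALSE, 31L))    # 9 -> dropped
    se <- presenceSE(present)
    f <- filterPrevalence(se)
    expect_true("g01" %in% f$retained)
    expect_false("g02" %in% f$retained)
    # column-sum oracle
    expect_setequal(f$retained, rownames(present)[rowSums(present) >= 10L])
    se2 <- applyPrevalenceFilter(se)
    se3 <- applyPrevalenceFilter(se2)
    expect_identical(dim(se2), dim(se3))
    expect_identical(rownames(se2), rownames(se3))
})

test_that("hypergeometric test matches the printed example and edge cases", {
    # N=10, k_a=5, k_b=4, obs=4; a ubiquitous filler genome keeps every
    # sample non-empty so N stays 10
    mk <- function(aIdx, bIdx) {
        present <- matrix(FALSE, 3L, 10L,
                          dimnames = list(c("a", "b", "zfill"),
                                          sprintf("s%02d", 1:10)))
        present["a", aIdx] <- TRUE
        present["b", bIdx] <- TRUE
        present["zfill", ] <- TRUE
        presenceSE(present)
    }
    pick <- function(res) res[res$genome_a == "a" & res$genome_b == "b", ]
    res <- pick(hypergeomCooccurrence(mk(1:5, 1:4)))
    expect_equal(res$expected, 2)
    expect_equal(res$ratio, 2)
    expect_equal(res$p, choose(5, 4) * choose(5, 0) / choose(10, 4),
                 tolerance = 1e-12)

    # ubiquitous genome: ratio 1, p = 1
    r2 <- pick(hypergeomCooccurrence(mk(1:10, seq(1, 10, 2))))
    expect_equal(r2$ratio, 1)
    expect_equal(r2$p, 1)

    # zero overlap: ratio 0, never significant
    r3 <- pick(hypergeomCooccurrence(mk(1:4, 5:8)))
    expect_equal(r3$ratio, 0)
    expect_false(r3$significant)
})

test_that("q-values are a monotone transform of p-values, never smaller", {
    set.seed(42)
    present <- matrix(runif(30 * 50) < 0.3, 30L, 50L,
                      dimnames = list(sprintf("g%02d", 1:30),
                                      sprintf("s%02d", 1:50)))
    res <- hypergeomCooccurrence(presenceSE(present))
    expect_true(all(res$q >= res$p - 1e-15))
    o <- order(res$p)
    expect_true(all(diff(res$q[o]) >= -1e-15))
    # simple_overlap == obs / min(k_a, k_b), literally
    se <- presenceSE(present)
    for (i in sample(nrow(res), 40L)) {
        so <- simpleOverlap(se, res$genome_a[i], res$genome_b[i])
        expect_identical(so, res$obs[i] / min(res$k_a[i], res$k_b[i]))
    }
})

test_that("permuting one genome's column preserves margins and ratio ~ 1", {
    set.seed(43)
    present <- matrix(runif(3 * 200) < 0.4, 3L, 200L,
                      dimnames = list(c("a", "b", "zfill"),
                                      sprintf("s%03d", 1:200)))
    present["zfill", ] <- TRUE   # keeps every sample non-empty, N fixed
    ratios <- replicate(200L, {
        p2 <- present
        p2["b", ] <- sample(p2["b", ])
        res <- hypergeomCooccurrence(presenceSE(p2))
        res$ratio[res$genome_a == "a" & res$genome_b == "b"]
    })
    expect_lt(abs(mean(ratios) - 1), 0.05)
})

test_that("simple overlap follows the set formula", {
    present <- matrix(FALSE, 2L, 4L,
                      dimnames = list(c("a", "b"), paste0("s", 1:4)))
    present["a", 1:3] <- TRUE      # {s1,s2,s3}
    present["b", 2:4] <- TRUE      # {s2,s3,s4}
    se <- presenceSE(present)
    expect_equal(simpleOverlap(se, "a", "b"), 2 / 3)
    # subset: min denominator gives 1
    present["b", ] <- c(TRUE, TRUE, FALSE, FALSE)
    expect_equal(simpleOverlap(presenceSE(present), "a", "b"), 1)
    present["b", ] <- FALSE
    expect_error(simpleOverlap(presenceSE(present), "a", "b"), "zero")
})

test_that("proportionality rho matches a direct clr computation", {
    # perfectly proportional profiles
    set.seed(44)
    base <- rlnorm(30L)
    rpkm <- rbind(g1 = base, g2 = 2 * base, g3 = rlnorm(30L))
    colnames(rpkm) <- sprintf("s%02d", 1:30)
    # with zero pseudocount effect (use tiny pseudocount) rho(g1,g2) -> 1
    rho <- proportionalityRho(rpkm, pseudocount = 1e-9)
    expect_equal(rho["g1", "g2"], 1, tolerance = 1e-6)
    expect_identical(diag(rho), c(g1 = 1, g2 = 1, g3 = 1))

    # 5x4 toy matrix against a hand-rolled oracle
    x <- matrix(c(1, 2, 3, 4, 5,
                  2, 1, 4, 3, 5,
                  9, 7, 5, 3, 1,
                  1, 1, 2, 2, 3), nrow = 4L, byrow = TRUE,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
    got <- proportionalityRho(x, pseudocount = 1)
    lg <- log(x + 1)
    clr <- sweep(lg, 2L, colMeans(lg))
    oracle <- function(i, j)
        1 - var(clr[i, ] - clr[j, ]) / (var(clr[i, ]) + var(clr[j, ]))
    for (i in 1:3) for (j in (i + 1):4)
        expect_equal(got[i, j], oracle(i, j))
    expect_identical(got, t(got))

    # independent noise: mean off-diagonal rho near zero (the clr closure
    # induces a small negative bias of order -1/(G-1), so use enough
    # genomes for it to vanish)
    set.seed(45)
    noise <- matrix(rlnorm(50 * 500), 50L, 500L,
                    dimnames = list(sprintf("g%02d", 1:50),
                                    sprintf("s%03d", 1:500)))
    rhoN <- proportionalityRho(noise)
    off <- rhoN[upper.tri(rhoN)]
    expect_lt(abs(mean(off)), 0.05)
})

test_that("size-fraction classification needs strict support and top RPKM", {
    mkSe <- function(presentIn, rpkmVals, fractions) {
        n <- length(fractions)
        present <- matrix(FALSE, 1L, n,
                          dimnames = list("g", sprintf("s%02d", 1:n)))
        present[1L, presentIn] <- TRUE
        rpkm <- matrix(0, 1L, n, dimnames = dimnames(present))
        rpkm[1L, presentIn] <- rpkmVals
        presenceSE(present, rpkm = rpkm, fraction = fractions)
    }
    fr <- c(rep("free_living", 8L), rep("combined_fl_pa", 4L))
    # 8/10 samples free-living with higher median there
    se <- mkSe(c(1:8, 9:10), c(rep(5, 8L), 1, 1), fr)
    out <- classifySizeFraction(se)
    expect_identical(out$class, "free_living")
    expect_equal(out$support, 0.8)
    # support exactly 0.75: unclassified (strict inequality)
    se2 <- mkSe(c(1:6, 9:10), c(rep(5, 6L), 1, 1), fr)
    expect_identical(classifySizeFraction(se2)$class, "unclassified")
    # support 0.8 but median rpkm higher in the other group: unclassified
    se3 <- mkSe(c(1:8, 9:10), c(rep(1, 8L), 9, 9), fr)
    expect_identical(classifySizeFraction(se3)$class, "unclassified")
})

test_that("fraction specialists planted in the fixture are recovered", {
    fx <- defaultFixture()
    se <- applyPrevalenceFilter(callPresence(fx$samples))
    cls <- classifySizeFraction(se)
    spec <- S4Vectors::metadata(fx$samples)$truth$specialists
    for (fr in names(spec)) {
        found <- cls$class[cls$genome_id %in% spec[[fr]]]
        expect_gt(length(found), 0L)
        expect_gte(mean(found == fr), 0.75)
    }
})

test_that("feature prevalence counts flagged present genomes per sample", {
    set.seed(46)
    present <- matrix(FALSE, 10L, 3L,
                      dimnames = list(sprintf("g%02d", 1:10), c("s1", "s2",
                                                                "s3")))
    present[, 1L] <- TRUE
    present[1:4, 2L] <- TRUE
    se <- presenceSE(present)
    flags <- setNames(c(rep(TRUE, 3L), rep(FALSE, 7L)), rownames(present))
    out <- featurePrevalence(se, flags)
    expect_equal(unname(out[1L]), 0.3)
    expect_equal(unname(out[2L]), 3 / 4)
    expect_true(is.na(out[3L]))
    expect_identical(unname(featurePrevalence(se, !flags & FALSE)[1L]), 0)
    # row-wise oracle on a random matrix
    pr <- matrix(runif(200) < 0.4, 20L, 10L,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("s%02d", 1:10)))
    fl <- setNames(runif(20) < 0.5, rownames(pr))
    got <- featurePrevalence(presenceSE(pr), fl)
    manual <- apply(pr, 2L, function(col)
        if (!sum(col)) NA_real_ else sum(col & fl) / sum(col))
    expect_equal(got, manual)
})

test_that("paired fraction tests detect planted fold changes", {
    expect_equal(pairedFractionTest(rep(0.2, 10L), rep(0.2, 10L)),
                 list(fold_change = 1, p = 1, n = 10L))
    set.seed(47)
    small <- runif(20L, 0.1, 0.4)
    out <- pairedFractionTest(small, 2 * small)
    expect_equal(out$fold_change, 2)
    expect_lt(out$p, 0.01)
    expect_error(pairedFractionTest(1:3, 2:4), "at least 6")
    # planted effect with noise, several features, BH corrected
    smallM <- data.frame(hgt = runif(20L, 0.1, 0.3),
                         mge = runif(20L, 0.1, 0.3),
                         null = runif(20L, 0.1, 0.3))
    largeM <- data.frame(hgt = smallM$hgt * 2 + rnorm(20L, 0, 0.02),
                         mge = smallM$mge * 1.8 + rnorm(20L, 0, 0.02),
                         null = smallM$null + rnorm(20L, 0, 0.02))
    res <- pairedFeatureTests(smallM, largeM)
    expect_true(all(res$q[res$feature %in% c("hgt", "mge")] < 0.05))
    expect_gt(res$fold_change[res$feature == "hgt"], 1.8)
})
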