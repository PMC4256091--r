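# additive-model association tests: OLS closed form vs lm, logistic vs
# glm and a likelihood-grid maximizer, CAF, scan cardinality and ordering

test_that("OLS slope, SE and p match the worked example", {
    f <- fitLinear(c(1, 1.2, 1.5, 1.7, 2, 2.2), c(0, 0, 1, 1, 2, 2))
    expect_equal(f$beta, 0.5)
    expect_equal(f$se, 0.06123724, tolerance = 1e-6)
    expect_equal(f$p, 0.001224915, tolerance = 1e-6)
    expect_equal(f$n, 6L)
    expect_equal(f$flag, "ok")
})

test_that("OLS agrees with stats::lm to 1e-10 on random instances", {
    set.seed(101)
    for (i in 1:200) {
        n <- sample(10:120, 1)
        g <- rbinom(n, 2, runif(1, 0.1, 0.6))
        if (length(unique(g)) < 2) next
        y <- rnorm(n, 3 + runif(1, -1, 1) * g, runif(1, 0.5, 4))
        f <- fitLinear(y, g)
        co <- summary(lm(y ~ g))$coefficients
        expect_equal(f$beta, co[2, 1], tolerance = 1e-10)
        expect_equal(f$se, co[2, 2], tolerance = 1e-10)
        expect_equal(f$p, co[2, 4], tolerance = 1e-10)
    }
})

test_that("degenerate OLS inputs are flagged, not errors", {
    expect_equal(fitLinear(c(1, 1, 1, 1), c(0, 1, 2, 1))$flag,
                 "constant_phenotype")
    expect_equal(fitLinear(c(1, 1, 1, 1), c(0, 1, 2, 1))$beta, 0)
    expect_equal(fitLinear(c(1, 2, 3), c(1, 1, 1))$flag,
                 "constant_genotype")
    expect_equal(fitLinear(c(1, 2), c(0, 1))$flag, "too_few")
    # missing values are dropped as complete cases
    f <- fitLinear(c(1, NA, 2, 3, 4), c(0, 1, NA, 1, 2))
    expect_equal(f$n, 3L)
})

test_that("OLS is exchangeable and scale-equivariant", {
    set.seed(5)
    g <- rbinom(60, 2, 0.4); y <- rnorm(60, 1 + 0.3 * g, 1)
    f <- fitLinear(y, g)
    perm <- sample(60)
    fp <- fitLinear(y[perm], g[perm])
    expect_equal(fp[c("beta", "se", "p")], f[c("beta", "se", "p")])
    f2 <- fitLinear(2 * y, g)
    expect_equal(f2$beta, 2 * f$beta)
    expect_equal(f2$se, 2 * f$se)
    expect_equal(f2$p, f$p)
})

test_that("logistic ML matches glm and flags separation", {
    set.seed(9)
    g <- rbinom(300, 2, 0.4)
    y <- rbinom(300, 1, plogis(-0.5 + 0.6 * g))
    f <- fitLogistic(y, g)
    gf <- glm(y ~ g, family = binomial())
    co <- summary(gf)$coefficients
    expect_equal(f$beta, co[2, 1], tolerance = 1e-6)
    expect_equal(f$se, co[2, 2], tolerance = 1e-6)
    expect_equal(f$p, co[2, 4], tolerance = 1e-6)
    # y = indicator(g == 2) is perfectly separated
    ysep <- as.integer(g == 2)
    expect_equal(fitLogistic(ysep, g)$flag, "separation")
    expect_equal(fitLogistic(rep(1L, 300), g)$flag, "one_level")
})

test_that("logistic ML agrees with a brute-force likelihood grid", {
    # independent oracle: nested grid search over (intercept, slope)
    gridMax <- function(y, g) {
        ll <- function(b0, b1) {
            eta <- b0 + b1 * g
            sum(y * eta - log1p(exp(eta)))
        }
        c0 <- 0; c1 <- 0; width <- 4
        for (step in 1:30) {
            b0s <- seq(c0 - width, c0 + width, length.out = 21)
            b1s <- seq(c1 - width, c1 + width, length.out = 21)
            val <- outer(b0s, b1s, Vectorize(ll))
            ix <- which(val == max(val), arr.ind = TRUE)[1, ]
            c0 <- b0s[ix[1]]; c1 <- b1s[ix[2]]
            width <- width / 2.5
        }
        c(c0, c1)
    }
    set.seed(31)
    for (i in 1:5) {
        g <- c(0, 0, 0, 1, 1, 1, 1, 2, 2, 0, 1, 2)
        y <- c(0, 1, 0, 0, 1, 1, 0, 1, 1, 0, 0, 1)[sample(12)]
        f <- fitLogistic(y, g)
        if (f$flag != "ok") next
        expect_equal(f$beta, gridMax(y, g)[2], tolerance = 1e-4)
    }
})

test_that("coded-allele frequency counts alleles in the analyzed subset", {
    expect_equal(codedAlleleFrequency(c(0, 1, 2, 2)), 0.625)
    expect_equal(codedAlleleFrequency(c(2, 2, 2)), 1)
    expect_true(is.na(codedAlleleFrequency(c(NA, NA))))
    set.seed(2)
    for (i in 1:25) {
        g <- rbinom(40, 2, runif(1))
        expect_equal(codedAlleleFrequency(g) +
                     codedAlleleFrequency(2 - g), 1)
    }
})

test_that("matrix scan equals the scalar fit under missingness", {
    set.seed(77)
    n <- 150
    G <- matrix(rbinom(n * 4, 2, 0.3), n)
    Y <- matrix(rnorm(n * 5), n)
    G[sample(length(G), 40)] <- NA
    Y[sample(length(Y), 60)] <- NA
    sc <- phewasKit:::.linearScanMatrix(G, Y)
    for (j in 1:4) for (m in 1:5) {
        f <- fitLinear(Y[, m], G[, j])
        if (f$flag != "ok") next
        expect_equal(sc$beta[j, m], f$beta, tolerance = 1e-8)
        expect_equal(sc$se[j, m], f$se, tolerance = 1e-8)
        expect_equal(sc$p[j, m], f$p, tolerance = 1e-8)
        expect_equal(sc$n[j, m], f$n)
    }
})

test_that("the scan emits one row per snp x measurement x survey x stratum", {
    cfg <- tinyConfig(seed = 13, n = c(A = 250, B = 250))
    expt <- simulateStudy(cfg)
    scan <- runScan(expt, transforms = FALSE, combined = FALSE)
    # 2 SNPs x 2 measurements x 2 surveys x 2 strata
    expect_equal(nrow(scan), 16)
    scanC <- runScan(expt, transforms = FALSE, combined = TRUE)
    expect_equal(nrow(scanC), 24)   # + 2 x 2 x 2 combined rows
    expect_setequal(unique(scanC$survey),
                    c("survey1", "survey2", "combined"))
    # deterministic ordering and reproducibility
    expect_equal(scanC, runScan(expt, transforms = FALSE))
    ord <- order(scanC$snp, scanC$class, scanC$measurement, scanC$survey,
                 scanC$stratum)
    expect_equal(ord, seq_len(nrow(scanC)))
})

test_that("scan p-values are uniform under the null", {
    cfg <- nullSimulationConfig(nSnps = 20, nPhenotypes = 250,
                                nPerStratum = 200, strata = "S1",
                                seed = 17)
    expt <- simulateStudy(cfg)
    scan <- runScan(expt, transforms = FALSE, combined = FALSE)
    p <- scan$p[scan$survey == "survey1"]
    expect_gte(length(p), 5000)
    expect_gt(ks.test(p, "punif")$p.value, 0.001)
    expect_lt(abs(mean(p < 0.01) - 0.01),
              3 * sqrt(0.01 * 0.99 / length(p)))
})

test_that("planted effect signs match the truth table at high power", {
    cfg <- tinyConfig(seed = 23, beta = 0.5, n = c(A = 2000, B = 2000))
    expt <- simulateStudy(cfg)
    scan <- runScan(expt, transforms = FALSE, combined = FALSE)
    hits <- scan[scan$snp == "rs1" & scan$class == "TraitOne", ]
    expect_true(all(hits$beta > 0))
    expect_true(all(hits$p < 1e-6))
})
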