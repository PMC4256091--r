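# the seven-criterion replication filter and the combined re-test

test_that("a qualifying cross-survey pair with matching sign is retained", {
    # patterned after a lipid-locus replication: both surveys p << 0.01,
    # negative direction, ample n and frequency
    res <- rbind(
        resultRow("rs646776", "Cholesterol", "NHW", "survey1",
                  "Serum cholesterol", beta = -7.66, p = 3.17e-6,
                  n = 2224L, caf = 0.77),
        resultRow("rs646776", "Cholesterol", "NHW", "survey2",
                  "Total cholesterol", beta = -0.014, p = 9.15e-7,
                  n = 3943L, caf = 0.78))
    ret <- applyReplicationCriteria(res,
                                    surveyLabels = c("survey1", "survey2"))
    expect_equal(nrow(ret), 1L)
    expect_equal(ret$direction, "-")
    expect_equal(ret$p_s1, 3.17e-6)
    expect_equal(ret$p_s2, 9.15e-7)
})

test_that("each failed criterion excludes the group", {
    base <- function(...) rbind(
        resultRow("rs1", "C1", "S", "survey1", "m1", ...),
        resultRow("rs1", "C1", "S", "survey2", "m2"))
    two <- function(r1, r2) rbind(r1, r2)
    labs <- c("survey1", "survey2")
    # opposite beta signs
    expect_equal(nrow(applyReplicationCriteria(
        base(beta = -1), surveyLabels = labs)), 0L)
    # n at or below 200 in one survey
    expect_equal(nrow(applyReplicationCriteria(
        base(n = 150L), surveyLabels = labs)), 0L)
    expect_equal(nrow(applyReplicationCriteria(
        base(n = 200L), surveyLabels = labs)), 0L)
    # p not strictly below 0.01
    expect_equal(nrow(applyReplicationCriteria(
        base(p = 0.01), surveyLabels = labs)), 0L)
    # caf not strictly above 0.01
    expect_equal(nrow(applyReplicationCriteria(
        base(caf = 0.01), surveyLabels = labs)), 0L)
    # present in one survey only
    expect_equal(nrow(applyReplicationCriteria(
        resultRow("rs1", "C1", "S", "survey1"), surveyLabels = labs)), 0L)
    # strata must match
    expect_equal(nrow(applyReplicationCriteria(two(
        resultRow("rs1", "C1", "S1", "survey1"),
        resultRow("rs1", "C1", "S2", "survey2")), surveyLabels = labs)), 0L)
    # classes must match
    expect_equal(nrow(applyReplicationCriteria(two(
        resultRow("rs1", "C1", "S", "survey1"),
        resultRow("rs1", "C2", "S", "survey2")), surveyLabels = labs)), 0L)
    # flagged fits never qualify; beta exactly 0 has no direction
    expect_equal(nrow(applyReplicationCriteria(
        base(flag = "separation"), surveyLabels = labs)), 0L)
    expect_equal(nrow(applyReplicationCriteria(
        base(beta = 0), surveyLabels = labs)), 0L)
    # all criteria met -> retained
    expect_equal(nrow(applyReplicationCriteria(
        base(), surveyLabels = labs)), 1L)
})

test_that("qualifying pairs must match on transform status", {
    res <- rbind(
        resultRow("rs1", "C1", "S", "survey1", "m", transform = "ln1p"),
        resultRow("rs1", "C1", "S", "survey2", "m", transform = "none"))
    expect_equal(nrow(applyReplicationCriteria(
        res, surveyLabels = c("survey1", "survey2"))), 0L)
})

test_that("the best measurement minimizes p with n and name tie-breaks", {
    res <- rbind(
        resultRow("rs1", "C1", "S", "survey1", "m1", p = 1e-5),
        resultRow("rs1", "C1", "S", "survey1", "m2", p = 3e-4),
        resultRow("rs1", "C1", "S", "survey1", "m3", p = 2e-3),
        resultRow("rs1", "C1", "S", "survey1", "m4", p = 9e-3),
        resultRow("rs1", "C1", "S", "survey2", "w2", p = 5e-3, n = 500L),
        resultRow("rs1", "C1", "S", "survey2", "w1", p = 5e-3, n = 500L),
        resultRow("rs1", "C1", "S", "survey2", "w3", p = 5e-3, n = 400L))
    ret <- applyReplicationCriteria(res,
                                    surveyLabels = c("survey1", "survey2"))
    expect_equal(ret$measurement_s1, "m1")
    expect_equal(ret$p_s1, 1e-5)
    # survey2 ties on p: larger n wins, then lexicographic name
    expect_equal(ret$measurement_s2, "w1")
    expect_equal(ret$n_pairs, 4L * 3L)
})

test_that("filter output is invariant to input row order", {
    expt <- simulateStudy(tinyConfig(seed = 31, beta = 0.4,
                                     n = c(A = 900, B = 900)))
    scan <- runScan(expt)
    ret1 <- applyReplicationCriteria(scan)
    set.seed(1)
    ret2 <- applyReplicationCriteria(scan[sample(nrow(scan)), ])
    expect_equal(ret1, ret2)
    expect_gte(nrow(ret1), 1L)
})

test_that("retained groups re-satisfy all seven criteria", {
    expt <- simulateStudy(tinyConfig(seed = 33, beta = 0.4,
                                     n = c(A = 900, B = 900),
                                     missingRate = 0.05))
    ret <- applyReplicationCriteria(runScan(expt))
    for (side in c("s1", "s2")) {
        expect_true(all(ret[[paste0("p_", side)]] < 0.01))
        expect_true(all(ret[[paste0("caf_", side)]] > 0.01))
        expect_true(all(ret[[paste0("n_", side)]] > 200))
    }
    expect_true(all(sign(ret$beta_s1) == sign(ret$beta_s2)))
})

test_that("combined re-tests attach where a pooled variable exists", {
    res <- rbind(
        resultRow("rs1", "C1", "S", "survey1"),
        resultRow("rs1", "C1", "S", "survey2"),
        resultRow("rs1", "C1", "S", "combined", "m1", p = 1e-10,
                  beta = -0.029, n = 6389L),
        resultRow("rs1", "C1", "S", "combined", "m2", p = 1e-4,
                  n = 6389L),
        resultRow("rs2", "C2", "S", "survey1"),
        resultRow("rs2", "C2", "S", "survey2"))
    ret <- combinedRetest(
        applyReplicationCriteria(res,
                                 surveyLabels = c("survey1", "survey2")),
        res)
    r1 <- ret[ret$snp == "rs1", ]
    expect_equal(r1$combined_p, 1e-10)       # lowest combined p attached
    expect_equal(r1$combined_beta, -0.029)
    expect_equal(r1$combined_n, 6389L)
    r2 <- ret[ret$snp == "rs2", ]
    expect_true(is.na(r2$combined_p))        # absence recorded, no error
})

test_that("combined n equals the sum of per-survey complete-case ns", {
    expt <- simulateStudy(tinyConfig(seed = 41, beta = 0.6,
                                     n = c(A = 700, B = 700),
                                     missingRate = 0.1))
    scan <- runScan(expt)
    key <- c("snp", "measurement", "stratum")
    s1 <- scan[scan$survey == "survey1", ]
    s2 <- scan[scan$survey == "survey2", ]
    cb <- scan[scan$survey == "combined", ]
    m <- merge(merge(s1[, c(key, "n")], s2[, c(key, "n")], by = key),
               cb[, c(key, "n")], by = key)
    expect_gt(nrow(m), 0)
    expect_true(all(m$n.x + m$n.y == m$n))
})
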