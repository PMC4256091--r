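# Unadjusted additive-model single-SNP association tests.
#
# Linear fits use the closed-form two-parameter OLS solution with a
# two-sided t test on n - 2 df for the slope; logistic fits are maximum
# likelihood (IRLS via stats::glm.fit) with a Wald normal test, plus
# explicit convergence and separation flags. Everything is complete-case
# per SNP-measurement pair; the coded-allele frequency is computed on each
# result's analyzed subset.

.emptyFit <- function(flag) list(beta = NA_real_, se = NA_real_,
                                 p = NA_real_, n = 0L, flag = flag)

#' Ordinary least squares of a phenotype on genotype dosage
#'
#' Fits \eqn{y = a + \beta g} by OLS on complete cases and tests the slope
#' with a two-sided t statistic on \eqn{n - 2} degrees of freedom. Constant
#' genotype, constant phenotype or fewer than three complete cases yield a
#' flagged, unavailable result rather than an error.
#'
#' @param y continuous phenotype values.
#' @param g genotype dosages (0/1/2 copies of the coded allele).
#' @return list: \code{beta} (effect per coded-allele copy), \code{se},
#'   \code{p}, \code{n} (complete cases), \code{flag} (\code{"ok"} or the
#'   reason the fit is unavailable).
#' @examples
#' fitLinear(c(1, 1.2, 1.5, 1.7, 2, 2.2), c(0, 0, 1, 1, 2, 2))
#' @export
fitLinear <- function(y, g) {
    ok <- !is.na(y) & !is.na(g)
    y <- y[ok]; g <- g[ok]
    n <- length(y)
    if (n < 3L) return(.emptyFit("too_few"))
    gc <- g - mean(g); yc <- y - mean(y)
    sxx <- sum(gc^2)
    if (sxx == 0) return(.emptyFit("constant_genotype"))
    sxy <- sum(gc * yc); syy <- sum(yc^2)
    beta <- sxy / sxx
    if (syy == 0)
        return(list(beta = 0, se = NA_real_, p = NA_real_, n = n,
                    flag = "constant_phenotype"))
    rss <- max(syy - beta * sxy, 0)
    if (rss == 0)
        return(list(beta = beta, se = 0, p = NA_real_, n = n,
                    flag = "perfect_fit"))
    se <- sqrt(rss / (n - 2) / sxx)
    tstat <- beta / se
    list(beta = beta, se = se, p = 2 * stats::pt(-abs(tstat), n - 2),
         n = n, flag = "ok")
}

#' Logistic regression of a binary phenotype on genotype dosage
#'
#' Maximum-likelihood logistic regression of y on g with intercept
#' (IRLS, relative deviance tolerance 1e-8, at most 50 iterations); the
#' two-sided p-value is the Wald test of \eqn{\beta/\mathrm{se}} against
#' the standard normal. A single observed outcome level makes the fit
#' unavailable; non-convergence or a standard error above 100 on the coded
#' scale (the separation signature) is flagged invalid.
#'
#' @inheritParams fitLinear
#' @param y binary phenotype coded 0/1.
#' @param seThreshold standard error above which the fit is flagged as
#'   separated.
#' @return list as in [fitLinear()]; flags \code{"one_level"},
#'   \code{"not_converged"}, \code{"separation"} mark invalid fits.
#' @export
fitLogistic <- function(y, g, seThreshold = 100) {
    ok <- !is.na(y) & !is.na(g)
    y <- y[ok]; g <- g[ok]
    n <- length(y)
    if (n < 3L) return(.emptyFit("too_few"))
    if (length(unique(y)) < 2L) return(.emptyFit("one_level"))
    if (length(unique(g)) < 2L) return(.emptyFit("constant_genotype"))
    X <- cbind(1, g)
    fit <- suppressWarnings(stats::glm.fit(
        X, y, family = stats::binomial(),
        control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
    beta <- unname(fit$coefficients[2])
    # unscaled covariance from the weighted least-squares decomposition
    cov <- tryCatch(chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE]),
                    error = function(e) NULL)
    se <- if (is.null(cov)) NA_real_ else sqrt(cov[2, 2])
    flag <- "ok"
    if (!fit$converged) flag <- "not_converged"
    else if (!is.finite(se) || se > seThreshold) flag <- "separation"
    p <- if (flag == "ok") 2 * stats::pnorm(-abs(beta / se)) else NA_real_
    list(beta = beta, se = se, p = p, n = n, flag = flag)
}

#' Coded-allele frequency of an analyzed genotype subset
#'
#' @param g genotype dosages (0/1/2, NA allowed).
#' @return sum of coded-allele copies over twice the non-missing count, or
#'   \code{NA} when all genotypes are missing.
#' @examples
#' codedAlleleFrequency(c(0, 1, 2, 2))  # 5/8
#' @export
codedAlleleFrequency <- function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    sum(g) / (2 * length(g))
}

# Vectorised pairwise-complete OLS scan: every column of G against every
# column of Y through six cross-products of NA-masked matrices. Exact
# complete-case algebra, identical to fitLinear() up to floating-point
# rearrangement.
.linearScanMatrix <- function(G, Y) {
    Mg <- !is.na(G); My <- !is.na(Y)
    G0 <- ifelse(Mg, G, 0); Y0 <- ifelse(My, Y, 0)
    storage.mode(Mg) <- "double"; storage.mode(My) <- "double"
    n   <- crossprod(Mg, My)
    Sg  <- crossprod(G0, My)
    Sg2 <- crossprod(G0^2, My)
    Sy  <- crossprod(Mg, Y0)
    Sy2 <- crossprod(Mg, Y0^2)
    Sgy <- crossprod(G0, Y0)
    sxx <- Sg2 - Sg^2 / n
    sxy <- Sgy - Sg * Sy / n
    syy <- Sy2 - Sy^2 / n
    beta <- sxy / sxx
    rss <- pmax(syy - beta * sxy, 0)
    se <- sqrt(rss / (n - 2) / sxx)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    caf <- Sg / (2 * n)
    flag <- matrix("ok", nrow(n), ncol(n))
    flag[n < 3] <- "too_few"
    flag[n >= 3 & sxx <= 0] <- "constant_genotype"
    flag[n >= 3 & sxx > 0 & syy <= 0] <- "constant_phenotype"
    beta[flag == "constant_phenotype"] <- 0
    bad <- flag != "ok"
    se[bad] <- NA; p[bad] <- NA
    pf <- flag == "ok" & rss == 0
    flag[pf] <- "perfect_fit"; p[pf] <- NA
    list(beta = beta, se = se, p = p, n = n, caf = caf, flag = flag)
}

# scan one survey's measurements, stratified; returns the standard result
# data.frame
.scanStudy <- function(study, meas) {
    G <- genotypes(study)
    vals <- meas$values; info <- meas$info
    if (!ncol(vals) || !ncol(G))
        return(.emptyScanResult())
    si <- snpInfo(study)
    strata <- sort(unique(sampleInfo(study)$stratum))
    out <- vector("list", length(strata))
    contIdx <- which(info$type == "continuous")
    binIdx <- which(info$type == "binary")
    for (sidx in seq_along(strata)) {
        st <- strata[sidx]
        rows <- sampleInfo(study)$stratum == st
        Gs <- G[rows, , drop = FALSE]
        blocks <- list()
        if (length(contIdx)) {
            sc <- .linearScanMatrix(Gs, vals[rows, contIdx, drop = FALSE])
            blocks[[length(blocks) + 1L]] <- data.frame(
                snp = rep(si$snp, times = length(contIdx)),
                coded_allele = rep(si$coded_allele,
                                   times = length(contIdx)),
                measurement = rep(info$measurement[contIdx],
                                  each = nrow(si)),
                phenotype = rep(info$phenotype[contIdx], each = nrow(si)),
                transform = rep(info$transform[contIdx], each = nrow(si)),
                class = rep(info$class[contIdx], each = nrow(si)),
                survey = surveyName(study), stratum = st,
                beta = as.vector(sc$beta), se = as.vector(sc$se),
                p = as.vector(sc$p), n = as.integer(sc$n),
                caf = as.vector(sc$caf), flag = as.vector(sc$flag),
                stringsAsFactors = FALSE)
        }
        if (length(binIdx)) {
            recs <- vector("list", length(binIdx) * nrow(si))
            k <- 0L
            for (m in binIdx) for (j in seq_len(nrow(si))) {
                f <- fitLogistic(vals[rows, m], Gs[, j])
                k <- k + 1L
                recs[[k]] <- data.frame(
                    snp = si$snp[j], coded_allele = si$coded_allele[j],
                    measurement = info$measurement[m],
                    phenotype = info$phenotype[m],
                    transform = info$transform[m], class = info$class[m],
                    survey = surveyName(study), stratum = st,
                    beta = f$beta, se = f$se, p = f$p, n = f$n,
                    caf = codedAlleleFrequency(
                        Gs[!is.na(vals[rows, m]), j]),
                    flag = f$flag, stringsAsFactors = FALSE)
            }
            blocks[[length(blocks) + 1L]] <-
                do.call(rbind, c(recs, make.row.names = FALSE))
        }
        out[[sidx]] <- do.call(rbind, c(blocks, make.row.names = FALSE))
    }
    do.call(rbind, c(out, make.row.names = FALSE))
}

.emptyScanResult <- function() {
    data.frame(snp = character(), coded_allele = character(),
               measurement = character(), phenotype = character(),
               transform = character(), class = character(),
               survey = character(), stratum = character(),
               beta = numeric(), se = numeric(), p = numeric(),
               n = integer(), caf = numeric(), flag = character(),
               stringsAsFactors = FALSE)
}

#' Run the full per-survey (and combined-survey) association scan
#'
#' One unadjusted additive-model test per SNP x measurement x survey x
#' stratum, complete-case per pair, no covariates. Combined-survey rows
#' (survey \code{"combined"}) are produced only for exactly harmonized
#' phenotypes (see [harmonizeCombined()]). Output ordering is
#' deterministic: snp, class, measurement, survey, stratum.
#'
#' @param experiment a [PhewasExperiment-class].
#' @param transforms include ln(y+1) copies of continuous measurements.
#' @param combined include the pooled combined-survey scan.
#' @return data.frame with columns snp, coded_allele, measurement,
#'   phenotype, transform, class, survey, stratum, beta, se, p, n, caf,
#'   flag.
#' @export
runScan <- function(experiment, transforms = TRUE, combined = TRUE) {
    stopifnot(is(experiment, "PhewasExperiment"))
    map <- classMap(experiment)
    parts <- lapply(surveys(experiment), function(s)
        .scanStudy(s, buildMeasurements(s, map, transforms = transforms)))
    if (combined) {
        pooled <- harmonizeCombined(experiment)
        if (!is.null(pooled)) {
            # pooled phenotypes keep survey-1 raw names; map them via the
            # first survey's entries under the combined label
            cmap <- map[map$survey == surveyName(surveys(experiment)[[1]]), ]
            cmap$survey <- "combined"
            parts[[length(parts) + 1L]] <-
                .scanStudy(pooled, buildMeasurements(pooled, cmap,
                                                     transforms = transforms))
        }
    }
    res <- do.call(rbind, c(parts, make.row.names = FALSE))
    if (!nrow(res)) return(.emptyScanResult())
    res[order(res$snp, res$class, res$measurement, res$survey,
              res$stratum), , drop = FALSE] -> res
    rownames(res) <- NULL
    res
}
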