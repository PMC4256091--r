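# Phenotype harmonization: log(y+1) transformation, A-versus-not-A
# binarization of categoricals, class binning, combined-survey pooling and
# the cohort summary table.

#' Natural log(y + 1) transformation of a nonnegative phenotype
#'
#' Every continuous measurement is offset by +1 before taking the natural
#' log so that values recorded as zero are retained (log(0 + 1) = 0) rather
#' than dropped. Missing values stay missing.
#'
#' @param values numeric vector, all non-missing values must be >= 0.
#' @param phenotype name used in the error message on negative input.
#' @return \code{log(values + 1)}.
#' @examples
#' transformLn1p(c(0, exp(1) - 1, NA))  # 0, 1, NA
#' @export
transformLn1p <- function(values, phenotype = "phenotype") {
    v <- values[!is.na(values)]
    if (length(v) && any(v < 0))
        stop("negative values in '", phenotype,
             "': log(y+1) transform requires y >= 0")
    log(values + 1)
}

#' Binarize a categorical phenotype into A-versus-not-A indicators
#'
#' One binary variable per observed category: 1 if the sample equals that
#' category, 0 otherwise; missing propagates. Inputs with fewer than two
#' observed categories are skipped with a warning (there is nothing to
#' contrast).
#'
#' @param values character/factor vector of category labels.
#' @param phenotype parent phenotype name, used to name the indicators
#'   (\code{"<phenotype>=<category>"}).
#' @return data.frame of 0/1 indicator columns, or \code{NULL} when fewer
#'   than two categories are observed.
#' @examples
#' binarizeCategorical(c("A", "B", "C", "B"), "allergy")
#' @export
binarizeCategorical <- function(values, phenotype = "phenotype") {
    values <- as.character(values)
    cats <- sort(unique(values[!is.na(values)]))
    if (length(cats) < 2L) {
        warning("'", phenotype, "' has fewer than two observed categories; ",
                "skipped")
        return(NULL)
    }
    out <- lapply(cats, function(cc) as.integer(values == cc))
    names(out) <- paste0(phenotype, "=", cats)
    as.data.frame(out, check.names = FALSE, optional = TRUE)
}

#' Bin survey phenotypes into phenotype classes
#'
#' Assigns each phenotype its curated class label from the class map.
#' Unmapped phenotypes are excluded from replication matching and reported.
#' Conflicting duplicate assignments are an error.
#'
#' @param descriptors data.frame with columns \code{survey},
#'   \code{phenotype} (raw name).
#' @param map class map data.frame (\code{survey}, \code{phenotype},
#'   \code{class}).
#' @return list with \code{assigned} (descriptors plus \code{class}, mapped
#'   rows only) and \code{unmapped} (raw names with no class).
#' @export
assignClasses <- function(descriptors, map) {
    descriptors <- as.data.frame(descriptors)
    map <- as.data.frame(map)
    key <- paste(map$survey, map$phenotype, sep = "\r")
    dup <- unique(key[duplicated(key)])
    if (length(dup)) {
        conf <- vapply(dup, function(k) {
            length(unique(map$class[key == k])) > 1L
        }, TRUE)
        if (any(conf))
            stop("conflicting class assignments for: ",
                 paste(sub("\r", " / ", dup[conf]), collapse = ", "))
        map <- map[!duplicated(key), ]
        key <- key[!duplicated(key)]
    }
    dkey <- paste(descriptors$survey, descriptors$phenotype, sep = "\r")
    idx <- match(dkey, key)
    descriptors$class <- map$class[idx]
    list(assigned = descriptors[!is.na(idx), , drop = FALSE],
         unmapped = descriptors[is.na(idx), , drop = FALSE])
}

# Expand one survey's raw phenotypes into analyzable measurements:
# continuous -> untransformed + ln(y+1) (the transformed copy is kept as a
# distinct measurement of the same class, and is skipped when negative
# values make the transform undefined); binary -> itself; categorical ->
# one A-versus-not-A indicator per observed category, inheriting the
# parent's class.
#' Build the measurement matrix for one survey
#'
#' @param study a [PhewasStudy-class].
#' @param map class map data.frame; phenotypes without a class are dropped
#'   from the measurement set (they cannot enter replication matching).
#' @param transforms add the ln(y+1) copies of continuous phenotypes
#'   (default TRUE).
#' @return list with \code{values} (samples x measurements numeric matrix,
#'   binary coded 0/1) and \code{info} (measurement metadata: phenotype,
#'   transform, type, class).
#' @export
buildMeasurements <- function(study, map, transforms = TRUE) {
    stopifnot(is(study, "PhewasStudy"))
    pinfo <- phenotypeInfo(study)
    pinfo$survey <- surveyName(study)
    binned <- assignClasses(pinfo[, c("survey", "phenotype", "type")], map)
    use <- binned$assigned
    ph <- phenotypes(study)
    vals <- list(); meta <- list()
    addCol <- function(name, v, phenotype, transform, type, class) {
        vals[[name]] <<- as.numeric(v)
        meta[[name]] <<- data.frame(measurement = name,
                                    phenotype = phenotype,
                                    transform = transform, type = type,
                                    class = class, stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(use))) {
        nm <- use$phenotype[k]; type <- use$type[k]; cl <- use$class[k]
        v <- ph[[nm]]
        if (type == "continuous") {
            addCol(nm, v, nm, "none", "continuous", cl)
            vv <- v[!is.na(v)]
            if (transforms && length(vv) && all(vv >= 0))
                addCol(paste0("(ln+1)", nm), log(v + 1), nm, "ln1p",
                       "continuous", cl)
        } else if (type == "binary") {
            addCol(nm, v, nm, "none", "binary", cl)
        } else {
            ind <- suppressWarnings(binarizeCategorical(v, nm))
            if (!is.null(ind))
                for (j in seq_along(ind))
                    addCol(names(ind)[j], ind[[j]], nm, "none", "binary", cl)
        }
    }
    values <- if (length(vals))
        matrix(unlist(vals, use.names = FALSE), nrow = nrow(ph),
               dimnames = list(sampleInfo(study)$sample_id, names(vals)))
    else matrix(numeric(), nrow = nrow(ph), ncol = 0)
    info <- if (length(meta))
        do.call(rbind, c(meta, make.row.names = FALSE))
    else data.frame(measurement = character(), phenotype = character(),
                    transform = character(), type = character(),
                    class = character())
    list(values = values, info = info, unmapped = binned$unmapped)
}

#' Pool exactly-harmonized phenotypes across the two surveys
#'
#' A combined-survey variable exists only when the identical raw phenotype
#' (same name, same type, same class) was measured in both surveys; classes
#' that were binned but not harmonized yield no combined variable. Sample
#' ids must be disjoint across surveys.
#'
#' @param experiment a [PhewasExperiment-class].
#' @return A [PhewasStudy-class] labelled \code{"combined"} restricted to
#'   the shared phenotypes and the SNPs present in both surveys, or
#'   \code{NULL} when nothing harmonizes.
#' @export
harmonizeCombined <- function(experiment) {
    stopifnot(is(experiment, "PhewasExperiment"))
    s1 <- surveys(experiment)[[1]]; s2 <- surveys(experiment)[[2]]
    if (any(sampleInfo(s1)$sample_id %in% sampleInfo(s2)$sample_id))
        stop("sample ids overlap across surveys; pooling would duplicate")
    p1 <- phenotypeInfo(s1); p2 <- phenotypeInfo(s2)
    k1 <- paste(p1$phenotype, p1$type); k2 <- paste(p2$phenotype, p2$type)
    shared <- intersect(k1, k2)
    if (!length(shared)) return(NULL)
    keep1 <- p1[k1 %in% shared, , drop = FALSE]
    snpsBoth <- intersect(snpInfo(s1)$snp, snpInfo(s2)$snp)
    G <- rbind(genotypes(s1)[, snpsBoth, drop = FALSE],
               genotypes(s2)[, snpsBoth, drop = FALSE])
    P <- rbind(phenotypes(s1)[, keep1$phenotype, drop = FALSE],
               phenotypes(s2)[, keep1$phenotype, drop = FALSE])
    samp <- rbind(sampleInfo(s1), sampleInfo(s2))
    si <- snpInfo(s1)
    PhewasStudy("combined", G, si[match(snpsBoth, si$snp), , drop = FALSE],
                P, keep1, samp)
}

#' Cohort summary: per-survey and pooled demographics
#'
#' Per-survey n, percent female and stratum percentages; pooled values are
#' count-weighted; the sex-by-survey statistic is the 2 x 2 Pearson
#' chi-square on female/male counts without continuity correction.
#'
#' @param samples1,samples2 per-survey sample tables with columns
#'   \code{stratum} and, for the sex summary, \code{sex} coded
#'   \code{"female"}/\code{"male"}.
#' @param surveyNames labels for the two surveys.
#' @return list with \code{perSurvey} (data.frame), \code{pooled} (list:
#'   \code{n}, \code{pctFemale}, \code{stratumPct}), and \code{sexBySurvey}
#'   (list: \code{chisq}, \code{df}, \code{p}); sex fields are absent (with
#'   a message) when a sex column is missing.
#' @examples
#' s1 <- data.frame(stratum = "NHW", sex = rep(c("female", "male"), c(6, 4)))
#' s2 <- data.frame(stratum = "NHW", sex = rep(c("female", "male"), c(5, 5)))
#' summarizeCohort(s1, s2)$pooled$pctFemale
#' @export
summarizeCohort <- function(samples1, samples2,
                            surveyNames = c("survey1", "survey2")) {
    ss <- list(samples1, samples2)
    n <- vapply(ss, nrow, 1L)
    hasSex <- all(vapply(ss, function(s) "sex" %in% names(s), TRUE))
    pctF <- if (hasSex)
        vapply(ss, function(s) 100 * mean(s$sex == "female", na.rm = TRUE),
               1) else rep(NA_real_, 2)
    strata <- sort(unique(c(samples1$stratum, samples2$stratum)))
    stratPct <- vapply(ss, function(s)
        100 * as.vector(table(factor(s$stratum, strata))) / nrow(s),
        numeric(length(strata)))
    stratPct <- matrix(stratPct, nrow = length(strata),
                       dimnames = list(strata, surveyNames))
    perSurvey <- data.frame(survey = surveyNames, n = n,
                            pctFemale = pctF, row.names = NULL)
    pooledStrat <- (stratPct[, 1] * n[1] + stratPct[, 2] * n[2]) / sum(n)
    pooled <- list(n = sum(n),
                   pctFemale = if (hasSex)
                       sum(pctF * n) / sum(n) else NA_real_,
                   stratumPct = pooledStrat)
    out <- list(perSurvey = perSurvey, pooled = pooled)
    if (hasSex) {
        counts <- vapply(ss, function(s)
            c(sum(s$sex == "female", na.rm = TRUE),
              sum(s$sex == "male", na.rm = TRUE)), numeric(2))
        if (all(rowSums(counts) > 0)) {
            chs <- suppressWarnings(
                stats::chisq.test(counts, correct = FALSE))
            out$sexBySurvey <- list(chisq = unname(chs$statistic),
                                    df = unname(chs$parameter),
                                    p = unname(chs$p.value))
        }
    } else message("no 'sex' column; sex summary omitted")
    out
}
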