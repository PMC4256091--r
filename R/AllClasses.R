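#' @import methods
NULL

.PHENOTYPE_TYPES <- c("continuous", "binary", "categorical")

#' PhewasStudy: one survey's genotypes, phenotypes and sample metadata
#'
#' Container for a single epidemiologic survey: an additive-coded genotype
#' matrix (samples x SNPs, values 0/1/2 counting copies of the coded allele,
#' \code{NA} for missing), a phenotype table (samples x phenotypes, mixed
#' continuous/binary/categorical columns), sample metadata (stratum, sex)
#' and per-SNP / per-phenotype annotation.
#'
#' @slot survey single character survey label (e.g. \code{"survey1"}).
#' @slot genotypes numeric matrix, samples in rows, SNPs in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @slot snpInfo data.frame with columns \code{snp}, \code{chrom},
#'   \code{pos}, \code{coded_allele}; one row per genotype column.
#' @slot phenotypes data.frame of raw phenotype values, one row per sample.
#' @slot phenotypeInfo data.frame with columns \code{phenotype},
#'   \code{type} (continuous/binary/categorical) and optionally
#'   \code{class}; one row per phenotype column.
#' @slot samples data.frame with columns \code{sample_id}, \code{stratum}
#'   and optionally \code{sex}; one row per sample.
#'
#' @seealso [PhewasStudy()] constructor, [simulateStudy()], [runScan()]
#' @export
setClass("PhewasStudy", representation(
    survey        = "character",
    genotypes     = "matrix",
    snpInfo       = "data.frame",
    phenotypes    = "data.frame",
    phenotypeInfo = "data.frame",
    samples       = "data.frame"
))

setValidity("PhewasStudy", function(object) {
    msg <- character()
    if (length(object@survey) != 1L || is.na(object@survey) ||
        !nzchar(object@survey))
        msg <- c(msg, "'survey' must be a single non-empty string")
    g <- object@genotypes
    if (nrow(g) != nrow(object@samples))
        msg <- c(msg, "genotype rows must match sample rows")
    if (nrow(object@phenotypes) != nrow(object@samples))
        msg <- c(msg, "phenotype rows must match sample rows")
    bad <- g[!is.na(g)]
    if (length(bad) && !all(bad %in% c(0, 1, 2)))
        msg <- c(msg, "genotype entries must be 0, 1, 2 or NA")
    if (ncol(g) != nrow(object@snpInfo))
        msg <- c(msg, "snpInfo must have one row per genotype column")
    if (!all(c("snp", "coded_allele") %in% names(object@snpInfo)))
        msg <- c(msg, "snpInfo needs columns 'snp' and 'coded_allele'")
    pi <- object@phenotypeInfo
    if (nrow(pi) != ncol(object@phenotypes))
        msg <- c(msg, "phenotypeInfo must have one row per phenotype column")
    if (!all(c("phenotype", "type") %in% names(pi)))
        msg <- c(msg, "phenotypeInfo needs columns 'phenotype' and 'type'")
    else if (!all(pi$type %in% .PHENOTYPE_TYPES))
        msg <- c(msg, sprintf("phenotype types must be one of: %s",
                              paste(.PHENOTYPE_TYPES, collapse = ", ")))
    if (!all(c("sample_id", "stratum") %in% names(object@samples)))
        msg <- c(msg, "samples needs columns 'sample_id' and 'stratum'")
    else if (anyDuplicated(object@samples$sample_id))
        msg <- c(msg, "sample_id values must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a PhewasStudy
#'
#' @param survey survey label.
#' @param genotypes samples x SNPs matrix of coded-allele counts (0/1/2/NA).
#' @param snpInfo data.frame (`snp`, `chrom`, `pos`, `coded_allele`).
#' @param phenotypes data.frame of raw phenotype values.
#' @param phenotypeInfo data.frame (`phenotype`, `type`, optional `class`).
#' @param samples data.frame (`sample_id`, `stratum`, optional `sex`).
#' @return A [PhewasStudy-class] object.
#' @examples
#' g <- matrix(rbinom(20, 2, 0.3), 10, 2,
#'             dimnames = list(NULL, c("rs1", "rs2")))
#' st <- PhewasStudy("survey1", g,
#'     snpInfo = data.frame(snp = c("rs1", "rs2"), chrom = "1",
#'                          pos = c(100L, 200L), coded_allele = "A"),
#'     phenotypes = data.frame(chol = rnorm(10, 200, 40)),
#'     phenotypeInfo = data.frame(phenotype = "chol", type = "continuous"),
#'     samples = data.frame(sample_id = sprintf("s%02d", 1:10),
#'                          stratum = "NHW"))
#' st
#' @export
PhewasStudy <- function(survey, genotypes, snpInfo, phenotypes,
                        phenotypeInfo, samples) {
    genotypes <- as.matrix(genotypes)
    storage.mode(genotypes) <- "double"
    if (is.null(colnames(genotypes)))
        colnames(genotypes) <- snpInfo$snp
    new("PhewasStudy", survey = survey, genotypes = genotypes,
        snpInfo = as.data.frame(snpInfo),
        phenotypes = as.data.frame(phenotypes, check.names = FALSE),
        phenotypeInfo = as.data.frame(phenotypeInfo),
        samples = as.data.frame(samples))
}

#' PhewasExperiment: a two-survey PheWAS input bundle
#'
#' Holds the two [PhewasStudy-class] surveys analyzed jointly, the
#' phenotype-to-class map used for harmonization, and (for simulated data)
#' the truth table of planted effects.
#'
#' @slot surveys list of two \code{PhewasStudy} objects.
#' @slot classMap data.frame with columns \code{survey}, \code{phenotype},
#'   \code{class}.
#' @slot truth data.frame of planted effects (\code{snp}, \code{class},
#'   \code{stratum}, \code{beta}, \code{sign}); zero rows for real data.
#' @slot metadata list of free-form provenance (e.g. the simulation config).
#' @export
setClass("PhewasExperiment", representation(
    surveys  = "list",
    classMap = "data.frame",
    truth    = "data.frame",
    metadata = "list"
))

setValidity("PhewasExperiment", function(object) {
    msg <- character()
    if (length(object@surveys) != 2L ||
        !all(vapply(object@surveys, is, TRUE, "PhewasStudy")))
        msg <- c(msg, "'surveys' must be a list of two PhewasStudy objects")
    else {
        labs <- vapply(object@surveys, function(s) s@survey, "")
        if (anyDuplicated(labs))
            msg <- c(msg, "survey labels must differ")
    }
    if (!all(c("survey", "phenotype", "class") %in% names(object@classMap)))
        msg <- c(msg, "classMap needs columns 'survey', 'phenotype', 'class'")
    if (length(msg)) msg else TRUE
})

#' Construct a PhewasExperiment
#'
#' @param survey1,survey2 [PhewasStudy-class] objects.
#' @param classMap data.frame (`survey`, `phenotype`, `class`).
#' @param truth optional truth table of planted effects.
#' @param metadata optional provenance list.
#' @return A [PhewasExperiment-class].
#' @export
PhewasExperiment <- function(survey1, survey2, classMap,
                             truth = NULL, metadata = list()) {
    if (is.null(truth))
        truth <- data.frame(snp = character(), class = character(),
                            stratum = character(), beta = numeric(),
                            sign = character())
    new("PhewasExperiment", surveys = list(survey1, survey2),
        classMap = as.data.frame(classMap), truth = as.data.frame(truth),
        metadata = metadata)
}

#' PhenotypeCorrelations: pairwise Pearson correlations of phenotypes
#'
#' @slot r symmetric matrix of Pearson correlations (unit diagonal where
#'   defined, \code{NA} where a cell's pairwise-complete n was insufficient
#'   or a phenotype had zero variance).
#' @slot n integer matrix of pairwise-complete sample sizes.
#' @slot survey,stratum labels identifying the analyzed subset.
#' @export
setClass("PhenotypeCorrelations", representation(
    r = "matrix", n = "matrix", survey = "character", stratum = "character"
))

setValidity("PhenotypeCorrelations", function(object) {
    msg <- character()
    if (!identical(dim(object@r), dim(object@n)))
        msg <- c(msg, "'r' and 'n' must have identical dimensions")
    if (nrow(object@r) != ncol(object@r))
        msg <- c(msg, "'r' must be square")
    r <- object@r[!is.na(object@r)]
    if (length(r) && any(abs(r) > 1 + 1e-8))
        msg <- c(msg, "correlations must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})
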