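# Accessor generics and show methods for the package's S4 classes.

#' @rdname PhewasStudy-class
#' @param object,x a \code{PhewasStudy} or \code{PhewasExperiment}.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname PhewasStudy-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))
#' @rdname PhewasStudy-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname PhewasStudy-class
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))
#' @rdname PhewasStudy-class
#' @export
setGeneric("phenotypeInfo", function(x) standardGeneric("phenotypeInfo"))
#' @rdname PhewasStudy-class
#' @export
setGeneric("surveyName", function(x) standardGeneric("surveyName"))
#' @rdname PhewasExperiment-class
#' @param x a \code{PhewasExperiment}.
#' @export
setGeneric("surveys", function(x) standardGeneric("surveys"))
#' @rdname PhewasExperiment-class
#' @export
setGeneric("classMap", function(x) standardGeneric("classMap"))
#' @rdname PhewasExperiment-class
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname PhenotypeCorrelations-class
#' @param x a \code{PhenotypeCorrelations}.
#' @export
setGeneric("correlations", function(x) standardGeneric("correlations"))
#' @rdname PhenotypeCorrelations-class
#' @export
setGeneric("pairCounts", function(x) standardGeneric("pairCounts"))

#' @rdname PhewasStudy-class
#' @export
setMethod("genotypes", "PhewasStudy", function(x) x@genotypes)
#' @rdname PhewasStudy-class
#' @export
setMethod("phenotypes", "PhewasStudy", function(x) x@phenotypes)
#' @rdname PhewasStudy-class
#' @export
setMethod("sampleInfo", "PhewasStudy", function(x) x@samples)
#' @rdname PhewasStudy-class
#' @export
setMethod("snpInfo", "PhewasStudy", function(x) x@snpInfo)
#' @rdname PhewasStudy-class
#' @export
setMethod("phenotypeInfo", "PhewasStudy", function(x) x@phenotypeInfo)
#' @rdname PhewasStudy-class
#' @export
setMethod("surveyName", "PhewasStudy", function(x) x@survey)

#' @rdname PhewasExperiment-class
#' @export
setMethod("surveys", "PhewasExperiment", function(x) x@surveys)
#' @rdname PhewasExperiment-class
#' @export
setMethod("classMap", "PhewasExperiment", function(x) x@classMap)
#' @rdname PhewasExperiment-class
#' @export
setMethod("truthTable", "PhewasExperiment", function(x) x@truth)

#' @rdname PhenotypeCorrelations-class
#' @export
setMethod("correlations", "PhenotypeCorrelations", function(x) x@r)
#' @rdname PhenotypeCorrelations-class
#' @export
setMethod("pairCounts", "PhenotypeCorrelations", function(x) x@n)

setMethod("show", "PhewasStudy", function(object) {
    cat("PhewasStudy '", object@survey, "'\n", sep = "")
    cat("  samples:   ", nrow(object@samples), " (",
        length(unique(object@samples$stratum)), " strata)\n", sep = "")
    cat("  SNPs:      ", ncol(object@genotypes), "\n", sep = "")
    tt <- table(factor(object@phenotypeInfo$type, levels = .PHENOTYPE_TYPES))
    cat("  phenotypes:", ncol(object@phenotypes),
        sprintf("(%d continuous, %d binary, %d categorical)\n",
                tt[["continuous"]], tt[["binary"]], tt[["categorical"]]))
})

setMethod("show", "PhewasExperiment", function(object) {
    labs <- vapply(object@surveys, surveyName, "")
    cat("PhewasExperiment with surveys:",
        paste(sQuote(labs), collapse = ", "), "\n")
    cat("  class map rows:", nrow(object@classMap),
        "(", length(unique(object@classMap$class)), "classes )\n")
    cat("  planted effects:", nrow(object@truth), "\n")
})

setMethod("show", "PhenotypeCorrelations", function(object) {
    cat("PhenotypeCorrelations:", nrow(object@r), "phenotypes,",
        "survey", sQuote(object@survey), "stratum",
        sQuote(object@stratum), "\n")
})
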