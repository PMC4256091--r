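# Plain-text readers and writers for the pipeline's interchange formats.

.writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}

.readTsv <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a genotype table
#'
#' Tab-separated: \code{sample_id}, \code{stratum}, optionally \code{sex},
#' then one 0/1/2 column per SNP.
#'
#' @param path TSV path.
#' @param snpInfo data.frame (\code{snp}, \code{chrom}, \code{pos},
#'   \code{coded_allele}); when NULL, minimal annotation is fabricated
#'   from the column names.
#' @return list(\code{genotypes}, \code{samples}, \code{snpInfo}).
#' @export
readGenotypeTable <- function(path, snpInfo = NULL) {
    d <- .readTsv(path)
    metaCols <- intersect(c("sample_id", "stratum", "sex"), names(d))
    snpCols <- setdiff(names(d), metaCols)
    G <- as.matrix(d[, snpCols, drop = FALSE])
    storage.mode(G) <- "double"
    if (is.null(snpInfo))
        snpInfo <- data.frame(snp = snpCols, chrom = NA_character_,
                              pos = NA_integer_, coded_allele = NA_character_,
                              stringsAsFactors = FALSE)
    list(genotypes = G, samples = d[, metaCols, drop = FALSE],
         snpInfo = snpInfo[match(snpCols, snpInfo$snp), , drop = FALSE])
}

#' Read additive-coded genotypes from a VCF
#'
#' Counts copies of the declared coded allele per sample from the GT
#' field. The coded allele defaults to the ALT allele of each record.
#' Requires the \pkg{vcfR} package.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @return list(\code{genotypes}, \code{snpInfo}) with genotypes samples x
#'   SNPs.
#' @export
readGenotypesVcf <- function(path) {
    if (!requireNamespace("vcfR", quietly = TRUE))
        stop("reading VCF requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    count <- function(x) {
        out <- rep(NA_real_, length(x))
        ok <- !is.na(x) & !grepl(".", x, fixed = TRUE)
        out[ok] <- vapply(strsplit(x[ok], "[/|]"),
                          function(a) sum(a == "1"), numeric(1))
        out
    }
    G <- matrix(count(as.vector(gt)), nrow = nrow(gt))
    G <- t(G)
    dimnames(G) <- list(colnames(gt), fix$ID)
    list(genotypes = G,
         snpInfo = data.frame(snp = fix$ID, chrom = fix$CHROM,
                              pos = as.integer(fix$POS),
                              coded_allele = fix$ALT,
                              stringsAsFactors = FALSE))
}

#' Read a phenotype table
#'
#' Tab-separated, keyed by \code{sample_id}.
#'
#' @param path TSV path.
#' @param types optional data.frame (\code{phenotype}, \code{type}); when
#'   NULL, numeric 0/1 columns are typed binary, other numeric continuous,
#'   character categorical.
#' @return list(\code{phenotypes}, \code{phenotypeInfo},
#'   \code{sample_id}).
#' @export
readPhenotypeTable <- function(path, types = NULL) {
    d <- .readTsv(path)
    if (!"sample_id" %in% names(d))
        stop("phenotype table needs a 'sample_id' column")
    ids <- d$sample_id
    d$sample_id <- NULL
    if (is.null(types)) {
        ty <- vapply(d, function(v) {
            if (!is.numeric(v)) "categorical"
            else if (all(v %in% c(0, 1, NA))) "binary"
            else "continuous"
        }, "")
        types <- data.frame(phenotype = names(d), type = unname(ty),
                            stringsAsFactors = FALSE)
    }
    list(phenotypes = d, phenotypeInfo = types, sample_id = ids)
}

#' Read a phenotype-to-class map
#'
#' Tab-separated: \code{survey}, \code{phenotype}, \code{class}.
#' @param path TSV path.
#' @return data.frame.
#' @export
readClassMap <- function(path) {
    m <- .readTsv(path)
    need <- c("survey", "phenotype", "class")
    if (!all(need %in% names(m)))
        stop("class map must have columns: ", paste(need, collapse = ", "))
    m
}

#' Read a class-to-related-group map
#'
#' Tab-separated: \code{class}, \code{group}; a class may belong to
#' several groups.
#' @param path TSV path.
#' @return data.frame.
#' @export
readRelatedGroups <- function(path) {
    m <- .readTsv(path)
    if (!all(c("class", "group") %in% names(m)))
        stop("related-group map must have columns 'class' and 'group'")
    m
}

#' Write a simulated experiment to plain-text files
#'
#' Genotype and phenotype TSVs per survey, the class map, and the truth
#' table, all round-trippable with [readExperimentDir()].
#'
#' @param experiment a [PhewasExperiment-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeExperimentDir <- function(experiment, dir) {
    stopifnot(is(experiment, "PhewasExperiment"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in surveys(experiment)) {
        sv <- surveyName(s)
        .writeTsv(cbind(sampleInfo(s), as.data.frame(genotypes(s))),
                  file.path(dir, paste0("genotypes_", sv, ".tsv")))
        .writeTsv(cbind(sample_id = sampleInfo(s)$sample_id,
                        phenotypes(s)),
                  file.path(dir, paste0("phenotypes_", sv, ".tsv")))
        .writeTsv(phenotypeInfo(s),
                  file.path(dir, paste0("phenotype_info_", sv, ".tsv")))
        .writeTsv(snpInfo(s), file.path(dir, paste0("snp_info_", sv,
                                                    ".tsv")))
    }
    .writeTsv(classMap(experiment), file.path(dir, "class_map.tsv"))
    .writeTsv(truthTable(experiment), file.path(dir, "truth.tsv"))
    invisible(dir)
}

#' Read an experiment directory written by [writeExperimentDir()]
#'
#' @param dir directory path.
#' @param surveyNames the two survey labels.
#' @return A [PhewasExperiment-class].
#' @export
readExperimentDir <- function(dir, surveyNames = c("survey1", "survey2")) {
    studies <- lapply(surveyNames, function(sv) {
        gi <- .readTsv(file.path(dir, paste0("snp_info_", sv, ".tsv")))
        gi$chrom <- as.character(gi$chrom)
        g <- readGenotypeTable(file.path(dir, paste0("genotypes_", sv,
                                                     ".tsv")), gi)
        pinfo <- .readTsv(file.path(dir, paste0("phenotype_info_", sv,
                                                ".tsv")))
        p <- readPhenotypeTable(file.path(dir, paste0("phenotypes_", sv,
                                                      ".tsv")),
                                types = pinfo)
        stopifnot(identical(p$sample_id, g$samples$sample_id))
        PhewasStudy(sv, g$genotypes, g$snpInfo, p$phenotypes, pinfo,
                    g$samples)
    })
    truthPath <- file.path(dir, "truth.tsv")
    truth <- if (file.exists(truthPath)) .readTsv(truthPath) else NULL
    if (!is.null(truth) && nrow(truth))
        truth$sign <- as.character(truth$sign)
    PhewasExperiment(studies[[1]], studies[[2]],
                     classMap = readClassMap(file.path(dir,
                                                       "class_map.tsv")),
                     truth = truth)
}
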