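# Config-driven end-to-end runs: harmonize -> scan per survey -> replication
# filter -> combined re-test -> classify -> correlate -> network, with a
# stage-keyed log, fixed output schemas and plot-ready exports.

.logLine <- function(log, stage, msg) {
    line <- sprintf("%s\t%s\t%s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg)
    c(log, line)
}

#' Assemble a run configuration
#'
#' @param experiment a [PhewasExperiment-class]; alternatively give
#'   \code{inputDir} (a directory written by [writeExperimentDir()]).
#' @param inputDir experiment directory, used when \code{experiment} is
#'   NULL.
#' @param catalog prior-association catalog data.frame (or TSV path), or
#'   NULL to skip classification.
#' @param relatedGroups class-to-group map data.frame (or TSV path).
#' @param geneTable gene table data.frame (or TSV path) for network
#'   annotation; NULL skips the network stage.
#' @param groupings named list from [readGmt()] (or a GMT path).
#' @param pThreshold,cafThreshold,minN replication thresholds, defaulting
#'   to 0.01 / 0.01 / 200.
#' @param outdir output directory for TSVs and the run log; NULL keeps
#'   results in memory only.
#' @param seed integer seed recorded with the run.
#' @return list of class \code{"phewasRunConfig"}.
#' @export
runConfig <- function(experiment = NULL, inputDir = NULL, catalog = NULL,
                      relatedGroups = NULL, geneTable = NULL,
                      groupings = NULL, pThreshold = 0.01,
                      cafThreshold = 0.01, minN = 200, outdir = NULL,
                      seed = 1L) {
    if (is.null(experiment) && is.null(inputDir))
        stop("either 'experiment' or 'inputDir' is required")
    if (any(c(pThreshold, cafThreshold, minN) <= 0))
        stop("thresholds must be positive")
    if (is.character(catalog)) catalog <- readCatalog(catalog)
    if (is.character(relatedGroups))
        relatedGroups <- readRelatedGroups(relatedGroups)
    if (is.character(geneTable)) geneTable <- readGeneTable(geneTable)
    if (is.character(groupings)) groupings <- readGmt(groupings)
    structure(list(experiment = experiment, inputDir = inputDir,
                   catalog = catalog, relatedGroups = relatedGroups,
                   geneTable = geneTable, groupings = groupings,
                   pThreshold = pThreshold, cafThreshold = cafThreshold,
                   minN = minN, outdir = outdir, seed = as.integer(seed)),
              class = "phewasRunConfig")
}

#' Run the full PheWAS pipeline
#'
#' Stages in order: cohort summary, harmonization + per-survey scan +
#' combined-survey scan, seven-criterion replication filter, combined
#' re-test, catalog classification, pleiotropy and generalization,
#' phenotype correlations (per survey and stratum, among phenotypes with a
#' retained result), and the SNP-gene-grouping network per stratum. The
#' same configuration and seed reproduce identical outputs.
#'
#' @param config a [runConfig()].
#' @return list: \code{cohort}, \code{scan}, \code{retained},
#'   \code{pairs}, \code{classified}, \code{pleiotropy},
#'   \code{generalization}, \code{summary}, \code{correlations} (list per
#'   survey/stratum), \code{networks} (igraph per stratum, pruned),
#'   \code{annotations}, \code{log}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "phewasRunConfig"))
    log <- character()
    expt <- config$experiment
    if (is.null(expt)) expt <- readExperimentDir(config$inputDir)
    s1 <- surveys(expt)[[1]]; s2 <- surveys(expt)[[2]]
    log <- .logLine(log, "input", sprintf(
        "surveys %s (n=%d) and %s (n=%d)", surveyName(s1),
        nrow(sampleInfo(s1)), surveyName(s2), nrow(sampleInfo(s2))))
    cohort <- summarizeCohort(sampleInfo(s1), sampleInfo(s2),
                              c(surveyName(s1), surveyName(s2)))
    scan <- runScan(expt)
    log <- .logLine(log, "scan", sprintf(
        "%d association results (%d flagged)", nrow(scan),
        sum(scan$flag != "ok")))
    rep <- applyReplicationCriteria(
        scan, surveyLabels = c(surveyName(s1), surveyName(s2)),
        pThreshold = config$pThreshold,
        cafThreshold = config$cafThreshold, minN = config$minN,
        pairs = TRUE)
    retained <- combinedRetest(rep$groups, scan)
    log <- .logLine(log, "replication", sprintf(
        "%d retained (snp, class, stratum) groups", nrow(retained)))
    classified <- pleio <- gener <- summaryCounts <- NULL
    if (!is.null(config$catalog)) {
        classified <- classifyAssociations(retained, config$catalog,
                                           config$relatedGroups)
        pleio <- detectPleiotropy(classified)
        gener <- assessGeneralization(classified)
        summaryCounts <- summarizeCategories(classified, pleio, gener)
        log <- .logLine(log, "classify", sprintf(
            "replicated=%d related=%d novel=%d pleiotropic=%d generalized=%d",
            summaryCounts$replicated, summaryCounts$related,
            summaryCounts$novel, summaryCounts$pleiotropicSnps,
            summaryCounts$generalized))
    }
    # correlations among significant phenotypes, per survey and stratum
    correlationsOut <- list()
    if (nrow(retained)) {
        sigClasses <- unique(retained$class)
        for (st in list(s1, s2)) {
            cmap <- classMap(expt)
            cmap <- cmap[cmap$survey == surveyName(st) &
                         cmap$class %in% sigClasses, , drop = FALSE]
            phen <- intersect(cmap$phenotype, names(phenotypes(st)))
            numeric_ok <- vapply(phenotypes(st)[phen], is.numeric, TRUE)
            phen <- phen[numeric_ok]
            if (length(phen) < 2L) next
            for (str in unique(retained$stratum)) {
                cm <- phenotypeCorrelations(st, phen, stratum = str)
                correlationsOut[[paste(surveyName(st), str, sep = ".")]] <-
                    cm
            }
        }
        log <- .logLine(log, "correlation", sprintf(
            "%d survey x stratum correlation matrices",
            length(correlationsOut)))
    }
    annotations <- networks <- NULL
    if (!is.null(config$geneTable) && nrow(retained)) {
        si <- snpInfo(s1)
        annotations <- annotateNearestGene(
            si[si$snp %in% retained$snp, c("snp", "chrom", "pos")],
            config$geneTable)
        networks <- list()
        for (str in unique(retained$stratum)) {
            g <- buildAssociationGraph(
                retained[retained$stratum == str, , drop = FALSE],
                annotations,
                if (is.null(config$groupings)) list() else config$groupings,
                stratum = str)
            networks[[str]] <- pruneComponents(g)
        }
        log <- .logLine(log, "network", sprintf(
            "%d strata; retained components: %s", length(networks),
            paste(vapply(networks, function(g)
                as.integer(igraph::components(g)$no), 1L),
                collapse = ",")))
    }
    bundle <- list(cohort = cohort, scan = scan, retained = retained,
                   pairs = rep$pairs, classified = classified,
                   pleiotropy = pleio, generalization = gener,
                   summary = summaryCounts,
                   correlations = correlationsOut, networks = networks,
                   annotations = annotations, log = log)
    if (!is.null(config$outdir)) .writeBundle(bundle, config)
    bundle
}

.writeBundle <- function(bundle, config) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outdir, f)
    .writeTsv(bundle$scan, out("scan_results.tsv"))
    .writeTsv(bundle$retained, out("retained_results.tsv"))
    if (!is.null(bundle$classified))
        .writeTsv(bundle$classified, out("classified_results.tsv"))
    if (!is.null(bundle$pleiotropy))
        .writeTsv(bundle$pleiotropy, out("pleiotropy.tsv"))
    if (!is.null(bundle$generalization))
        .writeTsv(bundle$generalization, out("generalization.tsv"))
    for (nm in names(bundle$correlations)) {
        cm <- bundle$correlations[[nm]]
        heatmapExport(cm, out(sprintf("correlation_%s.tsv", nm)))
        .writeTsv(correlationPartners(cm),
                  out(sprintf("correlation_partners_%s.tsv", nm)))
    }
    if (!is.null(bundle$networks))
        for (nm in names(bundle$networks)) {
            writeNetworkSif(bundle$networks[[nm]],
                            out(sprintf("network_%s.sif", nm)))
            writeNetworkGraphml(bundle$networks[[nm]],
                                out(sprintf("network_%s.graphml", nm)))
        }
    if (!is.null(bundle$summary))
        jsonlite::write_json(bundle$summary, out("run_summary.json"),
                             auto_unbox = TRUE, pretty = TRUE)
    writeLines(bundle$log, out("run_log.txt"))
    invisible(config$outdir)
}

#' Per-SNP sun-plot table
#'
#' Rows for one SNP's qualifying measurements within its retained groups,
#' sorted by ascending p-value so that -log10(p) descends clockwise when
#' plotted radially from the top.
#'
#' @param scan scan results from [runScan()].
#' @param retained retained groups from [applyReplicationCriteria()].
#' @param snp SNP id.
#' @param pThreshold,cafThreshold,minN the qualifying thresholds.
#' @return data.frame: survey, transform, phenotype, measurement, stratum,
#'   class, direction, p, neg_log10_p, beta, n.
#' @export
sunPlotTable <- function(scan, retained, snp, pThreshold = 0.01,
                         cafThreshold = 0.01, minN = 200) {
    keep <- retained[retained$snp == snp, , drop = FALSE]
    qual <- .qualifyingRows(scan[scan$snp == snp, , drop = FALSE],
                            setdiff(unique(scan$survey), "combined"),
                            pThreshold, cafThreshold, minN)
    key <- paste(qual$class, qual$stratum)
    qual <- qual[key %in% paste(keep$class, keep$stratum), , drop = FALSE]
    qual <- qual[order(qual$p, qual$measurement), , drop = FALSE]
    data.frame(survey = qual$survey, transform = qual$transform,
               phenotype = qual$phenotype, measurement = qual$measurement,
               stratum = qual$stratum, class = qual$class,
               direction = ifelse(qual$beta > 0, "+", "-"),
               p = qual$p, neg_log10_p = -log10(qual$p),
               beta = qual$beta, n = qual$n, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Replication-matrix export table
#'
#' One row per retained group mirroring the matrix-figure layout:
#' per-survey availability flags for transformed/untransformed qualifying
#' measurements, best p, direction, beta, CAF and n per survey, plus the
#' combined re-test columns when present.
#'
#' @param retained retained groups (after [combinedRetest()] if combined
#'   columns are wanted).
#' @param pairs qualifying-pair table from
#'   \code{applyReplicationCriteria(..., pairs = TRUE)}.
#' @return data.frame.
#' @export
replicationMatrixTable <- function(retained, pairs = NULL) {
    out <- retained
    out$s1_untransformed <- out$transform_s1 == "none"
    out$s1_ln1p <- out$transform_s1 == "ln1p"
    out$s2_untransformed <- out$transform_s2 == "none"
    out$s2_ln1p <- out$transform_s2 == "ln1p"
    if (!is.null(pairs) && nrow(pairs)) {
        key <- paste(pairs$snp, pairs$class, pairs$stratum, sep = "\r")
        okey <- paste(out$snp, out$class, out$stratum, sep = "\r")
        out$s1_untransformed <- okey %in%
            key[pairs$transform == "none"]
        out$s1_ln1p <- okey %in% key[pairs$transform == "ln1p"]
        out$s2_untransformed <- out$s1_untransformed
        out$s2_ln1p <- out$s1_ln1p
    }
    front <- c("snp", "coded_allele", "class", "stratum", "direction",
               "s1_untransformed", "s1_ln1p", "s2_untransformed",
               "s2_ln1p")
    out[, c(front, setdiff(names(out), front)), drop = FALSE]
}
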