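# Pairwise Pearson correlations among PheWAS-significant phenotypes, the
# r > 0.6 partner report, and the clustered |r| heatmap export.

#' Pairwise phenotype correlations for one survey and stratum
#'
#' Pearson correlations on pairwise-complete observations among the named
#' phenotypes, restricted to one stratum. Cells with fewer than
#' \code{minPairs} complete pairs, and all cells of a zero-variance
#' phenotype, are marked unavailable (NA).
#'
#' @param study a [PhewasStudy-class].
#' @param phenotypes character vector of phenotype column names (at least
#'   two), typically those carrying a significant PheWAS result.
#' @param stratum stratum label to restrict to (NULL: all samples).
#' @param minPairs minimum pairwise-complete n per computed cell.
#' @return A [PhenotypeCorrelations-class].
#' @export
phenotypeCorrelations <- function(study, phenotypes, stratum = NULL,
                                  minPairs = 3L) {
    stopifnot(is(study, "PhewasStudy"), length(phenotypes) >= 2L)
    miss <- setdiff(phenotypes, names(study@phenotypes))
    if (length(miss))
        stop("unknown phenotypes: ", paste(miss, collapse = ", "))
    X <- study@phenotypes[, phenotypes, drop = FALSE]
    rows <- if (is.null(stratum)) rep(TRUE, nrow(X))
            else sampleInfo(study)$stratum == stratum
    X <- as.matrix(as.data.frame(lapply(X[rows, , drop = FALSE],
                                        as.numeric),
                                 check.names = FALSE, optional = TRUE))
    n <- crossprod(!is.na(X))
    storage.mode(n) <- "integer"
    r <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
    zeroVar <- vapply(seq_len(ncol(X)), function(j)
        stats::var(X[, j], na.rm = TRUE) %in% c(0, NA), TRUE)
    if (any(zeroVar)) {
        message("zero-variance phenotypes excluded from correlations: ",
                paste(colnames(X)[zeroVar], collapse = ", "))
        r[zeroVar, ] <- NA; r[, zeroVar] <- NA
    }
    r[n < minPairs] <- NA
    dimnames(r) <- list(phenotypes, phenotypes)
    dimnames(n) <- dimnames(r)
    new("PhenotypeCorrelations", r = r, n = n,
        survey = surveyName(study),
        stratum = if (is.null(stratum)) "all" else stratum)
}

#' Report correlation partners above a threshold
#'
#' For each phenotype, partners with signed Pearson r strictly greater
#' than the threshold. Each unordered pair appears in both orientations so
#' the per-phenotype listing is symmetric.
#'
#' @param cm a [PhenotypeCorrelations-class].
#' @param threshold strict lower bound on signed r (default 0.6).
#' @return data.frame: \code{phenotype}, \code{partner}, \code{r},
#'   \code{n}.
#' @export
correlationPartners <- function(cm, threshold = 0.6) {
    stopifnot(is(cm, "PhenotypeCorrelations"))
    r <- correlations(cm); n <- pairCounts(cm)
    out <- data.frame(phenotype = character(), partner = character(),
                      r = numeric(), n = integer(),
                      stringsAsFactors = FALSE)
    if (!nrow(r)) return(out)
    idx <- which(!is.na(r) & r > threshold &
                 row(r) != col(r), arr.ind = TRUE)
    if (!nrow(idx)) return(out)
    out <- data.frame(phenotype = rownames(r)[idx[, 1]],
                      partner = colnames(r)[idx[, 2]],
                      r = r[idx], n = n[idx], stringsAsFactors = FALSE)
    out[order(out$phenotype, out$partner), , drop = FALSE]
}

#' Clustered absolute-correlation matrix for heatmap export
#'
#' Takes absolute values of the correlations and orders rows/columns by
#' hierarchical clustering (complete linkage on the Euclidean distance
#' between |r| rows, with unavailable cells treated as 0 for ordering
#' only), the fixed scheme that makes orderings reproducible.
#'
#' @param cm a [PhenotypeCorrelations-class].
#' @param file optional path: writes the ordered matrix as TSV and the
#'   leaf order to \code{<file>.order.txt}.
#' @return list: \code{matrix} (ordered |r| matrix), \code{order} (leaf
#'   labels), \code{hclust}.
#' @export
heatmapExport <- function(cm, file = NULL) {
    stopifnot(is(cm, "PhenotypeCorrelations"))
    A <- abs(correlations(cm))
    A0 <- A; A0[is.na(A0)] <- 0
    hc <- stats::hclust(stats::dist(A0), method = "complete")
    ord <- rownames(A)[hc$order]
    M <- A[ord, ord, drop = FALSE]
    if (!is.null(file)) {
        utils::write.table(cbind(phenotype = rownames(M), as.data.frame(M)),
                           file, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        writeLines(ord, paste0(file, ".order.txt"))
    }
    list(matrix = M, order = ord, hclust = hc)
}
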