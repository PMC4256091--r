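# The seven-criterion significance filter: an association must be observed
# in both surveys, with p < 0.01, coded-allele frequency > 0.01, sample
# size > 200, for the same stratum, the same phenotype class, and the same
# direction of effect. Thresholds are strict inequalities as stated.

.qualifyingRows <- function(results, surveyLabels, pThreshold, cafThreshold,
                            minN) {
    keep <- results$survey %in% surveyLabels &
        results$flag == "ok" &
        is.finite(results$p) & results$p < pThreshold &
        is.finite(results$caf) & results$caf > cafThreshold &
        results$n > minN &
        is.finite(results$beta) & results$beta != 0
    results[keep, , drop = FALSE]
}

# all cross-survey qualifying pairs within one (snp, class, stratum) group:
# pairs must match on transform status (betas on different scales are not
# comparable) and agree in beta sign
.groupPairs <- function(g1, g2) {
    pairs <- merge(g1, g2, by = "transform", suffixes = c("_s1", "_s2"))
    if (!nrow(pairs)) return(pairs)
    pairs <- pairs[sign(pairs$beta_s1) == sign(pairs$beta_s2), ,
                   drop = FALSE]
    pairs
}

#' Apply the seven-criterion cross-survey replication filter
#'
#' A (snp, class, stratum) group is retained iff at least one measurement
#' in each survey satisfies p < \code{pThreshold}, caf >
#' \code{cafThreshold} and n > \code{minN}, where the two surveys'
#' qualifying measurements match on transform status and agree in beta
#' sign. Within each survey the best qualifying measurement is the one
#' with minimum p (ties: larger n, then lexicographic measurement name).
#' An exactly zero beta has no direction and cannot qualify.
#'
#' @param results scan output from [runScan()].
#' @param surveyLabels the two per-survey labels (default: the two
#'   non-combined surveys present).
#' @param pThreshold,cafThreshold,minN the replication thresholds
#'   (defaults 0.01, 0.01, 200; strict).
#' @param pairs also return the full table of qualifying measurement
#'   pairs.
#' @return data.frame of retained groups: snp, coded_allele, class,
#'   stratum, direction (+/-), n_pairs, mixed_direction, and the
#'   best-per-survey measurement fields (\code{*_s1}, \code{*_s2}). With
#'   \code{pairs = TRUE}, a list \code{(groups, pairs)}.
#' @export
applyReplicationCriteria <- function(results,
                                     surveyLabels = NULL,
                                     pThreshold = 0.01,
                                     cafThreshold = 0.01,
                                     minN = 200,
                                     pairs = FALSE) {
    if (is.null(surveyLabels))
        surveyLabels <- setdiff(unique(results$survey), "combined")
    stopifnot(length(surveyLabels) == 2L)
    qual <- .qualifyingRows(results, surveyLabels, pThreshold, cafThreshold,
                            minN)
    qual <- qual[order(qual$snp, qual$class, qual$stratum,
                       qual$measurement), , drop = FALSE]
    groupsOut <- list(); pairsOut <- list()
    if (nrow(qual)) {
        key <- paste(qual$snp, qual$class, qual$stratum, sep = "\r")
        for (k in unique(key)) {
            rows <- qual[key == k, , drop = FALSE]
            g1 <- rows[rows$survey == surveyLabels[1], , drop = FALSE]
            g2 <- rows[rows$survey == surveyLabels[2], , drop = FALSE]
            if (!nrow(g1) || !nrow(g2)) next
            pp <- .groupPairs(
                g1[, c("measurement", "transform", "beta", "se", "p", "n",
                       "caf")],
                g2[, c("measurement", "transform", "beta", "se", "p", "n",
                       "caf")])
            if (!nrow(pp)) next
            # best pair: smallest min p, then smallest max p, then names
            ord <- order(pmin(pp$p_s1, pp$p_s2), pmax(pp$p_s1, pp$p_s2),
                         pp$measurement_s1, pp$measurement_s2)
            pp <- pp[ord, , drop = FALSE]
            dir <- ifelse(pp$beta_s1[1] > 0, "+", "-")
            sameDir <- sign(pp$beta_s1) == sign(pp$beta_s1[1])
            ppDir <- pp[sameDir, , drop = FALSE]
            best <- function(side) {
                cols <- paste0(c("measurement", "beta", "se", "p", "n",
                                 "caf"), "_", side)
                d <- unique(ppDir[, c("transform", cols), drop = FALSE])
                d <- d[order(d[[paste0("p_", side)]],
                             -d[[paste0("n_", side)]],
                             d[[paste0("measurement_", side)]]), ,
                       drop = FALSE]
                d <- d[1, , drop = FALSE]
                names(d)[1] <- paste0("transform_", side)
                d[, c(cols[1], paste0("transform_", side), cols[-1]),
                  drop = FALSE]
            }
            parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
            grp <- data.frame(snp = parts[1],
                              coded_allele = rows$coded_allele[1],
                              class = parts[2], stratum = parts[3],
                              direction = dir,
                              n_pairs = nrow(pp),
                              mixed_direction = !all(sameDir),
                              stringsAsFactors = FALSE)
            grp <- cbind(grp, best("s1"), best("s2"))
            groupsOut[[k]] <- grp
            if (pairs) {
                pp$snp <- parts[1]; pp$class <- parts[2]
                pp$stratum <- parts[3]
                pairsOut[[k]] <- pp
            }
        }
    }
    groups <- if (length(groupsOut))
        do.call(rbind, c(groupsOut, make.row.names = FALSE))
    else .emptyRetained()
    groups <- groups[order(groups$snp, groups$class, groups$stratum), ,
                     drop = FALSE]
    rownames(groups) <- NULL
    if (!pairs) return(groups)
    list(groups = groups,
         pairs = if (length(pairsOut))
             do.call(rbind, c(pairsOut, make.row.names = FALSE))
         else NULL)
}

.emptyRetained <- function() {
    cols <- c("snp", "coded_allele", "class", "stratum", "direction")
    base <- as.data.frame(setNames(rep(list(character()), length(cols)),
                                   cols), stringsAsFactors = FALSE)
    base$n_pairs <- integer(); base$mixed_direction <- logical()
    for (side in c("s1", "s2")) {
        base[[paste0("measurement_", side)]] <- character()
        base[[paste0("transform_", side)]] <- character()
        base[[paste0("beta_", side)]] <- numeric()
        base[[paste0("se_", side)]] <- numeric()
        base[[paste0("p_", side)]] <- numeric()
        base[[paste0("n_", side)]] <- integer()
        base[[paste0("caf_", side)]] <- numeric()
    }
    base
}

#' Attach combined-survey re-tests to retained groups
#'
#' Where a pooled combined-survey variable exists for a retained group's
#' class, the minimum-p valid combined result for that (snp, class,
#' stratum) is attached; absence is recorded as NA, not an error.
#'
#' @param groups retained groups from [applyReplicationCriteria()].
#' @param results scan output containing \code{survey == "combined"} rows.
#' @return \code{groups} with columns \code{combined_measurement},
#'   \code{combined_transform}, \code{combined_beta}, \code{combined_se},
#'   \code{combined_p}, \code{combined_n}, \code{combined_caf}.
#' @export
combinedRetest <- function(groups, results) {
    comb <- results[results$survey == "combined" & results$flag == "ok" &
                    is.finite(results$p), , drop = FALSE]
    out <- groups
    nr <- nrow(out)
    out$combined_measurement <- rep(NA_character_, nr)
    out$combined_transform <- rep(NA_character_, nr)
    out$combined_beta <- rep(NA_real_, nr)
    out$combined_se <- rep(NA_real_, nr)
    out$combined_p <- rep(NA_real_, nr)
    out$combined_n <- rep(NA_integer_, nr)
    out$combined_caf <- rep(NA_real_, nr)
    if (!nrow(comb) || !nrow(out)) return(out)
    ckey <- paste(comb$snp, comb$class, comb$stratum, sep = "\r")
    gkey <- paste(out$snp, out$class, out$stratum, sep = "\r")
    for (i in seq_len(nrow(out))) {
        cand <- comb[ckey == gkey[i], , drop = FALSE]
        if (!nrow(cand)) next
        cand <- cand[order(cand$p, -cand$n, cand$measurement), ,
                     drop = FALSE]
        out$combined_measurement[i] <- cand$measurement[1]
        out$combined_transform[i] <- cand$transform[1]
        out$combined_beta[i] <- cand$beta[1]
        out$combined_se[i] <- cand$se[1]
        out$combined_p[i] <- cand$p[1]
        out$combined_n[i] <- cand$n[1]
        out$combined_caf[i] <- cand$caf[1]
    }
    out
}
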