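# Classify retained results against a catalog of previously reported
# SNP-phenotype associations (replicated / related / novel), detect
# pleiotropy (one SNP, two or more distinct phenotype classes) and
# cross-stratum generalization.

#' Read a prior-association catalog
#'
#' Tab-separated with columns \code{snp}, \code{prior_class},
#' \code{related_group} (optional, may be empty), \code{direction}
#' (\code{+}/\code{-}, optional) and \code{source}.
#'
#' @param path catalog TSV path.
#' @return data.frame.
#' @export
readCatalog <- function(path) {
    cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE, na.strings = c("NA", ""))
    need <- c("snp", "prior_class")
    if (!all(need %in% names(cat)))
        stop("catalog must have columns: ", paste(need, collapse = ", "))
    for (opt in c("related_group", "direction", "source"))
        if (is.null(cat[[opt]])) cat[[opt]] <- NA_character_
    if (any(!nzchar(cat$snp) | is.na(cat$snp)))
        stop("catalog rows must name a SNP")
    cat
}

# related-group tags for a class: rows of the class-group map plus
# related_group tags of catalog entries whose prior class is this class
.classGroups <- function(class, catalog, relatedGroups) {
    g <- character()
    if (!is.null(relatedGroups))
        g <- c(g, relatedGroups$group[relatedGroups$class == class])
    g <- c(g, catalog$related_group[!is.na(catalog$related_group) &
                                    catalog$prior_class == class])
    unique(g[!is.na(g)])
}

#' Classify retained results against the catalog
#'
#' Category is a function of (snp, class, catalog) only: an exact class
#' match with a catalog entry for the SNP is \code{replicated}; otherwise a
#' shared related-group tag between the result class and any of the SNP's
#' catalog entries is \code{related}; otherwise \code{novel} (including
#' SNPs absent from the catalog entirely). Direction agreement with the
#' catalog is reported but never changes the category.
#'
#' @param groups retained groups from [applyReplicationCriteria()] (or any
#'   data.frame with \code{snp}, \code{class} and optionally
#'   \code{direction}).
#' @param catalog data.frame from [readCatalog()].
#' @param relatedGroups optional class-to-group map (columns \code{class},
#'   \code{group}), e.g. one lipid group covering HDL-C, LDL-C, total
#'   cholesterol and triglycerides.
#' @return \code{groups} plus \code{category} (replicated/related/novel),
#'   \code{matched_prior} (semicolon-joined matching catalog classes or
#'   groups) and \code{direction_agreement} (same/opposite/unknown).
#' @export
classifyAssociations <- function(groups, catalog, relatedGroups = NULL) {
    out <- groups
    nr <- nrow(out)
    out$category <- rep(NA_character_, nr)
    out$matched_prior <- rep(NA_character_, nr)
    out$direction_agreement <- rep("unknown", nr)
    for (i in seq_len(nrow(out))) {
        ent <- catalog[catalog$snp == out$snp[i], , drop = FALSE]
        exact <- ent[!is.na(ent$prior_class) &
                     ent$prior_class == out$class[i], , drop = FALSE]
        if (nrow(exact)) {
            out$category[i] <- "replicated"
            out$matched_prior[i] <- paste(unique(exact$prior_class),
                                          collapse = ";")
            dirs <- unique(exact$direction[!is.na(exact$direction)])
            if (length(dirs) == 1L && "direction" %in% names(out))
                out$direction_agreement[i] <-
                    if (dirs == out$direction[i]) "same" else "opposite"
            next
        }
        myGroups <- .classGroups(out$class[i], catalog, relatedGroups)
        entGroups <- unique(ent$related_group[!is.na(ent$related_group)])
        shared <- intersect(myGroups, entGroups)
        if (length(shared)) {
            out$category[i] <- "related"
            out$matched_prior[i] <- paste(shared, collapse = ";")
        } else {
            out$category[i] <- "novel"
        }
    }
    out
}

#' Detect pleiotropic SNPs among retained results
#'
#' One record per SNP whose retained results span two or more distinct
#' phenotype classes, across any strata; per-class strata and directions
#' are carried along.
#'
#' @param groups retained (optionally classified) groups with columns
#'   \code{snp}, \code{class}, \code{stratum}, \code{direction}.
#' @return data.frame: \code{snp}, \code{n_classes}, \code{classes}
#'   (semicolon-joined \code{"class (stratum dir, ...)"} descriptors).
#' @export
detectPleiotropy <- function(groups) {
    if (!nrow(groups))
        return(data.frame(snp = character(), n_classes = integer(),
                          classes = character(), stringsAsFactors = FALSE))
    sp <- split(groups, groups$snp)
    recs <- lapply(sp, function(g) {
        cls <- sort(unique(g$class))
        if (length(cls) < 2L) return(NULL)
        desc <- vapply(cls, function(cc) {
            rows <- g[g$class == cc, , drop = FALSE]
            rows <- rows[order(rows$stratum), , drop = FALSE]
            paste0(cc, " (", paste(paste(rows$stratum, rows$direction),
                                   collapse = ", "), ")")
        }, "")
        data.frame(snp = g$snp[1], n_classes = length(cls),
                   classes = paste(desc, collapse = "; "),
                   stringsAsFactors = FALSE)
    })
    recs <- recs[!vapply(recs, is.null, TRUE)]
    if (!length(recs))
        return(data.frame(snp = character(), n_classes = integer(),
                          classes = character(), stringsAsFactors = FALSE))
    out <- do.call(rbind, c(recs, make.row.names = FALSE))
    out[order(out$snp), , drop = FALSE]
}

#' Assess cross-stratum generalization of retained results
#'
#' A (snp, class) group retained in two or more strata with identical
#' direction of effect is flagged \code{generalized}; multi-stratum groups
#' with mixed directions are \code{discordant}; everything else is
#' \code{single}.
#'
#' @inheritParams detectPleiotropy
#' @return data.frame: \code{snp}, \code{class}, \code{n_strata},
#'   \code{strata}, \code{directions}, \code{status}.
#' @export
assessGeneralization <- function(groups) {
    if (!nrow(groups))
        return(data.frame(snp = character(), class = character(),
                          n_strata = integer(), strata = character(),
                          directions = character(), status = character(),
                          stringsAsFactors = FALSE))
    key <- paste(groups$snp, groups$class, sep = "\r")
    recs <- lapply(unique(key), function(k) {
        g <- groups[key == k, , drop = FALSE]
        strata <- sort(unique(g$stratum))
        dirs <- unique(g$direction)
        status <- if (length(strata) < 2L) "single"
                  else if (length(dirs) == 1L) "generalized"
                  else "discordant"
        data.frame(snp = g$snp[1], class = g$class[1],
                   n_strata = length(strata),
                   strata = paste(strata, collapse = ";"),
                   directions = paste(sort(dirs), collapse = ";"),
                   status = status, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(recs, make.row.names = FALSE))
    out[order(out$snp, out$class), , drop = FALSE]
}

#' Summarize classification, pleiotropy and generalization counts
#'
#' @param classified output of [classifyAssociations()].
#' @param pleiotropy optional output of [detectPleiotropy()]; computed from
#'   \code{classified} when NULL.
#' @param generalization optional output of [assessGeneralization()];
#'   computed when NULL.
#' @return list of counts: \code{total}, \code{replicated},
#'   \code{related}, \code{novel}, \code{pleiotropicSnps},
#'   \code{generalized}.
#' @export
summarizeCategories <- function(classified, pleiotropy = NULL,
                                generalization = NULL) {
    if (is.null(pleiotropy)) pleiotropy <- detectPleiotropy(classified)
    if (is.null(generalization))
        generalization <- assessGeneralization(classified)
    tab <- table(factor(classified$category,
                        levels = c("replicated", "related", "novel")))
    list(total = nrow(classified),
         replicated = unname(tab[["replicated"]]),
         related = unname(tab[["related"]]),
         novel = unname(tab[["novel"]]),
         pleiotropicSnps = nrow(pleiotropy),
         generalized = sum(generalization$status == "generalized"))
}
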