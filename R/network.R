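# SNP -> nearest gene -> pathway/grouping association networks. Nearest
# genes are assigned by minimal absolute distance on the same chromosome
# (1-based coordinates, closed gene spans, strand ignored); groupings are
# consumed from GMT files; the pruning rule keeps only connected
# components with two or more PheWAS SNPs whose genes are linked through a
# shared grouping.

#' Read a BED-like gene table
#'
#' Tab-separated with columns \code{chrom}, \code{start}, \code{end},
#' \code{symbol}; 1-based closed spans.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readGeneTable <- function(path) {
    g <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "symbol")
    if (!all(need %in% names(g)))
        stop("gene table must have columns: ", paste(need, collapse = ", "))
    g$chrom <- as.character(g$chrom)
    g
}

#' Read gene groupings from a GMT file
#'
#' Standard GMT: one grouping per line, tab-separated
#' \code{name<TAB>source/description<TAB>gene1<TAB>gene2...}.
#'
#' @param path GMT path.
#' @return named list of character vectors of gene symbols; the
#'   \code{"source"} attribute on each element carries the description
#'   field.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    out <- list()
    for (ln in lines) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop("malformed GMT line (need name, description, >=1 gene): ",
                 substr(ln, 1, 60))
        genes <- unique(f[-(1:2)])
        attr(genes, "source") <- f[2]
        out[[f[1]]] <- genes
    }
    out
}

#' Annotate SNPs with their nearest gene
#'
#' For each SNP, the gene on the same chromosome with minimal absolute
#' distance; distance is 0 iff the position lies within the closed gene
#' span, negative upstream of the span start, positive downstream of the
#' span end. Ties are broken lexicographically by gene symbol. SNPs on a
#' chromosome with no genes are returned unannotated (NA) with a message.
#'
#' @param snps data.frame with columns \code{snp}, \code{chrom},
#'   \code{pos} (1-based); an optional \code{context} column is carried
#'   through (context strings are consumed from annotation, not
#'   recomputed).
#' @param genes gene table from [readGeneTable()].
#' @return data.frame: \code{snp}, \code{chrom}, \code{pos}, \code{gene},
#'   \code{distance} (and \code{context} when supplied).
#' @export
annotateNearestGene <- function(snps, genes) {
    snps <- as.data.frame(snps)
    out <- data.frame(snp = snps$snp, chrom = as.character(snps$chrom),
                      pos = snps$pos, gene = NA_character_,
                      distance = NA_real_, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(out))) {
        g <- genes[genes$chrom == out$chrom[i], , drop = FALSE]
        if (!nrow(g)) next
        pos <- out$pos[i]
        d <- ifelse(pos < g$start, pos - g$start,
                    ifelse(pos > g$end, pos - g$end, 0))
        best <- order(abs(d), g$symbol)[1]
        out$gene[i] <- g$symbol[best]
        out$distance[i] <- d[best]
    }
    if (anyNA(out$gene))
        message("no gene on the same chromosome for: ",
                paste(out$snp[is.na(out$gene)], collapse = ", "))
    if (!is.null(snps$context)) out$context <- snps$context
    out
}

#' Build a typed SNP-gene-grouping-class association network
#'
#' Nodes are typed snp / gene / grouping / phenotype-class; edges link
#' SNPs to their associated classes (\code{association}), SNPs to their
#' nearest genes (\code{annotation}) and genes to groupings
#' (\code{membership}). A grouping node is added only when at least two of
#' the graph's genes are members (a single-member grouping can never link
#' genes, and this keeps grouping nodes non-orphan). Results should come
#' from a single stratum, mirroring stratified reporting.
#'
#' @param groups retained groups for one stratum (\code{snp},
#'   \code{class} columns).
#' @param annotations output of [annotateNearestGene()].
#' @param groupings named list from [readGmt()] (several files may be
#'   concatenated with \code{c()}).
#' @param stratum label stored as a graph attribute.
#' @return an \pkg{igraph} graph with vertex attribute \code{type}.
#' @export
buildAssociationGraph <- function(groups, annotations, groupings,
                                  stratum = "all") {
    snps <- unique(groups$snp)
    ann <- annotations[annotations$snp %in% snps & !is.na(annotations$gene),
                       , drop = FALSE]
    genes <- unique(ann$gene)
    classes <- unique(groups$class)
    edges <- list()
    edges$assoc <- data.frame(
        from = groups$snp, to = paste0("class:", groups$class),
        type = "association", stringsAsFactors = FALSE)
    edges$annot <- data.frame(from = ann$snp, to = ann$gene,
                              type = "annotation", stringsAsFactors = FALSE)
    member <- list()
    for (gname in names(groupings)) {
        hit <- intersect(groupings[[gname]], genes)
        if (length(hit) >= 2L)
            member[[gname]] <- data.frame(
                from = hit, to = paste0("grouping:", gname),
                type = "membership", stringsAsFactors = FALSE)
    }
    if (length(member))
        edges$member <- do.call(rbind, c(member, make.row.names = FALSE))
    edf <- unique(do.call(rbind, c(unname(edges), make.row.names = FALSE)))
    vertices <- data.frame(
        name = c(snps, genes,
                 paste0("class:", classes),
                 if (length(member)) paste0("grouping:", names(member))),
        type = c(rep("snp", length(snps)), rep("gene", length(genes)),
                 rep("class", length(classes)),
                 rep("grouping", length(member))),
        stringsAsFactors = FALSE)
    gr <- igraph::graph_from_data_frame(edf, directed = FALSE,
                                        vertices = vertices)
    gr <- igraph::set_graph_attr(gr, "stratum", stratum)
    gr
}

#' Prune an association network to multi-SNP pathway-linked components
#'
#' Keeps only connected components that contain two or more PheWAS SNP
#' nodes AND at least one grouping node linking two or more genes within
#' the component (the genes may be chained through several groupings).
#' Components built around a single SNP, or whose genes share no grouping,
#' are dropped. The operation is idempotent.
#'
#' @param graph output of [buildAssociationGraph()].
#' @return the induced subgraph on the retained components.
#' @export
pruneComponents <- function(graph) {
    comp <- igraph::components(graph)
    vtype <- igraph::vertex_attr(graph, "type")
    keepMember <- rep(FALSE, igraph::vcount(graph))
    for (ci in seq_len(comp$no)) {
        vidx <- which(comp$membership == ci)
        if (sum(vtype[vidx] == "snp") < 2L) next
        gidx <- vidx[vtype[vidx] == "grouping"]
        linked <- any(vapply(gidx, function(v) {
            nb <- igraph::neighbors(graph, v)
            sum(vtype[as.integer(nb)] == "gene") >= 2L
        }, TRUE))
        if (length(gidx) && linked) keepMember[vidx] <- TRUE
    }
    igraph::induced_subgraph(graph, which(keepMember))
}

#' Write a network as a SIF file
#'
#' Simple interaction format: \code{source<TAB>edgeType<TAB>target}, plus
#' a companion \code{<file>.types.txt} mapping node names to types.
#'
#' @param graph an igraph graph with a \code{type} edge attribute.
#' @param path output path.
#' @export
writeNetworkSif <- function(graph, path) {
    e <- igraph::as_data_frame(graph, what = "edges")
    writeLines(paste(e$from, e$type, e$to, sep = "\t"), path)
    v <- igraph::as_data_frame(graph, what = "vertices")
    writeLines(paste(v$name, v$type, sep = "\t"),
               paste0(path, ".types.txt"))
    invisible(path)
}

#' Write a network as GraphML (node-type attributes preserved)
#'
#' @param graph an igraph graph.
#' @param path output path.
#' @export
writeNetworkGraphml <- function(graph, path) {
    igraph::write_graph(graph, path, format = "graphml")
    invisible(path)
}
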