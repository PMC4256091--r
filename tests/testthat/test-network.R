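# nearest-gene annotation, GMT parsing, typed graphs and pruning

genes <- readGeneTable(fx("genes_grch37.tsv"))
snpPos <- read.delim(fx("snp_positions_grch37.tsv"),
                     stringsAsFactors = FALSE)
snpPos$chrom <- as.character(snpPos$chrom)
gmt <- readGmt(fx("pathways.gmt"))

test_that("GMT files parse into named gene sets with sources", {
    expect_named(gmt, c("TGF_beta_receptor_pathway",
                        "urate_metabolic_process",
                        "glycerolipid_metabolism",
                        "PPAR_signaling_pathway"))
    expect_setequal(as.character(gmt$urate_metabolic_process),
                    c("ABCG2", "SLC2A9"))
    expect_equal(attr(gmt$glycerolipid_metabolism, "source"), "KEGG")
})

test_that("nearest-gene distances match the published annotation", {
    ann <- annotateNearestGene(snpPos, genes)
    get <- function(s) ann[ann$snp == s, ]
    # inside a gene span -> distance 0
    expect_equal(get("rs2231142")$gene, "ABCG2")
    expect_equal(get("rs2231142")$distance, 0)
    expect_equal(get("rs328")$gene, "LPL")
    expect_equal(get("rs328")$distance, 0)
    # downstream intergenic SNP: 19,452 bases beyond the span end
    expect_equal(get("rs12678919")$gene, "LPL")
    expect_equal(get("rs12678919")$distance, 19452)
    # upstream SNP: 500 bases before the span start, negative sign
    expect_equal(get("rs1800588")$gene, "LIPC")
    expect_equal(abs(get("rs1800588")$distance), 500)
    expect_lt(get("rs1800588")$distance, 0)
    # context strings are consumed, not recomputed
    expect_equal(get("rs2231142")$context, "STOP-GAIN")
})

test_that("annotation agrees with an exhaustive oracle on random tables", {
    bruteNearest <- function(snp, genes) {
        g <- genes[genes$chrom == snp$chrom, ]
        if (!nrow(g)) return(NULL)
        d <- vapply(seq_len(nrow(g)), function(i) {
            if (snp$pos >= g$start[i] && snp$pos <= g$end[i]) 0
            else min(abs(snp$pos - g$start[i]), abs(snp$pos - g$end[i]))
        }, 1)
        sel <- which(d == min(d))
        sel <- sel[order(g$symbol[sel])][1]
        list(gene = g$symbol[sel], absdist = d[sel])
    }
    set.seed(99)
    for (rep in 1:25) {
        ng <- sample(3:12, 1)
        gtab <- data.frame(chrom = sample(c("1", "2"), ng, TRUE),
                           start = sample.int(1e5, ng),
                           symbol = paste0("G", seq_len(ng)),
                           stringsAsFactors = FALSE)
        gtab$end <- gtab$start + sample.int(2e4, ng)
        stab <- data.frame(snp = paste0("s", 1:8),
                           chrom = sample(c("1", "2", "3"), 8, TRUE),
                           pos = sample.int(1.2e5, 8),
                           stringsAsFactors = FALSE)
        ann <- suppressMessages(annotateNearestGene(stab, gtab))
        for (i in 1:8) {
            oracle <- bruteNearest(stab[i, ], gtab)
            if (is.null(oracle)) {
                expect_true(is.na(ann$gene[i]))
            } else {
                expect_equal(ann$gene[i], oracle$gene)
                expect_equal(abs(ann$distance[i]), oracle$absdist)
            }
        }
    }
})

test_that("genes sharing a pathway connect SNPs into one component", {
    # two SNPs in different genes joined by one shared grouping
    groups <- data.frame(snp = c("rs328", "rs174547"),
                         class = c("HDL Cholesterol", "Ferritin"),
                         stratum = "MA", stringsAsFactors = FALSE)
    ann <- annotateNearestGene(snpPos, genes)
    g <- buildAssociationGraph(groups, ann, gmt, stratum = "MA")
    expect_true("grouping:TGF_beta_receptor_pathway" %in%
                igraph::V(g)$name)
    comp <- igraph::components(g)
    expect_equal(comp$membership[["rs328"]],
                 comp$membership[["rs174547"]])
    pruned <- pruneComponents(g)
    expect_true(all(c("rs328", "rs174547") %in%
                    igraph::V(pruned)$name))
})

test_that("one gene with two SNPs plus a shared grouping is retained", {
    # urate pattern: one SNP in ABCG2, two in SLC2A9, genes share the
    # urate grouping -> a single retained component with 3 SNPs
    groups <- data.frame(
        snp = c("rs2231142", "rs6855911", "rs7442295"),
        class = "Kidney (Uric Acid)", stratum = "MA",
        stringsAsFactors = FALSE)
    ann <- annotateNearestGene(snpPos, genes)
    pruned <- pruneComponents(buildAssociationGraph(groups, ann, gmt))
    vn <- igraph::V(pruned)$name
    expect_true(all(c("rs2231142", "rs6855911", "rs7442295") %in% vn))
    expect_equal(igraph::components(pruned)$no, 1L)
})

test_that("grouping chains join components across pathways", {
    # glycerolipid links LIPC-LPL; PPAR links LPL-APOA5: one retained
    # component containing all three SNPs
    groups <- data.frame(
        snp = c("rs1800588", "rs328", "rs3135506"),
        class = c("Folate", "HDL Cholesterol", "Triglycerides"),
        stratum = "MA", stringsAsFactors = FALSE)
    ann <- annotateNearestGene(snpPos, genes)
    pruned <- pruneComponents(buildAssociationGraph(groups, ann, gmt))
    expect_equal(igraph::components(pruned)$no, 1L)
    expect_true(all(c("rs1800588", "rs328", "rs3135506") %in%
                    igraph::V(pruned)$name))
})

test_that("single-SNP and unlinked components are dropped", {
    ann <- annotateNearestGene(snpPos, genes)
    # single SNP
    g1 <- buildAssociationGraph(
        data.frame(snp = "rs328", class = "HDL Cholesterol",
                   stratum = "MA"), ann, gmt)
    expect_equal(igraph::vcount(pruneComponents(g1)), 0L)
    # two SNPs, two genes, no shared grouping
    g2 <- buildAssociationGraph(
        data.frame(snp = c("rs2338104", "rs780094"),
                   class = c("Hearing", "Glucose"), stratum = "NHW"),
        ann, gmt)
    expect_equal(igraph::vcount(pruneComponents(g2)), 0L)
    # no groupings at all -> disjoint single-SNP stars, all dropped
    g3 <- buildAssociationGraph(
        data.frame(snp = c("rs328", "rs174547"),
                   class = c("HDL Cholesterol", "Ferritin"),
                   stratum = "MA"), ann, list())
    expect_equal(igraph::vcount(pruneComponents(g3)), 0L)
})

test_that("pruning is idempotent and components stay valid", {
    groups <- data.frame(
        snp = c("rs1800588", "rs328", "rs3135506", "rs2338104"),
        class = c("Folate", "HDL Cholesterol", "Triglycerides",
                  "Hearing"),
        stratum = "MA", stringsAsFactors = FALSE)
    ann <- annotateNearestGene(snpPos, genes)
    g <- buildAssociationGraph(groups, ann, gmt)
    p1 <- pruneComponents(g)
    p2 <- pruneComponents(p1)
    expect_equal(igraph::vcount(p1), igraph::vcount(p2))
    expect_equal(igraph::ecount(p1), igraph::ecount(p2))
    vtype <- igraph::V(p1)$type
    expect_gte(sum(vtype == "snp"), 2L)
    expect_gte(sum(vtype == "grouping"), 1L)
})

test_that("networks export to SIF and GraphML", {
    groups <- data.frame(snp = c("rs328", "rs174547"),
                         class = c("HDL Cholesterol", "Ferritin"),
                         stratum = "MA", stringsAsFactors = FALSE)
    ann <- annotateNearestGene(snpPos, genes)
    g <- buildAssociationGraph(groups, ann, gmt)
    sif <- tempfile(fileext = ".sif")
    writeNetworkSif(g, sif)
    lines <- readLines(sif)
    expect_true(any(grepl("^rs328\tannotation\tLPL$", lines)))
    xml <- tempfile(fileext = ".graphml")
    writeNetworkGraphml(g, xml)
    expect_true(any(grepl("graphml", readLines(xml, n = 3))))
    unlink(c(sif, paste0(sif, ".types.txt"), xml))
})
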