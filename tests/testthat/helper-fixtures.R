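# shared helpers: extdata paths and small purpose-built configurations

fx <- function(f) system.file("extdata", f, package = "phewasKit")

# minimal two-class continuous config for fast end-to-end runs
tinyConfig <- function(seed = 1L, beta = 0.6, missingRate = 0,
                       n = c(A = 400, B = 400), harmonized = TRUE) {
    snps <- data.frame(snp = c("rs1", "rs2"), chrom = "1",
                       pos = c(1000L, 2000L), coded_allele = "A",
                       freq_A = c(0.3, 0.4), freq_B = c(0.35, 0.45),
                       stringsAsFactors = FALSE)
    phen <- data.frame(class = c("TraitOne", "TraitTwo"),
                       type = "continuous", baseline = c(10, 20),
                       noiseSD = c(1, 1),
                       harmonized = harmonized,
                       categories = NA_character_,
                       stringsAsFactors = FALSE)
    eff <- if (beta != 0)
        data.frame(snp = "rs1", class = "TraitOne", strata = "all",
                   beta = beta, stringsAsFactors = FALSE)
    else NULL
    simulationConfig(strata = c("A", "B"), nPerStratum = n, snps = snps,
                     phenotypes = phen, effects = eff,
                     missingRate = missingRate, seed = seed)
}

# hand-built scan-result row for replication-filter unit tests
resultRow <- function(snp = "rs1", class = "C1", stratum = "S",
                      survey = "survey1", measurement = "m1",
                      transform = "none", beta = 1, p = 0.001,
                      n = 1000L, caf = 0.3, flag = "ok") {
    data.frame(snp = snp, coded_allele = "A", measurement = measurement,
               phenotype = measurement, transform = transform,
               class = class, survey = survey, stratum = stratum,
               beta = beta, se = abs(beta) / 2, p = p, n = n, caf = caf,
               flag = flag, stringsAsFactors = FALSE)
}
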