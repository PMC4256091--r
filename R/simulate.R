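# Synthetic two-survey generator: Hardy-Weinberg genotypes with
# stratum-specific allele frequencies, planted additive effects, correlated
# phenotype blocks via shared latent factors, and MCAR missingness.

# Deterministic per-stream seed so each component (genotypes, phenotypes,
# sex, missingness) is reproducible on its own from the single config seed.
.streamSeed <- function(seed, stream) {
    h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
    as.integer((as.numeric(seed) * 48271 + h) %% (2^31 - 1))
}

#' Build and validate a simulation configuration
#'
#' Defines a two-survey, multi-stratum population: SNPs with per-stratum
#' coded-allele frequencies, phenotype classes with baselines and noise,
#' planted additive effects (possibly pleiotropic, possibly
#' stratum-restricted), latent-factor correlation blocks, and an MCAR
#' missingness rate.
#'
#' @param strata character vector of stratum labels.
#' @param nPerStratum named integer vector, samples per stratum per survey.
#' @param snps data.frame with columns \code{snp}, \code{chrom}, \code{pos},
#'   \code{coded_allele} and one \code{freq_<stratum>} column per stratum
#'   (coded-allele frequency in [0, 1]).
#' @param phenotypes data.frame with columns \code{class}, \code{type}
#'   (continuous/binary/categorical), \code{baseline} (mean for continuous,
#'   prevalence for binary), \code{noiseSD} (continuous), \code{harmonized}
#'   (logical: same raw name in both surveys, enabling a combined-survey
#'   variable) and optionally \code{categories} (semicolon-separated labels
#'   for categorical phenotypes).
#' @param effects data.frame of planted effects: \code{snp}, \code{class},
#'   \code{strata} (semicolon-separated labels or \code{"all"}),
#'   \code{beta} per coded-allele copy (phenotype units, or log-odds for
#'   binary classes). Zero rows for a null population.
#' @param blocks list of correlation blocks, each
#'   \code{list(classes = c(...), loading = x)}: members share a standard
#'   normal latent factor entering with coefficient \code{loading}, so two
#'   members with loadings \eqn{\lambda_1,\lambda_2} and noise SDs
#'   \eqn{\sigma_1,\sigma_2} correlate at
#'   \eqn{\lambda_1\lambda_2/\sqrt{(\lambda_1^2+\sigma_1^2)(\lambda_2^2+\sigma_2^2)}}.
#' @param missingRate MCAR missingness proportion in [0, 1), applied
#'   independently to every observed genotype and phenotype cell.
#' @param femaleProportion length-2 numeric, per-survey female proportions.
#' @param surveyNames length-2 character survey labels.
#' @param seed integer master seed, expanded into per-stream seeds.
#' @return A validated list of class \code{"phewasSimConfig"}.
#' @seealso [defaultSimulationConfig()], [simulateStudy()]
#' @export
simulationConfig <- function(strata, nPerStratum, snps, phenotypes,
                             effects = NULL, blocks = list(),
                             missingRate = 0, femaleProportion = c(0.5, 0.5),
                             surveyNames = c("survey1", "survey2"),
                             seed = 1L) {
    if (is.null(effects))
        effects <- data.frame(snp = character(), class = character(),
                              strata = character(), beta = numeric())
    if (is.null(names(nPerStratum)))
        names(nPerStratum) <- as.character(strata)
    cfg <- list(strata = as.character(strata),
                nPerStratum = nPerStratum, snps = as.data.frame(snps),
                phenotypes = as.data.frame(phenotypes),
                effects = as.data.frame(effects), blocks = blocks,
                missingRate = missingRate,
                femaleProportion = femaleProportion,
                surveyNames = as.character(surveyNames),
                seed = as.integer(seed))
    .validateSimConfig(cfg)
    class(cfg) <- "phewasSimConfig"
    cfg
}

.validateSimConfig <- function(cfg) {
    if (length(cfg$nPerStratum) != length(cfg$strata) ||
        any(cfg$nPerStratum < 1))
        stop("config error: 'nPerStratum' must give a positive size per stratum")
    fcols <- paste0("freq_", cfg$strata)
    if (!all(fcols %in% names(cfg$snps)))
        stop("config error: snps table must have columns ",
             paste(fcols, collapse = ", "))
    fr <- as.matrix(cfg$snps[, fcols, drop = FALSE])
    if (any(is.na(fr)) || any(fr < 0) || any(fr > 1))
        stop("config error: coded-allele frequencies must lie in [0, 1]")
    if (!all(cfg$phenotypes$type %in% .PHENOTYPE_TYPES))
        stop("config error: unknown phenotype type: ",
             paste(setdiff(cfg$phenotypes$type, .PHENOTYPE_TYPES),
                   collapse = ", "))
    if (cfg$missingRate < 0 || cfg$missingRate >= 1)
        stop("config error: 'missingRate' must lie in [0, 1)")
    if (length(cfg$surveyNames) != 2L)
        stop("config error: exactly two survey names are required")
    if (nrow(cfg$effects)) {
        if (!all(cfg$effects$snp %in% cfg$snps$snp))
            stop("config error: planted effect names unknown SNP: ",
                 paste(setdiff(cfg$effects$snp, cfg$snps$snp), collapse = ", "))
        if (!all(cfg$effects$class %in% cfg$phenotypes$class))
            stop("config error: planted effect names unknown class: ",
                 paste(setdiff(cfg$effects$class, cfg$phenotypes$class),
                       collapse = ", "))
    }
    for (b in cfg$blocks)
        if (!all(b$classes %in% cfg$phenotypes$class))
            stop("config error: correlation block names unknown class")
    invisible(TRUE)
}

# raw phenotype name for a class in one survey under the deterministic
# renaming scheme; harmonized classes keep one shared name
.rawName <- function(class, harmonized, surveyName) {
    ifelse(harmonized, class, paste0(class, " [", surveyName, "]"))
}

#' Simulate genotypes for both surveys
#'
#' Draws, per survey and stratum, genotype counts from Hardy-Weinberg
#' proportions at the stratum's coded-allele frequency
#' (\eqn{g \sim \mathrm{Binomial}(2, p)}). Returns *complete* genotypes;
#' MCAR missingness is overlaid by [simulateStudy()] so that phenotypes can
#' be generated from the true genotypes first.
#'
#' @param config a [simulationConfig()].
#' @return list with one element per survey, each
#'   \code{list(genotypes, samples)}.
#' @export
simulateGenotypes <- function(config) {
    stopifnot(inherits(config, "phewasSimConfig"))
    set.seed(.streamSeed(config$seed, "genotypes"))
    out <- list()
    for (sv in seq_along(config$surveyNames)) {
        svname <- config$surveyNames[sv]
        gl <- list(); sl <- list()
        for (st in config$strata) {
            n <- config$nPerStratum[[st]]
            p <- config$snps[[paste0("freq_", st)]]
            g <- vapply(p, function(pp) rbinom(n, 2L, pp), numeric(n))
            if (is.null(dim(g))) g <- matrix(g, nrow = n)
            colnames(g) <- config$snps$snp
            gl[[st]] <- g
            sl[[st]] <- data.frame(
                sample_id = sprintf("%s_%s_%05d", svname, st, seq_len(n)),
                stratum = st, stringsAsFactors = FALSE)
        }
        out[[svname]] <- list(genotypes = do.call(rbind, gl),
                              samples = do.call(rbind, sl))
    }
    # sex drawn in its own stream so genotype draws are unaffected
    set.seed(.streamSeed(config$seed, "sex"))
    for (sv in seq_along(out)) {
        n <- nrow(out[[sv]]$samples)
        out[[sv]]$samples$sex <- ifelse(
            runif(n) < config$femaleProportion[sv], "female", "male")
        rownames(out[[sv]]$samples) <- NULL
    }
    out
}

#' Simulate phenotypes from genotypes, with a truth table
#'
#' Continuous phenotypes follow an additive genetic model:
#' baseline + sum(effect x genotype) + latent-factor term + Gaussian noise.
#' Binary phenotypes apply a logistic link to the same linear predictor with
#' intercept chosen to hit the configured prevalence. Categorical phenotypes
#' are drawn from their category set (no genetic effect). Survey-specific
#' raw names differ for non-harmonized classes while class labels agree.
#'
#' @param config a [simulationConfig()].
#' @param genotypes the complete genotypes from [simulateGenotypes()].
#' @return \code{list(phenotypes = <per-survey data.frame>, truth, classMap,
#'   phenotypeInfo)}.
#' @export
simulatePhenotypes <- function(config, genotypes) {
    stopifnot(inherits(config, "phewasSimConfig"))
    set.seed(.streamSeed(config$seed, "phenotypes"))
    ph <- config$phenotypes
    eff <- config$effects
    out <- list(); classMap <- list(); phenoInfo <- list()
    for (sv in seq_along(config$surveyNames)) {
        svname <- config$surveyNames[sv]
        G <- genotypes[[svname]]$genotypes
        samples <- genotypes[[svname]]$samples
        n <- nrow(samples)
        # latent factors: one standard-normal draw per block per sample
        factors <- lapply(config$blocks, function(b) rnorm(n))
        cols <- list()
        for (k in seq_len(nrow(ph))) {
            cl <- ph$class[k]; type <- ph$type[k]
            lp <- numeric(n)
            if (nrow(eff)) {
                rows <- which(eff$class == cl)
                for (r in rows) {
                    strs <- eff$strata[r]
                    inStr <- if (identical(strs, "all")) rep(TRUE, n)
                             else samples$stratum %in%
                                  strsplit(strs, ";", fixed = TRUE)[[1]]
                    g <- G[, eff$snp[r]]
                    lp <- lp + ifelse(inStr, eff$beta[r] * g, 0)
                }
            }
            for (b in seq_along(config$blocks))
                if (cl %in% config$blocks[[b]]$classes)
                    lp <- lp + config$blocks[[b]]$loading * factors[[b]]
            if (type == "continuous") {
                y <- ph$baseline[k] + lp + rnorm(n, 0, ph$noiseSD[k])
            } else if (type == "binary") {
                pr <- stats::plogis(stats::qlogis(ph$baseline[k]) + lp)
                y <- rbinom(n, 1L, pr)
            } else if (type == "categorical") {
                cats <- strsplit(ph$categories[k], ";", fixed = TRUE)[[1]]
                y <- sample(cats, n, replace = TRUE)
            } else stop("config error: unknown phenotype type: ", type)
            cols[[.rawName(cl, ph$harmonized[k], svname)]] <- y
        }
        out[[svname]] <- as.data.frame(cols, check.names = FALSE,
                                       optional = TRUE)
        classMap[[svname]] <- data.frame(
            survey = svname,
            phenotype = .rawName(ph$class, ph$harmonized, svname),
            class = ph$class, stringsAsFactors = FALSE)
        phenoInfo[[svname]] <- data.frame(
            phenotype = .rawName(ph$class, ph$harmonized, svname),
            type = ph$type, class = ph$class, stringsAsFactors = FALSE)
    }
    truth <- .buildTruth(config)
    list(phenotypes = out, truth = truth,
         classMap = do.call(rbind, c(classMap, make.row.names = FALSE)),
         phenotypeInfo = phenoInfo)
}

.buildTruth <- function(config) {
    eff <- config$effects
    if (!nrow(eff))
        return(data.frame(snp = character(), class = character(),
                          stratum = character(), beta = numeric(),
                          sign = character()))
    rows <- lapply(seq_len(nrow(eff)), function(r) {
        strs <- if (identical(eff$strata[r], "all")) config$strata
                else strsplit(eff$strata[r], ";", fixed = TRUE)[[1]]
        data.frame(snp = eff$snp[r], class = eff$class[r], stratum = strs,
                   beta = eff$beta[r],
                   sign = ifelse(eff$beta[r] > 0, "+", "-"),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Simulate a full two-survey experiment
#'
#' Runs [simulateGenotypes()] and [simulatePhenotypes()], overlays MCAR
#' missingness on the observed genotype and phenotype cells, and bundles
#' everything into a [PhewasExperiment-class] carrying the truth table.
#'
#' @param config a [simulationConfig()]; default
#'   [defaultSimulationConfig()].
#' @return A [PhewasExperiment-class].
#' @examples
#' expt <- simulateStudy(defaultSimulationConfig(seed = 7, scale = 0.05))
#' expt
#' @export
simulateStudy <- function(config = defaultSimulationConfig()) {
    stopifnot(inherits(config, "phewasSimConfig"))
    geno <- simulateGenotypes(config)
    phen <- simulatePhenotypes(config, geno)
    set.seed(.streamSeed(config$seed, "missingness"))
    studies <- list()
    for (sv in config$surveyNames) {
        G <- geno[[sv]]$genotypes
        P <- phen$phenotypes[[sv]]
        if (config$missingRate > 0) {
            G[matrix(runif(length(G)) < config$missingRate,
                     nrow(G))] <- NA
            for (j in seq_along(P))
                P[[j]][runif(nrow(P)) < config$missingRate] <- NA
        }
        studies[[sv]] <- PhewasStudy(
            survey = sv, genotypes = G,
            snpInfo = config$snps[, c("snp", "chrom", "pos", "coded_allele")],
            phenotypes = P, phenotypeInfo = phen$phenotypeInfo[[sv]],
            samples = geno[[sv]]$samples)
    }
    PhewasExperiment(studies[[1]], studies[[2]], classMap = phen$classMap,
                     truth = phen$truth, metadata = list(config = config))
}

#' Default study-like simulation configuration
#'
#' Emulates a two-survey collection with three self-reported race-ethnicity
#' strata (NHW/NHB/MA) at roughly the published per-survey stratum sizes,
#' per-survey female proportions 0.5667/0.5179, ten SNPs with
#' stratum-specific coded-allele frequencies, a lipid-style correlated
#' phenotype block (loading 0.45, noise SD 0.25, pair correlation 0.76),
#' one pleiotropic SNP planted
#' on three classes plus two single-class effects, and 5% MCAR missingness.
#'
#' @param seed master seed.
#' @param scale multiplier on the per-stratum sample sizes (use < 1 for
#'   quick examples and tests).
#' @param missingRate MCAR rate; default 0.05.
#' @param effects override the planted-effect table (\code{NULL} keeps the
#'   defaults; pass a zero-row data.frame for a null population).
#' @return A \code{"phewasSimConfig"}.
#' @export
defaultSimulationConfig <- function(seed = 1L, scale = 1,
                                    missingRate = 0.05, effects = NULL) {
    strata <- c("NHW", "NHB", "MA")
    nPer <- pmax(50L, as.integer(round(c(NHW = 3300, NHB = 1730,
                                         MA = 1975) * scale)))
    snps <- data.frame(
        snp = sprintf("rs%04d", 1:10),
        chrom = as.character(c(1, 2, 4, 4, 8, 8, 11, 12, 15, 19)),
        pos = c(55496039L, 27730940L, 89052323L, 9935910L, 19844222L,
                118184783L, 61570783L, 109895168L, 58723675L, 11163562L),
        coded_allele = c("T", "T", "C", "G", "G", "T", "T", "G", "T", "G"),
        freq_NHW = c(0.20, 0.35, 0.10, 0.25, 0.12, 0.30, 0.32, 0.45,
                     0.21, 0.18),
        freq_NHB = c(0.25, 0.28, 0.05, 0.30, 0.10, 0.40, 0.15, 0.40,
                     0.50, 0.22),
        freq_MA  = c(0.22, 0.40, 0.18, 0.28, 0.15, 0.33, 0.45, 0.42,
                     0.30, 0.20),
        stringsAsFactors = FALSE)
    phen <- data.frame(
        class = c("Cholesterol", "Triglycerides", "HDL Cholesterol",
                  "Kidney (Uric Acid)", "Protoporphyrin",
                  "Blood Pressure (Diastolic)", "Vitamin E", "Folate",
                  "Glucose", "White Blood Cell", "Body Measurements (Arm)",
                  "Smoking", "Allergy"),
        type = c(rep("continuous", 11), "binary", "categorical"),
        baseline = c(5.2, 1.5, 1.3, 5.5, 60, 72, 900, 12, 95, 7.2, 31,
                     0.25, NA),
        noiseSD = c(0.25, 0.25, 0.25, 1.1, 14, 11, 180, 3.0, 22, 2.1, 4.6,
                    NA, NA),
        harmonized = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE,
                       TRUE, TRUE, FALSE, TRUE, TRUE),
        categories = c(rep(NA, 12), "none;seasonal;perennial"),
        stringsAsFactors = FALSE)
    if (is.null(effects))
        effects <- data.frame(
            # rs0003 is pleiotropic: three classes, mixed directions,
            # patterned after a missense urate-transporter variant
            snp = c("rs0003", "rs0003", "rs0003", "rs0009", "rs0007"),
            class = c("Kidney (Uric Acid)", "Protoporphyrin",
                      "Blood Pressure (Diastolic)", "Vitamin E", "Folate"),
            strata = c("NHW;MA", "NHW;MA", "MA", "NHW", "NHB"),
            beta = c(-0.45, -6.5, 4.5, 75, -1.9),
            stringsAsFactors = FALSE)
    simulationConfig(
        strata = strata, nPerStratum = nPer, snps = snps,
        phenotypes = phen, effects = effects,
        blocks = list(list(classes = c("Cholesterol", "Triglycerides",
                                       "HDL Cholesterol"), loading = 0.45)),
        missingRate = missingRate,
        femaleProportion = c(0.5667, 0.5179),
        surveyNames = c("survey1", "survey2"), seed = seed)
}

#' Read a simulation configuration from a YAML file
#'
#' The YAML mirrors [simulationConfig()]'s arguments; \code{snps},
#' \code{phenotypes} and \code{effects} are lists of records, \code{blocks}
#' a list of \code{classes}/\code{loading} pairs.
#'
#' @param path YAML path.
#' @return A validated \code{"phewasSimConfig"}.
#' @export
readSimulationConfig <- function(path) {
    y <- yaml::read_yaml(path)
    toDf <- function(x) if (is.null(x)) NULL else
        do.call(rbind, lapply(x, function(r)
            as.data.frame(r, stringsAsFactors = FALSE)))
    simulationConfig(
        strata = y$strata,
        nPerStratum = unlist(y$nPerStratum),
        snps = toDf(y$snps), phenotypes = toDf(y$phenotypes),
        effects = toDf(y$effects),
        blocks = if (is.null(y$blocks)) list() else
            lapply(y$blocks, function(b)
                list(classes = unlist(b$classes), loading = b$loading)),
        missingRate = if (is.null(y$missingRate)) 0 else y$missingRate,
        femaleProportion = if (is.null(y$femaleProportion)) c(0.5, 0.5)
                           else unlist(y$femaleProportion),
        surveyNames = if (is.null(y$surveyNames))
            c("survey1", "survey2") else unlist(y$surveyNames),
        seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Null simulation configuration for calibration studies
#'
#' A population with no planted effects, no correlation blocks and no
#' missingness: independent standard-normal continuous phenotypes and HWE
#' genotypes at a common allele frequency. Useful for p-value uniformity
#' checks and replication-filter null calibration, where every
#' (snp, class, stratum) group is a true null.
#'
#' @param nSnps,nPhenotypes numbers of SNPs and phenotype classes.
#' @param nPerStratum samples per stratum per survey.
#' @param strata stratum labels.
#' @param freq common coded-allele frequency.
#' @param seed master seed.
#' @return A \code{"phewasSimConfig"}.
#' @export
nullSimulationConfig <- function(nSnps = 100, nPhenotypes = 1000,
                                 nPerStratum = 300,
                                 strata = c("S1", "S2"), freq = 0.3,
                                 seed = 1L) {
    snps <- data.frame(snp = sprintf("snp%04d", seq_len(nSnps)),
                       chrom = "1", pos = seq_len(nSnps) * 1000L,
                       coded_allele = "A", stringsAsFactors = FALSE)
    for (st in strata) snps[[paste0("freq_", st)]] <- freq
    phen <- data.frame(class = sprintf("pheno%04d", seq_len(nPhenotypes)),
                       type = "continuous", baseline = 0, noiseSD = 1,
                       harmonized = FALSE, categories = NA_character_,
                       stringsAsFactors = FALSE)
    simulationConfig(strata,
                     stats::setNames(rep(nPerStratum, length(strata)),
                                     strata),
                     snps, phen, effects = NULL, blocks = list(),
                     missingRate = 0, seed = seed)
}
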