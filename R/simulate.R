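#' Build a simulation configuration
#'
#' Defaults describe the screen conditions the package is designed around:
#' lentiviral transduction at MOI 0.3 so most carrier cells hold a single
#' guide, a four-state cardiomyocyte trajectory
#' (progenitor < early < mid < late), five non-targeting control guides,
#' and an ambient sgRNA background well below the carrier UMI level so the
#' per-guide cumulative UMI curve has a knee. The default library is
#' deliberately small (2 targets x 3 guides + 5 NT): what the knee caller
#' sees is the number of carrier cells per guide, so a scaled-down screen
#' must preserve carriers-per-guide (about 55 here at 2000 cells, versus
#' roughly 200 in a full-size screen), not the guide count.
#'
#' @param nCells number of cells to simulate.
#' @param clusterNames ordered trajectory state labels.
#' @param clusterProportions baseline state probabilities (sum to 1).
#' @param moi mean guides per cell (Poisson mean).
#' @param ambientRate mean ambient UMIs per (cell, guide) pair.
#' @param carrierUmiMean mean UMIs for a truly carried guide.
#' @param nTargets,guidesPerTarget,nNtGuides guide library design.
#' @param effectTable named list target -> named vector of positive
#'   multiplicative state-odds shifts; omitted targets have no effect.
#' @param markerGenesPerCluster marker genes per trajectory state.
#' @param targetGeneRepression fractional knockdown of a target's linked
#'   gene in carrier cells, in [0,1].
#' @param mitoMean,mitoSd per-cell mitochondrial fraction distribution.
#' @param doubletRate fraction of cells receiving a second hashing tag.
#' @param seed integer seed.
#' @return A validated [SimulationConfig-class].
#' @examples
#' simulationConfig(nCells = 100, seed = 1)
#' @export
simulationConfig <- function(nCells = 2000,
                             clusterNames = c("progenitor", "early", "mid", "late"),
                             clusterProportions = c(0.25, 0.30, 0.25, 0.20),
                             moi = 0.3,
                             ambientRate = 0.5,
                             carrierUmiMean = 50,
                             nTargets = 2,
                             guidesPerTarget = 3,
                             nNtGuides = 5,
                             effectTable = list(),
                             markerGenesPerCluster = 10,
                             targetGeneRepression = 0.8,
                             mitoMean = 0.05, mitoSd = 0.03,
                             doubletRate = 0.05,
                             seed) {
    if (missing(seed)) stop("seed must be given explicitly")
    new("SimulationConfig",
        nCells = as.integer(nCells), clusterNames = clusterNames,
        clusterProportions = clusterProportions, moi = moi,
        ambientRate = ambientRate, carrierUmiMean = carrierUmiMean,
        nTargets = as.integer(nTargets),
        guidesPerTarget = as.integer(guidesPerTarget),
        nNtGuides = as.integer(nNtGuides), effectTable = effectTable,
        markerGenesPerCluster = as.integer(markerGenesPerCluster),
        targetGeneRepression = targetGeneRepression,
        mitoMean = mitoMean, mitoSd = mitoSd, doubletRate = doubletRate,
        seed = as.integer(seed))
}

#' Simulate a guide library
#'
#' Produces `nTargets * guidesPerTarget` targeting guides (class
#' `enhancer`, each target linked to one gene symbol) plus `nNtGuides`
#' non-targeting controls.
#'
#' @param nTargets number of targeted elements (>= 1).
#' @param guidesPerTarget guides designed against each element (>= 1).
#' @param nNtGuides number of non-targeting controls (>= 0).
#' @param seed integer seed (kept for interface symmetry; the library is
#'   deterministic in the design counts).
#' @return A [GuideLibrary-class].
#' @examples
#' simulateLibrary(2, 3, 4, seed = 1)
#' @export
simulateLibrary <- function(nTargets, guidesPerTarget, nNtGuides, seed = 0) {
    if (nTargets < 1 || guidesPerTarget < 1)
        stop("nTargets and guidesPerTarget must be >= 1")
    if (nNtGuides < 0) stop("nNtGuides must be >= 0")
    tgt <- sprintf("ENH%02d", seq_len(nTargets))
    tab <- data.frame(
        guide_id = sprintf("sg%s_%d", rep(tgt, each = guidesPerTarget),
                           rep(seq_len(guidesPerTarget), nTargets)),
        target_id = rep(tgt, each = guidesPerTarget),
        class = "enhancer",
        gene = rep(sprintf("GENE%02d", seq_len(nTargets)), each = guidesPerTarget),
        stringsAsFactors = FALSE)
    if (nNtGuides > 0) {
        tab <- rbind(tab, data.frame(
            guide_id = sprintf("sgNT_%d", seq_len(nNtGuides)),
            target_id = "NT", class = "non_targeting", gene = NA_character_,
            stringsAsFactors = FALSE))
    }
    GuideLibrary(tab)
}

.rnbinomMu <- function(n, mu, size = 10) {
    out <- integer(length(mu))
    pos <- mu > 0
    out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = size)
    out
}

#' Simulate a full synthetic screen
#'
#' Draws, per cell: a Poisson(MOI) number of carried guides; a trajectory
#' state from the baseline proportions with odds multiplied by the effect
#' table entries of the carried targets; a unique pseudotime rank ordered
#' by state with uniform jitter within state; guide UMIs (negative
#' binomial around `carrierUmiMean` for carriers, Poisson ambient
#' background in every cell); marker/housekeeping/mitochondrial/target
#' gene expression (negative binomial, markers elevated in their state,
#' target genes repressed in carrier cells); and hashing-tag UMIs with a
#' configurable doublet rate. Identical config and seed give bit-identical
#' output.
#'
#' @param config a [SimulationConfig-class].
#' @return A [SyntheticScreen-class].
#' @examples
#' scr <- simulateScreen(simulationConfig(nCells = 200, seed = 7))
#' scr
#' @export
simulateScreen <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    n <- config@nCells
    states <- config@clusterNames
    nStates <- length(states)
    lib <- simulateLibrary(config@nTargets, config@guidesPerTarget,
                           config@nNtGuides, config@seed)
    allGuides <- guideIds(lib)
    guideTarget <- stats::setNames(lib@table$target_id, lib@table$guide_id)
    unknown <- setdiff(names(config@effectTable), targetIds(lib))
    if (length(unknown))
        stop("effect table references unknown targets: ",
             paste(unknown, collapse = ", "))
    barcodesV <- sprintf("BC%06d", seq_len(n))

    ## guide carriage: Poisson(moi) truncated at library size
    nCarried <- pmin(stats::rpois(n, config@moi), length(allGuides))
    truthGuides <- lapply(nCarried, function(k)
        if (k == 0) character() else sample(allGuides, k))

    ## state assignment: baseline odds shifted by carried-target effects
    odds <- matrix(rep(config@clusterProportions, each = n), n, nStates,
                   dimnames = list(barcodesV, states))
    for (i in seq_len(n)) {
        tg <- unique(guideTarget[truthGuides[[i]]])
        for (tt in tg) {
            ef <- config@effectTable[[tt]]
            if (!is.null(ef)) odds[i, names(ef)] <- odds[i, names(ef)] * ef
        }
    }
    stateIdx <- integer(n)
    if (n) {
        prob <- odds / rowSums(odds)
        u <- stats::runif(n)
        cum <- t(apply(prob, 1, cumsum))
        stateIdx <- rowSums(u > cum) + 1L
    }
    truthStates <- states[stateIdx]

    ## pseudotime: ordered by state, uniform jitter within state
    pt <- integer(n)
    if (n) pt[order(stateIdx + stats::runif(n))] <- 0:(n - 1L)

    ## guide UMIs: ambient Poisson everywhere + carrier negative binomial
    G <- length(allGuides)
    ambient <- matrix(stats::rpois(n * G, config@ambientRate), n, G,
                      dimnames = list(barcodesV, allGuides))
    for (i in seq_len(n)) {
        gs <- truthGuides[[i]]
        if (length(gs))
            ambient[i, gs] <- ambient[i, gs] +
                .rnbinomMu(length(gs), rep(config@carrierUmiMean, length(gs)))
    }
    guideUmis <- CountMatrix(ambient)

    ## expression: markers, housekeeping, target genes, mito genes
    nMk <- config@markerGenesPerCluster
    markerGenes <- sprintf("MK_%s_%d", rep(states, each = nMk),
                           rep(seq_len(nMk), nStates))
    targetGenes <- sprintf("GENE%02d", seq_len(config@nTargets))
    hkGenes <- sprintf("HK_%d", 1:20)
    mtGenes <- sprintf("MT-%d", 1:5)
    genes <- c(markerGenes, targetGenes, hkGenes, mtGenes)
    mu <- matrix(0, n, length(genes), dimnames = list(barcodesV, genes))
    mu[, markerGenes] <- 1.0
    for (s in seq_len(nStates)) {
        cols <- markerGenes[seq_len(nMk) + (s - 1L) * nMk]
        mu[stateIdx == s, cols] <- 5.0
    }
    mu[, targetGenes] <- 5.0
    mu[, hkGenes] <- 5.0
    for (i in seq_len(n)) {
        tg <- unique(guideTarget[truthGuides[[i]]])
        tg <- tg[tg != "NT"]
        if (length(tg)) {
            linked <- unique(lib@table$gene[lib@table$target_id %in% tg])
            linked <- linked[!is.na(linked)]
            mu[i, linked] <- mu[i, linked] * (1 - config@targetGeneRepression)
        }
    }
    counts <- matrix(.rnbinomMu(n * (length(genes) - 5L),
                                as.vector(mu[, setdiff(genes, mtGenes), drop = FALSE]),
                                size = 2),
                     n, length(genes) - 5L)
    ## mitochondrial content: per-cell fraction ~ clipped normal
    mitoFrac <- pmin(pmax(stats::rnorm(n, config@mitoMean, config@mitoSd), 0), 0.97)
    nonMito <- rowSums(counts)
    mitoTot <- stats::rpois(n, mitoFrac / (1 - mitoFrac) * nonMito)
    mtCounts <- matrix(0L, n, 5L)
    for (i in seq_len(n)) {
        if (mitoTot[i] > 0)
            mtCounts[i, ] <- as.integer(stats::rmultinom(1, mitoTot[i], rep(0.2, 5)))
    }
    expr <- cbind(counts, mtCounts)
    dimnames(expr) <- list(barcodesV, genes)
    expression <- CountMatrix(expr)

    ## hashing tags: one dominant tag per cell, doublets get a second
    hashTags <- sprintf("Hash%d", 1:4)
    hAmb <- matrix(stats::rpois(n * 4L, config@ambientRate), n, 4L,
                   dimnames = list(barcodesV, hashTags))
    tag1 <- if (n) sample.int(4L, n, replace = TRUE) else integer()
    isDoublet <- stats::runif(n) < config@doubletRate
    for (i in seq_len(n)) {
        hAmb[i, tag1[i]] <- hAmb[i, tag1[i]] + .rnbinomMu(1, 100)
        if (isDoublet[i]) {
            tag2 <- sample(setdiff(1:4, tag1[i]), 1)
            hAmb[i, tag2] <- hAmb[i, tag2] + .rnbinomMu(1, 100)
        }
    }
    hashUmis <- CountMatrix(hAmb)

    new("SyntheticScreen", expression = expression, guideUmis = guideUmis,
        hashUmis = hashUmis, truthGuides = truthGuides,
        truthStates = truthStates, truthPseudotime = pt,
        library = lib, config = config)
}

#' Write a synthetic screen to disk as plain-text fixtures
#'
#' Emits Matrix Market triplets for the expression, guide and hash
#' matrices, the library as TSV, and the ground truth (carried guides,
#' states, pseudotime ranks) as TSV. The file set round-trips losslessly
#' through [readCountTriplet()] / [readTsv()].
#'
#' @param screen a [SyntheticScreen-class].
#' @param directory output directory.
#' @return `directory`, invisibly.
#' @export
writeFixture <- function(screen, directory) {
    stopifnot(is(screen, "SyntheticScreen"))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(directory)) stop("cannot create directory: ", directory)
    writeCountTriplet(screen@expression, file.path(directory, "expression"))
    writeCountTriplet(screen@guideUmis, file.path(directory, "guides"))
    writeCountTriplet(screen@hashUmis, file.path(directory, "hashes"))
    writeTsv(libraryTable(screen@library), file.path(directory, "library.tsv"))
    bc <- barcodes(screen@expression)
    writeTsv(data.frame(cell = bc, state = screen@truthStates,
                        pseudotime_rank = screen@truthPseudotime,
                        stringsAsFactors = FALSE),
             file.path(directory, "truth_cells.tsv"))
    ng <- lengths(screen@truthGuides)
    writeTsv(data.frame(cell = as.character(rep(bc, ng)),
                        guide = as.character(unlist(screen@truthGuides,
                                                    use.names = FALSE)),
                        stringsAsFactors = FALSE),
             file.path(directory, "truth_guides.tsv"))
    invisible(directory)
}

#' Read a fixture directory written by [writeFixture()]
#'
#' @param directory fixture directory.
#' @return A named list with elements `expression`, `guideUmis`,
#'   `hashUmis` ([CountMatrix-class]), `library` ([GuideLibrary-class]),
#'   `truthCells` and `truthGuides` (data.frames).
#' @export
readFixture <- function(directory) {
    list(expression = readCountTriplet(file.path(directory, "expression")),
         guideUmis = readCountTriplet(file.path(directory, "guides")),
         hashUmis = readCountTriplet(file.path(directory, "hashes")),
         library = GuideLibrary(readTsv(file.path(directory, "library.tsv"))),
         truthCells = readTsv(file.path(directory, "truth_cells.tsv")),
         truthGuides = readTsv(file.path(directory, "truth_guides.tsv")))
}
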