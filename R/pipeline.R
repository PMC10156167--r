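#' Run the full screen analysis pipeline
#'
#' Orchestrates the stages in fixed order: obtain data (simulate from a
#' `simulation` block, or read a fixture directory), hashing singlet
#' retention (when hash data exist), mitochondrial/gene filtering, guide
#' assignment and removal of guide-less cells, small-cluster removal,
#' layer construction, NT debiasing and per-target guide QC, then the
#' per-target statistics: hypergeometric cluster enrichment/depletion,
#' pseudotime shift, and the resampling Z-test on the late-state gene
#' set. All intermediate artifacts are written under `outDir`; rerunning
#' with an identical config and seed reproduces a byte-identical report.
#'
#' @param config named list (e.g. from [readConfig()]) with exactly one
#'   of `simulation` (arguments to [simulationConfig()]) or `inputs`
#'   (`dir`: a fixture directory as written by [writeFixture()]).
#'   Optional elements: `clusters`, `mito_prefix` (default `"MT-"`),
#'   `mito_max` (0.20), `min_cluster_frac` (0.01), `alpha` (0.05),
#'   `n_iter` (1000), `use_hashing` (TRUE when hash data present),
#'   `seed` (required).
#' @param outDir output directory for artifacts and `report.json`.
#' @return The report, a named list (invisibly also written as JSON).
#' @export
runPipeline <- function(config, outDir) {
    if (is.null(config$seed)) stop("config error: seed must be explicit")
    hasSim <- !is.null(config$simulation)
    hasInp <- !is.null(config$inputs)
    if (hasSim == hasInp)
        stop("config error: exactly one of 'simulation' or 'inputs' required")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    alpha <- config$alpha %||% 0.05
    nIter <- config$n_iter %||% 1000
    mitoPrefix <- config$mito_prefix %||% "MT-"
    mitoMax <- config$mito_max %||% 0.20
    minClusterFrac <- config$min_cluster_frac %||% 0.01
    seed <- as.integer(config$seed)

    ledger <- list()
    note <- function(stage, n) {
        ledger[[stage]] <<- n
        message(sprintf("[%s] cells: %d", stage, n))
    }

    ## stage 1: data
    if (hasSim) {
        simArgs <- config$simulation
        simArgs$seed <- simArgs$seed %||% seed
        simArgs$effectTable <- lapply(simArgs$effectTable, unlist)
        cfg <- do.call(simulationConfig, simArgs)
        scr <- simulateScreen(cfg)
        dat <- list(expression = scr@expression, guideUmis = scr@guideUmis,
                    hashUmis = scr@hashUmis, library = scr@library,
                    states = stats::setNames(scr@truthStates,
                                             barcodes(scr@expression)),
                    pseudotime = stats::setNames(scr@truthPseudotime,
                                                 barcodes(scr@expression)))
    } else {
        fx <- readFixture(config$inputs$dir)
        dat <- list(expression = fx$expression, guideUmis = fx$guideUmis,
                    hashUmis = fx$hashUmis, library = fx$library,
                    states = stats::setNames(fx$truthCells$state,
                                             fx$truthCells$cell),
                    pseudotime = stats::setNames(fx$truthCells$pseudotime_rank,
                                                 fx$truthCells$cell))
    }
    cells <- barcodes(dat$expression)
    note("input", length(cells))

    ## stage 2: hashing singlets
    useHash <- config$use_hashing %||% (ncol(umiCounts(dat$hashUmis)) > 0)
    if (isTRUE(useHash) && ncol(umiCounts(dat$hashUmis)) > 0) {
        hl <- assignHashSinglets(dat$hashUmis)
        cells <- intersect(cells, names(hl))
    }
    note("hash_singlets", length(cells))

    ## stage 3: mito / gene filters
    expr <- dat$expression[cells, ]
    mito <- computeMitoFraction(expr, mitoPrefix)
    fg <- filterCellsGenes(expr, mito, mitoMax = mitoMax)
    cells <- fg$cells
    note("mito_filter", length(cells))

    ## stage 4: guide assignment on retained cells
    assignment <- assignGuides(dat$guideUmis[cells, ], dat$library)
    cells <- dropUnassignedCells(assignment)
    note("guide_detected", length(cells))

    ## stage 5: cluster annotation + small-cluster filter
    labels <- dat$states[cells]
    keptClusters <- filterSmallClusters(labels, minClusterFrac)
    keptClusters <- intersect(config$clusters %||% keptClusters, keptClusters)
    cells <- cells[labels %in% keptClusters]
    labels <- dat$states[cells]
    note("cluster_filter", length(cells))

    ## stage 6: layers
    layers <- makeLayers(dat$expression[cells, fg$genes])

    ## stage 7: guide QC
    qc <- qcGuides(assignment, labels, dat$library, keptClusters, alpha)
    ntBgCells <- intersect(
        setdiff(cellsWithGuide(assignment, qc$ntBackgroundGuides),
                cellsWithGuide(assignment,
                               setdiff(guideIds(dat$library),
                                       ntGuides(dat$library)))),
        cells)

    ## stage 8: per-target statistics
    ## trajectory order of the retained clusters, by median pseudotime
    ordered <- keptClusters[order(vapply(keptClusters, function(s)
        stats::median(dat$pseudotime[cells[labels == s]]), numeric(1)))]
    lateState <- utils::tail(ordered, 1)
    lateGenes <- character()
    if (length(ordered) >= 2 &&
        min(table(labels)[ordered[length(ordered) - 1:0]]) >= 3) {
        ps <- pairwiseStateGenes(layers@logLayer, labels,
                                 ordered[length(ordered)],
                                 ordered[length(ordered) - 1])
        lateGenes <- ps$genesA
    }
    enrichRows <- list(); shiftRows <- list(); gsRows <- list()
    for (tgt in targetIds(dat$library)) {
        g <- intersect(intersect(guidesForTarget(dat$library, tgt),
                                 qc$retainedGuides),
                       colnames(assignment@adjusted))
        tCells <- intersect(cellsWithGuide(assignment, g), cells)
        if (!length(tCells) || !length(ntBgCells)) next
        et <- hypergeomClusterTest(tCells, ntBgCells, labels, keptClusters)
        et <- cbind(target = tgt, et, stringsAsFactors = FALSE)
        enrichRows[[tgt]] <- et
        sh <- pseudotimeShiftTest(dat$pseudotime[tCells],
                                  dat$pseudotime[ntBgCells])
        shiftRows[[tgt]] <- data.frame(
            target = tgt, n_target = length(tCells),
            n_background = length(ntBgCells), U = sh$U, p = sh$p,
            median_diff = sh$medianDiff, stringsAsFactors = FALSE)
        if (length(lateGenes) && length(lateState)) {
            pLate <- tCells[labels[tCells] == lateState]
            cLate <- ntBgCells[labels[ntBgCells] == lateState]
            if (length(pLate) >= 1 && length(cLate) >= length(pLate)) {
                zt <- genesetResamplingZtest(layers@logLayer, lateGenes,
                                             pLate, cLate, nIter = nIter,
                                             seed = seed)
                gsRows[[tgt]] <- data.frame(
                    target = tgt, gene_set = "late_state",
                    n_perturbed = zt$nPerturbed,
                    observed_mean = zt$observedMean, null_mean = zt$nullMean,
                    null_sd = zt$nullSd, z = zt$z, p_enrich = zt$pEnrich,
                    p_deplete = zt$pDeplete, stringsAsFactors = FALSE)
            }
        }
    }
    enrich <- if (length(enrichRows)) do.call(rbind, c(enrichRows,
        list(make.row.names = FALSE))) else data.frame()
    if (nrow(enrich))
        enrich$p_deplete_bh <- stats::p.adjust(enrich$p_deplete, "BH")
    shifts <- if (length(shiftRows)) do.call(rbind, c(shiftRows,
        list(make.row.names = FALSE))) else data.frame()
    genesets <- if (length(gsRows)) do.call(rbind, c(gsRows,
        list(make.row.names = FALSE))) else data.frame()

    ## artifacts
    writeTsv(assignmentTable(assignment), file.path(outDir, "assignments.tsv"))
    writeTsv(kneeReport(assignment), file.path(outDir, "knee_report.tsv"))
    writeTsv(qc$report, file.path(outDir, "guide_qc.tsv"))
    if (nrow(enrich)) writeTsv(enrich, file.path(outDir, "enrichment.tsv"))
    if (nrow(shifts)) writeTsv(shifts, file.path(outDir, "pseudotime_shift.tsv"))
    if (nrow(genesets)) writeTsv(genesets, file.path(outDir, "geneset_ztest.tsv"))

    report <- list(
        meta = list(package = "screenkit",
                    version = as.character(utils::packageVersion("screenkit")),
                    seed = seed, alpha = alpha, n_iter = nIter,
                    clusters = as.list(keptClusters)),
        cell_ledger = ledger,
        guide_qc = list(nt_background = as.list(qc$ntBackgroundGuides),
                        nt_removed = as.list(as.character(qc$ntRemoved)),
                        retained_guides = as.list(sort(qc$retainedGuides))),
        late_gene_set = as.list(sort(lateGenes)),
        enrichment = enrich, pseudotime_shift = shifts,
        geneset_ztest = genesets)
    writeJsonReport(report, file.path(outDir, "report.json"))
    invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check a pipeline report against the packaged JSON schema
#'
#' Verifies the structural contract of `report.json`: all properties the
#' packaged schema marks as required are present, with the expected JSON
#' types at the top level.
#'
#' @param report a report list (from [runPipeline()]) or a path to a
#'   report JSON file.
#' @return TRUE invisibly; otherwise an error naming the missing field.
#' @export
validateReportSchema <- function(report) {
    if (is.character(report)) report <- jsonlite::read_json(report)
    schema <- jsonlite::read_json(system.file("schema",
        "screen_report.schema.json", package = "screenkit"))
    missing <- setdiff(unlist(schema$required), names(report))
    if (length(missing))
        stop("report is missing required fields: ",
             paste(missing, collapse = ", "))
    for (nm in names(schema$properties)) {
        tp <- schema$properties[[nm]]$type
        if (nm %in% names(report) && tp == "object" &&
            !is.list(report[[nm]]) && !is.data.frame(report[[nm]]))
            stop("report field '", nm, "' must be an object")
    }
    invisible(TRUE)
}
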