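#' Debias the non-targeting control background
#'
#' A non-targeting (NT) guide that itself lands in a biased cell-state
#' distribution would corrupt the control background used by every
#' downstream test. Each NT guide's cluster distribution is tested
#' against the pool of cells carrying any retained NT guide with a
#' two-tailed hypergeometric test per cluster; p-values are Bonferroni
#' corrected over (clusters x 2 tails x number of NT guides). Flagged
#' guides are removed iteratively, most significant first, retesting the
#' shrunken pool after each removal, until none are flagged or only two
#' NT guides remain.
#'
#' @param assignment a [GuideAssignment-class].
#' @param labels named cluster labels; only labeled cells are used.
#' @param ntGuideIds character vector of NT guide ids (>= 2).
#' @param clusters clusters over which distributions are compared
#'   (default: all labels).
#' @param alpha significance threshold after correction (default 0.05).
#' @return Character vector of retained NT guide ids; removed guides are
#'   recorded in the `removed` attribute.
#' @export
debiasNtBackground <- function(assignment, labels, ntGuideIds,
                               clusters = NULL, alpha = 0.05) {
    if (length(ntGuideIds) < 2)
        stop("need at least 2 NT guides to define a background")
    if (is.null(clusters)) clusters <- sort(unique(labels))
    labeled <- names(labels)[labels %in% clusters]
    current <- ntGuideIds
    removed <- character()
    repeat {
        if (length(current) <= 2) break
        pool <- intersect(cellsWithGuide(assignment, current), labeled)
        if (!length(pool)) break
        poolLab <- labels[pool]
        minP <- vapply(current, function(g) {
            cg <- intersect(cellsWithGuide(assignment, g), pool)
            if (!length(cg)) return(1)
            n <- length(cg); N <- length(pool)
            min(vapply(clusters, function(cl) {
                K <- sum(poolLab == cl)
                k <- sum(labels[cg] == cl)
                min(stats::phyper(k, K, N - K, n),
                    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
            }, numeric(1)))
        }, numeric(1))
        bonf <- length(clusters) * 2 * length(current)
        adj <- pmin(minP * bonf, 1)
        if (!any(adj < alpha)) break
        worst <- current[which.min(adj)]
        removed <- c(removed, worst)
        current <- setdiff(current, worst)
    }
    structure(current, removed = removed)
}

## All 2^k - 1 non-empty guide subsets, ordered by size then by
## lexicographic guide ids within size.
.guideCombos <- function(guides) {
    guides <- sort(guides)
    out <- list()
    for (s in seq_along(guides))
        out <- c(out, utils::combn(guides, s, simplify = FALSE))
    out
}

#' Hypergeometric p-value lists over all guide combinations of a target
#'
#' For every non-empty subset of a target's guides, the cells carrying
#' any subset guide are pooled and compared with the NT background by a
#' hypergeometric test in every trajectory cluster. This yields
#' 2 x |clusters| p-value lists (depletion and enrichment per cluster),
#' each sorted in descending order of significance (ascending p) with
#' ties broken by the subset enumeration order (size, then lexicographic
#' guide ids). Subsets whose pooled cell set is empty get p = 1 in both
#' directions so they can never sort left.
#'
#' @param targetGuides the target's guide ids (k >= 2; fewer returns
#'   `NULL`, a skip signal exempting the target from filtering).
#' @param assignment a [GuideAssignment-class].
#' @param labels named cluster labels.
#' @param ntBackgroundCells cell barcodes of the debiased NT background.
#' @param clusters clusters to test (default: all labels).
#' @return A list with `combos` (list of guide-id vectors) and `lists`:
#'   one data.frame (`combo` index, `p`) per (cluster x direction),
#'   named `<cluster>.deplete` / `<cluster>.enrich`; or `NULL` when
#'   k < 2.
#' @export
enumerateCombinationPvalues <- function(targetGuides, assignment, labels,
                                        ntBackgroundCells, clusters = NULL) {
    if (length(targetGuides) < 2) return(NULL)
    if (!length(ntBackgroundCells)) stop("NT background is empty")
    if (is.null(clusters)) clusters <- sort(unique(labels))
    labeled <- names(labels)[labels %in% clusters]
    combos <- .guideCombos(targetGuides)
    bg <- intersect(ntBackgroundCells, labeled)
    pmat <- array(NA_real_, c(length(combos), length(clusters), 2),
                  dimnames = list(NULL, clusters, c("deplete", "enrich")))
    for (ci in seq_along(combos)) {
        cells <- intersect(cellsWithGuide(assignment, combos[[ci]]), labeled)
        bgi <- setdiff(bg, cells)
        if (!length(cells) || !length(bgi)) {
            pmat[ci, , ] <- 1
            next
        }
        n <- length(cells); N <- n + length(bgi)
        for (cl in clusters) {
            k <- sum(labels[cells] == cl)
            K <- k + sum(labels[bgi] == cl)
            pmat[ci, cl, "deplete"] <- stats::phyper(k, K, N - K, n)
            pmat[ci, cl, "enrich"] <- stats::phyper(k - 1, K, N - K, n,
                                                    lower.tail = FALSE)
        }
    }
    lists <- list()
    for (cl in clusters) for (dir in c("deplete", "enrich")) {
        p <- pmat[, cl, dir]
        ord <- order(p, seq_along(p))  # stable: ties keep enumeration order
        lists[[paste(cl, dir, sep = ".")]] <-
            data.frame(combo = ord, p = p[ord])
    }
    list(combos = combos, lists = lists)
}

#' Flag uniquely biased guides from combination p-value lists
#'
#' In each sorted p-value list a cutoff is drawn at `2^(k-1)` - the
#' number of combinations that contain any fixed guide. For each guide,
#' the number of top-cutoff combinations containing it is scored for
#' over-representation with a hypergeometric tail
#' `P(X >= count)`, `X ~ Hypergeom(N = 2^k - 1, K = 2^(k-1),
#' n = 2^(k-1))`. A guide is flagged by a list only when its
#' over-representation is significant *and* it is the only guide flagged
#' in that list (uniquely biased). The union of flags over all lists
#' forms the removal candidates; if strictly more than half of the
#' target's guides are candidates, all guides are kept.
#'
#' Because a target's combination p-values are strongly dependent (every
#' subset containing a guide shares that guide's cells), the guide with
#' the largest random deviation tends to monopolize the top of a list
#' even under the null, where its underlying p-values are unremarkable.
#' The default `method = "corrected"` therefore (1) Bonferroni-corrects
#' the over-representation threshold across the lists and (2) requires
#' the flagged guide's most significant combination in that list to pass
#' `alpha / (n_lists * n_combinations)` - i.e. there must be genuine
#' distributional signal, not just a noise-ordered monopoly.
#' `method = "literal"` applies the unadjusted threshold `alpha` with no
#' signal gate; it is kept for comparison but removes a guide from a
#' large fraction of perfectly exchangeable targets at k = 4.
#'
#' @param pvalueLists result of [enumerateCombinationPvalues()].
#' @param alpha significance level (default 0.05).
#' @param method `"corrected"` (default) or `"literal"`, see Details.
#' @return List with `removed` (guide ids), `candidates`, `keptAll`
#'   (logical) and `perList` (data.frame of per-list counts, p-values
#'   and flags).
#' @export
flagBiasedGuides <- function(pvalueLists, alpha = 0.05,
                             method = c("corrected", "literal")) {
    method <- match.arg(method)
    combos <- pvalueLists$combos
    guides <- sort(unique(unlist(combos)))
    k <- length(guides)
    cutoff <- 2^(k - 1)
    Ntot <- 2^k - 1
    nLists <- length(pvalueLists$lists)
    thrCount <- if (method == "corrected") alpha / nLists else alpha
    thrSignal <- if (method == "corrected") alpha / (nLists * Ntot) else 1
    perList <- list()
    candidates <- character()
    for (nm in names(pvalueLists$lists)) {
        lst <- pvalueLists$lists[[nm]]
        top <- lst$combo[seq_len(min(cutoff, nrow(lst)))]
        inTop <- vapply(guides, function(g)
            vapply(combos[top], function(cc) g %in% cc, logical(1)),
            logical(length(top)))
        inTop <- matrix(inTop, nrow = length(top))
        counts <- colSums(inTop)
        pOver <- stats::phyper(counts - 1, cutoff, Ntot - cutoff, cutoff,
                               lower.tail = FALSE)
        bestP <- vapply(seq_along(guides), function(j)
            if (any(inTop[, j])) min(lst$p[seq_along(top)][inTop[, j]]) else 1,
            numeric(1))
        sig <- pOver < thrCount & bestP < thrSignal
        uniquely <- if (sum(sig) == 1) guides[sig] else character()
        candidates <- union(candidates, uniquely)
        perList[[nm]] <- data.frame(list = nm, guide = guides, count = counts,
                                    p_over = pOver, best_p = bestP,
                                    flagged = sig, stringsAsFactors = FALSE)
    }
    keptAll <- length(candidates) > k / 2
    list(removed = if (keptAll) character() else sort(candidates),
         candidates = sort(candidates), keptAll = keptAll,
         perList = do.call(rbind, perList))
}

#' Per-target sgRNA quality filtration
#'
#' Runs the full two-stage guide filtration: (1) debias the NT control
#' background with [debiasNtBackground()]; (2) for every target with at
#' least two guides, remove uniquely biased guides via
#' [enumerateCombinationPvalues()] and [flagBiasedGuides()].
#'
#' @param assignment a [GuideAssignment-class].
#' @param labels named cluster labels (trajectory cells only).
#' @param library a [GuideLibrary-class].
#' @param clusters clusters over which distributions are compared.
#' @param alpha significance threshold (default 0.05).
#' @return List with `retainedGuides`, `ntBackgroundGuides`,
#'   `ntRemoved`, and `report`: one row per target (guides tested,
#'   combinations evaluated, removed guides, kept_all flag).
#' @export
qcGuides <- function(assignment, labels, library, clusters = NULL,
                     alpha = 0.05) {
    nt <- ntGuides(library)
    ntKept <- debiasNtBackground(assignment, labels, nt, clusters, alpha)
    targeting <- setdiff(guideIds(library), nt)
    ntBgCells <- setdiff(cellsWithGuide(assignment, ntKept),
                         cellsWithGuide(assignment, targeting))
    rows <- list()
    removedAll <- character()
    for (tgt in targetIds(library)) {
        g <- intersect(guidesForTarget(library, tgt),
                       colnames(assignment@adjusted))
        pv <- enumerateCombinationPvalues(g, assignment, labels, ntBgCells,
                                          clusters)
        if (is.null(pv)) {
            rows[[tgt]] <- data.frame(target = tgt, n_guides = length(g),
                                      n_combinations = 0L, removed = "",
                                      kept_all = FALSE, skipped = TRUE,
                                      stringsAsFactors = FALSE)
            next
        }
        fl <- flagBiasedGuides(pv, alpha)
        removedAll <- c(removedAll, fl$removed)
        rows[[tgt]] <- data.frame(target = tgt, n_guides = length(g),
                                  n_combinations = length(pv$combos),
                                  removed = paste(fl$removed, collapse = ","),
                                  kept_all = fl$keptAll, skipped = FALSE,
                                  stringsAsFactors = FALSE)
    }
    report <- if (length(rows))
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else data.frame(target = character(), n_guides = integer(),
                    n_combinations = integer(), removed = character(),
                    kept_all = logical(), skipped = logical(),
                    stringsAsFactors = FALSE)
    list(retainedGuides = c(setdiff(targeting, removedAll), ntKept),
         ntBackgroundGuides = as.character(ntKept),
         ntRemoved = attr(ntKept, "removed"),
         report = report)
}
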