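#' @include AllClasses.R io.R biomarkers.R abundance.R differential.R cluster.R predict.R
NULL

.asLogicalFlag <- function(x) {
    if (is.logical(x)) return(x)
    tolower(as.character(x)) %in% c("true", "1", "yes")
}

#' Read a pipeline configuration file
#'
#' Parses a simple \code{key = value} file (one setting per line,
#' \code{#} comments allowed).  Recognized keys mirror the arguments of
#' [runPipeline()]: \code{alignment}, \code{counts}, \code{metadata},
#' \code{out_dir}, \code{orders} (comma-separated), \code{ld_prune},
#' \code{across_orders}, \code{keep_universal}, \code{mode},
#' \code{n_iterations}, \code{fdr_cutoff}, \code{linkage},
#' \code{cluster_k}, \code{predict}, \code{n_repeats},
#' \code{test_fraction}, \code{seed}, \code{threads}.
#'
#' @param path configuration file
#' @return named list of parsed settings
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("no such config file: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
    bad <- lines[lengths(kv) == 0L]
    if (length(bad)) stop("unparseable config line: '", bad[1L], "'")
    cfg <- stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
    cfg <- lapply(cfg, trimws)
    num <- intersect(names(cfg), c("n_iterations", "fdr_cutoff",
                                   "test_fraction"))
    for (k in num) cfg[[k]] <- as.numeric(cfg[[k]])
    int <- intersect(names(cfg), c("seed", "threads", "n_repeats",
                                   "cluster_k"))
    for (k in int) cfg[[k]] <- as.integer(cfg[[k]])
    flg <- intersect(names(cfg), c("ld_prune", "across_orders",
                                   "keep_universal", "predict"))
    for (k in flg) cfg[[k]] <- .asLogicalFlag(cfg[[k]])
    if ("orders" %in% names(cfg))
        cfg$orders <- as.integer(strsplit(cfg$orders, ",")[[1L]])
    cfg
}

#' Run the full SBB pipeline
#'
#' Orchestrates validate, extract, aggregate, test, cluster and
#' (optionally) predict, writing each stage's outputs plus a JSON run
#' manifest to \code{outDir}.  All randomness derives from the single
#' \code{seed} via fixed per-stage offsets, so a re-run with the same
#' inputs and settings reproduces every output.  On a stage error the
#' pipeline aborts naming the stage, leaving earlier outputs in place next
#' to a \code{FAILED} marker file.
#'
#' @param alignment aligned FASTA path or an [AlignedSeqSet-class]
#' @param counts count-table path (TSV) or a [CountTable-class]
#' @param metadata metadata path (TSV) or a [StudyDesign-class]
#' @param outDir output directory (created if needed)
#' @param orders biomarker orders to extract, a subset of \code{1:3}
#' @param ldPrune,acrossOrders,keepUniversal see [extractBiomarkers()]
#' @param mode force \code{"paired"}/\code{"unpaired"}; NULL keeps the
#'   metadata's mode (forcing unpaired drops the pair ids)
#' @param nIterations permutations for the null (default 100,000)
#' @param fdrCutoff significance threshold for reporting and clustering
#' @param linkage,clusterK clustering parameters (see [clusterBiomarkers()])
#' @param predict run the phenotype-prediction benchmark
#' @param nRepeats,testFraction see [evaluatePrediction()]
#' @param seed master seed
#' @param threads see [buildNullDistribution()]
#' @return (invisibly) a list with the in-memory stage results and the
#'   manifest
#' @export
runPipeline <- function(alignment, counts, metadata, outDir,
                        orders = c(1L, 2L), ldPrune = TRUE,
                        acrossOrders = TRUE, keepUniversal = FALSE,
                        mode = NULL, nIterations = 1e5, fdrCutoff = 0.1,
                        linkage = "average", clusterK = NULL,
                        predict = TRUE, nRepeats = 100L,
                        testFraction = 0.2, seed = 1L, threads = 1L) {
    orders <- unique(as.integer(orders))
    if (length(orders) == 0L || anyNA(orders) || !all(orders %in% 1:3))
        stop("orders must be a non-empty subset of {1, 2, 3}")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    failMarker <- file.path(outDir, "FAILED")
    if (file.exists(failMarker)) unlink(failMarker)
    timings <- list()
    stage <- function(name, expr) {
        t0 <- proc.time()[["elapsed"]]
        out <- tryCatch(expr, error = function(e) {
            writeLines(sprintf("stage '%s' failed: %s", name,
                               conditionMessage(e)), failMarker)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE)
        })
        timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
        out
    }

    inputs <- stage("load", {
        seqs <- if (is(alignment, "AlignedSeqSet")) alignment
                else readAlignedFasta(alignment)
        ct <- if (is(counts, "CountTable")) counts else readCountTable(counts)
        des <- if (is(metadata, "StudyDesign")) metadata
               else readMetadata(metadata)
        if (!is.null(mode) && mode != des@mode) {
            des <- if (mode == "unpaired")
                StudyDesign(des@sampleIds, des@phenotype,
                            familyId = des@familyId, mode = "unpaired")
            else stop("cannot force paired mode without pair ids")
        }
        list(seqs = seqs, counts = ct, design = des)
    })
    stage("validate", validateDataset(inputs$seqs, inputs$counts,
                                      inputs$design))

    ext <- stage("extract", {
        e <- extractBiomarkers(inputs$seqs, orders = orders,
                               prune = ldPrune, acrossOrders = acrossOrders,
                               keepUniversal = keepUniversal)
        writeBiomarkerMembership(e$biomarkers,
                                 file.path(outDir, "biomarkers.tsv"))
        if (!is.null(e$classes))
            utils::write.table(e$classes,
                               file.path(outDir, "ld_classes.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        e
    })

    ga <- stage("aggregate", {
        g <- aggregateByGroup(relAbundance(inputs$counts), ext$biomarkers)
        writeGroupAbundance(g, file.path(outDir, "group_abundance.tsv"))
        g
    })

    res <- stage("test", {
        r <- sbbDiffAbundance(ga, inputs$design, nIterations = nIterations,
                              seed = seed, threads = threads)
        utils::write.table(resultTable(r),
                           file.path(outDir, "results.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(fdrCurve(r),
                           file.path(outDir, "fdr_curve.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        r
    })

    clust <- stage("cluster", {
        sm <- withCallingHandlers(
            significantBiomarkers(res, ext$biomarkers, fdrCutoff),
            warning = function(w) invokeRestart("muffleWarning"))
        if (nrow(sm) >= 2L) {
            ca <- clusterBiomarkers(sm, linkage = linkage, k = clusterK)
            mrg <- ca@biomarkerTree$merge
            utils::write.table(
                data.frame(step = seq_len(nrow(mrg)),
                           child1 = mrg[, 1L], child2 = mrg[, 2L],
                           height = ca@biomarkerTree$height),
                file.path(outDir, "cluster_linkage.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
            if (length(ca@biomarkerClusters))
                utils::write.table(
                    data.frame(biomarker = names(ca@biomarkerClusters),
                               cluster = ca@biomarkerClusters),
                    file.path(outDir, "cluster_assignment.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
            ca
        } else NULL
    })

    pred <- if (predict) stage("predict", {
        p <- evaluatePrediction(ga, inputs$design, nRepeats = nRepeats,
                                testFraction = testFraction,
                                seed = seed + 1L)
        utils::write.table(
            data.frame(repeat_index = seq_along(aucValues(p)),
                       auc = aucValues(p)),
            file.path(outDir, "prediction_auc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
            list(median_auc = medianAuc(p), sd_auc = sdAuc(p),
                 n_repeats = p@nRepeats, test_fraction = p@testFraction),
            file.path(outDir, "prediction_summary.json"),
            auto_unbox = TRUE, digits = NA)
        p
    }) else NULL

    manifest <- list(
        package = "SBBtools",
        version = as.character(utils::packageVersion("SBBtools")),
        parameters = list(orders = orders, ld_prune = ldPrune,
                          across_orders = acrossOrders,
                          keep_universal = keepUniversal,
                          mode = inputs$design@mode,
                          n_iterations = nIterations,
                          fdr_cutoff = fdrCutoff, linkage = linkage,
                          cluster_k = clusterK, predict = predict,
                          n_repeats = nRepeats,
                          test_fraction = testFraction, threads = threads),
        seeds = list(master = seed, test = seed, predict = seed + 1L),
        n_asvs = length(inputs$seqs),
        n_samples = length(sampleIds(inputs$design)),
        n_biomarkers = ncol(membership(ext$biomarkers)),
        n_significant = sum(resultTable(res)$fdr < fdrCutoff),
        stage_seconds = timings,
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(list(inputs = inputs, extraction = ext, groupAbundance = ga,
                   result = res, clustering = clust, prediction = pred,
                   manifest = manifest))
}
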