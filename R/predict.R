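#' @include AllClasses.R
NULL

#' Phenotype-prediction benchmark with repeated train/test splits
#'
#' Evaluates a group-abundance feature table for host-phenotype prediction
#' with a random-forest classifier (100 trees, otherwise default
#' parameters) under \code{nRepeats} random train/test splits (default
#' 100 repeats of 80\%/20\%).  Each repeat records the held-out ROC curve
#' and ROC-AUC; the evaluation reports the median AUC with a +/- 1
#' standard-deviation interval and a pointwise-median ROC band on a fixed
#' false-positive-rate grid.
#'
#' In paired designs both members of a pair travel to the same side of the
#' split (set \code{respectPairs = FALSE} to disable this leakage guard).
#' A split that leaves the test set with a single class is redrawn with a
#' warning.  Each repeat's result depends only on (\code{seed}, repeat
#' index), so repeats are reproducible independently of each other.
#'
#' @param ga a [GroupAbundanceTable-class] (features = group abundances)
#' @param design a [StudyDesign-class]
#' @param nRepeats number of random splits
#' @param testFraction held-out fraction of samples (or of pairs)
#' @param seed integer seed; NULL uses the current RNG state
#' @param respectPairs keep pairs on one side of the split
#' @param nTrees trees per forest
#' @return a [PredictionEvaluation-class]
#' @export
evaluatePrediction <- function(ga, design, nRepeats = 100L,
                               testFraction = 0.2, seed = NULL,
                               respectPairs = TRUE, nTrees = 100L) {
    stopifnot(is(ga, "GroupAbundanceTable"), is(design, "StudyDesign"))
    .checkDesignSize(design)
    M <- assay(ga, "groupabund")
    loc <- match(design@sampleIds, colnames(M))
    if (anyNA(loc)) stop("design samples missing from the abundance table")
    X <- t(M[, loc, drop = FALSE])
    colnames(X) <- make.names(rownames(M))   # model-safe feature names
    y <- factor(design@phenotype, levels = c("control", "case"))
    n <- nrow(X)

    if (!is.null(seed)) set.seed(seed)
    repeatSeeds <- sample.int(2^31 - 2, nRepeats)

    byPair <- respectPairs && design@mode == "paired"
    if (byPair) {
        pid <- factor(design@pairId, levels = unique(design@pairId))
        pairMembers <- split(seq_len(n), pid)
        nUnits <- nlevels(pid)
    } else {
        nUnits <- n
    }
    nTestUnits <- max(1L, round(nUnits * testFraction))
    if (nTestUnits >= nUnits) stop("testFraction leaves no training data")

    fprGrid <- seq(0, 1, by = 0.01)
    aucs <- numeric(nRepeats)
    tprMat <- matrix(NA_real_, nRepeats, length(fprGrid))
    for (r in seq_len(nRepeats)) {
        set.seed(repeatSeeds[r])
        for (attempt in seq_len(100L)) {
            testUnits <- sample.int(nUnits, nTestUnits)
            testIdx <- if (byPair) unlist(pairMembers[testUnits]) else testUnits
            if (length(unique(y[testIdx])) == 2L &&
                length(unique(y[-testIdx])) == 2L) break
            if (attempt == 100L)
                stop("could not draw a two-class train/test split")
            warning("split left one class empty; resampling")
        }
        rf <- randomForest::randomForest(x = X[-testIdx, , drop = FALSE],
                                         y = y[-testIdx], ntree = nTrees)
        score <- stats::predict(rf, X[testIdx, , drop = FALSE],
                                type = "prob")[, "case"]
        ro <- pROC::roc(response = y[testIdx], predictor = score,
                        levels = c("control", "case"), direction = "<",
                        quiet = TRUE)
        aucs[r] <- as.numeric(pROC::auc(ro))
        fpr <- 1 - ro$specificities
        tpr <- ro$sensitivities
        ord <- order(fpr, tpr)
        tprMat[r, ] <- stats::approx(fpr[ord], tpr[ord], xout = fprGrid,
                                     method = "constant", f = 0, rule = 2,
                                     ties = max)$y
    }
    tprMed <- apply(tprMat, 2L, stats::median)
    tprSd <- apply(tprMat, 2L, stats::sd)
    roc <- data.frame(fpr = fprGrid, tpr_median = tprMed,
                      tpr_lo = pmax(0, tprMed - tprSd),
                      tpr_hi = pmin(1, tprMed + tprSd))
    new("PredictionEvaluation", auc = aucs, roc = roc,
        nRepeats = as.integer(nRepeats), testFraction = testFraction,
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}
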