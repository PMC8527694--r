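#' @include AllClasses.R
NULL

#' Read a multiple-sequence-aligned FASTA file
#'
#' Reads equal-width aligned ASV sequences.  Case is normalized, U is
#' mapped to T, and ambiguity characters (plus \code{.}) are mapped to the
#' gap state, so downstream biomarker extraction only ever sees
#' \code{A,C,G,T,-}.
#'
#' @param path path to an aligned FASTA file
#' @return an [AlignedSeqSet-class]; record order is preserved
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a1", "ACG", ">a2", "A-G"), fa)
#' readAlignedFasta(fa)
#' @export
readAlignedFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    x <- Biostrings::readBStringSet(path)
    if (length(x) == 0L) stop("empty FASTA input: ", path)
    ids <- sub("\\s.*$", "", names(x))
    if (anyDuplicated(ids))
        stop("duplicate FASTA header: '", ids[duplicated(ids)][1L], "'")
    names(x) <- ids
    w <- Biostrings::width(x)
    if (length(unique(w)) != 1L)
        stop(sprintf(
            "ragged alignment widths (%d vs %d); first offending record: '%s'",
            w[1L], w[w != w[1L]][1L], ids[which(w != w[1L])[1L]]))
    AlignedSeqSet(x)
}

#' Write an AlignedSeqSet as FASTA
#'
#' @param seqs an [AlignedSeqSet-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeAlignedFasta <- function(seqs, path) {
    Biostrings::writeXStringSet(seqs, path, width = 20000L)
    invisible(path)
}

#' Read an ASV count table
#'
#' Reads a tab-separated table (first column = ASV id, header = sample ids)
#' or a BIOM-format JSON file (sparse or dense, via \pkg{biomformat}).
#' Cells must be non-negative integers and every sample must have a
#' positive total count.
#'
#' @param path input path
#' @param format \code{"tsv"} or \code{"biom-json"}
#' @param transpose set TRUE when the file is samples x ASVs (both
#'   orientations occur in the wild); applies to the TSV reader
#' @return a [CountTable-class], ASVs x samples
#' @export
readCountTable <- function(path, format = c("tsv", "biom-json"),
                           transpose = FALSE) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("no such file: ", path)
    if (format == "tsv") {
        df <- utils::read.delim(path, check.names = FALSE,
                                stringsAsFactors = FALSE)
        if (ncol(df) < 2L) stop("count table needs a label column plus >= 1 sample")
        m <- as.matrix(df[, -1L, drop = FALSE])
        rownames(m) <- as.character(df[[1L]])
        if (transpose) m <- t(m)
    } else {
        b <- biomformat::read_biom(path)
        m <- as.matrix(biomformat::biom_data(b))
    }
    storage.mode(m) <- "double"
    bad <- which(!is.finite(m) | m < 0 | m != round(m))
    if (length(bad)) {
        rc <- arrayInd(bad[1L], dim(m))
        stop(sprintf("count at (%s, %s) is not a non-negative integer",
                     rownames(m)[rc[1L]], colnames(m)[rc[2L]]))
    }
    tot <- colSums(m)
    if (any(tot == 0))
        stop("sample '", colnames(m)[which(tot == 0)[1L]],
             "' has zero total count")
    CountTable(m)
}

#' Write a CountTable as TSV
#'
#' @param counts a [CountTable-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeCountTable <- function(counts, path) {
    m <- assay(counts, "counts")
    df <- data.frame(asv_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read sample metadata into a StudyDesign
#'
#' Expects a tab-separated file with columns \code{sample_id} and
#' \code{phenotype} (values \code{case}/\code{control}), and optionally
#' \code{pair_id} and \code{family_id}.  The design mode is inferred as
#' paired iff \code{pair_id} is present and fully populated.
#'
#' @param path metadata TSV path
#' @return a [StudyDesign-class]
#' @export
readMetadata <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c("sample_id", "phenotype")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stop("metadata lacks column(s): ",
                           paste(miss, collapse = ", "))
    pid <- if ("pair_id" %in% colnames(df)) as.character(df$pair_id) else NULL
    if (!is.null(pid)) pid[pid == ""] <- NA_character_
    fid <- if ("family_id" %in% colnames(df)) as.character(df$family_id) else NULL
    if (!is.null(fid)) fid[fid == ""] <- NA_character_
    mode <- if (!is.null(pid) && !anyNA(pid)) "paired" else "unpaired"
    if (mode == "unpaired") pid <- NULL
    StudyDesign(df$sample_id, df$phenotype, pairId = pid, familyId = fid,
                mode = mode)
}

#' Write a StudyDesign as metadata TSV
#'
#' @param design a [StudyDesign-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeMetadata <- function(design, path) {
    df <- data.frame(sample_id = design@sampleIds,
                     phenotype = design@phenotype,
                     stringsAsFactors = FALSE)
    if (!all(is.na(design@pairId))) df$pair_id <- design@pairId
    if (!all(is.na(design@familyId))) df$family_id <- design@familyId
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Cross-validate alignment, counts and metadata
#'
#' Confirms that every counted ASV has an aligned sequence (hard error
#' otherwise: no biomarkers can be extracted for it), that count and design
#' sample ids match one-to-one, and warns about aligned ASVs that were
#' never counted (allowed).
#'
#' @param seqs an [AlignedSeqSet-class]
#' @param counts a [CountTable-class]
#' @param design a [StudyDesign-class]
#' @return a list with elements \code{ok} (TRUE) and \code{warnings}
#'   (character vector, possibly empty), invisibly-checkable as a report
#' @export
validateDataset <- function(seqs, counts, design) {
    missingSeq <- setdiff(asvIds(counts), asvIds(seqs))
    if (length(missingSeq))
        stop("ASV(s) in counts missing from alignment: ",
             paste(utils::head(missingSeq, 5L), collapse = ", "))
    if (!setequal(sampleIds(counts), sampleIds(design)) ||
        length(sampleIds(counts)) != length(sampleIds(design)))
        stop("count-table and metadata sample ids do not match one-to-one")
    warnings <- character(0)
    neverCounted <- setdiff(asvIds(seqs), asvIds(counts))
    if (length(neverCounted))
        warnings <- c(warnings, sprintf(
            "%d aligned ASV(s) absent from the count table (first: %s)",
            length(neverCounted), neverCounted[1L]))
    list(ok = TRUE, warnings = warnings,
         nAsvs = length(asvIds(counts)), nSamples = length(sampleIds(counts)))
}

#' Export biomarker membership as TSV
#'
#' One row per (biomarker, carrier ASV): columns \code{biomarker_label},
#' \code{order}, \code{asv_id}.
#'
#' @param bm a [BiomarkerMatrix-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeBiomarkerMembership <- function(bm, path) {
    m <- bm@membership
    tm <- as(m, "TsparseMatrix")
    df <- data.frame(biomarker_label = colnames(m)[tm@j + 1L],
                     order = bm@order[tm@j + 1L],
                     asv_id = rownames(m)[tm@i + 1L],
                     stringsAsFactors = FALSE)
    df <- df[order(match(df$biomarker_label, colnames(m)), df$asv_id), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Export a group-abundance table as TSV
#'
#' @param ga a [GroupAbundanceTable-class]
#' @param path output path
#' @return \code{path}, invisibly
#' @export
writeGroupAbundance <- function(ga, path) {
    m <- assay(ga, "groupabund")
    df <- data.frame(group_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
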