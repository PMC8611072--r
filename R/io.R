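#' Read DHS hotspot intervals from a BED3+ file
#'
#' Coordinates follow the BED convention: half-open, 0-based. An optional
#' 4th column supplies the interval id; otherwise ids are
#' \code{"chrom:start-end"}. Intervals are returned sorted by
#' (chrom, start); rows with identical coordinates are collapsed and the
#' number of collapsed duplicates recorded in
#' \code{S4Vectors::metadata(x)$duplicates} (with a warning).
#'
#' @param path BED file path.
#' @return a \link[GenomicRanges]{GRanges} named by interval id.
#' @export
readHotspotsBed <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty BED file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(nf < 3L)
    if (length(bad))
        stop("malformed BED line ", bad[1L], ": fewer than 3 fields")
    chrom <- vapply(parts, `[[`, "", 1L)
    start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
    badnum <- which(is.na(start) | is.na(end))
    if (length(badnum))
        stop("malformed BED line ", badnum[1L], ": non-numeric coordinates")
    if (any(start < 0))
        stop("malformed BED line ", which(start < 0)[1L],
             ": negative coordinate")
    rev <- which(start >= end)
    if (length(rev))
        stop("BED line ", rev[1L], ": start >= end")
    id <- ifelse(nf >= 4L, vapply(parts, function(p) p[min(4L, length(p))], ""),
                 sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end)))
    key <- paste(chrom, start, end)
    dup <- duplicated(key)
    ndup <- sum(dup)
    if (ndup) {
        warning(ndup, " duplicate interval(s) collapsed")
        chrom <- chrom[!dup]; start <- start[!dup]; end <- end[!dup]
        id <- id[!dup]
    }
    if (anyDuplicated(id))
        stop("interval ids not unique: ",
             paste(head(unique(id[duplicated(id)]), 5L), collapse = ", "))
    ord <- order(chrom, start)
    gr <- GenomicRanges::GRanges(chrom[ord],
        IRanges::IRanges(start = start[ord] + 1L, end = end[ord]))
    names(gr) <- id[ord]
    S4Vectors::metadata(gr)$duplicates <- ndup
    gr
}

#' Read gene TSS annotation from a BED file
#'
#' Expects BED with at least 4 columns (chrom, start, end, gene_id) and an
#' optional 6th strand column (default \code{+}). The TSS is the interval
#' start for \code{+} genes and \code{end - 1} for \code{-} genes (0-based).
#' Genes appearing on multiple rows are canonicalized to the strand-aware
#' most-upstream TSS (smallest coordinate on \code{+}, largest on \code{-}).
#'
#' @param path BED file path.
#' @return a width-1 \link[GenomicRanges]{GRanges} of TSS positions named by
#'   gene id, with strand set.
#' @export
readTssBed <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty TSS BED file: ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 4L))
        stop("malformed TSS BED line ", which(nf < 4L)[1L],
             ": need chrom, start, end, gene_id")
    chrom <- vapply(parts, `[[`, "", 1L)
    start <- as.numeric(vapply(parts, `[[`, "", 2L))
    end <- as.numeric(vapply(parts, `[[`, "", 3L))
    gene <- vapply(parts, `[[`, "", 4L)
    strand <- ifelse(nf >= 6L,
                     vapply(parts, function(p) p[min(6L, length(p))], ""), "+")
    if (!all(strand %in% c("+", "-")))
        stop("strand must be '+' or '-'")
    tss0 <- ifelse(strand == "+", start, end - 1)  # 0-based TSS
    df <- data.frame(gene, chrom, tss0, strand, stringsAsFactors = FALSE)
    pick <- unlist(lapply(split(seq_len(nrow(df)), df$gene), function(i) {
        s <- df$strand[i][1L]
        if (!all(df$strand[i] == s) || !all(df$chrom[i] == df$chrom[i][1L]))
            stop("gene '", df$gene[i][1L],
                 "' annotated on multiple strands/chromosomes")
        if (s == "+") i[which.min(df$tss0[i])] else i[which.max(df$tss0[i])]
    }), use.names = FALSE)
    df <- df[pick, , drop = FALSE]
    gr <- GenomicRanges::GRanges(df$chrom,
        IRanges::IRanges(start = df$tss0 + 1L, width = 1L),
        strand = df$strand)
    names(gr) <- df$gene
    sort(gr)
}

#' Read a feature-by-sample TSV matrix together with its sample sheet
#'
#' The matrix file has a header of sample ids and feature ids in the first
#' column. The sample sheet is a TSV with columns \code{sample_id},
#' \code{donor}, \code{day}. Missing or non-numeric cells are rejected with
#' their (feature, sample) coordinates.
#'
#' @param matrixPath path to the matrix TSV.
#' @param sheetPath path to the sample sheet TSV.
#' @return a \linkS4class{TimeCourseExperiment} with columns ordered by
#'   (day, donor).
#' @export
readMatrixWithSamples <- function(matrixPath, sheetPath) {
    raw <- read.delim(matrixPath, header = TRUE, sep = "\t",
                      check.names = FALSE, colClasses = "character")
    if (ncol(raw) < 2L) stop("matrix needs a feature column plus samples")
    feat <- raw[[1L]]
    vals <- as.matrix(raw[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                   dimnames = dimnames(vals)))
    bad <- which(is.na(num), arr.ind = TRUE)
    if (nrow(bad))
        stop("non-numeric or missing cell at (",
             feat[bad[1L, 1L]], ", ", colnames(vals)[bad[1L, 2L]], ")")
    rownames(num) <- feat
    sheet <- read.delim(sheetPath, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    if (!all(c("sample_id", "donor", "day") %in% colnames(sheet)))
        stop("sample sheet needs columns sample_id, donor, day")
    TimeCourseExperiment(num, sheet)
}

#' Read motif hits and aggregate them per (DHS, TF)
#'
#' Accepts either a pre-intersected TSV with columns
#' \code{dhs_id, tf_name[, hit_count]} or a FIMO-dialect TSV with columns
#' \code{motif_id, sequence_name, start, stop} (genomic, 1-based inclusive
#' as FIMO emits when scanning chromosomes). FIMO hits are assigned to the
#' interval containing the motif midpoint (a midpoint exactly at an
#' interval's BED \code{end} does not overlap); hits covering no interval
#' are dropped and counted in \code{attr(x, "dropped")}.
#'
#' @param path hits TSV path; an empty file yields an empty table.
#' @param intervals \link[GenomicRanges]{GRanges} of DHS intervals (required
#'   for the FIMO dialect).
#' @return data.frame with columns dhs_id, tf_name, hit_count.
#' @export
readFimoHits <- function(path, intervals = NULL) {
    empty <- data.frame(dhs_id = character(), tf_name = character(),
                        hit_count = integer(), stringsAsFactors = FALSE)
    first <- readLines(path, n = 1L)
    if (!length(first) || !nzchar(first)) {
        attr(empty, "dropped") <- 0L
        return(empty)
    }
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "")
    cn <- colnames(tab)
    if (all(c("dhs_id", "tf_name") %in% cn)) {
        cnt <- if ("hit_count" %in% cn) tab$hit_count else rep(1L, nrow(tab))
        if (any(cnt < 0)) stop("negative hit_count")
        out <- aggregate(cnt, list(dhs_id = tab$dhs_id,
                                   tf_name = tab$tf_name), sum)
        names(out)[3L] <- "hit_count"
        out$hit_count <- as.integer(out$hit_count)
        out <- out[order(out$dhs_id, out$tf_name), , drop = FALSE]
        rownames(out) <- NULL
        attr(out, "dropped") <- 0L
        return(out)
    }
    if (all(c("motif_id", "sequence_name", "start", "stop") %in% cn)) {
        if (is.null(intervals))
            stop("FIMO-dialect hits need the DHS intervals")
        if (!nrow(tab)) { attr(empty, "dropped") <- 0L; return(empty) }
        s0 <- tab$start - 1L                    # to 0-based half-open
        e0 <- tab$stop
        mid0 <- floor((s0 + e0 - 1) / 2)        # 0-based midpoint position
        hitGr <- GenomicRanges::GRanges(tab$sequence_name,
            IRanges::IRanges(start = mid0 + 1L, width = 1L))
        ov <- GenomicRanges::findOverlaps(hitGr, intervals, select = "first")
        dropped <- sum(is.na(ov))
        keep <- !is.na(ov)
        if (!any(keep)) {
            attr(empty, "dropped") <- dropped
            return(empty)
        }
        out <- aggregate(rep(1L, sum(keep)),
                         list(dhs_id = names(intervals)[ov[keep]],
                              tf_name = tab$motif_id[keep]), sum)
        names(out)[3L] <- "hit_count"
        out$hit_count <- as.integer(out$hit_count)
        out <- out[order(out$dhs_id, out$tf_name), , drop = FALSE]
        rownames(out) <- NULL
        attr(out, "dropped") <- dropped
        return(out)
    }
    stop("unknown motif-hit dialect; expected columns (dhs_id, tf_name",
         "[, hit_count]) or FIMO columns (motif_id, sequence_name, start, ",
         "stop)")
}

#' Write a table with the package's stable numeric convention
#'
#' Numeric columns are printed with 12 significant digits ('%.12g': plain
#' notation down to 1e-4, '.' decimal), so that writing then reading
#' reproduces values to full printed precision and reruns are
#' byte-identical.
#'
#' @param df data.frame to write.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTable <- function(df, path) {
    out <- df
    for (j in seq_along(out))
        if (is.double(out[[j]])) out[[j]] <- fmtNum(out[[j]])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, eol = "\n")
    invisible(path)
}

#' Read a table written by \code{writeTable}
#' @param path TSV path.
#' @return data.frame.
#' @export
readTable <- function(path)
    read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
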