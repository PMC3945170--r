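#' Island context of a genomic position
#'
#' Classifies positions relative to a set of CpG islands (CGIs) on the
#' same chromosome. A position inside a CGI (boundaries inclusive) is
#' \code{"Island"}; a position within \code{shore_bp} of the nearest CGI
#' boundary is \code{"Shore"} (this single category merges the
#' manufacturer's north/south shores and shelves); anything farther is
#' \code{"OpenSea"}. Distances are in base pairs on 1-based inclusive
#' coordinates, and the boundary distance \code{shore_bp} itself still
#' counts as shore.
#'
#' @param pos integer vector of 1-based positions.
#' @param islands CGIs on the same chromosome: a two-column
#'   matrix/data.frame of (start, end) or a \code{GRanges}. May be empty,
#'   in which case everything is open sea.
#' @param shore_bp shore half-width in bp (default 4000).
#' @return character vector in \code{c("Island","Shore","OpenSea")}.
#' @examples
#' deriveIslandContext(c(500, 4900, 4901), cbind(400, 900))
#' @export
deriveIslandContext <- function(pos, islands, shore_bp = 4000) {
    pos <- as.numeric(pos)
    if (inherits(islands, "GRanges")) {
        islands <- cbind(GenomicRanges::start(islands),
                         GenomicRanges::end(islands))
    }
    islands <- as.matrix(islands)
    out <- rep("OpenSea", length(pos))
    if (nrow(islands) == 0L || length(pos) == 0L) return(out)
    if (any(islands[, 2] < islands[, 1]))
        stop("island end < start")
    starts <- islands[, 1]; ends <- islands[, 2]
    dmin <- rep(Inf, length(pos))
    for (j in seq_along(starts)) {
        d <- pmax(starts[j] - pos, pos - ends[j], 0)
        dmin <- pmin(dmin, d)
    }
    out[dmin <= shore_bp] <- "Shore"
    out[dmin == 0] <- "Island"
    out
}

#' Island context for probes across chromosomes
#'
#' Vectorized wrapper over [deriveIslandContext()]: probes on
#' chromosomes absent from the island set fall in open sea.
#'
#' @param chrom character vector of probe chromosomes.
#' @param pos probe positions (1-based).
#' @param islands data.frame with columns chrom, start, end.
#' @inheritParams deriveIslandContext
#' @return character vector of island contexts, one per probe.
#' @export
probeIslandContext <- function(chrom, pos, islands, shore_bp = 4000) {
    stopifnot(length(chrom) == length(pos))
    out <- rep("OpenSea", length(pos))
    for (ch in unique(chrom)) {
        idx <- which(chrom == ch)
        isl <- islands[islands$chrom == ch, c("start", "end"), drop = FALSE]
        out[idx] <- deriveIslandContext(pos[idx], isl, shore_bp)
    }
    out
}

#' Transcript model
#'
#' A minimal transcript description sufficient for gene-context calls:
#' strand, transcription start site (TSS), gene body, first exon and
#' optional UTRs, all on 1-based inclusive coordinates.
#'
#' @param transcript_id accession string.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param tss 1-based TSS position; must sit at the strand-appropriate
#'   end of the body.
#' @param body_start,body_end gene body interval.
#' @param first_exon_start,first_exon_end first exon, within the body.
#' @param utr5_start,utr5_end,utr3_start,utr3_end optional UTR intervals
#'   (NA when absent).
#' @return a one-row data.frame.
#' @export
transcriptModel <- function(transcript_id, chrom, strand, tss,
                            body_start, body_end,
                            first_exon_start, first_exon_end,
                            utr5_start = NA, utr5_end = NA,
                            utr3_start = NA, utr3_end = NA) {
    stopifnot(strand %in% c("+", "-"),
              body_start >= 1, body_end >= body_start,
              first_exon_start >= body_start, first_exon_end <= body_end,
              first_exon_end >= first_exon_start)
    if (strand == "+" && tss != body_start)
        stop("on '+' strand the TSS must equal body_start")
    if (strand == "-" && tss != body_end)
        stop("on '-' strand the TSS must equal body_end")
    data.frame(transcript_id = transcript_id, chrom = chrom,
               strand = strand, tss = tss,
               body_start = body_start, body_end = body_end,
               first_exon_start = first_exon_start,
               first_exon_end = first_exon_end,
               utr5_start = utr5_start, utr5_end = utr5_end,
               utr3_start = utr3_start, utr3_end = utr3_end,
               stringsAsFactors = FALSE)
}

.inInterval <- function(pos, a, b) {
    !is.na(a) && !is.na(b) && pos >= a && pos <= b
}

#' Gene context of a position relative to one transcript
#'
#' Returns the probe class used throughout the pipeline: within 200 bp
#' upstream of the TSS is \code{"TSS200"}; within 1500 bp (but beyond
#' 200) is \code{"TSS1500"}; inside the body the precedence is first
#' exon, then 5'UTR, then 3'UTR, then \code{"Body"}. "Upstream" is
#' measured against the transcript strand. Positions outside the body
#' and more than 1500 bp upstream get \code{NA} (no link).
#'
#' @param pos 1-based position on the transcript's chromosome.
#' @param tx a transcript model row from [transcriptModel()].
#' @return one of "TSS200","TSS1500","FirstExon","UTR5","UTR3","Body",
#'   or NA_character_.
#' @export
deriveGeneContext <- function(pos, tx) {
    upstream <- if (tx$strand == "+") tx$tss - pos else pos - tx$tss
    if (upstream >= 1 && upstream <= 200) return("TSS200")
    if (upstream >= 201 && upstream <= 1500) return("TSS1500")
    if (.inInterval(pos, tx$body_start, tx$body_end)) {
        if (.inInterval(pos, tx$first_exon_start, tx$first_exon_end))
            return("FirstExon")
        if (.inInterval(pos, tx$utr5_start, tx$utr5_end)) return("UTR5")
        if (.inInterval(pos, tx$utr3_start, tx$utr3_end)) return("UTR3")
        return("Body")
    }
    NA_character_
}

#' Parse the GeneLinks manifest column
#'
#' @param probe_id probe identifiers (recycled against gene_links).
#' @param gene_links character vector of semicolon-delimited
#'   \code{transcript:context} pairs ("" for unlinked probes).
#' @return long data.frame (probe_id, transcript_id, gene_context), zero
#'   rows if no probe is linked.
#' @export
parseGeneLinks <- function(probe_id, gene_links) {
    stopifnot(length(probe_id) == length(gene_links))
    keep <- !is.na(gene_links) & nzchar(gene_links)
    if (!any(keep))
        return(data.frame(probe_id = character(), transcript_id = character(),
                          gene_context = character(), stringsAsFactors = FALSE))
    parts <- strsplit(gene_links[keep], ";", fixed = TRUE)
    n <- lengths(parts)
    flat <- unlist(parts, use.names = FALSE)
    tc <- strsplit(flat, ":", fixed = TRUE)
    bad <- lengths(tc) != 2L
    if (any(bad))
        stop("malformed GeneLinks entry: ", flat[which(bad)[1]])
    tc <- do.call(rbind, tc)
    ctx <- tc[, 2]
    unknown <- !(ctx %in% .CONTEXT_GENE)
    if (any(unknown))
        stop("unknown gene context: ", ctx[which(unknown)[1]])
    data.frame(probe_id = rep(probe_id[keep], n),
               transcript_id = tc[, 1], gene_context = ctx,
               stringsAsFactors = FALSE)
}

.formatGeneLinks <- function(links) {
    # links: long data.frame -> named character vector by probe_id
    if (nrow(links) == 0) return(character())
    vapply(split(links, factor(links$probe_id, levels = unique(links$probe_id))),
           function(d) paste(d$transcript_id, d$gene_context,
                             sep = ":", collapse = ";"),
           character(1))
}

#' Read a probe manifest CSV
#'
#' The manifest has one row per CpG probe with columns \code{ProbeID},
#' \code{Chr}, \code{Pos}, \code{GeneLinks} (semicolon-delimited
#' \code{transcript:context} pairs; empty for unlinked probes),
#' \code{IsCpG} and either a precomputed \code{IslandContext} column or
#' nearest-CGI coordinates \code{CGIStart}/\code{CGIEnd} (NA when the
#' probe has no CGI within reach), from which the island context is
#' derived with [deriveIslandContext()] semantics. Coordinates are
#' 1-based inclusive (array MAPINFO convention).
#'
#' @param path CSV file path.
#' @param shore_bp shore half-width used when deriving context from CGI
#'   coordinates.
#' @return data.frame with columns probe_id, chrom, pos, gene_links,
#'   island_context, is_cpg.
#' @export
readManifest <- function(path, shore_bp = 4000) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("ProbeID", "Chr", "Pos", "GeneLinks", "IsCpG")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("manifest is missing columns: ", paste(miss, collapse = ", "))
    bad <- which(is.na(df$ProbeID) | !nzchar(df$ProbeID) |
                 is.na(df$Pos) | df$Pos < 1)
    if (length(bad))
        stop("malformed manifest row at line ", bad[1] + 1L)
    dup <- which(duplicated(df$ProbeID))
    if (length(dup))
        stop("duplicate probe_id '", df$ProbeID[dup[1]],
             "' at line ", dup[1] + 1L)
    if ("IslandContext" %in% colnames(df)) {
        ic <- df$IslandContext
        if (!all(ic %in% .CONTEXT_ISLAND))
            stop("malformed manifest row at line ",
                 which(!(ic %in% .CONTEXT_ISLAND))[1] + 1L,
                 ": bad IslandContext")
    } else if (all(c("CGIStart", "CGIEnd") %in% colnames(df))) {
        ic <- rep("OpenSea", nrow(df))
        has <- !is.na(df$CGIStart) & !is.na(df$CGIEnd)
        ic[has] <- vapply(which(has), function(i) {
            deriveIslandContext(df$Pos[i],
                                cbind(df$CGIStart[i], df$CGIEnd[i]),
                                shore_bp)
        }, character(1))
    } else {
        stop("manifest needs IslandContext or CGIStart/CGIEnd columns")
    }
    links <- df$GeneLinks
    links[is.na(links)] <- ""
    parseGeneLinks(df$ProbeID, links)  # validates syntax
    data.frame(probe_id = df$ProbeID, chrom = df$Chr, pos = df$Pos,
               gene_links = links, island_context = ic,
               is_cpg = as.logical(df$IsCpG), stringsAsFactors = FALSE)
}

#' Write a probe manifest CSV
#'
#' Inverse of [readManifest()]: writes the precomputed
#' \code{IslandContext} dialect, so write-then-read is the identity.
#'
#' @param records manifest data.frame as returned by [readManifest()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeManifest <- function(records, path) {
    need <- c("probe_id", "chrom", "pos", "gene_links",
              "island_context", "is_cpg")
    stopifnot(all(need %in% colnames(records)))
    out <- data.frame(ProbeID = records$probe_id, Chr = records$chrom,
                      Pos = records$pos, GeneLinks = records$gene_links,
                      IslandContext = records$island_context,
                      IsCpG = records$is_cpg)
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    invisible(path)
}

#' Export CGI and shore intervals as BED
#'
#' Writes the islands and their flanking shore intervals in BED format
#' (0-based half-open; converted from the package's 1-based inclusive
#' coordinates at this boundary).
#'
#' @param islands data.frame with columns chrom, start, end.
#' @param path output BED path.
#' @param shore_bp shore half-width in bp.
#' @return the path, invisibly.
#' @export
exportContextBed <- function(islands, path, shore_bp = 4000) {
    rows <- list()
    for (i in seq_len(nrow(islands))) {
        ch <- islands$chrom[i]; s <- islands$start[i]; e <- islands$end[i]
        rows[[length(rows) + 1L]] <-
            data.frame(chrom = ch, start = s - 1L, end = e, name = "CGI")
        rows[[length(rows) + 1L]] <-
            data.frame(chrom = ch, start = max(0L, s - shore_bp - 1L),
                       end = s - 1L, name = "Shore")
        rows[[length(rows) + 1L]] <-
            data.frame(chrom = ch, start = e, end = e + shore_bp,
                       name = "Shore")
    }
    bed <- do.call(rbind, rows)
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Exclude probes by chromosome and CpG rules
#'
#' Drops probes mapping to the sex chromosomes and/or probes not
#' interrogating a CpG dinucleotide, and reports per-rule removal
#' counts.
#'
#' @param records manifest data.frame ([readManifest()]).
#' @param rules character subset of c("sex_chromosomes", "non_cpg").
#' @return list with \code{records} (retained rows) and \code{removed}
#'   (named counts per rule).
#' @export
excludeProbes <- function(records, rules = c("sex_chromosomes", "non_cpg")) {
    rules <- match.arg(rules, several.ok = TRUE)
    removed <- c(sex_chromosomes = 0L, non_cpg = 0L)
    keep <- rep(TRUE, nrow(records))
    if ("sex_chromosomes" %in% rules) {
        chrom <- sub("^chr", "", records$chrom, ignore.case = TRUE)
        sex <- toupper(chrom) %in% c("X", "Y")
        removed["sex_chromosomes"] <- sum(sex & keep)
        keep <- keep & !sex
    }
    if ("non_cpg" %in% rules) {
        nc <- !records$is_cpg
        removed["non_cpg"] <- sum(nc & keep)
        keep <- keep & !nc
    }
    list(records = records[keep, , drop = FALSE], removed = removed)
}
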