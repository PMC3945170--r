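test_that("island context: containment, 4-kb shore boundary, open sea", {
    cgi <- cbind(400, 900)
    expect_equal(deriveIslandContext(500, cgi), "Island")
    # boundary-inclusive shore: distance exactly 4000 bp
    expect_equal(deriveIslandContext(4900, cgi), "Shore")
    expect_equal(deriveIslandContext(4901, cgi), "OpenSea")
    expect_equal(deriveIslandContext(400, cgi), "Island")
    expect_equal(deriveIslandContext(900, cgi), "Island")
    # no islands on the chromosome
    expect_equal(deriveIslandContext(123, cgi[0, , drop = FALSE]),
                 "OpenSea")
})

test_that("island context agrees with a brute-force distance scan", {
    set.seed(101)
    for (rep in 1:5) {
        starts <- sort(sample(1:200000, 6)) * 3L
        islands <- cbind(starts, starts + sample(200:2000, 6))
        pos <- sample(1:650000, 400)
        got <- deriveIslandContext(pos, islands)
        want <- vapply(pos, islandContextBrute, character(1),
                       islands = islands)
        expect_identical(got, want)
    }
})

test_that("shore around an isolated CGI spans exactly 8000 positions", {
    cgi <- cbind(50000, 51000)
    pos <- 40000:61000
    ctx <- deriveIslandContext(pos, cgi)
    expect_equal(sum(ctx == "Shore"), 8000)
    expect_equal(sum(ctx == "Island"), 1001)
})

test_that("gene context precedence and strand handling", {
    tx <- transcriptModel("NM_1", "chr1", "+", tss = 10000,
                          body_start = 10000, body_end = 30000,
                          first_exon_start = 10000, first_exon_end = 10199,
                          utr5_start = 10000, utr5_end = 10349,
                          utr3_start = 29700, utr3_end = 30000)
    expect_equal(deriveGeneContext(10000 - 100, tx), "TSS200")
    expect_equal(deriveGeneContext(10000 - 1000, tx), "TSS1500")
    expect_equal(deriveGeneContext(10000 - 1500, tx), "TSS1500")
    expect_equal(deriveGeneContext(10000 - 1501, tx), NA_character_)
    expect_equal(deriveGeneContext(10100, tx), "FirstExon")  # beats UTR5
    expect_equal(deriveGeneContext(10300, tx), "UTR5")
    expect_equal(deriveGeneContext(29800, tx), "UTR3")
    expect_equal(deriveGeneContext(20000, tx), "Body")
    expect_equal(deriveGeneContext(40000, tx), NA_character_)
})

test_that("gene context is invariant under coordinate reflection", {
    # reflect transcript and probes about a point, flip strand
    tx_p <- transcriptModel("NM_1", "chr1", "+", tss = 10000,
                            body_start = 10000, body_end = 30000,
                            first_exon_start = 10000,
                            first_exon_end = 10199,
                            utr5_start = 10000, utr5_end = 10349,
                            utr3_start = 29700, utr3_end = 30000)
    M <- 100000  # reflection: pos -> M - pos
    tx_m <- transcriptModel("NM_1", "chr1", "-", tss = M - 10000,
                            body_start = M - 30000, body_end = M - 10000,
                            first_exon_start = M - 10199,
                            first_exon_end = M - 10000,
                            utr5_start = M - 10349, utr5_end = M - 10000,
                            utr3_start = M - 30000, utr3_end = M - 29700)
    set.seed(7)
    for (pos in c(sample(8000:32000, 50), 8499, 8500, 9800, 9999)) {
        expect_identical(deriveGeneContext(pos, tx_p),
                         deriveGeneContext(M - pos, tx_m),
                         info = paste("pos", pos))
    }
})

test_that("manifest round-trips and validates", {
    rec <- data.frame(
        probe_id = c("cg1", "cg2", "cg3"),
        chrom = c("chr1", "chr2", "chr2"),
        pos = c(100L, 2000L, 30000L),
        gene_links = c("NM_1:TSS200;NM_2:Body", "NM_3:UTR5", ""),
        island_context = c("Island", "Shore", "OpenSea"),
        is_cpg = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
    path <- withr::local_tempfile(fileext = ".csv")
    writeManifest(rec, path)
    back <- readManifest(path)
    expect_identical(back, rec)
    # multi-link order preserved
    links <- parseGeneLinks(back$probe_id, back$gene_links)
    expect_identical(links$transcript_id[links$probe_id == "cg1"],
                     c("NM_1", "NM_2"))
    # duplicate probe id
    dup <- rec; dup$probe_id <- c("cg1", "cg1", "cg3")
    writeManifest(dup, path)
    expect_error(readManifest(path), "duplicate")
    # malformed row names its line
    bad <- rec; bad$pos[2] <- -5L
    writeManifest(bad, path)
    expect_error(readManifest(path), "line 3")
})

test_that("manifest with CGI columns derives island context", {
    set.seed(11)
    n <- 60
    cgi_start <- sample(1000:50000, n)
    cgi_end <- cgi_start + sample(200:1500, n)
    pos <- cgi_start + sample(-6000:6000, n)
    pos <- pmax(pos, 1)
    df <- data.frame(ProbeID = paste0("cg", 1:n), Chr = "chr1", Pos = pos,
                     GeneLinks = "", IsCpG = TRUE,
                     CGIStart = cgi_start, CGIEnd = cgi_end)
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(df, path, row.names = FALSE)
    man <- readManifest(path)
    want <- vapply(seq_len(n), function(i)
        islandContextBrute(pos[i], cbind(cgi_start[i], cgi_end[i])),
        character(1))
    expect_identical(man$island_context, want)
})

test_that("probe exclusion rules drop sex chromosomes and non-CpGs", {
    rec <- data.frame(probe_id = paste0("cg", 1:4),
                      chrom = c("chr1", "chrX", "chrY", "chr2"),
                      pos = 1:4, gene_links = "",
                      island_context = "OpenSea",
                      is_cpg = c(TRUE, TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
    out <- excludeProbes(rec)
    expect_identical(out$records$probe_id, "cg1")
    expect_equal(unname(out$removed["sex_chromosomes"]), 2L)
    expect_equal(unname(out$removed["non_cpg"]), 1L)
    only_sex <- excludeProbes(rec, "sex_chromosomes")
    expect_identical(only_sex$records$probe_id, c("cg1", "cg4"))
})

test_that("BED export converts to 0-based half-open coordinates", {
    isl <- data.frame(chrom = "chr5", start = 10001L, end = 10500L)
    path <- withr::local_tempfile(fileext = ".bed")
    exportContextBed(isl, path)
    bed <- read.table(path, sep = "\t")
    cgi <- bed[bed$V4 == "CGI", ]
    expect_equal(cgi$V2, 10000)   # 1-based 10001 -> 0-based 10000
    expect_equal(cgi$V3, 10500)
    shores <- bed[bed$V4 == "Shore", ]
    expect_equal(shores$V3 - shores$V2, c(4000, 4000))
})
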