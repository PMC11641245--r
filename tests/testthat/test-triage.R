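library(GenomicRanges)

make_gene <- function(chrom = "chr2L", start = 1001, end = 1300,
                      exon_ranges = list(c(1001, 1100), c(1201, 1300)),
                      up = c(1, 500), dn = c(2001, 2500)) {
  list(
    gene = GRanges(chrom, IRanges(start, end)),
    exons = if (is.null(exon_ranges)) NULL else
      GRanges(chrom, IRanges(vapply(exon_ranges, `[`, numeric(1), 1),
                             vapply(exon_ranges, `[`, numeric(1), 2))),
    upstream = GRanges(chrom, IRanges(up[1], up[2])),
    downstream = GRanges(chrom, IRanges(dn[1], dn[2]))
  )
}

test_that("gene territory = introns plus flanking intergenic intervals", {
  g <- make_gene()
  terr <- gene_territory(g$gene, g$upstream, g$downstream, exons = g$exons)
  expect_equal(start(terr), c(501, 1101, 1301))
  expect_equal(end(terr), c(1000, 1200, 2000))
  # never intersects exons or neighbor bodies
  expect_false(any(overlapsAny(terr, g$exons)))
  expect_false(any(overlapsAny(terr, c(g$upstream, g$downstream))))

  # single-exon gene: only the two intergenic intervals remain
  se <- make_gene(exon_ranges = list(c(1001, 1300)))
  terr_se <- gene_territory(se$gene, se$upstream, se$downstream,
                            exons = se$exons)
  expect_equal(length(terr_se), 2L)

  # abutting neighbor contributes no interval on that side
  ab <- make_gene(up = c(1, 1000))
  terr_ab <- gene_territory(ab$gene, ab$upstream, ab$downstream,
                            exons = ab$exons)
  expect_false(any(start(terr_ab) < 1001))

  # no exon structure: whole gene body used, with a warning
  expect_warning(
    terr_body <- gene_territory(g$gene, g$upstream, g$downstream),
    "gene body"
  )
  expect_true(overlapsAny(g$gene, terr_body, type = "within"))

  # invalid neighbors rejected
  expect_error(gene_territory(g$gene, GRanges("chr2L", IRanges(900, 1100)),
                              g$downstream, exons = g$exons), "overlap")
  expect_error(gene_territory(g$gene, g$downstream, g$upstream,
                              exons = g$exons), "before|after")
  expect_error(gene_territory(g$gene, GRanges("chrX", IRanges(1, 500)),
                              g$downstream, exons = g$exons), "chromosome")
})

test_that("peak clustering is a symmetric gap rule matching a brute-force scan", {
  a <- GRanges("chr3R", IRanges(100, 200))
  expect_true(clustered(a, GRanges("chr3R", IRanges(150, 250))))
  expect_true(clustered(a, GRanges("chr3R", IRanges(201, 300))))  # abutting
  expect_false(clustered(a, GRanges("chr3R", IRanges(801, 900)),
                         max_gap = 500))
  expect_true(clustered(a, GRanges("chr3R", IRanges(700, 900)),
                        max_gap = 500))
  expect_error(clustered(a, GRanges("chrX", IRanges(100, 200))), "chromosome")

  set.seed(60)
  starts <- sample.int(10000, 30)
  peaks <- GRanges("chr2R", IRanges(starts, width = sample(50:300, 30,
                                                           replace = TRUE)))
  for (gap in c(0, 100, 1000)) {
    for (i in 1:10) {
      pair <- sample.int(30, 2)
      a <- peaks[pair[1]]; b <- peaks[pair[2]]
      # brute-force gap: bases strictly between the two intervals
      gap_ab <- max(0, max(start(a), start(b)) - min(end(a), end(b)) - 1)
      expect_equal(clustered(a, b, max_gap = gap), gap_ab <= gap)
      expect_equal(clustered(a, b, max_gap = gap), clustered(b, a, max_gap = gap))
    }
  }
})

test_that("direct-target triage implements the clustered-peak criterion", {
  g <- make_gene()
  terr <- gene_territory(g$gene, g$upstream, g$downstream, exons = g$exons)

  # Jumu and Tin peaks overlapping in the intron -> direct
  peaks <- GRanges("chr2L", IRanges(c(1110, 1150), c(1160, 1190)),
                   tf = c("Jumu", "Tin"))
  call <- classify_direct_target(terr, peaks, gene = "g1")
  expect_equal(call$status, "direct")
  expect_equal(call$supporting_tfs, "Tin")
  expect_equal(call$best_gap, 0)

  # no Jumu peak in the territory (one sits inside an exon) -> no_jumu_peak
  peaks2 <- GRanges("chr2L", IRanges(c(1020, 1150), c(1060, 1190)),
                    tf = c("Jumu", "Tin"))
  expect_equal(classify_direct_target(terr, peaks2)$status, "no_jumu_peak")

  # Jumu peak with the nearest partner beyond max_gap -> jumu_only
  peaks3 <- GRanges("chr2L", IRanges(c(520, 1900), c(560, 1950)),
                    tf = c("Jumu", "Myb"))
  only <- classify_direct_target(terr, peaks3, max_gap = 500)
  expect_equal(only$status, "jumu_only")
  expect_equal(only$best_gap, 1339)
  expect_equal(classify_direct_target(terr, peaks3,
                                      max_gap = 2000)$status, "direct")

  expect_error(classify_direct_target(terr, GRanges("chr2L",
                                                    IRanges(1, 2), tf = "Foo")),
               "unknown TF")
})

test_that("triage is order-invariant and monotone in max_gap", {
  g <- make_gene()
  set.seed(61)
  n <- 40
  starts <- sample(1:2500, n)
  peaks <- GRanges("chr2L", IRanges(starts, width = 40),
                   tf = sample(c("Jumu", "Tin", "Twi", "Mad"), n,
                               replace = TRUE))
  genes <- list(g1 = g)
  gaps <- c(0, 50, 200, 1000)
  statuses <- vapply(gaps, function(mg) {
    triage_genes(genes, peaks, max_gap = mg)$status
  }, character(1))
  rank <- c(no_jumu_peak = 0, jumu_only = 1, direct = 2)
  expect_true(all(diff(rank[statuses]) >= 0))  # growing gap never demotes

  shuffled <- peaks[sample(n)]
  expect_equal(triage_genes(genes, shuffled, max_gap = 200)$status,
               triage_genes(genes, peaks, max_gap = 200)$status)
  expect_equal(triage_genes(genes, shuffled, max_gap = 200)$supporting_tfs,
               triage_genes(genes, peaks, max_gap = 200)$supporting_tfs)
})

test_that("BED peak files round-trip bit-exactly through write/read", {
  set.seed(62)
  peaks <- GRanges("chr2L", IRanges(sort(sample.int(5000, 12)), width = 100),
                   tf = rep(c("Jumu", "Tin", "Hand"), 4))
  path <- file.path(withr::local_tempdir(), "peaks.bed")
  write_peaks_bed(peaks, path)
  back <- read_peaks_bed(path)
  expect_equal(start(back), start(peaks))
  expect_equal(end(back), end(peaks))
  expect_equal(as.character(back$tf), as.character(peaks$tf))
  # second round-trip is byte-identical
  path2 <- file.path(withr::local_tempdir(), "peaks2.bed")
  write_peaks_bed(back, path2)
  expect_identical(readLines(path), readLines(path2))

  # per-TF files pool to the same calls as one pooled file
  tfs <- unique(peaks$tf)
  dir <- withr::local_tempdir()
  paths <- vapply(tfs, function(tf) {
    p <- file.path(dir, paste0(tf, ".bed"))
    write_peaks_bed(peaks[peaks$tf == tf], p)
    p
  }, character(1))
  names(paths) <- tfs
  split_peaks <- read_peaks_bed(paths)
  g <- make_gene(dn = c(5200, 5400))
  genes <- list(g1 = g)
  expect_equal(triage_genes(genes, split_peaks, max_gap = 100)$status,
               triage_genes(genes, peaks, max_gap = 100)$status)
})
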