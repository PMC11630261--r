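layout <- make_layout(c(chr1 = 10000))
gene <- make_gene("g1", "chr1", 3000, 5000)
index <- build_feature_index(gene, layout, promoter_window = 1000)

test_that("peaks are labelled at their anchor and the distribution sums to 1", {
  peaks <- tibble::tibble(chrom = "chr1",
                          start = c(2100, 3600, 8000), end = c(2300, 3800, 8200),
                          summit = NA_real_)
  ann <- assign_peaks(peaks, index)
  expect_equal(as.character(ann$feature), c("promoter", "coding_exon", "intergenic"))
  d <- feature_distribution(ann)
  expect_equal(sum(d$fraction), 1)
  expect_equal(d$fraction[d$feature == "promoter"], 1 / 3)
  # a recorded summit overrides the midpoint
  pk <- tibble::tibble(chrom = "chr1", start = 2900, end = 3300, summit = 2950)
  expect_equal(as.character(assign_peaks(pk, index)$feature), "promoter")
  pk$summit <- NA_real_
  expect_equal(as.character(assign_peaks(pk, index)$feature), "coding_exon")
  expect_error(feature_distribution(assign_peaks(peaks[0, ], index)), "empty")
})

test_that("marked_genes uses >= 1 bp overlap of promoter-plus-body, half-open", {
  # promoter of g1 is [2000, 3000); a peak ending exactly at 2000 shares 0 bp
  touching <- tibble::tibble(chrom = "chr1", start = 1800, end = 2000, summit = NA_real_)
  expect_length(marked_genes(touching, gene, layout, 1000), 0)
  over <- tibble::tibble(chrom = "chr1", start = 1800, end = 2001, summit = NA_real_)
  expect_equal(marked_genes(over, gene, layout, 1000), "g1")
  # two peaks in one gene count once; promoter-only peaks count
  two <- tibble::tibble(chrom = "chr1", start = c(2100, 4000), end = c(2200, 4100),
                        summit = NA_real_)
  expect_equal(marked_genes(two, gene, layout, 1000), "g1")
})

test_that("marked_genes is monotone under peak addition", {
  lay <- make_layout(c(chrA = 20000, chrB = 20000))
  genes <- rand_genes(lay, 10, seed = 3)
  pk1 <- rand_peaks(lay, 20, seed = 4)
  pk2 <- dplyr::bind_rows(pk1, rand_peaks(lay, 20, seed = 5))
  m1 <- marked_genes(pk1, genes, lay, 1000)
  m2 <- marked_genes(pk2, genes, lay, 1000)
  expect_true(all(m1 %in% m2))
})

test_that("venn regions partition the union and match per-gene enumeration", {
  v <- multiway_venn(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(v$n[v$region == "A"], 1)
  expect_equal(v$n[v$region == "B"], 1)
  expect_equal(v$n[v$region == "A&B"], 1)
  ident <- multiway_venn(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(ident$n[ident$region == "A&B"], 2)
  expect_equal(sum(ident$n), 2)

  sets <- withr::with_seed(9, lapply(1:3, function(i) sample(sprintf("g%03d", 1:200), 100)))
  names(sets) <- c("m1", "m2", "m3")
  v3 <- multiway_venn(sets)
  expect_equal(sum(v3$n), length(unique(unlist(sets))))
  # brute force per gene
  uni <- unique(unlist(sets))
  pattern <- sapply(sets, function(s) uni %in% s)
  for (i in seq_len(nrow(v3))) {
    want <- unlist(v3[i, c("m1", "m2", "m3")])
    expect_equal(v3$n[i], sum(apply(pattern, 1, function(p) all(p == want))))
  }
  expect_error(multiway_venn(list(a = "x")), "between 2 and 4")
})

test_that("genome coverage merges overlaps and equals the per-base oracle", {
  lay <- make_layout(c(chr1 = 1000))
  one <- tibble::tibble(chrom = "chr1", start = 100, end = 200, summit = NA_real_)
  expect_equal(genome_coverage(one, lay), 0.1)
  expect_equal(genome_coverage(dplyr::bind_rows(one, one), lay), 0.1)
  lay2 <- make_layout(c(chrA = 60000, chrB = 40000))
  pk <- rand_peaks(lay2, 200, seed = 21)
  expect_equal(genome_coverage(pk, lay2), oracle_coverage_fraction(pk, lay2))
})

test_that("peak length histogram bins right-open and totals the peak count", {
  pk <- tibble::tibble(chrom = "chr1", start = c(0, 1000, 2000),
                       end = c(250, 1650, 2200), summit = NA_real_)
  h <- peak_length_histogram(pk, c(0, 200, 700, Inf))
  expect_equal(h$n, c(0, 3, 0))  # lengths 250, 650 and the boundary length 200
  # length exactly on an edge goes to the bin it opens
  pk2 <- tibble::tibble(chrom = "chr1", start = 0, end = 200, summit = NA_real_)
  h2 <- peak_length_histogram(pk2, c(0, 200, 700, Inf))
  expect_equal(h2$n, c(0, 1, 0))
  expect_equal(sum(peak_length_histogram(pk[0, ], c(0, 100, Inf))$n), 0)
  expect_error(peak_length_histogram(pk, c(0, 0, 10)), "increasing")
})

test_that("metagene profile is flat under uniform coverage and localises TSS signal", {
  lay <- make_layout(c(chr1 = 40000))
  genes <- dplyr::bind_rows(
    make_gene("g1", "chr1", 5000, 9000),
    make_gene("g2", "chr1", 15000, 20000),
    make_gene("g3", "chr1", 30000, 36000, strand = "-"))
  full <- tibble::tibble(chrom = "chr1", start = 0, end = 40000, summit = NA_real_)
  prof <- metagene_profile(full, genes, lay)
  expect_true(all(abs(prof$mean_signal - 1) < 1e-12))
  expect_equal(nrow(prof), 20 + 100 + 40)

  # signal only on [tss, tss+500) of each gene -> elevated just after the TSS
  sig <- tibble::tibble(chrom = "chr1",
                        start = c(5000, 15000, 35500), end = c(5500, 15500, 36000),
                        summit = NA_real_)
  p2 <- metagene_profile(sig, genes, lay)
  up <- p2$mean_signal[p2$zone == "upstream"]
  body <- p2$mean_signal[p2$zone == "body"]
  expect_true(all(up == 0))
  expect_true(all(body[1:5] > 0))
  expect_true(all(body[60:100] == 0))
  expect_true(all(p2$mean_signal[p2$zone == "downstream"] == 0))
})

test_that("a minus-strand gene mirrors its reflected plus-strand twin", {
  L <- 30000
  lay <- make_layout(c(chr1 = L))
  gp <- make_gene("gp", "chr1", 10000, 14000, strand = "+")
  gm <- make_gene("gm", "chr1", L - 14000, L - 10000, strand = "-")
  pk <- rand_peaks(lay, 40, seed = 8)
  pk_m <- tibble::tibble(chrom = "chr1", start = L - pk$end, end = L - pk$start,
                         summit = NA_real_)
  prof_p <- metagene_profile(pk, gp, lay)
  prof_m <- metagene_profile(pk_m, gm, lay)
  expect_equal(prof_m$mean_signal, prof_p$mean_signal)
})

test_that("metagene profile is invariant to gene order and clips flanks as missing", {
  lay <- make_layout(c(chr1 = 30000))
  genes <- rand_genes(lay, 6, seed = 13, min_len = 500, max_len = 2000)
  pk <- rand_peaks(lay, 30, seed = 14)
  p1 <- metagene_profile(pk, genes, lay)
  p2 <- metagene_profile(pk, genes[sample(nrow(genes)), ], lay)
  expect_equal(p1$mean_signal, p2$mean_signal)
  # gene at the chromosome start: upstream flank is missing, not zero
  edge <- make_gene("ge", "chr1", 100, 1500)
  pe <- metagene_profile(pk, edge, lay)
  expect_true(all(is.nan(pe$mean_signal[pe$zone == "upstream"][1:2])))
})
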