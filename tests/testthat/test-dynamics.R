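test_that("DE thresholding includes the fold-change boundary and is strict on FDR", {
  de <- tibble::tibble(gene_id = paste0("g", 1:5),
                       log2FC = c(1.5, 1.0, -3, 0.5, -1.0),
                       FDR = c(0.01, 0.01, 0.05, 0.001, 0.049))
  out <- call_de(de)
  expect_equal(out$direction, c("up", "up", "ns", "ns", "down"))
  expect_equal(sum(out$direction == "up" & out$direction == "down"), 0)
})

test_that("simple_de: pseudocount identity, zero-variance handling and BH null control", {
  expr <- tibble::tibble(gene_id = c("a", "b"),
                         CK_1 = c(0, 3), CK_2 = c(0, 3),
                         NaCl_1 = c(0, 3), NaCl_2 = c(0, 3))
  de <- simple_de(expr)
  expect_equal(de$log2FC, c(0, 0))
  expect_equal(de$pvalue, c(1, 1))

  # null simulation: empirical false-discovery rate controlled at the BH level
  withr::with_seed(31, {
    n <- 1000
    m <- matrix(2^rnorm(n * 6, 3, 0.5), n)
    expr2 <- tibble::as_tibble(as.data.frame(m))
    names(expr2) <- c(paste0("CK_", 1:3), paste0("NaCl_", 1:3))
    expr2 <- dplyr::bind_cols(tibble::tibble(gene_id = paste0("g", 1:n)), expr2)
  })
  de2 <- simple_de(expr2)
  expect_lte(sum(de2$FDR < 0.05), 5)  # near-zero rejections on pure null
  expect_true(all(de2$FDR >= de2$pvalue - 1e-12))
})

test_that("gain/loss classification follows the marked-state and Jaccard rules", {
  lay <- make_layout(c(chr1 = 50000))
  genes <- dplyr::bind_rows(
    make_gene("g_gain", "chr1", 5000, 7000),
    make_gene("g_stable", "chr1", 15000, 17000),
    make_gene("g_replace", "chr1", 25000, 27000),
    make_gene("g_absent", "chr1", 35000, 37000))
  pk <- function(starts, ends) tibble::tibble(chrom = "chr1", start = starts,
                                              end = ends, summit = NA_real_,
                                              mark = "H3K9ac", condition = NA)
  # CK: stable gene marked, replace gene has 400 bp
  ck <- pk(c(15200, 25000), c(15600, 25400))
  # NaCl: gain gene newly marked; stable identical; replace swapped to a
  # disjoint 100 bp peak (Jaccard 0, signal down -> loss)
  na <- pk(c(5200, 15200, 26000), c(5600, 15600, 26100))
  dyn <- mark_gain_loss(ck, na, genes, lay)
  expect_equal(dyn$status[dyn$gene_id == "g_gain"], "gain")
  expect_equal(dyn$status[dyn$gene_id == "g_stable"], "stable")
  expect_equal(dyn$jaccard[dyn$gene_id == "g_stable"], 1)
  expect_equal(dyn$status[dyn$gene_id == "g_replace"], "loss")
  expect_equal(dyn$status[dyn$gene_id == "g_absent"], "absent")
  expect_setequal(unique(dyn$status), c("gain", "loss", "stable", "absent"))

  # swapping conditions swaps gain and loss exactly
  rev <- mark_gain_loss(na, ck, genes, lay)
  map <- c(gain = "loss", loss = "gain", stable = "stable", absent = "absent")
  expect_equal(unname(map[dyn$status]), rev$status)

  bad <- dplyr::mutate(na, mark = "H3K4me3")
  expect_error(mark_gain_loss(ck, bad, genes, lay), "different marks")
})

test_that("concordance classes pair mark direction with expression direction", {
  de <- call_de(tibble::tibble(gene_id = c("u1", "u2", "d1", "n1"),
                               log2FC = c(2, 1.5, -2, 0.1),
                               FDR = c(0.01, 0.01, 0.01, 0.9)))
  dyn1 <- tibble::tibble(gene_id = c("u1", "u2", "d1", "n1"),
                         status = c("gain", "stable", "loss", "gain"))
  dyn3 <- tibble::tibble(gene_id = c("u1", "u2", "d1", "n1"),
                         status = c("gain", "loss", "gain", "stable"))
  rep <- concordance(de, list(H3K9ac = dyn1, H3K27me3 = dyn3))
  cls <- rep$classes
  expect_equal(cls$genes[cls$class == "H3K9ac-gain/up"][[1]], "u1")
  expect_equal(cls$genes[cls$class == "H3K9ac-loss/down"][[1]], "d1")
  expect_equal(cls$genes[cls$class == "H3K27me3-loss/up"][[1]], "u2")
  # H3K27me3 gain on an upregulated gene is discordant: in no class
  expect_false("u1" %in% unlist(cls$genes[cls$mark == "H3K27me3" & cls$mark_status == "gain"]))
  expect_equal(rep$coverage$n_covered[rep$coverage$de_direction == "up"], 2)
  g <- glance(rep)
  expect_equal(g$frac_down_covered, 1)
})

test_that("promoter rate counts condition-specific peak anchors", {
  lay <- make_layout(c(chr1 = 60000))
  genes <- purrr::map_dfr(1:5, function(i) {
    make_gene(paste0("g", i), "chr1", i * 10000, i * 10000 + 2000)
  })
  index <- build_feature_index(genes, lay, promoter_window = 2000)
  # 8 peaks anchored in promoters, 2 inside gene bodies, all NaCl-only
  prom_pk <- tibble::tibble(chrom = "chr1",
                            start = c(8200, 8600, 18200, 18600, 28200, 28600, 38200, 48200),
                            end = c(8200, 8600, 18200, 18600, 28200, 28600, 38200, 48200) + 300,
                            summit = NA_real_)
  body_pk <- tibble::tibble(chrom = "chr1", start = c(11000, 21000),
                            end = c(11300, 21300), summit = NA_real_)
  nacl <- dplyr::bind_rows(prom_pk, body_pk)
  ck <- nacl[0, ]
  pr <- promoter_rate(genes$gene_id, nacl, ck, index, genes, lay)
  expect_equal(pr$n_changed_peaks, 10)
  expect_equal(pr$promoter_rate_peaks, 0.8)
  expect_warning(pr0 <- promoter_rate(genes$gene_id, ck, nacl, index, genes, lay),
                 "no condition-specific")
  expect_true(is.na(pr0$promoter_rate_peaks))
})

test_that("fold-change correlations hit exact values on linear relations", {
  de <- tibble::tibble(gene_id = paste0("g", 1:10), log2FC = seq(-2, 2.5, by = 0.5))
  dyn_pos <- tibble::tibble(gene_id = de$gene_id, log_ratio = 2 * de$log2FC)
  dyn_neg <- tibble::tibble(gene_id = de$gene_id, log_ratio = -de$log2FC)
  fc <- fc_correlation(list(H3K4me3 = dyn_pos, H3K27me3 = dyn_neg), de)
  expect_equal(fc$r[fc$var1 == "H3K4me3" & fc$var2 == "expression"], 1)
  expect_equal(fc$r[fc$var1 == "H3K27me3" & fc$var2 == "expression"], -1)
  expect_equal(fc$r[fc$var1 == "H3K4me3" & fc$var2 == "H3K27me3"], -1)
  const <- tibble::tibble(gene_id = de$gene_id, log_ratio = 0)
  expect_warning(fc2 <- fc_correlation(list(H3K4me3 = const), de), "constant")
  expect_true(is.na(fc2$r[1]))
})

test_that("variability score matches hand arithmetic and the per-base oracle", {
  lay <- make_layout(c(chr1 = 1000))
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 100, summit = NA_real_)
  b <- tibble::tibble(chrom = "chr1", start = 50, end = 150, summit = NA_real_)
  vs <- variability_score(a, b)
  expect_equal(vs$score, 2 / 3)  # 1 - 50/150
  expect_equal(variability_score(a, a)$score, 0)
  disj <- tibble::tibble(chrom = "chr1", start = 500, end = 600, summit = NA_real_)
  expect_equal(variability_score(a, disj)$score, 1)
  expect_warning(v0 <- variability_score(a[0, ], a[0, ]), "empty")
  expect_equal(v0$score, 0)
  lay2 <- make_layout(c(chrA = 40000, chrB = 30000))
  for (seed in 1:5) {
    pa <- rand_peaks(lay2, 50, seed = seed)
    pb <- rand_peaks(lay2, 50, seed = seed + 77)
    got <- variability_score(pa, pb)
    expect_equal(got$jaccard, oracle_jaccard(pa, pb, lay2))
    expect_equal(got$score, variability_score(pb, pa)$score)  # symmetric
    expect_true(got$score >= 0 && got$score <= 1)
  }
})

test_that("metabolite gates reproduce the hand truth table including boundaries", {
  tab <- tibble::tibble(
    metabolite_id = paste0("m", 1:8),
    ion_mode = rep(c("pos", "neg"), 4),
    VIP = c(1.3, 0.9, 1.0, 2.0, 1.5, 1.2, 3.0, 1.1),
    FC = c(2.0, 3.0, 2.5, 1.5, 0.5, 0.667, 1.6, 0.6),
    pvalue = c(0.01, 0.001, 0.01, 0.01, 0.04, 0.04, 0.05, 0.002))
  out <- filter_metabolites(tab)
  # m1 passes up; m2 fails VIP; m3 VIP not > 1; m4 FC not > 1.5;
  # m5 down; m6 FC not < 0.667; m7 p not < 0.05; m8 down
  expect_equal(out$direction,
               c("up", "ns", "ns", "ns", "down", "ns", "ns", "down"))
  s <- metabolite_summary(out)
  expect_equal(s$n_up[s$ion_mode == "pos"], 1)
  expect_equal(s$n_down[s$ion_mode == "pos"], 1)  # m5
  expect_equal(s$n_down[s$ion_mode == "neg"], 1)  # m8
  # stricter preset
  strict <- filter_metabolites(tab, fc_up = 2, fc_down = 0.5, p_max = 0.05)
  expect_equal(strict$direction[1], "ns")  # FC 2.0 is not > 2
})
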