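small_cfg <- function(seed = 5, preset = "default", ...) {
  sim_config(seed = seed, preset = preset, n_chrom = 2, chrom_length = 4e5,
             n_genes = 80, n_concordant = 24, n_metab_pos = 40, n_metab_neg = 30, ...)
}

test_that("identical seeds give byte-identical output trees", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_epigenome(small_cfg(seed = 9), outdir = d1)
  simulate_epigenome(small_cfg(seed = 9), outdir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  d3 <- withr::local_tempdir()
  simulate_epigenome(small_cfg(seed = 10), outdir = d3)
  expect_false(identical(readLines(file.path(d1, "expression.tsv")),
                         readLines(file.path(d3, "expression.tsv"))))
})

test_that("every emitted file parses back through the readers without diagnostics", {
  d <- withr::local_tempdir()
  w <- simulate_epigenome(small_cfg(seed = 2), outdir = d)
  lay_tab <- readr::read_tsv(file.path(d, "genome.tsv"), show_col_types = FALSE)
  layout <- genome_layout(lay_tab$chrom, lay_tab$length)
  genes <- read_gff3(file.path(d, "genes.gff3"), layout)
  expect_equal(nrow(genes), nrow(w$genes))
  for (m in names(w$peaks)) {
    for (cond in c("CK", "NaCl")) {
      pk <- read_bed(file.path(d, "peaks", paste0(m, "_", cond, ".bed")), layout)
      expect_equal(pk[c("chrom", "start", "end")],
                   w$peaks[[m]][[cond]][c("chrom", "start", "end")])
    }
  }
  expect_no_error(read_bed(file.path(d, "te.bed"), layout))
  expect_no_error(read_bed(file.path(d, "rechip_AB.bed"), layout))
  expect_equal(nrow(read_expression(file.path(d, "expression.tsv"))), nrow(genes))
  expect_no_error(read_metabolite_table(file.path(d, "metabolites.tsv")))
})

test_that("planted mark statuses are exactly re-derivable from the emitted peaks", {
  w <- simulate_epigenome(small_cfg(seed = 13, preset = "noisefree"))
  for (m in c("H3K4me3", "H3K9ac", "H3K27me3")) {
    dyn <- mark_gain_loss(w$peaks[[m]]$CK, w$peaks[[m]]$NaCl, w$genes, w$layout,
                          promoter_window = w$config$promoter_window)
    truth <- w$truth$genes[[paste0(m, "_status")]][match(dyn$gene_id,
                                                         w$truth$genes$gene_id)]
    expect_equal(dyn$status, truth)
  }
})

test_that("planted bivalent genes carry both marks and the truth file lists them", {
  d <- withr::local_tempdir()
  w <- simulate_epigenome(small_cfg(seed = 4), outdir = d)
  ids <- readr::read_tsv(file.path(d, "truth", "bivalent_genes.tsv"),
                         show_col_types = FALSE)$gene_id
  expect_setequal(ids, w$truth$bivalent_genes)
  expect_equal(length(ids), round(0.1 * nrow(w$genes)))
  tg <- w$truth$genes
  biv <- tg[tg$bivalent, ]
  expect_true(all(biv$H3K9ac_ck == 1 & biv$H3K27me3_ck == 1))
  # and the emitted CK peak sets do cover their promoters with both marks
  called <- call_bivalent(w$peaks$H3K9ac$CK, w$peaks$H3K27me3$CK, w$layout,
                          genes = w$genes)
  expect_true(all(w$truth$bivalent_genes %in% called$genes))
})

test_that("degenerate all-zero emissions produce no peaks from those states", {
  ht <- .default_truth <- sim_config()$hmm_truth
  ht$E[,] <- 0
  cfg <- small_cfg(seed = 6, hmm_truth = ht, te_het_bias = 0,
                   mark_probs = matrix(0, 4, 3,
                                       dimnames = list(c("high", "mid", "low", "none"),
                                                       c("H3K4me3", "H3K9ac", "H3K27me3"))),
                   bivalent_fraction = 0, n_concordant = 0)
  w <- simulate_epigenome(cfg)
  for (m in names(w$peaks)) expect_equal(nrow(w$peaks[[m]]$CK), 0)
})

test_that("background gain/loss rates land near their nominal values", {
  w <- simulate_epigenome(sim_config(seed = 30, n_chrom = 2, chrom_length = 1e6,
                                     n_genes = 220, n_concordant = 0,
                                     n_metab_pos = 10, n_metab_neg = 10))
  tg <- w$truth$genes
  # H3K9ac loss among CK-marked genes: rate 0.12 (z-coupling preserves the mean)
  marked <- tg$H3K9ac_ck == 1
  frac <- mean(tg$H3K9ac_status[marked] == "loss")
  n <- sum(marked)
  expect_lt(abs(frac - 0.12), 3 * sqrt(0.12 * 0.88 / n) + 0.02)
})

test_that("invalid configurations are rejected before any file is written", {
  expect_error(sim_config(bivalent_fraction = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(background_gain = c(H3K4me3 = 0.8, H3K9ac = 0.1, H3K27me3 = 0.1),
                          background_loss = c(H3K4me3 = 0.4, H3K9ac = 0.1, H3K27me3 = 0.1)),
               "exceed 1")
  expect_error(sim_config(nonsense_field = 1), "unknown")
})
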