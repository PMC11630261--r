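bins_from_X <- function(X, chrom = "chr1") {
  n <- nrow(X)
  out <- tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * 200,
                        end = seq_len(n) * 200, bin = seq_len(n))
  for (m in seq_len(ncol(X))) out[[paste0("m", m)]] <- X[, m]
  out
}

rand_model <- function(K, M, seed) {
  withr::with_seed(seed, {
    pi <- runif(K); pi <- pi / sum(pi)
    A <- matrix(runif(K * K), K); A <- A / rowSums(A)
    E <- matrix(runif(K * M, 0.05, 0.95), K, M)
    list(pi = pi, A = A, E = E)
  })
}

as_model <- function(m, marks) {
  structure(list(K = length(m$pi), marks = marks, pi = m$pi, A = m$A,
                 E = m$E, loglik = NA, seed = NA), class = "bernoulli_hmm")
}

test_that("forward log-likelihood equals the path-enumeration oracle", {
  for (seed in 1:8) {
    K <- sample(1:3, 1)
    Tn <- sample(2:8, 1)
    M <- sample(1:3, 1)
    m <- rand_model(K, M, seed)
    X <- withr::with_seed(seed + 50, matrix(rbinom(Tn * M, 1, 0.5), Tn, M))
    bins <- bins_from_X(X)
    model <- as_model(m, paste0("m", seq_len(M)))
    ll <- hmm_loglik(bins, model)
    expect_equal(ll, enum_hmm_loglik(X, m$pi, m$A, m$E), tolerance = 1e-12)
  }
})

test_that("forward-backward marginals sum to one at every bin", {
  m <- rand_model(3, 2, 11)
  X <- withr::with_seed(12, matrix(rbinom(400, 1, 0.4), 200, 2))
  g <- hmm_posterior(bins_from_X(X), as_model(m, c("m1", "m2")))
  expect_true(all(abs(rowSums(g) - 1) < 1e-9))
})

test_that("K = 1 fit recovers the closed form: emissions are column means", {
  X <- withr::with_seed(4, matrix(rbinom(300, 1, c(0.3, 0.7, 0.5)), 100, 3, byrow = TRUE))
  bins <- bins_from_X(X)
  fit <- fit_hmm(bins, K = 1, seed = 1, n_restarts = 1)
  expect_equal(as.vector(fit$E), colMeans(X), tolerance = 1e-12)
  expect_equal(fit$A, matrix(1, 1, 1))
  seg <- decode_states(bins, fit)
  expect_true(all(seg$state == 1))
})

test_that("Baum-Welch log-likelihood is monotone non-decreasing", {
  X <- withr::with_seed(7, matrix(rbinom(2000, 1, 0.3), 500, 4))
  fit <- fit_hmm(bins_from_X(X), K = 3, seed = 2, n_restarts = 2, max_iter = 60)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
})

test_that("viterbi path beats every enumerated alternative and decoding is exact without noise", {
  m <- rand_model(2, 2, 21)
  X <- withr::with_seed(22, matrix(rbinom(12, 1, 0.5), 6, 2))
  bins <- bins_from_X(X)
  model <- as_model(m, c("m1", "m2"))
  vit <- decode_states(bins, model, method = "viterbi")$state
  lp_vit <- enum_hmm_path_logprob(vit, X, m$pi, m$A, m$E)
  paths <- expand.grid(rep(list(1:2), 6))
  lps <- apply(paths, 1, function(p) enum_hmm_path_logprob(p, X, m$pi, m$A, m$E))
  expect_gte(lp_vit, max(lps) - 1e-10)

  # deterministic distinct 0/1 emissions: decoding recovers the generating path
  det <- list(pi = c(0.5, 0.5), A = matrix(c(0.9, 0.1, 0.1, 0.9), 2),
              E = rbind(c(1, 0), c(0, 1)))
  sim <- simulate_hmm_sequence(det$pi, det$A, det$E, lengths = 300, seed = 5)
  dbins <- bins_from_X(sim$X)
  dmodel <- as_model(det, c("m1", "m2"))
  expect_equal(decode_states(dbins, dmodel, "viterbi")$state, sim$states)
  expect_equal(decode_states(dbins, dmodel, "posterior")$state, sim$states)
})

test_that("fitting and decoding are invariant to chromosome order", {
  m <- rand_model(2, 3, 31)
  X1 <- withr::with_seed(32, matrix(rbinom(300, 1, 0.4), 100, 3))
  X2 <- withr::with_seed(33, matrix(rbinom(240, 1, 0.6), 80, 3))
  b12 <- dplyr::bind_rows(bins_from_X(X1, "c1"), bins_from_X(X2, "c2"))
  b21 <- dplyr::bind_rows(bins_from_X(X2, "c2"), bins_from_X(X1, "c1"))
  f12 <- fit_hmm(b12, K = 2, seed = 9, n_restarts = 2, max_iter = 40)
  f21 <- fit_hmm(b21, K = 2, seed = 9, n_restarts = 2, max_iter = 40)
  expect_equal(f12$E, f21$E, tolerance = 1e-10)
  expect_equal(f12$loglik, f21$loglik, tolerance = 1e-10)
  model <- as_model(m, paste0("m", 1:3))
  s12 <- decode_states(b12, model)
  s21 <- decode_states(b21, model)
  expect_equal(s12$state[s12$chrom == "c1"], s21$state[s21$chrom == "c1"])
})

test_that("fixed seed gives bit-identical fits and restarts keep the best likelihood", {
  X <- withr::with_seed(41, matrix(rbinom(1200, 1, 0.35), 300, 4))
  bins <- bins_from_X(X)
  f1 <- fit_hmm(bins, K = 3, seed = 17, n_restarts = 3, max_iter = 50)
  f2 <- fit_hmm(bins, K = 3, seed = 17, n_restarts = 3, max_iter = 50)
  expect_identical(f1$E, f2$E)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("planted-model parameters are recovered after optimal state matching", {
  truth <- list(
    pi = c(0.3, 0.3, 0.2, 0.2),
    A = 0.88 * diag(4) + 0.12 * matrix(0.25, 4, 4),
    E = rbind(c(0.95, 0.9, 0.05, 0.05), c(0.05, 0.8, 0.85, 0.05),
              c(0.05, 0.05, 0.9, 0.1), c(0.02, 0.02, 0.05, 0.95))
  )
  sim <- simulate_hmm_sequence(truth$pi, truth$A, truth$E,
                               lengths = rep(5000, 4), seed = 77)
  bins <- dplyr::bind_rows(purrr::map(1:4, function(s) {
    bins_from_X(sim$X[sim$seq_id == s, ], paste0("c", s))
  }))
  fit <- fit_hmm(bins, K = 4, seed = 3, n_restarts = 3)
  p <- match_states(fit$E, truth$E)
  expect_lt(max(abs(fit$E[p, ] - truth$E)), 0.05)
  expect_lt(max(abs(fit$A[p, p] - truth$A)), 0.1)
})

test_that("state-number scan reports BIC and recovers a small planted K", {
  truth <- list(pi = c(0.4, 0.3, 0.3),
                A = 0.85 * diag(3) + 0.15 * matrix(1 / 3, 3, 3),
                E = rbind(c(0.95, 0.05, 0.05), c(0.05, 0.95, 0.05), c(0.05, 0.05, 0.95)))
  sim <- simulate_hmm_sequence(truth$pi, truth$A, truth$E, lengths = 3000, seed = 19)
  bins <- bins_from_X(sim$X)
  scan <- scan_state_number(bins, K_range = 2:5, seed = 7, n_restarts = 2,
                            max_iter = 100)
  expect_equal(nrow(scan), 4)
  expect_equal(scan$n_params, (2:5 - 1) + (2:5) * (2:5 - 1) + (2:5) * 3)
  best <- scan$K[which.min(scan$bic)]
  expect_true(abs(best - 3) <= 1)
  one <- scan_state_number(bins, K_range = 4, seed = 7, n_restarts = 1, max_iter = 30)
  expect_equal(nrow(one), 1)
})

test_that("binarization follows overlap and Poisson-tail rules", {
  layout <- make_layout(c(chr1 = 2000))
  bins <- bin_genome(layout, 200)
  pk <- tibble::tibble(chrom = "chr1", start = 450, end = 1050, summit = NA_real_)
  b <- binarize_marks(list(H3K4me3 = pk), bins)
  expect_equal(b$H3K4me3, as.integer(seq_len(10) %in% 3:6))  # bins 3..6 touch [450,1050)
  empty <- binarize_marks(list(H3K4me3 = pk[0, ]), bins)
  expect_true(all(empty$H3K4me3 == 0))

  # Poisson: mean 2, count 2 -> upper-tail p ~ 0.32 >= 1e-4 -> 0
  counts <- c(2, 2, 2, 2, 2, 2, 2, 2, 2, 2)
  expect_equal(sum(binarize_marks(list(s = counts), bins,
                                  method = "poisson_signal")$s), 0)
  # direct-summation tail check: a large count is called
  counts[3] <- 12
  pb <- binarize_marks(list(s = counts), bins, method = "poisson_signal")
  lam <- mean(counts)
  tail_direct <- 1 - sum(exp(-lam) * lam^(0:11) / factorial(0:11))
  expect_equal(pb$s[3], as.integer(tail_direct < 1e-4))
  expect_warning(binarize_marks(list(s = rep(0, 10)), bins, method = "poisson_signal"),
                 "all-zero")
})

test_that("state dynamics counts differing bins and the full cross table", {
  lay <- make_layout(c(chr1 = 2000))
  bins <- bin_genome(lay, 200)
  seg_a <- dplyr::mutate(bins, state = c(1, 1, 2, 2, 3, 3, 1, 1, 2, 2))
  seg_b <- dplyr::mutate(bins, state = c(1, 2, 2, 2, 3, 1, 1, 1, 2, 3))
  sd <- state_dynamics(seg_a, seg_b)
  expect_equal(sd$fraction_dynamic, 0.3)
  tr <- sd$transitions
  expect_equal(tr$n[tr$state_a == 1 & tr$state_b == 2], 1)
  expect_equal(sum(tr$n[tr$state_a == 2]), 4)
  expect_equal(state_dynamics(seg_a, seg_a)$fraction_dynamic, 0)
  seg_c <- dplyr::mutate(bins, state = c(2, 2, 3, 3, 1, 1, 2, 2, 3, 3))
  expect_equal(state_dynamics(seg_a, seg_c)$fraction_dynamic, 1)
  expect_error(state_dynamics(seg_a, seg_b[1:5, ]), "same binned genome")
})

test_that("uniform random segmentation has near-unit feature enrichments", {
  lay <- make_layout(c(chr1 = 100000))
  genes <- rand_genes(lay, 10, seed = 55)
  idx <- build_feature_index(genes, lay, promoter_window = 1000)
  bins <- bin_genome(lay, 200)
  seg <- withr::with_seed(56, dplyr::mutate(bins, state = sample(1:2, nrow(bins), TRUE)))
  attr(seg, "K") <- 2
  ann <- annotate_states(seg, lay, index = idx)
  expect_equal(sum(ann$states$genome_fraction), 1)
  big <- ann$feature_enrichment[ann$feature_enrichment$class %in%
                                  c("intergenic", "coding_exon"), ]
  expect_true(all(abs(big$fold_enrichment - 1) < 0.25))
  # closed form on a toy layout: one state exactly covering one TE class
  bins2 <- bin_genome(make_layout(c(c1 = 1000)), 100)
  seg2 <- dplyr::mutate(bins2, state = c(rep(1, 2), rep(2, 8)))
  attr(seg2, "K") <- 3
  te <- tibble::tibble(chrom = "c1", start = 0, end = 200, class = "Gypsy")
  ann2 <- annotate_states(seg2, make_layout(c(c1 = 1000)), te = te)
  fe <- ann2$te_enrichment
  expect_equal(fe$fold_enrichment[fe$state == 1], 1000 / 200)
  expect_true(is.na(fe$fold_enrichment[fe$state == 3]))  # absent state: missing
})
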