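# Bernoulli-emission hidden Markov model over binarized mark calls.
#
# The emission model is a product of independent Bernoullis per mark
# (ChromHMM's model): P(x | state k) = prod_m E[k,m]^x_m (1 - E[k,m])^(1-x_m).
# Chromosomes are treated as independent observation sequences. Numerics use
# per-position scaling constants, so likelihoods never underflow even on
# millions of bins; results are bit-identical for a fixed seed.

.EM_CLAMP <- 1e-10

# Extract the binary observation matrix and per-chromosome row indices from a
# binarized-bins tibble (coordinate columns + one 0/1 column per mark).
.binarized_matrix <- function(bins, marks = NULL) {
  if (is.null(marks)) marks <- setdiff(names(bins), c("chrom", "start", "end", "bin"))
  if (length(marks) == 0) stop("no mark columns found")
  X <- as.matrix(bins[marks])
  if (!all(X %in% c(0, 1))) stop("binarized matrix entries must be 0/1")
  storage.mode(X) <- "double"
  seqs <- split(seq_len(nrow(bins)), factor(bins$chrom, levels = unique(bins$chrom)))
  list(X = X, marks = marks, seqs = seqs)
}

# Per-position emission likelihood matrix (T x K), with E clamped away from
# 0/1 only inside the likelihood so stored parameters stay exact.
.emission_lik <- function(X, E, log = FALSE) {
  Ec <- pmin(pmax(E, .EM_CLAMP), 1 - .EM_CLAMP)
  logB <- X %*% t(log(Ec)) + (1 - X) %*% t(log(1 - Ec))
  if (log) logB else exp(logB)
}

#' Fit a Bernoulli-emission HMM to binarized mark calls
#'
#' Baum-Welch (EM) with `n_restarts` random seeded initialisations, keeping
#' the restart with the highest log-likelihood. The log-likelihood is
#' asserted non-decreasing at every iteration. With `K = 1` the fit reduces
#' to the closed form: emissions are the column means of the data.
#'
#' @param bins Binarized bins tibble ([binarize_marks()]): coordinate columns
#'   plus one 0/1 column per mark.
#' @param K Number of chromatin states (>= 1).
#' @param seed Integer seed controlling the random restarts; fixed seed gives
#'   bit-identical results.
#' @param n_restarts Number of random initialisations (default 3).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-4).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param marks Mark columns to use; defaults to every non-coordinate column.
#' @return A `bernoulli_hmm` object: `K`, `marks`, `pi`, `A` (K x K
#'   transitions), `E` (K x M emission probabilities), `loglik`, `ll_trace`
#'   (per kept restart), `n_iter`, `converged`, `seed`, `n_bins`.
#' @export
fit_hmm <- function(bins, K, seed = 1, n_restarts = 3, tol = 1e-4,
                    max_iter = 500, marks = NULL) {
  stopifnot(K >= 1, n_restarts >= 1)
  bm <- .binarized_matrix(bins, marks)
  X <- bm$X
  if (nrow(X) == 0) stop("empty binarized matrix")
  M <- ncol(X)
  n_distinct <- nrow(unique(X))
  if (K > n_distinct) {
    warning(sprintf("K = %d exceeds the %d distinct observed rows; degenerate states possible",
                    K, n_distinct))
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init <- list(
        pi = .rnorm_simplex(K),
        A = t(apply(matrix(stats::runif(K * K, 0.05, 1), K), 1, function(v) v / sum(v))),
        E = matrix(stats::runif(K * M, 0.1, 0.9), K, M)
      )
      fit <- .baum_welch(X, bm$seqs, init, tol, max_iter)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  structure(list(K = K, marks = bm$marks, pi = best$pi, A = best$A,
                 E = matrix(best$E, K, M, dimnames = list(NULL, bm$marks)),
                 loglik = best$loglik, ll_trace = best$ll_trace,
                 n_iter = best$n_iter, converged = best$converged,
                 seed = seed, n_bins = nrow(X)),
            class = "bernoulli_hmm")
}

.rnorm_simplex <- function(K) {
  v <- stats::runif(K, 0.05, 1)
  v / sum(v)
}

.baum_welch <- function(X, seqs, init, tol, max_iter) {
  pi <- init$pi; A <- init$A; E <- init$E
  K <- length(pi)
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  it <- 0
  repeat {
    it <- it + 1
    ll <- 0
    gamma1 <- numeric(K)
    xi_tot <- matrix(0, K, K)
    gX <- matrix(0, K, ncol(X))
    gsum <- numeric(K)
    for (idx in seqs) {
      if (length(idx) == 0) next
      B <- .emission_lik(X[idx, , drop = FALSE], E)
      fb <- .cpp_forward_backward(B, pi, A)
      ll <- ll + fb$loglik
      gamma1 <- gamma1 + fb$gamma[1, ]
      xi_tot <- xi_tot + fb$xi
      gX <- gX + t(fb$gamma) %*% X[idx, , drop = FALSE]
      gsum <- gsum + colSums(fb$gamma)
    }
    if (ll < ll_prev - 1e-8 * max(1, abs(ll_prev))) {
      stop(sprintf("Baum-Welch log-likelihood decreased (%.10g -> %.10g)", ll_prev, ll))
    }
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && abs(ll - ll_prev) < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    ll_prev <- ll
    # M-step
    pi <- gamma1 / sum(gamma1)
    rs <- rowSums(xi_tot)
    A <- xi_tot / ifelse(rs > 0, rs, 1)
    A[rs == 0, ] <- 1 / K
    E <- gX / ifelse(gsum > 0, gsum, 1)
    E[gsum == 0, ] <- 0.5
  }
  list(pi = pi, A = A, E = E, loglik = ll, ll_trace = ll_trace,
       n_iter = it, converged = converged)
}

#' Forward log-likelihood of binarized data under an HMM
#'
#' @param bins Binarized bins tibble.
#' @param model A `bernoulli_hmm`.
#' @return Total log-likelihood over all chromosome sequences.
#' @export
hmm_loglik <- function(bins, model) {
  bm <- .binarized_matrix(bins, model$marks)
  sum(purrr::map_dbl(bm$seqs, function(idx) {
    if (length(idx) == 0) return(0)
    B <- .emission_lik(bm$X[idx, , drop = FALSE], model$E)
    .cpp_forward_backward(B, model$pi, model$A)$loglik
  }))
}

#' Posterior state marginals per bin
#'
#' Forward-backward marginals; each row sums to 1.
#' @inheritParams hmm_loglik
#' @return Matrix of `n_bins` x `K` posterior probabilities.
#' @export
hmm_posterior <- function(bins, model) {
  bm <- .binarized_matrix(bins, model$marks)
  out <- matrix(NA_real_, nrow(bm$X), model$K)
  for (idx in bm$seqs) {
    if (length(idx) == 0) next
    B <- .emission_lik(bm$X[idx, , drop = FALSE], model$E)
    out[idx, ] <- .cpp_forward_backward(B, model$pi, model$A)$gamma
  }
  out
}

#' Decode per-bin chromatin states
#'
#' `posterior` labels each bin with the argmax of its forward-backward
#' marginal; `viterbi` returns the jointly most probable path. Both are
#' deterministic given the model.
#'
#' @inheritParams hmm_loglik
#' @param method `"posterior"` (default) or `"viterbi"`.
#' @return The bins tibble with a `state` column (1..K); attribute `K`.
#' @export
decode_states <- function(bins, model, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  bm <- .binarized_matrix(bins, model$marks)
  state <- integer(nrow(bm$X))
  if (method == "posterior") {
    g <- hmm_posterior(bins, model)
    state <- max.col(g, ties.method = "first")
  } else {
    logpi <- log(pmax(model$pi, .EM_CLAMP))
    logA <- log(pmax(model$A, .EM_CLAMP))
    for (idx in bm$seqs) {
      if (length(idx) == 0) next
      logB <- .emission_lik(bm$X[idx, , drop = FALSE], model$E, log = TRUE)
      state[idx] <- .cpp_viterbi(logB, logpi, logA)
    }
  }
  out <- bins[c("chrom", "start", "end", if ("bin" %in% names(bins)) "bin")]
  out$state <- as.integer(state)
  structure(out, K = model$K, method = method,
            class = c("state_segmentation", class(out)))
}

#' Scan the number of chromatin states
#'
#' Fits one model per candidate `K` (same seed policy for each) and reports
#' log-likelihood and BIC, where
#' `BIC = -2 LL + (K - 1 + K(K-1) + K M) log(n_bins)`.
#' The choice of K is left to the caller; the BIC argmin is a default guide.
#'
#' @inheritParams fit_hmm
#' @param K_range Candidate state counts (default 8:20, the usual range
#'   explored for plant chromatin-state maps).
#' @return Tibble `K`, `loglik`, `n_params`, `bic`, `converged`.
#' @export
scan_state_number <- function(bins, K_range = 8:20, seed = 1, n_restarts = 3,
                              tol = 1e-4, max_iter = 500, marks = NULL) {
  stopifnot(length(K_range) >= 1)
  purrr::map_dfr(K_range, function(K) {
    fit <- fit_hmm(bins, K = K, seed = seed, n_restarts = n_restarts,
                   tol = tol, max_iter = max_iter, marks = marks)
    M <- length(fit$marks)
    n_params <- (K - 1) + K * (K - 1) + K * M
    tibble::tibble(K = K, loglik = fit$loglik, n_params = n_params,
                   bic = -2 * fit$loglik + n_params * log(fit$n_bins),
                   converged = fit$converged)
  })
}

#' Sample an observation sequence from a Bernoulli HMM
#'
#' Generator used both by the synthetic-data module and by parameter-recovery
#' tests: samples the hidden state path and the per-mark Bernoulli emissions.
#'
#' @param pi,A,E HMM parameters (initial, transition, emission).
#' @param lengths Integer vector of sequence lengths (one per chromosome).
#' @param seed Integer seed.
#' @return List with `states` (integer vector per sequence, concatenated),
#'   `X` (0/1 matrix), `seq_id` (sequence index per row).
#' @export
simulate_hmm_sequence <- function(pi, A, E, lengths, seed = 1) {
  K <- length(pi)
  M <- ncol(E)
  withr::with_seed(seed, {
    states <- integer(0); seq_id <- integer(0)
    for (s in seq_along(lengths)) {
      Tn <- lengths[s]
      st <- integer(Tn)
      st[1] <- sample.int(K, 1, prob = pi)
      for (t in seq_len(Tn - 1)) st[t + 1] <- sample.int(K, 1, prob = A[st[t], ])
      states <- c(states, st)
      seq_id <- c(seq_id, rep(s, Tn))
    }
    X <- matrix(stats::rbinom(length(states) * M, 1, E[states, ]),
                nrow = length(states), ncol = M)
  })
  list(states = states, X = X, seq_id = seq_id)
}

#' Match states of an estimated model to a reference by emission similarity
#'
#' Greedy optimal assignment minimising total L1 distance between emission
#' rows (exact Hungarian-style search over permutations for K <= 8).
#'
#' @param E_est,E_ref Emission matrices with equal dimensions.
#' @return Integer permutation `p` such that `E_est[p, ]` aligns with `E_ref`.
#' @export
match_states <- function(E_est, E_ref) {
  K <- nrow(E_ref)
  stopifnot(nrow(E_est) == K)
  cost <- outer(seq_len(K), seq_len(K),
                Vectorize(function(i, j) sum(abs(E_est[i, ] - E_ref[j, ]))))
  if (K <= 8) {
    perms <- .permutations(K)
    tot <- apply(perms, 1, function(p) sum(cost[cbind(p, seq_len(K))]))
    perms[which.min(tot), ]
  } else {
    p <- integer(K)
    free <- seq_len(K)
    for (j in order(apply(cost, 2, min))) {
      i <- free[which.min(cost[free, j])]
      p[j] <- i
      free <- setdiff(free, i)
    }
    p
  }
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))
  }))
}

#' @export
print.bernoulli_hmm <- function(x, ...) {
  cat(sprintf("Bernoulli-emission HMM: K = %d states, %d marks, %d bins\n",
              x$K, length(x$marks), x$n_bins))
  cat(sprintf("log-likelihood %.4f after %d iterations (%s)\n", x$loglik,
              x$n_iter, if (x$converged) "converged" else "not converged"))
  cat("Emission probabilities:\n")
  print(round(x$E, 3))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted chromatin-state HMM
#'
#' One row per (state, mark) with the emission probability, plus the state's
#' initial probability and self-transition persistence.
#' @param x A `bernoulli_hmm`.
#' @param ... Unused.
#' @export
tidy.bernoulli_hmm <- function(x, ...) {
  tibble::tibble(
    state = rep(seq_len(x$K), each = length(x$marks)),
    mark = rep(x$marks, x$K),
    emission = as.vector(t(x$E)),
    initial = rep(x$pi, each = length(x$marks)),
    persistence = rep(diag(x$A), each = length(x$marks))
  )
}

#' Model-level summary of a fitted chromatin-state HMM
#' @param x A `bernoulli_hmm`.
#' @param ... Unused.
#' @export
glance.bernoulli_hmm <- function(x, ...) {
  n_params <- (x$K - 1) + x$K * (x$K - 1) + x$K * length(x$marks)
  tibble::tibble(K = x$K, n_marks = length(x$marks), n_bins = x$n_bins,
                 loglik = x$loglik, n_params = n_params,
                 bic = -2 * x$loglik + n_params * log(x$n_bins),
                 n_iter = x$n_iter, converged = x$converged)
}
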