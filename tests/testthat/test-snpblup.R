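test_that("the matrix-free operator agrees with a dense MME assembly", {
  case <- tiny_mme_case(n = 6, N = 8, T = 3, seed = 42)
  op <- mme_operator(case$centered, case$traits, case$prior,
                     record_weight = case$w, epsilon = case$eps)
  dense <- dense_mme(op$M, case$traits$R, case$w, case$eps,
                     vsnp_blocks(case$prior))
  dim_sys <- nrow(dense$A)
  set.seed(1)
  for (k in 1:5) {
    v <- rnorm(dim_sys)
    expect_rel_equal(apply_mme(op, v), as.vector(dense$A %*% v), 1e-9)
  }
  expect_equal(apply_mme(op, numeric(dim_sys)), numeric(dim_sys))
})

test_that("the operator is symmetric on random vector pairs", {
  case <- tiny_mme_case(n = 7, N = 9, T = 3, seed = 43)
  op <- mme_operator(case$centered, case$traits, case$prior,
                     record_weight = case$w, epsilon = case$eps)
  d <- 3 + 7 * 3 + ncol(case$centered$matrix) * 3
  set.seed(2)
  for (k in 1:20) {
    v <- rnorm(d); u <- rnorm(d)
    lhs <- sum(apply_mme(op, v) * u)
    rhs <- sum(v * apply_mme(op, u))
    expect_equal(lhs, rhs, tolerance = 1e-8)
  }
})

test_that("preconditioner blocks equal the diagonal blocks of the dense assembly", {
  case <- tiny_mme_case(n = 5, N = 6, T = 3, seed = 44)
  op <- mme_operator(case$centered, case$traits, case$prior,
                     record_weight = case$w, epsilon = case$eps)
  prec <- block_preconditioner(op)
  dense <- dense_mme(op$M, case$traits$R, case$w, case$eps,
                     vsnp_blocks(case$prior))
  T <- 3; n <- 5; N <- ncol(case$centered$matrix)
  expect_equal(prec$P_mu, solve(dense$A[1:T, 1:T]), tolerance = 1e-10,
               ignore_attr = TRUE)
  for (i in c(1, n)) {
    idx <- T + (i - 1) * T + seq_len(T)
    expect_equal(matrix(prec$Pa[i, ], T, T), solve(dense$A[idx, idx]),
                 tolerance = 1e-10)
  }
  for (j in c(1, N)) {
    idx <- T + n * T + (j - 1) * T + seq_len(T)
    expect_equal(matrix(prec$Ps[j, ], T, T), solve(dense$A[idx, idx]),
                 tolerance = 1e-10)
  }
  # applying the preconditioner twice equals the dense (M^-1)^2
  Minv <- matrix(0, nrow(dense$A), ncol(dense$A))
  Minv[1:T, 1:T] <- prec$P_mu
  for (i in seq_len(n)) {
    idx <- T + (i - 1) * T + seq_len(T)
    Minv[idx, idx] <- matrix(prec$Pa[i, ], T, T)
  }
  for (j in seq_len(N)) {
    idx <- T + n * T + (j - 1) * T + seq_len(T)
    Minv[idx, idx] <- matrix(prec$Ps[j, ], T, T)
  }
  set.seed(3)
  v <- rnorm(nrow(Minv))
  expect_rel_equal(apply_preconditioner(prec, apply_preconditioner(prec, v)),
                   as.vector(Minv %*% Minv %*% v), 1e-10)
})

test_that("PCG matches a dense direct solve", {
  for (seed in c(42, 77)) {
    case <- tiny_mme_case(n = 6, N = 8, T = 3, seed = seed)
    fit <- fit_snpblup(case$centered, case$Y, case$traits, case$prior,
                       record_weight = case$w, epsilon = case$eps,
                       tolerance = 1e-11)
    expect_true(fit$converged)
    dense <- dense_mme(case$centered$matrix, case$traits$R, case$w, case$eps,
                       vsnp_blocks(case$prior))
    x_dense <- solve(dense$A, dense$rhs_of(case$Y))
    x_pcg <- c(fit$mu_hat, as.vector(t(fit$u_hat)), as.vector(t(fit$b_hat)))
    expect_rel_equal(x_pcg, x_dense, 1e-7)
  }
})

test_that("u approaches Zb as epsilon shrinks", {
  case <- tiny_mme_case(n = 10, N = 12, T = 3, seed = 45)
  gap <- vapply(c(0.01, 0.001, 1e-4), function(eps) {
    fit <- fit_snpblup(case$centered, case$Y, case$traits, case$prior,
                       record_weight = case$w, epsilon = eps,
                       tolerance = 1e-11)
    Mb <- case$centered$matrix %*% fit$b_hat
    sqrt(sum((fit$u_hat - Mb)^2)) / sqrt(sum(fit$u_hat^2))
  }, numeric(1))
  expect_lt(gap[1], 0.05)
  expect_true(all(diff(gap) < 0))   # monotone decrease over the epsilon sweep
})

test_that("unweighted SNP-BLUP equals the dense GBLUP-equivalent construction", {
  case <- tiny_mme_case(n = 8, N = 10, T = 3, seed = 46, scheme = "unweighted")
  fit <- fit_snpblup(case$centered, case$Y, case$traits, case$prior,
                     record_weight = case$w, epsilon = case$eps,
                     tolerance = 1e-11)
  M <- case$centered$matrix
  n <- nrow(M); T <- 3
  # genomic covariance of u: (M M' / scale_sum) x G + eps I, traits in animals
  K <- kronecker(tcrossprod(M) / case$centered$scale_sum, case$traits$G) +
    diag(case$eps, n * T)
  Vtot <- K + kronecker(diag(1 / case$w, n), case$traits$R)
  X <- kronecker(matrix(1, n, 1), diag(T))
  y <- as.vector(t(case$Y))
  Vinv <- solve(Vtot)
  mu_gls <- solve(t(X) %*% Vinv %*% X, t(X) %*% Vinv %*% y)
  u_blup <- K %*% Vinv %*% (y - X %*% mu_gls)
  expect_rel_equal(fit$mu_hat, as.vector(mu_gls), 1e-6)
  expect_rel_equal(as.vector(t(fit$u_hat)), as.vector(u_blup), 1e-6)
})

test_that("the solution is invariant to SNP permutation with matching prior blocks", {
  case <- tiny_mme_case(n = 8, N = 10, T = 3, seed = 47)
  fit1 <- fit_snpblup(case$centered, case$Y, case$traits, case$prior,
                      record_weight = case$w, epsilon = case$eps,
                      tolerance = 1e-11)
  N <- ncol(case$centered$matrix)
  set.seed(9)
  perm <- sample(N)
  centered2 <- case$centered
  centered2$matrix <- centered2$matrix[, perm, drop = FALSE]
  centered2$map <- centered2$map[perm, , drop = FALSE]
  centered2$allele_freq <- centered2$allele_freq[perm]
  prior2 <- case$prior
  prior2$smat <- prior2$smat[perm, , drop = FALSE]
  fit2 <- fit_snpblup(centered2, case$Y, case$traits, prior2,
                      record_weight = case$w, epsilon = case$eps,
                      tolerance = 1e-11)
  expect_equal(fit2$b_hat[order(perm), ], fit1$b_hat, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit2$u_hat, fit1$u_hat, tolerance = 1e-8)
})

test_that("the true residual is non-increasing across checkpoints and reported", {
  case <- tiny_mme_case(n = 12, N = 15, T = 3, seed = 48)
  op <- mme_operator(case$centered, case$traits, case$prior,
                     record_weight = case$w, epsilon = case$eps)
  wY <- case$w * case$Y
  rhs <- c(as.vector(op$Rinv %*% colSums(wY)),
           as.vector(t(wY %*% op$Rinv)),
           rep(0, ncol(case$centered$matrix) * 3))
  sol <- solve_mme(op, rhs, tolerance = 1e-10, check_every = 50)
  expect_true(sol$converged)
  expect_lt(sol$rel_residual, 1e-10)
  expect_true(all(diff(sol$history$rel_residual) <= 0))
  # zero right-hand side solves trivially
  sol0 <- solve_mme(op, rep(0, length(rhs)))
  expect_equal(sol0$x, rep(0, length(rhs)))
})

test_that("predictions are Z_v b_hat and consistent with fitted breeding values", {
  case <- tiny_mme_case(n = 10, N = 12, T = 3, seed = 49)
  fit <- fit_snpblup(case$centered, case$Y, case$traits, case$prior,
                     record_weight = case$w, epsilon = case$eps,
                     tolerance = 1e-11)
  # zero effects predict zero
  b0 <- fit$b_hat * 0
  expect_equal(unname(predict_gebv(b0, case$centered)),
               matrix(0, 10, 3))
  # single-SNP forced arithmetic
  Z1 <- matrix(0.5, 1, 1, dimnames = list("v1", "s1"))
  centered1 <- structure(
    list(matrix = Z1, allele_freq = 0.5, scale_sum = 0.5,
         map = tibble::tibble(chromosome = "chr1", snp_id = "s1", position = 1L),
         reference_ids = "v1", n_dropped_monomorphic = 0L, n_imputed = 0L),
    class = "centered_genotypes")
  b1 <- matrix(c(1, 0, 0), 1, 3, dimnames = list("s1", paste0("t", 1:3)))
  expect_equal(unname(predict_gebv(b1, centered1)[1, ]), c(0.5, 0, 0))
  # training predictions equal u_hat within the epsilon coupling tolerance
  pred <- predict(fit, case$centered)
  expect_lt(sqrt(sum((pred - fit$u_hat)^2)) / sqrt(sum(fit$u_hat^2)), 0.02)
  # SNP set mismatch is caught
  expect_error(predict_gebv(b1, case$centered), "SNP set")
})
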