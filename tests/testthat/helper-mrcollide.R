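# Shared fixtures, built in code at test time.

# Small genotype matrix with known ids/alleles for toolkit tests.
make_test_geno <- function(n = 200, m = 5, seed = 1, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.1, 0.4)
  dos <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m,
                dimnames = list(NULL, paste0("rs", seq_len(m))))
  info <- data.frame(id = paste0("rs", seq_len(m)),
                     chrom = as.character(rep_len(1:2, m)),
                     pos = seq_len(m) * 1000L,
                     effect_allele = "A", other_allele = "G",
                     maf = maf, stringsAsFactors = FALSE)
  genotype_matrix(dos, info)
}

# Simple one-exposure instrumental DGP used across estimator tests:
# X = Gc gamma + c_x U + e, Y = beta X + c_y U + e_y (+ per-SNP alpha).
make_iv_dgp <- function(n = 2000, m = 10, beta = 0.3, gamma_scale = 0.15,
                        c_x = 0, c_y = 0, alpha = NULL, seed = 1) {
  set.seed(seed)
  maf <- runif(m, 0.1, 0.4)
  G <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m,
              dimnames = list(NULL, paste0("g", seq_len(m))))
  Gc <- sweep(G, 2, 2 * maf)
  gamma <- gamma_scale * runif(m, 0.5, 1.5)
  U <- rnorm(n)
  x <- drop(Gc %*% gamma) + c_x * U + rnorm(n)
  if (is.null(alpha)) alpha <- numeric(m)
  y <- beta * x + drop(Gc %*% alpha) + c_y * U + rnorm(n)
  list(G = G, Gc = Gc, x = x, y = y, U = U, gamma = gamma, maf = maf,
       beta = beta)
}

expect_within <- function(value, target, tol) {
  expect_lt(abs(value - target), tol)
}
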