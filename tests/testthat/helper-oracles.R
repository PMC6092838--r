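# Independent dense oracles used across tests. These deliberately avoid the
# package's sparse machinery: A by the tabular recursion, likelihoods and
# GLS/BLUP through explicit dense V.

# dense numerator relationship matrix, tabular method (parents before
# offspring, 0 = unknown)
oracle_tab_A <- function(sire, dam) {
  n <- length(sire)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    if (i > 1) for (j in seq_len(i - 1)) {
      a <- 0
      if (s > 0) a <- a + 0.5 * A[j, s]
      if (d > 0) a <- a + 0.5 * A[j, d]
      A[i, j] <- A[j, i] <- a
    }
  }
  A
}

# random sorted pedigree: founders then offspring of random earlier pairs
oracle_rand_ped <- function(n_founders, n_extra) {
  sire <- rep(0L, n_founders); dam <- rep(0L, n_founders)
  for (k in seq_len(n_extra)) {
    p <- sort(sample(length(sire), 2))
    sire <- c(sire, p[1]); dam <- c(dam, p[2])
  }
  list(sire = sire, dam = dam, n = length(sire))
}

# REML -2 log-likelihood via explicit dense V (X assumed full rank)
oracle_m2ll <- function(y, X, Vlist, theta) {
  V <- Reduce(`+`, Map(`*`, Vlist, theta))
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  as.numeric((n - p) * log(2 * pi) + determinant(V)$modulus +
               determinant(XVX)$modulus + t(y) %*% P %*% y)
}

# dense GLS fixed effects and BLUP of one random term u with V(u) = G s_u
oracle_gls <- function(y, X, Vlist, theta, Zu, G, s_u) {
  V <- Reduce(`+`, Map(`*`, Vlist, theta))
  Vi <- solve(V)
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  uhat <- s_u * G %*% t(Zu) %*% Vi %*% (y - X %*% bhat)
  list(b = as.numeric(bhat), u = as.numeric(uhat))
}

# toy records on a random pedigree; returns everything tests need to build
# both package designs and dense oracles (oracle matrices in pedigree order)
oracle_toy <- function(n_founders = 8, n_extra = 16, n_rec = 18,
                       n_lit = 5, n_pen = 4) {
  rp <- oracle_rand_ped(n_founders, n_extra)
  n_rec <- min(n_rec, rp$n)
  ped <- pedigree(tibble::tibble(animal = seq_len(rp$n), sire = rp$sire,
                                 dam = rp$dam))
  A <- oracle_tab_A(rp$sire, rp$dam)[ped$animal, ped$animal]
  rec <- tibble::tibble(animal = sample(rp$n, n_rec),
                        litter = sample(seq_len(n_lit), n_rec, TRUE),
                        pen = sample(seq_len(n_pen), n_rec, TRUE),
                        y = rnorm(n_rec, 10, 4))
  list(ped = ped, A = A, rec = rec)
}

# dense V component list for a design (oracle A in pedigree order)
oracle_vlist <- function(des, A, terms) {
  V <- list()
  if ("litter" %in% terms) V <- c(V, list(as.matrix(Matrix::tcrossprod(des$Zl))))
  if ("pen" %in% terms) V <- c(V, list(as.matrix(Matrix::tcrossprod(des$Zc))))
  V <- c(V, list(as.matrix(des$Za %*% A %*% Matrix::t(des$Za))),
         list(diag(des$R)))
  V
}

# small simulation config for fast tests
tiny_config <- function(...) {
  sim_config(n_sires = 3, n_dams_per_sire = 6, n_generations = 4,
             n_pheno_generations = 2, ...)
}
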