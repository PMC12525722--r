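# The three loss components and their weighted combination, with
# independent brute-force oracles.

# naive per-element implementations, sharing no code with the package
oracle_ce <- function(p, q, y) {
  total <- 0
  for (r in seq_along(y)) {
    total <- total - log(p[r, y[r] + 1]) - log(q[r, y[r] + 1])
  }
  total
}

oracle_kl <- function(p, q) {
  total <- 0
  for (r in seq_len(nrow(p))) {
    for (c in seq_len(ncol(p))) {
      if (p[r, c] > 0) total <- total + p[r, c] * log(p[r, c] / q[r, c])
    }
  }
  total
}

oracle_cmd <- function(D, H, K) {
  moment <- function(X, k) {
    mu <- colSums(X) / nrow(X)
    out <- numeric(ncol(X))
    for (i in seq_len(nrow(X))) out <- out + (X[i, ] - mu)^k
    out / nrow(X)
  }
  total <- sqrt(sum((colSums(D) / nrow(D) - colSums(H) / nrow(H))^2))
  for (k in 2:K) {
    total <- total + sqrt(sum((moment(D, k) - moment(H, k))^2))
  }
  total
}

rand_simplex2 <- function(m, seed) {
  withr::with_seed(seed, {
    a <- stats::runif(m, 0.01, 0.99)
    cbind(a, 1 - a, deparse.level = 0)
  })
}

test_that("supervised loss: closed forms and oracle agreement", {
  u <- matrix(0.5, 1, 2)
  expect_equal(supervised_loss(u, u, 1L), 2 * log(2))
  onehot <- matrix(c(0, 1), 1)
  expect_equal(supervised_loss(onehot, onehot, 1L), 0)
  for (seed in 1:50) {
    m <- withr::with_seed(seed, sample(1:30, 1))
    p <- rand_simplex2(m, seed)
    q <- rand_simplex2(m, seed + 10000)
    y <- withr::with_seed(seed + 20000, stats::rbinom(m, 1, 0.5))
    expect_equal(supervised_loss(p, q, y), oracle_ce(p, q, y),
                 tolerance = 1e-12)
  }
})

test_that("output matching: KL closed forms, additivity and non-negativity", {
  p <- rand_simplex2(5, 1)
  expect_equal(output_matching_loss(p, p), 0)
  expect_equal(output_matching_loss(matrix(c(1, 0), 1), matrix(0.5, 1, 2)),
               log(2))
  single <- output_matching_loss(p[1, , drop = FALSE],
                                 rand_simplex2(1, 99))
  doubled <- output_matching_loss(p[c(1, 1), ], rand_simplex2(1, 99)[c(1, 1), ])
  expect_equal(doubled, 2 * single)
  for (seed in 1:100) {
    m <- withr::with_seed(seed, sample(1:20, 1))
    pp <- rand_simplex2(m, seed + 1)
    qq <- rand_simplex2(m, seed + 2)
    got <- output_matching_loss(pp, qq)
    expect_gte(got, 0) # Gibbs inequality
    expect_equal(got, oracle_kl(pp, qq), tolerance = 1e-12)
  }
})

test_that("central moments: degenerate and symmetric cases", {
  v <- matrix(c(2, -1, 3), 1)
  for (k in 2:5) expect_equal(central_moments(v, k), rep(0, 3))
  X <- matrix(c(-1, 1), 2, 1)
  expect_equal(central_moments(X, 2), 1)
  expect_equal(central_moments(X, 3), 0)
  expect_error(central_moments(matrix(numeric(0), 0, 2), 2), "at least one")
})

test_that("cmd_loss: closed forms, symmetry and oracle agreement", {
  expect_equal(cmd_loss(matrix(c(0, 0), 1), matrix(c(1, 1), 1)), sqrt(2))
  D <- withr::with_seed(3, matrix(stats::rnorm(40), 10))
  expect_equal(cmd_loss(D, D), 0)
  H <- withr::with_seed(4, matrix(stats::rnorm(40), 10))
  expect_equal(cmd_loss(D, H), cmd_loss(H, D))
  expect_gte(cmd_loss(D, H), 0)
  expect_error(cmd_loss(D, H[, 1:2]), "column")
  for (seed in 1:100) {
    dims <- withr::with_seed(seed, c(sample(1:50, 2, replace = TRUE),
                                     sample(1:8, 1)))
    Dr <- withr::with_seed(seed + 1, matrix(stats::rnorm(dims[1] * dims[3]),
                                            dims[1]))
    Hr <- withr::with_seed(seed + 2, matrix(stats::rnorm(dims[2] * dims[3]),
                                            dims[2]))
    expect_equal(cmd_loss(Dr, Hr, K = 5), oracle_cmd(Dr, Hr, 5),
                 tolerance = 1e-9)
  }
})

test_that("total_loss combines components linearly with defaults (1, 2)", {
  lb <- total_loss(1, 2, 3)
  expect_equal(lb$total, 9) # 1 + 1*2 + 2*3
  expect_equal(total_loss(5, 100, 200, alpha = 0, gamma = 0)$total, 5)
  for (seed in 1:20) {
    comp <- withr::with_seed(seed, stats::runif(3, 0, 10))
    expect_equal(total_loss(comp[1], comp[2], comp[3])$total,
                 comp[1] + comp[2] + 2 * comp[3])
    w <- withr::with_seed(seed + 50, stats::runif(2, 0, 3))
    expect_equal(total_loss(comp[1], comp[2], comp[3], w[1], w[2])$total,
                 comp[1] + w[1] * comp[2] + w[2] * comp[3])
  }
  expect_error(total_loss(1, 1, 1, alpha = -1), "non-negative")
})

test_that("tape losses agree with the plain implementations and their
           gradients match finite differences", {
  # agreement of the differentiable forms with the public functions
  m <- 6; d <- 3
  logit_p <- withr::with_seed(21, matrix(stats::rnorm(m * 2), m))
  logit_q <- withr::with_seed(22, matrix(stats::rnorm(m * 2), m))
  D <- withr::with_seed(23, matrix(stats::rnorm(5 * d), 5))
  H <- withr::with_seed(24, matrix(stats::rnorm(7 * d), 7))
  soft <- function(z) t(apply(z, 1, function(r) exp(r) / sum(exp(r))))

  tape <- mvddi:::ad_tape()
  np <- mvddi:::ad_param(tape, logit_p)
  nq <- mvddi:::ad_param(tape, logit_q)
  kl_node <- mvddi:::.ad_kl_from_logits(np, nq)
  expect_equal(as.numeric(kl_node$value),
               output_matching_loss(soft(logit_p), soft(logit_q)),
               tolerance = 1e-10)

  tape2 <- mvddi:::ad_tape()
  nD <- mvddi:::ad_param(tape2, D)
  nH <- mvddi:::ad_param(tape2, H)
  cmd_node <- mvddi:::.ad_cmd(nD, nH, K = 5L)
  expect_equal(as.numeric(cmd_node$value), cmd_loss(D, H, K = 5),
               tolerance = 1e-10)

  # finite-difference gradient checks on tiny instances
  fd_check <- function(valfun, X, gX, label) {
    eps <- 1e-5
    idx <- rbind(c(1, 1), c(2, 2))
    for (r in seq_len(nrow(idx))) {
      Xp <- X; Xp[idx[r, 1], idx[r, 2]] <- Xp[idx[r, 1], idx[r, 2]] + eps
      Xm <- X; Xm[idx[r, 1], idx[r, 2]] <- Xm[idx[r, 1], idx[r, 2]] - eps
      fd <- (valfun(Xp) - valfun(Xm)) / (2 * eps)
      expect_equal(gX[idx[r, 1], idx[r, 2]], fd, tolerance = 1e-4,
                   label = label)
    }
  }
  # KL gradient wrt p-logits
  mvddi:::ad_backward(tape, kl_node)
  fd_check(function(X) {
    t <- mvddi:::ad_tape()
    as.numeric(mvddi:::.ad_kl_from_logits(
      mvddi:::ad_param(t, X), mvddi:::ad_const(t, logit_q))$value)
  }, logit_p, np$grad, "KL p-logit gradient")
  # CMD gradient wrt D
  mvddi:::ad_backward(tape2, cmd_node)
  fd_check(function(X) {
    t <- mvddi:::ad_tape()
    as.numeric(mvddi:::.ad_cmd(mvddi:::ad_param(t, X),
                               mvddi:::ad_const(t, H), 5L)$value)
  }, D, nD$grad, "CMD D gradient")
  # supervised CE gradient wrt logits
  y <- c(1L, 0L, 1L, 1L, 0L, 0L)
  tape3 <- mvddi:::ad_tape()
  nl <- mvddi:::ad_param(tape3, logit_p)
  ce_node <- mvddi:::ad_ce_logits(nl, y + 1L)
  mvddi:::ad_backward(tape3, ce_node)
  fd_check(function(X) {
    t <- mvddi:::ad_tape()
    as.numeric(mvddi:::ad_ce_logits(mvddi:::ad_param(t, X), y + 1L)$value)
  }, logit_p, nl$grad, "CE logit gradient")
})
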