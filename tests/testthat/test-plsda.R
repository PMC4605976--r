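# Printed 4x2 fixture with a one-step NIPALS hand computation:
#   X = [-1 -1; -0.5 0.5; 0.5 -0.5; 1 1],  y = (-1, -1, 1, 1)
#   w  = X'y / ||X'y||      = (3, 1)/sqrt(10)
#   t  = Xw                 = (-4, -1, 1, 4)/sqrt(10)
#   q  = y't / t't          = 10/sqrt(10) / (34/10) = sqrt(10) * 10/34
#   p  = X't / t't,   b = w q / (p'w)  = (15/17, 5/17)
fixture_X <- matrix(c(-1, -0.5, 0.5, 1, -1, 0.5, -0.5, 1), 4, 2)
fixture_y <- c(-1, -1, 1, 1)

test_that("one-component fit reproduces the hand-worked NIPALS fixture", {
  m <- fit_plsda(fixture_X, fixture_y, ncomp = 1, scale = FALSE)
  expect_equal(unname(m$W[, 1]), c(3, 1) / sqrt(10), tolerance = 1e-12)
  expect_equal(unname(m$T[, 1]), c(-4, -1, 1, 4) / sqrt(10),
               tolerance = 1e-12)
  expect_equal(unname(m$b), c(15 / 17, 5 / 17), tolerance = 1e-12)
})

test_that("fit matches an independent PLS implementation", {
  set.seed(5)
  X <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("v", 1:8)))
  y <- rep(c(-1, 1), each = 15)
  m <- fit_plsda(X, y, ncomp = 3)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = TRUE)
  expect_equal(unname(diag(abs(cor(m$T, mo$variates$X)))), rep(1, 3),
               tolerance = 1e-8)
  ours <- predict(m, X)$score
  theirs <- unname(predict(mo, X)$predict[, 1, 3]) - mean(y)
  expect_equal(unname(ours), theirs, tolerance = 1e-8)
})

test_that("regression-vector path agrees with the score path", {
  mt <- rand_table(10, 12, p = 7, seed = 41)
  m <- fit_plsda(mt, ncomp = 3)
  via_b <- m$X_scaled %*% m$b
  via_t <- m$T %*% m$q
  expect_equal(via_b, via_t, tolerance = 1e-8)
  # score columns mutually orthogonal
  G <- crossprod(m$T)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
})

test_that("a perfectly ordered univariate predictor separates classes", {
  x <- matrix(1:10, ncol = 1, dimnames = list(NULL, "v1"))
  y <- rep(c(-1, 1), each = 5)
  m <- fit_plsda(x, y, ncomp = 1)
  pred <- predict(m, x)
  expect_equal(auc(pred$score, y, positive = "1"), 1.0)
})

test_that("duplicated columns get identical coefficients", {
  set.seed(13)
  x1 <- rnorm(16)
  X <- cbind(a = x1, b = x1, c = rnorm(16))
  y <- rep(c(-1, 1), each = 8)
  m <- fit_plsda(X, y, ncomp = 2)
  expect_equal(unname(m$b["a"]), unname(m$b["b"]), tolerance = 1e-8)
})

test_that("prediction handles training data, ties and degenerate input", {
  mt <- rand_table(6, 6, p = 5, seed = 51)
  m <- fit_plsda(mt, ncomp = 2)
  pr <- predict(m, mt)
  expect_equal(unname(pr$score), unname(drop(m$X_scaled %*% m$b)),
               tolerance = 1e-12)
  # duplicated test row scores identically
  two <- mt$values[c(3, 3), ]
  rownames(two) <- c("r1", "r2")
  s2 <- predict(m, two)$score
  expect_equal(s2[[1]], s2[[2]])
  # score exactly on the cut-off goes to the negative-coded class
  m0 <- m
  m0$b[] <- 0
  cls <- predict(m0, mt)$class
  expect_true(all(cls == m$y_coding[["negative"]]))
  # variable mismatch is an error
  expect_error(predict(m, mt$values[, 1:3]), "missing model variables")
})

test_that("rank and class prerequisites are enforced", {
  x <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fit_plsda(x, rep(c(-1, 1), 3), ncomp = 5), "rank")
  expect_error(fit_plsda(x, rep(1, 6)), "single-class")
})

test_that("LOO complexity selection favours the informative dimension", {
  hits <- 0L
  for (i in 1:100) {
    set.seed(600 + i)
    n <- 60
    y <- rep(c(-1, 1), each = n / 2)
    # strictly null noise block: orthogonalized against the response so
    # the only y-related structure is the single predictive variable
    noise <- qr.resid(qr(cbind(1, y)), matrix(rnorm(n * 9), n, 9))
    X <- cbind(sig = y * 3 + rnorm(n, sd = 0.3), noise)
    colnames(X) <- paste0("v", 1:10)
    if (select_complexity_loo(X, y, A_max = 4) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
  expect_identical(as.integer(select_complexity_loo(
    matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b"))),
    rep(c(-1, 1), 10), A_max = 1)), 1L)
})

test_that("LOO error is near one half for a pure-noise response", {
  errs <- vapply(1:100, function(i) {
    set.seed(700 + i)
    X <- matrix(rnorm(24 * 6), 24, 6,
                dimnames = list(NULL, paste0("v", 1:6)))
    y <- rep(c(-1, 1), each = 12)
    a <- select_complexity_loo(X, y, A_max = 3)
    attr(a, "loo_error")[as.integer(a)]
  }, numeric(1))
  expect_lt(abs(mean(errs) - 0.5), 0.15)
})

test_that("VIP scores follow the closed form and its normalization", {
  # mean squared VIP is 1 for any fitted model
  for (i in 1:5) {
    mt <- rand_table(7, 9, p = 4 + i, seed = 80 + i)
    m <- fit_plsda(mt, ncomp = 2)
    expect_equal(mean(vip_scores(m)^2), 1.0, tolerance = 1e-10)
  }
  # single variable: VIP identically 1
  m1 <- fit_plsda(matrix(c(1, 3, 2, 5, 4, 6), ncol = 1,
                         dimnames = list(NULL, "only")),
                  rep(c(-1, 1), each = 3), ncomp = 1)
  expect_equal(unname(vip_scores(m1)), 1.0, tolerance = 1e-12)
  # A = 1 with w = (1, 0): VIP = (sqrt(2), 0)
  y <- c(-1, -1, 1, 1)
  X <- cbind(a = y * 1.0, b = c(-1, 1, -1, 1))  # b orthogonal to y
  m2 <- fit_plsda(X, y, ncomp = 1, scale = FALSE)
  expect_equal(unname(m2$W[, 1]), c(1, 0), tolerance = 1e-12)
  expect_equal(unname(vip_scores(m2)), c(sqrt(2), 0), tolerance = 1e-12)
})

test_that("target projection conserves per-variable sums of squares", {
  for (i in 1:5) {
    mt <- rand_table(8, 10, p = 6, seed = 90 + i)
    m <- fit_plsda(mt, ncomp = 3)
    for (recon in c(FALSE, TRUE)) {
      tp <- target_projection(m, reconstructed = recon)
      tot <- colSums((if (recon) m$T %*% t(m$P) else m$X_scaled)^2)
      expect_equal(unname(tp$explained + tp$residual), unname(tot),
                   tolerance = 1e-8)
      expect_true(all(tp$residual >= 0))
    }
  }
})

test_that("one-component target projection reduces to the component", {
  mt <- rand_table(9, 9, p = 5, seed = 101)
  m <- fit_plsda(mt, ncomp = 1)
  tp <- target_projection(m)
  r <- cor(tp$t_tp, m$T[, 1])
  expect_equal(abs(r), 1, tolerance = 1e-10)
  # SR equals the single-component explained/residual ratio: regress
  # each variable on the (single-component) predictive score
  sr <- selectivity_ratio(tp)
  sr_oracle <- apply(m$X_scaled, 2, function(xj) {
    f <- lm(xj ~ tp$t_tp - 1)
    sum(fitted(f)^2) / sum(resid(f)^2)
  })
  expect_equal(unname(sr), unname(sr_oracle), tolerance = 1e-8)
})

test_that("selectivity ratio matches a least-squares projection oracle", {
  mt <- rand_table(10, 10, p = 3, seed = 111)
  m <- fit_plsda(mt, ncomp = 2)
  tp <- target_projection(m)
  sr <- selectivity_ratio(tp)
  sr_oracle <- apply(m$X_scaled, 2, function(xj) {
    f <- lm(xj ~ tp$t_tp - 1)
    sum(fitted(f)^2) / sum(resid(f)^2)
  })
  expect_equal(unname(sr), unname(sr_oracle), tolerance = 1e-8)
  # explained SS is the squared covariance with the predictive score,
  # so a variable orthogonal to t_tp would have none
  j <- which.min(abs(cor(m$X_scaled, tp$t_tp)))
  expect_equal(unname(tp$explained[j]),
               sum(m$X_scaled[, j] * tp$t_tp)^2 / sum(tp$t_tp^2),
               tolerance = 1e-10)
})

test_that("SR ranking at one component matches correlation ranking", {
  for (i in 1:10) {
    mt <- rand_table(8, 8, p = 6, seed = 120 + i)
    m <- fit_plsda(mt, ncomp = 1)
    tp <- target_projection(m)
    sr <- selectivity_ratio(tp)
    r2 <- as.numeric(cor(m$X_scaled, m$T[, 1]))^2
    expect_identical(order(sr), order(r2))
  }
})
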