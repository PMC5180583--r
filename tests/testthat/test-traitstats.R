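test_that("OLS fit matches hand least-squares and lm conventions", {
  d <- data.frame(x = c(1, 2, 3), y = c(1, 2, 4))
  f <- fitOls(d, modelSpec("y", "x"))
  expect_equal(unname(f$coefficients), c(-2 / 3, 1.5), tolerance = 1e-12)
  expect_equal(f$rss, 1 / 6, tolerance = 1e-12)
  expect_equal(f$r2, 27 / 28, tolerance = 1e-12)
  expect_equal(f$adj_r2, 13 / 14, tolerance = 1e-12)
  # log-likelihood convention equals logLik.lm (normalizing constants in)
  set.seed(14)
  d2 <- data.frame(a = rnorm(12), b = rnorm(12))
  d2$y <- 1 + 2 * d2$a - d2$b + rnorm(12)
  f2 <- fitOls(d2, modelSpec("y", c("a", "b")))
  lmfit <- lm(y ~ a + b, d2)
  expect_equal(f2$loglik, as.numeric(logLik(lmfit)), tolerance = 1e-10)
  expect_equal(f2$k, attr(logLik(lmfit), "df"))
})

test_that("OLS fit flags degeneracies", {
  d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  d$x2 <- d$x
  expect_error(fitOls(d, modelSpec("y", c("x", "x2"))), "collinear")
  expect_warning(f <- fitOls(d, modelSpec("y", "x")), "perfect fit")
  expect_equal(f$loglik, Inf)
  expect_error(fitOls(d[1:2, ], modelSpec("y", "x")), "insufficient")
})

test_that("AICc applies the small-sample correction", {
  # correction term 2k(k+1)/(n-k-1): 8 at n = 10, k = 4
  expect_equal(aicc(0, 4, 10) - (2 * 4 - 0), 8)
  # converges to AIC for large n
  expect_lt(abs(aicc(-12, 3, 1e7) - (2 * 3 + 24)), 1e-5)
  expect_error(aicc(0, 9, 10), "undefined")
})

test_that("model enumeration covers all subsets under marginality", {
  expect_length(enumerateModels(c("a", "b", "c")), 8)
  expect_length(enumerateModels(c(canonicalRegions(), "body_length")), 512)
  withIa <- enumerateModels(c("body_length", "face", "head_dorsal"),
                            interactions = list(c("body_length", "face")))
  hasIa <- Filter(function(s) length(s$interactions) > 0, withIa)
  expect_gt(length(hasIa), 0)
  for (s in hasIa)
    expect_true(all(c("body_length", "face") %in% s$mains))
  # AICc-finiteness screening at small n is reported: with n = 8 the
  # 5-term model (k = 7) would leave no residual degrees of freedom
  expect_message(small <- enumerateModels(c("a", "b", "c", "d", "e"), n = 8),
                 "excluded")
  expect_true(all(vapply(small, function(s) length(s$mains), integer(1)) <=
                    4))
  expect_length(small, 31)
})

test_that("ranking matches a brute-force lm/AIC oracle", {
  set.seed(33)
  n <- 24
  d <- data.frame(matrix(rnorm(n * 5), n, 5))
  names(d) <- paste0("p", 1:5)
  d$y <- 1 + 0.8 * d$p1 - 1.2 * d$p3 + rnorm(n)
  rt <- rankModels(d, "y", mains = paste0("p", 1:5))
  # oracle: every subset via lm(), AIC() + explicit correction, own sort
  preds <- paste0("p", 1:5)
  oracle <- do.call(rbind, lapply(0:31, function(bit) {
    sel <- preds[bitwAnd(bit, 2^(0:4)) > 0]
    fo <- if (length(sel)) paste("y ~", paste(sel, collapse = "+"))
          else "y ~ 1"
    fit <- lm(as.formula(fo), d)
    k <- attr(logLik(fit), "df")
    data.frame(model = if (length(sel)) paste(sel, collapse = " + ")
                       else "(intercept)",
               aicc = AIC(fit) + 2 * k * (k + 1) / (n - k - 1))
  }))
  oracle <- oracle[order(oracle$aicc, oracle$model), ]
  expect_equal(rt$model, oracle$model)
  expect_equal(rt$aicc, oracle$aicc, tolerance = 1e-9)
  # weight identities
  expect_equal(sum(rt$weight), 1, tolerance = 1e-12)
  expect_equal(rt$delta[1], 0)
  expect_true(all(diff(rt$acc_weight) >= -1e-12))
  expect_equal(rt$acc_weight[nrow(rt)], 1, tolerance = 1e-12)
})

test_that("Akaike weights follow the closed form in delta", {
  # two-candidate set engineered so the AICc gap is exactly 4.80
  w1 <- exp(0) / (exp(0) + exp(-4.80 / 2))
  expect_equal(round(w1, 4), 0.9168)
  expect_equal(round(1 - w1, 4), 0.0832)
  set.seed(51)
  d <- data.frame(x = rnorm(20)); d$y <- d$x + rnorm(20)
  rt <- rankModels(d, "y", candidates = list(modelSpec("y", "x"),
                                             modelSpec("y")))
  expect_equal(rt$weight,
               exp(-rt$delta / 2) / sum(exp(-rt$delta / 2)),
               tolerance = 1e-12)
  # single candidate: delta 0, weight 1
  rt1 <- rankModels(d, "y", candidates = list(modelSpec("y", "x")))
  expect_equal(rt1$delta, 0); expect_equal(rt1$weight, 1)
  expect_equal(rt1$acc_weight, 1)
})

test_that("ranking is invariant to a constant shift of all log-likelihoods", {
  # delta and weights depend only on AICc differences
  ll <- c(-40, -42, -45); k <- c(3, 4, 5); n <- 20
  a1 <- mapply(aicc, ll, k, n)
  a2 <- mapply(aicc, ll + 7, k, n)
  expect_equal(a1 - min(a1), a2 - min(a2), tolerance = 1e-12)
})

test_that("noiseless data identify the true predictor via the degenerate rule", {
  tt <- makeTraitTable(syntheticTraitConfig(trueTerms = "face", residSd = 0,
                                            seed = 77))
  expect_warning(
    rt <- suppressMessages(rankModels(tt$table, "svd",
                                      mains = canonicalRegions())),
    "perfect fit")
  expect_equal(rt$model[1], "face")
  expect_true(is.na(rt$weight[1]))
  expect_equal(sum(rt$weight, na.rm = TRUE), 1, tolerance = 1e-12)
})

test_that("dropping a predictor never increases R-squared", {
  set.seed(61)
  d <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  d$y <- d$a + 0.5 * d$b + rnorm(15)
  full <- fitOls(d, modelSpec("y", c("a", "b", "c")))
  for (drop in c("a", "b", "c")) {
    sub <- fitOls(d, modelSpec("y", setdiff(c("a", "b", "c"), drop)))
    expect_lte(sub$r2, full$r2 + 1e-12)
  }
})

test_that("VIF matches its definition and the car oracle", {
  # two orthogonal predictors
  d <- data.frame(a = c(-1, 1, -1, 1, 0), b = c(-1, -1, 1, 1, 0))
  expect_equal(unname(vif(d, c("a", "b"))), c(1, 1), tolerance = 1e-12)
  # exact correlation 0.6
  x <- c(-1, 1, -1, 1) * sqrt(2)
  z <- c(-1, -1, 1, 1) * sqrt(2)
  d2 <- data.frame(a = x, b = 0.6 * x + 0.8 * z)
  expect_equal(unname(vif(d2, c("a", "b"))), rep(1 / (1 - 0.36), 2),
               tolerance = 1e-9)
  # perfectly collinear
  d3 <- data.frame(a = 1:5, b = 2 * (1:5))
  w3 <- capture_warnings(v3 <- vif(d3, c("a", "b")))
  expect_match(w3, "collinear", all = TRUE)
  expect_true(all(is.infinite(v3)))
  # independent oracle on random data
  skip_if_not_installed("car")
  set.seed(71)
  d4 <- data.frame(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  d4$b <- d4$b + 0.7 * d4$a
  d4$y <- rnorm(20)
  ours <- vif(d4, c("a", "b", "c"))
  theirs <- car::vif(lm(y ~ a + b + c, d4))
  expect_equal(unname(ours), unname(theirs[names(ours)]), tolerance = 1e-9)
})

test_that("trait tables round-trip through CSV with normalized names", {
  tt <- makeTraitTable(syntheticTraitConfig(seed = 9))
  f <- file.path(tempdir(), "traits.csv")
  write.csv(tt$table, f, row.names = FALSE)
  back <- readTraitTable(f)
  expect_identical(back$species, tt$table$species)
  expect_equal(back$face, tt$table$face, tolerance = 1e-12)
  expect_error(readTraitTable(file.path(tempdir(), "absent.csv")), "exist")
})
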