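test_that("median-of-ratios size factors behave and match DESeq2", {
  # identical columns: all factors 1
  m <- matrix(rep(c(5, 50, 500), 3), 3, 3)
  expect_equal(unname(size_factors(m)), rep(1, 3))
  # hand-computed example
  m2 <- matrix(c(10, 20, 100, 200, 1000, 2000), 3, 2, byrow = TRUE)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  # scale equivariance: multiplying one column by c multiplies its factor by
  # exactly c relative to the others (size factors are identified only up to
  # the geometric-mean normalization of the pseudo-reference)
  m3 <- m2
  m3[, 2] <- m3[, 2] * 5
  s2 <- size_factors(m2)
  s3 <- size_factors(m3)
  expect_equal(s3[2] / s3[1], 5 * s2[2] / s2[1], tolerance = 1e-12)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "size factors")
  # independent implementation (odd feature count, where the even-median
  # convention cannot differ)
  skip_if_not_installed("DESeq2")
  set.seed(8)
  y <- matrix(rnbinom(21 * 6, mu = 80, size = 5) + 1L, 21, 6)
  expect_equal(unname(size_factors(y)),
               unname(DESeq2::estimateSizeFactorsForMatrix(y)),
               tolerance = 1e-12)
})

test_that("the VST is monotone, anchored at zero, and flattens variance", {
  cm <- matrix(c(0L, 4L, 8L, 0L, 2L, 16L), 3, 2)
  v <- vst(cm, size_factors = c(1, 1))
  expect_equal(v[1, 1], 0)                      # zero count -> log2(1) = 0
  expect_true(all(diff(v[, 1]) > 0))            # monotone in counts
  cm2 <- cm
  cm2[2, 1] <- cm2[2, 1] * 2L
  expect_gt(vst(cm2, c(1, 1))[2, 1], v[2, 1])
  # variance flattening on NB data: per-decile sd varies < 2x
  set.seed(13)
  mus <- 2^runif(1000, 4, 10)
  cnb <- matrix(rnbinom(1000 * 40, mu = rep(mus, 40), size = 1 / 0.05),
                1000, 40)
  vt <- vst(cnb, rep(1, 40))
  sds <- apply(vt, 1, sd)
  dec <- cut(rank(mus), 10)
  per_dec <- tapply(sds, dec, mean)
  expect_lt(max(per_dec) / min(per_dec), 2)
})

test_that("moment dispersion estimates recover Poisson and NB regimes", {
  set.seed(14)
  po <- matrix(rpois(400 * 50, 2^runif(400, 4, 9)), 400, 50)
  expect_lte(median(estimate_dispersion(po, rep(1, 50))), 0.01)
  nb <- matrix(rnbinom(400 * 50, mu = 2^runif(400, 4, 9), size = 5), 400, 50)
  a <- median(estimate_dispersion(nb, rep(1, 50)))
  expect_gte(a, 0.1)
  expect_lte(a, 0.3)
  cst <- rbind(po[1:10, ], matrix(7L, 1, 50))
  expect_equal(unname(estimate_dispersion(cst, rep(1, 50))[11]), 1e-8)
  expect_error(estimate_dispersion(po[, 1, drop = FALSE]), "2 samples")
})

test_that("the NB Wald fit matches an independent NB GLM and planted truth", {
  set.seed(5)
  n <- 30
  grp <- rep(c("A", "B"), each = n)
  md <- data.frame(group = grp, age = round(runif(2 * n, 45, 80)),
                   batch = factor(sample(1:2, 2 * n, TRUE)))
  mu <- 50 * 2^(0.8 * (grp == "B"))
  y <- matrix(rnbinom(20 * 2 * n, mu = rep(mu, each = 20), size = 10),
              20, 2 * n, dimnames = list(sprintf("f%02d", 1:20), NULL))
  r <- nb_wald_test(y, md, c("B", "A"), covariates = c("batch", "age"),
                    size_factors = rep(1, 2 * n),
                    dispersions = rep(0.1, 20), tol = 1e-12, maxit = 200)
  expect_true(all(r$converged))
  expect_equal(r$wald_z, r$log2FC / r$se, tolerance = 1e-9)
  expect_true(all(r$p_adj >= r$p - 1e-15, na.rm = TRUE))
  skip_if_not_installed("MASS")
  agec <- md$age - mean(md$age)
  g <- relevel(factor(grp), "A")
  for (i in c(1L, 7L, 20L)) {
    fit <- stats::glm(y[i, ] ~ g + md$batch + agec,
                      family = MASS::negative.binomial(theta = 10,
                                                       link = "log"))
    sm <- summary(fit, dispersion = 1)$coefficients
    expect_equal(r$log2FC[i], unname(coef(fit)[2]) / log(2),
                 tolerance = 1e-5)
    expect_equal(r$se[i], unname(sm[2, 2]) / log(2), tolerance = 1e-5)
  }
})

test_that("Wald results are symmetric under swapping the contrast", {
  set.seed(6)
  grp <- rep(c("A", "B"), each = 12)
  md <- data.frame(group = grp)
  y <- matrix(rnbinom(30 * 24, mu = 60, size = 8), 30, 24)
  a <- nb_wald_test(y, md, c("B", "A"), covariates = character(),
                    size_factors = rep(1, 24), dispersions = rep(0.12, 30),
                    tol = 1e-12, maxit = 200)
  b <- nb_wald_test(y, md, c("A", "B"), covariates = character(),
                    size_factors = rep(1, 24), dispersions = rep(0.12, 30),
                    tol = 1e-12, maxit = 200)
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-12)
  expect_true(max(abs(a$p - b$p)) < 1e-12)
})

test_that("identical group profiles give zero fold change and p = 1", {
  md <- data.frame(group = rep(c("A", "B"), each = 4))
  y <- matrix(rep(c(10L, 25L, 3L, 70L), 2), 2, 8)
  r <- nb_wald_test(y, md, c("B", "A"), covariates = character(),
                    size_factors = rep(1, 8), dispersions = rep(0.1, 2))
  expect_equal(r$log2FC, c(0, 0), tolerance = 1e-10)
  expect_equal(r$p, c(1, 1), tolerance = 1e-8)
})

test_that("planted fold changes are recovered without bias", {
  set.seed(7)
  n <- 20
  grp <- rep(c("HC", "CRC"), each = n)
  md <- data.frame(group = grp)
  nf <- 200
  mu0 <- 2^runif(nf, 5, 9)
  mu <- outer(mu0, 2^(1.5 * (grp == "CRC")))
  y <- matrix(rnbinom(nf * 2 * n, mu = mu, size = 10), nf, 2 * n)
  # unit size factors: every feature carries the planted effect, so depth
  # normalization would absorb it by construction
  r <- nb_wald_test(y, md, c("CRC", "HC"), covariates = character(),
                    size_factors = rep(1, 2 * n))
  expect_lt(abs(mean(r$log2FC) - 1.5), 0.3)
})

test_that("BH adjustment matches the step-up definition and handles NAs", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(15)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))  # order-preserving
  # NAs excluded from the number of tests
  p_na <- c(p, NA)
  expect_equal(bh_adjust(p_na)[1:50], adj)
  expect_true(is.na(bh_adjust(p_na)[51]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("DE calling applies the strict FDR and fold-change thresholds", {
  res <- data.frame(feature_id = c("a", "b", "c", "d"),
                    log2FC = c(0.51, 0.5, -0.51, -2),
                    p_adj = c(0.009, 0.009, 0.009, 0.011))
  de <- call_de(res)
  expect_identical(de$up, "a")          # 0.51 > 0.5 and 0.009 < 0.01
  expect_identical(de$down, "c")        # b: boundary lfc; d: boundary p
  empty <- call_de(res[0, ])
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
})

test_that("three-way set logic partitions shared and unique features", {
  up_ap <- list(up = c("a", "b"), down = "z")
  up_crc <- list(up = c("b", "c"), down = "z")
  crc_ap <- list(up = character(), down = character())
  tw <- three_way_summary(up_crc, up_ap, crc_ap)
  expect_identical(tw$regions$shared_up, "b")
  expect_identical(tw$regions$unique_up_ap, "a")
  expect_identical(tw$regions$unique_up_crc, "c")
  expect_identical(tw$regions$shared_down, "z")
  disjoint <- three_way_summary(list(up = "x", down = character()),
                                list(up = "y", down = character()),
                                crc_ap)
  expect_length(disjoint$regions$shared_up, 0)
  expect_error(three_way_summary(up_crc, up_ap, list(up = "a")), "down")
})
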