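scan_small <- function(qtls, seed = 7, iterations = 1500, burn_in = 400,
                       lines = 188, chroms = c(C1 = 100, C2 = 100, C3 = 100),
                       resid_sd = 0.5, n_families = 3, ...) {
  d <- make_dataset(chromosomes = chroms, marker_spacing_cM = 5, qtls = qtls,
                    n_families = n_families, lines_per_family = lines,
                    resid_sd = resid_sd, seed = seed, ...)
  scan <- mfqtl_scan(d$adjusted, d$genotypes,
                     control = mcmc_control(iterations = iterations,
                                            burn_in = burn_in, thin = 5,
                                            seed = seed + 1))
  list(data = d, scan = scan)
}

test_that("QTL intensity is the per-chromosome sum of posterior probabilities", {
  f <- make_field(c(0.2, 0.3, 0.5))
  expect_equal(qtl_intensity(f, "C1"), 1.0)
  expect_equal(qtl_intensity(make_field(c(0, 0, 0)), "C1"), 0)
  expect_error(qtl_intensity(f, "C9"), "unknown chromosome")
})

test_that("intensities sum to the posterior mean number of QTLs", {
  res <- scan_small(list(qtl_spec("C2", 50, 1, c(1, 1, 1))),
                    iterations = 600, burn_in = 200, lines = 60)
  sc <- res$scan
  expect_equal(sum(sc$intensity), mean(sc$samples$N), tolerance = 1e-10)
  expect_true(all(sc$field$p >= 0 & sc$field$p <= 1))
})

test_that("a strong shared QTL is localized with full segregation", {
  res <- scan_small(list(qtl_spec("C2", 50, 1, c(1, 1, 1))),
                    iterations = 2000, burn_in = 500)
  sc <- res$scan
  expect_equal(names(which.max(sc$intensity)), "C2")
  f <- sc$field
  rows <- f$chromosome == "C2"
  wpos <- sum(f$p[rows] * f$mid[rows]) / sum(f$p[rows])
  weff <- sum(f$p[rows] * f$effect[rows]) / sum(f$p[rows])
  expect_lt(abs(wpos - 50), 5)
  expect_lt(abs(weff - 1), 0.2)
  pk <- which(rows)[which.max(f$p[rows])]
  seg <- unlist(f[pk, grep("^seg_prob_", names(f))])
  expect_true(all(seg > 0.9))
})

test_that("family-specific segregation structure is recovered", {
  res <- scan_small(list(qtl_spec("C1", 40, 1, c(1, 0, 0))),
                    iterations = 2000, burn_in = 500)
  f <- res$scan$field
  rows <- f$chromosome == "C1"
  pk <- which(rows)[which.max(f$p[rows])]
  expect_gt(f$seg_prob_F1[pk], 0.9)
  expect_lt(f$seg_prob_F2[pk], 0.5)
  expect_lt(f$seg_prob_F3[pk], 0.5)
})

test_that("null phenotypes keep the posterior QTL count below the prior mean", {
  res <- scan_small(list(), iterations = 1200, burn_in = 300)
  sc <- res$scan
  expect_lt(mean(sc$samples$N), sc$priors$lambda)
})

test_that("the posterior field is invariant to line order", {
  d <- make_dataset(chromosomes = c(C1 = 60), marker_spacing_cM = 5,
                    qtls = list(qtl_spec("C1", 30, 1, c(1, 1))),
                    n_families = 2, lines_per_family = 40, seed = 3)
  ctl <- mcmc_control(iterations = 400, burn_in = 100, thin = 2, seed = 9)
  s1 <- mfqtl_scan(d$adjusted, d$genotypes, control = ctl)
  perm <- sample(nrow(d$adjusted))
  s2 <- mfqtl_scan(d$adjusted[perm, ], d$genotypes, control = ctl)
  expect_equal(s1$field$p, s2$field$p, tolerance = 1e-12)
  expect_equal(s1$field$effect, s2$field$effect, tolerance = 1e-12)
})

test_that("permutation thresholds are order statistics of the maxima", {
  expect_equal(threshold_from_maxima(1:100, 0.05), 96)
  expect_equal(threshold_from_maxima(rep(3.3, 40), 0.05), 3.3)
  expect_error(threshold_from_maxima(1:10, 0.001), ">= 1")
  expect_error(
    permutation_threshold(data.frame(), NULL, n_perm = 10),
    "n_perm")
})

test_that("QTL calling applies the threshold and the 2x splitting rule", {
  # no call below threshold
  y <- stats::setNames(rnorm(20), paste0("L", 1:20))
  u <- matrix(sample(c(-1, 1), 20 * 5, TRUE), 20, 5,
              dimnames = list(names(y), NULL))
  f <- make_field(rep(0.09, 5), effect = 0.5)
  sc <- fake_scan(f, y, u)
  expect_equal(nrow(call_qtls(sc, 0.5)), 0)

  # bimodal field above twice the threshold splits into two QTLs
  p <- c(0.05, 0.6, 0.9, 0.1, 0.01, 0.02, 0.7, 0.8, 0.12, 0.05)
  f2 <- make_field(p, effect = 1)
  u2 <- matrix(sample(c(-1, 1), 20 * 10, TRUE), 20, 10,
               dimnames = list(names(y), NULL))
  sc2 <- fake_scan(f2, y, u2)
  thr <- sum(p) / 2.5
  calls <- call_qtls(sc2, thr)
  expect_equal(nrow(calls), 2)
  expect_lt(calls$position_cM[1], 4)
  expect_gt(calls$position_cM[2], 5)
  expect_true(all(calls$intensity > thr))

  # degenerate weights: position is the occupied interval midpoint
  f3 <- make_field(c(0, 1, 0), effect = 1)
  f3$mid <- c(10.5, 11.5, 12.5)
  sc3 <- fake_scan(f3, y, u2[, 1:3])
  calls3 <- call_qtls(sc3, 0.5)
  expect_equal(calls3$position_cM, 11.5)

  # 2x exceeded but no valid boundary: falls back to one QTL
  f4 <- make_field(c(1, 1, 1), effect = 1)
  sc4 <- fake_scan(f4, y, u2[, 1:3])
  expect_warning(calls4 <- call_qtls(sc4, 1.2), "no valid boundary")
  expect_equal(nrow(calls4), 1)
})

test_that("contribution reflects the explained variance fraction", {
  # zero effect -> zero contribution
  y <- stats::setNames(rnorm(50), paste0("L", 1:50))
  u <- matrix(sample(c(-1, 1), 50 * 3, TRUE), 50, 3,
              dimnames = list(names(y), NULL))
  f <- make_field(c(0, 1, 0), effect = 0)
  expect_equal(qtl_contribution(fake_scan(f, y, u), 1:3), 0)

  # noiseless balanced single QTL -> contribution ~ 1
  ub <- matrix(rep(c(-1, 1), each = 25), 50, 1)
  rownames(ub) <- names(y)
  yq <- stats::setNames(drop(ub) * 1.0, names(y))
  fq <- make_field(1, effect = 1)
  expect_equal(qtl_contribution(fake_scan(fq, yq, ub), 1), 1,
               tolerance = 1e-10)

  # simulated a = 1, sigma_e = 1: contribution ~ 0.5
  res <- scan_small(list(qtl_spec("C1", 50, 1, c(1, 1, 1))),
                    iterations = 1500, burn_in = 400, resid_sd = 1,
                    chroms = c(C1 = 100, C2 = 100))
  calls <- suppressWarnings(call_qtls(res$scan, 0.3))
  c1 <- calls[calls$chromosome == "C1", ]
  expect_equal(nrow(c1), 1)
  expect_lt(abs(c1$contribution - 0.5), 0.1)
})

test_that("a single-family scan agrees with OLS at the true interval", {
  d <- make_dataset(chromosomes = c(C1 = 80), marker_spacing_cM = 5,
                    qtls = list(qtl_spec("C1", 40, 1, 1)),
                    n_families = 1, lines_per_family = 150,
                    resid_sd = 0.2, seed = 17)
  sc <- mfqtl_scan(d$adjusted, d$genotypes,
                   priors = scan_priors(pi_s = 1),  # s fixed at 1
                   control = mcmc_control(iterations = 1500, burn_in = 400,
                                          thin = 5, seed = 18))
  calls <- suppressWarnings(call_qtls(sc, threshold = 0.5))
  expect_equal(nrow(calls), 1)
  weff <- calls$effect
  expect_lt(abs(calls$position_cM - 40), 5)
  true_l <- which(d$grid$start <= 40 & d$grid$end > 40)
  x <- d$genotypes$hard[d$adjusted$line_id, true_l]
  fit <- stats::lm(d$adjusted$value ~ x)
  ols <- stats::coef(fit)[["x"]]
  se <- sqrt(diag(stats::vcov(fit)))[["x"]]
  expect_lt(abs(weff - ols), 2 * se)
})
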