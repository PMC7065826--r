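make_plots <- function(values, lines, envs, family = "F1", trait = "t") {
  data.frame(line_id = lines, family = family, environment = envs,
             rep = 1L, trait = trait, value = values,
             stringsAsFactors = FALSE)
}

test_that("single-environment adjustment reduces to plot means", {
  set.seed(1)
  pl <- make_plots(rnorm(10), sprintf("L%02d", 1:10), "e1")
  adj <- adjust_for_environment(pl, "t")
  expect_equal(stats::setNames(adj$value, adj$line_id),
               stats::setNames(pl$value, pl$line_id)[adj$line_id])
})

test_that("season adjustment removes an additive environment shift", {
  set.seed(2)
  lines <- sprintf("L%02d", 1:20)
  base <- rnorm(20, 10)
  noise <- rnorm(40, 0, 0.3)
  pl0 <- make_plots(rep(base, 2) + noise, rep(lines, 2),
                    rep(c("e1", "e2"), each = 20))
  delta <- 3.7
  pl1 <- pl0
  pl1$value[pl1$environment == "e2"] <- pl1$value[pl1$environment == "e2"] + delta
  a0 <- adjust_for_environment(pl0, "t")
  a1 <- adjust_for_environment(pl1, "t")
  # with sum-to-zero environment effects the shift moves line values by a
  # common constant (delta/2); between-line differences are identical
  diffs <- a1$value - a0$value
  expect_lt(max(diffs) - min(diffs), 1e-10)
  expect_equal(diffs[1], delta / 2, tolerance = 1e-10)
  eff <- attr(a1, "env_effects")
  expect_equal(sum(eff), 0, tolerance = 1e-10)
  expect_equal(unname(eff["e2"] - eff["e1"]) -
               unname(attr(a0, "env_effects")["e2"] - attr(a0, "env_effects")["e1"]),
               delta, tolerance = 1e-10)
})

test_that("adjustment is order-invariant and idempotent", {
  set.seed(3)
  lines <- sprintf("L%02d", 1:15)
  pl <- make_plots(rnorm(45), rep(lines, 3), rep(c("e1", "e2", "e3"), each = 15))
  pl <- pl[-c(2, 17, 40), ]                 # unbalanced
  a1 <- adjust_for_environment(pl, "t")
  a2 <- adjust_for_environment(pl[sample.int(nrow(pl)), ], "t")
  expect_equal(a1, a2)

  # idempotence: correcting the plot table leaves a second pass inert
  eff <- attr(a1, "env_effects")
  pl_c <- pl
  pl_c$value <- pl$value - eff[pl$environment]
  a3 <- adjust_for_environment(pl_c, "t")
  expect_equal(a3$value, a1$value, tolerance = 1e-10)

  expect_error(adjust_for_environment(pl, "nope"), "not present")
  pl_na <- pl
  pl_na$value[pl_na$line_id == "L01"] <- NA
  expect_warning(adjust_for_environment(pl_na, "t"), "zero observations")
})

test_that("realized kinship equals the mean cross-product of codes", {
  g <- matrix(c(1, 1, -1, 1, -1,
                1, 1, -1, 1, -1,
                -1, -1, 1, -1, 1), nrow = 5,
              dimnames = list(paste0("m", 1:5), c("a", "b", "c")))
  K <- realized_kinship(g)
  expect_equal(K["a", "a"], 1)
  expect_equal(K["a", "b"], 1)              # identical lines
  expect_equal(K["a", "c"], -1)             # complementary lines

  set.seed(4)
  g2 <- matrix(sample(c(-1, 1), 10 * 30, replace = TRUE), nrow = 30,
               dimnames = list(paste0("m", 1:30), paste0("L", 1:10)))
  K2 <- realized_kinship(g2)
  brute <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) brute[i, j] <- mean(g2[, i] * g2[, j])
  expect_equal(unname(K2), brute, tolerance = 1e-12)

  g3 <- g2; g3[5, ] <- NA
  expect_warning(K3 <- realized_kinship(g3), "all-missing")
  expect_equal(dim(K3), c(10, 10))
})

test_that("REML heritability matches ANOVA components under K = I", {
  set.seed(5)
  n_l <- 80; r <- 3
  va <- 2; ve <- 1
  gval <- rnorm(n_l, 0, sqrt(va))
  lines <- rep(sprintf("L%02d", 1:n_l), each = r)
  y <- 10 + gval[rep(1:n_l, each = r)] + rnorm(n_l * r, 0, sqrt(ve))
  K <- diag(n_l); dimnames(K) <- list(sprintf("L%02d", 1:n_l),
                                      sprintf("L%02d", 1:n_l))
  h <- marker_heritability(y, K, lines = lines)

  means <- tapply(y, lines, mean)
  msb <- r * stats::var(means)
  msw <- sum((y - means[lines])^2) / (n_l * (r - 1))
  va_aov <- (msb - msw) / r
  ve_aov <- msw
  expect_equal(h$va, va_aov, tolerance = 1e-5)
  expect_equal(h$ve, ve_aov, tolerance = 1e-5)
  expect_true(h$conf_int[1] <= h$h2 && h$h2 <= h$conf_int[2])

  # shift invariance
  h2b <- marker_heritability(y + 100, K, lines = lines)
  expect_equal(h2b$h2, h$h2, tolerance = 1e-6)
})

test_that("pure-noise phenotypes give near-zero heritability", {
  set.seed(6)
  d <- make_dataset(chromosomes = c(C1 = 60, C2 = 60), marker_spacing_cM = 4,
                    n_families = 2, lines_per_family = 250,
                    resid_sd = 1, family_means = c(0, 0), seed = 11)
  K <- realized_kinship(d$table)
  y <- stats::setNames(rnorm(500), colnames(d$table$geno))
  h <- marker_heritability(y, K)
  expect_lt(h$h2, 0.1)
})

test_that("simulated heritability is recovered from realized kinship", {
  set.seed(7)
  d <- make_dataset(chromosomes = c(C1 = 80, C2 = 80), marker_spacing_cM = 4,
                    n_families = 3, lines_per_family = 188,
                    resid_sd = 1, family_means = c(0, 0, 0), seed = 13)
  K <- realized_kinship(d$table)
  h2_true <- 0.6
  ids <- colnames(d$table$geno)
  L <- t(chol(K + diag(1e-8, nrow(K))))
  est <- replicate(5, {
    g <- drop(L %*% rnorm(length(ids)))
    g <- g * sqrt(h2_true / stats::var(g))
    y <- stats::setNames(g + rnorm(length(ids), 0, sqrt(1 - h2_true)), ids)
    marker_heritability(y, K)$h2
  })
  expect_lt(abs(mean(est) - h2_true), 0.1)
})

test_that("trait correlations match the Pearson formula and are symmetric", {
  adj <- data.frame(line_id = rep(sprintf("L%d", 1:5), 3),
                    family = "F1",
                    trait = rep(c("t1", "t2", "t3"), each = 5),
                    value = c(1, 2, 3, 4, 5,
                              -1, -2, -3, -4, -5,
                              2.0, 1.0, 4.0, 3.5, 2.5))
  tc <- trait_correlations(adj)
  expect_equal(diag(tc$r), c(t1 = 1, t2 = 1, t3 = 1))
  expect_equal(tc$r["t1", "t2"], -1)
  expect_lt(tc$p["t1", "t2"], 1e-8)
  expect_true(tc$significant["t1", "t2"])
  x <- c(1, 2, 3, 4, 5); y <- c(2.0, 1.0, 4.0, 3.5, 2.5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(tc$r["t1", "t3"], r_hand, tolerance = 1e-12)
  expect_equal(tc$r, t(tc$r))
  expect_equal(tc$p_holm, t(tc$p_holm))
  expect_true(all(tc$p_holm[upper.tri(tc$p_holm)] >=
                  tc$p[upper.tri(tc$p)] - 1e-15))

  adj_const <- adj
  adj_const$value[adj_const$trait == "t3"] <- 1
  w <- testthat::capture_warnings(tc3 <- trait_correlations(adj_const))
  expect_match(w, "constant trait", all = FALSE)
  expect_true(is.na(tc3$r["t1", "t3"]))
})
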