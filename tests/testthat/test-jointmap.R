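test_that("DH recombination fractions are discordance fractions", {
  a <- c(1, 1, -1, -1, 1, 1, -1, 1, -1, 1)
  expect_equal(as.numeric(estimate_rf_dh(a, a)), 0)
  b <- a; b[c(3, 8)] <- -b[c(3, 8)]
  expect_equal(as.numeric(estimate_rf_dh(a, b)), 0.2)
  r <- estimate_rf_dh(a, -a)
  expect_equal(as.numeric(r), 1)
  expect_true(attr(r, "unlinked"))
  expect_error(estimate_rf_dh(c(NA, NA), c(1, NA)), "jointly scored")
  # missing codes excluded from the denominator
  b2 <- a; b2[1] <- NA
  expect_equal(attr(estimate_rf_dh(a, b2), "n"), 9)
})

test_that("joint maps pool recombinant counts across families", {
  # family 1: 2 recombinants / 100; family 2: 4 / 100 -> pooled r = 0.03
  mk <- c("m1", "m2")
  f1 <- matrix(1, 2, 100, dimnames = list(mk, paste0("a", 1:100)))
  f1[1, 1:50] <- -1; f1[2, 1:50] <- -1          # both markers segregate
  f1[2, c(1, 51)] <- -f1[2, c(1, 51)]           # 2 discordant lines
  f2 <- matrix(1, 2, 100, dimnames = list(mk, paste0("b", 1:100)))
  f2[1, 1:50] <- -1; f2[2, 1:50] <- -1
  f2[2, c(1, 2, 51, 52)] <- -f2[2, c(1, 2, 51, 52)]  # 4 discordant
  phys <- data.frame(marker = mk, chromosome = "C1", Mb = c(1, 2))
  jm <- build_joint_map(list(f1, f2), phys)
  expect_equal(diff(jm$cM), kosambi_cM(6 / 200), tolerance = 1e-12)

  # single family degenerates to the per-family estimate
  jm1 <- build_joint_map(list(f1), phys)
  expect_equal(diff(jm1$cM), kosambi_cM(0.02), tolerance = 1e-12)

  # a marker segregating in no family is dropped
  f1b <- rbind(f1, m3 = rep(1, 100))
  f2b <- rbind(f2, m3 = rep(1, 100))
  phys3 <- rbind(phys, data.frame(marker = "m3", chromosome = "C1", Mb = 3))
  expect_warning(jm3 <- build_joint_map(list(f1b, f2b), phys3),
                 "segregating in no family")
  expect_equal(nrow(jm3), 2)
})

test_that("joint map length is recovered from simulated multifamily data", {
  cfg <- sim_config(n_families = 3, lines_per_family = 188,
                    chromosomes = c(C1 = 100), marker_spacing_cM = 10,
                    seed = 21)
  map <- simulate_map(cfg)
  set.seed(21)
  fams <- lapply(1:3, function(i) simulate_dh_genotypes(map, 188))
  phys <- data.frame(marker = map$marker, chromosome = map$chromosome,
                     Mb = map$Mb)
  jm <- build_joint_map(fams, phys)
  expect_lt(abs(max(jm$cM) - 100) / 100, 0.1)
})

test_that("the interval grid tiles chromosomes in 1-cM pieces", {
  g <- interval_grid(c(C1 = 10.4, C2 = 3))
  expect_equal(nrow(g), 11 + 3)
  expect_equal(g$interval, 1:14)
  w <- g$end - g$start
  expect_true(all(abs(w[-11] - 1) < 1e-12 | seq_along(w)[-11] > 11))
  expect_equal(w[11], 0.4, tolerance = 1e-12)   # final partial interval kept
  expect_equal(g$start[g$chromosome == "C1"], 0:10)
  # no overlap, full cover
  for (chr in c("C1", "C2")) {
    gc <- g[g$chromosome == chr, ]
    expect_equal(gc$start[-1], gc$end[-nrow(gc)])
  }
})

test_that("interval imputation matches the two-flank Markov formula", {
  d <- kosambi_cM(0.1)
  # markers flanking the midpoint of interval 16 (mid 15.5) at r = 0.1 each
  map <- data.frame(marker = c("mL", "mR"), chromosome = "C1",
                    cM = c(15.5 - d, 15.5 + d))
  grid <- interval_grid(c(C1 = 31))
  geno <- matrix(c(1L, 1L, 1L, -1L, -1L, -1L), nrow = 2,
                 dimnames = list(c("mL", "mR"), c("QQ", "Qq", "qq")))
  gt <- genotype_table(map, geno, c(QQ = "F1", Qq = "F1", qq = "F1"))
  ig <- impute_interval_genotypes(gt, grid)
  rLR <- 0.1 + 0.1 - 2 * 0.01
  expect_equal(ig$u["QQ", 16], 2 * (0.9 * 0.9 / (1 - rLR)) - 1,
               tolerance = 1e-10)              # ~ 0.9756
  expect_equal(ig$u["Qq", 16], 0, tolerance = 1e-10)  # discordant, symmetric
  expect_equal(ig$u["qq", 16], -(2 * (0.9 * 0.9 / (1 - rLR)) - 1),
               tolerance = 1e-10)
  # at a scored marker's interval the observed code is returned
  iL <- which(grid$start <= map$cM[1] & grid$end > map$cM[1])
  expect_equal(ig$u["QQ", iL], 1)
  expect_equal(ig$u["qq", iL], -1)
  # beyond the terminal marker: single-flank decay u = g (1 - 2r)
  r30 <- inverse_kosambi(30.5 - map$cM[2])
  expect_equal(ig$u["QQ", 31], 1 - 2 * r30, tolerance = 1e-10)
})

test_that("imputation equals brute-force gamete enumeration on a 3-marker toy", {
  # markers at 0, 7, 20 cM; middle marker unobserved
  map <- data.frame(marker = c("m1", "m2", "m3"), chromosome = "C1",
                    cM = c(0, 7, 20))
  grid <- interval_grid(c(C1 = 20))
  combos <- expand.grid(g1 = c(1L, -1L), g3 = c(1L, -1L))
  geno <- rbind(m1 = combos$g1, m2 = NA_integer_, m3 = combos$g3)
  colnames(geno) <- paste0("L", 1:4)
  gt <- genotype_table(map, geno, stats::setNames(rep("F1", 4), colnames(geno)))
  ig <- impute_interval_genotypes(gt, grid)

  # independent oracle: enumerate the 2^3 gamete configurations of the
  # chain (m1, locus, m3) with per-gap no-interference probabilities
  enumerate_u <- function(x, g1, g3) {
    r1 <- inverse_kosambi(x - 0); r2 <- inverse_kosambi(20 - x)
    num <- 0; den <- 0
    for (gx in c(1, -1)) {
      pr <- 0.5 * (if (gx == g1) 1 - r1 else r1) * (if (g3 == gx) 1 - r2 else r2)
      den <- den + pr
      num <- num + gx * pr
    }
    num / den
  }
  for (l in which(grid$mid > 0.5 & grid$mid < 19.5)) {
    x <- grid$mid[l]
    near_marker <- any(abs(map$cM[c(1, 3)] - x) < 0.5 &
                       grid$start[l] <= map$cM[c(1, 3)] &
                       grid$end[l] > map$cM[c(1, 3)])
    if (near_marker) next                  # those intervals take the code
    for (j in 1:4) {
      expect_equal(ig$u[j, l], enumerate_u(x, combos$g1[j], combos$g3[j]),
                   tolerance = 1e-10)
    }
  }
})

test_that("hard calls recover withheld markers at a fine grid", {
  cfg <- sim_config(n_families = 1, lines_per_family = 200,
                    chromosomes = c(C1 = 50), marker_spacing_cM = 1, seed = 31)
  map <- simulate_map(cfg)
  set.seed(31)
  g <- simulate_dh_genotypes(map, 200)
  keep <- seq(1, nrow(map), by = 2)            # genotype every 2nd marker
  gt <- genotype_table(map[keep, ], g[keep, , drop = FALSE],
                       stats::setNames(rep("F1", 200), colnames(g)))
  grid <- interval_grid(c(C1 = 50))
  ig <- impute_interval_genotypes(gt, grid)
  held <- setdiff(seq_len(nrow(map)), keep)
  err <- 0; tot <- 0
  for (t in held) {
    l <- which(grid$start <= map$cM[t] & grid$end > map$cM[t])
    if (!length(l)) next
    err <- err + sum(ig$hard[, l] != g[t, ])
    tot <- tot + 200
  }
  expect_lt(err / tot, 0.02)
})

test_that("lines without markers on a chromosome impute to zero", {
  map <- data.frame(marker = c("a", "b"), chromosome = c("C1", "C2"),
                    cM = c(5, 5))
  geno <- matrix(c(1L, NA, -1L, NA), nrow = 2,
                 dimnames = list(c("a", "b"), c("L1", "L2")))
  gt <- genotype_table(map, geno, c(L1 = "F1", L2 = "F1"))
  grid <- interval_grid(c(C1 = 10, C2 = 10))
  expect_warning(ig <- impute_interval_genotypes(gt, grid), "no scored marker")
  expect_true(all(ig$u["L1", grid$chromosome == "C2"] == 0))
  expect_true(all(ig$u["L2", grid$chromosome == "C2"] == 0))
  expect_true(all(abs(ig$u["L1", grid$chromosome == "C1"]) > 0))
})
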