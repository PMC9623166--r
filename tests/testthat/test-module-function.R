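fake_partition <- function(module_of_node) {
  sizes <- table(module_of_node)
  structure(list(module_of_node = module_of_node,
                 sizes = setNames(as.integer(sizes), names(sizes)),
                 main_modules = as.integer(names(sizes)),
                 modularity = NA_real_),
            class = "module_partition")
}

test_that("module_abundance is the mean member z-score", {
  set.seed(4)
  rel <- matrix(rexp(6 * 5), 6, 5,
                dimnames = list(paste0("S", 1:6), paste0("O", 1:5)))
  rel <- rel / rowSums(rel)
  part <- fake_partition(setNames(c(1L, 1L, 1L, 2L, 2L), paste0("O", 1:5)))
  ma <- module_abundance(rel, part)
  # oracle: z-then-mean by hand
  z <- apply(rel, 2, function(x) (x - mean(x)) / sd(x))
  expect_equal(ma[, "M1"], rowMeans(z[, 1:3]), tolerance = 1e-12)
  expect_equal(ma[, "M2"], rowMeans(z[, 4:5]), tolerance = 1e-12)
  expect_true(all(abs(colMeans(ma)) < 1e-12))

  # single-member module equals that OTU's z-scores
  p1 <- fake_partition(setNames(1L, "O1"))
  expect_equal(module_abundance(rel, p1)[, "M1"], z[, "O1"])

  # identical profiles: module abundance equals either member's z-score
  rel2 <- rel; rel2[, 2] <- rel2[, 1]
  ma2 <- module_abundance(rel2, fake_partition(setNames(c(1L, 1L),
                                                        c("O1", "O2"))))
  expect_equal(ma2[, "M1"], z[, "O1"])

  # size-weighted average over modules equals the overall z-score mean
  w <- as.numeric(part$sizes[c("1", "2")])
  expect_equal(as.numeric(ma %*% w / sum(w)), unname(rowMeans(z)),
               tolerance = 1e-12)

  expect_error(module_abundance(rel[, 1:3],
                                fake_partition(setNames(1L, "O5"))),
               "absent")
})

test_that("module_richness counts members present per sample", {
  counts <- rbind(S1 = c(3, 0, 1, 5), S2 = c(0, 0, 0, 2))
  colnames(counts) <- paste0("O", 1:4)
  part <- fake_partition(setNames(c(1L, 1L, 1L, 2L), paste0("O", 1:4)))
  r <- module_richness(counts, part, 1)
  expect_equal(unname(r), c(2L, 0L))
  expect_equal(unname(module_richness(counts, part, 2)), c(1L, 1L))
  # brute-force scan on a random table
  set.seed(8)
  big <- matrix(rbinom(60, 3, 0.4), 6, 10,
                dimnames = list(paste0("S", 1:6), paste0("O", 1:10)))
  p2 <- fake_partition(setNames(rep(1:2, each = 5), paste0("O", 1:10)))
  expect_equal(unname(module_richness(big, p2, 2)),
               as.integer(rowSums(big[, 6:10] > 0)))
  expect_error(module_richness(counts, part, 99), "unknown module")
})

test_that("module_function_correlation flags the driving module", {
  set.seed(10)
  n <- 30
  ma <- cbind(M1 = rnorm(n), M2 = rnorm(n))
  rownames(ma) <- paste0("S", 1:n)
  fp <- cbind(geneA = exp(2 * ma[, "M1"] + rnorm(n, sd = 0.1)),
              noise = rexp(n))
  rownames(fp) <- rownames(ma)
  rep <- module_function_correlation(ma, fp)
  expect_gt(rep$rho["M1", "geneA"], 0.9)
  expect_lt(rep$p["M1", "geneA"], 0.001)
  expect_equal(rep$stars["M1", "geneA"], "***")
  expect_gt(rep$p["M2", "noise"], 0.05)
  # monotone function of module abundance gives rho exactly 1
  fp2 <- cbind(g = exp(ma[, "M1"]))
  rownames(fp2) <- rownames(ma)
  expect_equal(module_function_correlation(ma, fp2)$rho["M1", "g"], 1)
  # sample mismatch errors with the offending ids
  bad <- fp; rownames(bad)[1] <- "XX"
  expect_error(module_function_correlation(ma, bad), "XX")
})

test_that("designate_core picks the module driving function", {
  set.seed(3)
  n <- 40
  ma <- cbind(M1 = rnorm(n), M2 = rnorm(n), M3 = rnorm(n))
  rownames(ma) <- paste0("S", 1:n)
  fp <- vapply(1:6, function(j) exp(ma[, "M2"] + rnorm(n, sd = 0.2)),
               numeric(n))
  colnames(fp) <- paste0("g", 1:6); rownames(fp) <- rownames(ma)
  rep <- module_function_correlation(ma, fp)
  expect_equal(designate_core(rep), 2L)
  # invariant to functional-variable column order
  rep2 <- module_function_correlation(ma, fp[, 6:1])
  expect_equal(designate_core(rep2), 2L)
  # no significant positives anywhere -> none-marker with warning
  # (deterministically pick a variable nearly rank-orthogonal to all modules)
  x <- rexp(n)
  while (max(abs(cor(rank(x), apply(ma, 2, rank)))) > 0.1) x <- rexp(n)
  null_rep <- module_function_correlation(
    ma, matrix(x, n, 1, dimnames = list(rownames(ma), "x")))
  expect_warning(core <- designate_core(null_rep), "no module")
  expect_true(is.na(core))
})

test_that("richness_function_regression matches closed-form OLS", {
  x <- c(3, 5, 7, 9, 11, 13)
  expect_equal(richness_function_regression(x, 2 * x)$slope, 2)
  expect_equal(richness_function_regression(x, 2 * x)$r_squared, 1)
  set.seed(12)
  r <- rpois(18, 20); z <- 0.1 * r + rnorm(18)
  got <- richness_function_regression(r, z)
  o <- oracle_ols(r, z)
  expect_equal(got$slope, o$slope)
  expect_equal(got$intercept, o$intercept)
  expect_equal(got$r_squared, o$r_squared)
  tstat <- o$slope / o$se
  expect_equal(got$p, 2 * pt(-abs(tstat), 16))
  expect_error(richness_function_regression(rep(5, 6), rnorm(6)),
               "zero variance")
  expect_error(richness_function_regression(1:2, 1:2), ">= 3")
})

test_that("functional_potential averages per-variable z-scores", {
  set.seed(2)
  fp <- matrix(rexp(24), 6, 4,
               dimnames = list(paste0("S", 1:6), paste0("v", 1:4)))
  got <- functional_potential(fp)
  z <- apply(fp, 2, function(x) (x - mean(x)) / sd(x))
  expect_equal(unname(got), unname(rowMeans(z)))
})
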