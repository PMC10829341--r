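test_that("TPM normalisation matches hand-computed rates", {
  m <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(compute_tpm(m, c(a = 1000, b = 1000))[, 1]),
               c(5e5, 5e5))
  m2 <- matrix(c(10, 20), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(compute_tpm(m2, c(a = 1000, b = 2000))[, 1]),
               c(5e5, 5e5)) # equal rates 0.01
  m3 <- matrix(c(0, 5), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(unname(compute_tpm(m3, c(a = 1234, b = 777))[, 1]),
               c(0, 1e6))
  expect_error(compute_tpm(m, c(a = 0, b = 1000)), "positive")
})

test_that("TPM columns sum to one million, all-zero columns stay zero", {
  set.seed(2)
  counts <- matrix(rpois(60, 20), 10, 6,
                   dimnames = list(paste0("c", 1:10), paste0("s", 1:6)))
  counts[, 4] <- 0
  tpm <- compute_tpm(counts, setNames(sample(1000:9000, 10),
                                      paste0("c", 1:10)))
  sums <- colSums(tpm)
  expect_equal(unname(sums[-4]), rep(1e6, 5), tolerance = 1e-6)
  expect_equal(unname(sums[4]), 0)
})

test_that("viral fraction is the viral TPM sum over one million, in percent", {
  tpm <- matrix(c(62700, 937300), 2, 1,
                dimnames = list(c("v", "h"), "s1"))
  expect_equal(unname(viral_fraction(tpm, "v")), 6.27)
  expect_equal(unname(viral_fraction(tpm, c("v", "h"))), 100)
  expect_equal(unname(viral_fraction(tpm, character(0))), 0)
})

test_that("Shannon index uses natural logs", {
  expect_equal(shannon_index(rep(5, 4)), log(4))
  expect_equal(shannon_index(c(10, 0, 0)), 0)
  p <- c(0.5, 0.25, 0.25)
  expect_equal(shannon_index(p), -sum(p * log(p)), tolerance = 1e-12)
  expect_equal(round(shannon_index(p), 4), 1.0397)
  expect_error(shannon_index(c(0, 0)), "all-zero")
})

test_that("Bray-Curtis matches the min-sum formula and its bounds", {
  x <- matrix(c(1, 1, 1, 0), 2, 2, dimnames = list(NULL, c("x", "y")))
  d <- bray_curtis(x)
  expect_equal(d["x", "y"], 1 / 3)
  same <- matrix(c(3, 2, 3, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(bray_curtis(same)["a", "b"], 0)
  disj <- matrix(c(5, 0, 0, 7), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  set.seed(9)
  m <- matrix(rpois(40, 5), 8, 5)
  colnames(m) <- paste0("s", 1:5)
  dd <- bray_curtis(m)
  expect_true(all(dd >= 0 & dd <= 1))
  expect_equal(dd, t(dd))
  expect_equal(unname(diag(dd)), rep(0, 5))
})

test_that("PERMANOVA pseudo-F agrees with an independent SS decomposition", {
  set.seed(31)
  m <- matrix(rpois(60, 8), 10, 6)
  colnames(m) <- paste0("s", 1:6)
  d <- bray_curtis(m)
  groups <- c(1, 1, 2, 2, 3, 3)
  fit <- permanova(d, groups, n_permutations = 99, seed = 1)
  expect_equal(fit$pseudo_F, oracle_pseudo_f(d, groups))
  # cross-check against the community-ecology reference implementation
  ad <- vegan::adonis2(as.dist(d) ~ g,
                       data = data.frame(g = factor(groups)),
                       permutations = 2)
  expect_equal(fit$pseudo_F, ad$F[1], tolerance = 1e-10)
})

test_that("PERMANOVA on exchangeable points gives p = 1", {
  d <- matrix(0, 6, 6)
  fit <- permanova(d, c(1, 1, 2, 2, 3, 3), n_permutations = 99, seed = 1)
  expect_equal(fit$p_value, 1)
})

test_that("exhaustive PERMANOVA equals full enumeration of arrangements", {
  # two well-separated triplets in one dimension
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- as.matrix(dist(x))
  groups <- c("a", "a", "a", "b", "b", "b")
  fit <- permanova(d, groups, n_permutations = 1000, seed = 1)
  expect_true(fit$exhaustive)
  arr <- oracle_label_arrangements(groups)
  f_obs <- oracle_pseudo_f(d, groups)
  f_all <- vapply(arr, function(g) oracle_pseudo_f(d, g), numeric(1))
  expect_equal(fit$p_value, mean(f_all >= f_obs))
  expect_gte(fit$p_value, 1 / length(arr)) # identity arrangement included
})

test_that("Benjamini-Hochberg adjustment reproduces hand-stepped values", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(c(1.0, 0.5)), c(1.0, 1.0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH output dominates the raw p-values and is monotone", {
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))
  }
})

test_that("depth-diversity regression matches the normal equations", {
  x <- c(2, 8, 17, 22, 28)
  y <- c(5.4, 5.1, 4.6, 4.4, 3.9)
  fit <- depth_diversity_regression(x, y)
  # closed-form OLS
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  yhat <- alpha + beta * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(fit$slope, beta)
  expect_equal(fit$intercept, alpha)
  expect_equal(fit$r_squared, r2)
  se <- sqrt(sum((y - yhat)^2) / 3 / sum((x - mean(x))^2))
  expect_equal(fit$p_value, 2 * pt(abs(beta / se), 3, lower.tail = FALSE))
  # degenerate shapes
  exact <- suppressWarnings(depth_diversity_regression(x, 2 + 3 * x))
  expect_equal(exact$r_squared, 1)
  flat <- depth_diversity_regression(x, rep(4, 5))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
  expect_error(depth_diversity_regression(rep(5, 4), 1:4), "constant")
})

test_that("Venn membership equals exhaustive set algebra", {
  set.seed(77)
  tpm <- matrix(rbinom(20 * 6, 1, 0.5) * runif(120, 1, 100), 20, 6)
  rownames(tpm) <- paste0("v", 1:20)
  colnames(tpm) <- paste0("s", 1:6)
  clusters <- list(shallow = c("s1", "s2"), mid = c("s3", "s4"),
                   deep = c("s5", "s6"))
  out <- venn_membership(tpm, clusters)
  presence <- vapply(clusters, function(s)
    rowSums(tpm[, s, drop = FALSE] > 0) > 0, logical(20))
  want <- oracle_venn(presence)
  for (i in seq_len(nrow(out)))
    expect_equal(out$count[i], want[[out$region[i]]])
  expect_equal(sum(out$count), sum(rowSums(tpm > 0) > 0))
  # single-cluster presence
  solo <- matrix(c(1, 0, 0, 0, 0, 0), 1, 6,
                 dimnames = list("v", paste0("s", 1:6)))
  vs <- venn_membership(solo, clusters)
  expect_equal(vs$count[vs$region == "shallow"], 1)
  expect_equal(sum(vs$count), 1)
  expect_error(venn_membership(tpm, list(a = "s1", b = character(0))),
               "empty")
})
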