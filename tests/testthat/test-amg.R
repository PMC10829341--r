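edge_df <- function(from, to, weight = 1) {
  data.frame(from = from, to = to, weight = weight,
             stringsAsFactors = FALSE)
}

clique_edges <- function(nodes, weight = 1) {
  pr <- combn(nodes, 2)
  edge_df(pr[1, ], pr[2, ], weight)
}

test_that("Markov clustering separates disconnected structures", {
  g <- rbind(clique_edges(c("a1", "a2", "a3")),
             clique_edges(c("b1", "b2", "b3")))
  cl <- mcl_cluster(g)
  expect_equal(length(unique(cl)), 2)
  expect_equal(length(unique(cl[c("a1", "a2", "a3")])), 1)
  expect_equal(length(unique(cl[c("b1", "b2", "b3")])), 1)
  # a single edge is one cluster
  expect_equal(length(unique(mcl_cluster(edge_df("x", "y")))), 1)
  # isolated nodes are singletons
  iso <- mcl_cluster(edge_df("x", "y"), nodes = c("p", "q"))
  expect_equal(length(unique(iso)), 3)
  expect_false(iso["p"] == iso["q"])
})

test_that("MCL output is a partition covering every node", {
  set.seed(12)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    nodes <- list()
    g <- NULL
    for (j in 1:k) {
      nd <- sprintf("n%d_%d", j, seq_len(sample(3:6, 1)))
      nodes[[j]] <- nd
      g <- rbind(g, clique_edges(nd, weight = runif(1, 0.5, 2)))
    }
    cl <- mcl_cluster(g)
    expect_setequal(names(cl), unlist(nodes))
    for (j in 1:k)
      expect_equal(length(unique(cl[nodes[[j]]])), 1)
    expect_equal(length(unique(cl)), k)
  }
})

test_that("OG abundance sums TPM over distinct member vOTUs", {
  tpm <- matrix(c(10, 20, 30, 1, 2, 3, 100, 200, 300), 3, 3, byrow = TRUE,
                dimnames = list(c("v1", "v2", "v3"), c("s1", "s2", "s3")))
  expect_equal(og_abundance("v2", tpm), c(s1 = 1, s2 = 2, s3 = 3))
  expect_equal(og_abundance(c("v1", "v1"), tpm), og_abundance("v1", tpm))
  expect_equal(og_abundance(c("v1", "v2", "v3"), tpm),
               c(s1 = 111, s2 = 222, s3 = 333))
  expect_error(og_abundance("v9", tpm), "unknown vOTU")
})

test_that("OG eligibility demands multiple non-prophage vOTUs and orders", {
  orders <- list(v1 = "O1", v2 = "O1", v3 = "O2", v4 = c("O1", "O2"))
  ogs <- list(single = c("v1"),
              one_order = c("v1", "v2"),
              with_prov = c("v1", "v3", "vp"),
              good = c("v1", "v3"))
  out <- eligible_ogs(ogs, provirus_votus = "vp", votu_host_orders = orders)
  e <- setNames(out$eligible, out$og)
  expect_false(e[["single"]])
  expect_false(e[["one_order"]])
  expect_true(e[["with_prov"]]) # provirus dropped, two vOTUs, two orders
  expect_true(e[["good"]])
  expect_equal(out$n_votus[out$og == "with_prov"], 2)
})

test_that("Pearson screen applies strict thresholds on r and p", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  chem <- data.frame(PO4 = -x, DO = rep(1, 12))
  ab <- matrix(x, 1, dimnames = list("og1", NULL))
  expect_warning(out <- pearson_screen(ab, chem), "constant")
  po4 <- out[out$variable == "PO4", ]
  expect_equal(po4$r, -1)
  expect_true(po4$retained)
  expect_false(out$retained[out$variable == "DO"])

  # thresholds are strict: |r| = 0.8 or p = 0.05 exactly are rejected
  expect_false(viroecol:::screen_retain(0.8, 1e-6))
  expect_false(viroecol:::screen_retain(-0.8, 1e-6))
  expect_true(viroecol:::screen_retain(0.8000001, 1e-6))
  expect_false(viroecol:::screen_retain(0.99, 0.05))
  expect_true(viroecol:::screen_retain(0.99, 0.0499))

  # toy n = 6 against the covariance formula
  a <- c(3, 1, 4, 1, 5, 9)
  bb <- c(2, 7, 1, 8, 2, 8)
  out3 <- pearson_screen(matrix(a, 1, dimnames = list("og", NULL)),
                         data.frame(DOC = bb))
  r_hand <- sum((a - mean(a)) * (bb - mean(bb))) /
    sqrt(sum((a - mean(a))^2) * sum((bb - mean(bb))^2))
  expect_equal(out3$r, r_hand)
  t_hand <- r_hand * sqrt(4 / (1 - r_hand^2))
  expect_equal(out3$p, 2 * pt(abs(t_hand), 4, lower.tail = FALSE))
})

test_that("retention is invariant to affine rescaling of chemistry units", {
  set.seed(13)
  ab <- matrix(runif(24, 1, 100), 2, 12,
               dimnames = list(c("og1", "og2"), NULL))
  chem <- data.frame(PO4 = -ab["og1", ] + rnorm(12, 0, 2),
                     SO4 = runif(12))
  base <- pearson_screen(ab, chem)
  resc <- pearson_screen(ab, data.frame(PO4 = 1000 * chem$PO4 + 5,
                                        SO4 = 0.01 * chem$SO4 - 3))
  expect_equal(base$retained, resc$retained)
  expect_equal(base$r, resc$r, tolerance = 1e-12)
})

test_that("co-occurrence probabilities match the worked examples", {
  m <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("fA", "fB"), c("v1", "v2")))
  m[2, ] <- c(1, 0) # N = 2, N1 = N2 = 1, co-occur at v1
  out <- cooccur_pairs(m)
  expect_equal(out$observed, 1)
  expect_equal(out$p_gt, 0.5)

  # function on every site: j is forced, p_gt = 1
  m2 <- rbind(fA = rep(1, 5), fB = c(1, 1, 0, 0, 0))
  out2 <- cooccur_pairs(m2)
  expect_equal(out2$observed, 2)
  expect_equal(out2$p_gt, 1)

  # N = 10, N1 = N2 = 5, all five shared
  m3 <- rbind(fA = c(rep(1, 5), rep(0, 5)), fB = c(rep(1, 5), rep(0, 5)))
  out3 <- cooccur_pairs(m3)
  expect_equal(out3$p_gt, 1 / 252, tolerance = 1e-12)
  expect_true(out3$significant)
  expect_error(cooccur_pairs(matrix(c(0, 2, 1, 1), 2, 2)), "binary")
})

test_that("co-occurrence law is a proper distribution", {
  set.seed(14)
  for (i in 1:20) {
    N <- sample(3:15, 1)
    m <- matrix(rbinom(2 * N, 1, runif(1, 0.2, 0.8)), 2, N)
    rownames(m) <- c("a", "b")
    out <- cooccur_pairs(m)
    pmf <- viroecol:::cooccur_pmf(out$N, out$N1, out$N2)
    expect_equal(sum(pmf), 1, tolerance = 1e-9)
    p_at <- unname(pmf[as.character(out$observed)])
    expect_equal(out$p_lt + out$p_gt - p_at, 1, tolerance = 1e-9)
    expect_true(out$observed >= max(0, out$N1 + out$N2 - out$N))
    expect_true(out$observed <= min(out$N1, out$N2))
    expect_equal(out$expected, out$N1 * out$N2 / out$N)
  }
})
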