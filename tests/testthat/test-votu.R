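make_id_matrix <- function(ids, default = 0.5) {
  m <- matrix(default, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  m
}

test_that("identical sequences cluster into one vOTU", {
  seqs <- rand_seq(6000)
  ct <- contig_table(id = c("a", "b"), length = c(6000, 6000),
                     sequence = c(seqs, seqs), is_viral = TRUE)
  out <- cluster_votus(ct, identity = "align")
  expect_equal(nrow(out), 1)
  expect_setequal(out$members[[1]], c("a", "b"))
})

test_that("the length-ratio guard separates a short high-identity candidate", {
  ids <- c("long", "short")
  m <- make_id_matrix(ids)
  m["long", "short"] <- m["short", "long"] <- 0.96
  ct <- data.frame(id = ids, length = c(6000, 3000))
  out <- cluster_votus(ct, identity = m)
  expect_equal(nrow(out), 2) # ratio 0.5 < 0.85 despite identity 0.96
})

test_that("greedy representative rule resolves chained similarities", {
  ids <- c("A", "B", "C")
  m <- make_id_matrix(ids)
  m["A", "B"] <- m["B", "A"] <- 0.96
  m["B", "C"] <- m["C", "B"] <- 0.96
  m["A", "C"] <- m["C", "A"] <- 0.90
  ct <- data.frame(id = ids, length = rep(6000, 3))
  out <- cluster_votus(ct, identity = m)
  expect_equal(nrow(out), 2)
  expect_setequal(out$members[[match("A", out$representative)]], c("A", "B"))
  expect_setequal(out$members[[match("C", out$representative)]], "C")
})

test_that("clustering agrees with a greedy-trace oracle on random instances", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    ids <- sprintf("c%02d", sample(n))
    lens <- sample(5000:12000, n, replace = TRUE)
    m <- make_id_matrix(ids, default = 0)
    for (pair in as.data.frame(combn(n, 2))) {
      v <- sample(c(runif(1, 0.3, 0.94), runif(1, 0.95, 1)), 1)
      m[pair[1], pair[2]] <- m[pair[2], pair[1]] <- v
    }
    ct <- data.frame(id = ids, length = lens)
    got <- cluster_votus(ct, identity = m)
    want <- oracle_greedy_clusters(ids, lens, m)
    got_sets <- lapply(got$members, sort)
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    # partition invariant
    expect_setequal(unlist(got$members), ids)
    # representative is the longest member (ties by id)
    for (i in seq_len(nrow(got))) {
      mem <- got$members[[i]]
      best <- mem[order(-lens[match(mem, ids)], mem)][1]
      expect_identical(got$representative[i], best)
    }
  }
})

test_that("lifestyle follows provirus flags and the lysogeny gene set", {
  ct <- contig_table(
    id = c("p", "i", "n"), length = rep(6000, 3),
    is_viral = TRUE, is_provirus = c(TRUE, FALSE, FALSE),
    annotations = list(character(0), "integrase", "polymerase"))
  expect_equal(classify_lifestyle("p", ct), "temperate")
  expect_equal(classify_lifestyle("i", ct), "temperate")
  expect_equal(classify_lifestyle("n", ct), "lytic")
  expect_equal(classify_lifestyle(c("n", "i"), ct), "temperate")
})

hit_row <- function(pid, alen, qlen = 10000, slen = 10000) {
  data.frame(percent_identity = pid, alignment_length = alen,
             query_length = qlen, subject_length = slen)
}

test_that("novelty tiers follow the identity and coverage rules", {
  expect_equal(classify_novelty(hit_row(95, 8000)), "known")
  expect_equal(classify_novelty(hit_row(70, 7500)), "similar")
  expect_equal(classify_novelty(hit_row(95, 6000)), "novel") # coverage 60%
  expect_equal(classify_novelty(hit_row(95, 6000, slen = 8000)), "known")
  expect_equal(classify_novelty(NULL), "novel")
  expect_equal(classify_novelty(hit_row(95, 8000)[0, ]), "novel")
  # boundaries: identity exactly 90 or 50 -> similar; below 50 -> novel
  expect_equal(classify_novelty(hit_row(90, 8000)), "similar")
  expect_equal(classify_novelty(hit_row(50, 8000)), "similar")
  expect_equal(classify_novelty(hit_row(49.9, 8000)), "novel")
  # multiple hits: the best qualifying one decides
  h <- rbind(hit_row(95, 5000), hit_row(60, 8000))
  expect_equal(classify_novelty(h), "similar")
})

test_that("raising identity or coverage never demotes the novelty tier", {
  tiers <- c(novel = 1, similar = 2, known = 3)
  set.seed(11)
  for (i in 1:50) {
    pid <- runif(1, 30, 99)
    alen <- sample(1000:9999, 1)
    base <- tiers[[classify_novelty(hit_row(pid, alen))]]
    up_id <- tiers[[classify_novelty(hit_row(min(100, pid + runif(1, 0, 20)),
                                             alen))]]
    up_cov <- tiers[[classify_novelty(hit_row(pid,
                                              min(10000, alen + 2000)))]]
    expect_gte(up_id, base)
    expect_gte(up_cov, base)
  }
})

test_that("catalog labels partition the vOTU set", {
  b <- default_bundle()
  res <- run_pipeline(b, seed = 1, thresholds = list(permutations = 199L))
  cat <- res$catalog
  expect_setequal(unlist(cat$members), b$contigs$id[b$contigs$is_viral])
  expect_true(all(cat$lifestyle %in% c("temperate", "lytic")))
  expect_true(all(cat$novelty %in% c("known", "similar", "novel")))
  # truth partition is recovered exactly under the planted identities
  truth <- split(b$truth$votu_members$contig, b$truth$votu_members$votu)
  expect_setequal(vapply(cat$members, function(m)
    paste(sort(m), collapse = ","), character(1)),
    vapply(truth, function(m) paste(sort(m), collapse = ","), character(1)))
})
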