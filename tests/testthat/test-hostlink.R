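arrays_df <- function(spacers, score = 0.9, host = "hc_001") {
  data.frame(host_contig = host, spacer = spacers, score = score,
             stringsAsFactors = FALSE)
}

test_that("spacer matching honours the edit and span filters", {
  set.seed(101)
  subject <- rand_seq(3000)
  spacer <- substr(subject, 1001, 1030) # 30 nt exact occurrence
  hits <- match_spacers(arrays_df(spacer), c(v1 = subject))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1000) # 0-based
  expect_equal(hits$end, 1030)
  expect_equal(hits$mismatches, 0)
  expect_equal(hits$gaps, 0)
  expect_equal(hits$strand, "+")

  one_sub <- sub_mutate(spacer, 1)
  h1 <- match_spacers(arrays_df(one_sub), c(v1 = subject))
  expect_true(any(h1$start == 1000 & h1$edits == 1))

  two_sub <- sub_mutate(spacer, 2)
  h2 <- match_spacers(arrays_df(two_sub), c(v1 = subject))
  expect_false(any(h2$start == 1000 & h2$end == 1030))

  short <- substr(subject, 1001, 1018) # 18 nt, below the 20 bp window
  expect_equal(nrow(match_spacers(arrays_df(short), c(v1 = subject))), 0)
})

test_that("reverse-complement occurrences are reported on the minus strand", {
  set.seed(102)
  subject <- rand_seq(2000)
  spacer_rc <- substr(subject, 501, 532)
  spacer <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spacer_rc)))
  hits <- match_spacers(arrays_df(spacer), c(v1 = subject))
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 500)
  expect_equal(hits$end, 532)
})

test_that("low-score arrays and non-ACGT spacers are excluded", {
  set.seed(103)
  subject <- rand_seq(1000)
  spacer <- substr(subject, 101, 132)
  low <- arrays_df(spacer, score = 0.3)
  expect_equal(nrow(match_spacers(low, c(v1 = subject))), 0)
  boundary <- arrays_df(spacer, score = 0.4) # score must exceed 0.4
  expect_equal(nrow(match_spacers(boundary, c(v1 = subject))), 0)
  amb <- arrays_df(sub("A", "N", spacer))
  expect_warning(h <- match_spacers(amb, c(v1 = subject)), "non-ACGT")
})

test_that("both engines agree on random instances with planted variants", {
  set.seed(104)
  for (i in 1:10) {
    subject <- rand_seq(sample(800:2000, 1))
    sp <- character(0)
    for (k in 1:8) {
      L <- sample(20:42, 1)
      s0 <- sample(nchar(subject) - L, 1)
      pl <- substr(subject, s0, s0 + L - 1)
      sp <- c(sp, switch(1 + (k %% 4),
                         pl, sub_mutate(pl, 1), sub_mutate(pl, 2),
                         rand_seq(L)))
    }
    arr <- arrays_df(sp)
    a <- match_spacers(arr, c(v = subject), engine = "scan")
    b <- match_spacers(arr, c(v = subject), engine = "dp")
    expect_identical(hit_key(a), hit_key(b))
    # emitted hits satisfy the type invariants
    expect_true(all(a$match_length >= 20 & a$match_length <= 75))
    expect_true(all(a$mismatches + a$gaps <= 1))
    expect_true(all(a$edits == a$mismatches + a$gaps))
  }
})

test_that("indel occurrences are found at one gap and bounded span", {
  set.seed(105)
  subject <- rand_seq(1500)
  base <- substr(subject, 701, 730)
  # spacer with an extra base: subject span is 30 = L - 1
  ins <- paste0(substr(base, 1, 12), "A", substr(base, 13, 30))
  h <- match_spacers(arrays_df(ins), c(v1 = subject))
  cand <- h[h$start == 700 & h$gaps == 1, ]
  expect_gte(nrow(cand), 1)
  expect_equal(cand$match_length, 30)
  # spacer with a base removed: subject span is 30 = L + 1
  del <- paste0(substr(base, 1, 14), substr(base, 16, 30))
  h2 <- match_spacers(arrays_df(del), c(v1 = subject))
  expect_true(any(h2$start == 700 & h2$gaps == 1 & h2$match_length == 30))
})

test_that("planted host links are recovered at mutation 0/1 but not 2", {
  for (mut in 0:2) {
    b <- generate_community(sim_config(seed = 60 + mut,
                                       spacer_mutation_rate = mut))
    viral <- b$contigs[b$contigs$is_viral, ]
    truth <- b$truth$host_links
    truth_sp <- truth[truth$evidence == "spacer", ]
    # map truth vOTUs to their representative sequences
    reps <- b$truth$votu_members$contig[
      !duplicated(b$truth$votu_members$votu)]
    seqs <- setNames(b$contigs$sequence[match(reps, b$contigs$id)],
                     b$truth$votu_members$votu[
                       !duplicated(b$truth$votu_members$votu)])
    hits <- match_spacers(b$annotations$spacers, seqs)
    got_pairs <- unique(paste(hits$votu, hits$host_contig))
    want_pairs <- unique(paste(truth_sp$votu, truth_sp$host_contig))
    if (mut <= 1) {
      expect_true(all(want_pairs %in% got_pairs))
    } else {
      expect_false(any(want_pairs %in% got_pairs))
    }
  }
})

test_that("tRNA links require exact full-length identity across contigs", {
  t1 <- "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGT"
  viral <- data.frame(contig = "vc_1", sequence = t1)
  hosts <- data.frame(contig = c("hc_1", "vc_1", "hc_2"),
                      sequence = c(t1, t1, sub_mutate(t1, 1)))
  out <- match_trnas(viral, hosts)
  expect_equal(out$host_contig, "hc_1") # self-hit and mismatch excluded
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(t1)))
  out_rc <- match_trnas(viral, data.frame(contig = "hc_3", sequence = rc))
  expect_equal(out_rc$host_contig, "hc_3")
})

test_that("prophage context links inherit the flank lineage", {
  prov <- data.frame(votu = c("v1", "v2", "v3"),
                     host_contig = c("h1", "h1", "h2"))
  tax <- data.frame(contig = "h1",
                    lineage = "d__Bacteria;p__Pseudomonadota;c__G;o__Burkholderiales;f__X;g__Y")
  expect_message(out <- prophage_host(prov, tax), "unclassified")
  expect_equal(nrow(out), 2) # two proviruses in one classified host
  expect_true(all(out$lineage == tax$lineage))
})

test_that("consensus assigns strict-majority phyla and records orders", {
  mklink <- function(votu, host, ev, phylum, ord = "O1") {
    data.frame(votu = votu, host_contig = host, evidence = ev,
               lineage = sprintf("d__Bacteria;p__%s;c__C;o__%s", phylum, ord),
               stringsAsFactors = FALSE)
  }
  links <- rbind(mklink("v1", "h1", "spacer", "X"),
                 mklink("v2", "h2", "spacer", "X", "O1"),
                 mklink("v2", "h3", "trna", "X", "O2"),
                 mklink("v2", "h4", "prophage", "Y", "O3"),
                 mklink("v3", "h5", "spacer", "X"),
                 mklink("v3", "h6", "trna", "Y"))
  out <- consensus_host(links)
  asn <- setNames(out$assignments$phylum, out$assignments$votu)
  expect_equal(unname(asn["v1"]), "X")
  expect_equal(unname(asn["v2"]), "X")   # 2 of 3: strict majority
  expect_true(is.na(asn["v3"]))          # tie
  expect_setequal(out$host_orders$v2, c("O1", "O2", "O3"))
  # stability under reordering
  out2 <- consensus_host(links[sample(nrow(links)), ])
  expect_equal(out2$assignments[order(out2$assignments$votu), ],
               out$assignments[order(out$assignments$votu), ],
               ignore_attr = TRUE)
})

test_that("phylum diversity pairs reuse the Shannon machinery", {
  vht <- data.frame(votu = c("v1", "v2", "v3", "v4"),
                    phylum = c("X", "X", "X", "Y"),
                    abundance = c(2, 1, 1, 5))
  dft <- data.frame(phylum = c("X", "X", "Y"),
                    system = c("RM", "CBASS", "RM"))
  out <- phylum_diversity_correlation(vht, dft)
  div <- out$diversity
  expect_equal(div$phage_shannon[div$phylum == "X"],
               shannon_index(c(2, 1, 1)))
  expect_equal(div$defence_shannon[div$phylum == "X"], log(2))
  expect_equal(div$phage_shannon[div$phylum == "Y"], 0) # singleton
  expect_equal(div$defence_shannon[div$phylum == "Y"], 0)
})
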