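# Independent oracles used across the suite.  Each reimplements the target
# quantity by brute force or a closed form, never by calling the package
# path it checks.

# greedy clustering retraced directly from its definition
oracle_greedy_clusters <- function(ids, lens, id_matrix,
                                   threshold = 0.95, ratio = 0.85) {
  ord <- order(-lens, ids)
  ids <- ids[ord]
  lens <- lens[ord]
  reps <- character(0)
  assignment <- list()
  for (i in seq_along(ids)) {
    joined <- NA
    for (k in seq_along(reps)) {
      r <- reps[k]
      if (lens[i] / lens[ids == r][1] < ratio) next
      if (id_matrix[ids[i], r] >= threshold) {
        joined <- k
        break
      }
    }
    if (is.na(joined)) {
      reps <- c(reps, ids[i])
      assignment[[length(reps)]] <- ids[i]
    } else {
      assignment[[joined]] <- c(assignment[[joined]], ids[i])
    }
  }
  lapply(assignment, sort)
}

# exhaustive distribution of the co-occurrence count: place the second
# function on every C(N, N2) subset of sites, first function fixed
oracle_cooccur_tail <- function(N, N1, N2, j_obs) {
  sites_a <- seq_len(N1)
  placements <- combn(N, N2)
  overlap <- apply(placements, 2, function(s) length(intersect(s, sites_a)))
  c(p_gt = mean(overlap >= j_obs), p_lt = mean(overlap <= j_obs))
}

# pseudo-F recomputed from scratch (squared distances, SS decomposition)
oracle_pseudo_f <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  g <- length(unique(groups))
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ((ss_tot - ss_w) / (g - 1)) / (ss_w / (n - g))
}

# all distinct arrangements of a label vector, as a list
oracle_label_arrangements <- function(groups) {
  perms <- unique(combinat_permn(groups))
  perms
}

# tiny multiset permutation enumerator (no extra packages)
combinat_permn <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- combinat_permn(x[-i])
    for (r in rest) out[[length(out) + 1]] <- c(x[i], r)
  }
  out
}

# Venn region counts by explicit set algebra
oracle_venn <- function(presence) {
  k <- ncol(presence)
  out <- list()
  for (size in 1:k) {
    for (cmb in as.data.frame(combn(k, size))) {
      inside <- rowSums(presence[, cmb, drop = FALSE]) == size &
        rowSums(presence) == size
      out[[paste(colnames(presence)[cmb], collapse = "&")]] <- sum(inside)
    }
  }
  out
}

# random DNA string
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# mutate k positions (substitutions)
sub_mutate <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  for (p in sample(length(ch), k))
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# canonical sortable representation of a spacer hit table for set equality
hit_key <- function(h) {
  if (nrow(h) == 0) return(character(0))
  sort(paste(h$spacer_index, h$votu, h$strand, h$start, h$end, h$edits))
}

default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 7,
                        planted_correlations = list(
                          list(family = 1, variable = "PO4", r = -0.95)))
      cache <<- generate_community(cfg)
    }
    cache
  }
})
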