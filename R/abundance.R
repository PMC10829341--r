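#' TPM-normalise a contig-by-sample count matrix
#'
#' Transcripts-per-million normalisation: per sample, each contig's count is
#' divided by its length to give a coverage rate, and rates are rescaled so
#' the column sums to one million.  This accounts jointly for library size
#' and contig length, making relative abundances comparable across samples.
#'
#' @param counts numeric matrix of non-negative read counts, contigs in rows
#'   and samples in columns.  Row names identify contigs.
#' @param lengths numeric vector of contig lengths in bp, positive, one per
#'   row of \code{counts} (recycled by name when named).
#' @return a matrix of the same shape; every column with at least one
#'   nonzero count sums to 1e6, all-zero columns remain all-zero.
#' @examples
#' m <- matrix(c(10, 20, 0, 5), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("s1", "s2")))
#' compute_tpm(m, c(c1 = 1000, c2 = 2000))
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_input("counts must be non-negative")
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts))
    stop_input("lengths must have one entry per contig row")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop_input("contig lengths must be positive and finite")
  rate <- counts / lengths
  denom <- colSums(rate)
  tpm <- sweep(rate, 2, ifelse(denom > 0, denom, 1), "/") * 1e6
  tpm[, denom == 0] <- 0
  dimnames(tpm) <- dimnames(counts)
  tpm
}

#' Per-sample viral fraction of a metagenome
#'
#' The percentage of each sample attributable to viral contigs: the TPM sum
#' over viral contigs divided by one million (the TPM sum over all contigs),
#' expressed in percent.
#'
#' @param tpm TPM matrix from \code{\link{compute_tpm}} (contigs x samples).
#' @param viral_ids character vector of viral contig ids (must be row names
#'   of \code{tpm}).
#' @return named numeric vector, percent per sample, in [0, 100].
#' @export
viral_fraction <- function(tpm, viral_ids) {
  tpm <- as.matrix(tpm)
  missing <- setdiff(viral_ids, rownames(tpm))
  if (length(missing) > 0)
    stop_input("viral ids absent from the TPM matrix: %s",
               paste(head(missing, 5), collapse = ", "))
  if (length(viral_ids) == 0) return(setNames(rep(0, ncol(tpm)), colnames(tpm)))
  colSums(tpm[viral_ids, , drop = FALSE]) / 1e6 * 100
}

#' Shannon diversity (natural log)
#'
#' H = -sum p_i ln p_i over the positive entries of an abundance vector,
#' computed with \code{vegan::diversity}.  Natural logarithms, consistent
#' with vegan's default.
#'
#' @param x non-negative abundance vector with at least one positive entry,
#'   or a matrix of such rows.
#' @return Shannon index in nats (one value per row for matrix input).
#' @export
shannon_index <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    if (any(rowSums(as.matrix(x)) <= 0))
      stop_input("undefined diversity: a row has no positive abundance")
    return(vegan::diversity(as.matrix(x), index = "shannon"))
  }
  if (any(x < 0)) stop_input("abundances must be non-negative")
  if (sum(x) <= 0)
    stop_input("undefined diversity: all-zero abundance vector")
  unname(vegan::diversity(matrix(x, nrow = 1), index = "shannon"))
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = 1 - 2 sum_i min(x_i, y_i) / sum_i (x_i + y_i), computed with
#' \code{vegan::vegdist} on the transposed matrix so that samples are
#' compared.
#'
#' @param mat abundance matrix, contigs/vOTUs in rows and samples in
#'   columns, non-negative.
#' @return symmetric sample-by-sample matrix with zero diagonal, entries in
#'   [0, 1].
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop_input("abundances must be non-negative")
  zero <- colSums(mat) == 0
  if (sum(zero) >= 2)
    stop_input("Bray-Curtis undefined for a pair of all-zero samples")
  as.matrix(vegan::vegdist(t(mat), method = "bray"))
}

# pseudo-F for a distance matrix and integer group labels.
# SS_total = sum_{i<j} d2_ij / N ; SS_within = sum_g sum_{i<j in g} d2_ij / n_g
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  sizes <- tabulate(groups)
  for (g in seq_along(sizes)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_between <- ss_total - ss_within
  g <- length(sizes)
  (ss_between / (g - 1)) / (ss_within / (n - g))
}

# distinct arrangements of a label multiset (columns of a matrix)
distinct_label_arrangements <- function(groups) {
  n <- length(groups)
  rec <- function(remaining) {
    if (length(remaining) == 0) return(matrix(integer(0), nrow = 0, ncol = 1))
    out <- list()
    for (g in unique(remaining)) {
      rest <- remaining[-match(g, remaining)]
      sub <- rec(rest)
      out[[length(out) + 1]] <- rbind(rep(g, ncol(sub)), sub)
    }
    do.call(cbind, out)
  }
  rec(sort(groups))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance: a pseudo-F statistic is
#' computed from within- and between-group sums of squared distances and its
#' null distribution obtained by permuting group labels.  The p-value uses
#' the (1 + b) / (1 + m) estimator, where b counts permuted statistics at
#' least as large as the observed one; when the number of distinct label
#' arrangements is no larger than \code{n_permutations}, all arrangements
#' are enumerated and the p-value is the exact proportion with F >= observed.
#'
#' @param dist sample-by-sample distance matrix (e.g.
#'   \code{\link{bray_curtis}}) or a \code{dist} object.
#' @param group_labels factor-like vector of group labels, one per sample;
#'   at least two groups and at least one group of size >= 2.
#' @param n_permutations number of random permutations (default 999).
#' @param seed optional integer seed for the permutation stream.
#' @return list of class \code{"permanova"} with elements
#'   \code{pseudo_F}, \code{p_value}, \code{n_permutations} (number of
#'   permutations actually used), \code{exhaustive} (logical), and the
#'   sums of squares \code{ss_between}, \code{ss_within}, \code{ss_total}.
#' @export
permanova <- function(dist, group_labels, n_permutations = 999, seed = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (length(group_labels) != n)
    stop_input("one group label per sample required")
  groups <- as.integer(factor(group_labels))
  sizes <- tabulate(groups)
  if (length(sizes) < 2) stop_input("PERMANOVA needs at least two groups")
  if (all(sizes == 1))
    stop_input("degenerate design: every group has a single sample")
  d2 <- d^2
  f_obs <- permanova_f(d2, groups)

  n_arr <- exp(lfactorial(n) - sum(lfactorial(sizes)))
  exhaustive <- is.finite(n_arr) && n_arr <= n_permutations
  if (exhaustive) {
    arr <- distinct_label_arrangements(groups)
    f_perm <- apply(arr, 2, function(g) permanova_f(d2, g))
    # degenerate distances can make F 0/0; treat NaN as no exceedance
    p <- mean(f_perm >= f_obs | (is.nan(f_perm) & is.nan(f_obs)), na.rm = FALSE)
    if (is.na(p)) p <- mean(ifelse(is.nan(f_perm), FALSE, f_perm >= f_obs))
    used <- ncol(arr)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      set.seed(seed)
    }
    b <- 0L
    for (i in seq_len(n_permutations)) {
      fp <- permanova_f(d2, sample(groups))
      if (!is.nan(fp) && fp >= f_obs) b <- b + 1L
      else if (is.nan(fp) && is.nan(f_obs)) b <- b + 1L
    }
    p <- (1 + b) / (1 + n_permutations)
    used <- n_permutations
  }
  if (is.nan(f_obs)) p <- 1 # no between- or within-group variation at all

  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in seq_along(sizes)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  structure(list(pseudo_F = f_obs, p_value = p, n_permutations = used,
                 exhaustive = exhaustive, ss_total = ss_total,
                 ss_within = ss_within, ss_between = ss_total - ss_within),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f, p = %.4g (%s, %d permutations)\n",
              x$pseudo_F, x$p_value,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA across groups with BH adjustment
#'
#' Runs \code{\link{permanova}} for every pair of group levels and adjusts
#' the p-values across contrasts with the Benjamini-Hochberg procedure.
#'
#' @inheritParams permanova
#' @return data frame with one row per contrast: \code{group_a},
#'   \code{group_b}, \code{pseudo_F}, \code{p_value}, \code{adjusted_p}.
#' @export
pairwise_permanova <- function(dist, group_labels, n_permutations = 999,
                               seed = NULL) {
  d <- as.matrix(dist)
  labs <- factor(group_labels)
  lev <- levels(labs)
  if (length(lev) < 2) stop_input("need at least two groups")
  pairs <- combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    keep <- labs %in% pairs[, k]
    fit <- permanova(d[keep, keep, drop = FALSE], droplevels(labs[keep]),
                     n_permutations = n_permutations,
                     seed = if (is.null(seed)) NULL else seed + k)
    data.frame(group_a = pairs[1, k], group_b = pairs[2, k],
               pseudo_F = fit$pseudo_F, p_value = fit$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- bh_adjust(out$p_value)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper around
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values in the input order, each >= the raw value.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_input("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Linear regression of diversity on depth
#'
#' Ordinary least squares of a diversity index (or any response) on water
#' depth, with the usual t-test for the slope.
#'
#' @param depths numeric vector of depths (m), not all equal, length >= 3.
#' @param shannon_values numeric response, same length.
#' @return list with \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{p_value} (two-sided, slope), \code{n}.
#' @export
depth_diversity_regression <- function(depths, shannon_values) {
  if (length(depths) != length(shannon_values))
    stop_input("depths and responses must have equal length")
  if (length(depths) < 3) stop_input("need at least three points")
  if (sd(depths) == 0) stop_input("depths are constant; slope undefined")
  if (sd(shannon_values) == 0)
    return(list(slope = 0, intercept = shannon_values[1], r_squared = 0,
                p_value = 1, n = length(depths)))
  fit <- lm(shannon_values ~ depths)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) < 2 || is.na(sm$coefficients[2, 4])) NA_real_
       else sm$coefficients[2, 4]
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p, n = length(depths))
}

#' Venn membership of vOTUs across depth clusters
#'
#' A vOTU is present in a depth cluster if its TPM is strictly positive in
#' at least one sample of that cluster.  Counts are returned for every
#' non-empty combination of clusters (the 2^k - 1 Venn regions).
#'
#' @param tpm vOTU-by-sample abundance matrix.
#' @param depth_clusters named list of character/integer vectors of sample
#'   columns; must be disjoint, non-empty and jointly cover only existing
#'   samples.
#' @return data frame with columns \code{region} (cluster names joined by
#'   \code{"&"}), \code{n_clusters} and \code{count}; region counts sum to
#'   the number of vOTUs present in any sample.
#' @export
venn_membership <- function(tpm, depth_clusters) {
  tpm <- as.matrix(tpm)
  if (is.null(names(depth_clusters)))
    names(depth_clusters) <- paste0("cluster", seq_along(depth_clusters))
  cols <- lapply(depth_clusters, function(s) {
    if (length(s) == 0) stop_input("empty depth cluster")
    if (is.character(s)) {
      if (!all(s %in% colnames(tpm)))
        stop_input("unknown sample in depth cluster")
      match(s, colnames(tpm))
    } else as.integer(s)
  })
  if (anyDuplicated(unlist(cols)))
    stop_input("depth clusters must be disjoint")
  presence <- vapply(cols, function(idx) {
    rowSums(tpm[, idx, drop = FALSE] > 0) > 0
  }, logical(nrow(tpm)))
  presence <- matrix(presence, nrow = nrow(tpm),
                     dimnames = list(rownames(tpm), names(depth_clusters)))
  k <- length(depth_clusters)
  regions <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(regions) <- names(depth_clusters)
  counts <- apply(regions, 1, function(mask) {
    sum(apply(presence, 1, function(p) all(p == as.logical(mask))))
  })
  data.frame(
    region = apply(regions, 1, function(mask)
      paste(names(depth_clusters)[as.logical(mask)], collapse = "&")),
    n_clusters = rowSums(regions),
    count = as.integer(counts),
    row.names = NULL, stringsAsFactors = FALSE)
}
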