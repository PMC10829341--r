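#' Markov clustering of a weighted similarity graph
#'
#' Flow-based graph clustering: the column-stochastic transition matrix
#' (with self-loops set to each node's maximum incident edge weight, 1 for
#' isolated nodes) is alternately expanded (matrix squaring) and inflated
#' (entrywise power \code{inflation} followed by column renormalisation),
#' with entries below \code{prune} removed, until the matrix changes by
#' less than \code{tol} or \code{max_iter} iterations.  Clusters are read
#' from attractor rows (nodes with positive diagonal); a node attracted by
#' several attractors is resolved to the lexicographically smallest
#' attractor id.
#'
#' @param graph data frame of undirected edges: \code{from}, \code{to},
#'   \code{weight} (>= 0, finite); or a symmetric weighted adjacency
#'   matrix with dimnames.
#' @param inflation inflation exponent, > 1 (default 1.5).
#' @param expansion matrix-power used for expansion (default 2).
#' @param prune entries below this are zeroed each iteration (default 1e-5).
#' @param tol convergence threshold on the max entry change (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @param nodes optional character vector of node ids to include even when
#'   isolated (no incident edges).
#' @return named character vector mapping node id to cluster id
#'   (\code{"OG_0001"}...), ordered by node id; clusters numbered by first
#'   appearance over sorted node ids.
#' @export
mcl_cluster <- function(graph, inflation = 1.5, expansion = 2L,
                        prune = 1e-5, tol = 1e-8, max_iter = 100L,
                        nodes = NULL) {
  if (inflation <= 1) stop_input("inflation must exceed 1")
  if (is.matrix(graph)) {
    A <- graph
    if (is.null(rownames(A))) stop_input("adjacency matrix needs dimnames")
  } else {
    if (!all(c("from", "to") %in% names(graph)))
      stop_input("graph needs 'from' and 'to' columns")
    w <- if ("weight" %in% names(graph)) graph$weight else
      rep(1, nrow(graph))
    if (any(!is.finite(w)) || any(w < 0))
      stop_input("edge weights must be finite and non-negative")
    ids <- sort(unique(c(graph$from, graph$to, nodes)))
    A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (k in seq_len(nrow(graph))) {
      i <- graph$from[k]; j <- graph$to[k]
      if (i == j) next # self-loops are set internally
      A[i, j] <- A[i, j] + w[k]
      A[j, i] <- A[j, i] + w[k]
    }
  }
  ids <- rownames(A)
  n <- length(ids)
  if (n == 0) stop_input("empty graph")
  loop <- apply(A, 2, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf <- sweep(Minf, 2, colSums(Minf), "/")
    Minf[Minf < prune] <- 0
    cs <- colSums(Minf)
    if (any(cs == 0)) stop_input("pruning emptied a column; lower 'prune'")
    Minf <- sweep(Minf, 2, cs, "/")
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < tol) break
  }
  attractors <- which(diag(M) > 0)
  membership <- setNames(rep(NA_character_, n), ids)
  for (a in attractors[order(ids[attractors])]) {
    in_cluster <- which(M[a, ] > 0)
    for (j in in_cluster)
      if (is.na(membership[j])) membership[j] <- ids[a]
  }
  # orphaned nodes (pruned out entirely) become singletons
  membership[is.na(membership)] <- ids[is.na(membership)]
  anchors <- unique(membership[order(names(membership))])
  og_ids <- setNames(sprintf("OG_%04d", seq_along(anchors)), anchors)
  out <- setNames(unname(og_ids[membership]), names(membership))
  out[order(names(out))]
}

#' Per-sample abundance of an orthologous group
#'
#' The abundance of an OG in a sample is the TPM sum over its distinct
#' member vOTUs; gene copy number within a vOTU is ignored, since
#' abundance is measured at the contig level.
#'
#' @param member_votus character vector of the OG's member vOTU ids
#'   (duplicates allowed, counted once).
#' @param tpm vOTU-by-sample TPM matrix.
#' @return named numeric vector of per-sample abundances.
#' @export
og_abundance <- function(member_votus, tpm) {
  votus <- unique(member_votus)
  missing <- setdiff(votus, rownames(tpm))
  if (length(missing) > 0)
    stop_input("unknown vOTU in orthologous group: %s",
               paste(head(missing, 5), collapse = ", "))
  colSums(as.matrix(tpm)[votus, , drop = FALSE])
}

#' Eligibility filter for OG-AMG correlation analysis
#'
#' Correlations between an OG's abundance and chemistry can be driven by
#' co-encoded functions or host associations rather than the AMG itself;
#' the filter keeps only OGs whose signal is attributable to multiple
#' active viruses.  Member genes carried by provirus vOTUs are dropped
#' first; an OG is then eligible if at least two distinct vOTUs remain and
#' their hosts span at least two distinct prokaryotic orders.
#'
#' @param og_members named list: OG id -> data frame with columns
#'   \code{gene} and \code{votu} (or a character vector of member vOTUs).
#' @param provirus_votus character vector of vOTU ids flagged provirus.
#' @param votu_host_orders named list: vOTU id -> character vector of host
#'   orders (as returned by \code{\link{consensus_host}}).
#' @return data frame: \code{og}, \code{n_votus} (after the provirus
#'   drop), \code{n_host_orders}, \code{eligible}; plus attribute
#'   \code{"members"}, the pruned member-vOTU list.
#' @export
eligible_ogs <- function(og_members, provirus_votus, votu_host_orders) {
  pruned <- lapply(og_members, function(m) {
    v <- if (is.data.frame(m)) m$votu else m
    unique(v[!(v %in% provirus_votus)])
  })
  rows <- lapply(names(pruned), function(og) {
    v <- pruned[[og]]
    orders <- unique(unlist(votu_host_orders[v], use.names = FALSE))
    orders <- orders[!is.na(orders)]
    data.frame(og = og, n_votus = length(v),
               n_host_orders = length(orders),
               eligible = length(v) >= 2 && length(orders) >= 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "members") <- pruned
  out
}

#' Pearson screen of OG abundances against water chemistry
#'
#' Product-moment correlation of each OG abundance vector with each
#' chemistry variable across samples, with the usual two-sided t-test on
#' n - 2 degrees of freedom.  A correlation is retained only when
#' p < \code{alpha} and |r| > \code{r_threshold}, both strict.  Constant
#' vectors yield an undefined r and are never retained.
#'
#' @param og_abundances matrix (or data frame) of OG abundances, OGs in
#'   rows, samples in columns.
#' @param chemistry data frame of chemistry variables, samples in rows
#'   (row names or a \code{sample} column matching the abundance columns),
#'   numeric columns such as DOC, Fe, NH3, NO3, PO4, SO4, salinity, DO.
#' @param alpha significance threshold (default 0.05, strict).
#' @param r_threshold absolute-correlation threshold (default 0.8, strict).
#' @return data frame: \code{og}, \code{variable}, \code{r}, \code{p},
#'   \code{retained}.
#' @export
pearson_screen <- function(og_abundances, chemistry, alpha = 0.05,
                           r_threshold = 0.8) {
  ab <- as.matrix(og_abundances)
  if ("sample" %in% names(chemistry)) {
    rownames(chemistry) <- chemistry$sample
    chemistry$sample <- NULL
  }
  chem <- chemistry[, vapply(chemistry, is.numeric, logical(1)), drop = FALSE]
  if (!is.null(colnames(ab)) && !is.null(rownames(chem))) {
    if (!all(colnames(ab) %in% rownames(chem)))
      stop_input("chemistry samples do not match abundance samples")
    chem <- chem[colnames(ab), , drop = FALSE]
  } else if (nrow(chem) != ncol(ab))
    stop_input("chemistry samples do not match abundance samples")
  if (ncol(ab) < 3) stop_input("need at least three paired samples")
  if (is.null(rownames(ab))) rownames(ab) <- paste0("OG_", seq_len(nrow(ab)))
  rows <- list()
  for (og in rownames(ab)) {
    x <- ab[og, ]
    for (v in colnames(chem)) {
      y <- chem[[v]]
      if (sd(x) == 0 || sd(y) == 0) {
        warning(sprintf("constant vector for %s ~ %s; r undefined", og, v))
        rows[[length(rows) + 1]] <-
          data.frame(og = og, variable = v, r = NA_real_, p = NA_real_,
                     retained = FALSE, stringsAsFactors = FALSE)
        next
      }
      ct <- cor.test(x, y, method = "pearson")
      rows[[length(rows) + 1]] <-
        data.frame(og = og, variable = v, r = unname(ct$estimate),
                   p = ct$p.value,
                   retained = screen_retain(ct$estimate, ct$p.value,
                                            alpha, r_threshold),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# retention rule of the correlation screen: both thresholds are strict
screen_retain <- function(r, p, alpha = 0.05, r_threshold = 0.8) {
  !is.na(r) && !is.na(p) && p < alpha && abs(r) > r_threshold
}

# exact hypergeometric law of the co-occurrence count j for one pair:
# P(j) = C(N1, j) C(N - N1, N2 - j) / C(N, N2) over the feasible range
cooccur_pmf <- function(N, N1, N2) {
  j <- max(0, N1 + N2 - N):min(N1, N2)
  setNames(dhyper(j, N1, N - N1, N2), j)
}

#' Pairwise AMG co-occurrence with an exact probabilistic null
#'
#' For each unordered pair of AMG functions, the number of vOTUs carrying
#' both is compared with the exact hypergeometric distribution of joint
#' presences given the two marginal frequencies (the probabilistic
#' species co-occurrence model of Veech).  \code{p_gt} is the probability
#' of observing at least the observed number of co-occurrences, and
#' \code{p_lt} at most; a pair co-occurs significantly more than expected
#' when \code{p_gt < alpha}.
#'
#' @param presence binary (0/1 or logical) matrix, functions in rows and
#'   vOTUs (sites) in columns.
#' @param alpha significance threshold for the \code{significant} flag
#'   (default 0.05, strict).
#' @return data frame per pair: \code{function_a}, \code{function_b},
#'   \code{N}, \code{N1}, \code{N2}, \code{observed}, \code{expected},
#'   \code{p_lt}, \code{p_gt}, \code{significant}.
#' @export
cooccur_pairs <- function(presence, alpha = 0.05) {
  m <- as.matrix(presence)
  if (is.logical(m)) m <- m * 1L
  if (!all(m %in% c(0, 1))) stop_input("presence matrix must be binary")
  N <- ncol(m)
  if (N < 2) stop_input("need at least two sites (vOTUs)")
  fns <- rownames(m) %||% paste0("fn", seq_len(nrow(m)))
  if (nrow(m) < 2)
    return(data.frame(function_a = character(0), function_b = character(0),
                      N = integer(0), N1 = integer(0), N2 = integer(0),
                      observed = integer(0), expected = numeric(0),
                      p_lt = numeric(0), p_gt = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  pairs <- combn(nrow(m), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    N1 <- sum(m[a, ]); N2 <- sum(m[b, ])
    j_obs <- sum(m[a, ] == 1 & m[b, ] == 1)
    pmf <- cooccur_pmf(N, N1, N2)
    j <- as.integer(names(pmf))
    data.frame(function_a = fns[a], function_b = fns[b],
               N = N, N1 = N1, N2 = N2, observed = j_obs,
               expected = N1 * N2 / N,
               p_lt = sum(pmf[j <= j_obs]),
               p_gt = sum(pmf[j >= j_obs]),
               significant = sum(pmf[j >= j_obs]) < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
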