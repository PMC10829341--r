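# hits from one engine on one (spacer, votu, strand); canonical columns
spacer_hit_frame <- function(raw, spacer_idx, host_contig, votu, strand, L) {
  if (nrow(raw) == 0) return(NULL)
  data.frame(spacer_index = spacer_idx, host_contig = host_contig,
             votu = votu, start = raw$start, end = raw$end,
             match_length = raw$end - raw$start,
             mismatches = ifelse(raw$end - raw$start == L, raw$edits, 0L),
             gaps = ifelse(raw$end - raw$start == L, 0L, 1L),
             edits = raw$edits, strand = strand,
             stringsAsFactors = FALSE)
}

# collapse overlapping duplicates of the same (spacer, votu, strand): gap
# variants of one locus shift the span by +-1 and overlap almost entirely;
# genuinely distinct occurrences of a >= 20 bp spacer do not.  Keep the
# fewest-edit span (ties: leftmost, then shortest).
dedup_spacer_hits <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(hits)
  key <- paste(hits$spacer_index, hits$host_contig, hits$votu, hits$strand)
  keep <- logical(nrow(hits))
  for (k in unique(key)) {
    idx <- which(key == k)
    h <- hits[idx, , drop = FALSE]
    ord <- order(h$edits, h$start, h$match_length)
    chosen <- integer(0)
    for (i in ord) {
      olap <- FALSE
      for (j in chosen) {
        ov <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j])
        if (ov >= min(h$match_length[i], h$match_length[j]) - 2) {
          olap <- TRUE
          break
        }
      }
      if (!olap) chosen <- c(chosen, i)
    }
    keep[idx[chosen]] <- TRUE
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$votu, out$host_contig, out$spacer_index, out$start), ,
      drop = FALSE]
}

#' Match CRISPR spacers against vOTU sequences
#'
#' Scans every spacer (both strands) against every vOTU sequence for
#' occurrences with at most one edit (a single substitution, or a single
#' 1-bp insertion or deletion — never both) and a matched span of 20--75 bp
#' on the vOTU.  Arrays are filtered to score > 0.4 before matching.
#' Overlapping duplicate hits of the same spacer at one locus (span shifts
#' of +-1 bp introduced by the gap variants) are collapsed to the
#' fewest-edit variant.
#'
#' Coordinates are 0-based, half-open, on the plus strand of the vOTU; the
#' strand of the matching spacer orientation is reported separately.
#'
#' @param arrays data frame of CRISPR arrays: \code{host_contig},
#'   \code{spacer} (ACGT string), \code{score}.  Spacers with non-ACGT
#'   characters are skipped with a warning.
#' @param votu_seqs named character vector of vOTU nucleotide sequences.
#' @param min_len,max_len matched-span window (defaults 20 and 75 bp).
#' @param max_edits maximum total edits (default 1; only 0 and 1 are
#'   supported).
#' @param score_threshold minimum CRISPR array score (default 0.4,
#'   exclusive).
#' @param engine \code{"scan"} (sliding-window Hamming plus single-indel
#'   variants, the default) or \code{"dp"} (the independent
#'   dynamic-programming engine, used for validation).
#' @return data frame of hits: \code{spacer_index} (row of \code{arrays}),
#'   \code{host_contig}, \code{votu}, \code{start}, \code{end},
#'   \code{match_length}, \code{mismatches}, \code{gaps}, \code{edits},
#'   \code{strand}.
#' @export
match_spacers <- function(arrays, votu_seqs, min_len = 20L, max_len = 75L,
                          max_edits = 1L, score_threshold = 0.4,
                          engine = c("scan", "dp")) {
  engine <- match.arg(engine)
  if (max_edits != 1L)
    stop_input("only the one-edit tolerance is supported")
  if (!all(c("host_contig", "spacer") %in% names(arrays)))
    stop_input("arrays need 'host_contig' and 'spacer' columns")
  if (is.null(names(votu_seqs)))
    stop_input("votu_seqs must be named by vOTU id")
  score <- if ("score" %in% names(arrays)) arrays$score else
    rep(Inf, nrow(arrays))
  fn <- if (engine == "scan") scan_hits_cpp else dp_hits_cpp
  out <- vector("list", 0)
  for (i in seq_len(nrow(arrays))) {
    if (!is.na(score[i]) && score[i] <= score_threshold) next
    sp <- toupper(arrays$spacer[i])
    if (grepl("[^ACGT]", sp)) {
      warning(sprintf("spacer %d contains non-ACGT characters; skipped", i))
      next
    }
    sp_rc <- revcomp(sp)
    L <- nchar(sp)
    for (v in names(votu_seqs)) {
      subj <- toupper(votu_seqs[[v]])
      out[[length(out) + 1]] <-
        spacer_hit_frame(fn(subj, sp, min_len, max_len),
                         i, arrays$host_contig[i], v, "+", L)
      out[[length(out) + 1]] <-
        spacer_hit_frame(fn(subj, sp_rc, min_len, max_len),
                         i, arrays$host_contig[i], v, "-", L)
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0)
    return(data.frame(spacer_index = integer(0), host_contig = character(0),
                      votu = character(0), start = integer(0),
                      end = integer(0), match_length = integer(0),
                      mismatches = integer(0), gaps = integer(0),
                      edits = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  dedup_spacer_hits(do.call(rbind, out))
}

#' Host links from identical tRNA sharing
#'
#' Links a vOTU to a host contig when a viral tRNA is identical, full
#' length, to a tRNA on another contig (either strand); self-hits on the
#' same parent contig are excluded.
#'
#' @param viral_trnas data frame: \code{contig} (viral contig or vOTU id),
#'   \code{sequence}.
#' @param all_trnas data frame of candidate host tRNAs: \code{contig},
#'   \code{sequence}.
#' @return data frame of links: \code{votu}, \code{host_contig},
#'   \code{evidence = "trna"}.
#' @export
match_trnas <- function(viral_trnas, all_trnas) {
  links <- list()
  vseq <- toupper(viral_trnas$sequence)
  hseq <- toupper(all_trnas$sequence)
  hrc <- revcomp(hseq)
  for (i in seq_along(vseq)) {
    hit <- (hseq == vseq[i] | hrc == vseq[i]) &
      all_trnas$contig != viral_trnas$contig[i]
    if (any(hit))
      links[[length(links) + 1]] <-
        data.frame(votu = viral_trnas$contig[i],
                   host_contig = all_trnas$contig[hit],
                   evidence = "trna", stringsAsFactors = FALSE)
  }
  if (length(links) == 0)
    return(data.frame(votu = character(0), host_contig = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  unique(do.call(rbind, links))
}

#' Host links from prophage genomic context
#'
#' A provirus integrated in a host contig inherits that contig's taxonomy:
#' each provirus record is linked to its flanking host contig, provided the
#' host has a classified lineage.
#'
#' @param proviruses data frame: \code{votu}, \code{host_contig}.
#' @param taxonomy data frame: \code{contig}, \code{lineage} (GTDB-style
#'   \code{d__;p__;c__;o__;...} string).
#' @return data frame of links: \code{votu}, \code{host_contig},
#'   \code{evidence = "prophage"}, \code{lineage}.
#' @export
prophage_host <- function(proviruses, taxonomy) {
  tax <- setNames(taxonomy$lineage, taxonomy$contig)
  lin <- unname(tax[proviruses$host_contig])
  keep <- !is.na(lin) & nzchar(lin)
  if (any(!keep))
    message(sprintf("%d provirus(es) with unclassified flank left unlinked",
                    sum(!keep)))
  data.frame(votu = proviruses$votu[keep],
             host_contig = proviruses$host_contig[keep],
             evidence = "prophage", lineage = lin[keep],
             stringsAsFactors = FALSE)
}

#' Consensus host phylum per vOTU
#'
#' Pools host links from all three evidence types, resolves each linked
#' host contig to a phylum, and assigns the strict-majority phylum per
#' vOTU; ties or absent links leave the vOTU unassigned.  The union of
#' host orders across links is recorded per vOTU (used by the AMG
#' eligibility filter) but never "assigned".
#'
#' @param links data frame with \code{votu}, \code{host_contig},
#'   \code{evidence}, and optionally a \code{lineage} column; lineages for
#'   rows without one are looked up in \code{taxonomy}.
#' @param taxonomy data frame: \code{contig}, \code{lineage}.
#' @return list with \code{assignments} (data frame \code{votu},
#'   \code{phylum}, \code{n_links}; \code{phylum} is NA when unassigned)
#'   and \code{host_orders} (named list of character vectors per vOTU).
#' @export
consensus_host <- function(links, taxonomy = NULL) {
  if (nrow(links) == 0)
    return(list(assignments = data.frame(votu = character(0),
                                         phylum = character(0),
                                         n_links = integer(0),
                                         stringsAsFactors = FALSE),
                host_orders = list()))
  lin <- if ("lineage" %in% names(links)) links$lineage
         else rep(NA_character_, nrow(links))
  if (!is.null(taxonomy)) {
    tax <- setNames(taxonomy$lineage, taxonomy$contig)
    need <- is.na(lin)
    lin[need] <- unname(tax[links$host_contig[need]])
  }
  parsed <- lapply(lin, parse_lineage)
  phyla <- vapply(parsed, `[[`, character(1), "phylum")
  orders <- vapply(parsed, `[[`, character(1), "order")
  bad <- is.na(phyla)
  if (any(bad))
    warning(sprintf("%d link(s) with unresolvable lineage skipped", sum(bad)))
  links <- links[!bad, , drop = FALSE]
  phyla <- phyla[!bad]
  orders <- orders[!bad]
  # set semantics: one vote per distinct (host contig, evidence) pair
  dupkey <- paste(links$votu, links$host_contig, links$evidence, phyla)
  keep <- !duplicated(dupkey)
  links <- links[keep, , drop = FALSE]
  phyla <- phyla[keep]
  orders <- orders[keep]
  votus <- sort(unique(links$votu))
  assign <- vapply(votus, function(v) {
    tab <- table(phyla[links$votu == v])
    if (length(tab) == 0) return(NA_character_)
    # strict majority: more than half of the votes; ties fail this too
    if (max(tab) * 2 <= sum(tab)) return(NA_character_)
    names(tab)[which.max(tab)]
  }, character(1))
  host_orders <- lapply(setNames(votus, votus), function(v) {
    sort(unique(orders[links$votu == v & !is.na(orders)]))
  })
  list(assignments = data.frame(votu = votus, phylum = unname(assign),
                                n_links = as.integer(table(links$votu)[votus]),
                                row.names = NULL, stringsAsFactors = FALSE),
       host_orders = host_orders)
}

#' Within-phylum phage and defence-system diversity and their relationship
#'
#' For each prokaryotic phylum, computes the Shannon diversity of the
#' vOTUs predicted to infect it (abundance-weighted when abundances are
#' supplied, otherwise by counts) and of the defence-system types carried
#' by its contigs, then fits a linear model of defence diversity on phage
#' diversity across phyla.
#'
#' @param votu_host_table data frame: \code{votu}, \code{phylum}, and
#'   optionally \code{abundance}.
#' @param defence_table data frame: \code{phylum}, \code{system} (defence
#'   system type), one row per detected system instance.
#' @return list with \code{diversity} (data frame \code{phylum},
#'   \code{phage_shannon}, \code{defence_shannon}) and \code{fit} (the
#'   \code{\link{depth_diversity_regression}}-style list, or NULL when
#'   fewer than three shared phyla).
#' @export
phylum_diversity_correlation <- function(votu_host_table, defence_table) {
  shared <- intersect(unique(votu_host_table$phylum),
                      unique(defence_table$phylum))
  dropped <- setdiff(union(unique(votu_host_table$phylum),
                           unique(defence_table$phylum)), shared)
  if (length(dropped) > 0)
    message(sprintf("excluding %d phylum(a) present in only one table",
                    length(dropped)))
  rows <- lapply(shared, function(ph) {
    vt <- votu_host_table[votu_host_table$phylum == ph, , drop = FALSE]
    ab <- if ("abundance" %in% names(vt)) {
      tapply(vt$abundance, vt$votu, sum)
    } else table(vt$votu)
    dt <- table(defence_table$system[defence_table$phylum == ph])
    data.frame(phylum = ph,
               phage_shannon = shannon_index(as.numeric(ab)),
               defence_shannon = shannon_index(as.numeric(dt)),
               stringsAsFactors = FALSE)
  })
  div <- do.call(rbind, rows)
  fit <- if (!is.null(div) && nrow(div) >= 3 && sd(div$phage_shannon) > 0)
    depth_diversity_regression(div$phage_shannon, div$defence_shannon)
  else NULL
  list(diversity = div, fit = fit)
}
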