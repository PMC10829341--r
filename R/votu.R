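# Lysogeny marker genes used for the temperate call.  Annotation labels are
# matched case-insensitively against this fixed set.
LYSOGENY_GENES <- c("integrase", "recombinase", "excisionase",
                    "CI/Cro repressor", "parA", "parB")

#' Build a contig table
#'
#' Light constructor/validator for the contig table used throughout the
#' package: one row per contig with its length, viral/provirus flags,
#' gene annotations and optional MAG membership.
#'
#' @param id character contig ids, unique.
#' @param length contig lengths in bp.
#' @param sequence optional nucleotide sequences (uppercased); when present,
#'   lengths must agree.
#' @param is_viral,is_provirus logical flags (default \code{FALSE}).
#' @param annotations list of character vectors of gene labels per contig.
#' @param mag_id optional bin identifier per contig.
#' @return data frame of class \code{"contig_table"}.
#' @export
contig_table <- function(id, length, sequence = NULL, is_viral = FALSE,
                         is_provirus = FALSE, annotations = NULL,
                         mag_id = NA_character_) {
  n <- base::length(id) # the 'length' argument shadows base::length here
  if (anyDuplicated(id)) stop_input("duplicate contig id")
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (any(nchar(sequence) != length))
      stop_input("sequence length disagrees with 'length' field")
  } else sequence <- rep(NA_character_, n)
  is_viral <- rep_len(as.logical(is_viral), n)
  is_provirus <- rep_len(as.logical(is_provirus), n)
  if (any(is_viral & length < 5000))
    stop_input("viral contigs must be >= 5,000 bp (contig floor)")
  if (is.null(annotations)) annotations <- rep(list(character(0)), n)
  df <- data.frame(id = as.character(id), length = as.integer(length),
                   sequence = sequence, is_viral = is_viral,
                   is_provirus = is_provirus,
                   mag_id = rep_len(as.character(mag_id), n),
                   stringsAsFactors = FALSE)
  df$annotations <- annotations
  class(df) <- c("contig_table", class(df))
  df
}

#' Global alignment percent identity between two nucleotide sequences
#'
#' Needleman-Wunsch identity via \code{Biostrings::pairwiseAlignment}
#' (\code{pid} type "PID1": identities over alignment length).  Intended for
#' small synthetic sequences; large-scale clustering should supply a
#' precomputed identity table to \code{\link{cluster_votus}}.
#'
#' @param a,b nucleotide strings.
#' @return identity in [0, 1].
#' @export
align_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

# resolve the identity between a candidate and a representative from either
# a symmetric named matrix/table or a function of two ids/sequences
identity_lookup <- function(identity, contigs) {
  if (is.function(identity)) {
    function(cand, rep) identity(cand, rep)
  } else {
    m <- as.matrix(identity)
    function(cand, rep) {
      if (!(cand %in% rownames(m)) || !(rep %in% colnames(m)))
        stop_input("missing identity value for pair (%s, %s)", cand, rep)
      m[cand, rep]
    }
  }
}

#' Greedy clustering of viral contigs into vOTUs
#'
#' CD-HIT-style greedy incremental clustering: contigs are sorted by length
#' descending (ties broken lexicographically by id) and each contig joins
#' the first existing cluster whose representative it matches at identity
#' >= \code{identity_threshold} with candidate/representative length ratio
#' >= \code{length_ratio}; otherwise it founds a new cluster.  Defaults
#' mirror CD-HIT \code{-c 0.95 -s 0.85}.
#'
#' @param contigs a \code{\link{contig_table}} (all rows flagged viral) or a
#'   data frame with at least \code{id} and \code{length} (and
#'   \code{sequence} when \code{identity} is a function of sequences).
#' @param identity either a symmetric matrix/data frame of pairwise
#'   identities in [0, 1] indexed by contig id, or a function
#'   \code{f(candidate_id, representative_id)} returning the identity.  Use
#'   \code{identity = "align"} to compute identities on the fly from the
#'   \code{sequence} column with \code{\link{align_identity}}.
#' @param identity_threshold minimum identity to join a cluster
#'   (default 0.95).
#' @param length_ratio minimum candidate/representative length ratio
#'   (default 0.85).
#' @return data frame with one row per vOTU: \code{votu} id
#'   (\code{"vOTU_0001"}...), \code{representative} (longest member),
#'   \code{members} (list column), \code{n_members}.
#' @export
cluster_votus <- function(contigs, identity = "align",
                          identity_threshold = 0.95, length_ratio = 0.85) {
  if (!all(c("id", "length") %in% names(contigs)))
    stop_input("contigs need 'id' and 'length' columns")
  if ("is_viral" %in% names(contigs) && !all(contigs$is_viral))
    stop_input("cluster_votus expects viral contigs only")
  ord <- order(-contigs$length, contigs$id)
  ids <- contigs$id[ord]
  lens <- setNames(contigs$length, contigs$id)[ids]
  if (identical(identity, "align")) {
    if (!"sequence" %in% names(contigs) || any(is.na(contigs$sequence)))
      stop_input("identity = \"align\" requires sequences")
    seqs <- setNames(contigs$sequence, contigs$id)
    lookup <- function(cand, rep) align_identity(seqs[[cand]], seqs[[rep]])
  } else lookup <- identity_lookup(identity, contigs)

  reps <- character(0)
  membership <- integer(length(ids))
  names(membership) <- ids
  for (cand in ids) {
    placed <- FALSE
    for (k in seq_along(reps)) {
      if (lens[[cand]] / lens[[reps[k]]] < length_ratio) next
      if (lookup(cand, reps[k]) >= identity_threshold) {
        membership[[cand]] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, cand)
      membership[[cand]] <- length(reps)
    }
  }
  members <- split(names(membership), membership)
  data.frame(
    votu = sprintf("vOTU_%04d", seq_along(reps)),
    representative = reps,
    n_members = lengths(members)[as.character(seq_along(reps))],
    members = I(unname(members[as.character(seq_along(reps))])),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Temperate/lytic lifestyle classification of a vOTU
#'
#' A vOTU is temperate if any member contig is a provirus or carries a
#' lysogeny-specific gene (integrase, recombinase, excisionase, CI/Cro
#' repressor, parA, parB); otherwise it is potentially lytic.
#'
#' @param members character vector of member contig ids.
#' @param contigs a \code{\link{contig_table}} indexed by id, providing
#'   \code{is_provirus} and \code{annotations}.
#' @return \code{"temperate"} or \code{"lytic"}.
#' @export
classify_lifestyle <- function(members, contigs) {
  idx <- match(members, contigs$id)
  if (anyNA(idx)) stop_input("member contig missing from contig table")
  if (any(contigs$is_provirus[idx], na.rm = TRUE)) return("temperate")
  ann <- unlist(contigs$annotations[idx], use.names = FALSE)
  if (length(ann) > 0 &&
      any(tolower(ann) %in% tolower(LYSOGENY_GENES)))
    return("temperate")
  "lytic"
}

#' Novelty tier of a vOTU from reference homology hits
#'
#' A hit qualifies if its alignment covers at least \code{coverage} of
#' either the query or the subject sequence.  Among qualifying hits the
#' maximum percent identity sets the tier: known (> 90\%), similar
#' (50--90\%, inclusive at both bounds), novel otherwise or with no
#' qualifying hit.
#'
#' @param hits data frame of homology hits for one vOTU with columns
#'   \code{percent_identity}, \code{alignment_length}, \code{query_length},
#'   \code{subject_length} (e.g. from \code{\link{read_homology_table}}),
#'   possibly empty.
#' @param coverage minimum fraction of query or subject covered
#'   (default 0.70).
#' @return \code{"known"}, \code{"similar"} or \code{"novel"}.
#' @export
classify_novelty <- function(hits, coverage = 0.70) {
  if (is.null(hits) || nrow(hits) == 0) return("novel")
  qcov <- hits$alignment_length / hits$query_length
  scov <- hits$alignment_length / hits$subject_length
  ok <- (qcov >= coverage) | (scov >= coverage)
  if (!any(ok)) return("novel")
  best <- max(hits$percent_identity[ok])
  if (best > 90) "known" else if (best >= 50) "similar" else "novel"
}

#' Assemble the vOTU catalogue
#'
#' Runs clustering, lifestyle and novelty classification and returns one
#' table with everything downstream stages need.
#'
#' @inheritParams cluster_votus
#' @param hits optional homology-hit table (see
#'   \code{\link{read_homology_table}}) whose \code{query} column holds
#'   member contig or vOTU representative ids.
#' @param family optional named vector of pass-through taxonomic family
#'   labels keyed by representative contig id.
#' @return the \code{\link{cluster_votus}} table with added columns
#'   \code{lifestyle}, \code{novelty} and \code{family}.
#' @export
build_catalog <- function(contigs, identity = "align", hits = NULL,
                          family = NULL, identity_threshold = 0.95,
                          length_ratio = 0.85) {
  viral <- contigs[contigs$is_viral, , drop = FALSE]
  cat <- cluster_votus(viral, identity, identity_threshold, length_ratio)
  cat$lifestyle <- vapply(cat$members, classify_lifestyle, character(1),
                          contigs = contigs)
  cat$novelty <- vapply(seq_len(nrow(cat)), function(i) {
    if (is.null(hits)) return("novel")
    h <- hits[hits$query %in% c(cat$representative[i], cat$members[[i]]), ,
              drop = FALSE]
    classify_novelty(h)
  }, character(1))
  cat$family <- if (is.null(family)) NA_character_
                else unname(family[cat$representative])
  cat
}
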