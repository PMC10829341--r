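#' Read contigs from a FASTA file
#'
#' Wraps \code{Biostrings::readDNAStringSet}: ids must be unique, sequences
#' are uppercased, line wrapping is irrelevant.  Only the first
#' whitespace-delimited token of each header is kept as the id.
#'
#' @param path FASTA file.
#' @return named character vector of uppercased sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop_input("format error: empty FASTA file %s", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop_input("format error: duplicate FASTA id '%s'",
               ids[duplicated(ids)][1])
  setNames(toupper(as.character(seqs)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output file.
#' @param width line-wrap width (default 70).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a 12-column tabular homology table (outfmt-6 dialect)
#'
#' Columns: query, subject, percent identity, alignment length, mismatches,
#' gap opens, query start, query end, subject start, subject end, e-value,
#' bit score.  Lines starting with \code{#} are skipped.  Query/subject
#' lengths, which the 12-column dialect lacks, are joined from
#' \code{lengths}, a named vector of sequence lengths.
#'
#' @param path tab-separated file.
#' @param lengths optional named vector mapping sequence id to length;
#'   adds \code{query_length}/\code{subject_length} columns where known.
#' @return data frame of typed hits.
#' @export
read_homology_table <- function(path, lengths = NULL) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(query = character(0), subject = character(0),
                      percent_identity = numeric(0),
                      alignment_length = integer(0), mismatches = integer(0),
                      gap_opens = integer(0), query_start = integer(0),
                      query_end = integer(0), subject_start = integer(0),
                      subject_end = integer(0), evalue = numeric(0),
                      bit_score = numeric(0), query_length = integer(0),
                      subject_length = integer(0), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 12)
  if (length(bad) > 0)
    stop_input("format error: line %d has %d columns, expected 12",
               lineno[bad[1]], length(fields[[bad[1]]]))
  m <- do.call(rbind, fields)
  out <- data.frame(
    query = m[, 1], subject = m[, 2],
    percent_identity = as.numeric(m[, 3]),
    alignment_length = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    query_start = as.integer(m[, 7]), query_end = as.integer(m[, 8]),
    subject_start = as.integer(m[, 9]), subject_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bit_score = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  if (!is.null(lengths)) {
    out$query_length <- unname(lengths[out$query])
    out$subject_length <- unname(lengths[out$subject])
  }
  out
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}

#' Write a synthetic bundle to a directory
#'
#' Lays out the plain-text input set the pipeline consumes:
#' \code{contigs.fasta}, \code{counts.tsv}, \code{chemistry.csv},
#' \code{sample_meta.tsv}, \code{annotations/*.tsv} and
#' \code{truth/*.tsv}.
#'
#' @param bundle a \code{"synthetic_bundle"} from
#'   \code{\link{generate_community}}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "annotations"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_fasta(setNames(bundle$contigs$sequence, bundle$contigs$id),
              file.path(dir, "contigs.fasta"))
  counts <- data.frame(contig = rownames(bundle$counts), bundle$counts,
                       check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(counts, file.path(dir, "counts.tsv"))
  utils::write.csv(bundle$chemistry, file.path(dir, "chemistry.csv"),
                   row.names = FALSE, quote = FALSE)
  write_tsv(bundle$sample_meta, file.path(dir, "sample_meta.tsv"))
  flags <- bundle$contigs[, c("id", "length", "is_viral", "is_provirus")]
  write_tsv(flags, file.path(dir, "annotations", "contig_flags.tsv"))
  for (nm in names(bundle$annotations)) {
    tab <- bundle$annotations[[nm]]
    if (!is.null(tab))
      write_tsv(tab, file.path(dir, "annotations", paste0(nm, ".tsv")))
  }
  for (nm in names(bundle$truth)) {
    write_tsv(bundle$truth[[nm]],
              file.path(dir, "truth", paste0(nm, ".tsv")))
  }
  invisible(dir)
}

#' Read a bundle directory back into memory
#'
#' Inverse of \code{\link{write_bundle}} for the input tables the pipeline
#' needs (truth tables are read too when present).
#'
#' @param dir a directory written by \code{\link{write_bundle}} or laid
#'   out the same way.
#' @return list with the same shape as a \code{"synthetic_bundle"}
#'   (without \code{config}).
#' @export
read_bundle <- function(dir) {
  seqs <- read_fasta(file.path(dir, "contigs.fasta"))
  counts_df <- read_tsv(file.path(dir, "counts.tsv"), check.names = FALSE)
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df$contig
  flags <- read_tsv(file.path(dir, "annotations", "contig_flags.tsv"))
  ann <- list()
  for (f in list.files(file.path(dir, "annotations"), pattern = "\\.tsv$")) {
    nm <- sub("\\.tsv$", "", f)
    if (nm == "contig_flags") next
    ann[[nm]] <- read_tsv(file.path(dir, "annotations", f))
  }
  lys <- ann$lysogeny
  ann_map <- if (!is.null(lys) && nrow(lys) > 0)
    split(lys$gene, lys$contig) else list()
  contigs <- contig_table(
    id = flags$id, length = flags$length,
    sequence = unname(seqs[flags$id]),
    is_viral = flags$is_viral, is_provirus = flags$is_provirus,
    annotations = lapply(flags$id, function(id)
      as.character(ann_map[[id]] %||% character(0))))
  truth <- list()
  tdir <- file.path(dir, "truth")
  if (dir.exists(tdir)) {
    for (f in list.files(tdir, pattern = "\\.tsv$")) {
      truth[[sub("\\.tsv$", "", f)]] <- read_tsv(file.path(tdir, f))
    }
  }
  structure(list(
    contigs = contigs, counts = counts,
    sample_meta = read_tsv(file.path(dir, "sample_meta.tsv")),
    chemistry = utils::read.csv(file.path(dir, "chemistry.csv"),
                                stringsAsFactors = FALSE),
    annotations = ann, truth = truth), class = "synthetic_bundle")
}
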