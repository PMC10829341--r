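# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# reverse complement for plain character vectors of ACGT strings; plain
# chartr/rev is far cheaper than S4 dispatch at the per-spacer call rate
revcomp <- function(x) {
  vapply(chartr("ACGTacgt", "TGCAtgca", x), function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

# random ACGT string(s); consumes the current RNG stream
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = "")
  }, character(1))
}

# parse a GTDB-style lineage "d__X;p__Y;c__Z;o__W;..." into named ranks
parse_lineage <- function(lineage) {
  ranks <- c(d = "domain", p = "phylum", c = "class", o = "order",
             f = "family", g = "genus")
  out <- setNames(rep(NA_character_, length(ranks)), ranks)
  if (is.na(lineage) || !nzchar(lineage)) return(out)
  parts <- strsplit(lineage, ";", fixed = TRUE)[[1]]
  for (p in parts) {
    p <- trimws(p)
    m <- regmatches(p, regexec("^([dpcofg])__(.*)$", p))[[1]]
    if (length(m) == 3 && nzchar(m[3])) out[ranks[[m[2]]]] <- m[3]
  }
  out
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_input("configuration error: '%s' must be a proportion in [0,1]", name)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != as.integer(x))
    stop_input("configuration error: '%s' must be an integer >= %d", name, min)
  invisible(as.integer(x))
}
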