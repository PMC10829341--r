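#' Default pipeline thresholds
#'
#' Every numeric cutoff used by the pipeline stages, overridable per call:
#' vOTU clustering identity 0.95 with length ratio 0.85, novelty coverage
#' 0.70 and identity tiers 90/50, CRISPR array score 0.4 with spacer spans
#' 20--75 bp at <= 1 edit, correlation screen alpha 0.05 with |r| > 0.8,
#' MCL inflation 1.5, PERMANOVA permutations 999.
#'
#' @return named list of thresholds.
#' @export
pipeline_defaults <- function() {
  list(identity_threshold = 0.95, length_ratio = 0.85,
       novelty_coverage = 0.70,
       spacer_min_len = 20L, spacer_max_len = 75L, spacer_max_edits = 1L,
       crispr_score = 0.4,
       alpha = 0.05, r_threshold = 0.8, inflation = 1.5,
       permutations = 999L)
}

stage_try <- function(stage, manifest_env, expr) {
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  manifest_env$done <- c(manifest_env$done, stage)
  res
}

# identity lookup backed by the generator's precomputed pair table;
# unlisted pairs fall back to the random-sequence background (~0.5)
identity_from_table <- function(tbl, background = 0.5) {
  key <- c(paste(tbl$a, tbl$b), paste(tbl$b, tbl$a))
  val <- c(tbl$identity, tbl$identity)
  map <- setNames(val, key)
  function(cand, rep) {
    v <- map[paste(cand, rep)]
    if (is.na(v)) background else unname(v)
  }
}

#' Run the full virome-ecology pipeline on a bundle
#'
#' Executes catalogue, abundance/stratification, host-linkage, AMG and
#' co-occurrence stages in order and returns a machine-readable summary.
#' With \code{out_dir} set, stage tables (votus.tsv, tpm.tsv,
#' viral_fraction.tsv, diversity.tsv, permanova.tsv, venn.tsv,
#' host_links.tsv, votu_hosts.tsv, phylum_diversity.tsv, orthogroups.tsv,
#' correlations.tsv, cooccurrence.tsv), \code{summary.json}, a
#' \code{cooccurrence_network.tsv} edge list of significant pairs, a
#' \code{MANIFEST} of completed stages and a \code{run.log} recording the
#' seed and every threshold used are written there.  Inputs are never
#' mutated.
#'
#' @param bundle a \code{"synthetic_bundle"} (from
#'   \code{\link{generate_community}} or \code{\link{read_bundle}}).
#' @param out_dir optional output directory.
#' @param seed integer seed for the permutation streams (default 1).
#' @param thresholds named list overriding \code{\link{pipeline_defaults}}
#'   entries.
#' @param hits optional homology-hit table for novelty tiering.
#' @return list with elements \code{catalog}, \code{votu_tpm},
#'   \code{viral_fraction}, \code{diversity}, \code{permanova},
#'   \code{pairwise_permanova}, \code{regression}, \code{venn},
#'   \code{host} (links, assignments, orders), \code{phylum_diversity},
#'   \code{orthogroups}, \code{eligibility}, \code{correlations},
#'   \code{cooccurrence} and \code{summary}.
#' @export
run_pipeline <- function(bundle, out_dir = NULL, seed = 1L,
                         thresholds = list(), hits = NULL) {
  th <- modifyList(pipeline_defaults(), thresholds)
  manifest <- new.env()
  manifest$done <- character(0)
  on.exit({
    if (!is.null(out_dir) && dir.exists(out_dir))
      writeLines(manifest$done, file.path(out_dir, "MANIFEST"))
  }, add = TRUE)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  contigs <- bundle$contigs
  counts <- bundle$counts
  viral <- contigs[contigs$is_viral, , drop = FALSE]

  ## ------------------------------------------------------------ catalog
  cat_res <- stage_try("catalog", manifest, {
    if (nrow(viral) == 0) {
      data.frame(votu = character(0), representative = character(0),
                 n_members = integer(0), members = I(list()),
                 lifestyle = character(0), novelty = character(0),
                 family = character(0), stringsAsFactors = FALSE)
    } else {
      idtbl <- bundle$annotations$identity
      identity <- if (!is.null(idtbl) && nrow(idtbl) >= 0)
        identity_from_table(idtbl) else "align"
      if (is.null(hits)) hits <- bundle$annotations$homology
      build_catalog(contigs, identity = identity, hits = hits,
                    identity_threshold = th$identity_threshold,
                    length_ratio = th$length_ratio)
    }
  })
  contig2votu <- if (nrow(cat_res) > 0)
    setNames(rep(cat_res$votu, lengths(cat_res$members)),
             unlist(cat_res$members)) else character(0)

  ## ---------------------------------------------------------- abundance
  ab <- stage_try("abundance", manifest, {
    tpm <- compute_tpm(counts, setNames(contigs$length, contigs$id))
    vf <- viral_fraction(tpm, viral$id)
    votu_tpm <- if (nrow(cat_res) > 0) {
      t(vapply(seq_len(nrow(cat_res)), function(i)
        colSums(tpm[cat_res$members[[i]], , drop = FALSE]),
        numeric(ncol(tpm))))
    } else matrix(0, 0, ncol(tpm), dimnames = list(NULL, colnames(tpm)))
    rownames(votu_tpm) <- cat_res$votu
    list(tpm = tpm, vf = vf, votu_tpm = votu_tpm)
  })

  ## ----------------------------------------------------------- stratify
  strat <- stage_try("stratify", manifest, {
    meta <- bundle$sample_meta
    shannon <- if (nrow(ab$votu_tpm) > 0 && all(colSums(ab$votu_tpm) > 0))
      apply(ab$votu_tpm, 2, shannon_index) else
        setNames(rep(NA_real_, ncol(counts)), colnames(counts))
    perm <- pw <- reg <- venn <- NULL
    if (nrow(ab$votu_tpm) > 1 && all(colSums(ab$votu_tpm) > 0) &&
        length(unique(meta$cluster)) >= 2) {
      bc <- bray_curtis(ab$votu_tpm)
      perm <- permanova(bc, meta$cluster, n_permutations = th$permutations,
                        seed = seed)
      pw <- pairwise_permanova(bc, meta$cluster,
                               n_permutations = th$permutations, seed = seed)
      clusters <- split(meta$sample, meta$cluster)
      venn <- venn_membership(ab$votu_tpm, clusters)
    }
    if (all(!is.na(shannon)) && sd(meta$depth) > 0)
      reg <- depth_diversity_regression(meta$depth, shannon)
    list(shannon = shannon, permanova = perm, pairwise = pw,
         regression = reg, venn = venn)
  })

  ## ----------------------------------------------------------- hostlink
  host <- stage_try("hostlink", manifest, {
    ann <- bundle$annotations
    votu_seqs <- if (nrow(cat_res) > 0 && !all(is.na(viral$sequence)))
      setNames(contigs$sequence[match(cat_res$representative, contigs$id)],
               cat_res$votu) else character(0)
    sp_hits <- if (!is.null(ann$spacers) && nrow(ann$spacers) > 0 &&
                   length(votu_seqs) > 0)
      match_spacers(ann$spacers, votu_seqs,
                    min_len = th$spacer_min_len, max_len = th$spacer_max_len,
                    score_threshold = th$crispr_score)
    else NULL
    links <- list()
    if (!is.null(sp_hits) && nrow(sp_hits) > 0)
      links$spacer <- data.frame(votu = sp_hits$votu,
                                 host_contig = sp_hits$host_contig,
                                 evidence = "spacer",
                                 stringsAsFactors = FALSE)
    if (!is.null(ann$trnas) && nrow(ann$trnas) > 0) {
      vt <- ann$trnas[ann$trnas$contig %in% viral$id, , drop = FALSE]
      at <- ann$trnas[!(ann$trnas$contig %in% viral$id), , drop = FALSE]
      tl <- match_trnas(vt, at)
      if (nrow(tl) > 0) {
        tl$votu <- unname(contig2votu[tl$votu])
        links$trna <- tl[!is.na(tl$votu), , drop = FALSE]
      }
    }
    if (!is.null(ann$proviruses) && nrow(ann$proviruses) > 0 &&
        !is.null(ann$taxonomy)) {
      pl <- prophage_host(ann$proviruses, ann$taxonomy)
      if (nrow(pl) > 0) {
        pl$votu <- unname(contig2votu[pl$votu])
        links$prophage <- pl[!is.na(pl$votu), , drop = FALSE]
      }
    }
    all_links <- if (length(links) > 0) {
      cols <- c("votu", "host_contig", "evidence")
      do.call(rbind, lapply(links, function(x) x[, cols, drop = FALSE]))
    } else data.frame(votu = character(0), host_contig = character(0),
                      evidence = character(0), stringsAsFactors = FALSE)
    cons <- consensus_host(all_links, bundle$annotations$taxonomy)
    list(links = all_links, spacer_hits = sp_hits,
         assignments = cons$assignments, host_orders = cons$host_orders)
  })

  ## ------------------------------------------------- phylum diversity
  phylum_div <- stage_try("phylum_diversity", manifest, {
    asn <- host$assignments
    def <- bundle$annotations$defence
    tax <- bundle$annotations$taxonomy
    if (is.null(def) || is.null(tax) || nrow(asn) == 0) NULL else {
      assigned <- asn[!is.na(asn$phylum), , drop = FALSE]
      if (nrow(assigned) == 0) NULL else {
        vht <- data.frame(
          votu = assigned$votu, phylum = assigned$phylum,
          abundance = rowMeans(ab$votu_tpm)[assigned$votu],
          stringsAsFactors = FALSE)
        tax_phy <- vapply(tax$lineage,
                          function(l) parse_lineage(l)[["phylum"]],
                          character(1))
        names(tax_phy) <- tax$contig
        dt <- data.frame(phylum = unname(tax_phy[def$contig]),
                         system = def$system, stringsAsFactors = FALSE)
        dt <- dt[!is.na(dt$phylum), , drop = FALSE]
        phylum_diversity_correlation(vht, dt)
      }
    }
  })

  ## ------------------------------------------------------------- amg
  amg <- stage_try("amg", manifest, {
    ann <- bundle$annotations
    if (is.null(ann$amgs) || nrow(ann$amgs) == 0) NULL else {
      amgs <- ann$amgs
      amgs$catalog_votu <- unname(contig2votu[amgs$votu])
      amgs <- amgs[!is.na(amgs$catalog_votu), , drop = FALSE]
      membership <- mcl_cluster(ann$similarity_graph,
                                inflation = th$inflation,
                                nodes = amgs$gene)
      amgs$og <- unname(membership[amgs$gene])
      og_members <- split(amgs[, c("gene", "votu", "catalog_votu")],
                          amgs$og)
      provirus_votus <- unique(contig2votu[
        viral$id[viral$is_provirus]])
      elig <- eligible_ogs(
        lapply(og_members, function(m)
          setNames(m$catalog_votu, m$gene)),
        provirus_votus = provirus_votus,
        votu_host_orders = host$host_orders)
      og_ab <- t(vapply(og_members, function(m)
        og_abundance(unique(m$catalog_votu), ab$votu_tpm),
        numeric(ncol(ab$votu_tpm))))
      chem <- bundle$chemistry[, c("sample", intersect(CHEM_VARS,
                                                       names(bundle$chemistry))),
                               drop = FALSE]
      corr <- pearson_screen(og_ab, chem,
                             alpha = th$alpha,
                             r_threshold = th$r_threshold)
      corr$eligible <- elig$eligible[match(corr$og, elig$og)]
      list(amgs = amgs, orthogroups = og_members, eligibility = elig,
           og_abundance = og_ab, correlations = corr)
    }
  })

  ## ----------------------------------------------------------- cooccur
  cooc <- stage_try("cooccur", manifest, {
    if (is.null(amg)) NULL else {
      amgs <- amg$amgs
      fns <- sort(unique(amgs$func))
      votus <- cat_res$votu
      pres <- matrix(0L, length(fns), length(votus),
                     dimnames = list(fns, votus))
      for (i in seq_len(nrow(amgs)))
        pres[amgs$func[i], amgs$catalog_votu[i]] <- 1L
      if (nrow(pres) >= 2 && ncol(pres) >= 2)
        cooccur_pairs(pres, alpha = th$alpha) else NULL
    }
  })

  ## ----------------------------------------------------------- summary
  lifestyle_frac <- if (nrow(cat_res) > 0)
    as.list(table(cat_res$lifestyle) / nrow(cat_res) * 100) else list()
  novelty_frac <- if (nrow(cat_res) > 0)
    as.list(table(cat_res$novelty) / nrow(cat_res) * 100) else list()
  host_rate <- if (nrow(cat_res) > 0)
    100 * sum(!is.na(host$assignments$phylum)) / nrow(cat_res) else 0
  retained <- if (!is.null(amg))
    amg$correlations[amg$correlations$retained, , drop = FALSE] else NULL
  summary <- list(
    seed = seed, thresholds = th,
    votu_count = nrow(cat_res),
    lifestyle_percent = lifestyle_frac,
    novelty_percent = novelty_frac,
    viral_fraction_percent = as.list(ab$vf),
    viral_fraction_mean = if (length(ab$vf)) mean(ab$vf) else 0,
    host_assignment_rate_percent = host_rate,
    eligible_og_count = if (!is.null(amg)) sum(amg$eligibility$eligible)
      else 0L,
    retained_correlations = if (!is.null(retained) && nrow(retained) > 0)
      retained[, c("og", "variable", "r", "p", "eligible")] else NULL,
    significant_cooccurrences = if (!is.null(cooc))
      sum(cooc$significant) else 0L,
    permanova_p = if (!is.null(strat$permanova))
      strat$permanova$p_value else NA_real_,
    depth_regression = strat$regression[c("slope", "r_squared", "p_value")])

  res <- list(catalog = cat_res, tpm = ab$tpm, votu_tpm = ab$votu_tpm,
              viral_fraction = ab$vf, shannon = strat$shannon,
              permanova = strat$permanova,
              pairwise_permanova = strat$pairwise,
              regression = strat$regression, venn = strat$venn,
              host = host, phylum_diversity = phylum_div,
              amg = amg, cooccurrence = cooc, summary = summary)

  if (!is.null(out_dir)) {
    write_pipeline_outputs(res, bundle, out_dir, th, seed)
    manifest$done <- c(manifest$done, "write")
  }
  res
}

write_pipeline_outputs <- function(res, bundle, out_dir, th, seed) {
  cat_out <- res$catalog
  if (nrow(cat_out) > 0) {
    cat_out$members <- vapply(cat_out$members, paste, character(1),
                              collapse = ",")
  } else cat_out$members <- character(0)
  write_tsv(cat_out, file.path(out_dir, "votus.tsv"))
  write_tsv(data.frame(contig = rownames(res$tpm), res$tpm,
                       check.names = FALSE), file.path(out_dir, "tpm.tsv"))
  write_tsv(data.frame(sample = names(res$viral_fraction),
                       viral_percent = unname(res$viral_fraction)),
            file.path(out_dir, "viral_fraction.tsv"))
  write_tsv(data.frame(sample = names(res$shannon),
                       shannon = unname(res$shannon)),
            file.path(out_dir, "diversity.tsv"))
  if (!is.null(res$pairwise_permanova))
    write_tsv(res$pairwise_permanova, file.path(out_dir, "permanova.tsv"))
  if (!is.null(res$venn))
    write_tsv(res$venn, file.path(out_dir, "venn.tsv"))
  write_tsv(res$host$links, file.path(out_dir, "host_links.tsv"))
  write_tsv(res$host$assignments, file.path(out_dir, "votu_hosts.tsv"))
  if (!is.null(res$phylum_diversity))
    write_tsv(res$phylum_diversity$diversity,
              file.path(out_dir, "phylum_diversity.tsv"))
  if (!is.null(res$amg)) {
    write_tsv(res$amg$amgs[, c("gene", "votu", "catalog_votu", "og",
                               "func", "category")],
              file.path(out_dir, "orthogroups.tsv"))
    write_tsv(res$amg$correlations, file.path(out_dir, "correlations.tsv"))
  }
  if (!is.null(res$cooccurrence)) {
    write_tsv(res$cooccurrence, file.path(out_dir, "cooccurrence.tsv"))
    sig <- res$cooccurrence[res$cooccurrence$significant, , drop = FALSE]
    write_tsv(sig[, c("function_a", "function_b", "observed", "p_gt")],
              file.path(out_dir, "cooccurrence_network.tsv"))
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  log_lines <- c(
    sprintf("viroecol %s", as.character(utils::packageVersion("viroecol"))),
    sprintf("R %s", getRversion()),
    sprintf("seed: %d", seed),
    sprintf("threshold %s: %s", names(th), vapply(th, format, character(1))))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
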