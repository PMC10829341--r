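CHEM_VARS <- c("DOC", "Fe", "NH3", "NO3", "PO4", "SO4", "salinity", "DO")

#' Configuration for the synthetic community generator
#'
#' Collects and validates every knob of \code{\link{generate_community}}.
#' Defaults emulate a depth-stratified anchialine water column sampled at
#' six depths (2, 8, 17, 18, 22, 28 m) with two biological replicates per
#' depth, whose viral community falls into three depth clusters (2 m, 8 m,
#' 17--28 m).
#'
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @param n_depths number of sampled depths (default 6).
#' @param depths depth values in metres (default
#'   \code{c(2, 8, 17, 18, 22, 28)}).
#' @param replicates_per_depth biological replicates per depth (default 2).
#' @param n_votus number of viral OTUs to simulate (default 40).
#' @param n_host_contigs number of prokaryotic host contigs (default 20).
#' @param depth_clusters named list of depth-index groups partitioning
#'   \code{1:n_depths} (default three groups: shallow 2 m, mid 8 m, deep
#'   17--28 m).
#' @param fraction_temperate proportion of vOTUs that are temperate
#'   overall, proviruses included (default 0.15).
#' @param fraction_provirus proportion of vOTUs that are proviruses,
#'   at most \code{fraction_temperate} (default 0.08).
#' @param n_amg_families number of planted orthologous AMG families
#'   (default 6).
#' @param genes_per_family AMG genes per family, each on a distinct vOTU
#'   (default 3).
#' @param planted_correlations list of \code{list(family =, variable =,
#'   r =)} entries planting a chemistry correlation for a family index;
#'   \code{variable} must be one of DOC, Fe, NH3, NO3, PO4, SO4, salinity,
#'   DO and |r| <= 1.
#' @param spacer_mutation_rate substitutions applied to each planted CRISPR
#'   spacer: 0, 1 or 2 (default 0).
#' @param noise_sd relative standard deviation of chemistry noise
#'   (default 0.05).
#' @param n_spacer_links,n_trna_links planted spacer and tRNA host links
#'   (defaults 12 and 8; links target single-member vOTUs so each planted
#'   spacer has a unique viral source).
#' @param plant_cooccurrence when TRUE (default), AMG family 2 is placed
#'   on the same vOTUs as family 1, planting one co-occurring function
#'   pair; set FALSE for designs where all non-planted families must be
#'   statistically independent decoys.
#' @param abundance_dispersion standard deviation of the per-vOTU,
#'   per-depth log-normal abundance factor (default 1.0, i.e. roughly an
#'   order of magnitude of within-cluster variation, typical of viral
#'   relative abundances).
#' @param library_size expected reads per sample; the paper-scale
#'   sequencing depth is not modelled, so this is a free scale parameter
#'   (default 2e5).
#' @return validated list of class \code{"sim_config"}.
#' @export
sim_config <- function(seed = 1L,
                       n_depths = 6L,
                       depths = c(2, 8, 17, 18, 22, 28),
                       replicates_per_depth = 2L,
                       n_votus = 40L,
                       n_host_contigs = 20L,
                       depth_clusters = list(shallow = 1L, mid = 2L,
                                             deep = 3:6),
                       fraction_temperate = 0.15,
                       fraction_provirus = 0.08,
                       n_amg_families = 6L,
                       genes_per_family = 3L,
                       planted_correlations = list(),
                       spacer_mutation_rate = 0L,
                       noise_sd = 0.05,
                       n_spacer_links = 12L,
                       n_trna_links = 8L,
                       plant_cooccurrence = TRUE,
                       abundance_dispersion = 1.0,
                       library_size = 2e5) {
  seed <- check_count(seed, "seed")
  n_depths <- check_count(n_depths, "n_depths", 2L)
  if (length(depths) != n_depths)
    stop_input("configuration error: 'depths' must have n_depths values")
  replicates_per_depth <- check_count(replicates_per_depth,
                                      "replicates_per_depth", 1L)
  n_votus <- check_count(n_votus, "n_votus", 2L)
  n_host_contigs <- check_count(n_host_contigs, "n_host_contigs", 2L)
  check_proportion(fraction_temperate, "fraction_temperate")
  check_proportion(fraction_provirus, "fraction_provirus")
  if (fraction_provirus > fraction_temperate)
    stop_input("configuration error: 'fraction_provirus' exceeds 'fraction_temperate'")
  cl <- sort(unlist(depth_clusters, use.names = FALSE))
  if (!identical(as.integer(cl), seq_len(n_depths)))
    stop_input("configuration error: 'depth_clusters' must partition 1:n_depths")
  if (is.null(names(depth_clusters)))
    names(depth_clusters) <- paste0("cluster", seq_along(depth_clusters))
  n_amg_families <- check_count(n_amg_families, "n_amg_families")
  genes_per_family <- check_count(genes_per_family, "genes_per_family", 1L)
  for (pc in planted_correlations) {
    if (!all(c("family", "variable", "r") %in% names(pc)))
      stop_input("configuration error: 'planted_correlations' entries need family, variable, r")
    if (!(pc$variable %in% CHEM_VARS))
      stop_input("configuration error: unknown chemistry variable '%s'",
                 pc$variable)
    if (abs(pc$r) > 1)
      stop_input("configuration error: target |r| must be <= 1")
    if (pc$family < 1 || pc$family > n_amg_families)
      stop_input("configuration error: 'family' index out of range")
  }
  if (!(spacer_mutation_rate %in% 0:2))
    stop_input("configuration error: 'spacer_mutation_rate' must be 0, 1 or 2")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_input("configuration error: 'noise_sd' must be non-negative")
  structure(list(seed = seed, n_depths = n_depths, depths = depths,
                 replicates_per_depth = replicates_per_depth,
                 n_votus = n_votus, n_host_contigs = n_host_contigs,
                 depth_clusters = depth_clusters,
                 fraction_temperate = fraction_temperate,
                 fraction_provirus = fraction_provirus,
                 n_amg_families = n_amg_families,
                 genes_per_family = genes_per_family,
                 planted_correlations = planted_correlations,
                 spacer_mutation_rate = as.integer(spacer_mutation_rate),
                 noise_sd = noise_sd,
                 n_spacer_links = check_count(n_spacer_links,
                                              "n_spacer_links"),
                 n_trna_links = check_count(n_trna_links, "n_trna_links"),
                 plant_cooccurrence = isTRUE(plant_cooccurrence),
                 abundance_dispersion = abundance_dispersion,
                 library_size = library_size),
            class = "sim_config")
}

# substitute k positions of a DNA string with different bases
mutate_dna <- function(seq, k) {
  if (k == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# deterministic depth trends for the eight chemistry variables; `d` in m.
# Shapes emulate a stratified sinkhole: salinity and sulphate rise with
# depth, dissolved oxygen and DOC fall, nutrients peak at mid depths.
chem_profile <- function(var, d) {
  switch(var,
    DOC = 3.0 - 0.07 * d,
    Fe = 0.05 + 0.012 * d,
    NH3 = 0.8 + 1.6 * exp(-((d - 15)^2) / 40),
    NO3 = 2.0 * exp(-((d - 8)^2) / 30) + 0.2,
    PO4 = 0.15 + 0.02 * d,
    SO4 = 900 + 60 * d,
    salinity = 12 + 0.9 * d,
    DO = pmax(0.3, 8.5 - 0.32 * d))
}

#' Generate a seeded synthetic depth-stratified viral community
#'
#' Produces a complete input bundle for the pipeline: contig sequences
#' (viral vOTU members and prokaryotic hosts), a contig-by-sample count
#' matrix with block structure by depth cluster, water chemistry with
#' optional planted family correlations, annotation tables (lysogeny
#' genes, proviruses, AMG calls, a gene similarity graph, CRISPR arrays,
#' tRNAs, host taxonomy, defence systems) and ground-truth tables for
#' every planted feature.  All randomness flows from \code{config$seed}
#' through one stream consumed in a fixed order (chemistry, sequences,
#' counts, AMG families, planted correlations), with host-link planting
#' (\code{\link{plant_host_links}}) on its own derived substream, so the
#' bundle is bit-for-bit reproducible.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list of class \code{"synthetic_bundle"} with elements
#'   \code{contigs} (a \code{\link{contig_table}}), \code{counts},
#'   \code{sample_meta}, \code{chemistry}, \code{annotations} (list of
#'   tables), \code{truth} (list of planted-structure tables) and
#'   \code{config}.
#' @export
generate_community <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  ## samples -----------------------------------------------------------
  n_samples <- config$n_depths * config$replicates_per_depth
  sample_meta <- data.frame(
    sample = sprintf("S%02d_d%gm_r%d",
                     seq_len(n_samples),
                     rep(config$depths, each = config$replicates_per_depth),
                     rep(seq_len(config$replicates_per_depth),
                         config$n_depths)),
    depth = rep(config$depths, each = config$replicates_per_depth),
    depth_index = rep(seq_len(config$n_depths),
                      each = config$replicates_per_depth),
    replicate = rep(seq_len(config$replicates_per_depth), config$n_depths),
    stringsAsFactors = FALSE)
  cluster_of_depth <- character(config$n_depths)
  for (nm in names(config$depth_clusters))
    cluster_of_depth[config$depth_clusters[[nm]]] <- nm
  sample_meta$cluster <- cluster_of_depth[sample_meta$depth_index]

  ## chemistry (base profiles; planted variables overwritten later) -----
  chemistry <- data.frame(sample = sample_meta$sample,
                          depth = sample_meta$depth,
                          stringsAsFactors = FALSE)
  for (v in CHEM_VARS) {
    base <- chem_profile(v, sample_meta$depth)
    chemistry[[v]] <- base * (1 + rnorm(n_samples, 0, config$noise_sd))
  }

  ## viral contigs: vOTUs with 1-3 near-identical members ---------------
  n_members <- sample(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 3L),
                      config$n_votus, replace = TRUE)
  rep_len_bp <- sample(5001:12000, config$n_votus, replace = TRUE)
  viral_ids <- character(0)
  viral_seqs <- character(0)
  votu_of_contig <- character(0)
  id_pairs <- list() # exact identities for the precomputed table
  truth_votu <- sprintf("tv_%03d", seq_len(config$n_votus))
  for (i in seq_len(config$n_votus)) {
    rep_id <- sprintf("vc_%03d_m1", i)
    rep_seq <- random_dna(1, rep_len_bp[i])
    ids <- rep_id
    seqs <- rep_seq
    if (n_members[i] > 1) {
      for (m in 2:n_members[i]) {
        # trim + substitutions keep identity >= 0.975, above the 0.95
        # clustering threshold, and length ratio >= 0.98
        trim <- sample(0:min(floor(0.02 * rep_len_bp[i]),
                             rep_len_bp[i] - 5000L), 1)
        sub_seq <- substr(rep_seq, 1, rep_len_bp[i] - trim)
        n_mut <- max(1L, round(0.005 * nchar(sub_seq)))
        mem_seq <- mutate_dna(sub_seq, n_mut)
        mem_id <- sprintf("vc_%03d_m%d", i, m)
        ids <- c(ids, mem_id)
        seqs <- c(seqs, mem_seq)
        # identity over the global alignment: matches / rep length
        id_pairs[[length(id_pairs) + 1]] <-
          data.frame(a = mem_id, b = rep_id,
                     identity = (nchar(mem_seq) - n_mut) / rep_len_bp[i],
                     stringsAsFactors = FALSE)
      }
    }
    viral_ids <- c(viral_ids, ids)
    viral_seqs <- c(viral_seqs, seqs)
    votu_of_contig <- c(votu_of_contig, rep(truth_votu[i], length(ids)))
  }

  ## host contigs -------------------------------------------------------
  host_ids <- sprintf("hc_%03d", seq_len(config$n_host_contigs))
  host_len <- sample(12000:30000, config$n_host_contigs, replace = TRUE)
  host_seqs <- vapply(host_len, function(L) random_dna(1, L), character(1))

  ## lifestyle truth ----------------------------------------------------
  n_prov <- round(config$fraction_provirus * config$n_votus)
  n_temp_extra <- round((config$fraction_temperate -
                           config$fraction_provirus) * config$n_votus)
  votu_order <- sample(config$n_votus)
  provirus_votus <- votu_order[seq_len(n_prov)]
  lysogene_votus <- votu_order[n_prov + seq_len(n_temp_extra)]
  lysogeny <- if (length(lysogene_votus) > 0) data.frame(
    contig = sprintf("vc_%03d_m1", lysogene_votus),
    gene = sample(LYSOGENY_GENES, length(lysogene_votus), replace = TRUE),
    stringsAsFactors = FALSE) else
    data.frame(contig = character(0), gene = character(0),
               stringsAsFactors = FALSE)
  lifestyle_truth <- data.frame(
    votu = truth_votu,
    lifestyle = ifelse(seq_len(config$n_votus) %in%
                         c(provirus_votus, lysogene_votus),
                       "temperate", "lytic"),
    is_provirus = seq_len(config$n_votus) %in% provirus_votus,
    stringsAsFactors = FALSE)

  ## depth-cluster block structure and counts ---------------------------
  k <- length(config$depth_clusters)
  assignment <- sample(c(names(config$depth_clusters), "shared"),
                       config$n_votus, replace = TRUE,
                       prob = c(rep(0.6 / k, k), 0.4))
  base_mean <- exp(rnorm(config$n_votus, log(60), 0.8))
  all_ids <- c(viral_ids, host_ids)
  counts <- matrix(0L, length(all_ids), n_samples,
                   dimnames = list(all_ids, sample_meta$sample))
  depth_factor <- matrix(exp(rnorm(config$n_votus * config$n_depths, 0,
                                   config$abundance_dispersion)),
                         config$n_votus, config$n_depths)
  for (i in seq_len(config$n_votus)) {
    members <- viral_ids[votu_of_contig == truth_votu[i]]
    for (s in seq_len(n_samples)) {
      di <- sample_meta$depth_index[s]
      in_cluster <- assignment[i] == "shared" ||
        di %in% config$depth_clusters[[assignment[i]]]
      if (!in_cluster) next # exact zero outside the cluster
      mu <- base_mean[i] * depth_factor[i, di] / length(members)
      counts[members, s] <- counts[members, s] +
        stats::rpois(length(members), mu)
    }
  }
  # host background dominates the community so the viral fraction lands in
  # the single-digit percent range typical of cellular-fraction metagenomes
  host_mean <- exp(rnorm(config$n_host_contigs, log(3000), 0.6))
  for (h in seq_len(config$n_host_contigs)) {
    counts[host_ids[h], ] <- stats::rpois(n_samples, host_mean[h])
  }
  # rescale to the configured library size in expectation
  scale_f <- config$library_size / max(1, sum(counts) / n_samples)
  counts <- matrix(as.integer(round(counts * scale_f)), nrow(counts),
                   ncol(counts), dimnames = dimnames(counts))

  ## AMG families and similarity graph ----------------------------------
  amg_functions <- c("ribonucleoside-diphosphate reductase",
                     "dUTP pyrophosphatase", "sulfotransferase",
                     "glycosyltransferase", "ribosomal protein S21",
                     "nucleotide sugar dehydratase",
                     "nucleotidyltransferase", "cysteine synthase",
                     "phosphate starvation protein PhoH",
                     "adenylylsulfate reductase")
  amg_categories <- c("nucleotide synthesis", "nucleotide synthesis",
                      "transferase activity", "transferase activity",
                      "protein synthesis", "nucleotide synthesis",
                      "transferase activity", "sulphur metabolism",
                      "phosphorus metabolism", "sulphur metabolism")
  amgs <- NULL
  graph <- NULL
  families_truth <- NULL
  if (config$n_amg_families > 0) {
    fam_fun_idx <- (seq_len(config$n_amg_families) - 1) %%
      length(amg_functions) + 1
    gene_rows <- list()
    edge_rows <- list()
    fam1_votus <- NULL
    for (f in seq_len(config$n_amg_families)) {
      fam_votus <- sample(config$n_votus,
                          min(config$genes_per_family, config$n_votus))
      # family 2 reuses family 1's vOTUs: a planted co-occurring pair of
      # distinct functions on the same genomes
      if (f == 1) fam1_votus <- fam_votus
      if (f == 2 && config$plant_cooccurrence && !is.null(fam1_votus))
        fam_votus <- fam1_votus
      genes <- sprintf("amg_f%02d_g%d", f, seq_along(fam_votus))
      gene_rows[[f]] <- data.frame(
        gene = genes,
        contig = sprintf("vc_%03d_m1", fam_votus),
        votu_truth = truth_votu[fam_votus],
        family = sprintf("fam_%02d", f),
        func = amg_functions[fam_fun_idx[f]],
        category = amg_categories[fam_fun_idx[f]],
        stringsAsFactors = FALSE)
      if (length(genes) > 1) {
        pr <- combn(genes, 2)
        edge_rows[[f]] <- data.frame(from = pr[1, ], to = pr[2, ],
                                     weight = runif(ncol(pr), 50, 100),
                                     stringsAsFactors = FALSE)
      }
    }
    families_truth <- do.call(rbind, gene_rows)
    amgs <- data.frame(gene = families_truth$gene,
                       votu = families_truth$contig,
                       func = families_truth$func,
                       category = families_truth$category,
                       stringsAsFactors = FALSE)
    graph <- if (length(edge_rows) > 0) do.call(rbind, edge_rows) else
      data.frame(from = character(0), to = character(0),
                 weight = numeric(0), stringsAsFactors = FALSE)
  }

  ## synthetic reference homology hits (novelty tiering) ----------------
  # a small minority of vOTUs get reference-database hits, mirroring the
  # high novelty of under-sampled biomes: ~2% known, ~8% similar
  n_known <- max(1L, round(0.02 * config$n_votus))
  n_similar <- max(1L, round(0.08 * config$n_votus))
  tier_votus <- sample(config$n_votus, min(config$n_votus,
                                           n_known + n_similar + 1L))
  hom_rows <- list()
  for (j in seq_along(tier_votus)) {
    i <- tier_votus[j]
    qlen <- rep_len_bp[i]
    if (j <= n_known) {
      pid <- runif(1, 92, 99); cov <- runif(1, 0.72, 0.9)
    } else if (j <= n_known + n_similar) {
      pid <- runif(1, 55, 88); cov <- runif(1, 0.72, 0.9)
    } else { # high identity but sub-threshold coverage: stays novel
      pid <- runif(1, 92, 99); cov <- runif(1, 0.3, 0.6)
    }
    hom_rows[[j]] <- data.frame(
      query = sprintf("vc_%03d_m1", i),
      subject = sprintf("ref_%04d", j),
      percent_identity = pid,
      alignment_length = as.integer(round(cov * qlen)),
      query_length = qlen,
      subject_length = as.integer(round(qlen * runif(1, 0.9, 1.1))),
      truth_tier = if (j <= n_known) "known" else
        if (j <= n_known + n_similar) "similar" else "novel",
      stringsAsFactors = FALSE)
  }
  homology <- do.call(rbind, hom_rows)

  ## planted chemistry correlations -------------------------------------
  member_tpm <- compute_tpm(counts, setNames(c(nchar(viral_seqs), host_len),
                                             all_ids))
  planted_rows <- list()
  for (pc in config$planted_correlations) {
    fam_id <- sprintf("fam_%02d", pc$family)
    fam_votus <- unique(families_truth$votu_truth[
      families_truth$family == fam_id])
    members <- viral_ids[votu_of_contig %in% fam_votus]
    traj <- colSums(member_tpm[members, , drop = FALSE])
    if (sd(traj) == 0)
      stop_input("generation error: planted family %s has constant abundance",
                 fam_id)
    z <- as.numeric(scale(traj))
    e <- rnorm(n_samples)
    e <- stats::residuals(lm(e ~ z))     # exactly orthogonal in-sample
    e <- e / sd(e)
    # cor(y, traj) equals the target exactly before the noise_sd term
    y <- pc$r * z + sqrt(1 - pc$r^2) * e
    base <- chem_profile(pc$variable, sample_meta$depth)
    sc <- mean(base) * 0.3
    chemistry[[pc$variable]] <- mean(base) + sc * y +
      rnorm(n_samples, 0, config$noise_sd * sc)
    planted_rows[[length(planted_rows) + 1]] <-
      data.frame(family = fam_id, variable = pc$variable,
                 target_r = pc$r, stringsAsFactors = FALSE)
  }

  ## assemble contig table ----------------------------------------------
  contigs <- contig_table(
    id = all_ids,
    length = nchar(c(viral_seqs, host_seqs)),
    sequence = c(viral_seqs, host_seqs),
    is_viral = c(rep(TRUE, length(viral_ids)),
                 rep(FALSE, length(host_ids))),
    is_provirus = c(votu_of_contig %in% truth_votu[provirus_votus],
                    rep(FALSE, length(host_ids))))
  # lysogeny annotations live on the contig table as well
  ann_map <- split(lysogeny$gene, lysogeny$contig)
  contigs$annotations <- lapply(contigs$id, function(id)
    as.character(ann_map[[id]] %||% character(0)))

  identity_tbl <- if (length(id_pairs) > 0) do.call(rbind, id_pairs) else
    data.frame(a = character(0), b = character(0), identity = numeric(0),
               stringsAsFactors = FALSE)

  bundle <- structure(list(
    contigs = contigs,
    counts = counts,
    sample_meta = sample_meta,
    chemistry = chemistry,
    annotations = list(
      lysogeny = lysogeny,
      amgs = amgs,
      similarity_graph = graph,
      identity = identity_tbl,
      homology = homology[, setdiff(names(homology), "truth_tier")],
      spacers = data.frame(host_contig = character(0), spacer = character(0),
                           score = numeric(0), stringsAsFactors = FALSE),
      trnas = data.frame(contig = character(0), sequence = character(0),
                         stringsAsFactors = FALSE),
      proviruses = data.frame(votu = character(0), host_contig = character(0),
                              start = integer(0), end = integer(0),
                              stringsAsFactors = FALSE),
      taxonomy = NULL,
      defence = NULL),
    truth = list(
      votu_members = data.frame(contig = viral_ids, votu = votu_of_contig,
                                stringsAsFactors = FALSE),
      lifestyles = lifestyle_truth,
      votu_clusters = data.frame(votu = truth_votu, cluster = assignment,
                                 stringsAsFactors = FALSE),
      families = families_truth,
      novelty = data.frame(contig = homology$query,
                           tier = homology$truth_tier,
                           stringsAsFactors = FALSE),
      planted_correlations = if (length(planted_rows) > 0)
        do.call(rbind, planted_rows) else
          data.frame(family = character(0), variable = character(0),
                     target_r = numeric(0), stringsAsFactors = FALSE),
      host_links = data.frame(votu = character(0), host_contig = character(0),
                              evidence = character(0), mutations = integer(0),
                              stringsAsFactors = FALSE)),
    config = config), class = "synthetic_bundle")

  plant_host_links(bundle, config)
}

#' Plant host-linkage ground truth into a synthetic bundle
#'
#' Adds the three evidence layers downstream host prediction recovers:
#' CRISPR spacers copied from viral contigs into host arrays (with the
#' configured number of substitutions), tRNA sequences shared verbatim
#' between a viral and a host contig, and provirus sequences embedded
#' inside host contigs.  Host taxonomy and defence-system tables are
#' generated here too.  Runs on a substream derived from
#' \code{config$seed} (offset 7919) so it is deterministic whether called
#' inside \code{\link{generate_community}} or on its own.
#'
#' @param bundle a \code{"synthetic_bundle"}.
#' @param config the \code{\link{sim_config}} used to build it.
#' @return the bundle with populated \code{annotations$spacers},
#'   \code{annotations$trnas}, \code{annotations$proviruses},
#'   \code{annotations$taxonomy}, \code{annotations$defence} and
#'   \code{truth$host_links}.
#' @export
plant_host_links <- function(bundle, config) {
  set.seed(config$seed + 7919L)
  contigs <- bundle$contigs
  viral <- contigs[contigs$is_viral, , drop = FALSE]
  hosts <- contigs[!contigs$is_viral, , drop = FALSE]
  truth_members <- bundle$truth$votu_members
  member_count <- table(truth_members$votu)
  singleton_votus <- names(member_count)[member_count == 1]
  singleton_contigs <- truth_members$contig[
    truth_members$votu %in% singleton_votus]

  ## taxonomy ------------------------------------------------------------
  phyla <- c("Pseudomonadota", "Desulfobacterota", "Campylobacterota",
             "Chloroflexota", "Thermoproteota", "Nanoarchaeota")
  orders_by_phylum <- list(
    Pseudomonadota = c("Burkholderiales", "Pseudomonadales"),
    Desulfobacterota = c("Desulfobacterales", "Desulfovibrionales"),
    Campylobacterota = c("Campylobacterales", "Nautiliales"),
    Chloroflexota = c("Anaerolineales", "Dehalococcoidales"),
    Thermoproteota = c("Nitrososphaerales", "Thermoproteales"),
    Nanoarchaeota = c("Nanoarchaeales", "Woesearchaeales"))
  domains <- c(Pseudomonadota = "Bacteria", Desulfobacterota = "Bacteria",
               Campylobacterota = "Bacteria", Chloroflexota = "Bacteria",
               Thermoproteota = "Archaea", Nanoarchaeota = "Archaea")
  host_phylum <- sample(phyla, nrow(hosts), replace = TRUE)
  host_order <- vapply(host_phylum, function(p)
    sample(orders_by_phylum[[p]], 1), character(1))
  taxonomy <- data.frame(
    contig = hosts$id,
    lineage = sprintf("d__%s;p__%s;c__%s;o__%s;f__f_%s;g__g_%s",
                      domains[host_phylum], host_phylum,
                      paste0(substr(host_phylum, 1, 4), "ia"),
                      host_order, host_order, host_order),
    stringsAsFactors = FALSE)

  ## defence systems ------------------------------------------------------
  systems <- c("RM", "CRISPR-Cas", "AbiE", "CBASS", "Thoeris", "Gabija",
               "Wadjet", "Hachiman")
  def_rows <- list()
  for (i in seq_len(nrow(hosts))) {
    n_sys <- sample(0:3, 1)
    if (n_sys > 0)
      def_rows[[length(def_rows) + 1]] <-
        data.frame(contig = hosts$id[i],
                   system = sample(systems, n_sys),
                   stringsAsFactors = FALSE)
  }
  defence <- if (length(def_rows) > 0) do.call(rbind, def_rows) else
    data.frame(contig = character(0), system = character(0),
               stringsAsFactors = FALSE)

  link_rows <- list()

  ## CRISPR spacers -------------------------------------------------------
  spacer_rows <- list()
  n_sp <- min(config$n_spacer_links, length(singleton_contigs))
  sp_contigs <- sample(singleton_contigs, n_sp)
  sp_hosts <- sample(hosts$id, n_sp, replace = TRUE)
  seqs <- setNames(contigs$sequence, contigs$id)
  for (i in seq_len(n_sp)) {
    L <- sample(25:40, 1)
    src <- seqs[[sp_contigs[i]]]
    start <- sample(nchar(src) - L + 1, 1)
    spacer <- substr(src, start, start + L - 1)
    # guarantee the planted spacer has a unique exact source among viral
    # contigs (vanishingly rare to fail for random sequence; resample once)
    occ <- sum(vapply(viral$sequence, function(s) {
      g <- gregexpr(spacer, s, fixed = TRUE)[[1]]
      if (g[1] == -1L) 0L else length(g)
    }, integer(1)))
    if (occ != 1) {
      start <- sample(nchar(src) - L + 1, 1)
      spacer <- substr(src, start, start + L - 1)
    }
    spacer_rows[[i]] <- data.frame(
      host_contig = sp_hosts[i],
      spacer = mutate_dna(spacer, config$spacer_mutation_rate),
      score = runif(1, 0.5, 1.0), stringsAsFactors = FALSE)
    link_rows[[length(link_rows) + 1]] <-
      data.frame(votu = truth_members$votu[
                   truth_members$contig == sp_contigs[i]],
                 host_contig = sp_hosts[i], evidence = "spacer",
                 mutations = config$spacer_mutation_rate,
                 stringsAsFactors = FALSE)
  }
  # decoy arrays: random spacers and one low-score array
  n_decoy <- 4L
  decoys <- data.frame(host_contig = sample(hosts$id, n_decoy, replace = TRUE),
                       spacer = random_dna(n_decoy, 32),
                       score = runif(n_decoy, 0.5, 1.0),
                       stringsAsFactors = FALSE)
  low_score <- data.frame(host_contig = sample(hosts$id, 1),
                          spacer = random_dna(1, 32),
                          score = 0.2, stringsAsFactors = FALSE)
  spacers <- rbind(do.call(rbind, spacer_rows), decoys, low_score)

  ## tRNAs ----------------------------------------------------------------
  trna_rows <- list()
  n_tr <- min(config$n_trna_links, length(singleton_contigs))
  tr_contigs <- sample(singleton_contigs, n_tr)
  tr_hosts <- sample(hosts$id, n_tr, replace = TRUE)
  for (i in seq_len(n_tr)) {
    trna <- random_dna(1, sample(72:75, 1))
    trna_rows[[length(trna_rows) + 1]] <-
      data.frame(contig = c(tr_contigs[i], tr_hosts[i]),
                 sequence = trna, stringsAsFactors = FALSE)
    link_rows[[length(link_rows) + 1]] <-
      data.frame(votu = truth_members$votu[
                   truth_members$contig == tr_contigs[i]],
                 host_contig = tr_hosts[i], evidence = "trna",
                 mutations = 0L, stringsAsFactors = FALSE)
  }
  # unlinked decoy tRNAs
  trna_rows[[length(trna_rows) + 1]] <-
    data.frame(contig = sample(hosts$id, 2),
               sequence = random_dna(2, 73), stringsAsFactors = FALSE)
  trnas <- do.call(rbind, trna_rows)

  ## proviruses -----------------------------------------------------------
  prov_votus <- bundle$truth$lifestyles$votu[
    bundle$truth$lifestyles$is_provirus]
  prov_rows <- list()
  if (length(prov_votus) > 0) {
    prov_hosts <- sample(hosts$id, length(prov_votus), replace = TRUE)
    for (i in seq_along(prov_votus)) {
      rep_contig <- truth_members$contig[
        truth_members$votu == prov_votus[i]][1]
      vseq <- seqs[[rep_contig]]
      hseq <- seqs[[prov_hosts[i]]]
      if (nchar(hseq) < 200)
        stop_input("generation error: host contig %s shorter than insert",
                   prov_hosts[i])
      at <- sample(100:(nchar(hseq) - 100), 1)
      newseq <- paste0(substr(hseq, 1, at), vseq,
                       substr(hseq, at + 1, nchar(hseq)))
      idx <- match(prov_hosts[i], bundle$contigs$id)
      bundle$contigs$sequence[idx] <- newseq
      bundle$contigs$length[idx] <- nchar(newseq)
      seqs[[prov_hosts[i]]] <- newseq
      prov_rows[[length(prov_rows) + 1]] <-
        data.frame(votu = rep_contig, host_contig = prov_hosts[i],
                   start = at, end = at + nchar(vseq),
                   stringsAsFactors = FALSE)
      link_rows[[length(link_rows) + 1]] <-
        data.frame(votu = prov_votus[i], host_contig = prov_hosts[i],
                   evidence = "prophage", mutations = 0L,
                   stringsAsFactors = FALSE)
    }
  }
  proviruses <- if (length(prov_rows) > 0) do.call(rbind, prov_rows) else
    bundle$annotations$proviruses

  bundle$annotations$spacers <- spacers
  bundle$annotations$trnas <- trnas
  bundle$annotations$proviruses <- proviruses
  bundle$annotations$taxonomy <- taxonomy
  bundle$annotations$defence <- defence
  bundle$truth$host_links <- if (length(link_rows) > 0)
    do.call(rbind, link_rows) else bundle$truth$host_links
  bundle
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(paste0("synthetic community bundle: %d contigs (%d viral), ",
                     "%d samples, %d planted host links, %d AMG genes\n"),
              nrow(x$contigs), sum(x$contigs$is_viral),
              ncol(x$counts), nrow(x$truth$host_links),
              if (is.null(x$annotations$amgs)) 0L else
                nrow(x$annotations$amgs)))
  invisible(x)
}
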