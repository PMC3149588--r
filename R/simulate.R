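# Seeded synthetic-data generators. They produce every input the pipeline
# consumes -- gene universe, antigen test sets, annotation catalogs, count
# features, protein sequences, organism x domain tables, BLAST hit tables --
# with planted effects and a ground-truth record, so every stage of the
# analysis has a recoverable signal. One master seed feeds independent named
# substreams, so adding a generator never perturbs existing outputs.

# Deterministic substream seed below 2^31, order-sensitive in the name.
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147480009
  as.integer((as.double(seed) * 7919 + h) %% 2147483629 + 1)
}

#' Configuration for the synthetic corpus
#'
#' Defaults emulate the motivating study design: six antigen test sets with
#' the published set sizes, a ~25000-gene universe with right-skewed
#' (log-normal) mean exon lengths whose mean falls in the published
#' 3800-6300 nt range, sparse binary annotations over four namespaces,
#' count features proportional to exon length, ELR-bearing protein
#' sequences, completely sequenced organisms in the published per-kingdom
#' counts (447 Bacteria, 39 Archaea, 82 Eukaryota), two domain schemes, and
#' per-organism BLAST hit lists.
#'
#' @param seed Master seed (integer).
#' @param n_genes Universe size.
#' @param test_set_sizes Named integer vector: one antigen test set per entry.
#' @param exon_length_log_mean,exon_length_log_sd Log-normal parameters for
#'   mean exon length (nucleotides).
#' @param exon_shift_per_set Additive shift on the log-mean for the genes of
#'   each test set (recycled); the planted "antigens have longer exons" effect.
#' @param namespaces Annotation namespace labels.
#' @param n_categories_per_namespace Categories per namespace.
#' @param base_annotation_prob Per-gene, per-category annotation probability.
#' @param planted_categories Data frame `set_index`, `namespace`,
#'   `category_index`, `test_prob`: categories whose annotation probability
#'   is raised to `test_prob` for the genes of the designated test set.
#' @param count_feature_rates Named vector: expected counts per kilobase of
#'   mean exon length for each count feature (SNPs, somatic mutations).
#' @param count_shift_per_set Multiplicative rate shift for test-set genes
#'   (recycled over sets).
#' @param feature_missing_prob Probability a gene is absent from a feature
#'   table (databases do not cover every gene).
#' @param seq_length Protein sequence length (residues).
#' @param motif_rate_test,motif_rate_ref Probability of carrying the planted
#'   motif for test-set genes and for all other genes.
#' @param motif Motif to plant, default `"ELR"`.
#' @param n_organisms_per_kingdom Named vector (BACTERIA, ARCHAEA, EUKARYOTA).
#' @param p_incomplete_org Probability an organism lacks the complete-genome flag.
#' @param schemes Domain classification schemes.
#' @param n_domains_per_scheme Domains per scheme.
#' @param domain_universality_prob Probability a domain is universal within a
#'   kingdom.
#' @param p_universal_in_org,p_background_in_org Presence probability of a
#'   domain in an organism of a kingdom where it is / is not universal.
#' @param universal_gene_prob_test,universal_gene_prob_ref Probability a
#'   test-set / other gene carries an ancient ("core-universal") domain.
#' @param background_hit_prob Baseline probability a gene is BLAST-similar to
#'   a given organism.
#' @param mimicry_plants Data frame `organism_index`, `test_prob`, `ref_prob`:
#'   organisms with elevated similarity probabilities (index into the
#'   generated organism list; defaults pick the first three eukaryotes).
#' @param n_decoy_hits Below-threshold BLAST rows added per organism to
#'   exercise the score/E-value filters.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 25000L,
                       test_set_sizes = c(cidb_serex_ag = 1471L,
                                          exp_serex_hag = 85L,
                                          exp_serex_tag = 74L,
                                          exp_chip_ag = 298L,
                                          phage_display_tag = 84L,
                                          lit_aag = 348L),
                       exon_length_log_mean = 8.0,
                       exon_length_log_sd = 0.6,
                       exon_shift_per_set = 0.3,
                       namespaces = c("go", "kegg", "location", "domain"),
                       n_categories_per_namespace = 100L,
                       base_annotation_prob = 0.05,
                       planted_categories = data.frame(
                         set_index = 1L, namespace = namespaces,
                         category_index = 1L, test_prob = 0.3,
                         stringsAsFactors = FALSE),
                       count_feature_rates = c(snp_synonymous = 2,
                                               snp_nonsynonymous = 1,
                                               somatic_mutation_count = 0.5),
                       count_shift_per_set = 1.3,
                       feature_missing_prob = 0.1,
                       seq_length = 300L,
                       motif_rate_test = 0.35,
                       motif_rate_ref = 0.15,
                       motif = "ELR",
                       n_organisms_per_kingdom = c(BACTERIA = 447L,
                                                   ARCHAEA = 39L,
                                                   EUKARYOTA = 82L),
                       p_incomplete_org = 0.05,
                       schemes = c("CATH", "PFAM"),
                       n_domains_per_scheme = 600L,
                       domain_universality_prob = 0.25,
                       p_universal_in_org = 0.9,
                       p_background_in_org = 0.2,
                       universal_gene_prob_test = 0.35,
                       universal_gene_prob_ref = 0.2,
                       background_hit_prob = 0.02,
                       mimicry_plants = NULL,
                       n_decoy_hits = 5L) {
  if (is.null(names(test_set_sizes)) || any(!nzchar(names(test_set_sizes))))
    stop("test_set_sizes must be a named vector")
  n_sets <- length(test_set_sizes)
  probs <- c(base_annotation_prob, feature_missing_prob, motif_rate_test,
             motif_rate_ref, p_incomplete_org, domain_universality_prob,
             p_universal_in_org, p_background_in_org, universal_gene_prob_test,
             universal_gene_prob_ref, background_hit_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (n_genes < 1L || any(test_set_sizes < 1L) ||
      n_categories_per_namespace < 1L)
    stop("sizes must be positive")
  if (is.null(mimicry_plants)) {
    n_pre <- sum(n_organisms_per_kingdom[c("BACTERIA", "ARCHAEA")])
    mimicry_plants <- data.frame(
      organism_index = n_pre + seq_len(min(3L, n_organisms_per_kingdom[["EUKARYOTA"]])),
      test_prob = 0.3, ref_prob = 0.02)
  }
  if (nrow(mimicry_plants) &&
      any(mimicry_plants$test_prob < 0 | mimicry_plants$test_prob > 1 |
          mimicry_plants$ref_prob < 0 | mimicry_plants$ref_prob > 1))
    stop("mimicry plant probabilities must be in [0, 1]")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 test_set_sizes = test_set_sizes,
                 exon_length_log_mean = exon_length_log_mean,
                 exon_length_log_sd = exon_length_log_sd,
                 exon_shift_per_set = rep_len(exon_shift_per_set, n_sets),
                 namespaces = namespaces,
                 n_categories_per_namespace = as.integer(n_categories_per_namespace),
                 base_annotation_prob = base_annotation_prob,
                 planted_categories = planted_categories,
                 count_feature_rates = count_feature_rates,
                 count_shift_per_set = rep_len(count_shift_per_set, n_sets),
                 feature_missing_prob = feature_missing_prob,
                 seq_length = as.integer(seq_length),
                 motif_rate_test = motif_rate_test,
                 motif_rate_ref = motif_rate_ref,
                 motif = toupper(motif),
                 n_organisms_per_kingdom = n_organisms_per_kingdom,
                 p_incomplete_org = p_incomplete_org,
                 schemes = schemes,
                 n_domains_per_scheme = as.integer(n_domains_per_scheme),
                 domain_universality_prob = domain_universality_prob,
                 p_universal_in_org = p_universal_in_org,
                 p_background_in_org = p_background_in_org,
                 universal_gene_prob_test = universal_gene_prob_test,
                 universal_gene_prob_ref = universal_gene_prob_ref,
                 background_hit_prob = background_hit_prob,
                 mimicry_plants = mimicry_plants,
                 n_decoy_hits = as.integer(n_decoy_hits)),
            class = "sim_config")
}

#' Generate the gene universe and antigen test sets
#'
#' Gene identifiers with log-normal mean exon lengths; each test set is an
#' independent draw from the universe (so sets may overlap, as real antigen
#' sets do), and test-set genes have their exon length redrawn with the
#' configured additive shift on the log-mean (the first set containing a
#' gene decides its shift).
#'
#' @param cfg A [sim_config].
#' @return List with `universe` (a `gene_universe`), `sets` (list of
#'   [gene_set]), and `truth` (planted parameters).
#' @export
generate_universe <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (any(cfg$test_set_sizes > cfg$n_genes))
    stop("test set size exceeds universe size")
  set.seed(substream_seed(cfg$seed, "universe"))
  ids <- sprintf("g%05d", seq_len(cfg$n_genes))
  len <- stats::rlnorm(cfg$n_genes, cfg$exon_length_log_mean,
                       cfg$exon_length_log_sd)
  set_names <- names(cfg$test_set_sizes)
  sets <- vector("list", length(set_names))
  shift <- rep(NA_real_, cfg$n_genes)
  for (i in seq_along(set_names)) {
    members <- sort(sample(ids, cfg$test_set_sizes[[i]]))
    sets[[i]] <- gene_set(set_names[[i]], members,
                          description = "synthetic antigen set")
    idx <- match(members, ids)
    fresh <- idx[is.na(shift[idx])]
    shift[fresh] <- cfg$exon_shift_per_set[[i]]
  }
  shifted <- which(!is.na(shift))
  len[shifted] <- stats::rlnorm(length(shifted),
                                cfg$exon_length_log_mean + shift[shifted],
                                cfg$exon_length_log_sd)
  names(sets) <- set_names
  list(universe = gene_universe(ids, len),
       sets = sets,
       truth = list(exon_shift_per_set = as.list(stats::setNames(
                      cfg$exon_shift_per_set, set_names)),
                    test_set_sizes = as.list(cfg$test_set_sizes)))
}

#' Generate binary annotation catalogs with planted enrichments
#'
#' Every gene is annotated to every category with the base probability;
#' planted (set, namespace, category) triples raise the probability to
#' `test_prob` for the designated test set's genes.
#'
#' @param cfg A [sim_config].
#' @param universe A `gene_universe` from [generate_universe].
#' @param sets Test sets from [generate_universe].
#' @return List with `catalogs` (named list of [annotation_catalog]) and
#'   `truth` (the planted triples with category ids resolved).
#' @export
generate_annotations <- function(cfg, universe, sets) {
  set.seed(substream_seed(cfg$seed, "annotations"))
  ids <- universe$gene_id
  n <- length(ids)
  plants <- cfg$planted_categories
  catalogs <- list()
  planted_out <- list()
  for (ns in cfg$namespaces) {
    cats <- list()
    for (j in seq_len(cfg$n_categories_per_namespace)) {
      cid <- sprintf("%s_c%03d", ns, j)
      p <- rep(cfg$base_annotation_prob, n)
      hit <- which(plants$namespace == ns & plants$category_index == j)
      for (h in hit) {
        set_genes <- sets[[plants$set_index[[h]]]]$members
        p[ids %in% set_genes] <- plants$test_prob[[h]]
        planted_out[[length(planted_out) + 1L]] <- list(
          set_name = sets[[plants$set_index[[h]]]]$name,
          namespace = ns, category_id = cid,
          test_prob = plants$test_prob[[h]])
      }
      cats[[cid]] <- ids[stats::runif(n) < p]
    }
    catalogs[[ns]] <- annotation_catalog(ns, cats)
  }
  list(catalogs = catalogs, truth = list(planted = planted_out))
}

#' Generate numeric count features tied to exon length
#'
#' Counts (SNPs by type, somatic mutations) are Poisson with rate
#' proportional to mean exon length (per kilobase), multiplied by the
#' configured shift for test-set genes; a fraction of genes is missing from
#' each feature, emulating incomplete database coverage.
#'
#' @param cfg A [sim_config].
#' @param universe,sets From [generate_universe].
#' @return List with `features` (named list of [numeric_feature]) and `truth`.
#' @export
generate_features <- function(cfg, universe, sets) {
  set.seed(substream_seed(cfg$seed, "features"))
  ids <- universe$gene_id
  n <- length(ids)
  mult <- rep(1, n)
  assigned <- rep(FALSE, n)
  for (i in seq_along(sets)) {
    idx <- match(sets[[i]]$members, ids)
    fresh <- idx[!assigned[idx]]
    mult[fresh] <- cfg$count_shift_per_set[[i]]
    assigned[fresh] <- TRUE
  }
  per_kb <- universe$mean_exon_length / 1000
  features <- list()
  for (f in names(cfg$count_feature_rates)) {
    lambda <- cfg$count_feature_rates[[f]] * per_kb * mult
    vals <- stats::rpois(n, lambda)
    miss <- stats::runif(n) < cfg$feature_missing_prob
    v <- as.numeric(vals[!miss])
    names(v) <- ids[!miss]
    features[[f]] <- numeric_feature(f, v)
  }
  list(features = features,
       truth = list(count_shift_per_set = as.list(stats::setNames(
         cfg$count_shift_per_set, names(sets)))))
}

# Replace the middle residue of every motif occurrence with a letter foreign
# to the motif, repeating until the sequence is motif-free.
strip_motif <- function(seqs, motif) {
  alphabet <- strsplit(AA_ALPHABET, "")[[1]]
  safe <- setdiff(alphabet, strsplit(motif, "")[[1]])[1]
  mid <- (nchar(motif) + 1L) %/% 2L
  repeat {
    has <- grepl(motif, seqs, fixed = TRUE)
    if (!any(has)) break
    pos <- regexpr(motif, seqs[has], fixed = TRUE)
    substr(seqs[has], pos + mid - 1L, pos + mid - 1L) <- safe
  }
  seqs
}

#' Generate protein sequences with a planted motif
#'
#' Random sequences over the 20-letter alphabet; accidental motif
#' occurrences are removed, then the motif is inserted at a random position
#' in each carrier gene, drawn with `motif_rate_test` for test-set genes and
#' `motif_rate_ref` otherwise -- so the motif-bearing genes are exactly the
#' recorded carriers.
#'
#' @param cfg A [sim_config].
#' @param universe,sets From [generate_universe].
#' @return List with `sequences` (named character vector) and `truth`
#'   (carrier gene ids).
#' @export
generate_sequences <- function(cfg, universe, sets) {
  set.seed(substream_seed(cfg$seed, "sequences"))
  ids <- universe$gene_id
  n <- length(ids)
  L <- cfg$seq_length
  alphabet <- strsplit(AA_ALPHABET, "")[[1]]
  m <- matrix(sample(alphabet, n * L, replace = TRUE), nrow = n)
  seqs <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  seqs <- strip_motif(seqs, cfg$motif)
  in_test <- ids %in% unique(unlist(lapply(sets, `[[`, "members"),
                                    use.names = FALSE))
  rate <- ifelse(in_test, cfg$motif_rate_test, cfg$motif_rate_ref)
  carrier <- stats::runif(n) < rate
  mlen <- nchar(cfg$motif)
  if (any(carrier)) {
    pos <- sample.int(L - mlen + 1L, sum(carrier), replace = TRUE)
    substr(seqs[carrier], pos, pos + mlen - 1L) <- cfg$motif
  }
  names(seqs) <- ids
  list(sequences = seqs,
       truth = list(motif = cfg$motif, carriers = ids[carrier]))
}

#' Generate organism metadata, organism x domain tables, and a domain-gene map
#'
#' Per kingdom, the configured number of organisms (a small fraction flagged
#' incomplete). Per scheme, each domain is universal within a kingdom with
#' `domain_universality_prob`; an organism carries a domain with
#' `p_universal_in_org` where it is universal and `p_background_in_org`
#' elsewhere. "Ancient-carrier" genes (probability `universal_gene_prob_test`
#' for test-set genes, `universal_gene_prob_ref` otherwise) are mapped to
#' core domains -- those universal in all three kingdoms -- so they land in
#' every UNIVERSAL set; other genes are mapped to never-universal domains.
#'
#' @param cfg A [sim_config].
#' @param universe,sets From [generate_universe].
#' @return List with `od` (an [organism_domains]), `domain_gene` (data
#'   frame), and `truth` (ancient carriers, per-scheme universal flags).
#' @export
generate_organism_domains <- function(cfg, universe, sets) {
  set.seed(substream_seed(cfg$seed, "organisms"))
  kingdoms <- rep(names(cfg$n_organisms_per_kingdom),
                  cfg$n_organisms_per_kingdom)
  org_ids <- unlist(lapply(names(cfg$n_organisms_per_kingdom), function(k) {
    sprintf("%s_%03d", tolower(substr(k, 1, 3)),
            seq_len(cfg$n_organisms_per_kingdom[[k]]))
  }), use.names = FALSE)
  complete <- stats::runif(length(org_ids)) >= cfg$p_incomplete_org
  ids <- universe$gene_id
  in_test <- ids %in% unique(unlist(lapply(sets, `[[`, "members"),
                                    use.names = FALSE))
  carrier <- stats::runif(length(ids)) <
    ifelse(in_test, cfg$universal_gene_prob_test, cfg$universal_gene_prob_ref)
  meta_list <- list(); dom_list <- list(); map_list <- list()
  universal_truth <- list()
  for (scheme in cfg$schemes) {
    nd <- cfg$n_domains_per_scheme
    dom_ids <- sprintf("%s_d%04d", scheme, seq_len(nd))
    uni <- matrix(stats::runif(nd * length(KINGDOMS)) <
                    cfg$domain_universality_prob,
                  nrow = nd,
                  dimnames = list(dom_ids, KINGDOMS))
    core <- dom_ids[rowSums(uni) == length(KINGDOMS)]
    never <- dom_ids[rowSums(uni) == 0L]
    if (length(core) == 0L)
      warning("scheme ", scheme,
              ": no domain is universal in all kingdoms; ancient carriers unmapped")
    # per-organism presence
    for (i in seq_along(org_ids)) {
      p <- ifelse(uni[, kingdoms[i]], cfg$p_universal_in_org,
                  cfg$p_background_in_org)
      present <- dom_ids[stats::runif(nd) < p]
      dom_list[[length(dom_list) + 1L]] <- data.frame(
        organism_id = org_ids[i], domain_id = present, scheme = scheme,
        stringsAsFactors = FALSE)
    }
    meta_list[[scheme]] <- data.frame(
      organism_id = org_ids, kingdom = kingdoms, complete = complete,
      scheme = scheme, stringsAsFactors = FALSE)
    # domain -> gene map (empty pools simply leave those genes unmapped)
    carrier_dom <- if (length(core)) sample(core, sum(carrier), replace = TRUE)
                   else character()
    other_dom <- if (length(never)) sample(never, sum(!carrier), replace = TRUE)
                 else character()
    map_list[[scheme]] <- data.frame(
      domain_id = c(carrier_dom, other_dom),
      gene_id = c(if (length(core)) ids[carrier] else character(),
                  if (length(never)) ids[!carrier] else character()),
      stringsAsFactors = FALSE)
    universal_truth[[scheme]] <- list(core_domains = core,
                                      n_universal_by_kingdom =
                                        as.list(colSums(uni)))
  }
  meta <- do.call(rbind, meta_list)
  rownames(meta) <- NULL
  domains <- do.call(rbind, dom_list)
  domain_gene <- do.call(rbind, map_list)
  rownames(domain_gene) <- NULL
  list(od = organism_domains(meta, domains),
       domain_gene = domain_gene,
       truth = list(ancient_carriers = ids[carrier],
                    schemes = universal_truth))
}

#' Generate BLAST tabular hits with planted organism enrichments
#'
#' For every organism, each gene is "similar" with the background
#' probability, or with the planted per-group probabilities for organisms in
#' `mimicry_plants`. Each similar gene yields one tabular row on the keep
#' side of the score and E-value thresholds; per organism, `n_decoy_hits`
#' additional rows fall on the violation side. Query ids are `p_<gene>` to
#' exercise the query-to-gene mapping.
#'
#' @param cfg A [sim_config].
#' @param universe,sets From [generate_universe].
#' @param organisms Organism metadata data frame (one row per organism;
#'   extra scheme rows are collapsed).
#' @return List with `hits`, `subject_organism`, `query_gene` data frames
#'   and `truth` (planted organisms, per-organism similar-gene lists).
#' @export
generate_blast_hits <- function(cfg, universe, sets, organisms) {
  set.seed(substream_seed(cfg$seed, "blast"))
  meta <- organisms[!duplicated(organisms$organism_id), , drop = FALSE]
  ids <- universe$gene_id
  n <- length(ids)
  in_test <- ids %in% unique(unlist(lapply(sets, `[[`, "members"),
                                    use.names = FALSE))
  plants <- cfg$mimicry_plants
  hit_rows <- list(); subj_rows <- list()
  truth_similar <- list()
  for (i in seq_len(nrow(meta))) {
    org <- meta$organism_id[i]
    p <- rep(cfg$background_hit_prob, n)
    pi <- which(plants$organism_index == i)
    if (length(pi)) {
      p[in_test] <- plants$test_prob[[pi[1]]]
      p[!in_test] <- plants$ref_prob[[pi[1]]]
    }
    sim <- ids[stats::runif(n) < p]
    nk <- length(sim)
    nd <- cfg$n_decoy_hits
    decoy_genes <- if (nd > 0) sample(ids, nd) else character()
    qg <- c(sim, decoy_genes)
    ntot <- nk + nd
    if (ntot == 0L) next
    subj <- sprintf("%s_s%04d", org, seq_len(ntot))
    alen <- sample.int(300L, ntot, replace = TRUE) + 50L
    # keep-side scores/E-values for real hits, violation side for decoys
    bit <- c(round(stats::runif(nk, 120, 400), 1),
             round(stats::runif(nd, 30, 99), 1))
    ev <- c(signif(10^stats::runif(nk, -50, -4), 3),
            signif(10^stats::runif(nd, -2.9, 0), 3))
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = paste0("p_", qg), subject_id = subj,
      percent_identity = round(stats::runif(ntot, 35, 95), 1),
      alignment_length = alen, mismatches = sample.int(50L, ntot, TRUE),
      gap_opens = sample.int(5L, ntot, TRUE) - 1L,
      q_start = 1L, q_end = alen, s_start = 1L, s_end = alen,
      evalue = ev, bit_score = bit, stringsAsFactors = FALSE)
    subj_rows[[length(subj_rows) + 1L]] <- data.frame(
      subject_id = subj, organism_id = org, stringsAsFactors = FALSE)
    if (meta$complete[i] && nk > 0L) truth_similar[[org]] <- sim
  }
  hits <- do.call(rbind, hit_rows)
  rownames(hits) <- NULL
  subject_organism <- do.call(rbind, subj_rows)
  rownames(subject_organism) <- NULL
  planted_orgs <- meta$organism_id[plants$organism_index]
  list(hits = hits,
       subject_organism = subject_organism,
       query_gene = data.frame(query_id = paste0("p_", ids), gene_id = ids,
                               stringsAsFactors = FALSE),
       truth = list(planted_organisms = as.list(stats::setNames(
                      asplit(plants[c("test_prob", "ref_prob")], 1),
                      planted_orgs)),
                    similar_counts = lapply(truth_similar, length)))
}

#' Write a complete synthetic corpus to disk
#'
#' Runs every generator under the config's master seed and writes all input
#' files the pipeline reads -- universe TSV, antigen GMT, per-namespace
#' annotation TSVs, feature TSV, protein FASTA, organism metadata and
#' organism-domain TSVs, domain-gene TSV, BLAST tabular, subject-organism
#' and query-gene TSVs -- plus a `ground_truth.json` manifest of every
#' planted parameter. Identical configs produce byte-identical corpora.
#'
#' @param cfg A [sim_config].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths plus the ground truth.
#' @export
simulate_corpus <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  uni <- generate_universe(cfg)
  ann <- generate_annotations(cfg, uni$universe, uni$sets)
  feat <- generate_features(cfg, uni$universe, uni$sets)
  seqs <- generate_sequences(cfg, uni$universe, uni$sets)
  orgd <- generate_organism_domains(cfg, uni$universe, uni$sets)
  blast <- generate_blast_hits(cfg, uni$universe, uni$sets, orgd$od$meta)

  paths <- list(universe = file.path(dir, "universe.tsv"),
                gmt = file.path(dir, "antigen_sets.gmt"),
                features = file.path(dir, "features.tsv"),
                fasta = file.path(dir, "sequences.fasta"),
                organisms = file.path(dir, "organisms.tsv"),
                organism_domains = file.path(dir, "organism_domains.tsv"),
                domain_genes = file.path(dir, "domain_genes.tsv"),
                blast = file.path(dir, "blast_hits.tsv"),
                subject_organisms = file.path(dir, "subject_organisms.tsv"),
                query_genes = file.path(dir, "query_genes.tsv"),
                truth = file.path(dir, "ground_truth.json"))
  write_universe(uni$universe, paths$universe)
  write_gmt(uni$sets, paths$gmt)
  ann_paths <- character()
  for (ns in names(ann$catalogs)) {
    p <- file.path(dir, sprintf("annotations_%s.tsv", ns))
    write_annotation_tsv(ann$catalogs[[ns]], p)
    ann_paths[[ns]] <- p
  }
  paths$annotations <- ann_paths
  # wide feature TSV; empty cell = missing
  ids <- uni$universe$gene_id
  fdf <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  for (f in names(feat$features)) {
    v <- feat$features[[f]]$values[ids]
    fdf[[f]] <- ifelse(is.na(v), "", format(v, trim = TRUE, scientific = FALSE))
  }
  utils::write.table(fdf, paths$features, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_protein_fasta(seqs$sequences, paths$fasta)
  utils::write.table(orgd$od$meta, paths$organisms, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(orgd$od$domains, paths$organism_domains, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(orgd$domain_gene, paths$domain_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(blast$hits, paths$blast, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(blast$subject_organism, paths$subject_organisms,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(blast$query_gene, paths$query_genes, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(seed = cfg$seed,
                universe = uni$truth, annotations = ann$truth,
                features = feat$truth,
                sequences = list(motif = seqs$truth$motif,
                                 n_carriers = length(seqs$truth$carriers),
                                 carriers = seqs$truth$carriers),
                organism_domains = orgd$truth,
                blast = blast$truth)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(ground_truth = truth)))
}
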