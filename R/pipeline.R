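## End-to-end orchestration: corpus filtering -> gene annotation ->
## country resolution -> count metrics -> transactions and itemset
## mining -> co-occurrence network analysis -> clustering, with every
## intermediate artifact written to disk and a reproducible JSON manifest
## (no timestamps: two runs with the same config and seed must produce
## byte-identical manifests).

#' Assemble a pipeline run configuration
#'
#' @param corpus Path to a JSON-lines corpus ([write_jsonl()] format).
#' @param lexicon Path to a 2-column tab-separated gene lexicon.
#' @param gazetteer Path to a tab-separated country gazetteer.
#' @param out_dir Output directory (created if missing).
#' @param min_weight Network edge-pruning threshold (default 10).
#' @param min_support_pct Itemset mining threshold in percent (default
#'   40, below every support the shipped analyses print).
#' @param tau Fuzzy-area membership threshold (default 0.6).
#' @param c_min,c_max Candidate fuzzy cluster counts.
#' @param m Fuzzifier.
#' @param metric Distance for the country dendrogram.
#' @param top_k_countries Size of the country ranking used for
#'   collaboration and unmentioned-gene reports.
#' @param seed Master seed; per-stage seeds are derived at fixed offsets
#'   so stages never share an RNG stream.
#' @return A list of class `run_config`.
#' @export
run_config <- function(corpus, lexicon, gazetteer, out_dir,
                       min_weight = 10, min_support_pct = 40,
                       tau = 0.6, c_min = 2L, c_max = 6L, m = 2,
                       metric = "cosine", top_k_countries = 10L,
                       seed = 1L) {
  structure(
    list(
      corpus = corpus, lexicon = lexicon, gazetteer = gazetteer,
      out_dir = out_dir, min_weight = min_weight,
      min_support_pct = min_support_pct, tau = tau,
      c_min = as.integer(c_min), c_max = as.integer(c_max), m = m,
      metric = metric, top_k_countries = as.integer(top_k_countries),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
      call. = FALSE
    )
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage over the configured corpus, writes all
#' intermediate artifacts under `out_dir`, and returns (and writes) a
#' run manifest recording the configuration, the record-count funnel
#' (retrieved -> complete -> gene-bearing), and per-stage outputs.
#' Any stage failure aborts with the stage name; artifacts written by
#' earlier stages are preserved.
#'
#' @param config A [run_config()], or a path to a YAML config.
#' @return The manifest list, invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  for (f in c("corpus", "lexicon", "gazetteer")) {
    if (!file.exists(config[[f]])) {
      stop("config error: ", f, " file not found: ", config[[f]], call. = FALSE)
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  stages <- character()
  outputs <- list()
  message("stage corpus_load")
  raw <- pipeline_stage("corpus_load", read_jsonl(config$corpus))
  n_retrieved <- length(raw)
  stages <- c(stages, "corpus_load")

  message("stage filter_complete")
  complete <- pipeline_stage("filter_complete", {
    x <- filter_complete(raw)
    write_jsonl(x, out("corpus_complete.jsonl"))
    x
  })
  outputs$corpus_complete <- "corpus_complete.jsonl"
  stages <- c(stages, "filter_complete")

  message("stage annotate")
  annotated <- pipeline_stage("annotate", {
    lex <- build_lexicon(config$lexicon)
    x <- filter_gene_bearing(annotate_corpus(complete, lex))
    write_jsonl(x, out("corpus_gene_bearing.jsonl"))
    x
  })
  outputs$corpus_gene_bearing <- "corpus_gene_bearing.jsonl"
  stages <- c(stages, "annotate")

  message("stage geo_resolve")
  resolved <- pipeline_stage("geo_resolve", {
    gaz <- build_gazetteer(config$gazetteer)
    cache <- new_geo_cache()
    x <- resolve_corpus_countries(annotated, gaz, cache)
    write_geo_cache(cache, out("geo_cache.tsv"))
    write_jsonl(x, out("corpus_resolved.jsonl"))
    x
  })
  outputs$corpus_resolved <- "corpus_resolved.jsonl"
  stages <- c(stages, "geo_resolve")

  message("stage metrics")
  counts <- pipeline_stage("metrics", {
    cc <- gene_country_counts(resolved)
    write_tidy_matrix(cc$counts, out("gene_country_counts.csv"), "n_abstracts")
    write_tidy_matrix(effort(cc), out("effort.csv"), "effort")
    utils::write.csv(collaborations(resolved), out("collaborations.csv"),
      row.names = FALSE
    )
    k <- min(config$top_k_countries, sum(rownames(cc$counts) != UNRESOLVED_ROW))
    top <- top_k(cc, "country", k)
    utils::write.csv(top, out("top_countries.csv"), row.names = FALSE)
    writeLines(
      unmentioned_by(cc, top$name),
      out("unmentioned_by_top_countries.txt")
    )
    cc
  })
  outputs$metrics <- c(
    "gene_country_counts.csv", "effort.csv", "collaborations.csv",
    "top_countries.csv", "unmentioned_by_top_countries.txt"
  )
  stages <- c(stages, "metrics")

  message("stage pattern_mining")
  mined <- pipeline_stage("pattern_mining", {
    db_c <- build_country_transactions(resolved)
    db_y <- build_year_transactions(resolved)
    write_baskets(db_c, out("transactions_country.basket"))
    write_baskets(db_y, out("transactions_year.basket"))
    it_c <- mine_maximal_closed(db_c, config$min_support_pct)
    it_y <- mine_maximal_closed(db_y, config$min_support_pct)
    utils::write.csv(it_c, out("itemsets_country.csv"), row.names = FALSE)
    utils::write.csv(it_y, out("itemsets_year.csv"), row.names = FALSE)
    list(country = it_c, year = it_y, db_year = db_y)
  })
  outputs$pattern_mining <- c(
    "transactions_country.basket", "transactions_year.basket",
    "itemsets_country.csv", "itemsets_year.csv"
  )
  stages <- c(stages, "pattern_mining")

  message("stage network")
  net_res <- pipeline_stage("network", {
    full <- build_network(resolved)
    giant <- giant_component(full)
    pruned <- prune_network(giant, config$min_weight)
    summ <- network_summary(full, giant, pruned)
    utils::write.csv(summ, out("network_summary.csv"), row.names = FALSE)
    cent <- network_centralities(pruned)
    comm <- network_communities(pruned, seed = config$seed + 101L)
    node_tab <- merge(cent, comm$membership, by = "gene", sort = TRUE)
    utils::write.csv(node_tab, out("network_nodes.csv"), row.names = FALSE)
    write_edge_list(pruned, out("network_pruned.edgelist"))
    write_graphml(pruned, out("network_pruned.graphml"))
    list(summary = summ, modularity = comm$modularity)
  })
  outputs$network <- c(
    "network_summary.csv", "network_nodes.csv",
    "network_pruned.edgelist", "network_pruned.graphml"
  )
  stages <- c(stages, "network")

  message("stage clustering")
  clus <- pipeline_stage("clustering", {
    keep <- rownames(counts$counts) != UNRESOLVED_ROW
    country_profiles <- counts$counts[keep, , drop = FALSE]
    dend <- hierarchical_complete(country_profiles, metric = config$metric)
    utils::write.csv(dend$merges, out("country_dendrogram.csv"), row.names = FALSE)
    if (requireNamespace("ape", quietly = TRUE)) {
      write_newick(dend, out("country_dendrogram.nwk"))
    }
    gy <- gene_year_matrix(resolved)
    cs <- seq(config$c_min, min(config$c_max, nrow(gy) - 1L))
    fits <- lapply(cs, function(ci) {
      fcm(gy,
        c = ci, m = config$m,
        seed = config$seed + 211L + ci
      )
    })
    vi <- validity_indices(gy, fits)
    utils::write.csv(vi, out("validity_indices.csv"), row.names = FALSE)
    best <- fits[[1]]
    memb <- as.data.frame(best$membership)
    names(memb) <- paste0("cluster_", seq_len(ncol(memb)))
    memb <- cbind(gene = best$data_rows, memb)
    utils::write.csv(memb, out("fcm_membership.csv"), row.names = FALSE)
    coords <- pca_2d(gy)
    utils::write.csv(
      data.frame(gene = rownames(coords), coords),
      out("pca_coords.csv"),
      row.names = FALSE
    )
    fa <- fuzzy_area_genes(best, tau = config$tau)
    writeLines(fa, out("fuzzy_area_genes.txt"))
    cross <- crossmatch_itemsets(
      mined$year[mined$year$maximal, , drop = FALSE],
      fa,
      universe = rownames(gy)
    )
    utils::write.csv(cross, out("itemset_fuzzy_crossmatch.csv"), row.names = FALSE)
    list(validity = vi)
  })
  outputs$clustering <- c(
    "country_dendrogram.csv", "validity_indices.csv", "fcm_membership.csv",
    "pca_coords.csv", "fuzzy_area_genes.txt", "itemset_fuzzy_crossmatch.csv"
  )
  stages <- c(stages, "clustering")

  manifest <- list(
    schema = 1L,
    package = "litgenet",
    version = as.character(utils::packageVersion("litgenet")),
    config = unclass(config),
    seed = config$seed,
    funnel = list(
      retrieved = n_retrieved,
      complete = length(complete),
      gene_bearing = length(annotated)
    ),
    stages = as.list(stages),
    outputs = outputs
  )
  jsonlite::write_json(manifest, out("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}
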