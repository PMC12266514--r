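# Orchestration of the factorial comparison: pseudobulk -> gene
# selection -> network inference (combined and single time point) ->
# network analysis -> enrichment -> differential analysis ->
# meta-comparison, with a manifest of every artifact written.

#' Build and validate a run configuration
#'
#' Mirrors the factorial design of the study: modeling x pseudo-bulk
#' method x zero handling x gene selection x k x algorithm x metric x
#' analysis strategy.  Invalid grid cells (zero handling outside
#' leiden/time, ARACNE or CLR with a non-MI metric) are rejected with an
#' error naming the cell.
#'
#' @param study An [expression_study()] or a directory readable by
#'   [read_expression_study()].
#' @param gene_sets A [gene_set_collection()] or a GMT path.
#' @param out_dir Output directory.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param modeling Subset of `c("combined", "single")`.
#' @param pseudobulk Subset of `c("leiden", "time", "seacell")`.
#' @param zero_mode Subset of `c("ignore_zeros", "with_zeros")`, applied
#'   to the leiden and time methods only.
#' @param selection Subset of `c("var", "sum", "deg")`.
#' @param k Gene counts for selection (default 500).
#' @param algorithms Subset of `c("aracne", "clr", "wgcna",
#'   "consensus")`.
#' @param metrics Similarity metrics; WGCNA pairs with each, ARACNE and
#'   CLR require `"mi"`.
#' @param analyses Subset of `c("gsea_deg", "gsea_bet", "gsea_cc",
#'   "community", "differential_terms", "differential_centrality")`.
#' @param n_metacells Metacell count for the seacell method.
#' @param n_perm GSEA permutations (default 200 for pipeline runs).
#' @param resolution Community-detection resolution.
#' @param aracne,clr,wgcna Per-algorithm parameter lists.
#' @param cells Optional explicit data frame of pseudobulk grid cells
#'   (columns `pseudobulk`, `zero_mode`) overriding the expansion.
#' @return A validated `run_config`.
#' @export
run_config <- function(study, gene_sets, out_dir, seed = 1,
                       modeling = c("combined", "single"),
                       pseudobulk = "time", zero_mode = "ignore_zeros",
                       selection = "var", k = 500,
                       algorithms = c("aracne", "clr"), metrics = "mi",
                       analyses = c("gsea_deg", "community"),
                       n_metacells = 30, n_perm = 200, resolution = 1,
                       aracne = list(), clr = list(), wgcna = list(),
                       cells = NULL) {
  modeling <- match.arg(modeling, several.ok = TRUE)
  stop_if_not(all(pseudobulk %in% c("leiden", "time", "seacell")),
              "unknown pseudobulk method")
  stop_if_not(all(zero_mode %in% c("ignore_zeros", "with_zeros")),
              "unknown zero_mode")
  stop_if_not(all(selection %in% c("var", "sum", "deg")),
              "unknown selection strategy")
  stop_if_not(all(algorithms %in% c("aracne", "clr", "wgcna", "consensus")),
              "unknown algorithm")
  stop_if_not(all(metrics %in% c("pearson", "spearman", "mi")),
              "unknown metric")
  stop_if_not(all(analyses %in% c("gsea_deg", "gsea_bet", "gsea_cc",
                                  "community", "differential_terms",
                                  "differential_centrality")),
              "unknown analysis strategy")
  cells <- cells %||% expand_pseudobulk_cells(pseudobulk, zero_mode)
  validate_pseudobulk_cells(cells)
  combos <- network_combos(algorithms, metrics)
  structure(list(study = study, gene_sets = gene_sets, out_dir = out_dir,
                 seed = as.integer(seed), modeling = modeling,
                 pseudobulk_cells = cells, selection = selection,
                 k = as.integer(k), algorithms = algorithms,
                 metrics = metrics, combos = combos, analyses = analyses,
                 n_metacells = as.integer(n_metacells),
                 n_perm = as.integer(n_perm), resolution = resolution,
                 aracne = aracne, clr = clr, wgcna = wgcna),
            class = "run_config")
}

expand_pseudobulk_cells <- function(pseudobulk, zero_mode) {
  rows <- list()
  for (m in pseudobulk) {
    if (m %in% c("leiden", "time")) {
      for (z in zero_mode)
        rows[[length(rows) + 1L]] <- data.frame(pseudobulk = m,
                                                zero_mode = z)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(pseudobulk = m,
                                              zero_mode = "n/a")
    }
  }
  do.call(rbind, rows)
}

validate_pseudobulk_cells <- function(cells) {
  bad <- cells$pseudobulk == "seacell" & cells$zero_mode != "n/a"
  if (any(bad))
    stop(sprintf("invalid grid cell: pseudobulk=seacell x zero_mode=%s (zero handling applies to leiden and time only)",
                 cells$zero_mode[which(bad)[1]]), call. = FALSE)
  invisible(cells)
}

# algorithm x metric expansion: WGCNA pairs with every requested metric;
# ARACNE and CLR are defined on mutual information only
network_combos <- function(algorithms, metrics) {
  rows <- list()
  for (alg in setdiff(algorithms, "consensus")) {
    if (alg %in% c("aracne", "clr")) {
      if (!"mi" %in% metrics)
        stop(sprintf("invalid grid cell: algorithm=%s requires metric=mi",
                     alg), call. = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(algorithm = alg, metric = "mi")
    } else {
      for (met in metrics)
        rows[[length(rows) + 1L]] <- data.frame(algorithm = alg,
                                                metric = met)
    }
  }
  do.call(rbind, rows) %||% data.frame(algorithm = character(),
                                       metric = character())
}

#' Load a run configuration from a YAML file
#' @param path YAML path whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

#' Run the full factorial comparison
#'
#' Executes every stage over the configured grid and writes all
#' artifacts plus a `manifest.json` listing each file with its
#' provenance tuple.  Existing artifacts are reused unless
#' `force = TRUE`, so a rerun with the same configuration performs no
#' recomputation and reproduces the manifest.
#'
#' @param config A [run_config()] (or list / YAML path coercible to
#'   one).
#' @param force Recompute artifacts that already exist (default FALSE).
#' @return The manifest, invisibly: list with `config` summary,
#'   `artifacts` (path, type, provenance) and `n_networks`.
#' @export
run_comparison <- function(config, force = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  study <- if (is.character(config$study))
    read_expression_study(config$study) else config$study
  sets <- if (is.character(config$gene_sets))
    read_gmt(config$gene_sets) else config$gene_sets
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seeds <- split_seed(config$seed, 4)
  names(seeds) <- c("pseudobulk", "network", "community", "gsea")

  artifacts <- list()
  add <- function(path, type, provenance = list()) {
    artifacts[[length(artifacts) + 1L]] <<-
      list(path = sub(paste0("^", out, "/?"), "", path), type = type,
           provenance = provenance)
  }
  assignments <- list()
  n_networks <- 0L

  for (ci in seq_len(nrow(config$pseudobulk_cells))) {
    cell <- config$pseudobulk_cells[ci, ]
    pb <- pipeline_pseudobulk(study, cell, config, seeds["pseudobulk"],
                              out, force, add)
    for (strategy in config$selection) {
      for (k in config$k) {
        sel <- pipeline_selection(pb, strategy, k, cell, out, force, add)
        for (modeling in config$modeling) {
          inputs <- assemble_time_point_inputs(pb, modeling)
          tp_results <- list()   # per time point, for differential
          for (lab in names(inputs)) {
            prov0 <- list(dataset = "study", modeling = modeling,
                          pseudobulk = cell$pseudobulk,
                          zero_mode = cell$zero_mode,
                          selection = strategy, k = as.character(k))
            nets <- pipeline_networks(inputs[[lab]], sel, config, prov0,
                                      lab, out, force, add,
                                      seeds["network"])
            n_networks <- n_networks + length(nets)
            for (nm in names(nets)) {
              res <- pipeline_analyze(nets[[nm]], sets, config, lab, out,
                                      force, add, seeds)
              assignments <- c(assignments, res$assignments)
              if (modeling == "single")
                tp_results[[lab]][[nm]] <- res
            }
          }
          if (modeling == "single" && length(tp_results) >= 2) {
            res <- pipeline_differential(tp_results, sets, config, out,
                                         force, add, seeds["gsea"])
            assignments <- c(assignments, res)
          }
        }
      }
    }
  }

  if (length(assignments) >= 2) {
    pipeline_meta(assignments, config, out, force, add)
  }

  manifest <- list(seed = config$seed,
                   n_networks = n_networks,
                   n_assignments = length(assignments),
                   artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# ---- stage helpers ----------------------------------------------------

pb_cell_tag <- function(cell) {
  if (cell$zero_mode == "with_zeros") paste0(cell$pseudobulk, "_w0")
  else cell$pseudobulk
}

pipeline_pseudobulk <- function(study, cell, config, seed, out, force, add) {
  dir.create(file.path(out, "pseudobulk"), showWarnings = FALSE)
  tag <- pb_cell_tag(cell)
  mpath <- file.path(out, "pseudobulk", paste0(tag, ".tsv"))
  lpath <- file.path(out, "pseudobulk", paste0(tag, ".labels.tsv"))
  if (file.exists(mpath) && file.exists(lpath) && !force) {
    m <- as.matrix(utils::read.delim(mpath, row.names = 1,
                                     check.names = FALSE))
    labs <- utils::read.delim(lpath, colClasses = "character")
    pb <- pseudobulk_matrix(m, rownames(m), colnames(m), labs$time,
                            method = if (cell$pseudobulk == "seacell")
                              "SEACell" else cell$pseudobulk,
                            zero_mode = cell$zero_mode)
  } else {
    pb <- switch(cell$pseudobulk,
      time = collapse_median(study,
                             pseudobulk_by_time_sampling(study, seed = seed),
                             zero_mode = cell$zero_mode),
      leiden = collapse_median(study,
                               pseudobulk_by_clustering(study, seed = seed),
                               zero_mode = cell$zero_mode),
      seacell = pseudobulk_metacell(study, config$n_metacells, seed = seed))
    utils::write.table(pb$matrix, mpath, sep = "\t", quote = FALSE,
                       col.names = NA)
    utils::write.table(data.frame(pseudobulk_id = pb$pseudobulk_ids,
                                  time = pb$time_labels),
                       lpath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  add(mpath, "pseudobulk_matrix", as.list(cell))
  add(lpath, "pseudobulk_labels", as.list(cell))
  pb
}

pipeline_selection <- function(pb, strategy, k, cell, out, force, add) {
  dir.create(file.path(out, "selection"), showWarnings = FALSE)
  path <- file.path(out, "selection",
                    sprintf("%s_%s%d.txt", pb_cell_tag(cell), strategy, k))
  if (file.exists(path) && !force) {
    sel <- gene_selection(strategy, k, readLines(path))
  } else {
    sel <- switch(strategy,
                  var = select_top_variable(pb, k),
                  sum = select_top_expressed_union(pb, k),
                  deg = select_top_differential(pb, k))
    write_gene_selection(sel, path)
  }
  add(path, "gene_selection",
      list(pseudobulk = cell$pseudobulk, zero_mode = cell$zero_mode,
           selection = strategy, k = as.character(k)))
  sel
}

net_key <- function(prov, lab) {
  key <- paste(prov$pseudobulk,
               if (prov$zero_mode == "with_zeros") "w0" else "z",
               prov$selection, prov$k, prov$modeling, lab, prov$algorithm,
               prov$metric, sep = "_")
  gsub("[^A-Za-z0-9_.-]", "-", key)   # "n/a" and friends must stay one path component
}

pipeline_networks <- function(input, sel, config, prov0, lab, out, force,
                              add, seed) {
  dir.create(file.path(out, "networks"), showWarnings = FALSE)
  sims <- list()
  get_sim <- function(metric) {
    if (is.null(sims[[metric]]))
      sims[[metric]] <<- compute_similarity(input, sel, metric)
    sims[[metric]]
  }
  nets <- list()
  for (i in seq_len(nrow(config$combos))) {
    alg <- config$combos$algorithm[i]; met <- config$combos$metric[i]
    prov <- utils::modifyList(prov0, list(algorithm = alg, metric = met))
    path <- file.path(out, "networks", paste0(net_key(prov, lab), ".tsv"))
    if (file.exists(path) && !force) {
      net <- read_network(path)
    } else {
      sim <- get_sim(met)
      net <- switch(alg,
        aracne = do.call(aracne_network,
                         c(list(sim = sim, seed = seed, provenance = prov),
                           config$aracne)),
        clr = do.call(clr_network,
                      c(list(sim = sim, provenance = prov), config$clr)),
        wgcna = do.call(wgcna_network,
                        c(list(sim = sim, provenance = prov),
                          config$wgcna)))
      write_network(net, path)
    }
    add(path, "network", net$provenance)
    add(paste0(path, ".provenance.json"), "network_provenance",
        net$provenance)
    nets[[paste(alg, met, sep = "_")]] <- net
  }
  if ("consensus" %in% config$algorithms && length(nets) >= 2) {
    prov <- utils::modifyList(prov0, list(algorithm = "consensus",
                                          metric = "n/a"))
    path <- file.path(out, "networks", paste0(net_key(prov, lab), ".tsv"))
    net <- if (file.exists(path) && !force) read_network(path) else {
      cn <- consensus_network(unname(nets), provenance = prov)
      write_network(cn, path)
      cn
    }
    add(path, "network", net$provenance)
    add(paste0(path, ".provenance.json"), "network_provenance",
        net$provenance)
    nets[["consensus"]] <- net
  }
  nets
}

centrality_for_analysis <- c(gsea_deg = "degree", gsea_bet = "betweenness",
                             gsea_cc = "closeness")

pipeline_analyze <- function(net, sets, config, lab, out, force, add,
                             seeds) {
  dir.create(file.path(out, "analysis"), showWarnings = FALSE)
  key <- net_key(net$provenance, lab)
  cent <- node_centralities(net)
  cpath <- file.path(out, "analysis", paste0(key, ".centrality.tsv"))
  if (!file.exists(cpath) || force)
    utils::write.table(as.data.frame(cent), cpath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  add(cpath, "centrality_table", net$provenance)
  size <- network_size_metrics(net)
  assignments <- list(); enrichments <- list()
  for (analysis in intersect(config$analyses, names(centrality_for_analysis))) {
    metric <- centrality_for_analysis[[analysis]]
    epath <- file.path(out, "analysis", paste0(key, ".", analysis, ".tsv"))
    if (file.exists(epath) && !force) {
      res <- read_enrichment(epath)
    } else {
      ranking <- ranked_gene_list(cent$gene, cent[[metric]])
      res <- preranked_gsea(ranking, sets, n_perm = config$n_perm,
                            seed = seeds[["gsea"]],
                            provenance = utils::modifyList(
                              net$provenance, list(analysis = analysis)))
      write_enrichment(res, epath)
    }
    add(epath, "enrichment", utils::modifyList(net$provenance,
                                               list(analysis = analysis)))
    assignments[[analysis]] <- term_assignment(
      paste(key, analysis, sep = "."),
      utils::modifyList(net$provenance, list(analysis = analysis)),
      significant_terms(res))
    enrichments[[analysis]] <- res
  }
  communities <- NULL
  if ("community" %in% config$analyses) {
    communities <- detect_communities(net, resolution = config$resolution,
                                      seed = seeds[["community"]])
    ppath <- file.path(out, "analysis", paste0(key, ".communities.tsv"))
    if (!file.exists(ppath) || force)
      utils::write.table(as.data.frame(communities), ppath, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    add(ppath, "community_partition", net$provenance)
    epath <- file.path(out, "analysis", paste0(key, ".community.tsv"))
    if (file.exists(epath) && !force) {
      res <- read_enrichment(epath)
      terms <- significant_terms(res)
    } else {
      comm_sets <- suppressMessages(community_gene_sets(communities))
      terms <- character(); all_rows <- list()
      for (cid in names(comm_sets)) {
        res_c <- hypergeometric_ora(comm_sets[[cid]], net$genes, sets)
        res_c$community <- cid
        all_rows[[cid]] <- as.data.frame(res_c)
        terms <- union(terms, significant_terms(res_c))
      }
      res <- do.call(rbind, all_rows) %||%
        data.frame(term = character(), overlap = integer(),
                   size = integer(), p = numeric(), q = numeric(),
                   significant = logical(), community = character())
      utils::write.table(res, epath, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    add(epath, "enrichment", utils::modifyList(net$provenance,
                                               list(analysis = "community")))
    assignments[["community"]] <- term_assignment(
      paste(key, "community", sep = "."),
      utils::modifyList(net$provenance, list(analysis = "community")),
      terms)
  }
  list(assignments = assignments, centralities = cent, size = size,
       enrichments = enrichments, key = key, provenance = net$provenance)
}

read_enrichment <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) df$significant <- logical()
  enrichment_result(df)
}

pipeline_differential <- function(tp_results, sets, config, out, force,
                                  add, gsea_seed) {
  dir.create(file.path(out, "differential"), showWarnings = FALSE)
  out_assignments <- list()
  net_names <- Reduce(intersect, lapply(tp_results, names))
  for (nm in net_names) {
    per_tp <- lapply(tp_results, `[[`, nm)
    prov <- per_tp[[1]]$provenance
    if ("differential_terms" %in% config$analyses) {
      for (analysis in names(per_tp[[1]]$enrichments)) {
        res_list <- lapply(per_tp, function(r) r$enrichments[[analysis]])
        uniq <- differential_terms(res_list)
        for (tp in names(uniq)) {
          id <- paste(per_tp[[tp]]$key, analysis, "diffterms", sep = ".")
          out_assignments[[id]] <- term_assignment(
            id, utils::modifyList(prov,
                                  list(analysis = "differential_terms")),
            uniq[[tp]])
        }
        dpath <- file.path(out, "differential",
                           paste0(per_tp[[1]]$key, ".", analysis,
                                  ".unique_terms.tsv"))
        if (!file.exists(dpath) || force) {
          df <- do.call(rbind, lapply(names(uniq), function(tp)
            if (length(uniq[[tp]]))
              data.frame(time = tp, term = uniq[[tp]]) else NULL)) %||%
            data.frame(time = character(), term = character())
          utils::write.table(df, dpath, sep = "\t", quote = FALSE,
                             row.names = FALSE)
        }
        add(dpath, "differential_terms",
            utils::modifyList(prov, list(analysis = "differential_terms")))
      }
    }
    if ("differential_centrality" %in% config$analyses) {
      metrics <- unique(centrality_for_analysis[
        intersect(config$analyses, names(centrality_for_analysis))])
      if (!length(metrics)) metrics <- "degree"
      for (met in metrics) {
        changes <- centrality_rank_change(lapply(per_tp, `[[`,
                                                 "centralities"), met)
        res <- differential_centrality_gsea(changes, sets,
                                            n_perm = config$n_perm,
                                            seed = gsea_seed,
                                            provenance = utils::modifyList(
                                              prov,
                                              list(analysis = "differential_centrality")))
        dpath <- file.path(out, "differential",
                           paste0(per_tp[[1]]$key, ".diffcent_", met,
                                  ".tsv"))
        if (!file.exists(dpath) || force) write_enrichment(res, dpath)
        add(dpath, "differential_centrality",
            utils::modifyList(prov,
                              list(analysis = "differential_centrality")))
        id <- paste(per_tp[[1]]$key, "diffcent", met, sep = ".")
        out_assignments[[id]] <- term_assignment(
          id, utils::modifyList(prov,
                                list(analysis = "differential_centrality")),
          significant_terms(res))
      }
    }
  }
  out_assignments
}

pipeline_meta <- function(assignments, config, out, force, add) {
  dir.create(file.path(out, "meta"), showWarnings = FALSE)
  apath <- file.path(out, "meta", "term_assignments.jsonl")
  if (!file.exists(apath) || force)
    write_term_assignments(unname(assignments), apath)
  add(apath, "term_assignments")
  D <- jaccard_distance_matrix(unname(assignments))
  labels <- cluster_similarity_graph(D, resolution = config$resolution,
                                     seed = config$seed)
  lpath <- file.path(out, "meta", "clusters.tsv")
  if (!file.exists(lpath) || force)
    utils::write.table(data.frame(id = names(labels), cluster = labels),
                       lpath, sep = "\t", quote = FALSE, row.names = FALSE)
  add(lpath, "result_clusters")
  enr <- suppressMessages(
    parameter_overrepresentation(labels, unname(assignments)))
  epath <- file.path(out, "meta", "parameter_enrichment.tsv")
  if (!file.exists(epath) || force)
    utils::write.table(as.data.frame(enr), epath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  add(epath, "parameter_enrichment")
  invisible(NULL)
}
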