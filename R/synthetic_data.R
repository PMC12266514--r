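#' Describe a planted co-expression module
#'
#' A module is a disjoint set of genes that share a latent activity
#' factor in the cells of its active time points, producing correlated
#' expression there and background behaviour everywhere else.
#'
#' @param genes Integer indices (into the gene range) of member genes.
#' @param times Integer indices of the time points at which the module
#'   is active.
#' @param cor Target within-module latent correlation, in (0, 1].
#' @return A `module_spec` list.
#' @export
module_spec <- function(genes, times, cor) {
  stop_if_not(length(genes) >= 2, "a module needs at least 2 genes")
  stop_if_not(is.numeric(cor) && length(cor) == 1 && cor > 0 && cor <= 1,
              "module 'cor' must be in (0, 1]")
  structure(list(genes = sort(unique(as.integer(genes))),
                 times = sort(unique(as.integer(times))),
                 cor = as.numeric(cor)),
            class = "module_spec")
}

#' Configuration for the synthetic expression-study generator
#'
#' Defines the study conditions under which the whole pipeline is
#' exercised: cell and gene counts, number of time points, planted
#' co-expression modules, dropout (zero inflation) and per-cell
#' sequencing-depth variation.  Counts are drawn from a negative
#' binomial whose log-mean carries a shared latent factor per module
#' per cell; the factor enters through the bounded transform
#' \eqn{\sigma (2\Phi(z) - 1)} so the library-size contribution of
#' module genes stays finite (depth normalization would otherwise
#' couple background genes) while the median expression remains
#' informative under pseudo-bulk aggregation.
#'
#' @param n_cells Number of cells (default 2000).
#' @param n_genes Number of genes (default 1500).
#' @param n_timepoints Number of time points, between 2 and 4.
#' @param modules List of [module_spec()] objects with disjoint gene sets.
#' @param dropout_rate Probability in `[0, 1)` that an entry is zeroed
#'   independently after counting (default 0.05).
#' @param depth_dispersion Standard deviation of the per-cell log-normal
#'   library-size factor (default 0.3).
#' @param seed Integer seed; the generator is a pure function of the
#'   configuration including this seed.
#' @param signal_sd Log-scale standard deviation of the module latent
#'   signal (default 3).
#' @param base_noise_sd Log-scale biological noise for background genes
#'   (default 0.3).
#' @param active_shift Log-scale mean shift of module genes in their
#'   active time points (default 1), giving time-restricted modules a
#'   differential-expression signature as well as co-expression.
#' @param nb_size Negative-binomial size (inverse overdispersion,
#'   default 5).
#' @param base_meanlog Mean of the log-normal distribution of per-gene
#'   baseline means (default `log(5)`).
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(n_cells = 2000, n_genes = 1500, n_timepoints = 3,
                             modules = list(), dropout_rate = 0.05,
                             depth_dispersion = 0.3, seed = 1,
                             signal_sd = 3, base_noise_sd = 0.3,
                             active_shift = 1, nb_size = 5,
                             base_meanlog = log(5)) {
  stop_if_not(n_cells >= 1 && n_genes >= 1, "n_cells and n_genes must be positive")
  stop_if_not(n_timepoints >= 2 && n_timepoints <= 4,
              "n_timepoints must be in [2, 4]")
  stop_if_not(dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must be in [0, 1)")
  stop_if_not(depth_dispersion > 0, "depth_dispersion must be positive")
  modules <- lapply(modules, function(m) {
    if (!inherits(m, "module_spec")) m <- do.call(module_spec, m)
    if (any(m$genes < 1 | m$genes > n_genes))
      stop("module gene index out of gene range", call. = FALSE)
    if (any(m$times < 1 | m$times > n_timepoints))
      stop("module time index out of time-point range", call. = FALSE)
    m
  })
  all_genes <- unlist(lapply(modules, `[[`, "genes"))
  stop_if_not(!anyDuplicated(all_genes), "module gene sets must be disjoint")
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_timepoints = as.integer(n_timepoints), modules = modules,
                 dropout_rate = dropout_rate,
                 depth_dispersion = depth_dispersion, seed = as.integer(seed),
                 signal_sd = signal_sd, base_noise_sd = base_noise_sd,
                 active_shift = active_shift, nb_size = nb_size,
                 base_meanlog = base_meanlog),
            class = "synthetic_config")
}

#' Construct an expression study
#'
#' The raw input of the pipeline: a non-negative cells-by-genes matrix of
#' normalized expression with one time label per cell.
#'
#' @param matrix Non-negative numeric cells-by-genes matrix.
#' @param cell_ids,gene_ids Unique identifiers matching the matrix
#'   dimensions.
#' @param time_labels One categorical label per cell.
#' @param truth Optional generating `synthetic_config` (present for
#'   synthetic studies, `NULL` for real data).
#' @return An `expression_study` object.
#' @export
expression_study <- function(matrix, cell_ids, gene_ids, time_labels,
                             truth = NULL) {
  matrix <- as.matrix(matrix)
  stop_if_not(all(matrix >= 0), "expression values must be non-negative")
  stop_if_not(nrow(matrix) == length(cell_ids) &&
              ncol(matrix) == length(gene_ids),
              "id lengths must match matrix dimensions")
  stop_if_not(length(time_labels) == nrow(matrix),
              "one time label per cell required")
  stop_if_not(!anyDuplicated(cell_ids) && !anyDuplicated(gene_ids),
              "cell_ids and gene_ids must be unique")
  dimnames(matrix) <- list(as.character(cell_ids), as.character(gene_ids))
  structure(list(matrix = matrix, cell_ids = as.character(cell_ids),
                 gene_ids = as.character(gene_ids),
                 time_labels = as.character(time_labels), truth = truth),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d cells x %d genes, %d time points (%s)%s\n",
              nrow(x$matrix), ncol(x$matrix),
              length(unique(x$time_labels)),
              paste(sort(unique(x$time_labels)), collapse = ", "),
              if (is.null(x$truth)) "" else ", with generating truth"))
  invisible(x)
}

#' Generate a synthetic expression study with planted modules
#'
#' Latent module activities drive correlated negative-binomial counts for
#' module genes during their active time points; background genes are
#' independent given depth.  Entries are zeroed independently with
#' probability `dropout_rate`, then counts are normalized per cell to the
#' median library size and log1p-transformed, so values resemble the
#' normalized matrices the pipeline consumes.  Deterministic given the
#' configuration seed.
#'
#' @param config A [synthetic_config()] object.
#' @return An [expression_study()] whose `truth` field stores `config`.
#' @export
generate_expression_study <- function(config) {
  stop_if_not(inherits(config, "synthetic_config"),
              "config must be a synthetic_config")
  n <- config$n_cells; g <- config$n_genes; tps <- config$n_timepoints
  with_seed(config$seed, {
    tp <- rep(seq_len(tps), length.out = n)
    mu <- exp(rnorm(g, config$base_meanlog, 1))
    depth <- exp(rnorm(n, 0, config$depth_dispersion))
    loglam <- matrix(rnorm(n * g, 0, config$base_noise_sd), n, g)
    loglam <- sweep(loglam, 2, log(mu), "+")
    for (m in config$modules) {
      act <- tp %in% m$times
      z <- rnorm(n)                       # shared latent, one per cell
      e <- matrix(rnorm(n * length(m$genes)), n, length(m$genes))
      lat <- sqrt(m$cor) * z + sqrt(1 - m$cor) * e
      # bounded latent effect: keeps the library-size contribution of
      # module genes finite (no lognormal mean blow-up) while the
      # median expression stays informative, so the planted correlation
      # survives both depth normalization and median pseudobulking
      eff <- config$signal_sd * (2 * stats::pnorm(lat) - 1)
      loglam[act, m$genes] <- sweep(eff[act, , drop = FALSE], 2,
                                    log(mu[m$genes]) + config$active_shift,
                                    "+")
    }
    lam <- sweep(exp(loglam), 1, depth, "*")
    cnt <- matrix(rnbinom(n * g, mu = lam, size = config$nb_size), n, g)
    if (config$dropout_rate > 0)
      cnt[matrix(runif(n * g) < config$dropout_rate, n, g)] <- 0
    tot <- rowSums(cnt)
    scale <- ifelse(tot > 0, stats::median(tot) / pmax(tot, 1), 1)
    x <- log1p(sweep(cnt, 1, scale, "*"))
    expression_study(x,
                     cell_ids = sprintf("cell_%05d", seq_len(n)),
                     gene_ids = sprintf("g%05d", seq_len(g)),
                     time_labels = sprintf("t%d", tp),
                     truth = config)
  })
}

#' Generate a gene-set collection matching a synthetic study
#'
#' One gene set per planted module (exact membership) plus `n_extra`
#' random sets of sizes 10 to 200 drawn from the study's genes.
#'
#' @param study An [expression_study()] carrying generator truth.
#' @param n_extra Number of additional random sets.
#' @param seed Seed for the random sets; defaults to the study's seed.
#' @return A `gene_set_collection`.
#' @export
generate_gene_sets <- function(study, n_extra = 0,
                               seed = study$truth$seed %||% 1) {
  stop_if_not(inherits(study, "expression_study"), "study required")
  if (is.null(study$truth)) stop("study has no generating truth", call. = FALSE)
  mods <- study$truth$modules
  sets <- lapply(mods, function(m) study$gene_ids[m$genes])
  names(sets) <- sprintf("module_%d", seq_along(mods))
  if (n_extra > 0) {
    extra <- with_seed(seed, {
      lapply(seq_len(n_extra), function(i) {
        size <- sample(10:min(200, length(study$gene_ids)), 1)
        sort(sample(study$gene_ids, size))
      })
    })
    names(extra) <- sprintf("random_%03d", seq_len(n_extra))
    sets <- c(sets, extra)
  }
  gene_set_collection(sets, name = "synthetic",
                      descriptions = sub("_", " set ", names(sets)))
}

#' Generate a synthetic PPI network with planted intermediate paths
#'
#' A random background graph over the study genes plus `planted_paths`
#' length-2 paths seedA-intermediate-seedB, where the seeds belong to
#' planted modules and the intermediate does not.  Direct seedA-seedB
#' edges of planted pairs are excluded so the planted path is a shortest
#' path.
#'
#' @param study An [expression_study()] with truth containing at least
#'   one module when `planted_paths > 0`.
#' @param planted_paths Number of planted length-2 paths (>= 0).
#' @param mean_degree Expected background degree (default 3; 0 gives a
#'   graph holding only the planted paths).
#' @param seed Seed; defaults to the study's seed.
#' @return A `ppi_network` whose `truth` records seeds and intermediates.
#' @export
generate_ppi_network <- function(study, planted_paths = 0, mean_degree = 3,
                                 seed = study$truth$seed %||% 1) {
  stop_if_not(planted_paths >= 0, "planted_paths must be >= 0")
  ids <- study$gene_ids
  module_genes <- if (!is.null(study$truth))
    ids[unlist(lapply(study$truth$modules, `[[`, "genes"))] else character()
  if (planted_paths > 0 && length(module_genes) < 2)
    stop("planted paths require a study with planted modules", call. = FALSE)
  with_seed(seed, {
    non_module <- setdiff(ids, module_genes)
    truth <- NULL
    planted_edges <- character()
    forbidden <- character()
    if (planted_paths > 0) {
      stop_if_not(length(non_module) >= planted_paths,
                  "not enough non-module genes for planted intermediates")
      inter <- sample(non_module, planted_paths)
      pairs <- t(vapply(seq_len(planted_paths),
                        function(i) sample(module_genes, 2), character(2)))
      truth <- data.frame(seed_a = pmin(pairs[, 1], pairs[, 2]),
                          seed_b = pmax(pairs[, 1], pairs[, 2]),
                          intermediate = inter, stringsAsFactors = FALSE)
      planted_edges <- c(edge_key(truth$seed_a, truth$intermediate),
                         edge_key(truth$intermediate, truth$seed_b))
      forbidden <- edge_key(truth$seed_a, truth$seed_b)
    }
    n <- length(ids)
    p <- if (n > 1) min(1, mean_degree / (n - 1)) else 0
    bg <- character()
    if (p > 0) {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- runif(nrow(idx)) < p
      bg <- edge_key(ids[idx[keep, 1]], ids[idx[keep, 2]])
    }
    keys <- setdiff(unique(c(planted_edges, bg)), forbidden)
    parts <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    edges <- if (length(keys))
      data.frame(from = parts[, 1], to = parts[, 2], stringsAsFactors = FALSE)
    else data.frame(from = character(), to = character())
    ppi_network(edges, nodes = ids, truth = truth)
  })
}

# ---- writers / readers ------------------------------------------------

#' Write an expression study to disk
#'
#' Either a sparse MTX triplet (`matrix.mtx`, `cells.tsv`, `genes.tsv`)
#' or a dense TSV (`matrix.tsv`, `cells.tsv`, `genes.tsv`), plus a
#' `truth.json` sidecar when generator truth is present.
#'
#' @param study An [expression_study()].
#' @param dir Output directory (created if missing).
#' @param format `"mtx"` or `"tsv"`.
#' @return `dir`, invisibly.
#' @export
write_expression_study <- function(study, dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- data.frame(cell_id = study$cell_ids, time = study$time_labels)
  utils::write.table(cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = study$gene_ids),
                     file.path(dir, "genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(study$matrix, sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
  } else {
    utils::write.table(study$matrix, file.path(dir, "matrix.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
  }
  if (!is.null(study$truth)) {
    truth <- study$truth
    truth$modules <- lapply(truth$modules, unclass)
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read an expression study written by [write_expression_study()]
#' @param dir Directory holding the study files.
#' @return An [expression_study()]; truth is restored when present.
#' @export
read_expression_study <- function(dir) {
  cells <- utils::read.delim(file.path(dir, "cells.tsv"),
                             colClasses = "character")
  genes <- utils::read.delim(file.path(dir, "genes.tsv"),
                             colClasses = "character")
  mtx_path <- file.path(dir, "matrix.mtx")
  m <- if (file.exists(mtx_path)) as.matrix(Matrix::readMM(mtx_path))
       else as.matrix(utils::read.delim(file.path(dir, "matrix.tsv"),
                                        row.names = 1, check.names = FALSE))
  truth <- NULL
  tpath <- file.path(dir, "truth.json")
  if (file.exists(tpath)) {
    raw <- jsonlite::read_json(tpath, simplifyVector = TRUE)
    mods <- raw$modules
    if (is.data.frame(mods)) mods <- split(mods, seq_len(nrow(mods)))
    raw$modules <- lapply(mods, function(m)
      module_spec(unlist(m$genes), unlist(m$times), m$cor))
    truth <- do.call(synthetic_config, raw[setdiff(names(raw), character())])
  }
  expression_study(m, cells$cell_id, genes$gene_id, cells$time, truth = truth)
}

#' Frozen configuration of the planted-structure recovery study
#'
#' The reference synthetic study used to validate end-to-end recovery:
#' 2000 cells, 400 genes, 3 time points and three 25-gene modules at
#' correlation 0.9, each active at exactly one time point.  Module
#' activity restricted in time is the planted structure this pipeline
#' is built to detect: it carries both a co-expression and a
#' differential-expression signature across time points.
#'
#' @param seed Integer seed.
#' @return A [synthetic_config()].
#' @export
recovery_study_config <- function(seed = 1) {
  synthetic_config(n_cells = 2000, n_genes = 400, n_timepoints = 3,
                   modules = list(module_spec(1:25, 1, 0.9),
                                  module_spec(26:50, 2, 0.9),
                                  module_spec(51:75, 3, 0.9)),
                   seed = seed)
}
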