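# Shared small fixtures built in code at test time.

small_study <- function(seed = 7, n_cells = 300, n_genes = 120,
                        modules = list(module_spec(1:15, 1:3, 0.9),
                                       module_spec(16:30, 2, 0.85))) {
  generate_expression_study(synthetic_config(
    n_cells = n_cells, n_genes = n_genes, n_timepoints = 3,
    modules = modules, seed = seed))
}

small_pb <- function(study = small_study(), seed = 3) {
  collapse_median(study,
                  pseudobulk_by_time_sampling(study, n_clusters = 4,
                                              cluster_size = 30,
                                              seed = seed),
                  zero_mode = "ignore_zeros")
}

# pseudobulk matrix wrapper around an arbitrary samples x genes matrix
pb_from_matrix <- function(m, time_labels = rep("t1", nrow(m))) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  pseudobulk_matrix(m, sprintf("pb%03d", seq_len(nrow(m))), colnames(m),
                    time_labels, method = "none", zero_mode = "n/a")
}

# similarity_matrix wrapper around an arbitrary symmetric value matrix
sim_from_matrix <- function(v, metric = "mi", data = NULL, bins = NULL) {
  genes <- if (is.null(colnames(v))) sprintf("g%03d", seq_len(ncol(v)))
           else colnames(v)
  dimnames(v) <- list(genes, genes)
  structure(list(genes = genes, values = v, metric = metric, data = data,
                 bins = bins), class = "similarity_matrix")
}
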