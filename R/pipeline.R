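#' Pipeline run configuration
#'
#' Collects every knob of the workflow. Defaults mirror the recommended
#' practice for ~50-gene panels: alpha 0.1, 300 cells (plate-based data; use
#' 600 for droplet-based), k = 50 feature genes, conditioning sets up to
#' size 3.
#'
#' @param case_path path to the case expression matrix (CSV/TSV/MTX).
#' @param control_path,tf_path,spike_matrix_path,spike_edges_path optional
#'   companion inputs.
#' @param format input format tag (`"csv"`, `"tsv"`, `"mtx"`).
#' @param genes_path,barcodes_path MTX companion files.
#' @param input_transform transform state of the stored values
#'   (`"raw"`, `"log2"`, `"zscore"`).
#' @param transform `"none"`, `"log2"`, or `"zscore"` applied after loading.
#' @param filter named list passed to [filter_spec()] (`NULL` for the
#'   packaged defaults when a control is present, otherwise no filtering).
#' @param response_genes response gene ids for feature selection (`NULL`
#'   skips selection and uses all filtered genes).
#' @param fs_method `"bahsic"`, `"tree"`, or `"both"` (union of the two).
#' @param k number of feature genes.
#' @param n_cells cells to sub-sample (`NULL` keeps all).
#' @param sampling `"random"` or `"first"`.
#' @param ci_method CI test tag (see [ci_tester()]).
#' @param alpha CI significance cut-off in (0, 1).
#' @param max_cond_size largest conditioning-set size.
#' @param B permutation count for `.perm` CI tests.
#' @param n_runs number of repeated inference runs for the stability report.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir output directory for artifacts.
#' @return A validated `run_config` list.
#' @export
run_config <- function(case_path, control_path = NULL, tf_path = NULL,
                       spike_matrix_path = NULL, spike_edges_path = NULL,
                       format = "csv", genes_path = NULL, barcodes_path = NULL,
                       input_transform = "raw", transform = "none",
                       filter = NULL,
                       response_genes = NULL, fs_method = "bahsic", k = 50L,
                       n_cells = NULL, sampling = "random",
                       ci_method = "dcc.gamma", alpha = 0.1,
                       max_cond_size = 3L, B = 100L, n_runs = 1L, seed = 1L,
                       out_dir = ".") {
  stopifnot_scalar_number(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  for (p in c(case_path, control_path, tf_path, spike_matrix_path,
              spike_edges_path, genes_path, barcodes_path)) {
    if (!is.null(p) && !file.exists(p))
      validation_error("input path does not exist: ", p)
  }
  if (!fs_method %in% c("bahsic", "tree", "both"))
    validation_error("unknown feature-selection method: ", fs_method)
  if (!transform %in% c("none", "log2", "zscore"))
    validation_error("unknown transform: ", transform)
  if (!input_transform %in% c("raw", "log2", "zscore"))
    validation_error("unknown input_transform: ", input_transform)
  cfg <- list(case_path = case_path, control_path = control_path,
              tf_path = tf_path, spike_matrix_path = spike_matrix_path,
              spike_edges_path = spike_edges_path, format = format,
              genes_path = genes_path, barcodes_path = barcodes_path,
              input_transform = input_transform, transform = transform,
              filter = filter,
              response_genes = response_genes, fs_method = fs_method,
              k = as.integer(k), n_cells = n_cells, sampling = sampling,
              ci_method = ci_method, alpha = alpha,
              max_cond_size = as.integer(max_cond_size), B = as.integer(B),
              n_runs = as.integer(n_runs), seed = as.integer(seed),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a flat key=value file
#'
#' Lines are `key = value`; `#` starts a comment. List-valued keys
#' (`response_genes`) are comma-separated; filter thresholds use the
#' `filter.<name>` prefix.
#'
#' @param path config file path.
#' @param overrides named list applied on top of the file values.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) parse_error("malformed config line: ", ln)
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = "="))
    kv[[key]] <- val
  }
  kv[names(overrides)] <- overrides
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  filt_keys <- grep("^filter\\.", names(kv), value = TRUE)
  filter <- NULL
  if (length(filt_keys)) {
    filter <- lapply(kv[filt_keys], as.numeric)
    names(filter) <- sub("^filter\\.", "", filt_keys)
  }
  rg <- kv$response_genes
  if (!is.null(rg) && is.character(rg))
    rg <- trimws(strsplit(rg, ",", fixed = TRUE)[[1L]])
  run_config(
    case_path = kv$case_path, control_path = kv$control_path,
    tf_path = kv$tf_path, spike_matrix_path = kv$spike_matrix_path,
    spike_edges_path = kv$spike_edges_path,
    format = kv$format %||% "csv", genes_path = kv$genes_path,
    barcodes_path = kv$barcodes_path,
    input_transform = kv$input_transform %||% "raw",
    transform = kv$transform %||% "none",
    filter = filter, response_genes = rg,
    fs_method = kv$fs_method %||% "bahsic", k = num(kv$k) %||% 50L,
    n_cells = num(kv$n_cells), sampling = kv$sampling %||% "random",
    ci_method = kv$ci_method %||% "dcc.gamma",
    alpha = num(kv$alpha) %||% 0.1,
    max_cond_size = num(kv$max_cond_size) %||% 3L,
    B = num(kv$B) %||% 100L, n_runs = num(kv$n_runs) %||% 1L,
    seed = num(kv$seed) %||% 1L, out_dir = kv$out_dir %||% ".")
}

# Prepend a comment line carrying the config hash to a text artifact.
embed_hash <- function(path, hash) {
  txt <- readLines(path)
  writeLines(c(paste0("# config_hash=", hash), txt), path)
  invisible(path)
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

#' Run the full causal-discovery pipeline
#'
#' Chains load -> transform -> attribute computation -> gene filtering ->
#' feature selection -> cell sub-sampling -> PC inference -> sign annotation,
#' with optional repeated runs (stability report) and spike-in QC. All
#' artifacts (edge list TSV + GML, attribute table, feature ranking, report
#' JSON, log) are written to the configured output directory and embed the
#' config hash.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the inferred `network`, the `report`, and
#'   the artifact `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hashed <- unclass(config)
  hashed$out_dir <- NULL  # analysis fingerprint, not output location
  cfg_hash <- object_hash(hashed)
  log_path <- file.path(config$out_dir, "run.log")
  logc <- file(log_path, "w")
  on.exit(close(logc), add = TRUE)
  pipeline_log(logc, "config hash ", cfg_hash)
  for (nm in names(config)) {
    val <- config[[nm]]
    if (!is.null(val) && !is.list(val))
      pipeline_log(logc, "param ", nm, " = ", paste(val, collapse = ","))
  }

  case <- load_expression(config$case_path, format = config$format,
                          genes_path = config$genes_path,
                          barcodes_path = config$barcodes_path,
                          transform = config$input_transform)
  if (config$transform != "none")
    case <- transform_expression(case, config$transform)
  control <- NULL
  if (!is.null(config$control_path)) {
    control <- load_expression(config$control_path, format = config$format,
                               transform = config$input_transform)
    if (config$transform != "none")
      control <- transform_expression(control, config$transform)
  }
  tf_list <- if (!is.null(config$tf_path)) readLines(config$tf_path) else NULL
  attrs <- compute_gene_attributes(case, control, tf_list)
  attrs_path <- file.path(config$out_dir, "gene_attributes.tsv")
  write_gene_attributes(attrs, attrs_path)
  embed_hash(attrs_path, cfg_hash)
  pipeline_log(logc, "attributes computed for ", nrow(attrs), " genes")

  genes <- attrs$gene
  if (!is.null(config$filter)) {
    spec <- do.call(filter_spec, config$filter)
    genes <- filter_genes(attrs, spec)
    pipeline_log(logc, "filter retained ", length(genes), " genes")
  }
  ranking_path <- NULL
  if (!is.null(config$response_genes)) {
    sub <- case
    sub$values <- case$values[unique(c(genes, config$response_genes)), ,
                              drop = FALSE]
    fs_seed <- derive_seed(config$seed, 11L)
    ranking <- switch(config$fs_method,
      bahsic = bahsic_select(sub, config$response_genes, k = config$k,
                             seed = fs_seed),
      tree = tree_importance_select(sub, config$response_genes, k = config$k,
                                    seed = fs_seed),
      both = {
        a <- bahsic_select(sub, config$response_genes, k = config$k,
                           seed = fs_seed)
        b <- tree_importance_select(sub, config$response_genes, k = config$k,
                                    seed = fs_seed)
        u <- combine_rankings(a, b, k_total = config$k)
        ranking_result(u, rep(NA_real_, length(u)), "bahsic+tree",
                       config$response_genes)
      })
    ranking_path <- file.path(config$out_dir, "feature_ranking.tsv")
    write_feature_ranking(ranking, ranking_path)
    embed_hash(ranking_path, cfg_hash)
    genes <- unique(c(config$response_genes, ranking$genes))
    pipeline_log(logc, "feature selection kept ", length(genes), " genes")
  }
  work <- case
  work$values <- case$values[genes, , drop = FALSE]

  spike <- NULL
  spike_genes <- character(0)
  if (!is.null(config$spike_matrix_path)) {
    spike <- read_spike_in(config$spike_matrix_path, config$spike_edges_path,
                           transform = work$transform)
    work <- integrate_spike_in(work, spike, seed = derive_seed(config$seed, 21L))
    spike_genes <- grep(paste0("^", spike$prefix), gene_ids(work),
                        value = TRUE)
    pipeline_log(logc, "integrated ", length(spike_genes), " spike-in genes")
  }
  if (!is.null(config$n_cells) && config$n_cells < ncol(work$values)) {
    work <- sample_cells(work, config$n_cells, mode = config$sampling,
                         seed = derive_seed(config$seed, 31L))
    pipeline_log(logc, "sub-sampled ", ncol(work$values), " cells")
  }

  data <- t(work$values)
  nets <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    tester <- ci_tester(config$ci_method, B = config$B,
                        seed = derive_seed(config$seed, 41L, r))
    net <- pc_infer(data, node_ids = colnames(data), tester = tester,
                    alpha = config$alpha,
                    max_cond_size = config$max_cond_size)
    nets[[r]] <- annotate_edge_signs(net, data)
    pipeline_log(logc, "run ", r, ": ", nrow(nets[[r]]$edges), " edges")
  }
  names(nets) <- paste0("run", seq_along(nets))
  network <- nets[[1L]]

  report <- list(config_hash = cfg_hash, ci_method = config$ci_method,
                 alpha = config$alpha, n_genes = length(gene_ids(work)),
                 n_cells = ncol(work$values),
                 n_edges = nrow(network$edges))
  if (config$n_runs >= 2L) {
    stab <- edge_stability(nets)
    stab_path <- file.path(config$out_dir, "stability.tsv")
    utils::write.table(stab$summary, stab_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    embed_hash(stab_path, cfg_hash)
    report$stability <- stab$summary
    cons <- consensus_network(nets)
    cons_path <- file.path(config$out_dir, "consensus_edges.tsv")
    write_edge_list(cons, cons_path)
    embed_hash(cons_path, cfg_hash)
    report$consensus_edges <- nrow(cons$edges)
    report$tpr_vs_consensus <- vapply(nets, tpr_vs_consensus, numeric(1L),
                                      consensus = cons)
  }
  if (length(spike_genes) > 0L) {
    exp_edges <- NULL
    if (!is.null(spike$expected_edges)) {
      exp_edges <- spike$expected_edges
      exp_edges$gene_a <- paste0(spike$prefix, exp_edges$gene_a)
      exp_edges$gene_b <- paste0(spike$prefix, exp_edges$gene_b)
    }
    report$spike_in <- spike_separation_report(network, spike_genes,
                                               exp_edges)
  }

  edges_path <- file.path(config$out_dir, "edges.tsv")
  write_edge_list(network, edges_path)
  embed_hash(edges_path, cfg_hash)
  gml_path <- file.path(config$out_dir, "network.gml")
  write_gml(network, gml_path)
  embed_hash(gml_path, cfg_hash)
  report_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  pipeline_log(logc, "wrote ", edges_path)
  invisible(list(network = network, report = report,
                 paths = list(edges = edges_path, attributes = attrs_path,
                              ranking = ranking_path, report = report_path,
                              log = log_path)))
}
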