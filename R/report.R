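# Metric table assembly, direction-aware normalization, composite ranking,
# and the one-command benchmark runner that chains all stages on fixtures or
# user-supplied containers.

#' Build a MetricReport from long rows
#'
#' @param rows data.frame with columns `method`, `dataset`, `task`,
#'   `metric`, `value`, `direction` (`"higher"` or `"lower"`).
#' @param provenance optional named list stored alongside (seed, config
#'   hash, versions).
#' @return A `MetricReport`.
#' @export
metric_report <- function(rows, provenance = list()) {
  needed <- c("method", "dataset", "task", "metric", "value", "direction")
  assert_that(all(needed %in% names(rows)),
              paste("rows must have columns:", paste(needed, collapse = ", ")))
  assert_that(all(rows$direction %in% c("higher", "lower")),
              "direction must be 'higher' or 'lower'")
  structure(list(rows = as.data.frame(rows), provenance = provenance),
            class = "MetricReport")
}

#' @export
print.MetricReport <- function(x, ...) {
  cat(sprintf("MetricReport: %d rows, %d methods, %d datasets, %d metrics\n",
              nrow(x$rows), length(unique(x$rows$method)),
              length(unique(x$rows$dataset)),
              length(unique(x$rows$metric))))
  invisible(x)
}

#' Normalize metric columns and rank methods by composite score
#'
#' Direction transforms orient every value higher-is-better (lower-is-better
#' metrics are negated; the printed 1-minus transforms of the spatial
#' metrics are applied upstream at computation time). Each (dataset, metric)
#' column is divided by its maximum when that maximum is positive, so the
#' best method scores 1; columns whose maximum is <= 0 are min-max rescaled
#' and flagged. The composite score is the unweighted mean of normalized
#' values per method (weights configurable), and methods are ranked by
#' descending composite with alphabetical tie-breaks. Negative raw metrics
#' survive normalization as negative normalized values.
#'
#' @param report A [metric_report()].
#' @param weights optional named numeric vector of per-metric weights.
#' @return list with `report` (rows plus `transformed`, `normalized`,
#'   `rescaled` columns), `ranking` (data.frame: method, composite, rank),
#'   `dropped` (all-missing metric columns removed, with a warning).
#' @export
normalize_and_rank <- function(report, weights = NULL) {
  stopifnot(inherits(report, "MetricReport"))
  rows <- report$rows
  assert_that(nrow(rows) >= 1, "report is empty")
  rows$transformed <- ifelse(rows$direction == "lower", -rows$value,
                             rows$value)
  rows$normalized <- NA_real_
  rows$rescaled <- FALSE
  dropped <- character()
  for (key in unique(paste(rows$dataset, rows$metric, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sel <- rows$dataset == parts[1] & rows$metric == parts[2]
    v <- rows$transformed[sel]
    if (all(is.na(v))) {
      warning(sprintf("metric '%s' on '%s' is all-missing: dropped",
                      parts[2], parts[1]))
      dropped <- c(dropped, key)
      rows <- rows[!sel, , drop = FALSE]
      next
    }
    mx <- max(v, na.rm = TRUE)
    if (mx > 0) {
      rows$normalized[sel] <- v / mx
    } else {
      mn <- min(v, na.rm = TRUE)
      rows$normalized[sel] <- if (mx == mn) 1 else (v - mn) / (mx - mn)
      rows$rescaled[sel] <- TRUE
    }
  }
  w_of <- function(metric) {
    if (is.null(weights)) 1 else weights[metric] %||% 1
  }
  comp <- vapply(sort(unique(rows$method)), function(m) {
    sel <- rows$method == m & !is.na(rows$normalized)
    w <- vapply(rows$metric[sel], w_of, numeric(1))
    sum(rows$normalized[sel] * w) / sum(w)
  }, numeric(1))
  ranking <- data.frame(method = names(comp), composite = unname(comp),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$composite, ranking$method), , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  list(report = rows, ranking = ranking, dropped = dropped)
}

#' Zero-shot metric panel for one embedding
#'
#' Builds the kNN graph, runs unified clustering to the annotated cell-type
#' count, and computes every applicable clustering/embedding/batch metric.
#'
#' @param emb An [embedding_set()].
#' @param ann A [cell_annotations()].
#' @param cfg A [batch_metric_config()].
#' @param k_graph kNN size for the clustering graph (default 15).
#' @param seed integer for the clustering heuristic.
#' @return named list of metric values; batch metrics are present only when
#'   batch labels are.
#' @export
zero_shot_metrics <- function(emb, ann, cfg = batch_metric_config(),
                              k_graph = 15, seed = 0L) {
  n <- length(emb$cell_ids)
  graph <- build_neighbor_graph(emb, k = min(max(k_graph, cfg$k_lisi,
                                                 cfg$k_kbet), n - 1L))
  clust <- unified_clustering(graph, n_target = length(unique(ann$cell_type)),
                              seed = seed)
  pa <- partition_agreement(as_partition(ann$cell_type), clust)
  out <- c(pa, list(
    asw = silhouette_label(emb, ann$cell_type),
    acc_knn = knn_accuracy(emb, ann$cell_type, cfg),
    gc = graph_connectivity(emb, ann$cell_type, cfg)
  ))
  lisi <- lisi_scores(emb, ann$cell_type, batch = ann$batch, cfg = cfg,
                      graph = graph)
  out$clisi_score <- lisi$clisi_score
  if (!is.null(ann$batch)) {
    out$ilisi_score <- lisi$ilisi_score
    out$bras <- bras(emb, ann$cell_type, ann$batch)
    out$kbet <- kbet(emb, ann$batch, cfg, graph = graph)
  }
  out
}

#' Spatial metric panel for one labeling
#'
#' @param counts A [count_matrix()] (markers + autocorrelation need counts).
#' @param ann A [cell_annotations()] with `spatial_xy`.
#' @param domains predicted domain labels (default: `ann$cell_type`).
#' @param cfg A [spatial_config()].
#' @param neighbors optional explicit spatial neighbor list.
#' @return named list: `moran_score`, `geary_score`, `chaos_score`,
#'   `pas_score` (all oriented higher-is-better).
#' @export
spatial_metric_panel <- function(counts, ann, domains = NULL,
                                 cfg = spatial_config(), neighbors = NULL) {
  assert_that(!is.null(ann$spatial_xy), "annotations lack spatial coordinates")
  domains <- domains %||% ann$cell_type
  ac <- spatial_autocorrelation(counts, domains, ann$spatial_xy, cfg,
                                neighbors = neighbors)
  list(moran_score = ac$moran_score,
       geary_score = ac$geary_score,
       chaos_score = as.numeric(chaos_score(ann$spatial_xy, domains)),
       pas_score = as.numeric(pas_score(ann$spatial_xy, domains, cfg,
                                        neighbors = neighbors)))
}

resolve_method_embedding <- function(d, method) {
  switch(method,
    embedding = {
      assert_that(!is.null(d$embedding),
                  "method 'embedding' needs an embedding in the dataset")
      d$embedding
    },
    expression = {
      assert_that(!is.null(d$counts), "method 'expression' needs counts")
      X <- if (d$counts$assay == "logexpr") d$counts$counts else
        lognorm(d$counts$counts)
      embedding_set(d$counts$cell_ids, X)
    },
    hvg_pca = {
      assert_that(!is.null(d$counts), "method 'hvg_pca' needs counts")
      split <- split_assignment(train_ids = d$counts$cell_ids,
                                test_ids = character(), seed = 0L)
      hvg_pca_embed(d$counts, split,
                    n_hvg = min(2000L, length(d$counts$gene_ids)),
                    n_pc = min(50L, length(d$counts$cell_ids) - 1L))
    },
    stop(sprintf("unknown method '%s'", method))
  )
}

build_config_dataset <- function(ds_cfg, seed) {
  if (!is.null(ds_cfg$path)) return(load_dataset(ds_cfg$path))
  fx <- ds_cfg$fixture
  assert_that(!is.null(fx), "dataset entry needs a 'path' or a 'fixture'")
  kind <- fx$kind %||% "mixture"
  if (kind == "mixture") {
    spec <- mixture_spec(
      n_cells = fx$n_cells %||% 600, n_types = fx$n_types %||% 3,
      n_batches = fx$n_batches %||% 1, dim = fx$dim %||% 16,
      type_separation = fx$type_separation %||% 8,
      batch_shift = fx$batch_shift %||% 0,
      seed = fx$seed %||% seed)
    mix <- make_mixture_embeddings(spec)
    dataset(mix$annotations, embedding = mix$embedding)
  } else if (kind == "spatial") {
    sp <- make_spatial_fixture(
      grid_rows = fx$grid_rows %||% 12, grid_cols = fx$grid_cols %||% 12,
      domain_layout = fx$domain_layout %||% "stripes",
      n_domains = fx$n_domains %||% 2,
      n_marker_genes_per_domain = fx$n_marker_genes_per_domain %||% 10,
      noise = fx$noise %||% 0, seed = fx$seed %||% seed)
    out <- dataset(sp$annotations, counts = sp$counts)
    attr(out, "rook_neighbors") <- sp$rook_neighbors
    out
  } else {
    stop(sprintf("unknown fixture kind '%s'", kind))
  }
}

read_benchmark_config <- function(config) {
  if (is.list(config)) return(config)
  if (grepl("\\.ya?ml$", config) && requireNamespace("yaml", quietly = TRUE)) {
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  }
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12g", x))
}

write_report_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full benchmark described by a config
#'
#' The config (YAML or JSON file, or an R list) names datasets (paths or
#' fixture specs), the embedding methods to score on each, and the tasks to
#' run (`zero_shot`, `spatial`, `few_shot`). Each stage failure is recorded
#' per (method, dataset, task) and the run continues. Outputs (a long
#' MetricReport TSV, a ranking TSV, a JSON report and a run log with the
#' config hash and resolved defaults) are byte-reproducible given identical
#' config and seeds: timestamps only appear in the log.
#'
#' @param config path to a YAML/JSON config, or an equivalent list.
#' @param out_dir output directory (default: the config's `out_dir`).
#' @return invisibly, a list with `report` (normalized MetricReport rows),
#'   `ranking`, `failures`, `files`.
#' @export
run_benchmark <- function(config, out_dir = NULL) {
  cfg <- read_benchmark_config(config)
  seed <- cfg$seed %||% 0L
  out_dir <- out_dir %||% cfg$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tasks <- cfg$tasks %||% c("zero_shot")
  rows <- list()
  failures <- list()
  notices <- character()
  add_rows <- function(method, ds_name, task, metrics, lower = character()) {
    for (nm in names(metrics)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        method = method, dataset = ds_name, task = task, metric = nm,
        value = as.numeric(metrics[[nm]]),
        direction = if (nm %in% lower) "lower" else "higher",
        stringsAsFactors = FALSE)
    }
  }
  for (ds_cfg in cfg$datasets) {
    ds_name <- ds_cfg$name %||% "dataset"
    d <- build_config_dataset(ds_cfg, seed)
    methods <- unlist(ds_cfg$methods) %||% "embedding"
    # a dataset entry may restrict the global task list
    ds_tasks <- intersect(tasks, unlist(ds_cfg$tasks) %||% tasks)
    for (method in methods) {
      emb <- tryCatch(resolve_method_embedding(d, method), error = identity)
      if (inherits(emb, "error")) {
        failures[[length(failures) + 1L]] <- list(
          method = method, dataset = ds_name, task = "embedding",
          error = conditionMessage(emb))
        next
      }
      if ("zero_shot" %in% ds_tasks) {
        res <- tryCatch(
          zero_shot_metrics(emb, d$annotations,
                            cfg = batch_metric_config(seed = seed),
                            seed = seed),
          error = identity)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <- list(
            method = method, dataset = ds_name, task = "zero_shot",
            error = conditionMessage(res))
        } else {
          add_rows(method, ds_name, "zero_shot", res)
        }
      }
      if ("spatial" %in% ds_tasks) {
        if (is.null(d$annotations$spatial_xy) || is.null(d$counts)) {
          notices <- c(notices, sprintf(
            "spatial task skipped for %s/%s: no spatial coordinates or counts",
            ds_name, method))
        } else {
          res <- tryCatch({
            graph <- build_neighbor_graph(emb, k = 15)
            clust <- unified_clustering(
              graph, n_target = length(unique(d$annotations$cell_type)),
              seed = seed)
            spatial_metric_panel(d$counts, d$annotations,
                                 domains = clust$labels,
                                 neighbors = attr(d, "rook_neighbors"))
          }, error = identity)
          if (inherits(res, "error")) {
            failures[[length(failures) + 1L]] <- list(
              method = method, dataset = ds_name, task = "spatial",
              error = conditionMessage(res))
          } else {
            add_rows(method, ds_name, "spatial", res)
          }
        }
      }
      if ("few_shot" %in% ds_tasks) {
        fs <- cfg$few_shot %||% list()
        res <- tryCatch({
          eps <- sample_episodes(
            d$annotations, n_way = fs$n_way %||% 5,
            k_shot = fs$k_shot %||% 1, n_trials = fs$n_trials %||% 20,
            query_per_class = fs$query_per_class %||% 50, seed = seed)
          evaluate_episodes(emb, d$annotations, eps)$mean
        }, error = identity)
        if (inherits(res, "error")) {
          failures[[length(failures) + 1L]] <- list(
            method = method, dataset = ds_name, task = "few_shot",
            error = conditionMessage(res))
        } else {
          add_rows(method, ds_name, "few_shot", as.list(res))
        }
      }
    }
  }
  assert_that(length(rows) > 0, "no metrics were produced")
  report <- metric_report(
    do.call(rbind, rows),
    provenance = list(config_hash = config_hash(cfg), seed = seed,
                      package_version = as.character(
                        utils::packageVersion("scembedeval"))))
  nr <- normalize_and_rank(report)
  files <- c(report = file.path(out_dir, "report_long.tsv"),
             ranking = file.path(out_dir, "ranking.tsv"),
             json = file.path(out_dir, "report.json"),
             log = file.path(out_dir, "run_log.json"))
  write_report_tsv(nr$report, files["report"])
  write_report_tsv(nr$ranking, files["ranking"])
  jsonlite::write_json(
    list(report = nr$report, ranking = nr$ranking,
         provenance = report$provenance),
    files["json"], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(
    list(provenance = report$provenance, tasks = tasks,
         failures = failures, notices = notices,
         timestamp = format(Sys.time(), tz = "UTC")),
    files["log"], auto_unbox = TRUE)
  if (length(notices)) message(paste(notices, collapse = "\n"))
  invisible(list(report = nr$report, ranking = nr$ranking,
                 failures = failures, files = files))
}
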