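#' Configuration for an end-to-end pipeline run
#'
#' Collects the file paths and thresholds of a full run: per-dataset mRNA
#' and miRNA expression with group annotations, the target map, optional
#' gene-set, interaction-network and marker inputs, and the screening
#' thresholds. The correlation step of the ceRNA screen runs within ONE
#' designated dataset (`corr_dataset`), with case and control samples
#' pooled; the cohorts are disjoint, so cross-dataset pooling is refused by
#' construction.
#'
#' @param mrna_paths,mirna_paths,groups_paths Character vectors (one entry
#'   per dataset, >= 2 datasets) of expression and annotation TSVs.
#' @param targets_path Target map TSV.
#' @param out_dir Output directory.
#' @param gmt_path,ppi_path,markers_path Optional inputs for enrichment,
#'   hub ranking and single-cell marker intersection.
#' @param p_max,lfc_min DE cutoffs (strict `p < p_max`, `|log2FC| >
#'   lfc_min`).
#' @param alpha Per-condition level of the ceRNA screen.
#' @param min_shared Minimum shared-miRNA count for candidate pairs.
#' @param top_k Number of hub genes to flag.
#' @param corr_dataset Index of the dataset feeding the correlation
#'   screens.
#' @param case Case group label (default `"IDD"`).
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Validated list of class `cerna_pipeline_config`.
#' @export
pipeline_config <- function(mrna_paths, mirna_paths, groups_paths,
                            targets_path, out_dir,
                            gmt_path = NULL, ppi_path = NULL,
                            markers_path = NULL,
                            p_max = 0.05, lfc_min = 1, alpha = 0.05,
                            min_shared = 1L, top_k = 10L,
                            corr_dataset = 1L, case = "IDD", seed = 1L) {
  nd <- length(mrna_paths)
  if (nd < 2L) {
    ct_stop("need >= 2 datasets for a consensus pipeline",
            class = "cerna_bad_config")
  }
  if (length(mirna_paths) != nd || length(groups_paths) != nd) {
    ct_stop("mrna_paths, mirna_paths, groups_paths must have equal length",
            class = "cerna_bad_config")
  }
  if (p_max <= 0 || p_max > 1 || lfc_min <= 0 || alpha < 0 || alpha > 1) {
    ct_stop("thresholds out of range", class = "cerna_bad_config")
  }
  if (corr_dataset < 1L || corr_dataset > nd) {
    ct_stop("'corr_dataset' must index one of the ", nd, " datasets",
            class = "cerna_bad_config")
  }
  inputs <- c(mrna_paths, mirna_paths, groups_paths, targets_path,
              gmt_path, ppi_path, markers_path)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    ct_stop("input file not found: ", missing[1L],
            class = "cerna_bad_config")
  }
  structure(list(mrna_paths = mrna_paths, mirna_paths = mirna_paths,
                 groups_paths = groups_paths, targets_path = targets_path,
                 out_dir = out_dir, gmt_path = gmt_path,
                 ppi_path = ppi_path, markers_path = markers_path,
                 p_max = p_max, lfc_min = lfc_min, alpha = alpha,
                 min_shared = as.integer(min_shared),
                 top_k = as.integer(top_k),
                 corr_dataset = as.integer(corr_dataset),
                 case = case, seed = as.integer(seed)),
            class = "cerna_pipeline_config")
}

#' Run the full ceRNA inference pipeline
#'
#' Executes, in order: per-dataset differential expression (mRNA and
#' miRNA), cross-dataset consensus with direction agreement, the
#' three-condition ceRNA triplet screen on the designated correlation
#' dataset, over-representation analysis of the consensus DEGs (if a GMT is
#' supplied; the universe is the measured gene set of the correlation
#' dataset), degree-based hub ranking (if an edge list is supplied), and
#' the bulk-vs-single-cell marker intersection (if marker lists are
#' supplied). Every stage writes its table under `out_dir` and the run ends
#' with a JSON manifest of row counts, thresholds and a config hash.
#' Re-running with identical config and inputs reproduces every output
#' byte-identically (the manifest differs only in its timestamp).
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "cerna_pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  note <- function(stage, ...) {
    counts <- list(...)
    stages[[stage]] <<- counts
    message(sprintf("[%s] %s", stage,
                    paste(names(counts), unlist(counts), sep = "=",
                          collapse = ", ")))
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      ct_stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
              class = "cerna_pipeline_error")
    })
  }
  nd <- length(cfg$mrna_paths)

  datasets <- run_stage("read", lapply(seq_len(nd), function(d) {
    list(mrna = read_expression(cfg$mrna_paths[d], cfg$groups_paths[d],
                                kind = "mrna", case = cfg$case),
         mirna = read_expression(cfg$mirna_paths[d], cfg$groups_paths[d],
                                 kind = "mirna", case = cfg$case))
  }))
  map <- run_stage("read", read_target_map(cfg$targets_path))
  note("read", datasets = nd, target_edges = nrow(map$edges))

  de_tables <- run_stage("diffexpr", lapply(seq_len(nd), function(d) {
    tab <- differential_expression(datasets[[d]]$mrna,
                                   p_max = cfg$p_max, lfc_min = cfg$lfc_min)
    write_de_table(tab, file.path(cfg$out_dir,
                                  sprintf("de_mrna_dataset%d.tsv", d)))
    mtab <- differential_expression(datasets[[d]]$mirna,
                                    p_max = cfg$p_max, lfc_min = cfg$lfc_min)
    write_de_table(mtab, file.path(cfg$out_dir,
                                   sprintf("de_mirna_dataset%d.tsv", d)))
    tab
  }))
  note("diffexpr", datasets = nd,
       significant = paste(vapply(de_tables, function(t) sum(t$significant),
                                  0L), collapse = "/"))

  degs <- run_stage("consensus", consensus_degs(de_tables))
  write_tsv_strict(as.data.frame(degs),
                   file.path(cfg$out_dir, "consensus_degs.tsv"))
  note("consensus", genes = nrow(degs))

  cd <- datasets[[cfg$corr_dataset]]
  screen <- run_stage("cerna",
                      screen_triplets(cd$mrna, cd$mirna, degs, map,
                                      alpha = cfg$alpha,
                                      min_shared = cfg$min_shared))
  write_tsv_strict(screen$audit, file.path(cfg$out_dir, "cerna_audit.tsv"))
  write_tsv_strict(screen$network$triplets,
                   file.path(cfg$out_dir, "cerna_network.tsv"))
  write_sif(screen$network, file.path(cfg$out_dir, "cerna_network.sif"))
  net_counts <- as.list(network_summary(screen$network))
  note("cerna", tested = nrow(screen$audit),
       accepted = net_counts$n_triplets, edges = net_counts$n_edges)
  if (net_counts$n_triplets == 0L) {
    message("[cerna] empty ceRNA network at alpha=", cfg$alpha,
            "; downstream enrichment still uses the consensus DEGs")
  }

  enr_rows <- NA_integer_
  if (!is.null(cfg$gmt_path)) {
    enr_rows <- run_stage("enrich", {
      universe <- rownames(cd$mrna$values)
      coll <- read_gmt(cfg$gmt_path, universe = universe)
      if (nrow(degs) == 0L) {
        message("[enrich] skipped: empty DEG query")
        0L
      } else {
        enr <- ora_enrich(degs, coll)
        write_tsv_strict(as.data.frame(enr),
                         file.path(cfg$out_dir, "enrichment.tsv"))
        nrow(enr)
      }
    })
    note("enrich", sets_tested = enr_rows)
  }

  hub_rows <- NA_integer_
  if (!is.null(cfg$ppi_path)) {
    hub_rows <- run_stage("hubs", {
      edges <- read_edge_list(cfg$ppi_path)
      hubs <- hub_genes(edges, top_k = cfg$top_k)
      write_tsv_strict(as.data.frame(hubs),
                       file.path(cfg$out_dir, "hub_genes.tsv"))
      nrow(hubs)
    })
    note("hubs", nodes = hub_rows)
  }

  marker_rows <- NA_integer_
  if (!is.null(cfg$markers_path)) {
    marker_rows <- run_stage("markers", {
      ml <- read_marker_lists(cfg$markers_path)
      hits <- intersect_markers(degs, ml)
      write_tsv_strict(hits,
                       file.path(cfg$out_dir, "marker_intersection.tsv"))
      nrow(hits)
    })
    note("markers", common_genes = marker_rows)
  }

  manifest <- list(
    package = "ceRNAtriad",
    version = as.character(utils::packageVersion("ceRNAtriad")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[setdiff(names(cfg), "out_dir")],
    config_hash = config_hash(cfg),
    stages = stages)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}

config_hash <- function(cfg) {
  # hash the analysis inputs and thresholds, not where output lands
  cfg <- unclass(cfg)[setdiff(names(unclass(cfg)), "out_dir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[ct_sort(names(cfg))], tmp,
                       auto_unbox = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

#' Intersect bulk consensus DEGs with single-cell marker lists
#'
#' The bulk-vs-single-cell integration step: genes that are both consensus
#' DEGs and markers of at least one cell cluster, with per-cluster
#' provenance. By default markers are pooled across clusters (union);
#' `per_cluster = TRUE` additionally returns the per-cluster breakdown.
#'
#' @param bulk_degs A `cerna_consensus` table or character vector of gene
#'   ids.
#' @param marker_lists Named list: cluster id -> character vector of marker
#'   genes.
#' @param per_cluster If `TRUE`, attach a per-cluster list of
#'   intersections as attribute `per_cluster`.
#' @return Data frame with columns `gene_id` and `clusters` (comma-joined
#'   cluster ids in which the gene is a marker), sorted by gene id.
#' @export
intersect_markers <- function(bulk_degs, marker_lists, per_cluster = FALSE) {
  ids <- if (inherits(bulk_degs, "cerna_consensus")) bulk_degs$gene_id
         else as.character(bulk_degs)
  if (length(ids) == 0L || length(marker_lists) == 0L) {
    ct_stop("need a nonempty DEG set and nonempty marker lists",
            class = "cerna_bad_input")
  }
  ids <- unique(ids)
  all_markers <- unique(unlist(marker_lists, use.names = FALSE))
  common <- ct_sort(intersect(ids, all_markers))
  clusters <- vapply(common, function(g) {
    paste(ct_sort(names(marker_lists)[vapply(marker_lists,
                                             function(m) g %in% m,
                                             TRUE)]), collapse = ",")
  }, "")
  out <- data.frame(gene_id = common, clusters = unname(clusters),
                    stringsAsFactors = FALSE)
  if (per_cluster) {
    attr(out, "per_cluster") <- lapply(marker_lists,
                                       function(m) ct_sort(intersect(ids, m)))
  }
  out
}
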