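# Strict tab-separated readers/writers. All writers order rows and columns
# lexicographically (C collation) and print doubles with "%.17g", so valid
# data round-trips byte-identically: read(write(x)) == x and
# write(read(f)) == f.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  ints <- is.finite(x) & x == round(x) & abs(x) < 1e15
  out[ints] <- sprintf("%d", as.integer(x[ints]))
  out
}

#' Write a data frame as deterministic TSV
#'
#' Tab-separated, header line, no quoting; doubles printed with enough
#' digits to round-trip exactly. Used by every table writer in the
#' package.
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_strict <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
    else out[[j]] <- as.character(out[[j]])
  }
  lines <- c(paste(names(out), collapse = "\t"),
             if (nrow(out)) do.call(paste, c(unname(out), sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_tsv_strict <- function(path, required, numeric_cols = character(0),
                            logical_cols = character(0)) {
  if (!file.exists(path)) {
    ct_stop("file not found: ", path, class = "cerna_io_error")
  }
  lines <- readLines(path)
  if (length(lines) == 0L) {
    ct_stop(path, ": empty file", class = "cerna_io_error")
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  missing <- setdiff(required, header)
  if (length(missing)) {
    ct_stop(path, ", line 1: missing column '", missing[1L], "'",
            class = "cerna_io_error")
  }
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(header))
  if (length(bad)) {
    ct_stop(path, ", line ", bad[1L] + 1L, ": expected ", length(header),
            " fields, found ", lengths(parts)[bad[1L]],
            class = "cerna_io_error")
  }
  df <- as.data.frame(
    stats::setNames(lapply(seq_along(header), function(j) {
      vapply(parts, `[`, "", j)
    }), header), stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in intersect(numeric_cols, header)) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad_row <- which(is.na(v) & !df[[cl]] %in% c("NA", "NaN"))
    if (length(bad_row)) {
      ct_stop(path, ", line ", bad_row[1L] + 1L, ": non-numeric value '",
              df[[cl]][bad_row[1L]], "' in column '", cl, "'",
              class = "cerna_io_error")
    }
    df[[cl]] <- v
  }
  for (cl in intersect(logical_cols, header)) {
    df[[cl]] <- df[[cl]] == "TRUE"
  }
  df
}

#' Write an expression dataset to TSV
#'
#' Writes the log2 expression matrix (first column `gene_id`, one column
#' per sample) and, optionally, the two-column sample annotation
#' (`sample_id`, `group`). Rows and sample columns are sorted
#' lexicographically so output is byte-stable.
#'
#' @param ds An [expression_dataset()].
#' @param path Output path for the matrix TSV.
#' @param groups_path Optional output path for the annotation TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(ds, path, groups_path = NULL) {
  stopifnot(inherits(ds, "cerna_expression"))
  g <- ct_sort(rownames(ds$values))
  s <- ct_sort(colnames(ds$values))
  m <- ds$values[g, s, drop = FALSE]
  df <- data.frame(gene_id = g, as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
  if (!is.null(groups_path)) {
    write_tsv_strict(data.frame(sample_id = s,
                                group = unname(ds$groups[s]),
                                stringsAsFactors = FALSE), groups_path)
  }
  invisible(path)
}

#' Read an expression dataset from TSV
#'
#' Counterpart of [write_expression()]. The matrix file must have a
#' `gene_id` first column and unique gene/sample ids; every sample must
#' appear in the annotation file. Non-numeric cells, duplicate ids and
#' unannotated samples are errors naming the offender.
#'
#' @param path Matrix TSV (first column `gene_id`).
#' @param groups_path Annotation TSV with columns `sample_id`, `group`.
#' @param kind `"mrna"` or `"mirna"`.
#' @param case Group label treated as case (default `"IDD"`).
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, groups_path, kind = c("mrna", "mirna"),
                            case = "IDD") {
  kind <- match.arg(kind)
  df <- read_tsv_strict(path, required = "gene_id")
  if (names(df)[1L] != "gene_id") {
    ct_stop(path, ": first column must be 'gene_id'", class = "cerna_io_error")
  }
  if (ncol(df) < 2L || nrow(df) == 0L) {
    ct_stop(path, ": empty expression matrix", class = "cerna_io_error")
  }
  if (anyDuplicated(df$gene_id)) {
    ct_stop(path, ": duplicated gene id '",
            df$gene_id[duplicated(df$gene_id)][1L], "'",
            class = "cerna_io_error")
  }
  samples <- names(df)[-1L]
  m <- matrix(NA_real_, nrow(df), length(samples),
              dimnames = list(df$gene_id, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      ct_stop(path, ", line ", bad + 1L, ": non-numeric value '",
              df[[j + 1L]][bad], "' for sample '", samples[j], "'",
              class = "cerna_io_error")
    }
    m[, j] <- v
  }
  gr <- read_tsv_strict(groups_path, required = c("sample_id", "group"))
  if (anyDuplicated(gr$sample_id)) {
    ct_stop(groups_path, ": duplicated sample id '",
            gr$sample_id[duplicated(gr$sample_id)][1L], "'",
            class = "cerna_io_error")
  }
  unannotated <- setdiff(samples, gr$sample_id)
  if (length(unannotated)) {
    ct_stop(path, ": sample '", unannotated[1L],
            "' missing from ", groups_path, class = "cerna_io_error")
  }
  groups <- stats::setNames(gr$group, gr$sample_id)[samples]
  expression_dataset(m, groups, kind = kind, case = case)
}

#' Read a miRNA-to-mRNA target map from TSV
#'
#' Two tab-separated columns `mirna_id`, `gene_id` with a header line.
#' Duplicate edges are collapsed; a malformed line is an error naming the
#' line number; an empty edge list yields an empty map with a warning.
#' Universes default to the observed ids and can be widened.
#'
#' @param path Target map TSV.
#' @param mirna_universe,mrna_universe Optional wider universes.
#' @return A [target_map()].
#' @export
read_target_map <- function(path, mirna_universe = NULL,
                            mrna_universe = NULL) {
  df <- read_tsv_strict(path, required = c("mirna_id", "gene_id"))
  empty_field <- which(df$mirna_id == "" | df$gene_id == "")
  if (length(empty_field)) {
    ct_stop(path, ", line ", empty_field[1L] + 1L, ": empty id",
            class = "cerna_io_error")
  }
  if (nrow(df) == 0L) {
    warning("empty target map: ", path)
  }
  if (is.null(mirna_universe) && nrow(df) == 0L) mirna_universe <- character(0)
  if (is.null(mrna_universe) && nrow(df) == 0L) mrna_universe <- character(0)
  target_map(df, mirna_universe = mirna_universe,
             mrna_universe = mrna_universe)
}

#' Write a target map to TSV
#'
#' @param map A [target_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(map, path) {
  stopifnot(inherits(map, "cerna_target_map"))
  write_tsv_strict(map$edges, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then members. A line with fewer than 3 fields is an error naming the
#' line.
#'
#' @param path GMT file.
#' @param universe Optional universe passed to [gene_set_collection()];
#'   defaults to the union of all members.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) {
    ct_stop("file not found: ", path, class = "cerna_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    ct_stop(path, ", line ", bad[1L], ": GMT line needs >= 3 fields",
            class = "cerna_io_error")
  }
  nms <- vapply(parts, `[`, "", 1L)
  desc <- stats::setNames(vapply(parts, `[`, "", 2L), nms)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), nms)
  gene_set_collection(sets, universe = universe, descriptions = desc)
}

#' Write a ceRNA network in SIF format
#'
#' One `mirna<TAB>targets<TAB>mrna` line per induced miRNA-mRNA edge,
#' sorted lexicographically; loadable by standard network tools.
#'
#' @param net A `cerna_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "cerna_network"))
  e <- net$edges
  lines <- if (nrow(e)) paste(e$mirna_id, "targets", e$gene_id, sep = "\t")
           else character(0)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write / read a differential-expression table
#'
#' TSV with columns `gene_id`, `log2fc`, `pvalue`, `padj_bh`,
#' `significant`, `direction`, rows sorted by gene id; the thresholds are
#' not stored in the file and must be re-supplied on read.
#'
#' @param tab A `cerna_de` table.
#' @param path File path.
#' @return `path` / the table.
#' @export
write_de_table <- function(tab, path) {
  cols <- c("gene_id", "log2fc", "pvalue", "padj_bh", "significant",
            "direction")
  stopifnot(all(cols %in% names(tab)))
  out <- as.data.frame(tab)[, cols]
  out <- out[ct_order(out$gene_id), , drop = FALSE]
  write_tsv_strict(out, path)
  invisible(path)
}

#' @rdname write_de_table
#' @param p_max,lfc_min Thresholds used to re-flag the table on read.
#' @export
read_de_table <- function(path, p_max = 0.05, lfc_min = 1) {
  df <- read_tsv_strict(path,
                        required = c("gene_id", "log2fc", "pvalue"),
                        numeric_cols = c("log2fc", "pvalue", "padj_bh"),
                        logical_cols = "significant")
  filter_degs(df, p_max = p_max, lfc_min = lfc_min)
}

#' Read an undirected interaction edge list
#'
#' TSV with columns `node_a`, `node_b` and an optional numeric `score`
#' (the shape of a STRING export). Consumed by [hub_genes()].
#'
#' @param path Edge list TSV.
#' @return Data frame with columns `node_a`, `node_b` and, if present,
#'   `score`.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_strict(path, required = c("node_a", "node_b"),
                        numeric_cols = "score")
  df[, intersect(c("node_a", "node_b", "score"), names(df)), drop = FALSE]
}

#' Read per-cluster marker gene lists
#'
#' TSV with columns `cluster_id`, `gene_id` (one marker per row), the form
#' in which single-cell marker calls enter the pipeline.
#'
#' @param path Marker TSV.
#' @return Named list: cluster id -> character vector of gene ids.
#' @export
read_marker_lists <- function(path) {
  df <- read_tsv_strict(path, required = c("cluster_id", "gene_id"))
  lapply(split(df$gene_id, df$cluster_id), function(g) ct_sort(unique(g)))
}

#' Write / read planted truth as JSON
#'
#' @param truth The `truth` element of a simulation.
#' @param path JSON path.
#' @return `path` / the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_chr_df <- function(d, cols) {
    if (length(d) == 0L || is.null(d[[cols[1L]]])) {
      return(stats::setNames(
        as.data.frame(replicate(length(cols), character(0),
                                simplify = FALSE)), cols))
    }
    as.data.frame(lapply(d[cols], as.character), stringsAsFactors = FALSE)
  }
  list(de_genes = {
         d <- x$de_genes
         if (length(d) == 0L || is.null(d$gene_id)) {
           data.frame(gene_id = character(0), sign = integer(0))
         } else {
           data.frame(gene_id = as.character(d$gene_id),
                      sign = as.integer(d$sign), stringsAsFactors = FALSE)
         }
       },
       triplets = as_chr_df(x$triplets, c("mrna_a", "mirna", "mrna_b")),
       planted_edges = as_chr_df(x$planted_edges, c("mirna_id", "gene_id")))
}

#' Write a simulated study to a directory
#'
#' Emits, per dataset `d`: `dataset<d>_mrna.tsv`, `dataset<d>_mirna.tsv`,
#' `dataset<d>_groups.tsv`; plus `target_map.tsv` and `truth.json`.
#'
#' @param sim A [simulate_paired_datasets()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cerna_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in seq_along(sim$datasets)) {
    ds <- sim$datasets[[d]]
    write_expression(ds$mrna, file.path(dir, sprintf("dataset%d_mrna.tsv", d)),
                     file.path(dir, sprintf("dataset%d_groups.tsv", d)))
    write_expression(ds$mirna,
                     file.path(dir, sprintf("dataset%d_mirna.tsv", d)))
  }
  write_target_map(sim$target_map, file.path(dir, "target_map.tsv"))
  write_truth(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
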