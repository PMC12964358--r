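# Input/output: the tab-separated SNV-table dialect (PyClone lineage), the
# pre-clustering dialect, and result serialization (edge lists, assignments,
# run summaries, Newick topology).

REQUIRED_SNV_COLS <- c("mutation_id", "sample_id", "ref_counts", "alt_counts",
                       "major_cn", "minor_cn")

#' Construct an SNV table from a data frame
#'
#' One row per mutation x sample with allele counts and copy-number context.
#' Optional columns `normal_cn` (default 2), `tumour_content` (default 1, or
#' supplied once via `tumour_content`), `error_rate` (default 0.001) and
#' `chrom` are filled in. The table must be rectangular: every mutation needs
#' a row in every sample. Mutation and sample order is first-appearance order
#' and is kept stable for the whole run.
#'
#' @param df data.frame with the required columns.
#' @param tumour_content optional per-sample tumour content (single value or
#'   named vector by sample) broadcast when the column is absent.
#' @return object of class `snv_table`.
#' @export
as_snv_table <- function(df, tumour_content = NULL) {
  missing_cols <- setdiff(REQUIRED_SNV_COLS, names(df))
  if (length(missing_cols) > 0)
    stop_validation("SNV table is missing required column(s): %s",
                    paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$mutation_id <- as.character(df$mutation_id)
  df$sample_id <- as.character(df$sample_id)
  if (is.null(df$normal_cn)) df$normal_cn <- 2L
  if (is.null(df$error_rate)) df$error_rate <- 0.001
  if (is.null(df$tumour_content)) {
    tc <- tumour_content %||% 1
    df$tumour_content <- if (length(tc) > 1L) unname(tc[df$sample_id]) else tc
  }
  if (any(df$minor_cn > df$major_cn))
    stop_validation("minor_cn > major_cn in %d row(s)",
                    sum(df$minor_cn > df$major_cn))
  if (any(df$ref_counts < 0 | df$alt_counts < 0))
    stop_validation("negative read counts")
  muts <- unique(df$mutation_id)
  samp <- unique(df$sample_id)
  key <- paste(df$mutation_id, df$sample_id, sep = "\r")
  if (anyDuplicated(key))
    stop_validation("duplicated (mutation, sample) rows")
  want <- as.vector(outer(muts, samp, paste, sep = "\r"))
  miss <- setdiff(want, key)
  if (length(miss) > 0)
    stop_validation("table is not rectangular; missing (mutation, sample) pairs: %s",
                    paste(gsub("\r", ", ", utils::head(miss, 5L)), collapse = "; "))
  structure(df, mutations = muts, samples = samp,
            class = c("snv_table", "data.frame"))
}

#' Read an SNV table from a tab-separated file
#'
#' @param path file with a header row and the columns of [as_snv_table()].
#' @param tumour_content optional per-sample tumour content broadcast when the
#'   file has no `tumour_content` column.
#' @return an `snv_table`.
#' @export
read_snv_table <- function(path, tumour_content = NULL) {
  if (!file.exists(path)) stop_validation("input file not found: %s", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  as_snv_table(df, tumour_content = tumour_content)
}

#' Write an SNV table to a tab-separated file
#'
#' @param table an `snv_table`.
#' @param path output path.
#' @export
write_snv_table <- function(table, path) {
  data.table::fwrite(as.data.frame(table), path, sep = "\t")
  invisible(path)
}

#' Read a pre-clustering file
#'
#' Tab-separated with columns `mutation_id` and `cluster_id` (the dialect of
#' prevalence-mixture pre-clustering tools). Cluster ids are re-indexed
#' densely to 1..K in first-appearance order of the file.
#'
#' @param path clustering file.
#' @param table optional `snv_table` to validate against: every table mutation
#'   must be clustered; clustered mutations absent from the table are dropped
#'   with a warning.
#' @return named integer vector: cluster index per mutation id.
#' @export
read_preclustering <- function(path, table = NULL) {
  if (!file.exists(path)) stop_validation("clustering file not found: %s", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  for (col in c("mutation_id", "cluster_id"))
    if (!col %in% names(df))
      stop_validation("clustering file is missing required column(s): %s", col)
  df <- df[!duplicated(df$mutation_id), , drop = FALSE]
  dense <- match(df$cluster_id, unique(df$cluster_id))
  assignment <- stats::setNames(dense, as.character(df$mutation_id))
  if (!is.null(table)) {
    muts <- attr(table, "mutations")
    absent <- setdiff(muts, names(assignment))
    if (length(absent) > 0)
      stop_validation("mutations missing from clustering file: %s",
                      paste(utils::head(absent, 5L), collapse = ", "))
    extra <- setdiff(names(assignment), muts)
    if (length(extra) > 0) {
      warning(sprintf("ignoring %d clustered mutation(s) not in the SNV table",
                      length(extra)))
      assignment <- assignment[muts]
      assignment <- stats::setNames(match(assignment, unique(assignment)), muts)
    }
  }
  assignment
}

#' Newick string of a clone tree topology
#'
#' Node-labelled, no branch lengths; the dummy root is labelled "root" and
#' real nodes by their integer label.
#'
#' @param tree a `clone_tree`.
#' @return character scalar ending in ";".
#' @export
to_newick <- function(tree) {
  ch <- tree_children(tree$parent)
  rec <- function(v) {
    lab <- if (v == 0L) "root" else as.character(v)
    kids <- ch[[v + 1L]]
    if (length(kids) == 0L) lab
    else sprintf("(%s)%s", paste(vapply(kids, rec, character(1)), collapse = ","), lab)
  }
  paste0(rec(0L), ";")
}

#' Write inference results to a directory
#'
#' Writes the MAP tree edge list (`map_tree_edges.tsv`: child_node,
#' parent_node), the mutation assignment table (`assignments.tsv`:
#' mutation_id, node, is_outlier; outliers have an empty node field), a JSON
#' run summary (`summary.json`: joint log-probability trace, seed, config) and
#' the Newick topology (`map_tree.nwk`).
#'
#' @param fit a `clonetree_fit` from [run_sampler()].
#' @param out_dir output directory (created if needed).
#' @param mutation_ids optional mutation labels (defaults to those of the fit).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(fit, out_dir, mutation_ids = NULL) {
  if (length(fit$trace) == 0) stop_validation("empty trace")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- fit$map_tree
  muts <- mutation_ids %||% fit$mutations %||% as.character(seq_len(tree$n_mutations))
  K <- length(tree$parent)
  edges <- data.frame(
    child_node = as.character(seq_len(K)),
    parent_node = ifelse(tree$parent == 0L, "root", as.character(tree$parent))
  )
  data.table::fwrite(edges, file.path(out_dir, "map_tree_edges.tsv"), sep = "\t")
  node_of <- rep(NA_character_, tree$n_mutations)
  for (v in seq_len(K)) node_of[tree$clusters[[v]]] <- as.character(v)
  assign <- data.frame(
    mutation_id = muts,
    node = ifelse(is.na(node_of), "", node_of),
    is_outlier = seq_len(tree$n_mutations) %in% tree$outliers
  )
  data.table::fwrite(assign, file.path(out_dir, "assignments.tsv"), sep = "\t")
  summary <- list(
    joint_log_prob_trace = vapply(fit$trace, `[[`, numeric(1), "joint"),
    map_joint_log_prob = fit$map_joint,
    seed = fit$seed,
    config = unclass(fit$config)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(to_newick(tree), file.path(out_dir, "map_tree.nwk"))
  invisible(out_dir)
}

#' Read a tree edge list back into a parent vector
#'
#' Inverse of the edge list written by [write_results()]; used for round
#' tripping and external comparison.
#'
#' @param path edge-list TSV with columns child_node, parent_node.
#' @return integer parent vector (0 = root).
#' @export
read_tree_edges <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  child <- as.integer(df$child_node)
  parent <- rep(0L, length(child))
  not_root <- df$parent_node != "root"
  parent[not_root] <- as.integer(df$parent_node[not_root])
  out <- integer(max(child))
  out[child] <- parent
  out
}
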