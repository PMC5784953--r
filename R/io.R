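# Readers and writers for the plain-text interchange formats: expression
# and label TSVs, pathway node/edge TSVs, GMT gene sets, result TSVs and
# JSON run configuration. Readers reject rather than coerce malformed data.

#' Read a log2 expression matrix from TSV
#'
#' First column = gene ids, header row = sample ids, numeric cells.
#'
#' @param path TSV file.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    abort(paste0("duplicated gene id: ",
                 paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)[1, ]
    abort(sprintf("non-numeric expression value at gene %s, sample %s",
                  genes[bad[1]], colnames(vals)[bad[2]]))
  }
  dimnames(num) <- list(genes, colnames(vals))
  num
}

#' Read sample group labels from TSV
#'
#' Two columns: `sample`, `group` (1 or 2). The file's sample order
#' dictates the column order of the assembled dataset.
#'
#' @param path TSV file.
#' @return Named integer vector of labels.
#' @export
read_labels <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = "ci")
  if (!all(c("sample", "group") %in% names(df))) {
    abort("labels file needs columns: sample, group")
  }
  if (!all(df$group %in% c(1L, 2L))) {
    abort("group labels must be 1 or 2")
  }
  setNames(df$group, df$sample)
}

#' Assemble an expression dataset from TSV files
#'
#' @param expr_path Expression TSV (see [read_expression()]).
#' @param labels_path Labels TSV (see [read_labels()]).
#' @return An [expression_dataset()] with columns ordered as in the labels
#'   file.
#' @export
read_expression_dataset <- function(expr_path, labels_path) {
  X <- read_expression(expr_path)
  y <- read_labels(labels_path)
  missing <- setdiff(names(y), colnames(X))
  if (length(missing)) {
    abort(paste0("labelled samples missing from expression matrix: ",
                 paste(missing, collapse = ", ")))
  }
  expression_dataset(X[, names(y), drop = FALSE], unname(y))
}

#' Write an expression dataset to TSV files
#'
#' @param data An [expression_dataset()].
#' @param expr_path,labels_path Output paths.
#' @return `data`, invisibly.
#' @export
write_expression_dataset <- function(data, expr_path, labels_path) {
  df <- dplyr::bind_cols(tibble(gene = rownames(data$X)),
                         as_tibble(data$X))
  readr::write_tsv(df, expr_path)
  readr::write_tsv(tibble(sample = colnames(data$X), group = data$y),
                   labels_path)
  invisible(data)
}

#' Read pathways from node/edge TSV tables
#'
#' Node table columns: `pathway_id`, `node_id`, `kind`, `members`
#' (semicolon-separated gene ids, empty for plain genes and compounds).
#' Edge table columns: `pathway_id`, `source`, `target`, `directed` (0/1),
#' `interaction_type`.
#'
#' @param nodes_path,edges_path TSV files.
#' @return Named list of [raw_pathway()] objects.
#' @export
read_pathways <- function(nodes_path, edges_path) {
  nodes <- readr::read_tsv(nodes_path, show_col_types = FALSE,
                           col_types = "cccc")
  edges <- readr::read_tsv(edges_path, show_col_types = FALSE,
                           col_types = "cccic")
  ids <- unique(nodes$pathway_id)
  out <- lapply(ids, function(pid) {
    nd <- nodes[nodes$pathway_id == pid, ]
    ed <- edges[edges$pathway_id == pid, ]
    members <- lapply(nd$members, function(m) {
      if (is.na(m) || m == "") character() else strsplit(m, ";", fixed = TRUE)[[1]]
    })
    raw_pathway(pid,
                tibble(node_id = nd$node_id, kind = nd$kind,
                       members = members),
                tibble(source = ed$source, target = ed$target,
                       directed = ed$directed == 1L,
                       interaction_type = ed$interaction_type))
  })
  setNames(out, ids)
}

#' Write raw pathways to node/edge TSV tables
#'
#' @param pathways List of [raw_pathway()].
#' @param nodes_path,edges_path Output paths.
#' @return `pathways`, invisibly.
#' @export
write_pathways <- function(pathways, nodes_path, edges_path) {
  nodes <- dplyr::bind_rows(lapply(pathways, function(p) {
    tibble(pathway_id = p$pathway_id, node_id = p$nodes$node_id,
           kind = p$nodes$kind,
           members = vapply(p$nodes$members, paste, character(1),
                            collapse = ";"))
  }))
  edges <- dplyr::bind_rows(lapply(pathways, function(p) {
    if (!nrow(p$edges)) return(NULL)
    tibble(pathway_id = p$pathway_id, source = p$edges$source,
           target = p$edges$target,
           directed = as.integer(p$edges$directed),
           interaction_type = p$edges$interaction_type)
  }))
  readr::write_tsv(nodes, nodes_path)
  readr::write_tsv(edges, edges_path)
  invisible(pathways)
}

#' Read GMT gene sets as edgeless pathways
#'
#' Standard GMT: name, description, then tab-separated gene ids. Each
#' entry becomes a gene-only, edgeless raw pathway (the gene-set view).
#'
#' @param path GMT file.
#' @return Named list of [raw_pathway()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort(paste0("malformed GMT line: ", substr(l, 1, 40)))
    genes <- unique(parts[-(1:2)])
    raw_pathway(parts[1],
                tibble(node_id = genes, kind = "gene",
                       members = replicate(length(genes), character(),
                                           simplify = FALSE)),
                tibble(source = character(), target = character(),
                       directed = logical(), interaction_type = character()))
  })
  setNames(out, vapply(out, function(p) p$pathway_id, character(1)))
}

#' Write a result table to TSV
#'
#' Deterministic row order (method, then pathway id); `extras` serialized
#' as a JSON string; p-values printed with 6 significant digits.
#'
#' @param results Result tibble from [run_method()].
#' @param path Output TSV.
#' @return `results`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- results[order(results$method, results$pathway_id), ]
  out$dep <- as.integer(out$dep)
  out$p_value <- signif(out$p_value, 6)
  out$extras <- vapply(out$extras, function(e) {
    as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA,
                                  null = "null", na = "null"))
  }, character(1))
  # JSON extras contain quotes but never tabs/newlines: write fields verbatim
  readr::write_tsv(out, path, quote = "none", escape = "none")
  invisible(results)
}

#' Run configuration
#'
#' Bundles the analysis settings and file paths of a run; serializes
#' losslessly to JSON. Defaults follow the benchmark conventions
#' (alpha 0.05, DEG threshold 0.05, 1000 permutations).
#'
#' @param methods Character vector of method names.
#' @param topology One of `"gpt"`, `"nogpt"`, `"mspt"`.
#' @param alpha,deg_theta,n_permutations,seed See [method_config()].
#' @param paths Named list of input/output paths (free-form).
#' @return A list of class `run_config`.
#' @export
run_config <- function(methods = c("spia", "prs", "cepa", "tappa",
                                   "topologygsa", "clipper", "degraph"),
                       topology = c("gpt", "nogpt", "mspt"),
                       alpha = 0.05, deg_theta = 0.05,
                       n_permutations = 1000, seed = 1, paths = list()) {
  topology <- match.arg(topology)
  structure(list(methods = methods, topology = topology, alpha = alpha,
                 deg_theta = deg_theta, n_permutations = n_permutations,
                 seed = seed, paths = paths),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(methods = x$methods, topology = x$topology, alpha = x$alpha,
             deg_theta = x$deg_theta, n_permutations = x$n_permutations,
             seed = x$seed, paths = as.list(x$paths))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config)
}

#' Write an experiment report to disk
#'
#' Emits the report's long rows as `rows.tsv`, each summary table as
#' `summary_<name>.tsv`, and a `manifest.json` recording the experiment,
#' the configuration used, and the library versions.
#'
#' @param report A `pb_report` (from the `ex*` experiment functions).
#' @param dir Output directory (created if needed).
#' @param config Optional [method_config()] (or any list) to record.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, dir, config = NULL) {
  stopifnot(inherits(report, "pb_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- report$rows
  if ("extras" %in% names(rows)) {
    rows$extras <- vapply(rows$extras, function(e) {
      as.character(jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA,
                                    null = "null", na = "null"))
    }, character(1))
  }
  readr::write_tsv(rows, file.path(dir, "rows.tsv"), quote = "none",
                   escape = "none")
  for (nm in names(report$summary)) {
    s <- report$summary[[nm]]
    if (!is.data.frame(s)) next
    s <- s[, !vapply(s, is.list, logical(1)), drop = FALSE]
    readr::write_tsv(s, file.path(dir, paste0("summary_", nm, ".tsv")))
  }
  manifest <- list(
    experiment = report$experiment,
    config = if (is.null(config)) NULL else unclass(config),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("pathwaybench"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
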