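#' @title Feature tables, trees, references and their on-disk formats
#' @description
#' All tables in the package are samples-as-rows, features-as-columns
#' numeric matrices carried in a light S3 container that records which
#' data block (metabolite, taxon, gene set) and unit the values belong
#' to.  On disk everything is TSV (UTF-8, "." decimal); missing
#' metabolite measurements are empty cells, which become `NA` in memory.
#' `NA` means "not detected" and is deliberately distinct from a real
#' zero: the detection filter counts non-`NA` cells.
#' @name tables_io
NULL

.BLOCKS <- c("metabolite", "taxon", "gene_set")
.UNITS  <- c("count", "concentration", "fraction", "scaled", "area")

#' Construct a feature table
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids). `NA` encodes
#'   "not detected".
#' @param block one of `"metabolite"`, `"taxon"`, `"gene_set"`.
#' @param unit one of `"count"`, `"concentration"`, `"fraction"`,
#'   `"scaled"`, `"area"`. Counts and concentrations must be
#'   non-negative; `"fraction"` rows must sum to 1.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, block, unit = "count") {
  block <- match.arg(block, .BLOCKS)
  unit <- match.arg(unit, .UNITS)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs sample ids as rownames and feature ids as colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids")
  if (unit %in% c("count", "concentration", "fraction", "area") &&
      any(values < 0, na.rm = TRUE))
    stop("negative values are not allowed for unit '", unit, "'")
  if (unit == "fraction") {
    rs <- rowSums(values, na.rm = TRUE)
    if (any(abs(rs - 1) > 1e-9))
      stop("relative-abundance rows must sum to 1")
  }
  structure(list(values = values, block = block, unit = unit),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features | block=%s unit=%s\n",
              nrow(x$values), ncol(x$values), x$block, x$unit))
  nd <- sum(is.na(x$values))
  if (nd > 0) cat(sprintf("  %d cells not detected (NA)\n", nd))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.matrix.feature_table <- function(x, ...) x$values

#' Sample and feature ids of a feature table
#' @param tbl a `feature_table`.
#' @return character vector.
#' @export
sample_ids <- function(tbl) rownames(tbl$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(tbl) colnames(tbl$values)

#' Subset a feature table by samples and/or features
#' @param tbl a `feature_table`.
#' @param samples,features character or index vectors; `NULL` keeps all.
#' @export
subset_table <- function(tbl, samples = NULL, features = NULL) {
  v <- tbl$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  out <- tbl
  out$values <- v
  out
}

#' Read a samples x features TSV into a feature table
#'
#' First column holds sample ids, header row the feature ids.  Empty
#' cells become `NA` ("not detected"); zeros stay real zeros.
#'
#' @param path TSV file path.
#' @inheritParams feature_table
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, block, unit = "count") {
  raw <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (ncol(raw) < 2) stop("expected at least one feature column in ", path)
  ids <- as.character(raw[[1]])
  feat <- colnames(raw)[-1]
  if (anyDuplicated(feat))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(feat[duplicated(feat)]), collapse = ", "))
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) storage.mode(m) <- "double"
  rownames(m) <- ids
  feature_table(m, block = block, unit = unit)
}

#' Write a feature table to TSV (lossless round trip)
#' @param tbl a `feature_table`.
#' @param path output path; `NA` cells are written as empty strings.
#' @export
write_feature_table <- function(tbl, path) {
  df <- data.frame(sample_id = rownames(tbl$values), tbl$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read per-sample metadata
#'
#' Requires columns `sample_id`, `group`, `subject_id`, `age_weeks`;
#' `group` must have exactly two levels for all group-wise statistics
#' (here: control and AD, the Japanese diet arm).
#'
#' @param path TSV path.
#' @param group_levels level order; first level is the reference
#'   (control) group.
#' @return data.frame with `group` as a two-level factor.
#' @export
read_sample_metadata <- function(path, group_levels = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "subject_id", "age_weeks")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (is.null(group_levels)) group_levels <- unique(df$group)
  df$group <- factor(df$group, levels = group_levels)
  if (nlevels(df$group) != 2)
    stop("`group` must have exactly 2 levels, found ", nlevels(df$group))
  df$age_weeks <- as.integer(df$age_weeks)
  df
}

#' @rdname read_sample_metadata
#' @param meta metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted Newick phylogeny
#'
#' Thin wrapper around [ape::read.tree()] that validates the pieces
#' UniFrac needs: unique leaf labels and finite, non-negative branch
#' lengths.  Unlabelled internal nodes are fine.
#'
#' @param path Newick file.
#' @param missing_length `NULL` (default) makes missing branch lengths an
#'   error; a number substitutes that value, with a message.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path, missing_length = NULL) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("cannot parse Newick in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("cannot parse Newick in ", path)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(NA_real_, nrow(tree$edge))
  if (anyNA(tree$edge.length)) {
    if (is.null(missing_length))
      stop("tree has ", sum(is.na(tree$edge.length)),
           " branches without lengths; pass `missing_length` to substitute")
    message("substituting ", missing_length, " for ",
            sum(is.na(tree$edge.length)), " missing branch lengths")
    tree$edge.length[is.na(tree$edge.length)] <- missing_length
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels")
  tree
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Gene-content reference for metagenome prediction
#'
#' Bundles the three pieces a PICRUSt-style prediction needs: 16S copy
#' numbers per taxon, a taxon x KO gene-count matrix, and a KO -> pathway
#' map.  KOs absent from the map are kept but flagged `unmapped`.
#'
#' @param copy_number named positive-integer vector (taxon -> 16S copies).
#' @param ko_content non-negative matrix, taxa in rows, KOs in columns.
#' @param pathway_map named list: KO id -> character vector of pathway ids.
#' @return object of class `gene_content_reference`.
#' @export
gene_content_reference <- function(copy_number, ko_content, pathway_map) {
  if (is.null(names(copy_number)) || any(copy_number < 1))
    stop("copy_number must be a named vector with values >= 1")
  if (!all(rownames(ko_content) %in% names(copy_number)))
    stop("every ko_content taxon needs a copy number")
  if (any(ko_content < 0)) stop("ko_content must be non-negative")
  unmapped <- setdiff(colnames(ko_content), names(pathway_map))
  structure(list(copy_number = copy_number, ko_content = ko_content,
                 pathway_map = pathway_map, unmapped = unmapped),
            class = "gene_content_reference")
}

#' Read / write a gene-content reference directory
#'
#' Expects `copy_number.tsv` (columns taxon, copies), `ko_content.tsv`
#' (taxon rows x KO columns) and `pathway_map.tsv` (columns ko, pathway;
#' one row per KO-pathway assignment) inside `dir`.
#'
#' @param dir directory path.
#' @export
read_gene_content_reference <- function(dir) {
  cn <- utils::read.delim(file.path(dir, "copy_number.tsv"),
                          stringsAsFactors = FALSE)
  copy_number <- stats::setNames(as.numeric(cn$copies), cn$taxon)
  ko <- utils::read.delim(file.path(dir, "ko_content.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  km <- as.matrix(ko[, -1, drop = FALSE]); rownames(km) <- ko[[1]]
  pm <- utils::read.delim(file.path(dir, "pathway_map.tsv"),
                          stringsAsFactors = FALSE)
  pathway_map <- split(pm$pathway, pm$ko)
  gene_content_reference(copy_number, km, pathway_map)
}

#' @rdname read_gene_content_reference
#' @param ref a `gene_content_reference`.
#' @export
write_gene_content_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(taxon = names(ref$copy_number), copies = ref$copy_number),
    file.path(dir, "copy_number.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(taxon = rownames(ref$ko_content), ref$ko_content,
               check.names = FALSE),
    file.path(dir, "ko_content.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  pm <- data.frame(
    ko = rep(names(ref$pathway_map), lengths(ref$pathway_map)),
    pathway = unlist(ref$pathway_map, use.names = FALSE))
  utils::write.table(pm, file.path(dir, "pathway_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Metabolite pathway library for over-representation analysis
#'
#' @param pathways named list: pathway id -> character vector of member
#'   metabolites.  Every member must belong to the universe.
#' @param universe character vector of all library metabolites; its
#'   length is the N of the hypergeometric test.
#' @return object of class `pathway_library`.
#' @export
pathway_library <- function(pathways, universe) {
  universe <- unique(universe)
  bad <- setdiff(unlist(pathways), universe)
  if (length(bad))
    stop("pathway members outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (length(universe) < max(c(0L, lengths(pathways))))
    stop("universe smaller than the largest pathway")
  structure(list(pathways = lapply(pathways, unique), universe = universe),
            class = "pathway_library")
}

#' Read / write a pathway library as long-format TSV
#'
#' Columns `set`, `member`; rows with `set == "universe"` enumerate the
#' library universe (so N survives the round trip), all other rows assign
#' members to pathways.
#' @param path TSV path.
#' @export
read_pathway_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  uni <- df$member[df$set == "universe"]
  pw <- df[df$set != "universe", , drop = FALSE]
  pathway_library(split(pw$member, pw$set), uni)
}

#' @rdname read_pathway_library
#' @param lib a `pathway_library`.
#' @export
write_pathway_library <- function(lib, path) {
  df <- rbind(
    data.frame(set = "universe", member = lib$universe),
    data.frame(set = rep(names(lib$pathways), lengths(lib$pathways)),
               member = unlist(lib$pathways, use.names = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Correlation network container
#'
#' @param nodes data.frame with columns `feature`, `block`, `cluster`,
#'   `direction` (which diet group the feature is elevated in).
#' @param edges data.frame with columns `source`, `target`, `rho`, `q`,
#'   `sign` (+1/-1).
#' @return object of class `correlation_network`.
#' @export
correlation_network <- function(nodes, edges) {
  stopifnot(all(c("feature", "block", "cluster", "direction") %in%
                  colnames(nodes)),
            all(c("source", "target", "rho", "q", "sign") %in% colnames(edges)))
  if (anyDuplicated(nodes$feature)) stop("duplicate node features")
  if (nrow(edges) &&
      !all(c(edges$source, edges$target) %in% nodes$feature))
    stop("edge endpoints missing from node table")
  structure(list(nodes = nodes, edges = edges), class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a correlation network as GraphML plus a flat edge list
#'
#' Writes `<prefix>.graphml` (via igraph, with node attributes block,
#' cluster, direction and edge attributes rho, q, sign) and
#' `<prefix>_edges.tsv`.  This export replaces interactive rendering:
#' downstream viewers load the GraphML.
#'
#' @param net a `correlation_network`.
#' @param prefix output path prefix.
#' @return invisibly, the two paths written.
#' @export
write_network <- function(net, prefix) {
  g <- igraph::graph_from_data_frame(
    d = if (nrow(net$edges)) net$edges[, c("source", "target", "rho",
                                           "q", "sign")]
        else data.frame(source = character(), target = character(),
                        rho = numeric(), q = numeric(), sign = numeric()),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$feature,
                          block = net$nodes$block,
                          cluster = as.character(net$nodes$cluster),
                          direction = net$nodes$direction))
  graphml <- paste0(prefix, ".graphml")
  igraph::write_graph(g, graphml, format = "graphml")
  edges_tsv <- paste0(prefix, "_edges.tsv")
  utils::write.table(net$edges, edges_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(graphml = graphml, edges = edges_tsv))
}

#' Read a network back from GraphML
#' @param path `.graphml` file written by [write_network()].
#' @return a `correlation_network`.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  nodes <- data.frame(feature = va$name, block = va$block,
                      cluster = va$cluster, direction = va$direction,
                      stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  ea <- igraph::edge_attr(g)
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      rho = if (nrow(el)) ea$rho else numeric(),
                      q = if (nrow(el)) ea$q else numeric(),
                      sign = if (nrow(el)) ea$sign else numeric(),
                      stringsAsFactors = FALSE)
  correlation_network(nodes, edges)
}

# run `code` with a reproducible RNG state when seed is given, leaving
# the caller's stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
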