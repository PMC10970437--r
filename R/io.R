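# Reading DepMap-dialect inputs and writing analysis outputs.

#' Read a DepMap-dialect expression CSV
#'
#' Expects cell-line ids in the first column and one column per gene.
#' Gene headers of the form `"SYMBOL (ENTREZID)"` are reduced to `SYMBOL`,
#' with the numeric id kept in `attr(, "entrez")`; duplicated symbols are
#' disambiguated by appending the id.
#'
#' @param path Path to the CSV file.
#' @return Numeric matrix, cell lines in rows, genes in columns.
#' @export
load_expression <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 comment.char = "#")
  if (ncol(df) < 2) stop("expression CSV needs an id column and >= 1 gene")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate cell-line ids in expression CSV")
  raw_names <- names(df)[-1]
  parsed <- parse_gene_headers(raw_names)
  x <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(x)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1]]))))[1]
    stop(sprintf("non-numeric expression value at row %d, column '%s'",
                 badrow, raw_names[bad]))
  }
  dimnames(x) <- list(ids, parsed$symbol)
  attr(x, "entrez") <- stats::setNames(parsed$entrez, parsed$symbol)
  x
}

# "MT2A (4502)" -> symbol MT2A, entrez "4502"; plain headers pass through.
parse_gene_headers <- function(nm) {
  rx <- "^(.*\\S)\\s+\\((\\d+)\\)$"
  has_id <- grepl(rx, nm)
  symbol <- ifelse(has_id, sub(rx, "\\1", nm), nm)
  entrez <- ifelse(has_id, sub(rx, "\\2", nm), NA_character_)
  dup <- duplicated(symbol) | duplicated(symbol, fromLast = TRUE)
  fixable <- dup & !is.na(entrez)
  symbol[fixable] <- paste0(symbol[fixable], "_", entrez[fixable])
  if (anyDuplicated(symbol)) stop("gene symbols not unique after parsing")
  list(symbol = symbol, entrez = entrez)
}

#' Read a drug-sensitivity CSV
#'
#' Two-column file: cell-line id, then one scalar sensitivity value per
#' line (e.g. a replicate-collapsed log fold change).
#'
#' @param path Path to the CSV file.
#' @return Named numeric vector.
#' @export
load_sensitivity <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2) stop("sensitivity CSV needs id and value columns")
  v <- suppressWarnings(as.numeric(df[[2]]))
  keep <- !is.na(v)
  if (!all(keep)) {
    message(sprintf("dropping %d cell line(s) with missing sensitivity",
                    sum(!keep)))
  }
  stats::setNames(v[keep], as.character(df[[1]])[keep])
}

#' Write networks as a long edge-list TSV
#'
#' One row per nonzero coefficient: `cell_line`, `regulator`, `target`,
#' `coefficient`.
#'
#' @param networks A [netprofiler()] fit or named list of coefficient
#'   matrices.
#' @param path Output file; an optional `header` comment line (prefixed
#'   `#`) records provenance.
#' @param header Optional comment string.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(networks, path, header = NULL) {
  nets <- as_network_list(networks)
  rows <- lapply(names(nets), function(id) {
    B <- nets[[id]]
    idx <- which(B != 0, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    data.frame(cell_line = id, regulator = colnames(B)[idx[, 2]],
               target = rownames(B)[idx[, 1]], coefficient = B[idx],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows) %||%
    data.frame(cell_line = character(), regulator = character(),
               target = character(), coefficient = numeric())
  write_tsv_commented(df, path, header)
}

write_tsv_commented <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a subnetwork (or any edge table) as GraphML
#'
#' Writes the directed graph with `weight` and `sign` edge attributes,
#' mirroring the convention of drawing positive and negative regulation in
#' different colours and edge thickness by strength.
#'
#' @param edges data.frame with columns `regulator`, `target` and
#'   optionally `median_weight` (see [median_edge_summary()]).
#' @param path Output `.graphml` file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(edges, path) {
  edges <- as.data.frame(edges)
  g <- igraph::graph_from_data_frame(edges[c("regulator", "target")],
                                     directed = TRUE)
  if (!is.null(edges$median_weight)) {
    igraph::E(g)$weight <- abs(edges$median_weight)
    igraph::E(g)$sign <- sign(edges$median_weight)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
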