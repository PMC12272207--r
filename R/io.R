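#' Read a connectome from delimited text
#'
#' Accepts a square numeric matrix in comma- or whitespace-delimited
#' text, with or without a header row and leading label column (both are
#' auto-detected). Validation and the absence threshold are applied via
#' [node_connectome()].
#'
#' @param path file path.
#' @param absence_threshold forwarded to [node_connectome()].
#' @return a [node_connectome()].
#' @export
read_connectome <- function(path, absence_threshold = 0.001) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tokens <- strsplit(trimws(first), if (sep == ",") "," else "[ \t]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(tokens[-1]))))
  df <- utils::read.table(path, sep = sep, header = has_header,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  if (!is.numeric(df[[1]])) {           # leading label column
    labels <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  } else if (has_header) {
    labels <- colnames(df)
  }
  A <- as.matrix(df)
  if (nrow(A) != ncol(A)) {
    stop("matrix is not square: ", nrow(A), "x", ncol(A))
  }
  storage.mode(A) <- "double"
  node_connectome(A, node_labels = labels,
                  absence_threshold = absence_threshold)
}

#' Write a connectome as delimited text
#'
#' @param connectome a [node_connectome()].
#' @param path output file.
#' @param sep field separator (default comma).
#' @param labels write the node labels as header row and leading column.
#' @export
write_connectome <- function(connectome, path, sep = ",", labels = TRUE) {
  stopifnot_connectome(connectome)
  A <- connectome$adjacency
  if (labels) {
    utils::write.table(A, path, sep = sep, quote = FALSE,
                       row.names = TRUE, col.names = NA)
  } else {
    utils::write.table(A, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write an edge list as delimited text (0-based node indices)
#'
#' @param edge_list an [build_edge_list()] result.
#' @param path output file.
#' @param sep field separator.
#' @export
write_edge_list <- function(edge_list, path, sep = "\t") {
  out <- data.frame(node_i = edge_list$i - 1L, node_j = edge_list$j - 1L,
                    weight = edge_list$w)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a node-to-network partition file
#'
#' Two-column delimited text: node label, network label; order gives the
#' node index.
#'
#' @param path file path.
#' @return a [canonical_partition()] with node labels as names of
#'   `node_to_network`.
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("partition file needs two columns: node, network")
  p <- canonical_partition(as.character(df[[2]]))
  names(p$node_to_network) <- as.character(df[[1]])
  p
}

#' Read a phenotype table (subject ID column plus numeric phenotypes)
#'
#' @param path delimited text file with a header; the first column is the
#'   subject ID (character), remaining columns numeric phenotypes.
#' @return data frame with character `subject` and numeric columns.
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df)[1] <- "subject"
  df$subject <- as.character(df$subject)
  df
}

#' Write a JSON run manifest
#'
#' @param manifest named list of settings, seeds, and output paths.
#' @param path output JSON file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
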