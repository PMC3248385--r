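#' Read a multi-label gene annotation table
#'
#' Expects a headerless two-column TSV `gene_id<TAB>category`, one row
#' per label; genes may carry several categories and unannotated genes
#' are simply absent.
#'
#' @param path TSV path.
#' @return An `annotation_map`: named list mapping gene id to a character
#'   vector of category labels, with the category universe in
#'   `attr(, "categories")`.
#' @export
read_annotation_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          sep = "\t")
  if (ncol(df) < 2L) stop_fmt("annotation table needs two columns: %s", path)
  annotation_map(stats::setNames(df[[2]], df[[1]]))
}

#' Build an annotation map from gene/category pairs
#'
#' @param labels named character vector: names are gene ids (repeated for
#'   multi-label genes), values are category labels; or a named list of
#'   character vectors.
#' @return An `annotation_map`.
#' @export
annotation_map <- function(labels) {
  if (is.list(labels)) {
    lst <- lapply(labels, function(v) sort(unique(as.character(v))))
  } else {
    lst <- lapply(split(unname(labels), names(labels)),
                  function(v) sort(unique(v)))
  }
  if (any(!nzchar(unlist(lst, use.names = FALSE))))
    stop_fmt("empty category label in annotation map")
  lst <- lst[lengths(lst) > 0]
  structure(lst, categories = sort(unique(unlist(lst, use.names = FALSE))),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("annotation_map: %d genes, %d categories\n",
              length(x), length(attr(x, "categories"))))
  invisible(x)
}

#' Read a species-to-phylum taxonomy table
#'
#' Headerless two-column TSV `species_id<TAB>phylum`.
#'
#' @param path TSV path.
#' @return Named character vector mapping species id to phylum.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          sep = "\t")
  if (ncol(df) < 2L) stop_fmt("taxonomy table needs two columns: %s", path)
  if (anyDuplicated(df[[1]]))
    stop_fmt("duplicate species in taxonomy: %s",
             df[[1]][duplicated(df[[1]])][1])
  stats::setNames(df[[2]], df[[1]])
}

#' Read a gene set (one id per line)
#' @param path text file path.
#' @return Character vector of unique gene ids.
#' @export
read_gene_set <- function(path) {
  ids <- readLines(path)
  unique(ids[nzchar(ids)])
}

#' Read an undirected interaction edge list
#'
#' Headerless two-column TSV `gene_a<TAB>gene_b`, e.g. a protein-protein
#' interaction network; self-pairs are dropped.
#'
#' @param path TSV path.
#' @return Data frame with columns gene_a, gene_b.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          sep = "\t")
  if (ncol(df) < 2L) stop_fmt("edge list needs two columns: %s", path)
  out <- data.frame(gene_a = df[[1]], gene_b = df[[2]],
                    stringsAsFactors = FALSE)
  out[out$gene_a != out$gene_b, ]
}
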