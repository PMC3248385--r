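#' Construct a binary phylogenetic profile matrix
#'
#' A profile matrix records the presence (1) or absence (0) of each gene's
#' ortholog across a panel of species: rows are genes (index i), columns
#' are species (index k). It is the sole input of the association stage
#' and carries the per-gene summaries `E_i` (number of species containing
#' gene i) and the balance score `X_i = min(E_i, N - E_i)` used for
#' prevalence filtering.
#'
#' @param x numeric/integer matrix of 0/1 values with unique rownames
#'   (gene ids) and unique colnames (species ids).
#' @return An object of class `profile_matrix`: a list with elements `x`
#'   (integer matrix), `gene_ids`, `species_ids`, `N` (species count),
#'   `E` (named presence counts) and `X` (named balance scores).
#' @export
profile_matrix <- function(x) {
  if (!is.matrix(x) || ncol(x) == 0L)
    stop_fmt("profile matrix must be a matrix with at least one species")
  # R normalizes zero-length rownames to NULL, so only require them for
  # non-empty gene sets
  if ((nrow(x) > 0L && is.null(rownames(x))) || is.null(colnames(x)))
    stop_fmt("profile matrix needs gene rownames and species colnames")
  if (anyDuplicated(rownames(x)))
    stop_fmt("duplicate gene id: %s",
             rownames(x)[duplicated(rownames(x))][1])
  if (anyDuplicated(colnames(x)))
    stop_fmt("duplicate species id: %s",
             colnames(x)[duplicated(colnames(x))][1])
  bad <- which(!(x %in% c(0, 1)) | is.na(x))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(x)) + 1L
    k <- ((bad[1] - 1L) %/% nrow(x)) + 1L
    stop_fmt("non-binary cell at gene '%s', species '%s': %s",
             rownames(x)[i], colnames(x)[k], format(x[bad[1]]))
  }
  storage.mode(x) <- "integer"
  E <- rowSums(x)
  structure(
    list(x = x,
         gene_ids = if (nrow(x)) rownames(x) else character(0),
         species_ids = colnames(x),
         N = ncol(x),
         E = E,
         X = pmin(E, ncol(x) - E)),
    class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d genes x %d species; fill %.3f\n",
              length(x$gene_ids), x$N, mean(x$x)))
  invisible(x)
}

#' @export
dim.profile_matrix <- function(x) dim(x$x)

#' Read a phylogenetic profile matrix from a TSV file
#'
#' Two dialects are supported. `"matrix"` expects a header line
#' `gene<TAB>sp1<TAB>sp2...` followed by one gene per row with 0/1 cells.
#' `"pairs"` expects a headerless two-column file of
#' `gene_id<TAB>species_id` occurrences (the form ortholog databases
#' ship); duplicated pairs collapse to a single presence and any species
#' never mentioned is absent everywhere unless listed in `species`.
#'
#' @param path path to a tab-separated file.
#' @param dialect `"matrix"` or `"pairs"`.
#' @param species optional character vector (or path to a one-id-per-line
#'   file) fixing the species universe for the pairs dialect.
#' @return A [profile_matrix].
#' @export
read_profile_matrix <- function(path, dialect = c("matrix", "pairs"),
                                species = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  if (dialect == "matrix") {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            colClasses = "character", sep = "\t")
    if (nrow(df) == 0L || ncol(df) < 2L)
      stop_fmt("empty profile matrix in %s", path)
    genes <- df[[1]]
    if (anyDuplicated(genes))
      stop_fmt("duplicate gene id in %s: %s", path,
               genes[duplicated(genes)][1])
    m <- as.matrix(df[, -1, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "numeric")
    rownames(m) <- genes
    bad <- which(is.na(m) | !(m %in% c(0, 1)))
    if (length(bad)) {
      i <- ((bad[1] - 1L) %% nrow(m)) + 1L
      k <- ((bad[1] - 1L) %/% nrow(m)) + 1L
      stop_fmt("non-binary cell for gene '%s', species '%s' in %s",
               rownames(m)[i], colnames(m)[k], path)
    }
    return(profile_matrix(m))
  }
  ## pairs dialect
  df <- utils::read.delim(path, header = FALSE, check.names = FALSE,
                          colClasses = "character", sep = "\t")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop_fmt("empty pair list in %s", path)
  genes <- unique(df[[1]])
  if (is.character(species) && length(species) == 1L && file.exists(species))
    species <- readLines(species)
  sps <- if (is.null(species)) unique(df[[2]]) else unique(as.character(species))
  missing_sp <- setdiff(unique(df[[2]]), sps)
  if (length(missing_sp))
    stop_fmt("pair list mentions species outside the supplied universe: %s",
             missing_sp[1])
  m <- matrix(0L, nrow = length(genes), ncol = length(sps),
              dimnames = list(genes, sps))
  m[cbind(match(df[[1]], genes), match(df[[2]], sps))] <- 1L
  profile_matrix(m)
}

#' Write a profile matrix as TSV
#'
#' Emits the `"matrix"` dialect consumed by [read_profile_matrix()]:
#' header `gene<TAB>...species...`, one gene per row, 0/1 cells.
#'
#' @param pm a [profile_matrix].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "profile_matrix"))
  df <- data.frame(gene = pm$gene_ids, pm$x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter genes by profile balance
#'
#' Keeps genes whose balance `X_i = min(E_i, N - E_i)` is at least
#' `x_th`. Genes that are too rare or too ubiquitous provide few
#' informative co-presences/co-absences, so their pairwise correlations
#' are dominated by chance and vertical co-inheritance; the cutoff drops
#' them before association estimation. The default 80 is appropriate for
#' panels of several hundred species and should be rescaled for smaller
#' panels (see [balance_distribution()] for choosing it by inspection).
#'
#' @param pm a [profile_matrix].
#' @param x_th non-negative integer threshold on `X_i`.
#' @return A list with `profile` (the filtered [profile_matrix], original
#'   gene order preserved) and `report` (a `filter_report`: data frame of
#'   gene_id, E, X, kept plus the threshold).
#' @export
filter_by_prevalence <- function(pm, x_th = 80) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (!is.numeric(x_th) || length(x_th) != 1L || x_th < 0)
    stop_fmt("x_th must be a single non-negative number")
  keep <- pm$X >= x_th
  report <- structure(
    data.frame(gene_id = pm$gene_ids, E = unname(pm$E), X = unname(pm$X),
               kept = unname(keep), stringsAsFactors = FALSE),
    x_th = x_th, class = c("filter_report", "data.frame"))
  if (!any(keep))
    stop_fmt("empty after filtering: no gene has X_i >= %s", format(x_th))
  list(profile = profile_matrix(pm$x[keep, , drop = FALSE]),
       report = report)
}

#' Write a prevalence filter report as TSV
#' @param report the `report` element of [filter_by_prevalence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Distribution of the balance score X_i
#'
#' Tabulates how many genes attain each value of
#' `X_i = min(E_i, N - E_i)`. On large ortholog panels the density decays
#' roughly as a power law above some X; the filtering threshold is chosen
#' where the empirical tail starts following that decay.
#'
#' @param pm a [profile_matrix].
#' @return Data frame with columns `X` (ascending) and `count`.
#' @export
balance_distribution <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  tab <- table(pm$X)
  data.frame(X = as.integer(names(tab)), count = as.integer(tab))
}
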