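#' Build the maximum relatedness subnetwork (MRS)
#'
#' Each gene points to at most two partners: its most correlogous gene
#' (the `argmax_j w_ij` over `w_ij > 0`) and its most anti-correlogous
#' gene (the `argmin_j w_ij` over `w_ij < 0`). Genes with no positive
#' (negative) partner simply lack that edge category; `w_ij = 0` belongs
#' to neither. Ties in `w` are broken deterministically toward the
#' lexicographically smallest gene id.
#'
#' @param w symmetric matrix of partial correlations with zero diagonal
#'   and gene ids as dimnames (e.g. the `w` of [association_pipeline()]).
#' @return An `mrs_graph`: list with `nodes` (gene ids) and `edges`
#'   (data frame: source, target, w, category in
#'   `{"correlog", "anticorrelog"}`).
#' @export
build_mrs <- function(w) {
  if (length(w) == 0L || nrow(w) == 0L)
    return(structure(list(nodes = character(0),
                          edges = empty_mrs_edges()),
                     class = "mrs_graph"))
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (is.null(rownames(w)))
    dimnames(w) <- list(paste0("g", seq_len(nrow(w))),
                        paste0("g", seq_len(nrow(w))))
  if (max(abs(w - t(w))) > 1e-10) stop_fmt("w must be symmetric")
  if (max(abs(diag(w))) > 1e-10) stop_fmt("w must have zero diagonal")
  ids <- rownames(w)
  pick <- function(row, self, decreasing) {
    cand <- if (decreasing) which(row > 0) else which(row < 0)
    cand <- setdiff(cand, self)
    if (!length(cand)) return(NA_integer_)
    ext <- if (decreasing) max(row[cand]) else min(row[cand])
    tied <- cand[row[cand] == ext]
    tied[order(ids[tied])][1]
  }
  src <- integer(0); tgt <- integer(0); cat_ <- character(0)
  for (i in seq_along(ids)) {
    jp <- pick(w[i, ], i, TRUE)
    jn <- pick(w[i, ], i, FALSE)
    if (!is.na(jp)) { src <- c(src, i); tgt <- c(tgt, jp); cat_ <- c(cat_, "correlog") }
    if (!is.na(jn)) { src <- c(src, i); tgt <- c(tgt, jn); cat_ <- c(cat_, "anticorrelog") }
  }
  edges <- data.frame(source = ids[src], target = ids[tgt],
                      w = w[cbind(src, tgt)], category = cat_,
                      stringsAsFactors = FALSE)
  structure(list(nodes = ids, edges = edges), class = "mrs_graph")
}

empty_mrs_edges <- function() {
  data.frame(source = character(0), target = character(0),
             w = numeric(0), category = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.mrs_graph <- function(x, ...) {
  cat(sprintf("mrs_graph: %d nodes, %d correlog edges, %d anti-correlog edges\n",
              length(x$nodes), sum(x$edges$category == "correlog"),
              sum(x$edges$category == "anticorrelog")))
  invisible(x)
}

#' Decompose the MRS into correlog groups
#'
#' Correlog groups are the connected components of the undirected
#' projection of the MRS correlog edges only; anti-correlog edges never
#' merge groups, so they end up bridging distinct groups. Group ids are
#' assigned by decreasing size, ties broken by the lexicographically
#' smallest member.
#'
#' @param mrs an `mrs_graph` from [build_mrs()].
#' @return A `correlog_group_set`: list with `membership` (data frame
#'   gene_id, group_id, group_size), `groups` (list of member vectors),
#'   `sizes` (named integer vector `N_g`) and `n_groups`.
#' @export
correlog_groups <- function(mrs) {
  stopifnot(inherits(mrs, "mrs_graph"))
  if (!length(mrs$nodes))
    return(structure(list(membership = data.frame(gene_id = character(0),
                                                  group_id = integer(0),
                                                  group_size = integer(0)),
                          groups = list(), sizes = integer(0), n_groups = 0L),
                     class = "correlog_group_set"))
  ce <- mrs$edges[mrs$edges$category == "correlog", c("source", "target")]
  g <- igraph::graph_from_data_frame(ce, directed = FALSE,
                                     vertices = data.frame(name = mrs$nodes))
  comp <- igraph::components(g)
  members <- split(mrs$nodes, comp$membership[mrs$nodes])
  members <- lapply(members, sort)
  ord <- order(-vapply(members, length, 1L),
               vapply(members, `[`, "", 1L))
  members <- members[ord]
  names(members) <- seq_along(members)
  sizes <- vapply(members, length, 1L)
  gid <- rep(seq_along(members), sizes)
  membership <- data.frame(gene_id = unlist(members, use.names = FALSE),
                           group_id = gid,
                           group_size = sizes[gid],
                           stringsAsFactors = FALSE)
  membership <- membership[match(mrs$nodes, membership$gene_id), ]
  rownames(membership) <- NULL
  structure(list(membership = membership, groups = members,
                 sizes = sizes, n_groups = length(members)),
            class = "correlog_group_set")
}

#' @export
print.correlog_group_set <- function(x, ...) {
  cat(sprintf("correlog_group_set: %d groups over %d genes (largest N_g = %d)\n",
              x$n_groups, nrow(x$membership),
              if (x$n_groups) max(x$sizes) else 0L))
  invisible(x)
}

#' Fraction of anti-correlog edges bridging distinct correlog groups
#'
#' In the MRS, correlog edges define cohesive gene modules while
#' anti-correlog edges are expected to connect different modules (the
#' modular picture in which mutually exclusive gene repertoires repel
#' each other). This computes the fraction of anti-correlog edges whose
#' endpoints lie in different correlog groups.
#'
#' @param mrs an `mrs_graph`.
#' @param groups the [correlog_groups()] of `mrs`.
#' @return List with `fraction` (NA-flagged when there are no anti
#'   edges), `n_anti` and `n_intergroup`.
#' @export
intergroup_anti_fraction <- function(mrs, groups) {
  stopifnot(inherits(mrs, "mrs_graph"), inherits(groups, "correlog_group_set"))
  ae <- mrs$edges[mrs$edges$category == "anticorrelog", ]
  if (!nrow(ae))
    return(list(fraction = NA_real_, n_anti = 0L, n_intergroup = 0L,
                note = "no anti-correlog edges"))
  gid <- stats::setNames(groups$membership$group_id,
                         groups$membership$gene_id)
  inter <- gid[ae$source] != gid[ae$target]
  list(fraction = mean(inter), n_anti = nrow(ae),
       n_intergroup = sum(inter), note = NULL)
}

#' Per-gene correlogous and anti-correlogous coupling strengths
#'
#' `S_i^p = sum_{j != i, w_ij > 0} w_ij` measures how tightly gene i is
#' correlogously coupled to the rest of the genome;
#' `S_i^n = sum_{j != i, w_ij < 0} |w_ij|` is the analogous magnitude for
#' anti-correlogous couplings.
#'
#' @param w symmetric partial-correlation matrix with zero diagonal.
#' @return Data frame with columns gene_id, S_p, S_n.
#' @export
coupling_strengths <- function(w) {
  stopifnot(is.matrix(w))
  ids <- rownames(w)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(w)))
  pos <- w; pos[pos < 0] <- 0
  neg <- w; neg[neg > 0] <- 0
  data.frame(gene_id = ids, S_p = rowSums(pos), S_n = rowSums(-neg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag gene pairs in the obligatory-interaction regime
#'
#' Pairs with partial correlation above the threshold (default 0.045, a
#' boundary at which the weight distribution of physically binding
#' protein pairs separates from that of arbitrary pairs) are flagged as
#' candidates for functionally obligatory interactions. The inequality
#' is strict.
#'
#' @param w symmetric partial-correlation matrix with zero diagonal.
#' @param threshold strict lower bound on `w_ij`.
#' @return Data frame (one row per unordered pair): gene_i, gene_j, w,
#'   obligatory (logical).
#' @export
obligatory_flag <- function(w, threshold = 0.045) {
  stopifnot(is.matrix(w))
  ids <- rownames(w)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(w)))
  ut <- which(upper.tri(w), arr.ind = TRUE)
  data.frame(gene_i = ids[ut[, 1]], gene_j = ids[ut[, 2]], w = w[ut],
             obligatory = w[ut] > threshold, stringsAsFactors = FALSE)
}

#' Verify the structural invariants of an MRS
#'
#' Asserts that (1) every node has out-degree at most one per edge
#' category with correctly signed weights; (2) following correlog edges,
#' weights are non-decreasing until a reciprocal (mutually chosen) pair
#' is reached; (3) every non-singleton correlog group contains at least
#' one reciprocal correlog pair; (4) group sizes sum to the node count.
#'
#' @param mrs an `mrs_graph`.
#' @param groups optional precomputed [correlog_groups()].
#' @return `TRUE` invisibly; stops with a message on violation.
#' @export
verify_mrs <- function(mrs, groups = correlog_groups(mrs)) {
  stopifnot(inherits(mrs, "mrs_graph"))
  e <- mrs$edges
  for (categ in c("correlog", "anticorrelog")) {
    sub <- e[e$category == categ, ]
    if (anyDuplicated(sub$source))
      stop_fmt("node with %s out-degree > 1", categ)
  }
  if (any(e$w[e$category == "correlog"] <= 0))
    stop_fmt("non-positive correlog edge weight")
  if (any(e$w[e$category == "anticorrelog"] >= 0))
    stop_fmt("non-negative anti-correlog edge weight")
  ce <- e[e$category == "correlog", ]
  succ <- stats::setNames(ce$target, ce$source)
  wout <- stats::setNames(ce$w, ce$source)
  reciprocal <- function(a) !is.na(succ[a]) && !is.na(succ[succ[a]]) &&
    succ[succ[a]] == a
  for (v in ce$source) {
    cur <- v
    seen <- character(0)
    while (!is.na(succ[cur]) && !(cur %in% seen)) {
      seen <- c(seen, cur)
      nxt <- succ[[cur]]
      if (reciprocal(cur)) break
      if (!is.na(succ[nxt]) && wout[[nxt]] < wout[[cur]] - 1e-12)
        stop_fmt("correlog chain weight decreased before a reciprocal pair (%s -> %s)",
                 cur, nxt)
      cur <- nxt
    }
  }
  for (g in groups$groups) {
    if (length(g) == 1L) next
    has_recip <- any(vapply(g, function(v) isTRUE(reciprocal(v)), TRUE))
    if (!has_recip)
      stop_fmt("non-singleton correlog group without a reciprocal pair")
  }
  if (sum(groups$sizes) != length(mrs$nodes))
    stop_fmt("group sizes do not sum to the node count")
  invisible(TRUE)
}

#' Write MRS edges as TSV and optionally GraphML
#'
#' @param mrs an `mrs_graph`.
#' @param path output TSV path (columns source, target, w, category).
#' @param graphml optional path for a GraphML rendering with the same
#'   attributes.
#' @return `path`, invisibly.
#' @export
write_mrs <- function(mrs, path, graphml = NULL) {
  stopifnot(inherits(mrs, "mrs_graph"))
  utils::write.table(mrs$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      mrs$edges, directed = TRUE,
      vertices = data.frame(name = mrs$nodes))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' Write correlog group membership as TSV
#'
#' @param groups a `correlog_group_set`.
#' @param path output TSV path (gene_id, group_id, group_size).
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  stopifnot(inherits(groups, "correlog_group_set"))
  utils::write.table(groups$membership, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
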