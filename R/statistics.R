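#' Analytic mean and standard deviation of distinct groups hit
#'
#' When `n_mapped` distinct gene slots are drawn uniformly at random
#' without replacement from the `M = sum(N_g)` slots of a correlog group
#' partition, the number of distinct groups receiving at least one gene
#' has mean `eta = sum_g p_g` with
#' `p_g = 1 - C(M - N_g, n) / C(M, n)` and variance
#' `sum_g p_g (1 - p_g) + sum_{g != h} (q_gh - p_g p_h)` with
#' `q_gh = p_g + p_h - 1 + C(M - N_g - N_h, n) / C(M, n)`
#' (binomial coefficients `C(a, b) = 0` for `a < b`). These are the
#' reference values against which an organism's observed group count is
#' standardized.
#'
#' @param group_sizes integer vector of group sizes `N_g` (all >= 1).
#' @param n_mapped number of genes mapped (0 <= n_mapped <= M).
#' @param replace if `TRUE`, use the with-replacement sampling model
#'   (`p_g = 1 - (1 - N_g/M)^n`) instead; provided for sensitivity
#'   analysis only.
#' @return List with `eta` and `sigma`.
#' @export
clustering_expectation <- function(group_sizes, n_mapped, replace = FALSE) {
  sizes <- as.numeric(group_sizes)
  if (!length(sizes) || any(sizes < 1 | sizes != floor(sizes)))
    stop_fmt("group sizes must be integers >= 1")
  M <- sum(sizes)
  n <- n_mapped
  if (n < 0 || n != floor(n)) stop_fmt("n_mapped must be a non-negative integer")
  if (n > M) stop_fmt("n_mapped (%d) exceeds the number of gene slots (%d)",
                      n, M)
  ratio <- if (replace) {
    function(a) ifelse(a < 0, 0, (a / M)^n)
  } else {
    function(a) ifelse(a < n, 0, exp(lchoose(a, n) - lchoose(M, n)))
  }
  p <- 1 - ratio(M - sizes)
  eta <- sum(p)
  r2 <- ratio(M - outer(sizes, sizes, "+"))
  q <- outer(p, p, "+") - 1 + r2
  covm <- q - outer(p, p)
  diag(covm) <- 0
  sigma2 <- sum(p * (1 - p)) + sum(covm)
  if (sigma2 < 1e-12) sigma2 <- 0   # cancellation residue in degenerate cases
  list(eta = eta, sigma = sqrt(sigma2))
}

#' Attainable range of distinct groups hit
#'
#' `n_max` assumes genes are spread over as many groups as possible;
#' `n_min` packs genes greedily into the largest groups. Observed counts
#' from [clustering_z()] always lie in this interval.
#'
#' @inheritParams clustering_expectation
#' @return List with `n_min` and `n_max`.
#' @export
clustering_bounds <- function(group_sizes, n_mapped) {
  sizes <- sort(as.numeric(group_sizes), decreasing = TRUE)
  M <- sum(sizes)
  if (n_mapped < 0 || n_mapped > M)
    stop_fmt("n_mapped must be in [0, %d]", M)
  if (n_mapped == 0) return(list(n_min = 0L, n_max = 0L))
  list(n_min = which(cumsum(sizes) >= n_mapped)[1],
       n_max = min(n_mapped, length(sizes)))
}

#' Clustering Z score of a gene set on the correlog groups
#'
#' Counts the number `n` of distinct correlog groups containing at least
#' one gene of the set, compares it with the analytic expectation under
#' uniform random mapping of the same number of genes
#' ([clustering_expectation()]), and reports `Z = (n - eta) / sigma`.
#' Strong clustering of an organism's gene repertoire on few groups
#' yields `Z` far below 0. Genes absent from the MRS are dropped and
#' counted.
#'
#' @param groups a `correlog_group_set`.
#' @param gene_set character vector of gene ids (duplicates ignored).
#' @param replace passed to [clustering_expectation()].
#' @return A `cluster_stat`: list with `n`, `eta`, `sigma`, `Z`
#'   (NA-flagged with a `note` when `sigma = 0`), `n_mapped`,
#'   `n_unmapped`.
#' @export
clustering_z <- function(groups, gene_set, replace = FALSE) {
  stopifnot(inherits(groups, "correlog_group_set"))
  gene_set <- unique(gene_set)
  memb <- groups$membership
  mapped <- intersect(gene_set, memb$gene_id)
  if (!length(mapped))
    stop_fmt("none of the %d genes map to the correlog groups",
             length(gene_set))
  n <- length(unique(memb$group_id[match(mapped, memb$gene_id)]))
  ex <- clustering_expectation(groups$sizes, length(mapped),
                               replace = replace)
  note <- NULL
  if (ex$sigma < 1e-12) {
    Z <- NA_real_
    note <- "sigma = 0 under the null (saturated or degenerate mapping); Z undefined"
  } else Z <- (n - ex$eta) / ex$sigma
  structure(list(n = n, eta = ex$eta, sigma = ex$sigma, Z = Z,
                 n_mapped = length(mapped),
                 n_unmapped = length(gene_set) - length(mapped),
                 note = note),
            class = "cluster_stat")
}

#' @export
print.cluster_stat <- function(x, ...) {
  cat(sprintf("cluster_stat: n = %d groups hit by %d genes; eta = %.3f, sigma = %.3f, Z = %s\n",
              x$n, x$n_mapped, x$eta, x$sigma,
              if (is.na(x$Z)) paste0("NA (", x$note, ")") else
                sprintf("%.3f", x$Z)))
  invisible(x)
}

## Annotation sets for the genes of each group; only annotated members.
group_annotation_sets <- function(groups, ann) {
  lapply(groups$groups, function(g) {
    g <- intersect(g, names(ann))
    unname(ann[g])
  })
}

## Fraction of groups with >1 annotated gene in which some category
## covers every annotated gene (max_c f_c^g = 1).
coherent_fraction <- function(sets_per_group) {
  elig <- sets_per_group[lengths(sets_per_group) > 1]
  if (!length(elig)) return(NA_real_)
  mean(vapply(elig, function(s) length(Reduce(intersect, s)) > 0, TRUE))
}

#' Functional coherence of correlog groups
#'
#' For group g and category c, `f_c^g = Ntilde_c^g / Ntilde^g`, where
#' `Ntilde^g` is the number of group members carrying at least one
#' category and `Ntilde_c^g` the number carrying category c. The summary
#' is the fraction of groups with `Ntilde^g > 1` in which some category
#' attains `f_c^g = 1` (all annotated members share a function).
#'
#' @param groups a `correlog_group_set`.
#' @param ann an `annotation_map`.
#' @return List with `table` (group_id, category, n_annotated, f),
#'   `summary` (the coherent fraction, NA if no eligible group) and
#'   `n_eligible`.
#' @export
functional_coherence <- function(groups, ann) {
  stopifnot(inherits(groups, "correlog_group_set"),
            inherits(ann, "annotation_map"))
  sets <- group_annotation_sets(groups, ann)
  rows <- lapply(seq_along(sets), function(gi) {
    s <- sets[[gi]]
    if (!length(s)) return(NULL)
    tab <- table(unlist(s, use.names = FALSE))
    data.frame(group_id = gi, category = names(tab),
               n_annotated = length(s),
               f = as.numeric(tab) / length(s),
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows),
       summary = coherent_fraction(sets),
       n_eligible = sum(lengths(sets) > 1))
}

## Permute annotation sets among annotated genes of equal annotation
## cardinality; returns the permuted annotation list (names = genes).
shuffle_annotations <- function(ann_list) {
  card <- lengths(ann_list)
  out <- ann_list
  for (k in unique(card)) {
    idx <- which(card == k)
    if (length(idx) > 1) out[idx] <- ann_list[sample(idx)]
  }
  out
}

#' Permutation Z score for the coherent-group fraction
#'
#' Null model: annotation sets are randomly exchanged among genes
#' carrying the same number of categories (so the multiset of annotation
#' sets and each gene's label count are preserved), and the coherent
#' fraction of [functional_coherence()] is recomputed.
#'
#' @param groups a `correlog_group_set`.
#' @param ann an `annotation_map`.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `observed`, `null_mean`, `null_sd`, `Z`
#'   (NA-flagged with `note` if the null is degenerate) and `null`.
#' @export
coherence_null_z <- function(groups, ann, n_perm = 1000, seed = 1) {
  stopifnot(inherits(groups, "correlog_group_set"),
            inherits(ann, "annotation_map"))
  if (n_perm < 100) stop_fmt("n_perm must be >= 100")
  genes <- intersect(groups$membership$gene_id, names(ann))
  ann_list <- unclass(ann)[genes]
  memb <- split(groups$membership$gene_id, groups$membership$group_id)
  frac_of <- function(alist) {
    sets <- lapply(memb, function(g) {
      g <- intersect(g, names(alist))
      unname(alist[g])
    })
    coherent_fraction(sets)
  }
  observed <- frac_of(ann_list)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    frac_of(shuffle_annotations(ann_list))
  }, 0))
  m <- mean(null); s <- stats::sd(null)
  note <- NULL
  if (is.na(s) || s < 1e-12) {
    Z <- NA_real_
    note <- "degenerate permutation null (sd = 0)"
    if (!is.na(observed) && !is.na(m) && observed == m) Z <- 0
  } else Z <- (observed - m) / s
  list(observed = observed, null_mean = m, null_sd = s, Z = Z,
       null = null, note = note)
}

#' Overlap of two functional categories on the correlog groups
#'
#' The ratio of the number of correlog groups containing genes of both
#' categories to the number containing genes of either, `Y` in
#' \[0, 1\]. `Y = 1` means the categories always co-segregate into the
#' same groups; for `c1 == c2`, `Y = 1` whenever the category occurs.
#'
#' @param groups a `correlog_group_set`.
#' @param ann an `annotation_map`.
#' @param c1,c2 category labels.
#' @return Scalar `Y`; `NA` with attribute `note` when neither category
#'   occurs in any group.
#' @export
category_overlap <- function(groups, ann, c1, c2) {
  stopifnot(inherits(groups, "correlog_group_set"),
            inherits(ann, "annotation_map"))
  sets <- group_annotation_sets(groups, ann)
  cats_per_group <- lapply(sets, function(s) unique(unlist(s, use.names = FALSE)))
  has1 <- vapply(cats_per_group, function(cc) c1 %in% cc, TRUE)
  has2 <- vapply(cats_per_group, function(cc) c2 %in% cc, TRUE)
  either <- has1 | has2
  if (!any(either))
    return(structure(NA_real_, note = "neither category occurs in any group"))
  sum(has1 & has2) / sum(either)
}

#' Permutation P value for a category-overlap ratio
#'
#' One-sided empirical P for the observed [category_overlap()] under the
#' cardinality-preserving annotation shuffle of [coherence_null_z()],
#' with the add-one convention `P = (1 + #{Y_null >= Y_obs}) / (1 + n_perm)`.
#'
#' @inheritParams category_overlap
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return List with `P`, `observed` and `null` (vector of null Y).
#' @export
category_overlap_p <- function(groups, ann, c1, c2, n_perm = 1000, seed = 1) {
  if (n_perm < 100) stop_fmt("n_perm must be >= 100")
  observed <- category_overlap(groups, ann, c1, c2)
  if (is.na(observed))
    return(list(P = NA_real_, observed = observed, null = NULL,
                note = attr(observed, "note")))
  genes <- intersect(groups$membership$gene_id, names(ann))
  ann_list <- unclass(ann)[genes]
  memb <- groups$groups
  y_of <- function(alist) {
    hits <- vapply(memb, function(g) {
      cc <- unique(unlist(alist[intersect(g, names(alist))],
                          use.names = FALSE))
      c(c1 %in% cc, c2 %in% cc)
    }, logical(2))
    either <- hits[1, ] | hits[2, ]
    if (!any(either)) return(NA_real_)
    sum(hits[1, ] & hits[2, ]) / sum(either)
  }
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    y_of(shuffle_annotations(ann_list))
  }, 0))
  k <- sum(null >= as.numeric(observed), na.rm = TRUE)
  list(P = (1 + k) / (1 + n_perm), observed = as.numeric(observed),
       null = null, note = NULL)
}

#' Construct a pair set
#'
#' @param gene_a,gene_b character vectors of gene ids (no self-pairs).
#' @param stratum optional per-pair stratum label (e.g. shortest-path
#'   length in an interaction network).
#' @return Data frame of class `pair_set`.
#' @export
pair_set <- function(gene_a, gene_b, stratum = NULL) {
  if (any(gene_a == gene_b)) stop_fmt("self-pairs are not allowed")
  df <- data.frame(gene_a = as.character(gene_a),
                   gene_b = as.character(gene_b),
                   stratum = if (is.null(stratum)) "all"
                             else as.character(stratum),
                   stringsAsFactors = FALSE)
  class(df) <- c("pair_set", "data.frame")
  df
}

#' Shortest-path strata for all gene pairs of an interaction network
#'
#' Computes breadth-first shortest-path lengths between all pairs of the
#' given genes present in the network; connected pairs are labeled with
#' their distance, unreachable pairs with `Inf` (and are excluded from
#' any stratum-matched null).
#'
#' @param edges data frame with columns gene_a, gene_b (undirected).
#' @param gene_ids genes of interest; must intersect the network nodes.
#' @return A `pair_set` with columns gene_a, gene_b, distance, stratum
#'   (character form of finite distances, `"unreachable"` otherwise).
#' @export
shortest_path_strata <- function(edges, gene_ids) {
  nodes <- intersect(unique(c(edges$gene_a, edges$gene_b)), gene_ids)
  if (!length(nodes))
    stop_fmt("no overlap between network nodes and the supplied genes")
  keep <- edges$gene_a %in% nodes & edges$gene_b %in% nodes
  g <- igraph::graph_from_data_frame(edges[keep, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  d <- igraph::distances(g)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  out <- data.frame(gene_a = rownames(d)[ut[, 1]],
                    gene_b = colnames(d)[ut[, 2]],
                    distance = d[ut],
                    stratum = ifelse(is.finite(d[ut]),
                                     as.character(d[ut]), "unreachable"),
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Compare a designated pair set's mean association against a matched null
#'
#' Tests whether a set of gene pairs (e.g. physically interacting
#' proteins, or isozyme pairs) carries systematically larger association
#' scores than arbitrary pairs. The null distribution is built by
#' repeatedly drawing, within each stratum (e.g. each shortest-path
#' length), the same number of random pairs from the stratum's
#' population and averaging; the observed mean is standardized against
#' these null means and a one-sided upper-tail Gaussian P is reported
#' (the null of averages is close to Gaussian by the CLT). The empirical
#' null means are also returned for audit.
#'
#' @param assoc an `association_result` or a plain symmetric matrix with
#'   gene-id dimnames.
#' @param pairs a [pair_set()] of designated pairs (strata optional).
#' @param null_pairs a [pair_set()] giving the candidate population per
#'   stratum; default: all unordered gene pairs of `assoc`, stratum
#'   `"all"`. Pairs with stratum `"unreachable"` are dropped.
#' @param n_draws number of null draws.
#' @param seed RNG seed.
#' @param statistic which matrix to use when `assoc` is an
#'   `association_result`: `"w"`, `"r"`, `"r_star"` or `"I"`.
#' @return List with `observed`, `per_stratum` (data frame of stratum,
#'   n_pairs, mean), `null_mean`, `null_sd`, `Z`, `P` (NA-flagged with
#'   `note` when the null sd is 0) and `null_means`.
#' @export
pairset_w_comparison <- function(assoc, pairs, null_pairs = NULL,
                                 n_draws = 1000, seed = 1,
                                 statistic = c("w", "r", "r_star", "I")) {
  statistic <- match.arg(statistic)
  mat <- if (inherits(assoc, "association_result")) assoc[[statistic]]
         else assoc
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  ids <- rownames(mat)
  pairs <- pairs[pairs$stratum != "unreachable", , drop = FALSE]
  bad <- setdiff(c(pairs$gene_a, pairs$gene_b), ids)
  if (length(bad))
    stop_fmt("pair set references gene absent from the association result: %s",
             bad[1])
  if (is.null(null_pairs)) {
    ut <- which(upper.tri(mat), arr.ind = TRUE)
    null_pairs <- pair_set(ids[ut[, 1]], ids[ut[, 2]])
  }
  null_pairs <- null_pairs[null_pairs$stratum != "unreachable", ,
                           drop = FALSE]
  val <- function(df) mat[cbind(match(df$gene_a, ids),
                                match(df$gene_b, ids))]
  pv <- val(pairs)
  observed <- mean(pv)
  per_stratum <- do.call(rbind, lapply(split(pv, pairs$stratum),
    function(v) data.frame(n_pairs = length(v), mean = mean(v))))
  per_stratum <- data.frame(stratum = rownames(per_stratum), per_stratum,
                            row.names = NULL, stringsAsFactors = FALSE)
  counts <- table(pairs$stratum)
  missing_strata <- setdiff(names(counts), unique(null_pairs$stratum))
  if (length(missing_strata))
    stop_fmt("null population has no pairs in stratum '%s'",
             missing_strata[1])
  nullv <- split(val(null_pairs), null_pairs$stratum)
  n_total <- sum(counts)
  null_means <- with_seed(seed, vapply(seq_len(n_draws), function(b) {
    tot <- 0
    for (s in names(counts)) {
      pop <- nullv[[s]]
      k <- counts[[s]]
      draw <- if (length(pop) < k) {
        sample(pop, k, replace = TRUE)
      } else sample(pop, k)
      tot <- tot + sum(draw)
    }
    tot / n_total
  }, 0))
  m <- mean(null_means); s <- stats::sd(null_means)
  if (any(vapply(names(counts), function(s2)
        length(nullv[[s2]]) < counts[[s2]], TRUE)))
    message("some strata smaller than the designated pair set; resampled with replacement")
  note <- NULL
  if (is.na(s) || s < 1e-15) {
    note <- "degenerate null (sd = 0)"
    if (isTRUE(all.equal(observed, m))) { Z <- 0; P <- 0.5 }
    else { Z <- NA_real_; P <- NA_real_ }
  } else {
    Z <- (observed - m) / s
    P <- stats::pnorm(Z, lower.tail = FALSE)
  }
  list(observed = observed, per_stratum = per_stratum, null_mean = m,
       null_sd = s, Z = Z, P = P, null_means = null_means, note = note)
}

#' Phylum-dispersion Z score of correlogous coupling strength
#'
#' Genes confined to few phyla tend to carry stronger total correlogous
#' coupling `S_i^p`. This regresses `S_i^p` on the number of distinct
#' phyla containing each gene (`n_phyla`, restricted to genes with
#' `n_phyla < n_phyla_max`), reports the OLS slope, its normalized form
#' (slope times `sd(n_phyla)/sd(S_p)`, i.e. the Pearson correlation),
#' and a Z score against surrogate profiles in which each gene's
#' presence vector is independently permuted across species (preserving
#' every `E_i`) and the whole pipeline (w, S_p, n_phyla) is recomputed.
#'
#' @param pm a [profile_matrix] (pre-filter).
#' @param taxonomy named character vector species -> phylum covering all
#'   species of `pm`.
#' @param x_th balance threshold for the embedded pipeline.
#' @param n_phyla_max genes with `n_phyla >=` this are excluded (default
#'   7).
#' @param n_perm number of surrogate datasets (>= 100).
#' @param seed RNG seed.
#' @param lambda_override optional fixed shrinkage intensity.
#' @return List with `slope_raw`, `slope_norm`, `Z`, `null_slopes`,
#'   `n_genes_used`.
#' @export
phylum_dispersion_z <- function(pm, taxonomy, x_th = 80, n_phyla_max = 7,
                                n_perm = 100, seed = 1,
                                lambda_override = NULL) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (n_perm < 100) stop_fmt("n_perm must be >= 100")
  if (!all(pm$species_ids %in% names(taxonomy)))
    stop_fmt("taxonomy does not cover species '%s'",
             setdiff(pm$species_ids, names(taxonomy))[1])
  phy <- unname(taxonomy[pm$species_ids])
  slopes_of <- function(x, strict) {
    pm2 <- profile_matrix(x)
    assoc <- association_pipeline(pm2, x_th = x_th,
                                  lambda_override = lambda_override)
    S <- coupling_strengths(assoc$w)
    xf <- assoc$profile$x
    nphyla <- apply(xf, 1, function(row) length(unique(phy[row == 1L])))
    sel <- nphyla < n_phyla_max
    if (length(unique(nphyla[sel])) < 3) {
      if (strict)
        stop_fmt("fewer than 3 distinct n_phyla values below %d",
                 n_phyla_max)
      return(c(NA_real_, NA_real_, sum(sel)))
    }
    xx <- nphyla[sel]; yy <- S$S_p[sel]
    slope <- stats::cov(xx, yy) / stats::var(xx)
    sdy <- stats::sd(yy)
    norm <- if (sdy == 0) 0 else slope * stats::sd(xx) / sdy
    c(slope, norm, sum(sel))
  }
  obs <- slopes_of(pm$x, strict = TRUE)
  null_slopes <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    xs <- t(apply(pm$x, 1, sample))
    dimnames(xs) <- dimnames(pm$x)
    slopes_of(xs, strict = FALSE)[2]
  }, 0))
  ok <- !is.na(null_slopes)
  m <- mean(null_slopes[ok]); s <- stats::sd(null_slopes[ok])
  Z <- if (is.na(s) || s < 1e-15) NA_real_ else (obs[2] - m) / s
  list(slope_raw = obs[1], slope_norm = obs[2], Z = Z,
       null_slopes = null_slopes, n_genes_used = as.integer(obs[3]))
}
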