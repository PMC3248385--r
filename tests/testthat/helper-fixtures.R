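# Shared fixtures and independent oracles. The oracles deliberately use
# naive formulations (double loops, recursion, exhaustive enumeration) so
# they stay independent of the vectorized implementation paths they check.

make_pm <- function(x, genes = NULL, species = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(x)))
  if (is.null(species)) species <- paste0("s", seq_len(ncol(x)))
  dimnames(x) <- list(genes, species)
  profile_matrix(x)
}

# Random binary profile with no constant gene (resamples offending rows).
random_binary_pm <- function(n_genes, n_species, p = 0.5) {
  x <- matrix(rbinom(n_genes * n_species, 1, p), n_genes, n_species)
  repeat {
    bad <- rowSums(x) %in% c(0L, n_species)
    if (!any(bad)) break
    x[bad, ] <- rbinom(sum(bad) * n_species, 1, p)
  }
  make_pm(x)
}

# Random well-conditioned correlation matrix (sample correlation of
# Gaussian data with more observations than variables).
random_corr <- function(p, n = 5 * p) {
  stats::cor(matrix(rnorm(n * p), n, p))
}

# Recursive pairwise partialization: condition out one variable at a
# time with the first-order formula until only the target pair remains.
partial_recursive <- function(r) {
  p <- nrow(r)
  dimnames(r) <- list(paste0("v", 1:p), paste0("v", 1:p))
  cond_one <- function(rr, k) {
    idx <- setdiff(seq_len(nrow(rr)), k)
    out <- diag(length(idx))
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (a == b) next
      i <- idx[a]; j <- idx[b]
      out[a, b] <- (rr[i, j] - rr[i, k] * rr[j, k]) /
        sqrt((1 - rr[i, k]^2) * (1 - rr[j, k]^2))
    }
    dimnames(out) <- list(rownames(rr)[idx], rownames(rr)[idx])
    out
  }
  w <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    rr <- r
    for (o in paste0("v", setdiff(seq_len(p), c(i, j))))
      rr <- cond_one(rr, which(rownames(rr) == o))
    w[i, j] <- w[j, i] <- rr[paste0("v", i), paste0("v", j)]
  }
  w
}

# Naive double-loop transcription of the identity-target shrinkage
# intensity (unbiased sd, per-pair variance of standardized products).
lambda_naive <- function(x) {
  N <- ncol(x); G <- nrow(x)
  num <- 0; den <- 0
  for (i in seq_len(G - 1)) for (j in (i + 1):G) {
    zi <- (x[i, ] - mean(x[i, ])) / sd(x[i, ])
    zj <- (x[j, ] - mean(x[j, ])) / sd(x[j, ])
    z <- zi * zj
    num <- num + N / (N - 1)^3 * sum((z - mean(z))^2)
    den <- den + (N / (N - 1) * mean(z))^2
  }
  if (den == 0) return(1)
  min(max(num / den, 0), 1)
}

# Exhaustive enumeration oracle for the distinct-groups-hit statistics.
enum_clustering <- function(sizes, n) {
  M <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  ns <- utils::combn(M, n, function(s) length(unique(lab[s])))
  c(eta = mean(ns), sigma = sqrt(mean(ns^2) - mean(ns)^2))
}

# All integer partitions of m (unordered group-size compositions).
all_partitions <- function(m, max_part = m) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  for (k in seq_len(min(m, max_part))) {
    for (rest in all_partitions(m - k, k)) out <- c(out, list(c(k, rest)))
  }
  out
}

# Hand-built correlog_group_set from a list of member vectors (sorted,
# sizes descending) for statistics tests that do not need a real MRS.
make_groups <- function(members) {
  members <- lapply(members, sort)
  ord <- order(-lengths(members), vapply(members, `[`, "", 1L))
  members <- members[ord]
  names(members) <- seq_along(members)
  sizes <- lengths(members)
  gid <- rep(seq_along(members), sizes)
  structure(list(
    membership = data.frame(gene_id = unlist(members, use.names = FALSE),
                            group_id = gid, group_size = sizes[gid],
                            stringsAsFactors = FALSE),
    groups = members, sizes = sizes, n_groups = length(members)),
    class = "correlog_group_set")
}

# Symmetric zero-diagonal random weight matrix.
random_w <- function(p, density = 0.7) {
  w <- matrix(0, p, p)
  ut <- upper.tri(w)
  vals <- runif(sum(ut), -1, 1) * rbinom(sum(ut), 1, density)
  w[ut] <- vals
  w <- w + t(w)
  dimnames(w) <- list(paste0("g", seq_len(p)), paste0("g", seq_len(p)))
  w
}

# Planted world of acceptance criterion 6 and several derived examples.
planted_world <- function(seed = 1) {
  model <- planted_model(n_species = 600, n_modules = 20,
                         genes_per_module = 5, activity_prob = 0.5,
                         fp_rate = 0.05, fn_rate = 0.05, seed = seed)
  gp <- generate_profiles(model)
  list(model = model, gp = gp)
}

# Fraction of MRS anti-correlog edges joining planted anti-paired modules.
anti_pair_fraction <- function(mrs, gp, model) {
  ae <- mrs$edges[mrs$edges$category == "anticorrelog", ]
  if (!nrow(ae)) return(NA_real_)
  ap <- model$anti_pairs
  ma <- gp$modules[ae$source]
  mb <- gp$modules[ae$target]
  mean(mapply(function(a, b) {
    !is.na(a) && !is.na(b) &&
      any((ap[, 1] == a & ap[, 2] == b) | (ap[, 1] == b & ap[, 2] == a))
  }, ma, mb))
}

# Phylum-dispersion fixture: loose narrow-span pair modules in distinct
# phyla vs tight broad modules, over a skewed synthetic taxonomy.
phylum_fixture <- function(seed = 11) {
  sizes <- c(60, 50, 50, 40, 40, 40, 20, 20)
  S <- sum(sizes)
  blocks <- phylum_blocks(S, sizes = sizes)
  span <- c(lapply(1:6, function(m) blocks[[m]]), rep(list(NULL), 6))
  model <- planted_model(n_species = S, n_modules = 12,
                         genes_per_module = c(rep(2, 6), rep(6, 6)),
                         activity_prob = 0.6, anti_pairs = NULL,
                         fp_rate = 0.01,
                         fn_rate = c(rep(0.4, 6), rep(0.02, 6)),
                         module_span = span, seed = seed)
  list(model = model, taxonomy = synthetic_taxonomy(S, sizes = sizes),
       gp = generate_profiles(model))
}
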