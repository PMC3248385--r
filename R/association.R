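#' Pearson correlation between binary gene profiles
#'
#' For genes i and j with presence counts `E_i`, `E_j` over `N` species
#' and co-presence count `C_ij` (species containing both), the
#' correlation is
#' `r_ij = (N C_ij - E_i E_j) / sqrt(E_i (N - E_i) E_j (N - E_j))`,
#' which equals the ordinary Pearson correlation of the two 0/1 vectors.
#'
#' @param pm a [profile_matrix]; every gene must satisfy `0 < E_i < N`
#'   (guaranteed after [filter_by_prevalence()] with `x_th >= 1`).
#' @return Symmetric correlation matrix with unit diagonal, dimnames =
#'   gene ids.
#' @export
pearson_binary <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  deg <- pm$E == 0L | pm$E == pm$N
  if (any(deg))
    stop_fmt("gene '%s' is present in %d of %d species: variance undefined; filter first",
             pm$gene_ids[which(deg)[1]], pm$E[which(deg)[1]], pm$N)
  x <- pm$x
  N <- pm$N
  E <- pm$E
  C <- tcrossprod(x)
  v <- E * (N - E)
  r <- (N * C - outer(E, E)) / sqrt(outer(v, v))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Mutual information between binary gene profiles
#'
#' Computes, for every gene pair, the mutual information of the joint
#' 2x2 presence/absence table across species,
#' `I_ij = sum_ab p(a,b) log( p(a,b) / (p(a) p(b)) )` with `0 log 0 = 0`.
#' The diagonal is the marginal entropy of each profile. Unlike the
#' partial-correlation weight, I is a purely pairwise measure and keeps
#' transitive (indirect) associations; it is provided for comparison.
#'
#' @param pm a [profile_matrix].
#' @param unit `"nats"` (natural log, default) or `"bits"`.
#' @return Symmetric non-negative matrix of mutual information.
#' @export
mutual_information <- function(pm, unit = c("nats", "bits")) {
  unit <- match.arg(unit)
  stopifnot(inherits(pm, "profile_matrix"))
  x <- pm$x
  N <- pm$N
  E <- pm$E
  n11 <- tcrossprod(x)
  n10 <- outer(E, rep(1, length(E))) - n11   # i present, j absent
  n01 <- t(n10)
  n00 <- N - n11 - n10 - n01
  term <- function(nab, na, nb) {
    out <- matrix(0, nrow(nab), ncol(nab))
    pos <- nab > 0
    out[pos] <- (nab[pos] / N) * log(nab[pos] * N / (na[pos] * nb[pos]))
    out
  }
  Ei <- outer(E, rep(1, length(E)))
  Ej <- t(Ei)
  I <- term(n11, Ei, Ej) + term(n10, Ei, N - Ej) +
    term(n01, N - Ei, Ej) + term(n00, N - Ei, N - Ej)
  I <- (I + t(I)) / 2
  I[I < 0] <- 0   # clip tiny negative rounding
  dimnames(I) <- list(pm$gene_ids, pm$gene_ids)
  if (unit == "bits") I <- I / log(2)
  I
}

#' Analytic shrinkage intensity for the correlation matrix
#'
#' Schaefer-Strimmer estimator with the identity shrinkage target:
#' standardize each profile with the unbiased (N-1) standard deviation,
#' form the per-species products `z_kij = z_ki z_kj`, and set
#' `lambda = sum_{i!=j} Var_hat(r_ij) / sum_{i!=j} r_ij^2`, where
#' `Var_hat(r_ij) = N/(N-1)^3 * sum_k (z_kij - mean_k z_kij)^2`,
#' clipped to \[0, 1\]. When the denominator is exactly zero (all
#' off-diagonal correlations vanish) the estimator degenerates and full
#' shrinkage `lambda = 1` is returned with a message.
#'
#' @param pm a [profile_matrix] with at least 2 species and every gene
#'   non-constant across species.
#' @return Scalar `lambda` in \[0, 1\].
#' @export
shrinkage_lambda <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (pm$N < 2) stop_fmt("need at least 2 species to estimate lambda")
  deg <- pm$E == 0L | pm$E == pm$N
  if (any(deg))
    stop_fmt("gene '%s' is constant across species; filter first",
             pm$gene_ids[which(deg)[1]])
  N <- pm$N
  Z <- scale(t(pm$x))                  # species x genes, sd uses N-1
  zbar <- crossprod(Z) / N             # mean_k z_ki z_kj
  sum_sq <- crossprod(Z^2)             # sum_k z_ki^2 z_kj^2
  var_hat <- N / (N - 1)^3 * (sum_sq - N * zbar^2)
  r <- N / (N - 1) * zbar
  off <- upper.tri(r)
  den <- 2 * sum(r[off]^2)
  if (den < 1e-12) {
    message("degenerate shrinkage: all off-diagonal correlations are 0; lambda set to 1")
    return(1)
  }
  clip01(2 * sum(var_hat[off]) / den)
}

#' Shrink a correlation matrix toward the identity
#'
#' `r*_ij = (1 - lambda) r_ij + lambda delta_ij`: off-diagonal entries
#' scaled by `1 - lambda`, diagonal fixed at 1. For any `lambda > 0` the
#' result is positive definite when `r` is a valid correlation matrix,
#' which makes the subsequent matrix inversion well conditioned even when
#' genes outnumber species.
#'
#' @param r symmetric correlation matrix with unit diagonal.
#' @param lambda shrinkage intensity in \[0, 1\].
#' @return The shrunk matrix `r_star`.
#' @export
shrink_correlation <- function(r, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop_fmt("lambda must be a single number in [0, 1], got %s",
             format(lambda))
  r_star <- (1 - lambda) * r
  diag(r_star) <- 1
  r_star
}

#' Partial correlations from a (shrunk) correlation matrix
#'
#' Inverts the correlation matrix and rescales the precision entries:
#' `w_ij = -p_ij / sqrt(p_ii p_jj)`, where `p` is the inverse of
#' `r_star`. Conditioning on all other genes removes transitive
#' correlations, so `w_ij > 0` marks a direct correlog association and
#' `w_ij < 0` an anti-correlog one. The diagonal is reported as 0 by
#' convention (self-association is meaningless).
#'
#' @param r_star symmetric positive-definite matrix, e.g. from
#'   [shrink_correlation()].
#' @return Symmetric matrix `w` with zero diagonal and entries in
#'   \[-1, 1\].
#' @export
partial_correlation <- function(r_star) {
  p <- tryCatch(chol2inv(chol(r_star)),
                error = function(e)
                  stop_fmt("correlation matrix is singular (%s); raise the shrinkage intensity lambda",
                           conditionMessage(e)))
  d <- diag(p)
  w <- -p / sqrt(outer(d, d))
  asym <- max(abs(w - t(w)))
  if (asym > 1e-10)
    stop_fmt("partial correlation matrix asymmetric beyond tolerance (%g)", asym)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  dimnames(w) <- dimnames(r_star)
  w
}

#' Full association pipeline on a profile matrix
#'
#' Runs prevalence filtering, Pearson correlation, analytic shrinkage,
#' partial correlation and mutual information, and bundles the results.
#'
#' @param pm a [profile_matrix].
#' @param x_th balance threshold passed to [filter_by_prevalence()].
#' @param lambda_override optional number in \[0, 1\] bypassing the
#'   analytic shrinkage intensity (sensitivity analysis; `1` shrinks to
#'   the identity and zeroes every `w_ij`).
#' @param mi_unit unit for mutual information, `"nats"` or `"bits"`.
#' @return An `association_result`: list with `gene_ids`, matrices `r`,
#'   `r_star`, `w`, `I`, scalar `lambda`, the `filter` report and the
#'   filtered `profile`.
#' @export
association_pipeline <- function(pm, x_th = 80, lambda_override = NULL,
                                 mi_unit = "nats") {
  f <- filter_by_prevalence(pm, x_th)
  pmf <- f$profile
  r <- pearson_binary(pmf)
  lambda <- if (is.null(lambda_override)) shrinkage_lambda(pmf) else {
    if (!is.numeric(lambda_override) || lambda_override < 0 ||
        lambda_override > 1)
      stop_fmt("lambda_override must be in [0, 1]")
    lambda_override
  }
  r_star <- shrink_correlation(r, lambda)
  w <- partial_correlation(r_star)
  I <- mutual_information(pmf, unit = mi_unit)
  structure(
    list(gene_ids = pmf$gene_ids, r = r, r_star = r_star, w = w, I = I,
         lambda = lambda, filter = f$report, profile = pmf),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result: %d genes, lambda = %.4f, %d correlog / %d anti-correlog pairs\n",
              length(x$gene_ids), x$lambda,
              sum(x$w[upper.tri(x$w)] > 0), sum(x$w[upper.tri(x$w)] < 0)))
  invisible(x)
}

#' Write pairwise association scores as a long-format edge list
#'
#' One row per unordered gene pair (i < j in the result's gene order)
#' with columns gene_i, gene_j, r, r_star, w, I.
#'
#' @param assoc an `association_result`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_association <- function(assoc, path) {
  stopifnot(inherits(assoc, "association_result"))
  ut <- which(upper.tri(assoc$w), arr.ind = TRUE)
  df <- data.frame(gene_i = assoc$gene_ids[ut[, 1]],
                   gene_j = assoc$gene_ids[ut[, 2]],
                   r = assoc$r[ut], r_star = assoc$r_star[ut],
                   w = assoc$w[ut], I = assoc$I[ut])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
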