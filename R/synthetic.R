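#' Specify a planted-module generative model for synthetic profiles
#'
#' The generator emulates the statistical structure the pipeline
#' assumes: disjoint gene modules that switch on and off together per
#' species (producing correlogy), pairs of modules constrained to be
#' mutually exclusive within a species (producing anti-correlogy),
#' presence/absence noise, and optional independent background genes.
#' Defaults describe a panel of 600 species carrying 20 five-gene
#' modules with activity probability 0.5 and 5% false-positive /
#' false-negative rates, with consecutive modules anti-paired.
#'
#' @param n_species number of species (columns).
#' @param n_modules,genes_per_module module layout; gene ids are
#'   `m<module>_g<gene>`, species ids `s<k>`.
#' @param activity_prob per-module probability `pi_g` that the module is
#'   active in a species (scalar or vector of length `n_modules`).
#' @param anti_pairs 2-column matrix (or list of length-2 vectors) of
#'   module indices constrained to mutual exclusivity; `"consecutive"`
#'   (default) pairs module 1 with 2, 3 with 4, ...; `NULL` for none.
#' @param fp_rate probability a gene is present although its module is
#'   inactive in that species; scalar or per-module vector (noise rates
#'   control how tightly a module's genes are coupled, hence their
#'   coupling strengths `S_i^p`).
#' @param fn_rate probability a gene is absent although its module is
#'   active; scalar or per-module vector.
#' @param n_background number of module-free genes with i.i.d. presence.
#' @param background_prob presence probability of background genes.
#' @param module_span optional list (length `n_modules`) of species index
#'   vectors outside which the module is forced inactive (`NULL` entries
#'   mean unrestricted). Restricting spans plants a relationship between
#'   a gene's taxonomic spread and its couplings, used by the
#'   phylum-dispersion analysis.
#' @param seed integer seed; every generator derives its stream from it,
#'   so a model is a pure function of its parameters.
#' @return A `planted_model` list.
#' @export
planted_model <- function(n_species = 600, n_modules = 20,
                          genes_per_module = 5, activity_prob = 0.5,
                          anti_pairs = "consecutive", fp_rate = 0.05,
                          fn_rate = 0.05, n_background = 0,
                          background_prob = 0.25, module_span = NULL,
                          seed = 1) {
  stopifnot(n_species >= 1, n_modules >= 1, all(genes_per_module >= 1),
            all(activity_prob >= 0 & activity_prob <= 1),
            all(fp_rate >= 0 & fp_rate <= 1),
            all(fn_rate >= 0 & fn_rate <= 1),
            background_prob >= 0, background_prob <= 1)
  if (identical(anti_pairs, "consecutive")) {
    k <- n_modules %/% 2
    anti_pairs <- if (k) cbind(2 * seq_len(k) - 1, 2 * seq_len(k))
                  else NULL
  } else if (is.list(anti_pairs)) {
    anti_pairs <- do.call(rbind, anti_pairs)
  }
  if (!is.null(anti_pairs)) {
    anti_pairs <- matrix(as.integer(anti_pairs), ncol = 2)
    if (any(anti_pairs < 1 | anti_pairs > n_modules) ||
        any(anti_pairs[, 1] == anti_pairs[, 2]))
      stop_fmt("anti_pairs must reference two distinct modules in 1..%d",
               n_modules)
  }
  pi_g <- rep_len(activity_prob, n_modules)
  gpm <- rep_len(genes_per_module, n_modules)
  modules <- lapply(seq_len(n_modules), function(m)
    sprintf("m%02d_g%02d", m, seq_len(gpm[m])))
  if (!is.null(module_span)) {
    if (length(module_span) != n_modules)
      stop_fmt("module_span must have one entry per module")
    bad <- unlist(module_span, use.names = FALSE)
    if (length(bad) && (any(bad < 1) || any(bad > n_species)))
      stop_fmt("module_span indices must be in 1..%d", n_species)
  }
  structure(
    list(n_species = n_species, modules = modules, activity_prob = pi_g,
         anti_pairs = anti_pairs,
         fp_rate = rep_len(fp_rate, n_modules),
         fn_rate = rep_len(fn_rate, n_modules),
         n_background = n_background, background_prob = background_prob,
         module_span = module_span, seed = as.integer(seed)),
    class = "planted_model")
}

## Per-generator RNG streams derived from the model seed, so that e.g.
## regenerating annotations does not perturb the profile draw.
model_seed <- function(model, salt)
  as.integer((as.numeric(model$seed) * 7 + as.numeric(salt)) %% 2147483647)

#' Generate a synthetic profile matrix from a planted model
#'
#' Per species, each module is drawn active with its probability; for
#' each anti-pair with both modules active, one of the two is
#' deactivated uniformly at random (keeping marginal activities
#' symmetric). A module gene is then present iff its module is active
#' and no false-negative dropout occurs, or the module is inactive and a
#' false-positive insertion occurs. Background genes are i.i.d.
#' Bernoulli.
#'
#' @param model a [planted_model()].
#' @return List with `profile` (a [profile_matrix]), `modules` (named
#'   vector gene -> module index, `NA` for background genes) and
#'   `activity` (module-by-species logical matrix).
#' @export
generate_profiles <- function(model) {
  stopifnot(inherits(model, "planted_model"))
  with_seed(model_seed(model, 0L), {
    S <- model$n_species
    nm <- length(model$modules)
    A <- matrix(stats::runif(nm * S) < model$activity_prob, nrow = nm)
    if (!is.null(model$module_span)) {
      for (m in seq_len(nm)) {
        span <- model$module_span[[m]]
        if (!is.null(span)) A[m, -span] <- FALSE
      }
    }
    if (!is.null(model$anti_pairs)) {
      for (p in seq_len(nrow(model$anti_pairs))) {
        a <- model$anti_pairs[p, 1]; b <- model$anti_pairs[p, 2]
        both <- A[a, ] & A[b, ]
        coin <- stats::runif(S) < 0.5
        A[a, both & coin] <- FALSE
        A[b, both & !coin] <- FALSE
      }
    }
    genes <- unlist(model$modules, use.names = FALSE)
    mod_of <- rep(seq_len(nm), lengths(model$modules))
    act <- A[mod_of, , drop = FALSE]
    noise <- matrix(stats::runif(length(genes) * S), nrow = length(genes))
    fn_g <- model$fn_rate[mod_of]   # recycles down columns: one rate per gene
    fp_g <- model$fp_rate[mod_of]
    x <- ifelse(act, noise >= fn_g, noise < fp_g)
    if (model$n_background > 0) {
      bg <- matrix(stats::runif(model$n_background * S) <
                     model$background_prob,
                   nrow = model$n_background)
      x <- rbind(x, bg)
      genes <- c(genes, sprintf("bg_g%03d", seq_len(model$n_background)))
      mod_of <- c(mod_of, rep(NA_integer_, model$n_background))
    }
    x <- matrix(as.integer(x), nrow = length(genes),
                dimnames = list(genes, sprintf("s%03d", seq_len(S))))
    rownames(A) <- sprintf("module%02d", seq_len(nm))
    colnames(A) <- colnames(x)
    list(profile = profile_matrix(x),
         modules = stats::setNames(mod_of, genes),
         activity = A)
  })
}

#' Generate a synthetic annotation map for a planted model
#'
#' Each module defines one functional category; each module gene is
#' annotated with its module's category with probability `purity` and
#' with a uniformly random other category otherwise. Background genes
#' stay unannotated.
#'
#' @param model a [planted_model()].
#' @param purity probability in \[0, 1\] that a gene keeps its module's
#'   category.
#' @return An `annotation_map`.
#' @export
generate_annotations <- function(model, purity = 1) {
  stopifnot(inherits(model, "planted_model"), purity >= 0, purity <= 1)
  with_seed(model_seed(model, 1L), {
    nm <- length(model$modules)
    cats <- sprintf("C%02d", seq_len(nm))
    genes <- unlist(model$modules, use.names = FALSE)
    mod_of <- rep(seq_len(nm), lengths(model$modules))
    keep <- stats::runif(length(genes)) < purity
    lab <- ifelse(keep, cats[mod_of],
                  cats[sample.int(nm, length(genes), replace = TRUE)])
    annotation_map(stats::setNames(lab, genes))
  })
}

#' Generate a synthetic interaction network for a planted model
#'
#' Random undirected graph over the module genes with independent edge
#' probability `within_prob` inside modules and `between_prob` across
#' modules; a stand-in for a protein-protein interaction network in
#' pair-set comparisons.
#'
#' @param model a [planted_model()].
#' @param within_prob,between_prob edge probabilities in \[0, 1\].
#' @return Data frame with columns gene_a, gene_b.
#' @export
generate_interactions <- function(model, within_prob = 0.5,
                                  between_prob = 0.02) {
  stopifnot(inherits(model, "planted_model"),
            within_prob >= 0, within_prob <= 1,
            between_prob >= 0, between_prob <= 1)
  with_seed(model_seed(model, 2L), {
    genes <- unlist(model$modules, use.names = FALSE)
    mod_of <- rep(seq_along(model$modules), lengths(model$modules))
    ut <- which(upper.tri(diag(length(genes))), arr.ind = TRUE)
    same <- mod_of[ut[, 1]] == mod_of[ut[, 2]]
    p <- ifelse(same, within_prob, between_prob)
    keep <- stats::runif(length(p)) < p
    data.frame(gene_a = genes[ut[keep, 1]], gene_b = genes[ut[keep, 2]],
               stringsAsFactors = FALSE)
  })
}

#' Generate synthetic organism gene sets from a planted model
#'
#' Each organism carries the union of the genes of a few randomly chosen
#' modules, with each gene independently dropped with probability
#' `dropout` — the situation in which gene repertoires cluster on few
#' correlog groups.
#'
#' @param model a [planted_model()].
#' @param n_organisms number of sets.
#' @param modules_per_organism modules drawn (without replacement) per
#'   organism.
#' @param dropout per-gene loss probability.
#' @return Named list of character gene-id vectors.
#' @export
generate_organism_sets <- function(model, n_organisms = 10,
                                   modules_per_organism = 3,
                                   dropout = 0.1) {
  stopifnot(inherits(model, "planted_model"),
            modules_per_organism <= length(model$modules),
            dropout >= 0, dropout <= 1)
  with_seed(model_seed(model, 3L), {
    sets <- lapply(seq_len(n_organisms), function(o) {
      mods <- sample.int(length(model$modules), modules_per_organism)
      genes <- unlist(model$modules[mods], use.names = FALSE)
      genes[stats::runif(length(genes)) >= dropout]
    })
    stats::setNames(sets, sprintf("org%03d", seq_len(n_organisms)))
  })
}

#' Synthetic species-to-phylum taxonomy
#'
#' Partitions the species of a planted model into contiguous equal-size
#' blocks, one synthetic phylum per block — the fixture consumed by
#' [phylum_dispersion_z()].
#'
#' @param n_species number of species (ids `s<k>` as produced by
#'   [generate_profiles()]).
#' @param n_phyla number of equal-size blocks (ignored when `sizes` is
#'   given).
#' @param sizes optional explicit phylum sizes summing to `n_species`;
#'   real phylum sizes are heavily skewed, and a skewed fixture keeps
#'   the surrogate `n_phyla` distribution non-degenerate.
#' @return Named character vector species id -> phylum label.
#' @export
synthetic_taxonomy <- function(n_species, n_phyla = 8, sizes = NULL) {
  if (is.null(sizes)) {
    stopifnot(n_phyla >= 1, n_phyla <= n_species)
    block <- ceiling(n_species / n_phyla)
    lab <- (seq_len(n_species) - 1) %/% block + 1
  } else {
    if (sum(sizes) != n_species)
      stop_fmt("phylum sizes must sum to n_species (%d)", n_species)
    lab <- rep(seq_along(sizes), sizes)
  }
  stats::setNames(sprintf("P%02d", lab), sprintf("s%03d", seq_len(n_species)))
}

#' Species index blocks for synthetic phyla
#'
#' Convenience inverse of [synthetic_taxonomy()]: the species indices of
#' each phylum block, usable as `module_span` entries in
#' [planted_model()].
#'
#' @inheritParams synthetic_taxonomy
#' @return List of integer vectors, one per phylum.
#' @export
phylum_blocks <- function(n_species, n_phyla = 8, sizes = NULL) {
  tax <- synthetic_taxonomy(n_species, n_phyla, sizes)
  unname(split(seq_len(n_species), tax))
}
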