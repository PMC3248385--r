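#' @keywords internal
"_PACKAGE"

## Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clip01 <- function(x) min(max(x, 0), 1)

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' used to score recovery of planted modules by inferred correlog groups.
#' Items with `NA` in either labeling are dropped.
#'
#' @param a,b vectors of cluster labels of equal length.
#' @return A number in (-1, 1]; 1 means identical partitions, 0 is the
#'   expected value for independent random partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !(is.na(a) | is.na(b))
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) return(NA_real_)
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_ij <- sum_a * sum_b / choose(n, 2)
  max_ij <- (sum_a + sum_b) / 2
  if (max_ij == exp_ij) return(1)
  (sum_ij - exp_ij) / (max_ij - exp_ij)
}
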