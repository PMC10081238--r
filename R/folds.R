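#' Partition samples into k equal, non-overlapping folds
#'
#' Randomly assigns n samples to k disjoint folds whose sizes differ by at
#' most one (the first `n %% k` folds receive the extra sample). When
#' stratification labels are supplied — by default the binary outcome, so
#' every fold contains both cases and controls — each stratum is split as
#' evenly as possible across folds while the overall size balance is
#' preserved.
#'
#' The assignment is deterministic given `(n, k, seed, strata)` and is drawn
#' in its own RNG substream: the caller's random-number stream is untouched.
#'
#' @param n number of samples.
#' @param k number of folds, `1 <= k <= n`.
#' @param seed integer seed recorded in the result.
#' @param strata optional length-n label vector; folds are balanced within
#'   each level.
#' @param min_fold_size optional guard: error if any fold ends up smaller.
#'   Callers testing a model with c covariates pass `c + 3` so every fold
#'   keeps at least one residual degree of freedom with margin.
#' @return An object of class `fold_assignment`: list with
#'   `fold_of_sample` (integer vector in `1..k`), `k`, `seed`, `stratified`.
#' @examples
#' fa <- partition_folds(10, 5, seed = 1)
#' table(fa$fold_of_sample)
#' @export
partition_folds <- function(n, k, seed, strata = NULL, min_fold_size = NULL) {
  if (!.is_count(n) || n < 1L) .stop("bad_input", "`n` must be a positive integer")
  if (!.is_count(k) || k < 1L || k > n)
    .stop("invalid_fold_count",
          sprintf("`k` must be an integer in [1, n]; got k = %s with n = %d",
                  format(k), n))
  if (!.is_count(seed)) .stop("bad_input", "`seed` must be an integer")
  n <- as.integer(n); k <- as.integer(k)
  if (!is.null(strata) && length(strata) != n)
    .stop("dimension", "`strata` must have length n")

  fold_of <- integer(n)
  .with_seed(seed, {
    if (is.null(strata)) {
      sizes <- rep.int(n %/% k, k)
      if (n %% k > 0L) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
      fold_of[sample.int(n)] <- rep.int(seq_len(k), sizes)
    } else {
      # Per stratum: every fold gets floor(s/k); the remainder goes to the
      # folds currently smallest (random tie-break). Inductively the fold
      # counts stay within 1 of each other after every stratum.
      counts <- integer(k)
      for (lev in sort(unique(as.character(strata)))) {
        idx <- which(as.character(strata) == lev)
        idx <- idx[sample.int(length(idx))]
        alloc <- rep.int(length(idx) %/% k, k)
        rem <- length(idx) %% k
        if (rem > 0L) {
          ord <- order(counts, sample.int(k))
          alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1L
        }
        counts <- counts + alloc
        fold_of[idx] <- rep.int(seq_len(k), alloc)
      }
    }
  })
  if (!is.null(min_fold_size)) {
    sizes <- tabulate(fold_of, nbins = k)
    if (min(sizes) < min_fold_size)
      .stop("insufficient_fold_size",
            sprintf("smallest fold has %d samples; need at least %d",
                    min(sizes), min_fold_size))
  }
  structure(list(fold_of_sample = fold_of, k = k, seed = as.integer(seed),
                 stratified = !is.null(strata)),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("fold_assignment: %d samples in %d fold(s) (seed %d%s)\n",
              length(x$fold_of_sample), x$k, x$seed,
              if (x$stratified) ", stratified" else ""))
  print(table(fold = x$fold_of_sample))
  invisible(x)
}
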