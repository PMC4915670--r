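#' Mantel permutation test of association between two distance matrices
#'
#' The statistic `R` is the Pearson correlation of the off-diagonal
#' lower-triangle entries of the two matrices, which must index the same
#' individuals in the same order.  Significance is one-sided for positive
#' association (the statistic is used as a similarity score between repeated
#' measurements): the rows and columns of `B` are permuted jointly and
#' `p = (1 + #\{R_perm >= R_obs\}) / (1 + n_perm)`.  When the matrices are
#' small (`n <= 8` individuals, `mode = "auto"`) all `n!` permutations are
#' enumerated instead and `p` is the exact proportion of permutations (the
#' identity included) reaching the observed `R`.
#'
#' `R` is reported as computed and may be negative; it is not clamped to
#' `[0, 1]`.
#'
#' @param A,B symmetric distance matrices (or `dist` objects) of the same
#'   dimension (`n >= 4`).
#' @param n_perm number of random permutations in sampling mode.
#' @param seed optional integer seed for the permutation stream.
#' @param mode `"auto"` (exact when `n <= 8`), `"sample"` or `"exact"`.
#' @return an object of class `"mantel_test"`: `R`, `p`, `n_perm` (number of
#'   non-identity permutations actually used), `n_specimens`, `mode`.
#' @references Mantel, N. (1967) The detection of disease clustering and a
#'   generalized regression approach. Cancer Research 27, 209-220.
#' @export
#' @examples
#' set.seed(7)
#' d1 <- dist(matrix(rnorm(20), 5))
#' mantel_test(d1, d1, mode = "exact")$R  # 1 by construction
mantel_test <- function(A, B, n_perm = 9999, seed = NULL,
                        mode = c("auto", "sample", "exact")) {
  mode <- match.arg(mode)
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  if (nrow(B) != n || ncol(A) != n || ncol(B) != n)
    stop("distance matrices must have the same dimension", call. = FALSE)
  if (n < 4) stop("need at least 4 individuals", call. = FALSE)
  lt <- lower.tri(A)
  a <- A[lt]; b <- B[lt]
  if (stats::sd(a) < 1e-30 || stats::sd(b) < 1e-30)
    stop("zero variance in a distance matrix; Mantel R undefined",
         call. = FALSE)
  obs <- stats::cor(a, b)
  if (mode == "auto") mode <- if (n <= 8) "exact" else "sample"

  if (mode == "exact") {
    perms <- .permutations(n)
    stats_all <- vapply(seq_len(nrow(perms)), function(i) {
      p <- perms[i, ]
      stats::cor(a, B[p, p][lt])
    }, numeric(1))
    p_val <- mean(stats_all >= obs - 1e-12)
    used <- nrow(perms) - 1L
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
    exceed <- with_seed(seed, {
      e <- 0L
      for (i in seq_len(n_perm)) {
        p <- sample.int(n)
        if (stats::cor(a, B[p, p][lt]) >= obs - 1e-12) e <- e + 1L
      }
      e
    })
    p_val <- (1 + exceed) / (1 + n_perm)
    used <- as.integer(n_perm)
  }
  structure(list(R = obs, p = p_val, n_perm = used, n_specimens = n,
                 mode = mode),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test (%s, one-sided): R = %.4f, p = %.4g (n = %d, %d permutations)\n",
              x$mode, x$R, x$p, x$n_specimens, x$n_perm))
  invisible(x)
}

# all permutations of 1..n as a matrix (n! rows); intended for n <= 8
.permutations <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(matrix(1L, 1, 1))
  if (n > 9L) stop("exhaustive enumeration limited to n <= 9", call. = FALSE)
  sub <- .permutations(n - 1L)
  blocks <- lapply(seq_len(n), function(pos) {
    # insert the value n at column 'pos' of every sub-permutation
    cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                  drop = FALSE]
  })
  do.call(rbind, blocks)
}
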