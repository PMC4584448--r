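# Dense 3-way tensor algebra used by the PARAFAC engine.
#
# Unfolding conventions (column-major, first listed index fastest):
#   mode 1: I x (JK), columns ordered j fast, k slow  -> pairs with kr(C, B)
#   mode 2: J x (IK), columns ordered i fast, k slow  -> pairs with kr(C, A)
#   mode 3: K x (IJ), columns ordered i fast, j slow  -> pairs with kr(B, A)

unfold_tensor <- function(x, mode) {
  d <- dim(x)
  stopifnot(length(d) == 3)
  switch(mode,
    `1` = matrix(x, d[1], d[2] * d[3]),
    `2` = matrix(aperm(x, c(2, 1, 3)), d[2], d[1] * d[3]),
    `3` = matrix(aperm(x, c(3, 1, 2)), d[3], d[1] * d[2]),
    abort_config("mode must be 1, 2 or 3")
  )
}

# column-wise Khatri-Rao product; rows of Y vary fastest
khatri_rao <- function(X, Y) {
  X[rep(seq_len(nrow(X)), each = nrow(Y)), , drop = FALSE] *
    Y[rep(seq_len(nrow(Y)), nrow(X)), , drop = FALSE]
}

# reconstruct a dense tensor from factor matrices
compose_parafac <- function(A, B, C) {
  d <- c(nrow(A), nrow(B), nrow(C))
  array(A %*% t(khatri_rao(C, B)), dim = d)
}

# congruence coefficients (cosine similarity) between columns of two matrices
congruence <- function(X, Y) {
  nx <- sqrt(colSums(X^2))
  ny <- sqrt(colSums(Y^2))
  crossprod(X, Y) / outer(pmax(nx, .Machine$double.eps),
                          pmax(ny, .Machine$double.eps))
}

# best one-to-one column matching maximizing the total of `score` (R x R);
# exhaustive for R <= 7, greedy beyond
match_columns <- function(score) {
  R <- nrow(score)
  if (R <= 7) {
    perms <- permutations_of(R)
    tot <- vapply(perms, function(p) sum(score[cbind(seq_len(R), p)]), 0)
    perms[[which.max(tot)]]
  } else {
    out <- integer(R)
    avail <- seq_len(R)
    for (i in order(-apply(score, 1, max))) {
      j <- avail[which.max(score[i, avail])]
      out[i] <- j
      avail <- setdiff(avail, j)
    }
    out
  }
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(permutations_of(n - 1L), function(p) {
      c(i, setdiff(seq_len(n), i)[p])
    })
  }))
}
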