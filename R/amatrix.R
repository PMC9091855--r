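#' Sparse inverse of the numerator relationship matrix
#'
#' Builds the inverse of the additive (numerator) relationship matrix A
#' directly from the pedigree by Henderson's rules with inbreeding, without
#' ever forming dense A. Inbreeding coefficients come from the
#' Meuwissen-Luo decomposition A = L D L' (each individual's row of L is
#' traced through its ancestors; `a_ii = sum_j L_ij^2 D_j`).
#'
#' @param ped A validated `Pedigree`.
#' @return List of class `AInverse` with `Ainv` (sparse symmetric
#'   `dgCMatrix`, rows/cols in pedigree order, dimnames = ids), `F` (named
#'   inbreeding coefficients) and `D` (Mendelian sampling variances).
#' @export
a_inverse <- function(ped) {
  ord <- pedigree_order(ped)
  ped <- ped[ord, , drop = FALSE]
  n <- nrow(ped)
  sire <- match(ped$sire, ped$id); sire[is.na(sire)] <- 0L
  dam <- match(ped$dam, ped$id); dam[is.na(dam)] <- 0L

  Fi <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    Fs <- if (s > 0) Fi[s] else -1
    Fd <- if (d > 0) Fi[d] else -1
    D[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (s == 0 || d == 0) {
      Fi[i] <- 0
    } else {
      # trace row i of L down through the ancestors
      L <- numeric(i)
      L[i] <- 1
      aii <- 0
      for (j in i:1) {
        lj <- L[j]
        if (lj == 0) next
        aii <- aii + lj * lj * D[j]
        if (sire[j] > 0) L[sire[j]] <- L[sire[j]] + 0.5 * lj
        if (dam[j] > 0) L[dam[j]] <- L[dam[j]] + 0.5 * lj
      }
      Fi[i] <- aii - 1
    }
  }

  # Henderson's rules: for each individual, alpha = 1/D_i contributes to
  # (i,i), (i,parents) and (parent,parent) blocks
  tri <- vector("list", n)
  for (i in seq_len(n)) {
    s <- sire[i]; d <- dam[i]
    alpha <- 1 / D[i]
    rows <- c(i); cols <- c(i); vals <- c(alpha)
    for (p in c(s, d)) {
      if (p > 0) {
        rows <- c(rows, i, p); cols <- c(cols, p, i)
        vals <- c(vals, -alpha / 2, -alpha / 2)
      }
    }
    par <- c(s, d)[c(s, d) > 0]
    for (a in par) for (b in par) {
      rows <- c(rows, a); cols <- c(cols, b); vals <- c(vals, alpha / 4)
    }
    tri[[i]] <- cbind(rows, cols, vals)
  }
  trip <- do.call(rbind, tri)
  Ainv <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                               dims = c(n, n), dimnames = list(ped$id, ped$id))
  Ainv <- Matrix::drop0(Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2))
  structure(list(Ainv = Ainv, F = stats::setNames(Fi, ped$id),
                 D = stats::setNames(D, ped$id)),
            class = "AInverse")
}

#' @export
#' @method print AInverse
print.AInverse <- function(x, ...) {
  cat(sprintf("A-inverse over %d individuals; mean inbreeding F = %.4f\n",
              nrow(x$Ainv), mean(x$F)))
  invisible(x)
}
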