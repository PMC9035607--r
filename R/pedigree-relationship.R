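#' Build the sparse inverse of the additive relationship matrix
#'
#' Classic sire-maternal-grandsire rules: for each bull with sire s and MGS
#' m, the vector (1, -1/2, -1/4) over (bull, s, m) contributes an outer
#' product scaled by d, where d is the inverse Mendelian-sampling variance:
#' 16/11 when both ancestors are known, 4/3 with sire only, 16/15 with MGS
#' only, and 1 for founders. Inbreeding is ignored, so the coefficients stay
#' closed-form; unknown ancestors are absorbed into d (genetic-group means
#' are carried by the model's fixed birth-year effects instead).
#'
#' @param pedigree a \linkS4class{SireMgsPedigree}.
#' @return a \linkS4class{RelationshipInverse}.
#' @export
buildAInverse <- function(pedigree) {
  e <- pedigreeEntries(pedigree)
  n <- nrow(e)
  if (n == 0) stop("pedigree error: empty pedigree")
  pos <- setNames(seq_len(n), e$bull_id)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  coefs <- c(1, -0.5, -0.25)
  for (i in seq_len(n)) {
    s <- e$sire_id[i]
    m <- e$mgs_id[i]
    sKnown <- !.isUnknownId(s)
    mKnown <- !.isUnknownId(m)
    d <- if (sKnown && mKnown) 16 / 11
         else if (sKnown) 4 / 3
         else if (mKnown) 16 / 15
         else 1
    idx <- c(i, if (sKnown) pos[[s]] else NA_integer_,
             if (mKnown) pos[[m]] else NA_integer_)
    for (a in 1:3) {
      if (is.na(idx[a])) next
      for (b in 1:3) {
        if (is.na(idx[b])) next
        ii <- c(ii, idx[a]); jj <- c(jj, idx[b])
        xx <- c(xx, d * coefs[a] * coefs[b])
      }
    }
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            symmetric = FALSE, repr = "T")
  m <- Matrix::forceSymmetric(as(m, "CsparseMatrix"))
  new("RelationshipInverse", matrix = m, indexMap = pos)
}

#' Dense additive relationship matrix by the tabular method
#'
#' Test oracle: builds A directly from the sire-MGS recursion
#' u_i = 1/2 u_s + 1/4 u_m + phi. Off-diagonals follow
#' a_ij = 1/2 a_(s(i),j) + 1/4 a_(m(i),j); diagonals follow the same
#' recursion, a_ii = d_i + 1/4 a_ss + 1/16 a_mm + 1/4 a_sm with the
#' closed-form Mendelian-sampling variance d_i (11/16, 3/4, 15/16 or 1).
#' Because d_i is not adjusted for parental relatedness (inbreeding
#' ignored), a_ii equals 1 exactly whenever a bull's sire and MGS are
#' unrelated and non-inbred, and the matrix is the exact inverse of
#' \code{\link{buildAInverse}} on every pedigree. Capped at 2,000 bulls.
#'
#' @param pedigree a \linkS4class{SireMgsPedigree}.
#' @return dense numeric matrix with bull ids as dimnames.
#' @export
relationshipMatrix <- function(pedigree) {
  e <- pedigreeEntries(pedigree)
  n <- nrow(e)
  if (n > 2000) stop("oracle-size error: pedigree exceeds 2,000 bulls")
  pos <- setNames(seq_len(n), e$bull_id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- if (!.isUnknownId(e$sire_id[i])) pos[[e$sire_id[i]]] else 0L
    m <- if (!.isUnknownId(e$mgs_id[i])) pos[[e$mgs_id[i]]] else 0L
    if (i > 1) {
      for (j in seq_len(i - 1L)) {
        a <- 0
        if (s > 0) a <- a + 0.5 * A[s, j]
        if (m > 0) a <- a + 0.25 * A[m, j]
        A[i, j] <- A[j, i] <- a
      }
    }
    d <- if (s > 0 && m > 0) 11 / 16
         else if (s > 0) 3 / 4
         else if (m > 0) 15 / 16
         else 1
    aii <- d
    if (s > 0) aii <- aii + 0.25 * A[s, s]
    if (m > 0) aii <- aii + 0.0625 * A[m, m]
    if (s > 0 && m > 0) aii <- aii + 0.25 * A[s, m]
    A[i, i] <- aii
  }
  dimnames(A) <- list(e$bull_id, e$bull_id)
  A
}
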