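#' Classical (Torgerson) multidimensional scaling of a distance matrix
#'
#' Embeds populations in low-dimensional coordinates from their pairwise
#' distance matrix by double centering (B = -1/2 J D^2 J) and
#' eigendecomposition, delegating to [stats::cmdscale()]. When the input is
#' an [RstMatrix-class], negative Rst estimates are clamped to zero first
#' (a negative differentiation estimate is sampling noise around zero, not a
#' usable distance). Negative eigenvalues — the signature of a non-Euclidean
#' input — are dropped with a warning; if fewer than `dims` positive
#' eigenvalues exist, fewer coordinate columns are returned and flagged.
#'
#' @param d an [RstMatrix-class] or a square symmetric numeric matrix of
#'   distances.
#' @param dims number of embedding dimensions requested (default 2).
#' @return list with `coords` (matrix, one row per population),
#'   `eigenvalues` (all eigenvalues of the centred matrix), and
#'   `dimsReturned`.
#' @export
classicalMDS <- function(d, dims = 2L) {
  if (is(d, "RstMatrix")) {
    m <- pmax(d@rst, 0)
    dimnames(m) <- list(d@labels, d@labels)
  } else m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("distance matrix must be square and symmetric", call. = FALSE)
  if (dims < 1L) stop("dims must be >= 1", call. = FALSE)
  fit <- stats::cmdscale(stats::as.dist(m), k = min(dims, nrow(m) - 1L),
                         eig = TRUE)
  ev <- fit$eig
  nPos <- sum(ev > max(abs(ev)) * 1e-10)
  if (any(ev < -max(abs(ev)) * 1e-10))
    warning("negative eigenvalues dropped: the distances are not exactly ",
            "Euclidean", call. = FALSE)
  keep <- min(dims, nPos)
  if (keep < dims)
    warning(sprintf("only %d positive eigenvalue(s); returning %d dimension(s)",
                    nPos, keep), call. = FALSE)
  coords <- fit$points[, seq_len(keep), drop = FALSE]
  colnames(coords) <- paste0("dim", seq_len(keep))
  list(coords = coords, eigenvalues = ev, dimsReturned = keep)
}
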