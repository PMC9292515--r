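## Expression-weighted transition matrices.

#' Match expression profiles onto network nodes
#'
#' Gene symbols are matched to node identifiers exactly but
#' case-insensitively. Network nodes without a matching gene get
#' expression 0 in every sample — they become unreachable sinks of the
#' walk — and their count is reported once.
#'
#' @param network a [SignalingNetwork-class].
#' @param expression an [ExpressionProfiles-class] (or a numeric matrix
#'   with gene rownames).
#' @param quiet suppress the unmatched-node message.
#' @return numeric matrix, network nodes x samples.
#' @export
matchExpression <- function(network, expression, quiet = FALSE) {
  vals <- if (is(expression, "ExpressionProfiles")) exprValues(expression)
          else as.matrix(expression)
  nd <- nodes(network)
  idx <- match(toupper(nd), toupper(rownames(vals)))
  out <- matrix(0, length(nd), ncol(vals),
                dimnames = list(nd, colnames(vals)))
  hit <- !is.na(idx)
  out[hit, ] <- vals[idx[hit], , drop = FALSE]
  if (!quiet && any(!hit))
    message(sprintf("%d of %d network node(s) absent from the expression matrix; expression set to 0",
                    sum(!hit), length(nd)))
  out
}

#' Build the per-sample transition matrix
#'
#' For node i with out-neighbours N(i) the unnormalised weight of edge
#' i -> j is `w_ij = E_i * E_j` (the default `"product"` weight), and
#' `p_ij = w_ij / sum_k w_ik` whenever the row total is positive. Because
#' of the row normalisation the global expression scale cancels, and with
#' the product weight `p_ij` reduces to node j's share of the expressed
#' out-neighbourhood whenever `E_i > 0`. Rows with zero total weight —
#' terminal TFs, unexpressed hubs, nodes whose whole out-neighbourhood is
#' unexpressed — get the standard dangling-node treatment: a uniform row
#' over all nodes, i.e. the walk restarts. A self-loop alternative was
#' rejected because it turns every zero-weight row into an absorbing
#' state with stationary probability at least 1/n regardless of
#' expression, which lets technical dropout dominate the single-cell
#' ranking. Edge signs never enter P; they matter only for compatibility
#' scoring.
#'
#' @param network a [SignalingNetwork-class].
#' @param expression named numeric vector (one sample; names are gene
#'   symbols, matched case-insensitively, missing nodes = 0) or a
#'   one-column matrix.
#' @param sample sample identifier stored in the result.
#' @param weight weight function: `"product"` (`E_i*E_j`, default),
#'   `"target"` (`E_j` alone) or `"min"` (`min(E_i, E_j)`).
#' @return a [TransitionMatrix-class].
#' @examples
#' net <- SignalingNetwork(data.frame(from = c("A", "A"), to = c("B", "C"),
#'                                    sign = c(1, 1)))
#' P <- buildTransitionMatrix(net, c(A = 2, B = 3, C = 1))
#' transitionMatrix(P)["A", ]   # 0, 0.75, 0.25
#' @export
buildTransitionMatrix <- function(network, expression, sample = "",
                                  weight = c("product", "target", "min")) {
  weight <- match.arg(weight)
  nd <- nodes(network)
  n <- length(nd)
  if (is.matrix(expression)) expression <- expression[, 1L]
  e <- setNames(rep(0, n), nd)
  idx <- match(toupper(nd), toupper(names(expression)))
  e[!is.na(idx)] <- expression[idx[!is.na(idx)]]
  if (any(e < 0)) stop("expression must be non-negative", call. = FALSE)
  if (all(e == 0)) stop("no expressed nodes in this sample", call. = FALSE)

  ed <- edgeTable(network)
  i <- match(ed$from, nd); j <- match(ed$to, nd)
  w <- switch(weight,
              product = e[i] * e[j],
              target  = ifelse(e[i] > 0, e[j], 0),
              min     = pmin(e[i], e[j]))
  rowTot <- rowsum(w, i)                       # totals for rows with edges
  tot <- setNames(rep(0, n), seq_len(n))
  tot[rownames(rowTot)] <- rowTot[, 1L]
  pos <- tot[as.character(i)] > 0
  p <- ifelse(pos, w / tot[as.character(i)], 0)
  keep <- p > 0
  dangling <- which(tot == 0)                 # zero-weight rows: uniform
  P <- Matrix::sparseMatrix(i = c(i[keep], rep(dangling, each = n)),
                            j = c(j[keep], rep(seq_len(n),
                                               times = length(dangling))),
                            x = c(p[keep], rep(1 / n, n * length(dangling))),
                            dims = c(n, n), dimnames = list(nd, nd))
  new("TransitionMatrix", nodes = nd, P = P, sample = as.character(sample))
}
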