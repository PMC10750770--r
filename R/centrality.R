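#' Expected influence and strength centrality
#'
#' Expected influence of node i is the signed sum of its edge weights,
#' `sum_j w_ij`; unlike strength (`sum_j |w_ij|`) it respects edge sign,
#' which matters in networks with negative edges where a node can
#' deactivate its neighbours. Both indices are also z-standardized across
#' nodes, matching the usual reporting convention for centrality tables.
#' The optional two-step variant adds the influence of each node's
#' neighbours: `EI2_i = EI1_i + sum_j w_ij * EI1_j`.
#'
#' @param network A `ggm_network` (or a bare symmetric weight matrix).
#' @param two_step Also compute two-step expected influence? Default
#'   `FALSE`.
#' @param notable_threshold z-score cutoff for flagging high-centrality
#'   nodes (strict `>`); default 1.
#' @return A `centrality_table` data frame: `node`, `strength`, `ei`,
#'   `z_strength`, `z_ei`, `notable` (and `ei2`, `z_ei2` if requested).
#'   If all edge weights are zero the z columns are `NA`, nothing is
#'   flagged and a warning is raised.
#' @export
expected_influence <- function(network, two_step = FALSE,
                               notable_threshold = 1) {
  W <- if (inherits(network, "ggm_network")) network$W else as.matrix(network)
  stopifnot(nrow(W) == ncol(W))
  diag(W) <- 0
  nodes <- colnames(W) %||% paste0("V", seq_len(ncol(W)))
  strength <- rowSums(abs(W))
  ei <- rowSums(W)
  zs <- function(v) {
    s <- sd(v)
    if (is.na(s) || s == 0) rep(NA_real_, length(v)) else (v - mean(v)) / s
  }
  z_strength <- zs(strength)
  z_ei <- zs(ei)
  if (all(W == 0)) {
    warning("all edge weights are zero: z-scores undefined, no nodes flagged",
            call. = FALSE)
  }
  out <- data.frame(
    node = nodes, strength = strength, ei = ei,
    z_strength = z_strength, z_ei = z_ei,
    notable = !is.na(z_ei) & z_ei > notable_threshold,
    row.names = NULL
  )
  if (two_step) {
    out$ei2 <- ei + as.numeric(W %*% ei)
    out$z_ei2 <- zs(out$ei2)
  }
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Nodes with notable expected influence
#'
#' @param table A `centrality_table` from [expected_influence()].
#' @param threshold Strict lower bound on the z-standardized expected
#'   influence; default 1.
#' @return Character vector of node labels with `z_ei > threshold`.
#' @export
notable_nodes <- function(table, threshold = 1) {
  stopifnot(all(c("node", "z_ei") %in% names(table)))
  table$node[!is.na(table$z_ei) & table$z_ei > threshold]
}
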