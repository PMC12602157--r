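#' Barber modularity of a weighted bipartite network
#'
#' For a donor x recipient weight matrix A with total weight W, row sums k
#' and column sums d, and a partition assigning module labels to donor
#' nodes (`row_labels`) and recipient nodes (`col_labels`),
#' `Q = (1/W) * sum_ij (A_ij - k_i d_j / W) * [row_labels_i == col_labels_j]`.
#' Donor and recipient copies of the same plant are distinct nodes and may
#' carry different labels. The all-in-one-module partition scores exactly
#' 0.
#'
#' @param flow non-negative weight matrix (donors x recipients).
#' @param row_labels,col_labels integer module labels per row / column.
#' @return Modularity Q, or `NA` when the matrix has zero total weight.
#' @export
barber_modularity <- function(flow, row_labels, col_labels) {
  W <- sum(flow)
  if (W <= 0) return(NA_real_)
  B <- flow - outer(rowSums(flow), colSums(flow)) / W
  sum(B[outer(row_labels, col_labels, "==")]) / W
}

# One label-propagation pass + merge loop from a given initial labelling.
# B is the (A - k d / W) null-adjusted matrix; returns list(row, col, Q).
.lpa_optimize <- function(flow, B, W, row_labels, col_labels) {
  m <- nrow(flow); n <- ncol(flow)
  score <- function() sum(B[outer(row_labels, col_labels, "==")]) / W

  propagate <- function() {
    changed <- FALSE
    for (i in sample.int(m)) {
      labs <- sort(unique(col_labels))
      s <- vapply(labs, function(l) sum(B[i, col_labels == l]), numeric(1))
      best <- max(s)
      cur <- row_labels[i]
      cur_s <- if (cur %in% labs) s[match(cur, labs)] else 0
      if (best > cur_s + 1e-12) {
        row_labels[i] <<- labs[which(s >= best - 1e-12)][1]  # smallest label id
        changed <- TRUE
      }
    }
    for (j in sample.int(n)) {
      labs <- sort(unique(row_labels))
      s <- vapply(labs, function(l) sum(B[row_labels == l, j]), numeric(1))
      best <- max(s)
      cur <- col_labels[j]
      cur_s <- if (cur %in% labs) s[match(cur, labs)] else 0
      if (best > cur_s + 1e-12) {
        col_labels[j] <<- labs[which(s >= best - 1e-12)][1]
        changed <- TRUE
      }
    }
    changed
  }

  merge_step <- function() {
    labs <- sort(unique(c(row_labels, col_labels)))
    if (length(labs) < 2) return(FALSE)
    best_gain <- 0; best_pair <- NULL
    for (a_i in seq_along(labs)[-length(labs)]) {
      for (b_i in seq((a_i + 1), length(labs))) {
        a <- labs[a_i]; b <- labs[b_i]
        ra <- row_labels == a; rb <- row_labels == b
        ca <- col_labels == a; cb <- col_labels == b
        gain <- (sum(B[ra, cb, drop = FALSE]) + sum(B[rb, ca, drop = FALSE])) / W
        if (gain > best_gain + 1e-12) { best_gain <- gain; best_pair <- c(a, b) }
      }
    }
    if (is.null(best_pair)) return(FALSE)
    row_labels[row_labels == best_pair[2]] <<- best_pair[1]
    col_labels[col_labels == best_pair[2]] <<- best_pair[1]
    TRUE
  }

  repeat {
    q_before <- score()
    while (propagate()) NULL
    while (merge_step()) NULL
    if (score() <= q_before + 1e-12) break
  }
  list(row = row_labels, col = col_labels, Q = score())
}

#' Weighted bipartite modularity by label propagation (single run)
#'
#' Local search maximizing Barber modularity: every node starts in its own
#' module (or in one of `init_modules` random modules), nodes are then
#' repeatedly reassigned, in random sweep order, to the available module
#' label that maximizes Q (current label kept on ties, otherwise smallest
#' label id), and whole-module merges are attempted, until Q stops
#' increasing. Returns a local optimum; use [dirt_lpa_wb_plus()] for the
#' multi-restart version.
#'
#' @param flow non-negative donor x recipient weight matrix with positive
#'   total weight.
#' @param init_modules optional number of initial modules; nodes are
#'   assigned to them uniformly at random. Default: one module per node.
#' @return List of class `bee_modules`: `row_labels`, `col_labels`
#'   (consecutive integers), `Q`.
#' @export
lpa_wb_plus <- function(flow, init_modules = NULL) {
  flow <- as.matrix(flow)
  m <- nrow(flow); n <- ncol(flow)
  W <- sum(flow)
  if (W <= 0) stop("flow matrix has zero total weight", call. = FALSE)
  if (m == 1 && n == 1) {
    return(structure(list(row_labels = 1L, col_labels = 1L, Q = 0),
                     class = "bee_modules"))
  }
  if (is.null(init_modules)) {
    row_labels <- seq_len(m)
    col_labels <- m + seq_len(n)
  } else {
    k <- max(1L, min(as.integer(init_modules), m + n))
    row_labels <- sample.int(k, m, replace = TRUE)
    col_labels <- sample.int(k, n, replace = TRUE)
  }
  fit <- .lpa_optimize(flow, flow - outer(rowSums(flow), colSums(flow)) / W,
                       W, row_labels, col_labels)
  relab <- match(c(fit$row, fit$col), sort(unique(c(fit$row, fit$col))))
  structure(list(row_labels = relab[seq_len(m)],
                 col_labels = relab[m + seq_len(n)],
                 Q = fit$Q),
            class = "bee_modules")
}

#' Weighted bipartite modularity with multiple restarts
#'
#' Runs [lpa_wb_plus()] from a grid of initial module counts (one run per
#' restart; the first restart starts from one-module-per-node, the others
#' from random assignments into 1..min(dim) modules) and keeps the
#' partition with the highest Barber modularity.
#'
#' @param flow non-negative donor x recipient weight matrix.
#' @param n_restarts number of optimizer runs (>= 1, default 20).
#' @return Best `bee_modules` fit across restarts.
#' @export
dirt_lpa_wb_plus <- function(flow, n_restarts = 20) {
  if (n_restarts < 1) stop("`n_restarts` must be at least 1", call. = FALSE)
  flow <- as.matrix(flow)
  max_mod <- max(1L, min(nrow(flow), ncol(flow)))
  best <- lpa_wb_plus(flow)
  if (n_restarts > 1) {
    grid <- rep(seq_len(max_mod), length.out = n_restarts - 1)
    for (k in grid) {
      fit <- lpa_wb_plus(flow, init_modules = k)
      if (fit$Q > best$Q + 1e-12) best <- fit
    }
  }
  best
}

#' Normalized bipartite modularity
#'
#' Divides the partition's Barber modularity by the modularity the same
#' partition achieves on the idealized network in which all
#' between-module edge weight is deleted. A perfectly modular network
#' (every donor module sends pollen only to its own recipient module)
#' scores 1; a network with no modular structure under the optimal
#' partition (e.g. a uniform complete bipartite network) scores 0, the
#' convention also used when the idealized modularity is zero or the
#' idealized network is empty.
#'
#' @param flow non-negative donor x recipient weight matrix.
#' @param partition a `bee_modules` fit (from [lpa_wb_plus()] or
#'   [dirt_lpa_wb_plus()]).
#' @return Normalized modularity in `[0, 1]`.
#' @export
normalize_modularity <- function(flow, partition) {
  flow <- as.matrix(flow)
  q <- barber_modularity(flow, partition$row_labels, partition$col_labels)
  if (!is.finite(q) || q <= 0) return(0)
  ideal <- flow
  ideal[!outer(partition$row_labels, partition$col_labels, "==")] <- 0
  if (sum(ideal) <= 0) return(0)
  q_max <- barber_modularity(ideal, partition$row_labels, partition$col_labels)
  if (!is.finite(q_max) || q_max <= 0) return(0)
  min(1, q / q_max)
}

#' @export
print.bee_modules <- function(x, ...) {
  cat(sprintf("<bee_modules> %d modules, Q = %.4f\n",
              length(unique(c(x$row_labels, x$col_labels))), x$Q))
  invisible(x)
}

#' Normalized modularity of a pollen-flow network in one call
#'
#' Convenience wrapper: optimizes the partition with
#' [dirt_lpa_wb_plus()] and returns the normalized modularity. An empty
#' matrix (no recorded transfer) yields `NA`.
#'
#' @inheritParams dirt_lpa_wb_plus
#' @return List with `Q`, `Q_norm`, and the `partition`.
#' @export
flow_modularity <- function(flow, n_restarts = 20) {
  if (length(flow) == 0 || sum(flow) <= 0) {
    return(list(Q = NA_real_, Q_norm = NA_real_, partition = NULL))
  }
  part <- dirt_lpa_wb_plus(flow, n_restarts = n_restarts)
  list(Q = part$Q, Q_norm = normalize_modularity(flow, part), partition = part)
}
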