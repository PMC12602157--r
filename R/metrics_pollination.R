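#' Pollen-flow matrix over a time window
#'
#' Sums recorded transfer amounts per (donor, recipient) pair within the
#' window and returns the weighted bipartite donor x recipient matrix.
#' Donors are plants that sent at least one recorded transfer in the
#' window, recipients those that received at least one; the two sets may
#' overlap, but a plant appearing in both roles contributes one row node
#' and one column node (the two roles are decomposed).
#'
#' @param ledger a transfer ledger (see [transfer_ledger()]).
#' @param window numeric `c(t0, t1)`; defaults to the whole ledger.
#' @return Numeric matrix with donor plant ids as rownames and recipient
#'   plant ids as colnames; `0 x 0` if the window holds no transfer.
#' @export
build_flow_matrix <- function(ledger, window = NULL) {
  if (!is.null(window)) ledger <- window_events(ledger, window)
  tot <- pair_totals(ledger)
  if (nrow(tot) == 0) return(matrix(numeric(0), 0, 0))
  donors <- sort(unique(tot$donor_plant))
  recips <- sort(unique(tot$recipient_plant))
  m <- matrix(0, length(donors), length(recips),
              dimnames = list(as.character(donors), as.character(recips)))
  m[cbind(match(tot$donor_plant, donors), match(tot$recipient_plant, recips))] <-
    tot$amount
  m
}

#' Lower weighted median
#'
#' Smallest `x` whose cumulative weight reaches half the total weight.
#'
#' @param x numeric values.
#' @param w non-negative weights.
#' @return The weighted median, `NA` if no positive weight.
#' @export
weighted_median <- function(x, w) {
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) == 0) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  x[which(cumsum(w) >= sum(w) / 2)[1]]
}

#' Population mating distance
#'
#' Pollen-weighted median of the Euclidean donor-recipient distances over
#' all recorded transfers in the window. Self-transfers (donor =
#' recipient, distance 0) are excluded by default: they are what the
#' self-pollination rate measures, and including them would drag the
#' median toward zero.
#'
#' @param ledger a transfer ledger.
#' @param env the `bee_env` the transfers happened in (for coordinates).
#' @param window numeric `c(t0, t1)`; defaults to the whole ledger.
#' @param include_self include donor = recipient transfers at distance 0.
#' @return Weighted median mating distance (m), `NA` if no (non-self)
#'   transfer lies in the window.
#' @export
mating_distance <- function(ledger, env, window = NULL, include_self = FALSE) {
  if (!is.null(window)) ledger <- window_events(ledger, window)
  if (!include_self) {
    ledger <- ledger[ledger$donor_plant != ledger$recipient_plant, , drop = FALSE]
  }
  if (nrow(ledger) == 0) return(NA_real_)
  dx <- env$xy[ledger$donor_plant, 1] - env$xy[ledger$recipient_plant, 1]
  dy <- env$xy[ledger$donor_plant, 2] - env$xy[ledger$recipient_plant, 2]
  unname(weighted_median(sqrt(dx^2 + dy^2), ledger$amount))
}

#' Self-pollination rate per plant
#'
#' Fraction of the pollen a plant received that came from itself. Plants
#' that received no pollen have no defined rate (`NA`).
#'
#' @param flow pollen-flow matrix from [build_flow_matrix()].
#' @return Named numeric vector over the recipient plants of `flow`.
#' @export
self_pollination_rate <- function(flow) {
  if (length(flow) == 0) return(numeric(0))
  recv <- colSums(flow)
  own <- vapply(colnames(flow), function(pl) {
    i <- match(pl, rownames(flow))
    if (is.na(i)) 0 else flow[i, pl]
  }, numeric(1))
  ifelse(recv > 0, own / recv, NA_real_)
}

#' Mate diversity per plant
#'
#' Number of distinct donor plants per recipient plant, the recipient
#' itself excluded. Transfer magnitude is deliberately ignored.
#'
#' @param flow pollen-flow matrix from [build_flow_matrix()].
#' @return Named integer vector over the recipient plants of `flow`.
#' @export
mate_diversity <- function(flow) {
  if (length(flow) == 0) return(integer(0))
  vapply(colnames(flow), function(pl) {
    donors <- rownames(flow)[flow[, pl] > 0]
    sum(donors != pl)
  }, integer(1))
}
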