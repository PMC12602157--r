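#' Pollen crop: per-source pollen carried by a bee
#'
#' A bee's pollen crop is a ledger of (source plant, remaining amount)
#' entries, most recent last. At every plant visit the bee deposits a
#' fraction `p` of each carried lot (geometric carryover: the previously
#' visited plant contributes `p`, the one before `p(1-p)`, then
#' `p(1-p)^2`, ...) and then picks up one fresh unit from the plant it is
#' standing on. Deposits below the recording cutoff are not logged, but the
#' lot still decays by `(1-p)`; lots that can never again yield a
#' recordable deposit (`remaining * p < cutoff`) are pruned, which leaves
#' the recorded ledger unchanged because the per-lot deposit sequence
#' decreases monotonically.
#'
#' @name pollen_crop
NULL

#' Create an empty pollen crop
#' @return A list with numeric `source` and `amount` vectors, both empty.
#' @export
empty_pollen_crop <- function() list(source = integer(0), amount = numeric(0))

#' Deposit carried pollen onto a plant, then pick up fresh pollen
#'
#' Executed once per plant visit, deposit first: each lot `(s, a)` in the
#' crop deposits `p * a` onto `recipient` and shrinks to `(1 - p) * a`.
#' Deposits of at least `cutoff` units are returned as transfer events
#' (donor = `s`, recipient = `recipient`); smaller ones are discarded.
#' After depositing, a 1-unit lot sourced from `recipient` is appended.
#' A bee revisiting a plant it still carries pollen from generates a
#' donor = recipient event: that is exactly what the self-pollination
#' metric measures.
#'
#' @param crop a pollen crop (see [empty_pollen_crop()]).
#' @param recipient plant id being visited.
#' @param p pollen deposition rate, strictly between 0 and 1.
#' @param cutoff minimal recordable transfer (pollen units, default 0.01).
#' @return List with the updated `crop` and a data frame `events` with
#'   columns `donor`, `amount` (possibly zero rows).
#' @export
#' @examples
#' crop <- empty_pollen_crop()
#' crop <- deposit_and_pickup(crop, 1, p = 0.5)$crop   # visit X
#' crop <- deposit_and_pickup(crop, 2, p = 0.5)$crop   # visit Y
#' deposit_and_pickup(crop, 3, p = 0.5)$events         # Y: 0.5, X: 0.25
deposit_and_pickup <- function(crop, recipient, p, cutoff = 0.01) {
  if (p <= 0 || p >= 1) stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  dep <- crop$amount * p
  rec <- dep >= cutoff
  events <- data.frame(donor = crop$source[rec], amount = dep[rec])
  remain <- crop$amount * (1 - p)
  keep <- remain * p >= cutoff          # still able to yield a recordable deposit
  crop <- list(source = c(crop$source[keep], as.integer(recipient)),
               amount = c(remain[keep], 1.0))
  list(crop = crop, events = events)
}

#' Groom: empty the pollen crop at the nest
#'
#' Back at the nest the bee grooms all pollen residues away, so no pollen
#' is carried over between foraging bouts. No transfer events are emitted.
#'
#' @param crop a pollen crop.
#' @return An empty pollen crop.
#' @export
groom <- function(crop) empty_pollen_crop()

#' Build a transfer ledger from individual events
#'
#' @param time,bee_id,donor,recipient,amount parallel vectors describing
#'   transfer events.
#' @return A data frame of class `bee_ledger`, ordered as given, with
#'   columns `time_s`, `bee_id`, `donor_plant`, `recipient_plant`,
#'   `amount`.
#' @export
transfer_ledger <- function(time = numeric(0), bee_id = integer(0),
                            donor = integer(0), recipient = integer(0),
                            amount = numeric(0)) {
  out <- data.frame(time_s = as.numeric(time), bee_id = as.integer(bee_id),
                    donor_plant = as.integer(donor),
                    recipient_plant = as.integer(recipient),
                    amount = as.numeric(amount))
  class(out) <- c("bee_ledger", "data.frame")
  out
}

#' Restrict a ledger (or visit log) to a time window
#'
#' @param x data frame with a `time_s` column.
#' @param window numeric `c(t0, t1)`; rows with `t0 <= time_s <= t1` are
#'   kept.
#' @return The filtered data frame.
#' @export
window_events <- function(x, window) {
  x[x$time_s >= window[1] & x$time_s <= window[2], , drop = FALSE]
}

#' Total transferred pollen per donor-recipient pair
#'
#' @param ledger a transfer ledger.
#' @return Data frame `donor_plant`, `recipient_plant`, `amount` with one
#'   row per pair with positive recorded transfer.
#' @export
pair_totals <- function(ledger) {
  if (nrow(ledger) == 0) {
    return(data.frame(donor_plant = integer(0), recipient_plant = integer(0),
                      amount = numeric(0)))
  }
  agg <- stats::aggregate(amount ~ donor_plant + recipient_plant,
                          data = ledger, FUN = sum)
  agg[order(agg$donor_plant, agg$recipient_plant), , drop = FALSE]
}
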