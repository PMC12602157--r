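# Independent oracles used across the suite. Each deliberately recomputes
# its quantity by a different route than the package implementation.

# Brute-force pollen ledger: walk a per-bout visit sequence and apply the
# geometric weights p, p(1-p), p(1-p)^2, ... directly per ordered visit
# pair. `bouts` is a list of integer vectors (plant visits per bout);
# grooming between bouts means pairs never span bouts.
oracle_pollen_totals <- function(bouts, p, cutoff = 0.01) {
  rows <- list()
  for (seq in bouts) {
    n <- length(seq)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        amt <- p * (1 - p)^(j - i - 1)
        if (amt >= cutoff) {
          rows[[length(rows) + 1]] <- data.frame(donor = seq[i],
                                                 recipient = seq[j],
                                                 amount = amt)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(donor = integer(0), recipient = integer(0),
                      amount = numeric(0)))
  }
  df <- do.call(rbind, rows)
  agg <- aggregate(amount ~ donor + recipient, data = df, FUN = sum)
  agg[order(agg$donor, agg$recipient), ]
}

# Run a visit sequence through the package's crop operations and return
# summed (donor, recipient) totals.
package_pollen_totals <- function(bouts, p, cutoff = 0.01) {
  rows <- list()
  for (seq in bouts) {
    crop <- empty_pollen_crop()
    for (pl in seq) {
      step <- deposit_and_pickup(crop, pl, p = p, cutoff = cutoff)
      crop <- step$crop
      if (nrow(step$events)) {
        rows[[length(rows) + 1]] <- data.frame(donor = step$events$donor,
                                               recipient = pl,
                                               amount = step$events$amount)
      }
    }
    crop <- groom(crop)
  }
  if (length(rows) == 0) {
    return(data.frame(donor = integer(0), recipient = integer(0),
                      amount = numeric(0)))
  }
  df <- do.call(rbind, rows)
  agg <- aggregate(amount ~ donor + recipient, data = df, FUN = sum)
  agg[order(agg$donor, agg$recipient), ]
}

# Exhaustive similarity index: scan every pair of length-`sub_len` windows
# of the two bouts with elementwise comparison (no string encoding), mark
# covered transitions, and apply s_ab / (2 l_ab).
oracle_similarity <- function(a, b, sub_len = 3) {
  l_ab <- max(length(a), length(b)) - 1
  if (l_ab < 1) return(0)
  windows <- function(v) {
    if (length(v) < sub_len) return(list())
    lapply(seq_len(length(v) - sub_len + 1), function(i) v[i:(i + sub_len - 1)])
  }
  wa <- windows(a); wb <- windows(b)
  cov_a <- logical(max(length(a) - 1, 0))
  cov_b <- logical(max(length(b) - 1, 0))
  for (i in seq_along(wa)) {
    for (j in seq_along(wb)) {
      if (all(wa[[i]] == wb[[j]])) {
        cov_a[i:(i + sub_len - 2)] <- TRUE
        cov_b[j:(j + sub_len - 2)] <- TRUE
      }
    }
  }
  (sum(cov_a) + sum(cov_b)) / (2 * l_ab)
}

# All set partitions of n labelled elements, as restricted growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, m) {
    k <- length(prefix)
    if (k == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (lab in seq_len(m + 1)) recurse(c(prefix, lab), max(m, lab))
  }
  recurse(integer(0), 0L)
  out
}

# Global maximum of Barber modularity by exhaustive enumeration of all
# partitions of the row + column node set. Feasible up to ~4x4.
oracle_max_modularity <- function(flow) {
  m <- nrow(flow); n <- ncol(flow)
  best <- -Inf
  for (p in all_partitions(m + n)) {
    q <- barber_modularity(flow, p[seq_len(m)], p[m + seq_len(n)])
    if (q > best) best <- q
  }
  best
}

# Small deterministic arena used by several unit tests.
toy_env <- function(n_plants = 5, seed = 99, ...) {
  generate_environment(n_plants, seed = seed, ...)
}
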