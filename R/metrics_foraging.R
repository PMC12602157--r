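#' Number of plant visits in a bout
#'
#' Counts every plant visit, including repeat visits to the same plant;
#' the nest is not counted.
#'
#' @param visits integer vector of plant ids visited during the bout, in
#'   order.
#' @return Visit count.
#' @export
visits_per_bout <- function(visits) length(visits)

#' Nectar intake rate of a bout
#'
#' Total nectar collected divided by the bout duration (nest departure to
#' nest return), in uL/s. A zero-duration bout has no defined rate and
#' returns `NA`.
#'
#' @param nectar_collected numeric vector (or scalar total) of nectar
#'   collected at each visit (uL).
#' @param depart_time,return_time bout endpoints (s).
#' @return Intake rate in uL/s, or `NA_real_`.
#' @export
nectar_intake_rate <- function(nectar_collected, depart_time, return_time) {
  dur <- return_time - depart_time
  if (!is.finite(dur) || dur <= 0) return(NA_real_)
  sum(nectar_collected) / dur
}

# Contiguous windows of `len` visits, encoded as strings for set matching.
.subsequences <- function(visits, len) {
  n <- length(visits)
  if (n < len) return(character(0))
  vapply(seq_len(n - len + 1),
         function(i) paste(visits[i:(i + len - 1)], collapse = ","),
         character(1))
}

#' Route similarity index between two consecutive bouts
#'
#' Quantifies how much two bouts share short contiguous visitation
#' subsequences. All windows of `sub_len` consecutive plant visits
#' (`sub_len - 1` transitions) are enumerated in each bout; a transition is
#' shared when it lies inside at least one window that occurs, as a
#' contiguous run, in both bouts. `s_ab` counts shared transitions in bout
#' a plus those in bout b, `l_ab` is the transition count of the longer
#' bout, and `SI = s_ab / (2 * l_ab)`. Identical bouts score 1; bouts with
#' no common subsequence score 0. Nest departures and returns are not part
#' of the sequences.
#'
#' @param bout_a,bout_b integer vectors of plant visits.
#' @param sub_len subsequence length in visits (default 3, i.e. 2
#'   transitions).
#' @return List with `value`, `s_ab`, `l_ab`.
#' @export
#' @examples
#' similarity_index(c(1, 2, 3, 4), c(1, 2, 3, 5))$value  # 2/3
similarity_index <- function(bout_a, bout_b, sub_len = 3) {
  if (sub_len < 2) stop("`sub_len` must be at least 2", call. = FALSE)
  l_ab <- max(length(bout_a), length(bout_b)) - 1L
  if (l_ab < 1L) return(list(value = 0, s_ab = 0L, l_ab = max(l_ab, 0L)))
  sub_a <- .subsequences(bout_a, sub_len)
  sub_b <- .subsequences(bout_b, sub_len)
  shared <- intersect(sub_a, sub_b)
  count_shared <- function(visits, subs) {
    n_tr <- length(visits) - 1L
    if (n_tr < 1L || length(shared) == 0) return(0L)
    covered <- logical(n_tr)
    for (i in which(subs %in% shared)) {
      covered[i:(i + sub_len - 2L)] <- TRUE     # transitions inside window i
    }
    sum(covered)
  }
  s_ab <- count_shared(bout_a, sub_a) + count_shared(bout_b, sub_b)
  list(value = s_ab / (2 * l_ab), s_ab = s_ab, l_ab = l_ab)
}

#' Local intensity of competition
#'
#' For a focal bee i over a time window: let `N_ij` be the number of
#' distinct plants i visited, `N_own` i's total visits to those plants and
#' `N_other` all other bees' visits to those same plants (same window).
#' The index is `N_other / (N_own * N_ij)`: 0 when no competitor touches
#' the focal bee's plants, larger the more its plant set is shared.
#'
#' @param visit_log data frame with columns `time_s`, `bee_id`, `node_id`
#'   (plant visits only).
#' @param focal_bee bee id.
#' @param window numeric `c(t0, t1)`.
#' @return The index, or `NA_real_` if the focal bee made no visit in the
#'   window.
#' @export
local_competition <- function(visit_log, focal_bee, window) {
  v <- window_events(visit_log, window)
  mine <- v[v$bee_id == focal_bee, , drop = FALSE]
  if (nrow(mine) == 0) return(NA_real_)
  plants <- unique(mine$node_id)
  n_own <- nrow(mine)
  n_other <- sum(v$bee_id != focal_bee & v$node_id %in% plants)
  n_other / (n_own * length(plants))
}

#' Per-plant visit and visitor counts in a window
#'
#' @param visit_log data frame with `time_s`, `bee_id`, `node_id`.
#' @param window numeric `c(t0, t1)`.
#' @param n_plants total number of plants (unvisited plants get zero rows).
#' @return Data frame `plant_id`, `n_visits`, `n_visitors`.
#' @export
visitors_per_plant <- function(visit_log, window, n_plants) {
  v <- window_events(visit_log, window)
  n_visits <- tabulate(v$node_id, nbins = n_plants)
  n_visitors <- integer(n_plants)
  if (nrow(v) > 0) {
    by_plant <- tapply(v$bee_id, factor(v$node_id, levels = seq_len(n_plants)),
                       function(b) length(unique(b)))
    n_visitors <- as.integer(ifelse(is.na(by_plant), 0L, by_plant))
  }
  data.frame(plant_id = seq_len(n_plants), n_visits = n_visits,
             n_visitors = n_visitors)
}
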