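#' Simulation configuration
#'
#' Bundles every behavioural and experimental parameter of a single
#' simulation run. Defaults follow the baseline study conditions: two
#' bees, learning rate 0.5, softmax sharpness 10, a 60-s working memory,
#' a crop holding five full plant loads, a 40,000-s run in 5-s timesteps,
#' and pollination metrics computed over the final 5000 s at the 29th
#' foraging bout.
#'
#' @param n_bees number of foraging bees.
#' @param alpha learning rate in `[0, 1]` (0 disables learning).
#' @param beta exploration-exploitation parameter (>= 0).
#' @param wm_span working-memory span (s): plants visited less than this
#'   long ago are excluded from the choice set.
#' @param crop_capacity_units crop capacity in multiples of `n_max`
#'   (default 5 full plant loads).
#' @param max_bout_distance maximal distance flown within a bout before a
#'   forced return (m); the homing leg is exempt.
#' @param speed flight speed (m/s).
#' @param nest_wait time spent in the nest between bouts (s).
#' @param p pollen deposition rate, strictly in (0, 1).
#' @param cutoff minimal recordable pollen transfer (units).
#' @param duration simulated time (s), divisible by `timestep`.
#' @param timestep timestep length (s, fixed at 5 in the study design).
#' @param analysis_window length of the terminal window used for the
#'   window-based metrics (s).
#' @param target_bout bout index used for the bout-level metrics; the
#'   route similarity index compares bouts `target_bout - 1` and
#'   `target_bout`.
#' @return A list of class `bee_sim_config`.
#' @export
bee_sim_config <- function(n_bees = 2, alpha = 0.5, beta = 10, wm_span = 60,
                           crop_capacity_units = 5, max_bout_distance = 3000,
                           speed = 3, nest_wait = 300, p = 0.5, cutoff = 0.01,
                           duration = 40000, timestep = 5,
                           analysis_window = 5000, target_bout = 29) {
  if (n_bees < 1) stop("`n_bees` must be at least 1", call. = FALSE)
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (beta < 0) stop("`beta` must be non-negative", call. = FALSE)
  if (wm_span < 0) stop("`wm_span` must be non-negative", call. = FALSE)
  if (crop_capacity_units <= 0) stop("`crop_capacity_units` must be positive", call. = FALSE)
  if (p <= 0 || p >= 1) stop("`p` must lie strictly in (0, 1)", call. = FALSE)
  if (duration %% timestep != 0) {
    stop("`duration` must be divisible by `timestep`", call. = FALSE)
  }
  if (analysis_window > duration) {
    stop("`analysis_window` cannot exceed `duration`", call. = FALSE)
  }
  structure(as.list(environment()), class = "bee_sim_config")
}

# Doubling growth for the preallocated log buffers.
.grow <- function(v, needed) {
  if (needed <= length(v)) return(v)
  length(v) <- max(needed, 2 * length(v))
  v
}

#' Run one simulation
#'
#' Executes the discrete-time loop. Every 5-s timestep: (1) every plant
#' below capacity refills linearly; (2) bees due to act this step are
#' processed in a freshly drawn random order. On arriving at a plant a bee
#' perceives the value of the realized transition from the pre-harvest
#' nectar, updates the corresponding Q entry, deposits carried pollen and
#' picks up a fresh unit, harvests into its crop, stores the visit in
#' working memory, and either picks the next plant by softmax over the
#' non-excluded plants or - when the crop is full, the distance cap would
#' be exceeded, or no plant is available - returns to the nest. On nest
#' arrival it grooms all pollen off, unloads, waits `nest_wait` seconds
#' and starts the next bout with a softmax choice from the nest row of its
#' Q-table. Travel takes `ceiling(d / (speed * timestep))` timesteps; all
#' arrival-step actions happen within the arrival timestep.
#'
#' @param env a `bee_env`.
#' @param config a `bee_sim_config`.
#' @param seed integer seed for the run (drives every random draw).
#' @return An object of class `bee_sim`: list with `visits` (plant-visit
#'   log), `transfers` (pollen ledger), `bouts` (completed-bout table),
#'   `q` (final per-bee Q matrices), `q0`, plus `env`, `config`, `seed`.
#' @export
run_simulation <- function(env, config = bee_sim_config(), seed = 1) {
  stopifnot(inherits(env, "bee_env"), inherits(config, "bee_sim_config"))
  set.seed(seed)
  dt <- config$timestep
  n_steps <- config$duration %/% dt
  np <- env$n_plants
  nb <- config$n_bees
  d <- env$dist
  p_d <- discovery_probabilities(env)
  q0 <- init_q(env, p_d)
  Q <- replicate(nb, q0, simplify = FALSE)
  alpha <- config$alpha; beta <- config$beta
  crop_capacity <- config$crop_capacity_units * env$n_max
  wm <- config$wm_span
  p <- config$p; cutoff <- config$cutoff
  speed_step <- config$speed * dt
  wait_steps <- max(1L, as.integer(round(config$nest_wait / dt)))
  plant_nodes <- seq.int(2L, np + 1L)

  n_t <- rep(env$n_max, np)
  renew <- env$n_max * dt / env$renewal_duration

  # per-bee state
  loc <- rep(1L, nb)                 # node occupied (or travel origin)
  dest <- rep(1L, nb)
  event_step <- rep(1L, nb)          # next step at which the bee acts
  event_type <- rep(0L, nb)          # 0 depart nest, 1 arrive plant, 2 arrive nest
  crop <- rep(0, nb)
  bout_dist <- rep(0, nb)
  bout_idx <- rep(1L, nb)
  bout_depart <- rep(NA_real_, nb)
  bout_visits <- rep(0L, nb)
  bout_nectar <- rep(0, nb)
  last_visit <- matrix(-Inf, nb, np)
  pol_src <- vector("list", nb)
  pol_amt <- vector("list", nb)
  for (b in seq_len(nb)) { pol_src[[b]] <- integer(0); pol_amt[[b]] <- numeric(0) }

  # growable log buffers
  v_n <- 0L
  v_time <- numeric(4096); v_bee <- integer(4096); v_bout <- integer(4096)
  v_node <- integer(4096); v_nect <- numeric(4096)
  t_n <- 0L
  t_time <- numeric(8192); t_bee <- integer(8192); t_donor <- integer(8192)
  t_recip <- integer(8192); t_amt <- numeric(8192)
  b_n <- 0L
  b_bee <- integer(256); b_idx <- integer(256); b_dep <- numeric(256)
  b_ret <- numeric(256); b_vis <- integer(256); b_nec <- numeric(256)
  b_dst <- numeric(256)

  travel_steps <- function(dd) max(1L, as.integer(ceiling(dd / speed_step)))

  pick_next <- function(b, node, now) {
    # softmax over plants outside working memory; NULL when none available
    open <- (now - last_visit[b, ]) >= wm
    if (node > 1L) open[node - 1L] <- FALSE
    cand <- plant_nodes[open]
    if (length(cand) == 0L) return(NULL)
    if (length(cand) == 1L) return(cand)
    qv <- Q[[b]][node, cand]
    w <- exp(beta * (qv - max(qv)))
    cand[sample.int(length(cand), 1L, prob = w)]
  }

  for (s in seq_len(n_steps)) {
    n_t <- pmin(env$n_max, n_t + renew)
    acting <- which(event_step == s)
    if (length(acting) == 0L) next
    if (length(acting) > 1L) acting <- acting[sample.int(length(acting))]
    now <- s * dt
    for (b in acting) {
      type <- event_type[b]
      if (type == 1L) {                        # ---- arrival at a plant ----
        node <- dest[b]; from <- loc[b]; pb <- node - 1L
        n_arr <- n_t[pb]
        v <- n_arr * p_d[from, node]
        Q[[b]][from, node] <- alpha * v + (1 - alpha) * Q[[b]][from, node]
        # pollen: deposit from every carried lot, then pick up one unit
        src <- pol_src[[b]]; amt <- pol_amt[[b]]
        if (length(src)) {
          dep <- amt * p
          rec <- which(dep >= cutoff)
          if (length(rec)) {
            t_new <- t_n + length(rec)
            if (t_new > length(t_time)) {
              t_time <- .grow(t_time, t_new); t_bee <- .grow(t_bee, t_new)
              t_donor <- .grow(t_donor, t_new); t_recip <- .grow(t_recip, t_new)
              t_amt <- .grow(t_amt, t_new)
            }
            idx <- (t_n + 1L):t_new
            t_time[idx] <- now; t_bee[idx] <- b
            t_donor[idx] <- src[rec]; t_recip[idx] <- pb; t_amt[idx] <- dep[rec]
            t_n <- t_new
          }
          amt <- amt * (1 - p)
          keep <- amt * p >= cutoff
          src <- src[keep]; amt <- amt[keep]
        }
        pol_src[[b]] <- c(src, pb); pol_amt[[b]] <- c(amt, 1.0)
        # harvest
        got <- min(n_arr, crop_capacity - crop[b])
        n_t[pb] <- n_arr - got
        crop[b] <- crop[b] + got
        bout_nectar[b] <- bout_nectar[b] + got
        bout_visits[b] <- bout_visits[b] + 1L
        v_n <- v_n + 1L
        if (v_n > length(v_time)) {
          v_time <- .grow(v_time, v_n); v_bee <- .grow(v_bee, v_n)
          v_bout <- .grow(v_bout, v_n); v_node <- .grow(v_node, v_n)
          v_nect <- .grow(v_nect, v_n)
        }
        v_time[v_n] <- now; v_bee[v_n] <- b; v_bout[v_n] <- bout_idx[b]
        v_node[v_n] <- pb; v_nect[v_n] <- got
        last_visit[b, pb] <- now
        loc[b] <- node
        # next destination or forced return
        go_home <- crop[b] >= crop_capacity
        nxt <- NULL
        if (!go_home) {
          nxt <- pick_next(b, node, now)
          if (is.null(nxt)) {
            go_home <- TRUE
          } else if (bout_dist[b] + d[node, nxt] > config$max_bout_distance) {
            go_home <- TRUE
          }
        }
        if (go_home) {
          leg <- d[node, 1L]
          bout_dist[b] <- bout_dist[b] + leg
          dest[b] <- 1L; event_type[b] <- 2L
          event_step[b] <- s + travel_steps(leg)
        } else {
          leg <- d[node, nxt]
          bout_dist[b] <- bout_dist[b] + leg
          dest[b] <- nxt; event_type[b] <- 1L
          event_step[b] <- s + travel_steps(leg)
        }
      } else if (type == 0L) {                 # ---- departure from nest ----
        nxt <- pick_next(b, 1L, now)
        if (is.null(nxt)) {                    # every plant in working memory
          event_step[b] <- s + 1L
        } else {
          bout_depart[b] <- now
          bout_dist[b] <- d[1L, nxt]
          bout_visits[b] <- 0L; bout_nectar[b] <- 0
          loc[b] <- 1L; dest[b] <- nxt; event_type[b] <- 1L
          event_step[b] <- s + travel_steps(d[1L, nxt])
        }
      } else {                                 # ---- arrival at the nest ----
        pol_src[[b]] <- integer(0); pol_amt[[b]] <- numeric(0)   # grooming
        b_n <- b_n + 1L
        if (b_n > length(b_bee)) {
          b_bee <- .grow(b_bee, b_n); b_idx <- .grow(b_idx, b_n)
          b_dep <- .grow(b_dep, b_n); b_ret <- .grow(b_ret, b_n)
          b_vis <- .grow(b_vis, b_n); b_nec <- .grow(b_nec, b_n)
          b_dst <- .grow(b_dst, b_n)
        }
        b_bee[b_n] <- b; b_idx[b_n] <- bout_idx[b]
        b_dep[b_n] <- bout_depart[b]; b_ret[b_n] <- now
        b_vis[b_n] <- bout_visits[b]; b_nec[b_n] <- bout_nectar[b]
        b_dst[b_n] <- bout_dist[b]
        crop[b] <- 0; bout_dist[b] <- 0
        bout_idx[b] <- bout_idx[b] + 1L
        loc[b] <- 1L; event_type[b] <- 0L
        event_step[b] <- s + wait_steps
      }
    }
  }

  visits <- data.frame(time_s = v_time[seq_len(v_n)], bee_id = v_bee[seq_len(v_n)],
                       bout_index = v_bout[seq_len(v_n)],
                       node_id = v_node[seq_len(v_n)],
                       nectar_collected_uL = v_nect[seq_len(v_n)])
  transfers <- transfer_ledger(t_time[seq_len(t_n)], t_bee[seq_len(t_n)],
                               t_donor[seq_len(t_n)], t_recip[seq_len(t_n)],
                               t_amt[seq_len(t_n)])
  bouts <- data.frame(bee_id = b_bee[seq_len(b_n)], bout_index = b_idx[seq_len(b_n)],
                      depart_s = b_dep[seq_len(b_n)], return_s = b_ret[seq_len(b_n)],
                      n_visits = b_vis[seq_len(b_n)], nectar_uL = b_nec[seq_len(b_n)],
                      distance_m = b_dst[seq_len(b_n)])
  structure(list(visits = visits, transfers = transfers, bouts = bouts,
                 q = Q, q0 = q0, env = env, config = config, seed = seed),
            class = "bee_sim")
}

#' @export
print.bee_sim <- function(x, ...) {
  cat(sprintf(
    "<bee_sim> %d bees, %d plants, %g s (seed %s)\n  %d plant visits, %d completed bouts, %d recorded pollen transfers\n",
    x$config$n_bees, x$env$n_plants, x$config$duration, format(x$seed),
    nrow(x$visits), nrow(x$bouts), nrow(x$transfers)))
  invisible(x)
}

#' Compute the full metric set for one simulation
#'
#' Bout-level foraging metrics (visit count, nectar intake rate, and the
#' route similarity index between the target bout and the one before it)
#' are evaluated at `config$target_bout`; bees that never completed that
#' bout get `NA`s. Window metrics (local intensity of competition,
#' visitors per plant, mating distance, self-pollination rate, mate
#' diversity, normalized pollen-network modularity) use the final
#' `config$analysis_window` seconds.
#'
#' @param sim a `bee_sim` object.
#' @param modularity compute the normalized pollen-network modularity
#'   (the most expensive metric); set `FALSE` to skip it.
#' @param modularity_restarts restarts for the modularity optimizer.
#' @return List with `bees` (one row per bee), `plants` (one row per
#'   plant), and `summary` (single row of per-run aggregates: bee metrics
#'   averaged over bees, plant metrics over plants).
#' @export
compute_all_metrics <- function(sim, modularity = TRUE,
                                modularity_restarts = 20) {
  cfg <- sim$config
  env <- sim$env
  tb <- cfg$target_bout
  window <- c(cfg$duration - cfg$analysis_window, cfg$duration)
  bees <- seq_len(cfg$n_bees)

  bee_rows <- do.call(rbind, lapply(bees, function(b) {
    bb <- sim$bouts[sim$bouts$bee_id == b, , drop = FALSE]
    row <- data.frame(bee_id = b, n_visits = NA_real_, intake_rate = NA_real_,
                      similarity = NA_real_, i_loc = NA_real_)
    tgt <- bb[bb$bout_index == tb, , drop = FALSE]
    if (nrow(tgt) == 1) {
      row$n_visits <- tgt$n_visits
      row$intake_rate <- nectar_intake_rate(tgt$nectar_uL, tgt$depart_s,
                                            tgt$return_s)
      prev <- sim$visits[sim$visits$bee_id == b &
                           sim$visits$bout_index == tb - 1L, "node_id"]
      cur <- sim$visits[sim$visits$bee_id == b &
                          sim$visits$bout_index == tb, "node_id"]
      if (any(bb$bout_index == tb - 1L)) {
        row$similarity <- similarity_index(prev, cur)$value
      }
    }
    row$i_loc <- local_competition(sim$visits, b, window)
    row
  }))

  vp <- visitors_per_plant(sim$visits, window, env$n_plants)
  flow <- build_flow_matrix(sim$transfers, window)
  selfp <- self_pollination_rate(flow)
  mdiv <- mate_diversity(flow)
  plant_rows <- data.frame(plant_id = seq_len(env$n_plants),
                           n_visits = vp$n_visits, n_visitors = vp$n_visitors,
                           self_pollination = NA_real_, mate_diversity = NA_real_)
  if (length(flow)) {
    rec <- as.integer(colnames(flow))
    plant_rows$self_pollination[rec] <- selfp
    plant_rows$mate_diversity[rec] <- mdiv
  }

  md <- mating_distance(sim$transfers, env, window)
  qn <- NA_real_
  if (modularity) qn <- flow_modularity(flow, n_restarts = modularity_restarts)$Q_norm

  summary <- data.frame(
    n_visits = mean(bee_rows$n_visits, na.rm = TRUE),
    intake_rate = mean(bee_rows$intake_rate, na.rm = TRUE),
    similarity = mean(bee_rows$similarity, na.rm = TRUE),
    i_loc = mean(bee_rows$i_loc, na.rm = TRUE),
    visitors_per_plant = mean(vp$n_visitors),
    mating_distance = md,
    self_pollination = if (all(is.na(plant_rows$self_pollination))) NA_real_
                       else mean(plant_rows$self_pollination, na.rm = TRUE),
    mate_diversity = if (all(is.na(plant_rows$mate_diversity))) NA_real_
                     else mean(plant_rows$mate_diversity, na.rm = TRUE),
    modularity = qn)
  summary[sapply(summary, is.nan)] <- NA_real_
  list(bees = bee_rows, plants = plant_rows, summary = summary)
}
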