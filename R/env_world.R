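#' Generate a random foraging environment
#'
#' Creates a square arena with the nest fixed at the origin and `n_plants`
#' plants whose x and y coordinates are drawn independently from a uniform
#' distribution over `[0, side_length]`. Every plant starts full
#' (`n_t = n_max`) and refills linearly at rate `n_max / renewal_duration`
#' whenever it is below capacity. Node 1 of the distance matrix is the nest;
#' plant `i` is node `i + 1`.
#'
#' @param n_plants number of plants (>= 1).
#' @param side_length side of the square arena in metres.
#' @param n_max maximal nectar per plant in microlitres.
#' @param renewal_duration time in seconds for a plant to refill from empty
#'   to `n_max`.
#' @param seed optional integer seed; when given the environment is
#'   reproducible bit-for-bit.
#'
#' @return An object of class `bee_env`: a list with `n_plants`,
#'   `side_length`, `n_max`, `renewal_duration`, `xy` (n_plants x 2 matrix),
#'   and `dist` ((n_plants + 1) square Euclidean distance matrix over
#'   nest + plants).
#' @export
#' @examples
#' env <- generate_environment(20, side_length = 1000, seed = 1)
#' env$dist[1, 2]  # nest-to-first-plant distance
generate_environment <- function(n_plants, side_length = 1000, n_max = 8,
                                 renewal_duration = 600, seed = NULL) {
  if (!is.numeric(n_plants) || n_plants < 1) {
    stop("`n_plants` must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(side_length) || side_length <= 0) {
    stop("`side_length` must be positive", call. = FALSE)
  }
  if (renewal_duration <= 0) stop("`renewal_duration` must be positive", call. = FALSE)
  n_plants <- as.integer(n_plants)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  xy <- cbind(x = stats::runif(n_plants, 0, side_length),
              y = stats::runif(n_plants, 0, side_length))
  new_bee_env(xy, side_length = side_length, n_max = n_max,
              renewal_duration = renewal_duration)
}

#' Build an environment from explicit plant coordinates
#'
#' @param xy two-column matrix (or data frame) of plant coordinates.
#' @param side_length arena side (m); defaults to the smallest square
#'   containing all plants.
#' @param n_max maximal nectar per plant (uL).
#' @param renewal_duration refill time from empty (s).
#' @return A `bee_env` object (see [generate_environment()]).
#' @export
new_bee_env <- function(xy, side_length = NULL, n_max = 8,
                        renewal_duration = 600) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  if (ncol(xy) != 2) stop("`xy` must have two columns (x, y)", call. = FALSE)
  if (is.null(side_length)) side_length <- max(xy, 1e-9)
  n_plants <- nrow(xy)
  dimnames(xy) <- list(NULL, c("x", "y"))
  nodes <- rbind(c(0, 0), xy)                      # nest is node 1
  d <- as.matrix(stats::dist(nodes))
  dimnames(d) <- NULL
  if (any(d[upper.tri(d)] == 0)) {
    stop("coincident nodes: two plants (or a plant and the nest) share a position",
         call. = FALSE)
  }
  structure(list(n_plants = n_plants, side_length = side_length,
                 n_max = n_max, renewal_duration = renewal_duration,
                 xy = xy, dist = d),
            class = "bee_env")
}

#' @export
print.bee_env <- function(x, ...) {
  cat(sprintf(
    "<bee_env> %d plants in a %g x %g m arena, nest at (0,0)\n  n_max = %g uL, renewal_duration = %g s\n",
    x$n_plants, x$side_length, x$side_length, x$n_max, x$renewal_duration))
  invisible(x)
}

#' Advance nectar renewal by one timestep
#'
#' Any plant below its maximum refills linearly at rate
#' `n_max / renewal_duration`; plants at capacity are unchanged. A plant
#' starting empty therefore returns to `n_max` exactly `renewal_duration`
#' seconds later (to within one timestep of discretization).
#'
#' @param n_t numeric vector of current nectar standing crops (uL).
#' @param n_max maximal nectar (scalar or vector, uL).
#' @param renewal_duration refill time from empty (s), scalar or vector.
#' @param dt timestep length in seconds (default 5).
#' @return Updated nectar vector, clamped to `[0, n_max]`.
#' @export
#' @examples
#' nectar_step(0, n_max = 20, renewal_duration = 200)  # one 5-s step: +0.5 uL
nectar_step <- function(n_t, n_max, renewal_duration, dt = 5) {
  pmin(n_max, n_t + n_max * dt / renewal_duration)
}

#' Harvest nectar from a plant
#'
#' The bee takes `min(n_t, crop_space)`; the plant keeps the rest.
#'
#' @param n_t nectar standing in the plant (uL).
#' @param crop_space remaining crop capacity of the bee (uL, >= 0).
#' @return List with `collected` and `remaining` (plant-side).
#' @export
harvest <- function(n_t, crop_space) {
  if (crop_space < 0) stop("`crop_space` must be non-negative", call. = FALSE)
  collected <- min(n_t, crop_space)
  list(collected = collected, remaining = n_t - collected)
}

#' Read / write a plant table
#'
#' The on-disk format is a plain CSV with columns
#' `plant_id,x,y,n_max,renewal_duration`; the nest is implicit at (0,0).
#'
#' @param path file path.
#' @param env a `bee_env` object (for the writer).
#' @return `read_environment_csv()` returns a `bee_env`.
#' @export
read_environment_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("plant_id", "x", "y", "n_max", "renewal_duration")
  if (!all(need %in% names(df))) {
    stop("environment CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  df <- df[order(df$plant_id), ]
  if (any(df$renewal_duration <= 0)) stop("renewal_duration must be positive", call. = FALSE)
  if (any(df$n_max <= 0)) stop("n_max must be positive", call. = FALSE)
  new_bee_env(df[, c("x", "y")], n_max = df$n_max[1],
              renewal_duration = df$renewal_duration[1])
}

#' @rdname read_environment_csv
#' @export
write_environment_csv <- function(env, path) {
  df <- data.frame(plant_id = seq_len(env$n_plants),
                   x = env$xy[, 1], y = env$xy[, 2],
                   n_max = env$n_max,
                   renewal_duration = env$renewal_duration)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
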