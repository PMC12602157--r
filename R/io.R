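#' Write a simulation record to plain CSV files
#'
#' Emits the visit log (`visits.csv`: time_s,bee_id,bout_index,node_id,
#' nectar_collected_uL), the pollen ledger (`transfers.csv`:
#' time_s,bee_id,donor_plant,recipient_plant,amount), the bout table
#' (`bouts.csv`), per-bee Q-table snapshots (`qtable_bee<i>.csv`:
#' from_node,to_node,q_value), the environment (`environment.csv`) and a
#' small run manifest (`manifest.csv`) echoing the resolved configuration
#' and seed.
#'
#' @param sim a `bee_sim` object.
#' @param dir output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_sim_record <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$visits, file.path(dir, "visits.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(sim$transfers), file.path(dir, "transfers.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$bouts, file.path(dir, "bouts.csv"), row.names = FALSE)
  write_environment_csv(sim$env, file.path(dir, "environment.csv"))
  for (b in seq_along(sim$q)) {
    write_qtable_csv(sim$q[[b]], file.path(dir, sprintf("qtable_bee%d.csv", b)))
  }
  cfg <- sim$config
  manifest <- data.frame(key = c(names(cfg), "seed"),
                         value = c(vapply(cfg, function(x) format(x), character(1)),
                                   format(sim$seed)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Q-table snapshot writer
#'
#' Long-format CSV `from_node,to_node,q_value` (node 1 is the nest, plant
#' i is node i + 1) for debugging and route analysis.
#'
#' @param q square Q matrix.
#' @param path output file.
#' @export
write_qtable_csv <- function(q, path) {
  n <- nrow(q)
  df <- data.frame(from_node = rep(seq_len(n), times = n),
                   to_node = rep(seq_len(n), each = n),
                   q_value = as.vector(q))
  df <- df[df$from_node != df$to_node, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a weighted edge list into a flow matrix
#'
#' CSV with header `donor,recipient,weight`; used by the standalone
#' modularity tool.
#'
#' @param path file path.
#' @return Donor x recipient weight matrix.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.csv(path)
  need <- c("donor", "recipient", "weight")
  if (!all(need %in% names(df))) {
    stop("edge list must have columns donor,recipient,weight", call. = FALSE)
  }
  led <- transfer_ledger(time = rep(0, nrow(df)), bee_id = rep(1L, nrow(df)),
                         donor = df$donor, recipient = df$recipient,
                         amount = df$weight)
  build_flow_matrix(led)
}
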