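POPS <- c("P1", "P2", "NS", "Int")

#' Build the network connectivity for a trial
#'
#' Constructs the neuron table, the population-level connection weight scheme
#' and the electrode placement for a given architecture. Connectivity is
#' all-to-all between the populations that a variant connects (self-connections
#' excluded); because every connection between a pair of populations shares one
#' weight, connectivity is stored compactly as a 4 x 4 (source x target) weight
#' matrix plus an existence mask.
#'
#' Weight rule in the full variant: strong within each selective population
#' (P1-P1, P2-P2), weak between selective populations and between selective and
#' non-selective pyramidal cells, medium for everything involving interneurons
#' and within NS.
#'
#' @param arch A [network_architecture()].
#' @param seed Integer seed; fixes the electrode placement.
#' @return A `wta_network` list with elements `neurons` (tibble: `neuron_id`,
#'   `population`, `class`, `distance_um`), `W`, `exists`, `arch`.
#' @export
#' @examples
#' net <- build_network(network_architecture(), seed = 1)
#' connection_weight(net, "P1", "P1")   # w_strong
build_network <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "network_architecture"))
  v <- arch$variant
  sizes <- switch(v,
    full = arch$sizes,
    disconnected = c(P1 = unname(arch$sizes["P1"]), P2 = 0, NS = 0, Int = 0),
    feedback_only = c(P1 = unname(arch$sizes["P1"]), P2 = 0, NS = 0,
                      Int = arch$n_int_feedback),
    recurrent_only = c(P1 = unname(arch$sizes["P1"]), P2 = 0, NS = 0, Int = 0)
  )
  population <- factor(rep(POPS, times = sizes), levels = POPS)
  n <- length(population)
  cls <- ifelse(population == "Int", "int", "pyr")

  W <- matrix(0, 4, 4, dimnames = list(POPS, POPS))
  ex <- matrix(FALSE, 4, 4, dimnames = list(POPS, POPS))
  if (v == "full") {
    W[] <- arch$w_medium
    ex[] <- TRUE
    W["P1", "P1"] <- W["P2", "P2"] <- arch$w_strong
    W["P1", "P2"] <- W["P2", "P1"] <- arch$w_weak
    W["P1", "NS"] <- W["NS", "P1"] <- arch$w_weak
    W["P2", "NS"] <- W["NS", "P2"] <- arch$w_weak
  } else if (v == "feedback_only") {
    W["P1", "Int"] <- W["Int", "P1"] <- arch$w_medium
    ex["P1", "Int"] <- ex["Int", "P1"] <- TRUE
  } else if (v == "recurrent_only") {
    W["P1", "P1"] <- arch$w_rec
    ex["P1", "P1"] <- TRUE
  }

  placement <- place_neurons(n, seed = seed)
  neurons <- tibble::tibble(
    neuron_id = seq_len(n),
    population = population,
    class = cls,
    distance_um = placement$distance_um
  )
  structure(list(neurons = neurons, W = W, exists = ex, arch = arch,
                 seed = seed),
            class = "wta_network")
}

#' @rdname build_network
#' @param net A `wta_network`.
#' @param from,to Population names (`"P1"`, `"P2"`, `"NS"`, `"Int"`).
#' @export
connection_weight <- function(net, from, to) {
  if (!net$exists[from, to]) return(0)
  net$W[from, to]
}

#' Connection weights as a tibble
#'
#' One row per (source population, target population) pair that is connected,
#' with its shared weight and synapse class (AMPA+NMDA from pyramidal sources,
#' GABA from interneurons).
#'
#' @param net A `wta_network`.
#' @return A tibble with columns `from`, `to`, `weight`, `synapse`.
#' @export
connection_table <- function(net) {
  present <- POPS[POPS %in% as.character(unique(net$neurons$population))]
  grid <- tidyr::expand_grid(from = POPS, to = POPS)
  grid <- dplyr::filter(
    grid,
    purrr::map2_lgl(.data$from, .data$to, ~ net$exists[.x, .y]),
    .data$from %in% present, .data$to %in% present
  )
  dplyr::mutate(
    grid,
    weight = purrr::map2_dbl(.data$from, .data$to, ~ net$W[.x, .y]),
    synapse = ifelse(.data$from == "Int", "GABA", "AMPA+NMDA")
  )
}
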