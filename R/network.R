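#' Corticostriatal network
#'
#' Two populations of cortical units encoding motor programs A and B, and two
#' striatal spiny projection neurons. Program A cells project to SPN 1 and
#' program B cells to SPN 2, with a crossover of `n_crossover` cells in each
#' population to the other SPN. Crossover synapses alone are subthreshold:
#' SPN firing requires at least `quorum` synchronous unit-weight inputs.
#'
#' @param n_per_program cortical units per program (default 11).
#' @param n_crossover cells of each population projecting to the other SPN
#'   (default 2).
#' @param w_init initial synaptic weight.
#' @param w_min,w_max hard weight bounds; weights are clipped after every
#'   update.
#' @param quorum synchronous unit-weight inputs needed to fire an SPN.
#' @return object of class `corticostriatal_network` with a `synapses` table
#'   (`pre_id`, `program`, `target_spn`, `w`, `crossover`).
#' @export
make_network <- function(n_per_program = 11, n_crossover = 2, w_init = 1,
                         w_min = 0, w_max = 2, quorum = 5) {
  stopifnot(n_per_program >= 1, n_crossover >= 0,
            n_crossover < n_per_program, w_min < w_max,
            w_init >= w_min, w_init <= w_max, quorum >= 1)
  one_pop <- function(program, own_spn, other_spn, offset) {
    cross <- seq_len(n_per_program) > (n_per_program - n_crossover)
    data.frame(pre_id = offset + seq_len(n_per_program), program = program,
               target_spn = ifelse(cross, other_spn, own_spn),
               w = w_init, crossover = cross)
  }
  syn <- rbind(one_pop("A", 1L, 2L, 0L),
               one_pop("B", 2L, 1L, n_per_program))
  structure(list(synapses = syn, n_per_program = n_per_program,
                 n_crossover = n_crossover, w_min = w_min, w_max = w_max,
                 quorum = quorum),
            class = "corticostriatal_network")
}

#' Mean synaptic weight of a pathway
#'
#' @param net a `corticostriatal_network`.
#' @param program source program (`"A"` or `"B"`).
#' @param target_spn target SPN (1 or 2); defaults to the program's own SPN.
#' @param direct_only drop crossover synapses (default `TRUE`).
#' @return mean weight of the selected synapses.
#' @export
mean_weight <- function(net, program, target_spn = NULL, direct_only = TRUE) {
  stopifnot(inherits(net, "corticostriatal_network"))
  s <- net$synapses
  if (is.null(target_spn)) target_spn <- if (program == "A") 1L else 2L
  sel <- s$program == program & s$target_spn == target_spn
  if (direct_only) sel <- sel & !s$crossover
  mean(s$w[sel])
}

clip_weights <- function(net) {
  net$synapses$w <- pmin(pmax(net$synapses$w, net$w_min), net$w_max)
  net
}

#' @export
print.corticostriatal_network <- function(x, ...) {
  cat(sprintf(paste0("corticostriatal_network: 2 x %d cortical units, ",
                     "%d-cell crossover, quorum %d\n"),
              x$n_per_program, x$n_crossover, x$quorum))
  cat(sprintf("  mean w: A->SPN1 %.3f, B->SPN2 %.3f (bounds [%g, %g])\n",
              mean_weight(x, "A"), mean_weight(x, "B"), x$w_min, x$w_max))
  invisible(x)
}
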