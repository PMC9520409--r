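#' Build the AV node network topology
#'
#' The AV node is represented by two chains of `n_per_chain` nodes (slow and
#' fast pathway) whose last nodes are connected to each other and to a single
#' coupling node.  All edges are bidirectional, so retrograde conduction is
#' possible within the pathways and between their last nodes.
#'
#' @param n_per_chain nodes per pathway chain (default 10; smaller chains are
#'   useful for oracle testing).
#' @return An object of class `av_topology` with `nodes` (id, role) and an
#'   `edges` two-column matrix of node ids.
#' @examples
#' topo <- build_network()
#' nrow(topo$nodes) # 21
#' @export
build_network <- function(n_per_chain = 10) {
  stopifnot(n_per_chain >= 1)
  L <- n_per_chain
  ids <- 0:(2 * L)
  role <- c(paste0("SP_", 1:L), paste0("FP_", 1:L), "CN")
  edges <- rbind(
    if (L > 1) cbind(0:(L - 2), 1:(L - 1)),            # SP chain
    if (L > 1) cbind(L + 0:(L - 2), L + 1:(L - 1)),    # FP chain
    c(L - 1, 2 * L - 1),                               # SP_L -- FP_L
    c(L - 1, 2 * L),                                   # SP_L -- CN
    c(2 * L - 1, 2 * L)                                # FP_L -- CN
  )
  colnames(edges) <- c("from", "to")
  structure(list(nodes = data.frame(id = ids, role = role), edges = edges,
                 n_per_chain = L),
            class = "av_topology")
}

#' Node degrees of an AV topology
#' @param topo an `av_topology`.
#' @return Named integer vector of degrees, one per node role.
#' @export
node_degrees <- function(topo) {
  stopifnot(inherits(topo, "av_topology"))
  deg <- tabulate(c(topo$edges[, 1], topo$edges[, 2]) + 1L,
                  nbins = nrow(topo$nodes))
  setNames(deg, topo$nodes$role)
}

#' Node conduction state
#'
#' Tracks what the excitation-gap rule needs: the arrival time of the most
#' recent conducted impulse and the refractory period that conduction set
#' (already including the tone scale in force at that moment).  A fresh node
#' (`last_arrival = NULL`) is fully recovered and conducts unconditionally.
#'
#' @param params the node's `pathway_params`.
#' @param last_arrival arrival time (ms) of the last conducted impulse, or
#'   `NULL` if the node has never conducted.
#' @param last_gap excitation gap (ms) at that conduction; `Inf` if fresh.
#' @param a_r tone scale in force at that conduction.
#' @return An object of class `node_state`.
#' @export
node_state <- function(params, last_arrival = NULL, last_gap = Inf, a_r = 1) {
  stopifnot(inherits(params, "pathway_params"))
  structure(list(params = params, last_arrival = last_arrival,
                 last_gap = last_gap,
                 r_prev = if (is.null(last_arrival)) NULL else
                   refractory_period(params, last_gap, a_r)),
            class = "node_state")
}

#' Excitation gap of an arriving impulse
#'
#' The interval between an impulse's arrival and the end of the node's
#' previous refractory period:
#' \eqn{\Delta t_k = t_k - t_{k-1} - R(\Delta t_{k-1})}.  Positive means the
#' impulse is conducted; zero or negative means blocked.  A node that has
#' never conducted returns `Inf` ("fully recovered": unconditional
#' conduction).
#'
#' @param arrival impulse arrival time (ms).
#' @param state a `node_state`.
#' @return The excitation gap in ms (may be <= 0), or `Inf` for a fresh node.
#' @export
excitation_gap <- function(arrival, state) {
  stopifnot(inherits(state, "node_state"))
  if (is.null(state$last_arrival)) return(Inf)
  if (arrival < state$last_arrival)
    stop("events must be processed chronologically")
  arrival - state$last_arrival - state$r_prev
}

as_step <- function(x, what) {
  # normalize a tone-scale spec to a right-continuous step function
  if (is.numeric(x) && length(x) == 1L) {
    if (x <= 0) stop(what, " must be > 0")
    return(list(breaks = -Inf, values = x))
  }
  if (is.list(x) && all(c("breaks", "values") %in% names(x))) {
    stopifnot(length(x$breaks) == length(x$values),
              !is.unsorted(x$breaks, strictly = TRUE), all(x$values > 0))
    b <- x$breaks
    b[1] <- -Inf # first value applies from the start
    return(list(breaks = b, values = x$values))
  }
  stop(what, " must be a positive scalar or list(breaks=, values=)")
}

#' Simulate ventricular activation from an atrial impulse series
#'
#' Runs the discrete-event propagation of atrial impulses through the
#' dual-pathway network.  Each atrial impulse is inserted simultaneously at
#' the first node of both pathways (slow pathway first in insertion order);
#' events are processed in (arrival time, insertion order).  An impulse
#' conducts iff the node is fresh or its excitation gap is strictly positive;
#' on conduction the node's refractory period and delay are recomputed from
#' the gap and new arrivals are scheduled at all adjacent nodes after the
#' conduction delay.  Conductions at the coupling node are the ventricular
#' activation times.
#'
#' @param aa numeric vector of atrial impulse times (ms), strictly increasing.
#' @param params a `model_params`.  Its `a_r`/`a_d` entries may each be either
#'   a positive scalar or a step schedule `list(breaks = , values = )` with
#'   breakpoints in ms (value `i` applies on `[breaks[i], breaks[i+1])`),
#'   as used for tilt protocols.
#' @param n_per_chain nodes per pathway chain (default 10).
#' @return Numeric vector of ventricular activation times (ms), strictly
#'   increasing.
#' @examples
#' p <- model_params(sp = pathway_params(300, 300, 100, 20, 0, 171),
#'                   fp = pathway_params(350, 300, 100, 5, 0, 163))
#' simulate_av(seq(0, 5000, by = 1000), p)
#' @export
simulate_av <- function(aa, params, n_per_chain = 10) {
  stopifnot(inherits(params, "model_params"))
  if (length(aa) == 0L) return(numeric(0))
  if (any(!is.finite(aa))) stop("atrial impulse times must be finite")
  if (is.unsorted(aa, strictly = TRUE))
    stop("atrial impulse times must be strictly increasing")
  ar <- as_step(params$a_r, "a_r")
  ad <- as_step(params$a_d, "a_d")
  unlist_pp <- function(p) as.numeric(unlist(p[c("r_min", "delta_r", "tau_r",
                                                 "d_min", "delta_d", "tau_d")]))
  v <- cpp_simulate_av(as.numeric(aa),
                       unlist_pp(params$sp), unlist_pp(params$fp),
                       unlist_pp(params$cn),
                       ar$breaks, ar$values, ad$breaks, ad$values,
                       as.integer(n_per_chain))
  if (length(v) > 1L) {
    stopifnot(!is.unsorted(v, strictly = TRUE),
              all(diff(v) >= min(ar$values) * params$cn$r_min - 1e-9))
  }
  v
}
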