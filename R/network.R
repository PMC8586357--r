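# The editing process as an explicit 15-state continuous-time Markov chain:
# construction, exact splitting probabilities by linear solve, and Gillespie
# simulation as a stochastic cross-check.

.STATE_LABELS <- c(
  "0"  = "free",
  "1"  = "CTC",
  "2"  = "cas9_bound",
  "3"  = "target_engaged",
  "4"  = "bystander_engaged",
  "5"  = "target_edited_bound",
  "6"  = "bystander_edited_bound",
  "7"  = "target_edited_released",
  "8"  = "bystander_edited_released",
  "9"  = "target_edited_bystander_engaged",
  "10" = "bystander_edited_target_engaged",
  "11" = "both_edited_bound",
  "12" = "TTT",
  "13" = "CTT",
  "14" = "TTC")

.ABSORBING <- c(CTC = 1L, TTT = 12L, CTT = 13L, TTC = 14L)

#' Build the 15-state editing network
#'
#' Materialises the editing process as a labelled directed graph with 15
#' states and 22 rate-carrying edges. Transient states cover Cas9
#' binding, cytidine engagement, chemistry and post-edit release; the four
#' absorbing states are the sequence products CTC, CTT, TTC and TTT.
#' Zero-rate edges (e.g. the rebinding edges when `m = 0`) are retained so
#' the network shape is parameter independent; simulation and the linear
#' solve handle them naturally.
#'
#' @param r a [rate_set()].
#' @return An object of class `kinetic_network` with components `states`
#'   (data.frame: id, label, absorbing), `edges` (data.frame: from, to,
#'   rate, rate_label) and `rates` (the input rate set).
#' @examples
#' net <- build_editing_network(rates_from_reduced(a3a_calibration()))
#' nrow(net$states)  # 15
#' @export
build_editing_network <- function(r) {
  stopifnot(inherits(r, "rate_set"))
  e <- data.frame(
    from = c(0L, 0L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 5L, 5L,
             7L, 7L, 9L, 9L, 6L, 6L, 8L, 8L, 10L, 10L, 11L),
    to   = c(2L, 1L, 0L, 3L, 4L, 2L, 5L, 2L, 6L, 7L, 9L,
             5L, 13L, 5L, 11L, 8L, 10L, 6L, 14L, 6L, 11L, 12L),
    rate = c(r$u0, r$u4, r$w0, r$u1, r$u2, r$w1, r$u3, r$w2, r$u3,
             r$w0, r$u2, r$m * r$u0, r$u4, r$w2, r$u3, r$w0, r$u1,
             r$m * r$u0, r$u4, r$w1, r$u3, r$w0),
    rate_label = c("u0", "u4", "w0", "u1", "u2", "w1", "u3", "w2", "u3",
                   "w0", "u2", "m*u0", "u4", "w2", "u3", "w0", "u1",
                   "m*u0", "u4", "w1", "u3", "w0"),
    stringsAsFactors = FALSE)
  states <- data.frame(
    id = 0:14,
    label = unname(.STATE_LABELS),
    absorbing = 0:14 %in% .ABSORBING,
    stringsAsFactors = FALSE)
  structure(list(states = states, edges = e, rates = r),
            class = "kinetic_network")
}

#' @export
print.kinetic_network <- function(x, ...) {
  cat(sprintf("Kinetic editing network: %d states (%d absorbing), %d edges\n",
              nrow(x$states), sum(x$states$absorbing), nrow(x$edges)))
  invisible(x)
}

# Jump-chain transition structure: list per transient state of target ids
# and probabilities, plus total exit rates.
.jump_chain <- function(net) {
  transient <- net$states$id[!net$states$absorbing]
  out <- lapply(transient, function(s) {
    sel <- net$edges$from == s
    list(to = net$edges$to[sel], rate = net$edges$rate[sel])
  })
  names(out) <- as.character(transient)
  tot <- vapply(out, function(o) sum(o$rate), numeric(1))
  bad <- names(tot)[!is.finite(tot) | tot <= 0]
  if (length(bad))
    stop_beselect(sprintf(
      "transient state(s) %s have zero total exit rate; absorption unreachable",
      paste(bad, collapse = ", ")), "beselect_singular_error")
  list(transient = transient, out = out, total = tot)
}

#' Exact splitting probabilities by linear solve
#'
#' Solves the standard first-step linear system over the transient states of
#' the network: with jump-chain matrix `Q` (transient to transient) and `R`
#' (transient to absorbing), the absorption probabilities are
#' `B = (I - Q)^{-1} R`. This is the package's independent oracle for the
#' closed-form expressions.
#'
#' @param net a [build_editing_network()] result.
#' @param start id of the starting transient state (default 0, the free
#'   substrate).
#' @return Named numeric vector of absorption probabilities over
#'   `c("CTC", "TTT", "CTT", "TTC")`; sums to 1.
#' @export
splitting_probabilities <- function(net, start = 0L) {
  stopifnot(inherits(net, "kinetic_network"))
  if (!start %in% net$states$id[!net$states$absorbing])
    stop_beselect(sprintf("start state %s is not a transient state", start),
                  "beselect_validation_error")
  jc <- .jump_chain(net)
  tr <- jc$transient
  nt <- length(tr)
  abs_ids <- net$states$id[net$states$absorbing]
  Q <- matrix(0, nt, nt, dimnames = list(tr, tr))
  R <- matrix(0, nt, length(abs_ids), dimnames = list(tr, abs_ids))
  for (i in seq_len(nt)) {
    o <- jc$out[[i]]
    pr <- o$rate / jc$total[[i]]
    for (k in seq_along(o$to)) {
      tgt <- o$to[[k]]
      if (tgt %in% abs_ids) {
        R[i, as.character(tgt)] <- R[i, as.character(tgt)] + pr[[k]]
      } else {
        Q[i, as.character(tgt)] <- Q[i, as.character(tgt)] + pr[[k]]
      }
    }
  }
  B <- tryCatch(solve(diag(nt) - Q, R),
                error = function(e) stop_beselect(
                  paste0("singular first-step system: ", conditionMessage(e)),
                  "beselect_singular_error"))
  p <- B[as.character(start), ]
  names(p) <- names(.ABSORBING)[match(as.integer(names(p)), .ABSORBING)]
  p[names(.ABSORBING)]
}

#' Gillespie simulation of the editing network
#'
#' Stochastic simulation algorithm on the continuous-time chain: every
#' trajectory starts in the free state and runs to absorption, with
#' exponential waiting times and next states chosen proportionally to rates.
#' All trajectories are advanced in lock step (vectorised over the embedded
#' jump chain), which leaves the per-trajectory law untouched. One seeded
#' generator per call; the caller's RNG stream is not disturbed.
#'
#' @param net a [build_editing_network()] result.
#' @param n_traj number of trajectories (>= 0).
#' @param seed integer seed; identical seeds give identical counts.
#' @param max_events cap on events per trajectory (default 1e6); exceeding
#'   it raises an error naming the likely degenerate rates.
#' @return An object of class `simulation_result`: `counts` (named integer,
#'   sums to `n_traj`), `freq`, `se` (binomial standard errors), `n_traj`,
#'   `seed`.
#' @examples
#' net <- build_editing_network(rates_from_reduced(a3a_calibration()))
#' simulate_gillespie(net, n_traj = 1000, seed = 7)
#' @export
simulate_gillespie <- function(net, n_traj, seed, max_events = 1e6) {
  stopifnot(inherits(net, "kinetic_network"))
  check_scalar_number(n_traj, "n_traj", nonneg = TRUE)
  n_traj <- as.integer(n_traj)
  outcomes <- names(.ABSORBING)
  counts <- stats::setNames(integer(length(outcomes)), outcomes)
  if (n_traj > 0) {
    jc <- .jump_chain(net)
    counts <- with_seed(seed, {
      state <- rep.int(0L, n_traj)
      alive <- rep.int(TRUE, n_traj)
      absorbed <- integer(n_traj)
      events <- 0L
      while (any(alive)) {
        events <- events + 1L
        if (events > max_events)
          stop_beselect(paste0(
            "trajectory exceeded max_events = ", format(max_events),
            "; rates are likely degenerate (near-zero exits or m*u0 loops)"),
            "beselect_simulation_error")
        idx_alive <- which(alive)
        cur <- state[idx_alive]
        # exponential waiting times (drawn for fidelity to the SSA; outcome
        # counts are waiting-time marginal)
        stats::rexp(length(idx_alive), rate = jc$total[as.character(cur)])
        for (s in unique(cur)) {
          o <- jc$out[[as.character(s)]]
          sel <- idx_alive[cur == s]
          nxt <- if (length(o$to) == 1L) rep.int(o$to, length(sel))
                 else o$to[sample.int(length(o$to), length(sel),
                                      replace = TRUE, prob = o$rate)]
          state[sel] <- nxt
        }
        hit <- alive & state %in% .ABSORBING
        absorbed[hit] <- state[hit]
        alive[hit] <- FALSE
      }
      tab <- table(factor(names(.ABSORBING)[match(absorbed, .ABSORBING)],
                          levels = outcomes))
      stats::setNames(as.integer(tab), outcomes)
    })
  }
  freq <- if (n_traj > 0) counts / n_traj else rep(NA_real_, length(counts))
  se <- if (n_traj > 0) sqrt(pmax(freq * (1 - freq), 0) / n_traj)
        else rep(NA_real_, length(counts))
  structure(list(counts = counts,
                 freq = stats::setNames(as.numeric(freq), outcomes),
                 se = stats::setNames(as.numeric(se), outcomes),
                 n_traj = n_traj, seed = seed),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Gillespie simulation: %d trajectories (seed %s)\n",
              x$n_traj, format(x$seed)))
  print(x$counts)
  invisible(x)
}

#' Export the network as GraphViz DOT
#'
#' @param net a [build_editing_network()] result.
#' @param path optional output file; when `NULL` the DOT source is returned
#'   as a character scalar.
#' @return The DOT source, invisibly when written to `path`.
#' @export
network_to_dot <- function(net, path = NULL) {
  stopifnot(inherits(net, "kinetic_network"))
  nodes <- sprintf('  %d [label="%d: %s"%s];', net$states$id, net$states$id,
                   net$states$label,
                   ifelse(net$states$absorbing, ", shape=doublecircle", ""))
  edges <- sprintf('  %d -> %d [label="%s = %g"];',
                   net$edges$from, net$edges$to, net$edges$rate_label,
                   net$edges$rate)
  dot <- paste(c("digraph editing_network {", "  rankdir=LR;", nodes, edges,
                 "}"), collapse = "\n")
  if (is.null(path)) return(dot)
  writeLines(dot, path)
  invisible(dot)
}

#' Export the network edge list as TSV
#'
#' Columns: `source`, `target`, `rate`, `label`.
#'
#' @param net a [build_editing_network()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
network_to_tsv <- function(net, path) {
  stopifnot(inherits(net, "kinetic_network"))
  df <- data.frame(source = net$edges$from, target = net$edges$to,
                   rate = net$edges$rate, label = net$edges$rate_label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
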