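#' Build directed tail-biting interaction networks
#'
#' Arcs run from the initiator (biter) to the recipient and are weighted by
#' bite counts, so a pig's in-strength is the total number of bites it
#' received and its out-strength the total it performed, regardless of how
#' many distinct pen-mates were involved.  Because bite events are sparse
#' within single observation periods, networks are by default aggregated
#' over all periods (one network per pen); per-period networks are
#' available with `aggregate = FALSE`.
#'
#' @param events Validated bite-event data frame
#'   (`pen_id,period,timestamp_min,biter,recipient`).
#' @param pen_id Pen to build the network for.
#' @param nodes Ordered pig ids of the pen.  Required so that pigs with no
#'   bites still appear as isolated nodes; events naming pigs outside
#'   `nodes` are a validation error.
#' @param periods Periods to cover; default all periods present in
#'   `events` for that pen.
#' @param aggregate If `TRUE` (default) sum counts over `periods` into one
#'   network; otherwise return a named list with one network per period.
#' @return A `bite_network` (list with `pen_id`, `periods`, `nodes`, `A`)
#'   or a list of them.
#' @export
build_bite_network <- function(events, pen_id, nodes, periods = NULL,
                               aggregate = TRUE) {
  ev <- events[events$pen_id == pen_id, , drop = FALSE]
  if (is.null(periods)) {
    periods <- sort(unique(ev$period))
    if (!length(periods)) periods <- NA_integer_
  }
  ev <- ev[ev$period %in% periods, , drop = FALSE]
  outside <- setdiff(unique(c(ev$biter, ev$recipient)), nodes)
  if (length(outside)) {
    stop(sprintf("bite event references pig(s) outside pen %s: %s", pen_id,
                 paste(outside, collapse = ", ")), call. = FALSE)
  }
  if (any(ev$biter == ev$recipient)) {
    stop("self-directed bite event", call. = FALSE)
  }
  count_matrix <- function(e, per) {
    A <- table(factor(e$biter, levels = nodes),
               factor(e$recipient, levels = nodes))
    A <- matrix(as.integer(A), length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    structure(list(pen_id = pen_id, periods = per, nodes = nodes, A = A),
              class = "bite_network")
  }
  if (aggregate) {
    count_matrix(ev, periods)
  } else {
    out <- lapply(periods, function(p) {
      count_matrix(ev[ev$period == p, , drop = FALSE], p)
    })
    names(out) <- as.character(periods)
    out
  }
}

#' @export
print.bite_network <- function(x, ...) {
  cat(sprintf(
    "Tail-biting network, pen %s (periods %s): %d pigs, %d bites\n",
    x$pen_id, paste(x$periods, collapse = ","), length(x$nodes), sum(x$A)))
  invisible(x)
}

#' Build one aggregated bite network per pen
#'
#' @param events Bite-event data frame.
#' @param roster Data frame with at least `pig_id` and `pen_id`, defining
#'   the node set of every pen.
#' @return Named list of `bite_network` objects, one per pen in `roster`.
#' @export
build_all_bite_networks <- function(events, roster) {
  pens <- sort(unique(roster$pen_id))
  out <- lapply(pens, function(p) {
    build_bite_network(events, p,
                       nodes = sort(roster$pig_id[roster$pen_id == p]))
  })
  names(out) <- pens
  out
}
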