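#' Simulate a herd design: roster, latent pig effects, preference matrices
#'
#' Builds the pig roster (pen, treatment, sex), latent sociality effects used
#' by the bite-event process, monotone body-weight trajectories, and one
#' symmetric lying-preference matrix per pen.
#'
#' Preference structures: `uniform` sets every off-diagonal weight to 1;
#' `hub` raises the weights of all dyads involving the pen's first pig to
#' `1 + kappa`; `block` splits the pen into two equal blocks and raises
#' within-block weights to `1 + kappa` (the half-littermate situation, where
#' familiarity is shared within litters of origin).
#'
#' @param config A [sim_config()] object.
#' @return An object of class `herd_design`: a list with elements
#'   `pigs` (data frame: `pig_id`, `pen_id`, `treatment`, `sex`, `s_out`,
#'   `s_in`), `weights` (data frame: `pig_id`, `pen_id`, `week`,
#'   `weight_kg`), and `preference` (named list of symmetric zero-diagonal
#'   matrices, one per pen).
#' @export
simulate_herd <- function(config) {
  validate_sim_config(config)
  k <- config$pigs_per_pen
  weeks <- seq(config$study_weeks[1], config$study_weeks[2])
  pigs <- vector("list", config$n_pens)
  wts <- vector("list", config$n_pens)
  pref <- vector("list", config$n_pens)
  pen_ids <- sprintf("pen%02d", seq_len(config$n_pens))
  for (p in seq_len(config$n_pens)) {
    set.seed(pen_seed(config$seed, p, 1L))
    pig_id <- sprintf("%s_p%d", pen_ids[p], seq_len(k))
    sex <- rep(c("barrow", "gilt"), each = k / 2L)
    pigs[[p]] <- data.frame(
      pig_id = pig_id,
      pen_id = pen_ids[p],
      treatment = config$treatments[p],
      sex = sex,
      s_out = stats::rnorm(k, 0, config$sigma_out),
      s_in = stats::rnorm(k, 0, config$sigma_in),
      stringsAsFactors = FALSE
    )
    # weekly weights: individual start and gain, gains floored to keep
    # trajectories strictly increasing
    w0 <- stats::rnorm(k, 25, 2)
    adg <- stats::rnorm(k, 6.9, 0.8)
    gain <- matrix(pmax(0.5, stats::rnorm(k * (length(weeks) - 1L),
                                          mean = rep(adg, length(weeks) - 1L),
                                          sd = 0.5)),
                   nrow = k)
    traj <- cbind(w0, w0 + t(apply(gain, 1L, cumsum)))
    wts[[p]] <- data.frame(
      pig_id = rep(pig_id, times = length(weeks)),
      pen_id = pen_ids[p],
      week = rep(weeks, each = k),
      weight_kg = as.vector(traj[, seq_along(weeks)]),
      stringsAsFactors = FALSE
    )
    W <- matrix(1, k, k)
    if (config$preference_structure == "hub") {
      W[1, ] <- W[, 1] <- 1 + config$kappa
    } else if (config$preference_structure == "block") {
      half <- k / 2L
      blk <- rep(c(1L, 2L), each = half)
      same <- outer(blk, blk, "==")
      W[same] <- 1 + config$kappa
    }
    diag(W) <- 0
    dimnames(W) <- list(pig_id, pig_id)
    pref[[p]] <- W
  }
  names(pref) <- pen_ids
  structure(list(
    pigs = do.call(rbind, pigs),
    weights = do.call(rbind, wts),
    preference = pref
  ), class = "herd_design")
}

#' @export
print.herd_design <- function(x, ...) {
  cat(sprintf("Herd design: %d pigs in %d pens (%s)\n",
              nrow(x$pigs), length(x$preference),
              paste(unique(x$pigs$treatment), collapse = "/")))
  invisible(x)
}

#' Simulate scan-sampled lying observations
#'
#' For every pen, observation period and scan instant, each pig lies
#' independently with probability `p_lie`.  Lying-together pairs among the
#' lying pigs are then formed by a weighted greedy matching: each admissible
#' dyad (both pigs lying, preference weight > 0) draws an exponential score
#' with rate equal to its preference weight, dyads are accepted in
#' increasing score order — equivalent to successive sampling proportional
#' to the weights — a pig can accumulate at most two lying-with neighbors
#' (mimicking row-lying against the pen wall without modelling pen
#' geometry), and acceptance stops once a matching-size number of pairs
#' (`floor(L/2)` for `L` lying pigs) has formed.  The stopping rule keeps
#' the per-scan contact graph sparse enough that dyadic preferences remain
#' expressed in the aggregated counts; running the greedy to saturation
#' would cap every pig at two neighbors and make the accepted edge set
#' almost independent of the weights.  The resulting partner relation is
#' symmetric and implies lying.
#'
#' @param herd A [simulate_herd()] result.
#' @param config The matching [sim_config()].
#' @return A data frame of scan records with columns `pen_id`, `period`,
#'   `scan_index`, `pig_id`, `lying` (0/1), `partners` (semicolon-separated
#'   `pig_id`s, empty when alone).
#' @export
simulate_lying_scans <- function(herd, config) {
  validate_sim_config(config)
  k <- config$pigs_per_pen
  pen_ids <- names(herd$preference)
  dy <- utils::combn(k, 2L)  # dyads as index pairs, fixed order
  out <- vector("list", length(pen_ids))
  for (p in seq_along(pen_ids)) {
    set.seed(pen_seed(config$seed, p, 2L))
    ids <- rownames(herd$preference[[p]])
    W <- herd$preference[[p]]
    wdy <- W[cbind(dy[1, ], dy[2, ])]
    n_rows <- length(config$periods) * config$scans_per_period * k
    lying_col <- integer(n_rows)
    partner_col <- character(n_rows)
    period_col <- integer(n_rows)
    scan_col <- integer(n_rows)
    r <- 0L
    for (per in config$periods) {
      for (s in seq_len(config$scans_per_period)) {
        lying <- stats::runif(k) < config$p_lie
        deg <- integer(k)
        partners <- vector("list", k)
        ok <- lying[dy[1, ]] & lying[dy[2, ]] & wdy > 0
        if (any(ok)) {
          idx <- which(ok)
          sc <- stats::rexp(length(idx), rate = wdy[idx])
          n_target <- sum(lying) %/% 2L  # matching-size number of pairs
          accepted <- 0L
          for (d in idx[order(sc)]) {
            if (accepted >= n_target) break
            a <- dy[1, d]; b <- dy[2, d]
            if (deg[a] < 2L && deg[b] < 2L) {
              deg[a] <- deg[a] + 1L
              deg[b] <- deg[b] + 1L
              accepted <- accepted + 1L
              partners[[a]] <- c(partners[[a]], ids[b])
              partners[[b]] <- c(partners[[b]], ids[a])
            }
          }
        }
        rows <- r + seq_len(k)
        lying_col[rows] <- as.integer(lying)
        partner_col[rows] <- vapply(partners, function(z) {
          paste(sort(z), collapse = ";")
        }, character(1))
        period_col[rows] <- per
        scan_col[rows] <- s
        r <- r + k
      }
    }
    out[[p]] <- data.frame(
      pen_id = pen_ids[p],
      period = period_col,
      scan_index = scan_col,
      pig_id = rep(ids, times = n_rows / k),
      lying = lying_col,
      partners = partner_col,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate directed tail-biting events
#'
#' For each directed within-pen dyad \eqn{i \to j} and each observation
#' period the bite count is Poisson with mean
#' \eqn{\lambda_0 \exp(s_{out}(i) + s_{in}(j))}, a log-additive
#' sender/receiver form that lets biter and victim heterogeneity be dialed
#' independently.  Events receive timestamps uniform over the 6-h window.
#'
#' @inheritParams simulate_lying_scans
#' @return A data frame of bite events: `pen_id`, `period`, `timestamp_min`
#'   (minutes into the observation window), `biter`, `recipient`.
#' @export
simulate_bite_events <- function(herd, config) {
  validate_sim_config(config)
  window_min <- config$scans_per_period * config$scan_interval
  pen_ids <- names(herd$preference)
  out <- list()
  for (p in seq_along(pen_ids)) {
    set.seed(pen_seed(config$seed, p, 3L))
    pg <- herd$pigs[herd$pigs$pen_id == pen_ids[p], ]
    k <- nrow(pg)
    rate <- config$bite_rate_base * exp(outer(pg$s_out, pg$s_in, "+"))
    diag(rate) <- 0
    for (per in config$periods) {
      counts <- matrix(stats::rpois(k * k, rate), k, k)
      diag(counts) <- 0L
      tot <- sum(counts)
      if (tot == 0L) next
      i <- rep(rep(seq_len(k), k), times = as.vector(counts))
      j <- rep(rep(seq_len(k), each = k), times = as.vector(counts))
      ts <- stats::runif(tot, 0, window_min)
      o <- order(ts)
      out[[length(out) + 1L]] <- data.frame(
        pen_id = pen_ids[p],
        period = per,
        timestamp_min = ts[o],
        biter = pg$pig_id[i][o],
        recipient = pg$pig_id[j][o],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(pen_id = character(), period = integer(),
                      timestamp_min = numeric(), biter = character(),
                      recipient = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# assessment ages (in weeks, fractional) over the study span
assessment_weeks <- function(config) {
  step <- 1 / config$assessments_per_week
  seq(config$study_weeks[1], config$study_weeks[2] - step, by = step)
}

#' Simulate tail-injury score trajectories
#'
#' Scores follow the 0-4 tail-injury scale (0 none, 1 healed lesions/minor
#' scabs, 2 blood without infection, 3 blood with infection, 4 partial or
#' complete tail loss) at twice-weekly assessments over the study span.
#' Between consecutive assessments the score escalates one level with
#' probability \eqn{1 - (1 - \mathrm{injury\_gain})^{b}} where \eqn{b} is
#' the number of bites the pig received in that window (events dated by
#' their observation-period week), capped at 4; when no bites occurred,
#' scores of 1-2 heal one level with probability `heal_prob` (higher scores
#' represent infected wounds that do not resolve between assessments).
#'
#' @inheritParams simulate_lying_scans
#' @param events Bite-event data frame as from [simulate_bite_events()].
#' @return A data frame with columns `pig_id`, `assessment_index`, `score`.
#' @export
simulate_tail_scores <- function(herd, events, config) {
  validate_sim_config(config)
  wk <- assessment_weeks(config)
  n_assess <- length(wk)
  pen_ids <- names(herd$preference)
  out <- vector("list", length(pen_ids))
  for (p in seq_along(pen_ids)) {
    set.seed(pen_seed(config$seed, p, 4L))
    pg <- herd$pigs[herd$pigs$pen_id == pen_ids[p], ]
    k <- nrow(pg)
    ev <- events[events$pen_id == pen_ids[p], , drop = FALSE]
    # bites received per pig per assessment window: an event in period week w
    # lands in the window that closes at the assessment of age w
    bites <- matrix(0L, k, n_assess, dimnames = list(pg$pig_id, NULL))
    if (nrow(ev)) {
      win <- match(ev$period, wk)
      if (anyNA(win)) {
        stop("bite events fall outside the assessment schedule", call. = FALSE)
      }
      tab <- table(factor(ev$recipient, levels = pg$pig_id), win)
      bites[, as.integer(colnames(tab))] <-
        bites[, as.integer(colnames(tab))] + unclass(tab)
    }
    score <- matrix(0L, k, n_assess)
    cur <- integer(k)
    for (a in seq_len(n_assess)) {
      if (a > 1L) {
        b <- bites[, a]
        esc <- stats::runif(k) < (1 - (1 - config$injury_gain)^b)
        heal <- b == 0L & cur >= 1L & cur <= 2L &
          stats::runif(k) < config$heal_prob
        cur <- pmin(4L, cur + as.integer(esc & b > 0L)) - as.integer(heal)
        cur <- pmax(0L, cur)
      }
      score[, a] <- cur
    }
    out[[p]] <- data.frame(
      pig_id = rep(pg$pig_id, times = n_assess),
      assessment_index = rep(seq_len(n_assess), each = k),
      score = as.integer(score),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res[order(res$pig_id, res$assessment_index), , drop = FALSE]
}

#' Simulate a complete study data set
#'
#' Convenience wrapper chaining [simulate_herd()], [simulate_lying_scans()],
#' [simulate_bite_events()] and [simulate_tail_scores()].
#'
#' @param config A [sim_config()].
#' @return A list with elements `config`, `herd`, `scans`, `bites`,
#'   `scores`.
#' @export
simulate_study <- function(config = sim_config()) {
  herd <- simulate_herd(config)
  scans <- simulate_lying_scans(herd, config)
  bites <- simulate_bite_events(herd, config)
  scores <- simulate_tail_scores(herd, bites, config)
  list(config = config, herd = herd, scans = scans, bites = bites,
       scores = scores)
}
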