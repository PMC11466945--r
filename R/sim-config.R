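#' Simulation configuration for synthetic pen-behavior data
#'
#' Bundles every parameter of the synthetic-data generator: the herd design
#' (pens, pigs per pen, litter-origin treatments), the scan-sampling scheme
#' for lying observations, the bite-event process, and the tail-injury
#' dynamics.  Defaults mirror the study design the generator emulates:
#' 12 pens of 8 pigs (4 barrows, 4 gilts) in three litter-origin treatments
#' (LM = littermates, HLM = half-littermates, NLM = non-littermates, 4 pens
#' each), three 6-h observation periods at 15, 19 and 23 weeks of age
#' scanned every 10 min (36 scans), and twice-weekly tail-injury
#' assessments over the 14-week growing-finishing phase (weeks 10-24).
#'
#' @param n_pens Number of pens.
#' @param pigs_per_pen Pigs per pen (default 8).
#' @param treatments Character vector of length `n_pens` assigning each pen
#'   to a litter-origin treatment; defaults to an equal split of
#'   `c("LM", "HLM", "NLM")` in pen order.
#' @param periods Integer vector of observation ages in weeks.
#' @param scans_per_period Scans per 6-h observation period (default 36).
#' @param scan_interval Minutes between scans (default 10).
#' @param p_lie Probability that a pig is lying at any scan.
#' @param preference_structure Dyadic lying-preference structure:
#'   `"uniform"` (all dyads equal), `"hub"` (one pig's dyads up-weighted,
#'   a highly social individual), or `"block"` (two half-pen blocks with
#'   elevated within-block preference, emulating half-littermate pens).
#' @param kappa Concentration parameter \eqn{\kappa \ge 0}: preferred dyads
#'   get weight \eqn{1 + \kappa}, all others 1.  `kappa = 0` collapses every
#'   structure to uniform.
#' @param bite_rate_base Expected number of bites per directed dyad per
#'   observation period before pig-level effects.
#' @param sigma_out,sigma_in Standard deviations of the log-scale biter
#'   (sender) and victim (receiver) pig effects.
#' @param injury_gain Per-bite probability parameter of score escalation:
#'   between assessments the score rises one level with probability
#'   \eqn{1 - (1 - \mathrm{injury\_gain})^{b}} where \eqn{b} is the number
#'   of bites received since the previous assessment.
#' @param heal_prob Per-assessment probability that a score of 1 or 2
#'   decreases by one level when no new bites occurred.
#' @param assessments_per_week Tail-scoring frequency (default 2,
#'   i.e. Monday and Friday).
#' @param study_weeks Length-2 integer vector giving the first and last
#'   week of age of the study period (default `c(10, 24)`).
#' @param seed Integer seed.  The generator derives one independent
#'   pseudo-random substream per pen from it, so adding pens does not
#'   perturb the data of existing pens.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_pens = 12L,
                       pigs_per_pen = 8L,
                       treatments = NULL,
                       periods = c(15L, 19L, 23L),
                       scans_per_period = 36L,
                       scan_interval = 10,
                       p_lie = 0.8,
                       preference_structure = c("uniform", "hub", "block"),
                       kappa = 0,
                       bite_rate_base = 0.25,
                       sigma_out = 0.8,
                       sigma_in = 0.5,
                       injury_gain = 0.4,
                       heal_prob = 0.08,
                       assessments_per_week = 2L,
                       study_weeks = c(10L, 24L),
                       seed = 1L) {
  preference_structure <- match.arg(preference_structure)
  n_pens <- as.integer(n_pens)
  pigs_per_pen <- as.integer(pigs_per_pen)
  if (is.null(treatments)) {
    treatments <- rep(c("LM", "HLM", "NLM"), length.out = n_pens)
    if (n_pens %% 3L == 0L) {
      treatments <- rep(c("LM", "HLM", "NLM"), each = n_pens / 3L)
    }
  }
  cfg <- structure(list(
    n_pens = n_pens,
    pigs_per_pen = pigs_per_pen,
    treatments = as.character(treatments),
    periods = as.integer(periods),
    scans_per_period = as.integer(scans_per_period),
    scan_interval = as.numeric(scan_interval),
    p_lie = p_lie,
    preference_structure = preference_structure,
    kappa = kappa,
    bite_rate_base = bite_rate_base,
    sigma_out = sigma_out,
    sigma_in = sigma_in,
    injury_gain = injury_gain,
    heal_prob = heal_prob,
    assessments_per_week = as.integer(assessments_per_week),
    study_weeks = as.integer(study_weeks),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk_prob <- function(p, what) {
    if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
      stop(sprintf("'%s' must be a probability in [0, 1]", what), call. = FALSE)
    }
  }
  chk_prob(cfg$p_lie, "p_lie")
  chk_prob(cfg$injury_gain, "injury_gain")
  chk_prob(cfg$heal_prob, "heal_prob")
  if (cfg$n_pens < 1L || cfg$pigs_per_pen < 1L) {
    stop("counts must be >= 1", call. = FALSE)
  }
  if (length(cfg$treatments) != cfg$n_pens) {
    stop("'treatments' must assign one treatment per pen", call. = FALSE)
  }
  if (cfg$kappa < 0) stop("'kappa' must be >= 0", call. = FALSE)
  if (cfg$bite_rate_base < 0) {
    stop("'bite_rate_base' must be >= 0", call. = FALSE)
  }
  if (cfg$sigma_out < 0 || cfg$sigma_in < 0) {
    stop("heterogeneity standard deviations must be >= 0", call. = FALSE)
  }
  if (cfg$pigs_per_pen %% 2L != 0L) {
    stop("pigs_per_pen must be even for a balanced barrow/gilt split",
         call. = FALSE)
  }
  if (cfg$scans_per_period < 1L || cfg$assessments_per_week < 1L) {
    stop("counts must be >= 1", call. = FALSE)
  }
  if (length(cfg$study_weeks) != 2L || diff(cfg$study_weeks) <= 0) {
    stop("'study_weeks' must be an increasing pair of week numbers",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic pen-behavior configuration\n")
  cat(sprintf("  %d pens x %d pigs; treatments: %s\n", x$n_pens,
              x$pigs_per_pen, paste(unique(x$treatments), collapse = "/")))
  cat(sprintf("  periods (wk): %s; %d scans every %g min; p_lie = %g\n",
              paste(x$periods, collapse = ", "), x$scans_per_period,
              x$scan_interval, x$p_lie))
  cat(sprintf("  preference: %s (kappa = %g)\n", x$preference_structure,
              x$kappa))
  cat(sprintf("  bites: base rate %g/dyad/period, sigma_out %g, sigma_in %g\n",
              x$bite_rate_base, x$sigma_out, x$sigma_in))
  cat(sprintf("  injury: gain %g, heal %g, %d assessments/wk, weeks %d-%d\n",
              x$injury_gain, x$heal_prob, x$assessments_per_week,
              x$study_weeks[1], x$study_weeks[2]))
  invisible(x)
}

# One independent substream per (pen, stage): a fixed linear hash into the
# 32-bit integer range.  Stages: 1 herd, 2 lying scans, 3 bites, 4 scores.
pen_seed <- function(seed, pen_index, stage) {
  as.integer((as.double(seed) * 7L + pen_index * 10007 + stage * 104729) %%
               2147483629)
}
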