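#' Pipeline configuration
#'
#' Declarative configuration for the full simulate/ingest -> networks ->
#' metrics -> injury scoring -> models pipeline.  Defaults mirror the
#' study design constants: 8 pigs per pen, 36 scans per 6-h period, three
#' observation periods, correlation threshold 0.8, victim cutoff at MTS 2.
#'
#' @param sim A [sim_config()] (used when no input CSVs are given).
#' @param scans_csv,bites_csv,scores_csv,roster_csv Optional paths to
#'   user-supplied observation tables; when all are `NULL` the synthetic
#'   generator supplies the data.
#' @param out_dir Output directory.
#' @param weighted_centralization,betweenness_weighted,min_hwi Metric
#'   options (see [pen_metrics()]; `min_hwi` zeroes association edges below
#'   the cutoff before metrics, default 0 = no thresholding).
#' @param cor_threshold Correlation-screen cutoff.
#' @param seed Seed recorded in the manifest; forwarded to `sim`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(seed = seed),
                            scans_csv = NULL, bites_csv = NULL,
                            scores_csv = NULL, roster_csv = NULL,
                            out_dir = tempfile("tailnet_run_"),
                            weighted_centralization = FALSE,
                            betweenness_weighted = NULL,
                            min_hwi = 0,
                            cor_threshold = 0.8,
                            seed = 1L) {
  structure(list(
    sim = sim, scans_csv = scans_csv, bites_csv = bites_csv,
    scores_csv = scores_csv, roster_csv = roster_csv, out_dir = out_dir,
    weighted_centralization = weighted_centralization,
    betweenness_weighted = betweenness_weighted,
    min_hwi = min_hwi, cor_threshold = cor_threshold,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim`
#' block mirrors [sim_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  seed <- y$seed %||% 1L
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  args <- c(list(sim = do.call(sim_config, sim_args)), y)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages, in order: (1) simulate or read the observation tables and write
#' them to `out_dir`; (2) aggregate scans and build one association network
#' per pen-period plus one aggregated bite network per pen; (3) compute
#' pen- and pig-level metrics; (4) score tails (MTS, classes, victims),
#' tabulate MTS class by treatment and run the chi-square test; (5) export
#' tidy CSVs.  A manifest records, per stage, row counts, output files with
#' MD5 hashes, elapsed time and status; rerunning with an identical
#' configuration and seed reproduces identical hashes.  A stage failure is
#' recorded in the manifest and downstream stages are skipped.
#'
#' @param config A [pipeline_config()].
#' @return List with `manifest` (data frame), `networks`, `metrics`,
#'   `injury`, and `data` (the observation tables).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  state <- new.env(parent = emptyenv())
  failed <- FALSE

  stage <- function(name, fun) {
    if (failed) {
      manifest[[length(manifest) + 1L]] <<- data.frame(
        stage = name, status = "skipped", n_out = NA_integer_,
        files = "", md5 = "", elapsed_s = NA_real_,
        stringsAsFactors = FALSE)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    warns <- character()
    res <- tryCatch(
      withCallingHandlers(fun(), warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) e)
    el <- proc.time()[["elapsed"]] - t0
    if (length(warns)) {
      message(sprintf("stage '%s': %d warning(s): %s", name, length(warns),
                      paste(utils::head(warns, 3L), collapse = " | ")))
    }
    if (inherits(res, "error")) {
      failed <<- TRUE
      manifest[[length(manifest) + 1L]] <<- data.frame(
        stage = name, status = paste("failed:", conditionMessage(res)),
        n_out = NA_integer_, files = "", md5 = "", elapsed_s = el,
        stringsAsFactors = FALSE)
    } else {
      manifest[[length(manifest) + 1L]] <<- data.frame(
        stage = name, status = "ok", n_out = res$n %||% NA_integer_,
        files = paste(basename(res$files %||% character()), collapse = ";"),
        md5 = paste(unname(tools::md5sum(res$files %||% character())),
                    collapse = ";"),
        elapsed_s = el, stringsAsFactors = FALSE)
    }
    invisible(NULL)
  }

  stage("ingest", function() {
    if (is.null(config$scans_csv)) {
      sim <- simulate_study(config$sim)
      state$scans <- sim$scans
      state$bites <- sim$bites
      state$scores <- sim$scores
      state$roster <- sim$herd$pigs[, c("pig_id", "pen_id", "treatment",
                                        "sex")]
      state$weights <- sim$herd$weights
      state$periods <- config$sim$periods
    } else {
      state$scans <- read_scans(config$scans_csv)
      state$bites <- read_bites(config$bites_csv)
      state$scores <- read_tail_scores(config$scores_csv)
      state$roster <- utils::read.csv(config$roster_csv,
                                      stringsAsFactors = FALSE)
      state$weights <- NULL
      state$periods <- sort(unique(state$scans$period))
    }
    f <- file.path(config$out_dir,
                   c("scans.csv", "bites.csv", "tail_scores.csv",
                     "roster.csv"))
    write_scans(state$scans, f[1])
    write_bites(state$bites, f[2])
    write_tail_scores(state$scores, f[3])
    utils::write.csv(state$roster, f[4], row.names = FALSE, quote = FALSE)
    list(n = nrow(state$scans), files = f)
  })

  stage("build_networks", function() {
    aggs <- aggregate_all_scans(state$scans)
    assoc <- lapply(aggs, function(a) {
      net <- build_association_network(a)
      if (config$min_hwi > 0) net$W[net$W < config$min_hwi] <- 0
      net
    })
    bites <- build_all_bite_networks(state$bites, state$roster)
    state$assoc <- assoc
    state$bitenets <- bites
    f <- file.path(config$out_dir, "association_edges.csv")
    edges <- do.call(rbind, lapply(assoc, function(net) {
      idx <- which(upper.tri(net$W) & net$W > 0, arr.ind = TRUE)
      if (!nrow(idx)) return(NULL)
      data.frame(pen_id = net$pen_id, period = net$period,
                 pig_a = net$nodes[idx[, 1]], pig_b = net$nodes[idx[, 2]],
                 hwi = net$W[idx], stringsAsFactors = FALSE)
    }))
    utils::write.csv(edges, f, row.names = FALSE, quote = FALSE)
    f2 <- file.path(config$out_dir, "bite_edges.csv")
    bedges <- do.call(rbind, lapply(bites, function(net) {
      idx <- which(net$A > 0, arr.ind = TRUE)
      if (!nrow(idx)) return(NULL)
      data.frame(pen_id = net$pen_id,
                 biter = net$nodes[idx[, 1]],
                 recipient = net$nodes[idx[, 2]],
                 count = net$A[idx], stringsAsFactors = FALSE)
    }))
    if (is.null(bedges)) {
      bedges <- data.frame(pen_id = character(), biter = character(),
                           recipient = character(), count = integer())
    }
    utils::write.csv(bedges, f2, row.names = FALSE, quote = FALSE)
    list(n = length(assoc) + length(bites), files = c(f, f2))
  })

  stage("metrics", function() {
    pen_assoc <- do.call(rbind, lapply(state$assoc, pen_metrics,
      weighted_centralization = config$weighted_centralization,
      betweenness_weighted = config$betweenness_weighted))
    pig_assoc <- do.call(rbind, lapply(state$assoc, pig_metrics,
      betweenness_weighted = config$betweenness_weighted))
    pen_bite <- do.call(rbind, lapply(state$bitenets, pen_metrics,
      weighted_centralization = config$weighted_centralization))
    pig_bite <- do.call(rbind, lapply(state$bitenets, pig_metrics))
    rownames(pen_assoc) <- rownames(pig_assoc) <- NULL
    rownames(pen_bite) <- rownames(pig_bite) <- NULL
    state$metrics <- list(pen_assoc = pen_assoc, pig_assoc = pig_assoc,
                          pen_bite = pen_bite, pig_bite = pig_bite)
    f <- file.path(config$out_dir,
                   c("pen_metrics_association.csv",
                     "pig_metrics_association.csv",
                     "pen_metrics_bite.csv", "pig_metrics_bite.csv"))
    utils::write.csv(pen_assoc, f[1], row.names = FALSE, quote = FALSE)
    utils::write.csv(pig_assoc, f[2], row.names = FALSE, quote = FALSE)
    utils::write.csv(pen_bite, f[3], row.names = FALSE, quote = FALSE)
    utils::write.csv(pig_bite, f[4], row.names = FALSE, quote = FALSE)
    list(n = nrow(pig_assoc) + nrow(pig_bite), files = f)
  })

  stage("score_tails", function() {
    mts <- score_tails(state$scores)
    tab <- mts_class_table(mts, state$roster)
    chi <- tryCatch(pearson_chi_square(tab), error = function(e) NULL)
    state$injury <- list(mts = mts, class_table = tab, chi_square = chi)
    f <- file.path(config$out_dir, c("mts.csv", "mts_class_table.csv",
                                     "mts_chi_square.csv"))
    utils::write.csv(mts, f[1], row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame.matrix(tab), f[2], row.names = TRUE,
                     quote = FALSE)
    chidf <- if (is.null(chi)) {
      data.frame(statistic = NA_real_, df = NA_integer_,
                 p_value = NA_real_)
    } else {
      data.frame(statistic = chi$statistic, df = chi$df,
                 p_value = chi$p_value)
    }
    utils::write.csv(chidf, f[3], row.names = FALSE, quote = FALSE)
    list(n = nrow(mts), files = f)
  })

  manifest_df <- do.call(rbind, manifest)
  mf <- file.path(config$out_dir, "manifest.csv")
  utils::write.csv(manifest_df, mf, row.names = FALSE)
  list(
    manifest = manifest_df,
    networks = list(association = state$assoc, bite = state$bitenets),
    metrics = state$metrics,
    injury = state$injury,
    data = list(scans = state$scans, bites = state$bites,
                scores = state$scores, roster = state$roster,
                weights = state$weights)
  )
}
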