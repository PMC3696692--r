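# Pipeline orchestration: one config drives the requested stages and a
# combined summary. Deterministic given (inputs, config, seed); every
# output directory carries the config hash in summary.json.

#' Run the flexibility-analysis pipeline from a config
#'
#' Executes the requested stages over a structure ensemble (from a
#' multi-MODEL PDB or the synthetic hinged-trajectory generator), a DEER
#' trace (from file or the synthetic generator) and an alignment (from
#' file or the synthetic generator), writing per-stage tables plus a
#' combined `summary.json` into `out_dir`. All referenced selections are
#' resolved before any stage runs, so a bad selection fails fast. Any
#' stage error aborts with a message naming the stage.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognised top-level fields:
#' \describe{
#'   \item{seed}{integer; drives every stochastic step (default 1).}
#'   \item{out_dir}{output directory (created if needed).}
#'   \item{trajectory}{`list(path=...)` to read a PDB ensemble, or
#'     `list(synthetic=TRUE, ...)` with [hinged_config()] overrides.}
#'   \item{selections}{named list of selection expressions.}
#'   \item{distances}{`list(pairs=list(c("selA","selB"), ...),
#'     bin_width=0.1, discard_first=0, weighting="mass")`.}
#'   \item{rmsf}{`list(selection="name CA")` — superposes onto the mean
#'     structure, writes the r.m.s.f. profile and theoretical B-factors.}
#'   \item{hbonds}{`list(chain=..., residue_range=c(lo,hi),
#'     d_NO_max=3.5, threshold_absent=0.3)`.}
#'   \item{contacts}{`list(probe=..., site=..., cutoff=4)` (selection
#'     names).}
#'   \item{deer}{`list(path=...)` or `list(synthetic=TRUE, ...)` with
#'     [deer_sim_config()] overrides; optional `alpha` (number or
#'     `"auto"`).}
#'   \item{glypro}{`list(path=..., format=..., region=...,
#'     spans=list(name=c(lo,hi)))` or `list(synthetic=TRUE, ...)` with
#'     [seq_set_config()] overrides.}
#' }
#' @return (invisibly) a list with the per-stage results and the summary.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% stop("config needs an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- substr(digest_config(config), 1, 16)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  results <- list()
  summary <- list(config_hash = cfg_hash, seed = seed)

  ensemble <- NULL
  if (!is.null(config$trajectory)) {
    ensemble <- stage("trajectory", {
      tr <- config$trajectory
      if (isTRUE(tr$synthetic)) {
        args <- tr[setdiff(names(tr), "synthetic")]
        args$seed <- args$seed %||% seed
        gen <- make_hinged_trajectory(do.call(hinged_config, args))
        results$trajectory_manifest <- gen$manifest
        gen$ensemble
      } else read_pdb_ensemble(tr$path)
    })
  }

  sels <- list()
  if (!is.null(config$selections)) {
    if (is.null(ensemble)) stop("selections given without a trajectory")
    sels <- stage("selections", {
      lapply_named(config$selections, function(expr, nm)
        resolve_selection(ensemble, expr, label = nm))
    })
  }

  if (!is.null(config$distances)) {
    results$distances <- stage("distances", {
      dc <- config$distances
      traces <- lapply(dc$pairs, function(pr)
        com_distance_trace(ensemble, sels[[pr[1]]], sels[[pr[2]]],
                           weighting = dc$weighting %||% "mass"))
      for (i in seq_along(traces))
        write_distance_trace_csv(traces[[i]], file.path(out_dir,
          sprintf("distance_%s_%s.csv", dc$pairs[[i]][1], dc$pairs[[i]][2])))
      hist <- pooled_histogram(traces, bin_width = dc$bin_width %||% 0.1,
                               discard_first = dc$discard_first %||% 0)
      write_histogram_tsv(hist, file.path(out_dir, "distance_histogram.tsv"))
      summary$distance_mean <- hist$mean
      summary$distance_min <- min(unlist(lapply(traces, `[[`, "d")))
      summary$distance_max <- max(unlist(lapply(traces, `[[`, "d")))
      list(traces = traces, histogram = hist)
    })
  }

  if (!is.null(config$rmsf)) {
    results$rmsf <- stage("rmsf", {
      sel <- resolve_selection(ensemble, config$rmsf$selection %||% "name CA")
      sup <- superpose(ensemble, sel)
      prof <- rmsf(sup, sel)
      bf <- rmsf_to_bfactor(prof)
      write_bfactor_csv(bf, file.path(out_dir, "theoretical_bfactors.csv"))
      summary$rmsf_mean <- mean(prof$rmsf)
      list(profile = prof, bfactors = bf)
    })
  }

  if (!is.null(config$hbonds)) {
    results$hbonds <- stage("hbonds", {
      hc <- config$hbonds
      crit <- hbond_criterion(d_NO_max = hc$d_NO_max %||% 3.5,
                              angle_min = hc$angle_min %||% 120,
                              use_hydrogens = hc$use_hydrogens %||% FALSE)
      rng <- seq(hc$residue_range[1], hc$residue_range[2])
      occ <- occupancy_map(ensemble, hc$chain, rng, crit)
      def <- call_defects(occ, threshold_absent = hc$threshold_absent %||% 0.30)
      write_occupancy_csv(def, file.path(out_dir, "hbond_defects.csv"))
      summary$n_defects <- sum(def$defect)
      def
    })
  }

  if (!is.null(config$contacts)) {
    results$contacts <- stage("contacts", {
      cc <- contact_count_trace(ensemble, sels[[config$contacts$probe]],
                                sels[[config$contacts$site]],
                                cutoff = config$contacts$cutoff %||% 4.0)
      write.csv(data.frame(frame = cc$frame_index, count = cc$count),
                file.path(out_dir, "contact_counts.csv"), row.names = FALSE)
      summary$max_contacts <- max(cc$count)
      cc
    })
  }

  if (!is.null(config$deer)) {
    results$deer <- stage("deer", {
      dc <- config$deer
      if (isTRUE(dc$synthetic)) {
        args <- dc[setdiff(names(dc), c("synthetic", "alpha"))]
        args$seed <- args$seed %||% seed
        gen <- make_synthetic_deer(do.call(deer_sim_config, args))
        trace <- gen$trace
      } else trace <- read_deer_trace(dc$path)
      grid <- r_grid()
      bc <- background_correct(trace)
      kern <- build_kernel(trace$t, grid)
      alpha <- dc$alpha %||% "auto"
      if (identical(alpha, "auto"))
        alpha <- as.numeric(select_alpha_lcurve(bc$form_factor, grid, kernel = kern))
      fit <- tikhonov_invert(bc$form_factor, grid, alpha, kernel = kern)
      write_pr_tsv(fit, file.path(out_dir, "distance_distribution.tsv"))
      st <- distribution_stats(fit$p_hat)
      summary$deer_mean_nm <- st$mean
      summary$deer_fwhm_nm <- st$fwhm
      fit
    })
  }

  if (!is.null(config$glypro)) {
    results$glypro <- stage("glypro", {
      gc <- config$glypro
      if (isTRUE(gc$synthetic)) {
        args <- gc[setdiff(names(gc), c("synthetic", "region", "spans",
                                        "path", "format"))]
        args$seed <- args$seed %||% seed
        block <- make_sequence_set(do.call(seq_set_config, args))$block
        region <- "full"
      } else {
        spans <- lapply(gc$spans, function(sp) c(sp[1], sp[2]))
        block <- read_alignment(gc$path, gc$format %||% "fasta", spans)
        region <- gc$region %||% names(spans)[1]
      }
      comp <- summarize_composition(block, region)
      write.csv(comp$counts, file.path(out_dir, "glypro_counts.csv"),
                row.names = FALSE)
      summary$mean_gly <- comp$marginals$mean_gly
      summary$mean_pro <- comp$marginals$mean_pro
      comp
    })
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, summary = summary))
}

lapply_named <- function(x, f) {
  out <- lapply(names(x), function(nm) f(x[[nm]], nm))
  names(out) <- names(x)
  out
}

# stable fingerprint of a config: canonical JSON, then a polynomial
# rolling hash kept below 2^48 (a provenance tag, not cryptographic)
digest_config <- function(config) {
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(js))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2^48
  sprintf("%014.0f", h)
}
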