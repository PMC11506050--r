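#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: the synthetic-cohort
#' spec (or an ingest directory), preprocessing constants (8 Hz analysis
#' rate; surface-Laplacian m = 4, lambda = 1e-5, Legendre order 50), surrogate
#' counts, significance levels, the demographic filter toggle, and the master
#' seed from which every random stream derives.
#'
#' @param cohort named list of [cohort_spec()] arguments.
#' @param input optional list(`dir`, `participants`) to ingest EDF/BDF files
#'   instead of simulating (see [read_cohort()]).
#' @param fs_out,transition,apply_csd,csd_m,csd_lambda,csd_nmax preprocessing
#'   parameters, see [preprocess_recording()].
#' @param psi_n_surrogates surrogates per channel for PSI significance (0
#'   skips per-channel p-values).
#' @param psi_alpha per-channel PSI significance level.
#' @param coupling_n_surrogates,coupling_alpha mPD-PSI coupling permutation
#'   test parameters.
#' @param stats_alpha channel-wise group-comparison level.
#' @param filter_age_sex apply the demographic participant filter before the
#'   group PSI comparison.
#' @param max_female_age filter threshold in years.
#' @param gradient_alpha diffusion-embedding normalization exponent.
#' @param gradient_null_perm permutations for the shuffled-control R-squared.
#' @param seed master integer seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = list(), input = NULL,
                            fs_out = 8, transition = 0.005, apply_csd = TRUE,
                            csd_m = 4, csd_lambda = 1e-5, csd_nmax = 50,
                            psi_n_surrogates = 10000, psi_alpha = 0.05,
                            coupling_n_surrogates = 10000, coupling_alpha = 0.001,
                            stats_alpha = 0.05, filter_age_sex = TRUE,
                            max_female_age = 38,
                            gradient_alpha = 0.5, gradient_null_perm = 100,
                            seed = 1) {
  structure(list(
    cohort = cohort, input = input,
    fs_out = fs_out, transition = transition, apply_csd = apply_csd,
    csd_m = csd_m, csd_lambda = csd_lambda, csd_nmax = csd_nmax,
    psi_n_surrogates = psi_n_surrogates, psi_alpha = psi_alpha,
    coupling_n_surrogates = coupling_n_surrogates,
    coupling_alpha = coupling_alpha,
    stats_alpha = stats_alpha, filter_age_sex = filter_age_sex,
    max_female_age = max_female_age,
    gradient_alpha = gradient_alpha, gradient_null_perm = gradient_null_perm,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Save / load a pipeline configuration (YAML)
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `save_config` returns `path` invisibly; `load_config` the config.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$input <- raw$input %||% NULL
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  fnv1a_hex(paste(deparse(unclass(config)), collapse = ""))
}

# Write a CSV carrying the config hash and band edges as a comment header.
write_isa_csv <- function(df, path, hash, bands, band_width) {
  edges <- paste(sprintf("%g-%g", bands, bands + band_width), collapse = ";")
  writeLines(sprintf("# isasync config=%s bands_hz=%s", hash, edges), path)
  suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                      append = TRUE, quote = FALSE))
  invisible(path)
}

#' Ingest a directory of EDF/BDF recordings
#'
#' Expects a participants table (CSV: id, group, sex, age, session, file,
#' montage) whose `file`/`montage` columns are paths relative to `dir`.
#'
#' @param dir data directory.
#' @param participants_file table name inside `dir`.
#' @return list of `isa_recording`s with the roster attached as attribute
#'   `participants`.
#' @export
read_cohort <- function(dir, participants_file = "participants.csv") {
  tab <- utils::read.csv(file.path(dir, participants_file),
                         stringsAsFactors = FALSE)
  need <- c("id", "group", "sex", "age", "session", "file", "montage")
  if (!all(need %in% names(tab)))
    isa_stop("isa_metadata", "participants table needs columns: %s",
             paste(need, collapse = ", "))
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    r <- read_recording(file.path(dir, tab$file[i]),
                        file.path(dir, tab$montage[i]))
    r$participant <- list(id = tab$id[i], index = match(tab$id[i], unique(tab$id)),
                          group = tab$group[i], sex = tab$sex[i],
                          age = tab$age[i])
    r$session <- tab$session[i]
    r
  })
  roster <- unique(tab[, c("id", "group", "sex", "age")])
  roster$index <- match(roster$id, unique(tab$id))
  attr(recs, "participants") <- roster
  recs
}

#' Run the full arousal-ISA synchronization pipeline
#'
#' Executes simulate (or ingest), preprocess, PSI summary, mPD-PSI coupling,
#' principal-gradient topography, and group statistics; writes tidy CSV/JSON
#' outputs plus a manifest to `out_dir`. Re-running with an identical config
#' reproduces every numeric output bit-for-bit.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `summaries`, `band_comparison` (and
#'   `band_comparison_filtered` when the demographic filter is on),
#'   `channelwise`, `coupling`, `gmpd`, `gradients`, `regressions`,
#'   `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  log_path <- file.path(out_dir, "log.txt")
  cat(sprintf("isasync pipeline, config %s\n", hash), file = log_path)
  stages <- list()
  tic <- function() proc.time()[["elapsed"]]
  log_stage <- function(name, t0, info = "") {
    stages[[length(stages) + 1]] <<- list(stage = name,
                                          seconds = round(tic() - t0, 2))
    cat(sprintf("[%s] done in %.2fs %s\n", name, tic() - t0, info),
        file = log_path, append = TRUE)
  }

  # -- simulate / ingest -------------------------------------------------
  t0 <- tic()
  ingest <- !is.null(config$input)
  if (ingest) {
    recs <- read_cohort(config$input$dir,
                        config$input$participants %||% "participants.csv")
    participants <- attr(recs, "participants")
    bands <- config$cohort$bands %||% seq(0.01, 0.10, by = 0.01)
    band_width <- config$cohort$band_width %||% 0.01
    by_part <- split(seq_along(recs),
                     vapply(recs, function(r) r$participant$id, ""))
  } else {
    spec <- do.call(cohort_spec, config$cohort)
    participants <- make_participants(spec)
    bands <- spec$bands
    band_width <- spec$band_width
  }
  log_stage("simulate", t0, sprintf("(%d participants)", nrow(participants)))

  # -- preprocess (streamed per participant/session) ---------------------
  t0 <- tic()
  cohort_phases <- list()
  conn <- list()  # conn[[group]][[band]] running sum of connectivity
  for (i in seq_len(nrow(participants))) {
    p <- participants[i, ]
    sessions <- if (ingest) {
      lapply(recs[by_part[[p$id]]], function(r) {
        preprocess_recording(r, bands, band_width, config$fs_out,
                             config$transition, config$apply_csd,
                             config$csd_m, config$csd_lambda, config$csd_nmax,
                             keep_filtered = TRUE)
      })
    } else {
      lapply(seq_len(spec$n_sessions), function(s) {
        rec <- generate_recording(spec, p, s)$recording
        preprocess_recording(rec, bands, band_width, config$fs_out,
                             config$transition, config$apply_csd,
                             config$csd_m, config$csd_lambda, config$csd_nmax,
                             keep_filtered = TRUE)
      })
    }
    filt <- lapply(seq_along(bands), function(b) {
      do.call(cbind, lapply(sessions, function(pt)
        pt$filtered_eeg[, pt$valid[, b], b, drop = TRUE]))
    })
    for (b in seq_along(bands)) {
      fc <- functional_connectivity(filt[[b]])
      key <- paste(p$group, b)
      conn[[key]] <- if (is.null(conn[[key]])) fc else conn[[key]] + fc
    }
    for (s in seq_along(sessions)) sessions[[s]]$filtered_eeg <- NULL
    cohort_phases[[i]] <- list(participant = p,
                               phases = collect_valid_phases(sessions))
  }
  n_per_group <- table(participants$group)
  log_stage("preprocess", t0)

  # -- psi ---------------------------------------------------------------
  t0 <- tic()
  summaries <- summarize_cohort(cohort_phases, bands,
                                n_surrogates = config$psi_n_surrogates,
                                alpha = config$psi_alpha,
                                seed = derive_seed(config$seed, "psi"))
  write_isa_csv(summaries, file.path(out_dir, "summaries.csv"),
                hash, bands, band_width)
  log_stage("psi", t0, sprintf("(%d rows)", nrow(summaries)))

  # -- coupling ----------------------------------------------------------
  t0 <- tic()
  coupling <- list()
  for (grp in names(n_per_group)) {
    for (b in seq_along(bands)) {
      sub <- summaries[summaries$group == grp & summaries$band == bands[b], ]
      cs <- coupling_significance(sub$mpd, sub$psi,
                                  n_surrogates = config$coupling_n_surrogates,
                                  alpha = config$coupling_alpha,
                                  seed = derive_seed(config$seed, "coupling",
                                                     grp, b))
      coupling[[paste(grp, bands[b], sep = "_")]] <-
        list(group = grp, band = bands[b], kl = cs$kl, p_value = cs$p_value,
             is_significant = cs$is_significant,
             is_significant_05 = cs$is_significant_05,
             surrogate_quantiles = as.list(cs$surrogate_quantiles))
    }
  }
  jsonlite::write_json(coupling, file.path(out_dir, "coupling.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("coupling", t0)

  # -- gradient ----------------------------------------------------------
  t0 <- tic()
  gradients <- list()
  regressions <- list()
  gmpd_tables <- list()
  for (grp in names(n_per_group)) {
    for (b in seq_along(bands)) {
      key <- paste(grp, bands[b], sep = "_")
      w <- conn[[paste(grp, b)]] / n_per_group[[grp]]
      grad <- principal_gradient(w, alpha = config$gradient_alpha)
      gm <- gmpd_map(summaries[summaries$group == grp &
                                 summaries$band == bands[b], ])
      # report sign: orient the gradient to correlate positively with |gmPD|
      sgn <- sign(stats::cor(gm$abs_gmpd, grad$gradient,
                             use = "complete.obs"))
      if (!is.na(sgn) && sgn < 0) grad$gradient <- -grad$gradient
      reg <- regress_gmpd_on_gradient(gm$abs_gmpd, grad$gradient)
      reg$shuffled_r2_mean <- shuffled_gradient_r2(
        gm$abs_gmpd, grad$gradient, n_perm = config$gradient_null_perm,
        seed = derive_seed(config$seed, "shuffle", grp, b))
      gradients[[key]] <- grad
      regressions[[key]] <- c(list(group = grp, band = bands[b]), reg)
      gm$gradient <- grad$gradient
      gm$group <- grp
      gmpd_tables[[key]] <- gm
    }
  }
  gmpd_all <- do.call(rbind, gmpd_tables)
  write_isa_csv(gmpd_all, file.path(out_dir, "gmpd_gradient.csv"),
                hash, bands, band_width)
  jsonlite::write_json(unname(regressions),
                       file.path(out_dir, "regression.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("gradient", t0)

  # -- stats -------------------------------------------------------------
  t0 <- tic()
  bc <- band_comparison(summaries)
  write_isa_csv(bc, file.path(out_dir, "band_comparison.csv"),
                hash, bands, band_width)
  bc_filt <- NULL
  if (isTRUE(config$filter_age_sex)) {
    kept <- participant_filter(participants, config$max_female_age)
    # the filtered contrast needs at least two participants per group
    if (all(table(factor(kept$group, levels = unique(participants$group))) >= 2)) {
      bc_filt <- band_comparison(summaries[summaries$participant %in% kept$id, ])
      write_isa_csv(bc_filt, file.path(out_dir, "band_comparison_filtered.csv"),
                    hash, bands, band_width)
    } else {
      cat("[stats] demographic filter left a group with < 2 participants; filtered comparison skipped\n",
          file = log_path, append = TRUE)
    }
  }
  cw <- do.call(rbind, lapply(bands, function(b) {
    res <- channelwise_comparison(summaries, b, alpha = config$stats_alpha)
    cbind(band = b, res$table)
  }))
  write_isa_csv(cw, file.path(out_dir, "channelwise.csv"),
                hash, bands, band_width)
  frac_sig <- vapply(bands, function(b)
    mean(cw$significant[cw$band == b]), numeric(1))
  summary_json <- list(
    n_bands = length(bands),
    pooled_rows_per_group_band = as.list(table(summaries$group) / length(bands)),
    frac_channels_expert_gt_novice = as.list(stats::setNames(frac_sig,
                                                             paste0("band_", bands))),
    psi_significant_fraction = if ("significant" %in% names(summaries))
      mean(summaries$significant) else NA
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage("stats", t0)

  manifest <- list(
    package = "isasync",
    version = as.character(utils::packageVersion("isasync")),
    config_hash = hash, seed = config$seed,
    stages = stages, bands = bands,
    n_participants = nrow(participants)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  save_config(config, file.path(out_dir, "config.yaml"))

  invisible(list(summaries = summaries, band_comparison = bc,
                 band_comparison_filtered = bc_filt, channelwise = cw,
                 coupling = coupling, gmpd = gmpd_all, gradients = gradients,
                 regressions = regressions, participants = participants,
                 manifest = manifest))
}

#' Topographic scatter plot of per-channel values
#'
#' Simple head-map: channels at their (x, y) montage positions, colored by
#' value (blue = low, red = high).
#'
#' @param montage montage data.frame.
#' @param values per-channel numeric values.
#' @param main plot title.
#' @return invisibly, the color vector used.
#' @export
plot_topography <- function(montage, values, main = "") {
  rng <- range(values, na.rm = TRUE)
  u <- if (diff(rng) > 0) (values - rng[1]) / diff(rng) else rep(0.5, length(values))
  cols <- grDevices::rgb(u, 0.2, 1 - u)
  graphics::plot(montage$x, montage$y, pch = 19, cex = 2, col = cols,
                 asp = 1, xlab = "left-right", ylab = "posterior-anterior",
                 main = main)
  invisible(cols)
}
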