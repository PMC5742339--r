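#' Pipeline run configuration
#'
#' Collects every stage parameter of an end-to-end run in one validated
#' object. Unknown names are rejected so that typos cannot silently fall
#' back to defaults. The fully resolved configuration is written next to
#' the outputs of every run.
#'
#' @param synthetic A [synthetic_spec()] describing the dataset to
#'   generate, or `NULL` when `input_dir` points at ingested data.
#' @param input_dir Directory of TSVs (layout of [write_dataset()]) to
#'   ingest instead of simulating.
#' @param tr_seconds Sampling interval for ingested data.
#' @param n_trim Lead volumes to drop.
#' @param band_low_hz,band_high_hz Band-pass edges.
#' @param fd_radius_mm Head-sphere radius for framewise displacement.
#' @param max_trans_mm,max_rot_deg Motion-exclusion thresholds.
#' @param global_signal Add the mean WM+CSF time course to the confound
#'   set (global-signal variant).
#' @param fdr_q,fdr_method,fdr_family FDR level, `"BY"`/`"BH"`, and
#'   `"per_measure"`/`"pooled"` family for the gFC screen.
#' @param fixed_set_alpha Selection level for the fixed positive set.
#' @param seed_parcel Seed parcel ID or index for the fixed-set and
#'   edge follow-up stages (`NULL` = first detected parcel, falling back
#'   to the synthetic spec's seed node).
#' @param whole_brain_edges Run the whole-brain edge screen (quadratic
#'   in parcel count).
#' @param out_dir Output directory for persisted intermediates (`NULL` =
#'   keep everything in memory only).
#' @return An object of class `gfc_run_config`.
#' @export
run_config <- function(synthetic = synthetic_spec(),
                       input_dir = NULL,
                       tr_seconds = 3,
                       n_trim = 6L,
                       band_low_hz = 0.01,
                       band_high_hz = 0.08,
                       fd_radius_mm = 50,
                       max_trans_mm = 2,
                       max_rot_deg = 2,
                       global_signal = FALSE,
                       fdr_q = 0.05,
                       fdr_method = c("BY", "BH"),
                       fdr_family = c("per_measure", "pooled"),
                       fixed_set_alpha = 0.05,
                       seed_parcel = NULL,
                       whole_brain_edges = TRUE,
                       out_dir = NULL) {
  cfg <- list(
    synthetic = synthetic, input_dir = input_dir, tr_seconds = tr_seconds,
    n_trim = as.integer(n_trim), band_low_hz = band_low_hz,
    band_high_hz = band_high_hz, fd_radius_mm = fd_radius_mm,
    max_trans_mm = max_trans_mm, max_rot_deg = max_rot_deg,
    global_signal = isTRUE(global_signal), fdr_q = fdr_q,
    fdr_method = match.arg(fdr_method), fdr_family = match.arg(fdr_family),
    fixed_set_alpha = fixed_set_alpha, seed_parcel = seed_parcel,
    whole_brain_edges = isTRUE(whole_brain_edges), out_dir = out_dir
  )
  if (is.null(cfg$synthetic) && is.null(cfg$input_dir)) {
    stop("either a synthetic spec or an input_dir is required")
  }
  structure(cfg, class = "gfc_run_config")
}

#' Load a run configuration from JSON or YAML
#'
#' Unknown keys are an error. The `synthetic` block, when present, is
#' passed through [synthetic_spec()].
#'
#' @param path `.json` or `.yaml`/`.yml` file.
#' @return A `gfc_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_spec, raw$synthetic)
  }
  do.call(run_config, raw)
}

ingest_dataset <- function(dir, tr_seconds) {
  files <- list.files(dir, pattern = "_rest1_ts\\.tsv$")
  if (!length(files)) stop(sprintf("no '*_rest1_ts.tsv' files found in %s", dir))
  subjects <- sub("_rest1_ts\\.tsv$", "", files)
  load_sess <- function(subj, sess) {
    ts <- read_tsv_matrix(file.path(dir, sprintf("%s_%s_ts.tsv", subj, sess)))
    motion <- read_motion_tsv(file.path(dir, sprintf("%s_%s_motion.tsv", subj, sess)))
    nui <- read_tsv_matrix(file.path(dir, sprintf("%s_%s_nuisance.tsv", subj, sess)))
    list(ts = ts, motion = motion, wm = nui[, "wm"], csf = nui[, "csf"])
  }
  subs <- lapply(subjects, function(s) list(rest1 = load_sess(s, "rest1"),
                                            rest2 = load_sess(s, "rest2")))
  names(subs) <- subjects
  list(subjects = subs, tr_seconds = tr_seconds)
}

clean_session <- function(sess, cfg, tr_seconds) {
  ts <- parcel_timeseries(sess$ts, tr_seconds = tr_seconds)
  ts <- trim_volumes(ts, cfg$n_trim)
  ts <- bandpass_filter(ts, cfg$band_low_hz, cfg$band_high_hz)
  conf <- cbind(sess$motion, wm = sess$wm, csf = sess$csf)
  if (cfg$global_signal) conf <- cbind(conf, global = rowMeans(cbind(sess$wm, sess$csf)))
  conf <- trim_volumes(conf, cfg$n_trim)
  conf <- bandpass_filter(conf, cfg$band_low_hz, cfg$band_high_hz,
                          tr_seconds = tr_seconds)
  # an ideally filtered confound is exactly zero-mean, but the filtered
  # design keeps an explicit intercept in regress_nuisance
  regress_nuisance(ts, conf, global_signal = cfg$global_signal)
}

#' Run the full connectivity-change pipeline
#'
#' Executes simulate-or-ingest, motion QC, signal cleaning,
#' connectivity, the gFC change screen, the fixed-positive-set
#' validation, the seed-restricted (and optionally whole-brain) edge
#' screens, and assembles a run report. Deterministic given the
#' synthetic spec's seed.
#'
#' @param cfg A [run_config()].
#' @return Object of class `gfc_run_report`: QC table, screen results,
#'   detected parcels, fixed set, restricted-delta test, edge tables,
#'   counts at every filter, and the resolved configuration.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "gfc_run_config"))
  if (!is.null(cfg$input_dir)) {
    data <- ingest_dataset(cfg$input_dir, cfg$tr_seconds)
    truth <- NULL
    tr <- data$tr_seconds
  } else {
    ds <- generate_dataset(cfg$synthetic)
    data <- list(subjects = ds$subjects)
    truth <- ds$truth
    tr <- cfg$synthetic$tr_seconds
  }
  subjects <- names(data$subjects)

  qc <- do.call(rbind, lapply(subjects, function(subj) {
    do.call(rbind, lapply(c("rest1", "rest2"), function(sess) {
      rec <- motion_exclusion(data$subjects[[subj]][[sess]]$motion,
                              cfg$max_trans_mm, cfg$max_rot_deg,
                              cfg$fd_radius_mm)
      cbind(data.frame(subject = subj, session = sess), rec)
    }))
  }))
  excluded_subjects <- unique(qc$subject[qc$excluded])
  keep <- setdiff(subjects, excluded_subjects)
  if (!length(keep)) stop("no subjects remain after motion QC")

  conn <- lapply(keep, function(subj) {
    lapply(stats::setNames(c("rest1", "rest2"), c("rest1", "rest2")), function(sess) {
      cleaned <- clean_session(data$subjects[[subj]][[sess]], cfg, tr)
      fisher_z(correlation_matrix(cleaned), subject = subj, session = sess)
    })
  })
  names(conn) <- keep
  stack <- conn_stack(conn)

  deltas <- stack_delta_gfc(stack)
  screen <- gfc_change_screen(deltas, q = cfg$fdr_q, method = cfg$fdr_method,
                              family = cfg$fdr_family)

  seed <- cfg$seed_parcel
  if (is.null(seed)) {
    seed <- if (nrow(screen$detected)) screen$detected$parcel[1]
            else if (!is.null(cfg$synthetic)) cfg$synthetic$seed_node
            else stack$parcel_ids[1]
  }
  fixed <- fixed_positive_set(stack, seed, alpha = cfg$fixed_set_alpha)
  restricted <- if (length(fixed$members)) {
    restricted_delta_gfc(stack, seed, fixed$members)
  } else NULL
  seed_edges <- edge_change_test(stack, "seed_restricted", seed = seed,
                                 q = cfg$fdr_q, method = cfg$fdr_method)
  wb_edges <- if (cfg$whole_brain_edges) {
    edge_change_test(stack, "whole_brain", q = cfg$fdr_q, method = cfg$fdr_method)
  } else NULL
  increased <- count_increased_edges(stack, seed)

  report <- structure(list(
    qc = qc,
    n_subjects_in = length(subjects),
    excluded_subjects = excluded_subjects,
    n_subjects_used = length(keep),
    screen = screen$results,
    detected = screen$detected,
    seed = stack$parcel_ids[seed_index(stack, seed)],
    fixed_set = fixed,
    restricted = restricted,
    seed_edges = seed_edges,
    wb_edges = wb_edges,
    n_increased_seed_edges = increased$n_increased,
    counts = list(
      parcels = length(stack$parcel_ids),
      gfc_tests = nrow(screen$results),
      seed_edge_tests = nrow(seed_edges),
      wb_edge_tests = if (is.null(wb_edges)) 0L else nrow(wb_edges)
    ),
    truth = truth,
    config = cfg
  ), class = "gfc_run_report")

  if (!is.null(cfg$out_dir)) persist_report(report, cfg$out_dir)
  report
}

persist_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_tsv(report$qc, file.path(dir, "qc.tsv"))
  write_table_tsv(report$screen, file.path(dir, "gfc_screen.tsv"))
  write_table_tsv(report$seed_edges, file.path(dir, "seed_edges.tsv"))
  if (!is.null(report$wb_edges)) {
    write_table_tsv(report$wb_edges, file.path(dir, "whole_brain_edges.tsv"))
  }
  jsonlite::write_json(
    list(seed = report$seed, members = report$fixed_set$members,
         alpha = report$fixed_set$alpha),
    file.path(dir, "fixed_set.json"), auto_unbox = TRUE, digits = NA)
  cfg <- report$config
  cfg$synthetic <- if (!is.null(cfg$synthetic)) unclass(cfg$synthetic)
  jsonlite::write_json(unclass(cfg), file.path(dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  summary_lines <- c(
    sprintf("subjects: %d in, %d used, %d excluded by motion QC",
            report$n_subjects_in, report$n_subjects_used,
            length(report$excluded_subjects)),
    sprintf("detected parcel-measure pairs: %d", nrow(report$detected)),
    sprintf("fixed set size: %d", length(report$fixed_set$members)),
    sprintf("significant seed edges: %d", sum(report$seed_edges$significant)),
    sprintf("seed edges increased: %d of %d", report$n_increased_seed_edges,
            nrow(report$seed_edges))
  )
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.gfc_run_report <- function(x, ...) {
  cat(sprintf("<gfc_run_report> %d/%d subjects used, %d parcels\n",
              x$n_subjects_used, x$n_subjects_in, x$counts$parcels))
  cat(sprintf("  detected parcel-measure pairs: %d\n", nrow(x$detected)))
  if (nrow(x$detected)) {
    cat(sprintf("    %s (%s): mean delta %.3f, t(%d) = %.2f, q = %.4g\n",
                x$detected$parcel, x$detected$measure, x$detected$mean,
                x$detected$df, x$detected$t, x$detected$q_adj))
  }
  cat(sprintf("  seed %s: fixed set %d members; significant seed edges %d; increased %d/%d\n",
              x$seed, length(x$fixed_set$members),
              sum(x$seed_edges$significant), x$n_increased_seed_edges,
              nrow(x$seed_edges)))
  invisible(x)
}
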