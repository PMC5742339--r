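#' Replicated detection-rate study for the gFC change screen
#'
#' Repeatedly generates a two-session dataset (no nuisance contamination,
#' so the time series feed the connectivity stage directly), runs the
#' per-parcel gFC change screen, and records whether the planted seed
#' node was detected on the positive-sum measure and whether any
#' parcel-measure family produced a rejection at all. With `delta_z = 0`
#' and `subject_sd_z = 0` this measures the family-level false-positive
#' rate of the screen; with a planted effect it measures power.
#'
#' @param nrep Number of replicate datasets.
#' @param base_seed First RNG seed; replicate `r` uses `base_seed + r - 1`.
#' @param n_subjects,n_parcels,n_timepoints Design size per replicate.
#' @param effect_mode,effect_targets,delta_z,subject_sd_z Planted effect,
#'   as in [synthetic_spec()].
#' @param q,method FDR level and procedure for the screen.
#' @return Data frame, one row per replicate: `replicate`,
#'   `seed_detected_pos` (seed significant on the gFC+ delta),
#'   `any_rejection` (any rejection in any measure family).
#' @export
simulate_screen_power <- function(nrep, base_seed,
                                  n_subjects = 44, n_parcels = 100,
                                  n_timepoints = 114,
                                  effect_mode = "diffuse",
                                  effect_targets = 0.3,
                                  delta_z = 0.05, subject_sd_z = 0.05,
                                  q = 0.05, method = "BY") {
  rows <- lapply(seq_len(nrep), function(r) {
    spec <- synthetic_spec(
      n_subjects = n_subjects, n_parcels = n_parcels,
      n_timepoints = n_timepoints, n_lead_volumes = 0,
      effect_mode = effect_mode, effect_targets = effect_targets,
      delta_z = delta_z, subject_sd_z = subject_sd_z,
      nuisance_amplitude = 0, rng_seed = base_seed + r - 1)
    st <- dataset_connectivity(generate_dataset(spec))
    det <- gfc_change_screen(stack_delta_gfc(st), q = q, method = method)$detected
    seed_id <- st$parcel_ids[spec$seed_node]
    data.frame(replicate = r,
               seed_detected_pos = any(det$parcel == seed_id &
                                         det$measure == "gfc_pos"),
               any_rejection = nrow(det) > 0)
  })
  do.call(rbind, rows)
}

#' Replicated detection-rate study for the per-connection screens
#'
#' For each replicate, plants a single focal seed-target edge shift and
#' runs both the seed-restricted and the whole-brain edge change screens
#' on the same data, recording whether each detects the planted edge.
#' Quantifies the power gain of restricting the correction family to the
#' seed's connections.
#'
#' @inheritParams simulate_screen_power
#' @param target Index of the planted target parcel.
#' @return Data frame per replicate: `detected_seed_scope`,
#'   `detected_whole_brain`.
#' @export
simulate_edge_power <- function(nrep, base_seed,
                                n_subjects = 44, n_parcels = 100,
                                n_timepoints = 114, target = 26L,
                                delta_z = 0.17, subject_sd_z = 0.22,
                                q = 0.05, method = "BY") {
  rows <- lapply(seq_len(nrep), function(r) {
    spec <- synthetic_spec(
      n_subjects = n_subjects, n_parcels = n_parcels,
      n_timepoints = n_timepoints, n_lead_volumes = 0,
      effect_mode = "focal", effect_targets = as.integer(target),
      delta_z = delta_z, subject_sd_z = subject_sd_z,
      nuisance_amplitude = 0, rng_seed = base_seed + r - 1)
    st <- dataset_connectivity(generate_dataset(spec))
    ids <- st$parcel_ids
    edge_hit <- function(tab) {
      any(tab$significant & tab$i == ids[spec$seed_node] & tab$j == ids[target])
    }
    seed_tab <- edge_change_test(st, "seed_restricted", seed = spec$seed_node,
                                 q = q, method = method)
    wb_tab <- edge_change_test(st, "whole_brain", q = q, method = method)
    data.frame(replicate = r,
               detected_seed_scope = edge_hit(seed_tab),
               detected_whole_brain = edge_hit(wb_tab))
  })
  do.call(rbind, rows)
}
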