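#' Run the full titration pipeline on a (synthetic) dataset
#'
#' Convenience driver chaining every stage: data generation (unless a
#' dataset is supplied), droplet QC and hashtag demultiplexing, CLR
#' normalization, major-type gating, per-antibody thresholding and
#' detectability calling, and panel optimization. Each intermediate result
#' is returned so downstream metrics can be computed without re-running
#' earlier stages.
#'
#' @param config A [generator_config()] (used when `dataset` is NULL).
#' @param seed Integer seed driving both data generation and the mixture
#'   fits.
#' @param dataset Optional pre-built [titration_dataset()]; `truth` is then
#'   NULL.
#' @param qc A [qc_params()].
#' @param thr A [threshold_params()].
#' @param q_frac Quality fraction for panel optimization.
#' @return A list: `dataset`, `truth`, `annotations`, `qc_report`, `clr`,
#'   `gate_thresholds`, `calls`, `binary`, `plan`.
#' @export
run_titration_pipeline <- function(config = default_config(), seed,
                                   dataset = NULL, qc = qc_params(),
                                   thr = threshold_params(), q_frac = 0.8) {
  truth <- NULL
  if (is.null(dataset)) {
    gen <- generate_dataset(config, seed)
    dataset <- gen$dataset
    truth <- gen$truth
  }
  qc_res <- run_qc(dataset, qc)
  clr <- clr_normalize(dataset$adt_counts)
  gates <- derive_gate_thresholds(clr, qc_res$annotations, dataset$panel,
                                  seed = seed)
  annotations <- gate_all(clr, qc_res$annotations, gates, dataset$panel)
  calls <- threshold_antibodies(clr, annotations, dataset$panel, thr,
                                seed = seed)
  binary <- binarize(clr, calls, annotations)
  plan <- build_optimized_panel(calls, dataset$panel, dataset$arms, q_frac)
  list(dataset = dataset, truth = truth, annotations = annotations,
       qc_report = qc_res$report, clr = clr, gate_thresholds = gates,
       calls = calls, binary = binary, plan = plan)
}

#' Detectable antibodies per concentration arm
#'
#' @param calls A `detect_calls` table.
#' @param panel A [panel_definition()]; isotype controls are excluded from
#'   the tally.
#' @return Named integer vector, arm label -> number of detectable
#'   target antibodies.
#' @export
detectable_counts <- function(calls, panel) {
  targets <- panel$antibody_id[!panel$is_isotype_control]
  sub <- calls[calls$antibody_id %in% targets, ]
  tapply(sub$detectable, sub$arm_label, sum)
}
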