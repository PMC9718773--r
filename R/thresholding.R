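#' Linear-interpolation percentile
#'
#' The frozen percentile convention used throughout thresholding: sort the
#' values and interpolate linearly at position `q/100 * (n - 1)` (the
#' classical type-7 definition).
#'
#' @param values Non-empty numeric vector.
#' @param q Percentile in `[0, 100]`.
#' @return The interpolated percentile.
#' @examples
#' percentile(0:19, 95)          # 18.05
#' percentile(c(10, 20, 30, 40, 50), 5)  # 12
#' @export
percentile <- function(values, q) {
  if (length(values) == 0L) stop("percentile of empty input", call. = FALSE)
  if (q < 0 || q > 100) stop("q must lie in [0, 100]", call. = FALSE)
  stats::quantile(values, probs = q / 100, names = FALSE, type = 7)
}

#' Detectability-calling parameters
#'
#' @param s_min Minimum Ashman's D separation for a clear
#'   negative/positive split (default 2, the classical bimodality cut).
#' @param f_min Minimum positive-population fraction (default 0.005, so
#'   antigens confined to rare types such as classical monocytes remain
#'   callable).
#' @param u_min Minimum fraction of cells above the isotype background for
#'   the ubiquitous-antigen rule (default 0.9).
#' @param min_above_background Minimum margin (CLR units) by which the
#'   positive-component mean must exceed the isotype background for the
#'   clear-split rule (default 0.4, about 1.5-fold above the background
#'   ceiling). This keeps splits *within* the discrete low-count background
#'   — whose upper half sits at the isotype ceiling itself — from passing as
#'   positive populations.
#' @param min_cells Minimum cells required for a population fit (default 50).
#' @return A `threshold_params` list.
#' @export
threshold_params <- function(s_min = 2, f_min = 0.005, u_min = 0.9,
                             min_above_background = 0.4, min_cells = 50L) {
  structure(list(s_min = s_min, f_min = f_min, u_min = u_min,
                 min_above_background = min_above_background,
                 min_cells = min_cells), class = "threshold_params")
}

#' Call detectability for one antibody in one arm
#'
#' Automates the ridge-plot judgment. If at least `u_min` of cells exceed
#' the isotype background, the antigen is ubiquitous — no negative
#' population exists, whatever internal structure the mixture found — and
#' the threshold is the 5th percentile of all values (mode `positive5`).
#' Otherwise, if the mixture fit shows a clearly separated positive
#' population (Ashman's D at or above `s_min`, positive fraction at or above
#' `f_min`, and a positive-component mean above the isotype background — so
#' a mere split within the discrete low-count background does not qualify),
#' the antibody is detectable and the threshold is the 95th percentile of
#' the negative-component values (mode `negative95`). Otherwise the antigen
#' is not detectable at this concentration (mode `none`, no threshold).
#'
#' @param fit A `mixture_fit` from [fit_population_model()].
#' @param isotype_background 95th percentile of the pooled isotype-control
#'   CLR values in the same arm.
#' @param params A [threshold_params()].
#' @return A one-row data.frame: `detectable`, `mode`, `threshold`,
#'   `separation`, `positive_fraction`.
#' @export
call_detectability <- function(fit, isotype_background,
                               params = threshold_params()) {
  stopifnot(inherits(fit, "mixture_fit"))
  sep <- fit$separation
  if (mean(fit$values > isotype_background) >= params$u_min) {
    return(data.frame(detectable = TRUE, mode = "positive5",
                      threshold = percentile(fit$values, 5),
                      separation = sep,
                      positive_fraction = fit$positive_fraction))
  }
  if (sep >= params$s_min && fit$positive_fraction >= params$f_min &&
      fit$means[2L] > isotype_background + params$min_above_background) {
    neg <- fit$values[fit$assignment == 1L]
    return(data.frame(detectable = TRUE, mode = "negative95",
                      threshold = percentile(neg, 95),
                      separation = sep,
                      positive_fraction = fit$positive_fraction))
  }
  data.frame(detectable = FALSE, mode = "none", threshold = NA_real_,
             separation = sep, positive_fraction = fit$positive_fraction)
}

#' Threshold every antibody in every concentration arm
#'
#' Drives [fit_population_model()] and [call_detectability()] over the full
#' panel. Detectability is assessed on all gated major-type cells of each
#' arm (cells labeled "remaining" are excluded from analyses, matching the
#' study design); the isotype background of an arm is the 95th percentile of
#' the pooled isotype-control CLR values over those cells. Isotype controls
#' themselves are also run through the caller (they are expected to come out
#' not detectable).
#'
#' @param clr_adt CLR-normalized ADT matrix (antibodies x droplets).
#' @param annotations Gated annotations (from [gate_all()]).
#' @param panel A [panel_definition()].
#' @param params A [threshold_params()].
#' @param seed Seed forwarded to the mixture fits.
#' @return A `detect_calls` data.frame: one row per antibody x arm with
#'   `antibody_id`, `arm_label`, `detectable`, `mode`, `threshold`,
#'   `separation`, `positive_fraction`.
#' @export
threshold_antibodies <- function(clr_adt, annotations, panel,
                                 params = threshold_params(), seed = 1L) {
  arm_labels <- unique(stats::na.omit(annotations$arm_label))
  iso_ids <- panel$antibody_id[panel$is_isotype_control]
  res <- vector("list", length(arm_labels) * nrow(panel))
  k <- 0L
  for (arm in arm_labels) {
    cells <- which(annotations$qc_pass &
                     !is.na(annotations$arm_label) &
                     annotations$arm_label == arm &
                     !is.na(annotations$major_type) &
                     annotations$major_type != "remaining")
    if (length(cells) < params$min_cells) {
      stop("arm ", arm, " has only ", length(cells),
           " gated major-type cells; too few for thresholding", call. = FALSE)
    }
    iso_bg <- percentile(as.vector(clr_adt[iso_ids, cells, drop = FALSE]), 95)
    for (i in seq_len(nrow(panel))) {
      fit <- fit_population_model(clr_adt[panel$antibody_id[i], cells],
                                  seed = seed, min_n = params$min_cells)
      call <- call_detectability(fit, iso_bg, params)
      k <- k + 1L
      res[[k]] <- cbind(data.frame(antibody_id = panel$antibody_id[i],
                                   arm_label = arm,
                                   stringsAsFactors = FALSE),
                        call)
    }
  }
  out <- do.call(rbind, res)
  class(out) <- c("detect_calls", "data.frame")
  out
}

#' Apply manual threshold overrides
#'
#' Replaces automated thresholds or verdicts for listed (antibody, arm)
#' pairs, marking them as manual — the escape hatch for cases where the
#' percentile rule does not trace the population limits accurately.
#'
#' @param calls A `detect_calls` table.
#' @param override_table Data.frame with columns `antibody_id`, `arm_label`,
#'   `threshold` and optionally `detectable`.
#' @return The updated `detect_calls` table (overridden rows have mode
#'   `"manual"`).
#' @export
apply_manual_overrides <- function(calls, override_table) {
  if (is.null(override_table) || nrow(override_table) == 0L) return(calls)
  key <- paste(calls$antibody_id, calls$arm_label)
  okey <- paste(override_table$antibody_id, override_table$arm_label)
  hit <- match(okey, key)
  if (anyNA(hit)) {
    stop("override references unknown (antibody, arm) pair(s): ",
         paste(okey[is.na(hit)], collapse = "; "), call. = FALSE)
  }
  calls$threshold[hit] <- override_table$threshold
  if ("detectable" %in% names(override_table)) {
    calls$detectable[hit] <- override_table$detectable
  } else {
    calls$detectable[hit] <- TRUE
  }
  calls$mode[hit] <- "manual"
  calls
}

#' Binarize ADT expression by the called thresholds
#'
#' A cell is positive for an antibody iff the antibody is detectable at the
#' cell's arm and the cell's CLR value is strictly above the threshold
#' (thresholds are the upper limits of the negative populations, so ties are
#' negative). Undetectable antibodies contribute all-negative rows for that
#' arm; cells without an arm label are all-negative.
#'
#' @param clr_adt CLR-normalized ADT matrix (antibodies x droplets).
#' @param calls A `detect_calls` table covering every (antibody, arm) pair.
#' @param annotations Annotations aligned with the columns of `clr_adt`.
#' @return Logical matrix, antibodies x droplets.
#' @export
binarize <- function(clr_adt, calls, annotations) {
  out <- matrix(FALSE, nrow(clr_adt), ncol(clr_adt),
                dimnames = dimnames(clr_adt))
  for (arm in unique(stats::na.omit(annotations$arm_label))) {
    cells <- which(!is.na(annotations$arm_label) & annotations$arm_label == arm)
    ca <- calls[calls$arm_label == arm, ]
    thr <- ca$threshold[match(rownames(clr_adt), ca$antibody_id)]
    det <- ca$detectable[match(rownames(clr_adt), ca$antibody_id)]
    if (anyNA(det)) {
      stop("missing detectability call for arm ", arm, ": ",
           paste(rownames(clr_adt)[is.na(det)], collapse = ", "),
           call. = FALSE)
    }
    thr[!det] <- Inf  # undetectable antibodies are never positive
    out[, cells] <- clr_adt[, cells, drop = FALSE] > thr
  }
  out
}
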