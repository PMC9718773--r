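## Antibody-panel optimization: pick each antibody's optimal concentration
## and compare the optimized panel's total antibody amount to alternatives.

OPTIMAL_CLASSES <- c("2x", "1x", "0.2x", "0.04x", "drop")
CLASS_WEIGHTS <- c("2x" = 2, "1x" = 1, "0.2x" = 0.2, "0.04x" = 0.04, "drop" = 0)

#' Select the optimal concentration class for one antibody
#'
#' Optimal is the lowest concentration that still gives sufficient staining
#' quality without loss of information: the lowest-factor arm at which the
#' antibody is detectable and retains at least `q_frac` of its best
#' negative/positive separation across arms. The separation criterion
#' applies only to arms called in `negative95` mode — for a ubiquitous
#' antigen (mode `positive5`) there is no negative population to separate
#' from, so any detectable arm qualifies. An antibody detectable nowhere is
#' dropped; the double concentration is selected only when it is the only
#' detectable arm or when every arm at or below 1x fails the quality
#' criterion.
#'
#' @param calls_ab One antibody's rows of a `detect_calls` table (one row
#'   per arm, all arms present).
#' @param arms A [concentration_arms()] table.
#' @param q_frac Quality fraction: minimum share of the best separation
#'   retained (default 0.8).
#' @return One of `"2x"`, `"1x"`, `"0.2x"`, `"0.04x"`, `"drop"`.
#' @export
select_optimal_concentration <- function(calls_ab, arms, q_frac = 0.8) {
  miss <- setdiff(arms$label, calls_ab$arm_label)
  if (length(miss) > 0L) {
    stop("missing detectability call for arm(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ord <- order(arms$factor)
  lab <- arms$label[ord]
  det <- calls_ab$detectable[match(lab, calls_ab$arm_label)]
  sep <- calls_ab$separation[match(lab, calls_ab$arm_label)]
  mode <- calls_ab$mode[match(lab, calls_ab$arm_label)]
  if (!any(det)) return("drop")
  split_arm <- det & mode == "negative95"
  ref <- if (any(split_arm)) max(sep[split_arm]) else 0
  for (i in seq_along(lab)) {
    if (det[i] && (mode[i] != "negative95" || sep[i] >= q_frac * ref)) {
      return(lab[i])
    }
  }
  lab[which(det)[sum(det)]]  # unreachable in practice: the best arm qualifies
}

#' Relative antibody amount of a panel plan
#'
#' The cost proxy for a panel: the sum over antibodies of their
#' concentration-class weight (2, 1, 0.2, 0.04, or 0 for dropped
#' antibodies), divided by the panel size. Full precision is returned;
#' rounding happens only at report time.
#'
#' @param class_counts Named integer vector over the concentration classes.
#' @param n_total Panel size; must equal the sum of the counts.
#' @param weights Class weights (defaults to the concentration factors).
#' @return The relative amount (1 = every antibody at the recommended
#'   concentration).
#' @examples
#' relative_amount(c("2x" = 7, "1x" = 80, "0.2x" = 33, "0.04x" = 8,
#'                   drop = 64), 192)  # 0.525625, reported as 0.53
#' @export
relative_amount <- function(class_counts, n_total, weights = CLASS_WEIGHTS) {
  unknown <- setdiff(names(class_counts), names(weights))
  if (length(unknown) > 0L) {
    stop("unknown concentration class(es): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (sum(class_counts) != n_total) {
    stop("class counts sum to ", sum(class_counts), ", expected n_total = ",
         n_total, call. = FALSE)
  }
  sum(class_counts * weights[names(class_counts)]) / n_total
}

#' Percent reduction between two panel amounts
#'
#' `100 * (1 - plan_a / plan_b)`: how much less antibody plan A needs than
#' plan B. Full precision; round to integer percent at report time.
#'
#' @param plan_a_amount,plan_b_amount Relative amounts, both positive.
#' @return Percent difference.
#' @export
compare_panels <- function(plan_a_amount, plan_b_amount) {
  if (plan_b_amount == 0) stop("comparison panel has zero amount", call. = FALSE)
  100 * (1 - plan_a_amount / plan_b_amount)
}

#' Build the optimized panel plan
#'
#' Applies [select_optimal_concentration()] to every target-detecting
#' antibody; isotype controls are always retained at the recommended
#' concentration (they are needed as the background yardstick and are not
#' titrated). Computes the plan's class counts, retained panel size and
#' relative antibody amount.
#'
#' @param calls A `detect_calls` table covering all antibodies and arms.
#' @param panel A [panel_definition()].
#' @param arms A [concentration_arms()] table.
#' @param q_frac Quality fraction forwarded to the per-antibody rule.
#' @return A `panel_plan` list: `plan` (antibody_id, is_isotype_control,
#'   optimal_class), `class_counts`, `n_retained`, `relative_amount`.
#' @export
build_optimized_panel <- function(calls, panel, arms, q_frac = 0.8) {
  ids <- panel$antibody_id
  missing <- setdiff(ids, unique(calls$antibody_id))
  if (length(missing) > 0L) {
    stop("detectability calls missing for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  optimal <- vapply(seq_along(ids), function(i) {
    if (panel$is_isotype_control[i]) return("1x")
    select_optimal_concentration(calls[calls$antibody_id == ids[i], ],
                                 arms, q_frac)
  }, "")
  plan <- data.frame(antibody_id = ids,
                     is_isotype_control = panel$is_isotype_control,
                     optimal_class = optimal, stringsAsFactors = FALSE)
  class_counts <- table(factor(optimal, levels = OPTIMAL_CLASSES))
  out <- list(plan = plan,
              class_counts = stats::setNames(as.integer(class_counts),
                                             names(class_counts)),
              n_retained = sum(optimal != "drop"),
              relative_amount = relative_amount(as.integer(class_counts) |>
                                                  stats::setNames(names(class_counts)),
                                                nrow(panel)))
  class(out) <- "panel_plan"
  out
}

#' @export
print.panel_plan <- function(x, ...) {
  cat(sprintf("Optimized panel: %d of %d antibodies retained\n",
              x$n_retained, sum(x$class_counts)))
  cat("  classes:", paste(sprintf("%s=%d", names(x$class_counts),
                                  x$class_counts), collapse = ", "), "\n")
  cat(sprintf("  relative antibody amount: %.2f (%.0f%% less than the full panel at 1x)\n",
              x$relative_amount, compare_panels(x$relative_amount, 1)))
  invisible(x)
}
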