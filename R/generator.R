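## Synthetic-data generator: droplet-level multi-concentration CITE-Seq data
## with known ground truth, emulating a hashed four-arm antibody titration of
## human PBMCs (192plex panel: 188 antibodies + 4 isotype controls, arms at
## 2x/1x/0.2x/0.04x of the recommended concentration, ~2000 cells per arm).

MAJOR_TYPES <- c("B", "CD4T", "CD8T", "CM", "NK", "remaining")
GATING_MARKERS <- c("CD3", "CD19", "CD4", "CD8", "CD14", "CD16", "CD56")
TIER_LEVELS <- c("detectable_at_0.04x", "detectable_at_0.2x",
                 "detectable_at_1x", "needs_2x", "undetectable", "isotype")

#' Default antibody panel plan for the synthetic generator
#'
#' One row per antibody of the 192plex panel, carrying the generator ground
#' truth: the optimal-concentration tier (8 antibodies best at 0.04x, 33 at
#' 0.2x, 76 at 1x, 7 needing 2x, 64 undetectable, 4 isotype controls), the
#' detection floor (the lowest arm at which the antibody is detectable:
#' 64 antibodies down to 0.04x, 52 more down to 0.2x, 8 more only at >= 1x,
#' cumulatively 64/116/124/124 across the four arms), the dose-response
#' half-saturation constant `K` (in concentration-factor units, `K =
#' floor/1.2` so the signal collapses just below the floor arm) with Hill
#' exponent `h = 5`, the expression category, and the set of expressing
#' major cell types. The seven gating markers (CD3, CD19, CD4, CD8, CD14,
#' CD16, CD56) are included with their canonical PBMC expression patterns;
#' three antibodies are ubiquitous (expressed in every cell, exercising the
#' lower-limit thresholding path).
#'
#' @return A data.frame with columns `antibody_id`, `target_name`,
#'   `is_isotype_control`, `tier`, `tier_factor`, `floor_factor`, `K`, `h`,
#'   `category`, and list-column `expressing_types`.
#' @export
default_panel_plan <- function() {
  # tier x floor combinations; K encodes the detection floor, while quality
  # loss below the tier arm comes from sub-saturation staining heterogeneity
  # (see generate_dataset)
  profiles <- data.frame(
    code  = c("A", "B", "C", "D", "E", "F", "G"),
    tier  = c("detectable_at_0.04x", "detectable_at_0.2x", "detectable_at_0.2x",
              "detectable_at_1x", "detectable_at_1x", "detectable_at_1x",
              "needs_2x"),
    floor = c(0.04, 0.04, 0.2, 0.04, 0.2, 1, 1),
    stringsAsFactors = FALSE
  )
  profiles$K <- profiles$floor / 1.2
  profiles$h <- 5
  expr_of <- function(category, multi_idx = 0L) {
    switch(category,
      ubiquitous   = MAJOR_TYPES,
      all_five     = c("B", "CD4T", "CD8T", "CM", "NK"),
      exclusive_B  = "B",
      exclusive_CM = "CM",
      exclusive_NK = "NK",
      multi        = MULTI_SUBSETS[[(multi_idx - 1L) %% length(MULTI_SUBSETS) + 1L]],
      stop("unknown category: ", category))
  }
  rows <- list()
  add <- function(id, target, code, category, expr) {
    rows[[length(rows) + 1L]] <<- list(id = id, target = target, code = code,
                                       category = category, expr = expr)
  }
  # gating markers with canonical PBMC expression, plus fixed named antibodies
  add("CD3",  "CD3",  "A", "multi",           c("CD4T", "CD8T"))
  add("CD19", "CD19", "A", "exclusive_B",     "B")
  add("CD8",  "CD8",  "A", "exclusive_other", "CD8T")
  add("CD16", "CD16", "A", "exclusive_NK",    "NK")
  add("UBQ1", "CD45-like-1", "A", "all_five", MAJOR_TYPES)
  add("UBQ2", "CD45-like-2", "A", "all_five", MAJOR_TYPES)
  add("UBQ3", "CD45-like-3", "A", "all_five", MAJOR_TYPES)
  add("ABB01", "B-antigen-01", "A", "exclusive_B", "B")
  add("CD4",  "CD4",  "B", "exclusive_other", "CD4T")
  add("CD56", "CD56", "B", "exclusive_NK",    "NK")
  add("CD14", "CD14", "D", "exclusive_CM",    "CM")
  for (i in 1:13) {
    add(sprintf("AF%02d", i), sprintf("pan-antigen-%02d", i), "C",
        "all_five", c("B", "CD4T", "CD8T", "CM", "NK"))
  }
  # remaining 100 detectable antibodies: spread categories across profiles
  slot_codes <- c(rep("B", 11), rep("C", 7), rep("D", 42), rep("E", 32),
                  "F", rep("G", 7))
  cats <- c(rep("exclusive_B", 19), rep("exclusive_CM", 16),
            rep("exclusive_NK", 3), rep("multi", 62))
  # fixed modular shuffle (stride 37, coprime with 100) so each profile gets
  # a mixture of categories; deterministic by construction
  pos <- ((seq_along(cats) - 1L) * 37L) %% length(cats) + 1L
  mixed <- character(length(cats))
  mixed[pos] <- cats
  multi_count <- 1L  # CD3 took the first multi subset
  for (i in seq_along(slot_codes)) {
    cat_i <- mixed[i]
    if (cat_i == "multi") {
      multi_count <- multi_count + 1L
      expr <- expr_of("multi", multi_count)
    } else {
      expr <- expr_of(cat_i)
    }
    add(sprintf("AB%03d", i), sprintf("antigen-%03d", i), slot_codes[i],
        cat_i, expr)
  }
  for (i in 1:64) {
    add(sprintf("NEG%02d", i), sprintf("absent-antigen-%02d", i), "U",
        "undetectable", character(0))
  }
  for (i in 1:4) {
    add(sprintf("ISO%d", i), sprintf("isotype-control-%d", i), "I",
        "isotype", character(0))
  }
  code <- vapply(rows, `[[`, "", "code")
  pidx <- match(code, profiles$code)
  tier <- ifelse(code == "U", "undetectable",
                 ifelse(code == "I", "isotype", profiles$tier[pidx]))
  tier_factor <- c(detectable_at_0.04x = 0.04, detectable_at_0.2x = 0.2,
                   detectable_at_1x = 1, needs_2x = 2)[tier]
  plan <- data.frame(
    antibody_id = vapply(rows, `[[`, "", "id"),
    target_name = vapply(rows, `[[`, "", "target"),
    is_isotype_control = code == "I",
    tier = tier,
    tier_factor = unname(tier_factor),    # NA for undetectable/isotype
    floor_factor = profiles$floor[pidx],  # NA for undetectable/isotype
    K = profiles$K[pidx],
    h = profiles$h[pidx],
    category = vapply(rows, `[[`, "", "category"),
    stringsAsFactors = FALSE
  )
  plan$expressing_types <- I(lapply(rows, `[[`, "expr"))
  stopifnot(!anyDuplicated(plan$antibody_id), nrow(plan) == 192L)
  plan
}

# Expression subsets used for multi-type antibodies (cycled
# deterministically). None covers more than ~75% of gated cells, so a
# multi-type antigen is never mistaken for a ubiquitous one.
MULTI_SUBSETS <- list(
  c("CD4T", "CD8T"), c("B", "CD8T"), c("CM", "NK"), c("B", "CM"),
  c("CD8T", "NK"), c("B", "CD4T"), c("B", "NK"), c("CD4T", "CM")
)

#' Construct a synthetic-generator configuration
#'
#' All knobs of the droplet-level generator. The defaults are the study
#' conditions of the titration experiment the generator emulates: four arms
#' (2x/1x/0.2x/0.04x), 2000 cells per arm, the printed PBMC composition
#' (B 4.9%, CD4 T 52.1%, CD8 T 12.1%, CM 2.6%, NK 14.1%, remaining 14.2%),
#' and a 192plex panel whose tier counts are 8/33/76/7 detectable-optimal
#' antibodies plus 64 undetectable and 4 isotype controls.
#'
#' @param n_cells_per_arm Droplets per concentration arm (default 2000).
#' @param composition Named fractions over the six major-type labels,
#'   summing to 1.
#' @param arms A [concentration_arms()] table.
#' @param panel_plan Antibody plan as from [default_panel_plan()].
#' @param signal_max Mean ADT signal at antibody saturation (counts).
#' @param background_rate Ambient ADT mean per antibody at 1x; scales
#'   linearly with the concentration factor (free-antibody encapsulation).
#' @param nb_dispersion Negative-binomial size parameter for ADT/RNA counts.
#' @param hto_signal_mean,hto_offtarget_mean Own-hashtag signal and ambient
#'   (off-target, per-droplet) hashtag means.
#' @param hto_negative_mean All-hashtag mean for HTO-negative droplets.
#' @param hto_nb_size,hto_ambient_size NB size parameters for hashtag signal
#'   and ambient counts.
#' @param hto_negative_fraction Fraction of droplets with failed hashing.
#' @param subsat_range Length-2 range of the per-cell staining-efficiency
#'   multiplier applied below an antibody's optimal (tier) arm: at
#'   sub-saturating concentration, staining becomes heterogeneous across
#'   cells, which widens the positive population and degrades separation
#'   without necessarily losing detectability.
#' @param doublet_fraction Fraction of droplets containing two cells
#'   (same-arm pairs: hashing happens per staining tube before pooling).
#' @param cross_arm_doublets If TRUE, doublet partners are drawn from a
#'   different arm (stress-test only; not the default chemistry).
#' @param mito_beta_params List with `viable` and `low_viability` Beta
#'   shape pairs for the mitochondrial fraction.
#' @param low_viability_fraction Fraction of dying (high-mito) cells.
#' @param markers_per_type Exclusive high-mean marker genes per major type.
#' @param n_housekeeping,n_mito_genes Housekeeping and mitochondrial gene
#'   counts.
#' @param marker_mean,marker_off_mean,housekeeping_mean RNA NB means for
#'   marker genes (own type / other types) and housekeeping genes.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_cells_per_arm = 2000,
                             composition = c(B = 0.049, CD4T = 0.521,
                                             CD8T = 0.121, CM = 0.026,
                                             NK = 0.141, remaining = 0.142),
                             arms = default_arms(),
                             panel_plan = default_panel_plan(),
                             signal_max = 500,
                             background_rate = 8,
                             nb_dispersion = 6,
                             hto_signal_mean = 500,
                             hto_offtarget_mean = 90,
                             hto_negative_mean = 4,
                             hto_nb_size = 200,
                             hto_ambient_size = 30,
                             hto_negative_fraction = 0.02,
                             subsat_range = c(0.02, 0.5),
                             doublet_fraction = 0.05,
                             cross_arm_doublets = FALSE,
                             mito_beta_params = list(viable = c(3, 80),
                                                     low_viability = c(8, 32)),
                             low_viability_fraction = 0.03,
                             markers_per_type = 10,
                             n_housekeeping = 50,
                             n_mito_genes = 10,
                             marker_mean = 30,
                             marker_off_mean = 0.05,
                             housekeeping_mean = 4) {
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("composition must sum to 1", call. = FALSE)
  }
  if (any(composition < 0 | composition > 1)) {
    stop("composition fractions must lie in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(composition), MAJOR_TYPES)) {
    stop("composition must be named with: ", paste(MAJOR_TYPES, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(inherits(arms, "concentration_arms"),
            n_cells_per_arm >= 1,
            signal_max > 0, background_rate >= 0, nb_dispersion > 0,
            all(is.na(panel_plan$K) | panel_plan$K > 0),
            doublet_fraction >= 0, doublet_fraction < 1,
            hto_negative_fraction >= 0, hto_negative_fraction < 1,
            low_viability_fraction >= 0, low_viability_fraction < 1)
  bad_tier <- setdiff(unique(panel_plan$tier), TIER_LEVELS)
  if (length(bad_tier) > 0L) {
    stop("unknown tier(s) in panel plan: ", paste(bad_tier, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    n_cells_per_arm = n_cells_per_arm,
    composition = composition[MAJOR_TYPES],
    arms = arms,
    panel_plan = panel_plan,
    signal_max = signal_max,
    background_rate = background_rate,
    nb_dispersion = nb_dispersion,
    hto_signal_mean = hto_signal_mean,
    hto_offtarget_mean = hto_offtarget_mean,
    hto_negative_mean = hto_negative_mean,
    hto_nb_size = hto_nb_size,
    hto_ambient_size = hto_ambient_size,
    hto_negative_fraction = hto_negative_fraction,
    subsat_range = subsat_range,
    doublet_fraction = doublet_fraction,
    cross_arm_doublets = cross_arm_doublets,
    mito_beta_params = mito_beta_params,
    low_viability_fraction = low_viability_fraction,
    markers_per_type = markers_per_type,
    n_housekeeping = n_housekeeping,
    n_mito_genes = n_mito_genes,
    marker_mean = marker_mean,
    marker_off_mean = marker_off_mean,
    housekeeping_mean = housekeeping_mean
  ), class = "generator_config")
}

#' Default generator configuration (the emulated study conditions)
#'
#' @return A [generator_config()] with all defaults: tier counts
#'   `{needs_2x: 7, detectable_at_1x: 76, detectable_at_0.2x: 33,
#'   detectable_at_0.04x: 8, undetectable: 64, isotype: 4}` and the printed
#'   1x cell-type proportions.
#' @export
default_config <- function() generator_config()

#' Antibody tier labels of a generator configuration
#' @param config A `generator_config`.
#' @return Named character vector, antibody id -> tier.
#' @export
antibody_tiers <- function(config) {
  stats::setNames(config$panel_plan$tier, config$panel_plan$antibody_id)
}

#' Ground-truth detectability table
#'
#' Expands the generator's per-antibody detection floors into an
#' antibody x arm logical table: an antibody is detectable at an arm iff the
#' arm's concentration factor is at or above the antibody's floor.
#' Undetectable antibodies and isotype controls are detectable nowhere. With
#' the default plan the per-arm totals are 124 (2x), 124 (1x), 116 (0.2x)
#' and 64 (0.04x).
#'
#' @param config A [generator_config()].
#' @return Logical matrix, antibodies x arms (dimnames set).
#' @export
truth_detectability <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  plan <- config$panel_plan
  out <- outer(plan$floor_factor, config$arms$factor,
               function(f, c) !is.na(f) & c >= f)
  dimnames(out) <- list(plan$antibody_id, config$arms$label)
  out
}

# Dose-response mean signal (counts) for each antibody at factor c:
# generalized saturation-binding curve S_max * c^h / (c^h + K^h).
signal_at <- function(config, c_factor) {
  plan <- config$panel_plan
  sig <- ifelse(is.na(plan$K), 0,
                config$signal_max * c_factor^plan$h /
                  (c_factor^plan$h + plan$K^plan$h))
  stats::setNames(sig, plan$antibody_id)
}

#' Generate a synthetic titration dataset with ground truth
#'
#' Draws, for each concentration arm, cell types from the configured
#' composition; ADT counts as negative binomial with mean = linear ambient
#' background plus a saturation-binding signal for antibodies expressed in
#' the cell's type; hashtag counts high on the cell's own hashtag with a
#' per-droplet ambient floor on the others; doublets as same-arm cell pairs
#' with summed ADT/RNA and doubled own-hashtag signal; HTO-negative droplets
#' with all hashtags near zero; and RNA counts giving each major type a set
#' of exclusive marker genes, with the mitochondrial fraction drawn from a
#' viable or low-viability Beta component.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; required (the generator never uses implicit
#'   global RNG state).
#' @return A list with `dataset` (a [titration_dataset()]) and `truth` (list
#'   with per-droplet data.frame `droplets`, per-antibody data.frame
#'   `antibodies`, and logical `detectability` matrix).
#' @export
generate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  if (missing(seed) || is.null(seed)) {
    stop("generate_dataset requires an explicit seed", call. = FALSE)
  }
  set.seed(as.integer(seed))
  plan <- config$panel_plan
  arms <- config$arms
  n_ab <- nrow(plan)
  n_hash <- nrow(arms)
  types <- MAJOR_TYPES
  comp <- config$composition

  # antibody x type expression indicator
  E <- matrix(FALSE, n_ab, length(types), dimnames = list(plan$antibody_id, types))
  for (i in seq_len(n_ab)) E[i, plan$expressing_types[[i]]] <- TRUE

  # gene registry
  mito_ids <- sprintf("MT-%02d", seq_len(config$n_mito_genes))
  marker_ids <- as.vector(t(outer(types, seq_len(config$markers_per_type),
                                  function(t, i) sprintf("MRK-%s-%02d", t, i))))
  hk_ids <- sprintf("HK-%02d", seq_len(config$n_housekeeping))
  gene_ids <- c(mito_ids, marker_ids, hk_ids)
  n_nonmito <- length(marker_ids) + length(hk_ids)
  # non-mito RNA mean per type (genes x types)
  rna_mu_type <- matrix(config$marker_off_mean, n_nonmito, length(types),
                        dimnames = list(c(marker_ids, hk_ids), types))
  for (t in types) {
    rna_mu_type[sprintf("MRK-%s-%02d", t, seq_len(config$markers_per_type)), t] <-
      config$marker_mean
  }
  rna_mu_type[hk_ids, ] <- config$housekeeping_mean

  adt_list <- list(); rna_list <- list(); hto_list <- list(); truth_list <- list()
  for (a in seq_len(nrow(arms))) {
    cf <- arms$factor[a]
    n <- config$n_cells_per_arm
    n_doub <- round(config$doublet_fraction * n)
    n_cells <- n + n_doub  # each doublet droplet holds one extra partner cell
    cell_type <- sample(types, n_cells, replace = TRUE, prob = comp)
    low_via <- stats::runif(n_cells) < config$low_viability_fraction

    # ADT: background + saturation signal for expressed antibodies; below an
    # antibody's optimal (tier) arm, staining is sub-saturating and
    # heterogeneous: per-cell efficiency drawn uniformly from subsat_range
    mu_sig <- signal_at(config, cf) * E[, cell_type, drop = FALSE]
    subsat <- !is.na(plan$tier_factor) & cf < plan$tier_factor
    if (any(subsat)) {
      # log-uniform efficiency: partial staining spreads expressing cells
      # evenly across the (log) intensity range between background and full
      # signal, the hallmark of a sub-saturating antibody concentration
      eff <- matrix(exp(stats::runif(sum(subsat) * n_cells,
                                     log(config$subsat_range[1]),
                                     log(config$subsat_range[2]))),
                    sum(subsat), n_cells)
      mu_sig[subsat, ] <- mu_sig[subsat, , drop = FALSE] * eff
    }
    mu_adt <- config$background_rate * cf + mu_sig
    adt_cells <- matrix(stats::rnbinom(n_ab * n_cells, size = config$nb_dispersion,
                                       mu = as.vector(mu_adt)),
                        n_ab, n_cells)

    # RNA: non-mito counts, then mitochondrial counts targeting a Beta fraction
    mu_rna <- rna_mu_type[, cell_type, drop = FALSE]
    rna_nm <- matrix(stats::rnbinom(n_nonmito * n_cells, size = config$nb_dispersion,
                                    mu = as.vector(mu_rna)),
                     n_nonmito, n_cells)
    bp <- config$mito_beta_params
    mito_frac <- ifelse(low_via,
                        stats::rbeta(n_cells, bp$low_viability[1], bp$low_viability[2]),
                        stats::rbeta(n_cells, bp$viable[1], bp$viable[2]))
    nm_tot <- colSums(rna_nm)
    mito_tot <- round(nm_tot * mito_frac / (1 - mito_frac))
    rna_mito <- vapply(seq_len(n_cells), function(i) {
      if (mito_tot[i] == 0) return(integer(config$n_mito_genes))
      as.integer(stats::rmultinom(1, mito_tot[i],
                                  rep(1, config$n_mito_genes)))
    }, integer(config$n_mito_genes))

    # collapse cells into droplets: droplets 1..n, doublet droplets get the
    # partner cell (index n + k) summed in
    doub_pos <- if (n_doub > 0) sample.int(n, n_doub) else integer(0)
    adt <- adt_cells[, seq_len(n), drop = FALSE]
    rna <- rbind(rna_mito, rna_nm)[, seq_len(n), drop = FALSE]
    if (n_doub > 0) {
      partner <- seq.int(n + 1L, n_cells)
      adt[, doub_pos] <- adt[, doub_pos] + adt_cells[, partner, drop = FALSE]
      rna[, doub_pos] <- rna[, doub_pos] +
        rbind(rna_mito, rna_nm)[, partner, drop = FALSE]
    }
    is_doublet <- seq_len(n) %in% doub_pos
    n_neg <- round(config$hto_negative_fraction * n)
    neg_pos <- if (n_neg > 0) sample(setdiff(seq_len(n), doub_pos), n_neg) else integer(0)
    is_negative <- seq_len(n) %in% neg_pos

    # HTO: per-droplet ambient on every hashtag plus own-hashtag signal
    # (doubled for same-arm doublets; ambient is a droplet property and is
    # not doubled, which is what makes the max/mean rule separate doublets)
    hto <- matrix(stats::rnbinom(n_hash * n, size = config$hto_ambient_size,
                                 mu = config$hto_offtarget_mean),
                  n_hash, n)
    own_mu <- rep(config$hto_signal_mean, n)
    own_mu[is_doublet] <- 2 * config$hto_signal_mean
    hto[a, ] <- hto[a, ] + stats::rnbinom(n, size = config$hto_nb_size, mu = own_mu)
    if (n_neg > 0) {
      hto[, neg_pos] <- matrix(stats::rnbinom(n_hash * n_neg,
                                              size = config$hto_ambient_size,
                                              mu = config$hto_negative_mean),
                               n_hash, n_neg)
    }
    if (config$cross_arm_doublets && n_doub > 0) {
      # stress-test variant: the partner cell carries another arm's hashtag
      other <- ((a + seq_len(n_doub) - 1L) %% nrow(arms)) + 1L
      for (k in seq_len(n_doub)) {
        hto[other[k], doub_pos[k]] <- hto[other[k], doub_pos[k]] +
          stats::rnbinom(1, size = config$hto_nb_size, mu = config$hto_signal_mean)
        hto[a, doub_pos[k]] <- hto[a, doub_pos[k]] -
          round(stats::rnbinom(1, size = config$hto_nb_size,
                               mu = config$hto_signal_mean) / 2)
      }
      hto[hto < 0] <- 0
    }

    adt_list[[a]] <- adt; rna_list[[a]] <- rna; hto_list[[a]] <- hto
    truth_list[[a]] <- data.frame(
      true_arm = arms$label[a],
      true_type = cell_type[seq_len(n)],
      is_doublet = is_doublet,
      is_hto_negative = is_negative,
      is_low_viability = low_via[seq_len(n)],
      stringsAsFactors = FALSE
    )
  }

  truth_droplets <- do.call(rbind, truth_list)
  barcodes <- sprintf("BC%06d", seq_len(nrow(truth_droplets)))
  truth_droplets <- cbind(barcode = barcodes, truth_droplets,
                          stringsAsFactors = FALSE)
  panel <- panel_definition(plan$antibody_id, plan$target_name,
                            plan$is_isotype_control)
  dataset <- titration_dataset(
    rna_counts = do.call(cbind, rna_list),
    adt_counts = do.call(cbind, adt_list),
    hto_counts = do.call(cbind, hto_list),
    gene_ids = gene_ids,
    mito_gene_ids = mito_ids,
    barcodes = barcodes,
    panel = panel,
    arms = arms
  )
  truth_antibodies <- data.frame(
    antibody_id = plan$antibody_id,
    tier = plan$tier,
    floor_factor = plan$floor_factor,
    category = plan$category,
    expressing_types = vapply(plan$expressing_types, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  list(dataset = dataset,
       truth = list(droplets = truth_droplets,
                    antibodies = truth_antibodies,
                    detectability = truth_detectability(config)))
}
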