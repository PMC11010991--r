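#' Configuration for the synthetic TMA cohort generator
#'
#' Builds the configuration object consumed by [simulate_spot()] and
#' [simulate_cohort()]. The generator emulates a tissue-microarray (TMA)
#' cohort of the kind produced by multiplexed immunofluorescence imaging:
#' one circular tissue spot per patient, thousands of segmented cells per
#' spot, eight phenotypes, and spatially contiguous regions whose cell-type
#' mixtures follow planted neighborhood archetypes. Patient survival is
#' linked to the per-patient frequency of a designated risk archetype.
#'
#' Defaults mirror a 64-patient TMA with 1.5 mm spots and six planted
#' neighborhood archetypes (see [default_archetypes()]).
#'
#' @param n_patients Number of patients (one spot each). Default 64.
#' @param spot_diameter Spot diameter in micrometres. Default 1500.
#' @param cells_per_spot Either a single count or a length-2 range from which
#'   the per-spot cell count is drawn uniformly. Default `c(1500, 3000)`.
#' @param archetypes Numeric matrix, one row per planted neighborhood
#'   archetype, columns in [cell_type_vocabulary()] order; each row is a
#'   composition on the simplex (sums to 1 within 1e-9).
#' @param region_layout `"voronoi_seeds"` (contiguous mosaic from random seed
#'   points, the default) or `"radial_bands"` (concentric equal-area annuli).
#' @param n_region_seeds_per_cn Seed points scattered per archetype under the
#'   `voronoi_seeds` layout. Default 1 (one contiguous domain per archetype
#'   per spot, matching the large architecture scale seen in tissue).
#' @param emission Marker emission model: a list with `meanlog_positive`,
#'   `sdlog_positive`, `meanlog_negative`, `sdlog_negative` giving log-normal
#'   parameters for the positive and negative intensity channels. Lineage
#'   markers of a cell's type (plus DAPI, always) draw from the positive
#'   channel; all other markers draw from the negative channel.
#' @param risk_cn Row name of the archetype whose per-patient frequency
#'   drives the hazard. Default `"Lymphoid"`.
#' @param survival_baseline Baseline exponential hazard per month. Default
#'   0.03 (median survival near two years at zero risk frequency).
#' @param survival_beta Log-hazard coefficient on the risk-archetype
#'   frequency. Default 3.
#' @param censoring_rate Fraction of patients subject to random early
#'   censoring, in `[0, 1)`. All patients are additionally censored
#'   administratively at `max_followup`. Default 0.2.
#' @param max_followup Maximum follow-up in months. Default 60.
#' @param seed Master integer seed; all randomness in the generator flows
#'   from it through per-stage derived streams.
#'
#' @return A `synth_config` list, validated.
#' @seealso [simulate_cohort()], [default_archetypes()]
#' @export
synth_config <- function(n_patients = 64,
                         spot_diameter = 1500,
                         cells_per_spot = c(1500, 3000),
                         archetypes = default_archetypes(),
                         region_layout = c("voronoi_seeds", "radial_bands"),
                         n_region_seeds_per_cn = 1,
                         emission = default_marker_emission(),
                         risk_cn = "Lymphoid",
                         survival_baseline = 0.03,
                         survival_beta = 3,
                         censoring_rate = 0.2,
                         max_followup = 60,
                         seed = 1L) {
  cfg <- list(
    n_patients = n_patients,
    spot_diameter = spot_diameter,
    cells_per_spot = cells_per_spot,
    archetypes = archetypes,
    region_layout = match.arg(region_layout),
    n_region_seeds_per_cn = n_region_seeds_per_cn,
    emission = emission,
    risk_cn = risk_cn,
    survival_baseline = survival_baseline,
    survival_beta = survival_beta,
    censoring_rate = censoring_rate,
    max_followup = max_followup,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

#' Default planted neighborhood archetypes
#'
#' Six composition archetypes representing recurring tumor-microenvironment
#' architectures: a near-pure stromal barrier, bulk tumor, a lymphocyte-rich
#' domain (the default risk archetype, dominated by CD4 and CD8 T cells), a
#' perivascular domain, a macrophage niche, and a reactive stroma that mixes
#' stromal cells with immune infiltrate. Rows sum to 1; columns follow
#' [cell_type_vocabulary()].
#'
#' @return A 6 x 8 numeric matrix with archetype row names.
#' @export
default_archetypes <- function() {
  vocab <- cell_type_vocabulary()
  a <- rbind(
    # Tumor Endo  CD8   CD4   OthT  Mac   B     Stroma
    Stroma_barrier   = c(0.02, 0.02, 0.01, 0.02, 0.01, 0.02, 0.00, 0.90),
    Bulk_tumor       = c(0.85, 0.02, 0.01, 0.01, 0.00, 0.03, 0.00, 0.08),
    Lymphoid         = c(0.01, 0.02, 0.32, 0.42, 0.10, 0.03, 0.05, 0.05),
    Perivascular     = c(0.05, 0.70, 0.02, 0.04, 0.02, 0.07, 0.00, 0.10),
    Macrophage_niche = c(0.08, 0.04, 0.05, 0.05, 0.03, 0.65, 0.00, 0.10),
    Reactive_stroma  = c(0.03, 0.03, 0.05, 0.06, 0.24, 0.13, 0.26, 0.20)
  )
  colnames(a) <- vocab
  a
}

#' @rdname synth_config
#' @export
default_marker_emission <- function() {
  list(
    meanlog_positive = log(60), sdlog_positive = 0.3,
    meanlog_negative = log(5),  sdlog_negative = 0.3
  )
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_patients < 1) abort("`n_patients` must be a positive count.")
  if (cfg$spot_diameter <= 0) abort("`spot_diameter` must be > 0.")
  cps <- cfg$cells_per_spot
  if (!length(cps) %in% c(1, 2) || any(cps < 1)) {
    abort("`cells_per_spot` must be a positive count or range.")
  }
  if (length(cps) == 2 && cps[2] < cps[1]) {
    abort("`cells_per_spot` range must be non-decreasing.")
  }
  a <- cfg$archetypes
  if (!is.matrix(a) || ncol(a) != length(cell_type_vocabulary()) ||
      !identical(colnames(a), cell_type_vocabulary())) {
    abort("`archetypes` must have one column per type in cell_type_vocabulary() order.")
  }
  if (any(a < 0) || any(abs(rowSums(a) - 1) > 1e-9)) {
    abort("each archetype row must be a composition summing to 1 (within 1e-9).")
  }
  if (is.null(rownames(a))) rownames(a) <- paste0("CN", seq_len(nrow(a)))
  if (!cfg$risk_cn %in% rownames(a)) {
    abort(sprintf("`risk_cn` (%s) is not a row of `archetypes`.", cfg$risk_cn))
  }
  if (cfg$n_region_seeds_per_cn < 1) abort("`n_region_seeds_per_cn` must be >= 1.")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1) {
    abort("`censoring_rate` must be in [0, 1).")
  }
  if (cfg$survival_baseline <= 0 || cfg$max_followup <= 0) {
    abort("`survival_baseline` and `max_followup` must be > 0.")
  }
  cfg$archetypes <- a
  cfg
}

# Scatter region seed points and return, per cell, the planted archetype of
# its nearest seed. Retries when a seed captures no cell.
plant_regions <- function(x, y, cfg, radius, centre) {
  n_cn <- nrow(cfg$archetypes)
  if (cfg$region_layout == "radial_bands") {
    # equal-area annuli, innermost band = archetype 1
    r2 <- (x - centre)^2 + (y - centre)^2
    band <- pmin(floor(r2 / (radius^2 / n_cn)) + 1, n_cn)
    return(list(region_id = band, region_cn = band))
  }
  n_seeds <- n_cn * cfg$n_region_seeds_per_cn
  seed_cn <- rep(seq_len(n_cn), times = cfg$n_region_seeds_per_cn)
  for (try in seq_len(25)) {
    sp <- runif_disk(n_seeds, radius, centre)
    d2 <- outer(x, sp$x, `-`)^2 + outer(y, sp$y, `-`)^2
    nearest <- max.col(-d2, ties.method = "first")
    if (all(tabulate(nearest, n_seeds) > 0)) {
      return(list(region_id = nearest, region_cn = seed_cn[nearest]))
    }
  }
  abort("could not place region seeds so that every region contains a cell; lower `n_region_seeds_per_cn` or raise `cells_per_spot`.")
}

# uniform points in a disk of given radius centred at (centre, centre)
runif_disk <- function(n, radius, centre) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  list(x = centre + r * cos(th), y = centre + r * sin(th))
}

#' Simulate one tissue spot
#'
#' Generates the segmented-cell table for a single circular spot: uniform
#' cell centroids within the disk, a contiguous planted-region mosaic, cell
#' types drawn i.i.d. from each region's archetype composition, and marker
#' intensities drawn from the two-channel log-normal emission model (lineage
#' markers and DAPI from the positive channel, everything else negative).
#'
#' @param config A [synth_config()].
#' @param patient_id Patient identifier (integer or string).
#' @param seed Integer seed for this spot; defaults to a stream derived from
#'   `config$seed` and the patient id.
#' @return A tibble with one row per cell: `cell_id`, `patient_id`,
#'   `spot_id`, `x_um`, `y_um`, eight `<marker>_intensity` columns, and
#'   ground-truth columns `region_id`, `true_cn`, `true_cell_type`.
#' @export
simulate_spot <- function(config, patient_id, seed = NULL) {
  config <- validate_synth_config(config)
  pid <- as.character(patient_id)
  if (is.null(seed)) seed <- derive_seed(config$seed, paste0("spot:", pid))
  radius <- config$spot_diameter / 2
  centre <- radius # origin at the spot's bounding-box corner

  with_seed(seed, {
    cps <- config$cells_per_spot
    n <- if (length(cps) == 2) {
      sample(seq(cps[1], cps[2]), 1)
    } else {
      as.integer(cps)
    }
    pos <- runif_disk(n, radius, centre)
    reg <- plant_regions(pos$x, pos$y, config, radius, centre)
    cn_names <- rownames(config$archetypes)
    type_idx <- vapply(reg$region_cn, function(k) {
      sample.int(ncol(config$archetypes), 1, prob = config$archetypes[k, ])
    }, integer(1))
    types <- cell_type_vocabulary()[type_idx]

    em <- config$emission
    markers <- marker_panel()
    defs <- defining_markers()
    inten <- matrix(rlnorm(n * length(markers),
                           em$meanlog_negative, em$sdlog_negative),
                    nrow = n, dimnames = list(NULL, marker_columns()))
    pos_draw <- matrix(rlnorm(n * length(markers),
                              em$meanlog_positive, em$sdlog_positive),
                       nrow = n)
    for (j in seq_along(markers)) {
      is_pos <- markers[j] == "DAPI" |
        vapply(types, function(tt) markers[j] %in% defs[[tt]], logical(1))
      inten[is_pos, j] <- pos_draw[is_pos, j]
    }

    tibble::tibble(
      cell_id = sprintf("%s_c%05d", pid, seq_len(n)),
      patient_id = pid,
      spot_id = paste0("spot_", pid),
      x_um = pos$x,
      y_um = pos$y
    ) |>
      dplyr::bind_cols(tibble::as_tibble(inten)) |>
      dplyr::mutate(
        region_id = reg$region_id,
        true_cn = cn_names[reg$region_cn],
        true_cell_type = types
      )
  })
}

#' Simulate survival outcomes from risk-archetype frequencies
#'
#' Draws one survival record per patient: event times are exponential with
#' hazard `survival_baseline * exp(survival_beta * risk_freq)`; a
#' `censoring_rate` fraction of patients receives an independent uniform
#' censoring time on `(0, max_followup)`, and everyone is censored
#' administratively at `max_followup`.
#'
#' @param risk_freq Numeric vector of per-patient risk-archetype frequencies.
#' @param config A [synth_config()] (hazard and censoring parameters).
#' @param seed Integer seed; defaults to a stream derived from `config$seed`.
#' @param patient_id Optional ids; defaults to names of `risk_freq` or 1..n.
#' @return Tibble: `patient_id`, `time_months`, `event` (1 = death observed,
#'   0 = censored).
#' @export
simulate_survival <- function(risk_freq, config, seed = NULL,
                              patient_id = NULL) {
  config <- validate_synth_config(config)
  if (is.null(seed)) seed <- derive_seed(config$seed, "survival")
  n <- length(risk_freq)
  if (is.null(patient_id)) {
    patient_id <- names(risk_freq) %||% as.character(seq_len(n))
  }
  with_seed(seed, {
    rate <- config$survival_baseline * exp(config$survival_beta * risk_freq)
    t_event <- rexp(n, rate)
    cens <- rep(config$max_followup, n)
    early <- runif(n) < config$censoring_rate
    cens[early] <- runif(sum(early), 0, config$max_followup)
    tibble::tibble(
      patient_id = as.character(patient_id),
      time_months = pmax(pmin(t_event, cens), 1e-6),
      event = as.integer(t_event <= cens)
    )
  })
}

#' Simulate a full synthetic cohort
#'
#' One spot per patient via [simulate_spot()], a per-patient ground-truth
#' summary (true risk-archetype frequency), and a linked survival table via
#' [simulate_survival()]. Identical configurations (including the seed)
#' produce identical cohorts.
#'
#' @param config A [synth_config()].
#' @return A `cn_cohort` list with tibbles `cells`, `survival`, and `truth`
#'   (`patient_id`, `risk_freq`).
#' @examples
#' cfg <- synth_config(n_patients = 2, cells_per_spot = 300, seed = 7)
#' coh <- simulate_cohort(cfg)
#' dplyr::count(coh$cells, patient_id)
#' @export
simulate_cohort <- function(config) {
  config <- validate_synth_config(config)
  ids <- sprintf("P%03d", seq_len(config$n_patients))
  cells <- purrr::map(ids, function(pid) simulate_spot(config, pid)) |>
    purrr::list_rbind()
  truth <- cells |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(risk_freq = mean(.data$true_cn == config$risk_cn),
                     .groups = "drop")
  survival <- simulate_survival(
    setNames(truth$risk_freq, truth$patient_id), config
  )
  structure(
    list(cells = cells, survival = survival, truth = truth, config = config),
    class = "cn_cohort"
  )
}

#' @export
print.cn_cohort <- function(x, ...) {
  cat(sprintf(
    "<cn_cohort> %d patients, %d cells, %d planted archetypes (risk: %s)\n",
    nrow(x$survival), nrow(x$cells), nrow(x$config$archetypes),
    x$config$risk_cn
  ))
  invisible(x)
}
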