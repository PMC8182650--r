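#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults encode
#' the study conditions of the screen the package models: the 12-point
#' beta-estradiol dose grid (nM), hourly-scale imaging over 48 h, SC and YNB
#' media, a 3% wild-type spike-in for pooled runs, and the qualitative
#' archetype mix observed for essential-gene strains (constitutive 33%,
#' constitutive-toxic 9.2%, non-functional 4.2%, dependent-toxic 4.7%,
#' dependent 49%).
#'
#' The logistic/Hill growth machinery (`carrying_capacity`, `growth_rate`,
#' `initial_area`, `ec50`, `hill`, `tox_ec50`, `tox_hill`, `leak`) is
#' simulation plumbing: any parameterization reproducing the five archetype
#' shapes is acceptable, and these are the package defaults. Sizes are in
#' pixel units on the scale of high-resolution plate scans, so a carrying
#' capacity of 10,000 px puts the toxicity caller's default distance
#' threshold (2,000, same units) in its working range.
#'
#' @param n_strains number of strains in the panel (including the spike-in
#'   wild type).
#' @param doses nonnegative, sorted inducer doses in nM.
#' @param timepoints imaging times in hours.
#' @param media subset of `c("SC", "YNB")`.
#' @param noise_sd relative (log-normal) colony-size noise.
#' @param read_depth reads per BAR-seq sample.
#' @param per_base_error substitution probability per sequenced base.
#' @param seed integer seed; together with the config it fully determines
#'   every generator output.
#' @param carrying_capacity saturating colony area, pixels.
#' @param growth_rate logistic rate, per hour.
#' @param initial_area pinned-colony starting area, pixels.
#' @param ec50,hill Hill midpoint (nM) and coefficient of the induction
#'   response.
#' @param tox_ec50,tox_hill Hill midpoint (nM) and coefficient of the
#'   toxicity response.
#' @param leak residual induction of a non-functional promoter (fraction of
#'   full induction).
#' @param archetype_mix named nonnegative weights over the five archetypes.
#' @param aux_fraction fraction of non-toxic strains additionally flagged as
#'   auxotroph-like (require induction on YNB only).
#' @param spike_in_fraction wild-type spike-in fraction of cells in pooled
#'   runs.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_strains = 500L,
                       doses = c(0, 0.01, 0.03, 0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000),
                       timepoints = seq(0, 48, by = 2),
                       media = c("SC", "YNB"),
                       noise_sd = 0.05,
                       read_depth = 1e6,
                       per_base_error = 0.005,
                       seed = 1L,
                       carrying_capacity = 10000,
                       growth_rate = 0.35,
                       initial_area = 50,
                       ec50 = 1,
                       hill = 1.2,
                       tox_ec50 = 30,
                       tox_hill = 2,
                       leak = 0.02,
                       archetype_mix = c(constitutive = 0.33,
                                         constitutive_toxic = 0.092,
                                         nonfunctional = 0.042,
                                         dependent_toxic = 0.047,
                                         dependent = 0.489),
                       aux_fraction = 0.05,
                       spike_in_fraction = 0.03) {
    cfg <- list(n_strains = as.integer(n_strains), doses = as.numeric(doses),
                timepoints = as.numeric(timepoints), media = media,
                noise_sd = noise_sd, read_depth = read_depth,
                per_base_error = per_base_error, seed = as.integer(seed),
                carrying_capacity = carrying_capacity,
                growth_rate = growth_rate, initial_area = initial_area,
                ec50 = ec50, hill = hill, tox_ec50 = tox_ec50,
                tox_hill = tox_hill, leak = leak,
                archetype_mix = archetype_mix, aux_fraction = aux_fraction,
                spike_in_fraction = spike_in_fraction)
    validate_sim_config(cfg)
    structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
    stopifnot(cfg$n_strains >= 2L)
    if (length(cfg$doses) == 0 || any(cfg$doses < 0))
        stop("doses must be nonnegative")
    if (is.unsorted(cfg$doses, strictly = TRUE))
        stop("doses must be sorted and distinct")
    if (length(cfg$timepoints) == 0)
        stop("timepoints must be non-empty")
    if (!all(cfg$media %in% c("SC", "YNB")))
        stop("media must be a subset of {SC, YNB}")
    stopifnot(cfg$noise_sd >= 0, cfg$per_base_error >= 0,
              cfg$per_base_error < 1, cfg$read_depth >= 1)
    if (!setequal(names(cfg$archetype_mix), ARCHETYPES))
        stop("archetype_mix must name exactly the five archetypes")
    if (any(cfg$archetype_mix < 0) || sum(cfg$archetype_mix) <= 0)
        stop("archetype_mix weights must be nonnegative with positive sum")
    stopifnot(cfg$spike_in_fraction > 0, cfg$spike_in_fraction < 1)
    invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
    cat("Simulation config:", x$n_strains, "strains,",
        length(x$doses), "doses,", length(x$timepoints), "timepoints,",
        "media:", paste(x$media, collapse = "/"), "\n")
    cat("  noise_sd:", x$noise_sd, " read_depth:", format(x$read_depth),
        " per_base_error:", x$per_base_error, " seed:", x$seed, "\n")
    invisible(x)
}
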