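#' Simulate archetype-driven colony growth across media, doses and time
#'
#' Each strain grows logistically from the pinned area towards a carrying
#' capacity modulated by two Hill responses to the inducer dose: an
#' induction response (midpoint `ec50`) that gates growth of
#' inducer-dependent archetypes, and a toxicity response (midpoint
#' `tox_ec50`) that reduces capacity of toxic archetypes at high dose by the
#' strain's `toxicity_effect`. Non-functional promoters retain only `leak`
#' of full induction; auxotroph-flagged strains additionally require
#' induction on minimal (YNB) medium but not on SC. Observed areas carry
#' multiplicative log-normal noise with relative standard deviation
#' `noise_sd`; the noise-free `true_area` is retained for tests.
#'
#' @param panel a [make_strain_panel()] panel.
#' @param config a [sim_config()].
#' @param n_replicates replicate colonies per strain/medium/dose.
#' @return data.frame of class `growth_table` with columns `strain_id`,
#'   `medium`, `dose_nM`, `time_h`, `replicate`, `true_area`, `area`.
#' @export
simulate_growth <- function(panel, config = sim_config(), n_replicates = 4L) {
    validate_strain_panel(panel)
    validate_sim_config(config)
    if (length(config$doses) == 0L || length(config$timepoints) == 0L)
        stop("doses and timepoints must be non-empty")
    set.seed(stage_seed(config$seed, "growth"))

    cells <- expand.grid(strain = seq_len(nrow(panel)),
                         medium = config$media,
                         dose_nM = config$doses,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keff <- effective_capacity(panel[cells$strain, ], cells$medium,
                               cells$dose_nM, config)

    grid <- expand.grid(cell = seq_len(nrow(cells)),
                        time_h = config$timepoints,
                        replicate = seq_len(n_replicates),
                        KEEP.OUT.ATTRS = FALSE)
    true_area <- logistic_area(grid$time_h, keff[grid$cell],
                               config$initial_area, config$growth_rate)
    noise <- if (config$noise_sd > 0) {
        rlnorm(nrow(grid), meanlog = -config$noise_sd^2 / 2,
               sdlog = config$noise_sd)
    } else rep(1, nrow(grid))

    out <- data.frame(strain_id = panel$strain_id[cells$strain[grid$cell]],
                      medium = cells$medium[grid$cell],
                      dose_nM = cells$dose_nM[grid$cell],
                      time_h = grid$time_h,
                      replicate = grid$replicate,
                      true_area = true_area,
                      area = true_area * noise,
                      stringsAsFactors = FALSE)
    attr(out, "config") <- config
    class(out) <- c("growth_table", "data.frame")
    out
}

# dose- and medium-dependent carrying capacity for a set of strain rows
effective_capacity <- function(rows, medium, dose, config) {
    ind <- hill_response(dose, config$ec50, config$hill)
    f_ind <- rep(1, nrow(rows))
    dep <- rows$archetype %in% c("dependent", "dependent_toxic")
    f_ind[dep] <- ind[dep]
    f_ind[rows$archetype == "nonfunctional"] <- config$leak
    needs_aux <- rows$aux_flag & medium == "YNB"
    f_ind[needs_aux] <- f_ind[needs_aux] * ind[needs_aux]
    f_tox <- 1 - rows$toxicity_effect *
        hill_response(dose, config$tox_ec50, config$tox_hill)
    config$carrying_capacity * f_ind * f_tox
}

# logistic colony area; a capacity at or below the pinned area means the
# colony never expands
logistic_area <- function(t, K, A0, r) {
    out <- rep(A0, length(t))
    grow <- K > A0
    if (any(grow)) {
        Kg <- K[grow]
        out[grow] <- Kg / (1 + ((Kg - A0) / A0) * exp(-r * t[grow]))
    }
    out
}

#' Simulate a two-dose overexpression screen for the toxicity caller
#'
#' Generates per-strain total growth (pixel units) on complete medium at 0
#' and 100 nM inducer with a planted fraction of toxic strains whose growth
#' at 100 nM is reduced by at least the lower bound of `effect_range`.
#' Per-strain baseline capacity varies log-normally (shared by both doses,
#' so it cancels along the diagonal) and measurements carry multiplicative
#' log-normal noise.
#'
#' @param n_strains screen size.
#' @param toxic_fraction fraction of strains with planted toxicity.
#' @param effect_range range of fractional growth reduction at 100 nM for
#'   toxic strains.
#' @param size_scale typical saturated colony size, pixels.
#' @param baseline_sd log-scale spread of per-strain baseline size.
#' @param noise_sd relative measurement noise.
#' @param seed integer seed.
#' @return data.frame with `strain_id`, `x` (growth at 0 nM), `y` (growth at
#'   100 nM), `true_toxic`.
#' @export
simulate_toxicity_screen <- function(n_strains = 5000L, toxic_fraction = 0.05,
                                     effect_range = c(0.5, 0.9),
                                     size_scale = 10000, baseline_sd = 0.1,
                                     noise_sd = 0.05, seed = 1L) {
    stopifnot(n_strains >= 2L, toxic_fraction >= 0, toxic_fraction <= 1)
    set.seed(stage_seed(seed, "toxscreen"))
    base <- size_scale * rlnorm(n_strains, -baseline_sd^2 / 2, baseline_sd)
    true_toxic <- runif(n_strains) < toxic_fraction
    effect <- ifelse(true_toxic,
                     runif(n_strains, effect_range[1], effect_range[2]), 0)
    mnoise <- function() rlnorm(n_strains, -noise_sd^2 / 2, noise_sd)
    data.frame(strain_id = sprintf("STR%05d", seq_len(n_strains)),
               x = base * mnoise(),
               y = base * (1 - effect) * mnoise(),
               true_toxic = true_toxic,
               stringsAsFactors = FALSE)
}
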