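#' Generate a synthetic strain panel with ground-truth phenotypes
#'
#' Builds the master table behind every simulated experiment: one row per
#' strain, carrying a unique 12-nt barcode (all pairwise Hamming distances
#' >= 5, so assignment with up to 2 mismatches is provably unambiguous), a
#' growth archetype, a native-expression level (TPM), an auxotrophy flag and
#' an injected toxicity effect. Exactly one row is the wild-type spike-in
#' strain used as the internal reference in pooled runs and on plates.
#'
#' Native expression is drawn conditionally on archetype: strains that grow
#' without inducer (constitutive behaviors) get low native TPM, strains that
#' need induction get high native TPM. This mirrors the observation that
#' leaky expression from the synthetic promoter suffices only for genes with
#' low native transcript levels, and gives the expression-growth association
#' statistics something real to detect.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `strain_panel` with columns `strain_id`,
#'   `gene_name`, `barcode`, `essential`, `native_expression`, `archetype`,
#'   `aux_flag`, `toxicity_effect`, `is_spike_in_wt`.
#' @export
make_strain_panel <- function(config = sim_config()) {
    validate_sim_config(config)
    n <- config$n_strains
    set.seed(stage_seed(config$seed, "panel"))

    barcode <- cpp_sample_barcodes(n, 12L, 5L)
    mix <- config$archetype_mix[ARCHETYPES]
    archetype <- c("constitutive",  # spike-in WT behaves like wild type
                   sample(ARCHETYPES, n - 1L, replace = TRUE,
                          prob = mix / sum(mix)))

    # leaky-promoter growth at 0 nM is only possible for lowly expressed
    # genes, so native TPM is drawn low for constitutive archetypes and
    # high for inducer-dependent ones
    meanlog <- c(constitutive = log(20), constitutive_toxic = log(30),
                 nonfunctional = log(80), dependent_toxic = log(150),
                 dependent = log(200))[archetype]
    native_expression <- rlnorm(n, meanlog = meanlog, sdlog = 0.9)

    toxic <- archetype %in% c("constitutive_toxic", "dependent_toxic")
    toxicity_effect <- ifelse(toxic, runif(n, 0.5, 0.9), 0)

    aux_flag <- !toxic & archetype %in% c("constitutive", "dependent") &
        runif(n) < config$aux_fraction
    aux_flag[1L] <- FALSE

    panel <- data.frame(
        strain_id = c("WT_SPIKE", sprintf("STR%04d", seq_len(n - 1L))),
        gene_name = c("WT", sprintf("GENE%04d", seq_len(n - 1L))),
        barcode = as.character(barcode),
        essential = archetype %in% c("nonfunctional", "dependent_toxic", "dependent"),
        native_expression = native_expression,
        archetype = archetype,
        aux_flag = aux_flag,
        toxicity_effect = toxicity_effect,
        is_spike_in_wt = c(TRUE, rep(FALSE, n - 1L)),
        stringsAsFactors = FALSE
    )
    class(panel) <- c("strain_panel", "data.frame")
    validate_strain_panel(panel)
    panel
}

#' Validate the invariants of a strain panel
#'
#' Checks barcode uniqueness and length, the minimum pairwise Hamming
#' distance (>= 5 by an all-pairs scan), the single-spike-in rule and
#' nonnegative native expression. Errors on the first violation.
#'
#' @param panel a `strain_panel`.
#' @return the panel, invisibly.
#' @export
validate_strain_panel <- function(panel) {
    stopifnot(is.data.frame(panel))
    need <- c("strain_id", "gene_name", "barcode", "essential",
              "native_expression", "archetype", "aux_flag",
              "toxicity_effect", "is_spike_in_wt")
    missing <- setdiff(need, names(panel))
    if (length(missing))
        stop("panel lacks columns: ", paste(missing, collapse = ", "))
    if (anyDuplicated(panel$barcode))
        stop("barcodes are not unique")
    if (any(nchar(panel$barcode) != 12L))
        stop("all barcodes must have length 12")
    if (nrow(panel) >= 2L && cpp_min_pairwise_hamming(panel$barcode) < 5L)
        stop("minimum pairwise barcode Hamming distance is below 5")
    if (sum(panel$is_spike_in_wt) != 1L)
        stop("panel must contain exactly one spike-in wild-type strain")
    if (any(panel$native_expression < 0))
        stop("native_expression must be nonnegative")
    if (!all(panel$archetype %in% ARCHETYPES))
        stop("unknown archetype value")
    if (any(panel$toxicity_effect < 0 | panel$toxicity_effect > 1))
        stop("toxicity_effect must lie in [0, 1]")
    invisible(panel)
}

#' @export
print.strain_panel <- function(x, ...) {
    cat("Strain panel:", nrow(x), "strains;",
        sum(x$aux_flag), "auxotroph-like,",
        sum(x$toxicity_effect > 0), "toxic;",
        "min barcode distance", cpp_min_pairwise_hamming(x$barcode), "\n")
    print(utils::head(as.data.frame(x), 4L))
    invisible(x)
}
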