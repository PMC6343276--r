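# Known configuration keys with defaults (NULL = required to be given
# either in the file or by the caller).
.CONFIG_DEFAULTS <- list(
    n_loci = 143L,
    maf_lower = 0.0015,
    maf_upper = 0.01,
    shape = NULL,          # filled with defaultMafShape()
    prevalence = 0.05,
    effect = "uniform_or",
    odds_ratio = 2.5,
    n_disease_loci = 10L,
    alpha_level = 0.05,
    n_cases = 2000L,
    n_controls = 2000L,
    n_datasets = 1000L,
    n_replicates = 30L,
    base_seed = 1L,
    seed = NULL,
    output_dir = ".",
    profile = NULL)

#' Read a run configuration from YAML
#'
#' Reads a flat key-value YAML run configuration, rejects unknown keys,
#' and fills unset keys with package defaults. The key set covers the
#' generator (`n_loci`, `maf_lower`, `maf_upper`, `shape`, `prevalence`,
#' `effect`, `odds_ratio`, `n_disease_loci`), the design (`n_cases`,
#' `n_controls`, `alpha_level`), and the run (`n_datasets`,
#' `n_replicates`, `base_seed`, `seed`, `output_dir`, `profile`).
#' Configurations round-trip losslessly through [writeRunConfig()].
#'
#' @param path YAML file path.
#' @return A named list of class `rvRunConfig`.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg))
        cfg <- list()
    unknown <- setdiff(names(cfg), names(.CONFIG_DEFAULTS))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    asRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a named list of configuration values (subset of the known
#'   keys).
#' @export
asRunConfig <- function(cfg = list()) {
    unknown <- setdiff(names(cfg), names(.CONFIG_DEFAULTS))
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    out <- .CONFIG_DEFAULTS
    out$shape <- defaultMafShape()
    for (k in names(cfg))
        out[[k]] <- cfg[[k]]
    if (!is.null(out$profile)) {
        profile <- match.arg(out$profile, c("paper", "ci"))
        if (profile == "paper") {
            out$n_datasets <- 1000L
            out$n_replicates <- 30L
        } else {
            out$n_datasets <- 200L
            out$n_replicates <- 5L
        }
        out$profile <- profile
    }
    if (!is.null(out$seed))
        out$base_seed <- as.integer(out$seed)
    structure(out, class = "rvRunConfig")
}

#' Write a run configuration to YAML
#'
#' @param config an `rvRunConfig` (or compatible named list).
#' @param path output YAML path.
#' @return Invisibly, `path`.
#' @export
writeRunConfig <- function(config, path) {
    cfg <- unclass(config)
    cfg <- cfg[!vapply(cfg, is.null, logical(1))]
    yaml::write_yaml(cfg, path)
    invisible(path)
}

#' Build a Scenario from a run configuration
#'
#' @param config an `rvRunConfig` from [readRunConfig()] /
#'   [asRunConfig()].
#' @return A [Scenario-class].
#' @export
scenarioFromConfig <- function(config) {
    stopifnot(inherits(config, "rvRunConfig"))
    Scenario(nCases = config$n_cases, nControls = config$n_controls,
             mafUpper = config$maf_upper, effect = config$effect,
             oddsRatio = config$odds_ratio,
             nDiseaseLoci = config$n_disease_loci,
             nLoci = config$n_loci, alphaLevel = config$alpha_level,
             prevalence = config$prevalence,
             mafLower = config$maf_lower, mafShape = config$shape)
}
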