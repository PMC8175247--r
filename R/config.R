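# Run configuration: a small YAML/JSON dialect describing norms, the
# environment distribution, the study design, criteria parameters and the
# pipeline step to run. Unknown keys are rejected with their field path;
# every run requires an explicit integer seed.

config_schema <- list(
  top = c("seed", "run", "norms", "environment", "design", "fixture",
          "criteria", "simulation", "output"),
  norm = c("genotype", "shape", "params", "domain"),
  environment = c("family", "params"),
  design = c("n_labs", "n_per_arm", "genotypes", "standardization",
             "within_noise_sd", "small_effect_sd", "delta0", "delta1"),
  fixture = c("n_studies", "x_range", "delta0", "delta1", "se_per_study",
              "n_per_arm"),
  criteria = c("z", "L", "confidence"),
  simulation = c("n_replicates", "s2_gxe"),
  output = c("dir")
)

reject_unknown <- function(x, allowed, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    abort_validation(sprintf("Unknown key(s) at %s: %s.",
                             path, paste(extra, collapse = ", ")))
  }
}

#' Load and validate a run configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) configuration, validates
#' it against the documented schema (unknown keys rejected, field paths in
#' error messages), fills in defaults (`z = 1.96`, `L = 0.0025`,
#' `confidence = 0.95`, `run = "simulate"`), and resolves all
#' cross-references (every genotype label used in the design must name a
#' defined norm). Relative file paths inside the config resolve against the
#' config's own directory.
#'
#' @param path Path to the configuration file.
#' @return An object of class `run_config` holding the canonical
#'   configuration list (`$raw`) plus built objects: `$norms` (named list of
#'   reaction norms), `$environment`, `$design`, `$fixture`, `$criteria`,
#'   `$simulation`, `$output`, `$seed`, `$run`.
#' @seealso [run_pipeline()], [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("Config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    # simplify atomic arrays to vectors (as yaml does) but keep object arrays
    # as lists so the two formats parse to the same structure
    json = jsonlite::fromJSON(path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
    abort_validation("Config must be a .yaml, .yml or .json file.")
  )
  build_config(raw, base_dir = dirname(path))
}

build_config <- function(raw, base_dir = ".") {
  if (!is.list(raw)) abort_validation("Config root must be a mapping.")
  reject_unknown(raw, config_schema$top, "<root>")
  if (is.null(raw$seed)) {
    abort_validation("Config field `seed` is required (explicit integer seed, no wall-clock seeding).")
  }
  seed <- check_seed(raw$seed)

  run <- raw$run %||% "simulate"
  if (!run %in% c("simulate", "gradient", "coverage", "rlm")) {
    abort_validation(sprintf(
      "`run` must be one of simulate, gradient, coverage, rlm; got %s.", run))
  }

  criteria <- raw$criteria %||% list()
  reject_unknown(criteria, config_schema$criteria, "criteria")
  criteria <- list(z = criteria$z %||% 1.96, L = criteria$L %||% 0.0025,
                   confidence = criteria$confidence %||% 0.95)
  check_number(criteria$z, "criteria.z", lower = 0, strict_lower = TRUE)
  check_number(criteria$L, "criteria.L", lower = 0, upper = 1, strict_lower = TRUE)
  z_from_confidence(criteria$confidence)

  simulation <- raw$simulation %||% list()
  reject_unknown(simulation, config_schema$simulation, "simulation")
  simulation <- list(n_replicates = as.integer(simulation$n_replicates %||% 1000L),
                     s2_gxe = simulation$s2_gxe %||% "oracle")

  output <- raw$output %||% list()
  reject_unknown(output, config_schema$output, "output")
  output <- list(dir = output$dir %||% "reactnorm-out")

  norms <- NULL
  if (!is.null(raw$norms)) {
    norms <- purrr::imap(raw$norms, function(spec, i) {
      reject_unknown(spec, config_schema$norm, sprintf("norms[%s]", i))
      build_norm_from_spec(spec, base_dir, sprintf("norms[%s]", i))
    })
    names(norms) <- vapply(norms, `[[`, character(1), "genotype")
    if (anyDuplicated(names(norms))) {
      abort_validation("Duplicate genotype labels in `norms`.")
    }
  }

  environment <- NULL
  if (!is.null(raw$environment)) {
    reject_unknown(raw$environment, config_schema$environment, "environment")
    environment <- build_env_from_spec(raw$environment, base_dir)
  }

  design <- NULL
  if (!is.null(raw$design)) {
    d <- raw$design
    reject_unknown(d, config_schema$design, "design")
    labels <- unlist(d$genotypes %||% names(norms))
    unknown <- setdiff(labels, names(norms))
    if (length(unknown)) {
      abort_validation(sprintf(
        "design.genotypes references undefined genotype label(s): %s.",
        paste(unknown, collapse = ", ")))
    }
    design <- study_design(
      n_labs = d$n_labs %||% 10, n_per_arm = d$n_per_arm %||% 10,
      genotypes = norms[labels],
      standardization = d$standardization %||% "heterogenized",
      within_noise_sd = d$within_noise_sd %||% 1,
      small_effect_sd = d$small_effect_sd %||% 0,
      delta0 = d$delta0 %||% 0, delta1 = d$delta1 %||% 0
    )
  }

  fixture <- NULL
  if (!is.null(raw$fixture)) {
    f <- raw$fixture
    reject_unknown(f, config_schema$fixture, "fixture")
    fixture <- list(
      n_studies = f$n_studies %||% 25,
      x_range = as.numeric(unlist(f$x_range %||% c(18, 30))),
      delta0 = f$delta0 %||% -4.8, delta1 = f$delta1 %||% 0.2,
      se_per_study = f$se_per_study %||% 0.3, n_per_arm = f$n_per_arm %||% 10
    )
  }

  canonical <- list(
    seed = seed, run = run,
    norms = raw$norms, environment = raw$environment, design = raw$design,
    fixture = fixture, criteria = criteria, simulation = simulation,
    output = output
  )
  canonical <- canonical[!vapply(canonical, is.null, logical(1))]
  structure(
    list(raw = canonical, seed = seed, run = run, norms = norms,
         environment = environment, design = design, fixture = fixture,
         criteria = criteria, simulation = simulation, output = output),
    class = "run_config"
  )
}

build_norm_from_spec <- function(spec, base_dir, path) {
  shape <- spec$shape %||% abort_validation(sprintf("%s.shape is required.", path))
  genotype <- spec$genotype %||% "g1"
  p <- spec$params %||% list()
  domain <- if (!is.null(spec$domain)) as.numeric(unlist(spec$domain)) else c(-Inf, Inf)
  switch(shape,
    flat = norm_flat(p$m %||% 0, domain, genotype),
    linear = norm_linear(p$intercept %||% 0, p$slope %||% 0, domain, genotype),
    quadratic = norm_quadratic(p$a %||% 0, p$b %||% 0, p$c2 %||% 0, domain, genotype),
    logistic = norm_logistic(p$lower %||% 0, p$upper %||% 1,
                             p$midpoint %||% 0, p$scale %||% 1, domain, genotype),
    tabulated = norm_tabulated(file = resolve_path(p$file, base_dir),
                               genotype = genotype),
    abort_validation(sprintf("%s.shape: unknown shape `%s`.", path, shape))
  )
}

build_env_from_spec <- function(spec, base_dir) {
  family <- spec$family %||% abort_validation("environment.family is required.")
  p <- spec$params %||% list()
  switch(family,
    gaussian = env_gaussian(p$mean %||% 0, p$sd %||% 1),
    uniform = env_uniform(p$min %||% 0, p$max %||% 1),
    tabulated = env_tabulated(file = resolve_path(p$file, base_dir)),
    abort_validation(sprintf("environment.family: unknown family `%s`.", family))
  )
}

resolve_path <- function(file, base_dir) {
  if (is.null(file)) abort_validation("A tabulated spec requires `params.file`.")
  if (file.exists(file)) file else file.path(base_dir, file)
}

#' Serialise a run configuration back to YAML
#'
#' Writes the canonical form of the configuration (defaults filled in) so
#' that parse -> serialise -> parse round-trips to an identical structure.
#'
#' @param config A `run_config` from [load_config()].
#' @param path Output path (`.yaml`).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config$raw, path)
  invisible(config)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> run = %s, seed = %d\n", x$run, x$seed))
  if (!is.null(x$norms)) cat("  genotypes:", paste(names(x$norms), collapse = ", "), "\n")
  invisible(x)
}
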