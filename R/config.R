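# Run configuration: a single YAML file with strict schema validation.
# Sections map onto the constructor arguments of the component configs, so
# the published protocol values (learning rate 0.001, batch 16, 50 epochs,
# patience 10, dropout 0.25, 80/10/10 split) are the defaults and every
# unstated parameter is visible and overridable.

.run_schema <- function() {
  list(
    synthetic = c(names(formals(phantomSpec)), "nSamples"),
    preprocess = names(formals(preprocessConfig)),
    model = names(formals(modelConfig)),
    train = names(formals(trainConfig)),
    paths = c("manifest", "outputDir")
  )
}

.log_info <- function(fmt, ...) {
  message(sprintf("INFO [%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run configuration
#'
#' The resolved configuration of a pipeline run: phantom generator spec
#' and sample count, preprocessing, model and training configurations,
#' and file-system paths.
#'
#' @slot synthetic a [PhantomSpec-class].
#' @slot nSamples number of samples `cmdSynth()` generates (config key `nSamples`).
#' @slot preprocess a [PreprocessConfig-class].
#' @slot model a [ModelConfig-class].
#' @slot train a [TrainConfig-class].
#' @slot paths named list with optional `manifest` and `outputDir`.
#' @export
setClass("RunConfig", representation(
  synthetic = "PhantomSpec", nSamples = "integer",
  preprocess = "PreprocessConfig", model = "ModelConfig",
  train = "TrainConfig", paths = "list"
))

#' Read and validate a run configuration
#'
#' Reads a YAML file with sections `synthetic`, `preprocess`, `model`,
#' `train` and `paths`. Unknown sections or keys are rejected by name;
#' every parameter not present in the file falls back to the package
#' default and is logged once, so nothing defaults silently.
#'
#' @param path YAML file, or `NULL` for an all-defaults configuration.
#' @param seed optional integer overriding both the synthetic and the
#'   training seed (the CLI `--seed` flag).
#' @return A [RunConfig-class].
#' @export
readRunConfig <- function(path = NULL, seed = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_io(sprintf("config '%s' not found", path))
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  schema <- .run_schema()
  unknown_sec <- setdiff(names(raw), names(schema))
  if (length(unknown_sec))
    stop_config(sprintf("unknown config section(s): %s",
                        paste(unknown_sec, collapse = ", ")))
  for (sec in names(raw)) {
    unknown <- setdiff(names(raw[[sec]]), schema[[sec]])
    if (length(unknown))
      stop_config(sprintf("unknown key(s) in section '%s': %s", sec,
                          paste(unknown, collapse = ", ")))
  }
  get_sec <- function(sec) raw[[sec]] %||% list()
  log_defaults <- function(sec, given) {
    defaulted <- setdiff(setdiff(schema[[sec]], "nSamples"), names(given))
    if (length(defaulted))
      .log_info("section '%s': using defaults for %s", sec,
                paste(defaulted, collapse = ", "))
  }
  syn <- get_sec("synthetic")
  n <- as.integer(syn$nSamples %||% 20L)
  syn$nSamples <- NULL
  log_defaults("synthetic", syn)
  if (!is.null(seed)) syn$seed <- as.integer(seed)
  spec <- do.call(phantomSpec, syn)
  pre <- get_sec("preprocess")
  log_defaults("preprocess", pre)
  precfg <- do.call(preprocessConfig, pre)
  mod <- get_sec("model")
  log_defaults("model", mod)
  modcfg <- do.call(modelConfig, mod)
  trn <- get_sec("train")
  log_defaults("train", trn)
  if (!is.null(seed)) trn$seed <- as.integer(seed)
  trncfg <- do.call(trainConfig, trn)
  new("RunConfig", synthetic = spec, nSamples = n, preprocess = precfg,
      model = modcfg, train = trncfg, paths = get_sec("paths"))
}

.runconfig_to_list <- function(cfg) {
  s <- cfg@synthetic
  p <- cfg@preprocess
  list(
    synthetic = list(imageSize = s@imageSize, nVessels = s@nVessels,
                     vesselRadiusRange = s@vesselRadiusRange,
                     clotFraction = s@clotFraction,
                     noiseSigma = s@noiseSigma,
                     backgroundLevel = s@backgroundLevel, seed = s@seed,
                     nSamples = cfg@nSamples),
    preprocess = list(claheClipLimit = p@claheClipLimit,
                      claheTiles = p@claheTiles, claheBins = p@claheBins,
                      denoiseKernel = p@denoiseKernel,
                      denoiseMethod = p@denoiseMethod,
                      gaussianSigma = p@gaussianSigma,
                      targetSize = p@targetSize,
                      normalizeRange = p@normalizeRange),
    model = .config_to_list(cfg@model),
    train = .trainconfig_to_list(cfg@train),
    paths = cfg@paths
  )
}

#' Write a resolved run configuration
#'
#' Echoes the fully resolved configuration (all defaults filled in) as
#' YAML, so any run is reproducible from its resolved config alone.
#'
#' @param cfg a [RunConfig-class].
#' @param path output YAML file.
#' @return invisibly, `path`.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(.runconfig_to_list(cfg), path)
  invisible(path)
}

# Log the run banner: seed, config hash, output directory.
.log_run <- function(cfg, what, outdir) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeRunConfig(cfg, tmp)
  .log_info("%s: seed %d, config %s, output '%s'", what,
            cfg@train@seed, substr(unname(tools::md5sum(tmp)), 1, 8),
            outdir %||% "<none>")
}
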