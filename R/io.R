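#' Load a run configuration from YAML/JSON
#'
#' Reads a flat configuration file, fills every omitted field with the
#' package default (an empty file yields the baseline top-dog + pipetting
#' regimen), and validates the result, reporting every violated invariant
#' at once. Nested sections `params`, `mut`, and `reproduction` accept the
#' corresponding constructor arguments.
#'
#' @param path file path (YAML; JSON also parses).
#' @return A [selection_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  build_config(raw)
}

build_config <- function(raw) {
  top_keys <- setdiff(names(formals(selection_config)),
                      c("params", "mut", "reproduction"))
  known <- c(top_keys, "params", "mut", "reproduction")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  sub <- function(name, ctor) {
    args <- raw[[name]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(ctor)))
    if (length(bad))
      stop("unknown ", name, " keys: ", paste(bad, collapse = ", "))
    do.call(ctor, args)
  }
  args <- raw[intersect(names(raw), top_keys)]
  args$params <- sub("params", hm_params)
  args$mut <- sub("mut", mutation_model)
  args$reproduction <- sub("reproduction", reproduction_spec)
  do.call(selection_config, args)
}

#' Save a run configuration to YAML
#'
#' Writes every field explicitly so that `load_config(save_config(x))` is
#' the identity.
#'
#' @param config a [selection_config()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$params <- unclass(cfg$params)[c("gHmax", "gMmax", "affHR", "affMR",
                                      "affMB", "fP", "cRM", "cRH", "cBM",
                                      "deltaH", "deltaM", "B0")]
  cfg$params$gHmax_bound <- config$params$bounds$gHmax
  if (is.null(cfg$params$B0)) cfg$params$B0 <- NULL
  cfg$mut <- unclass(config$mut)[c("P_mut", "p_null", "s_plus", "s_minus",
                                   "epistasis_g", "fP_init", "mutable")]
  cfg$reproduction <- unclass(config$reproduction)
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' List or load the shipped scenario presets
#'
#' Preset configuration files for the standard scenarios (baseline
#' pipetting, cell sorting, top-tier, long maturation, measurement noise,
#' fast-Helper coexistence, random control, fixed-fold dilution,
#' monoculture group selection, pregrowth) live under
#' `inst/extdata/presets`.
#'
#' @param name preset name (without extension); `NULL` lists the available
#'   presets.
#' @return A [selection_config()], or a character vector of names.
#' @export
preset <- function(name = NULL) {
  dir <- system.file("extdata", "presets", package = "commsel")
  files <- list.files(dir, pattern = "\\.yaml$")
  if (is.null(name)) return(sub("\\.yaml$", "", files))
  path <- file.path(dir, paste0(name, ".yaml"))
  if (!file.exists(path))
    stop("unknown preset '", name, "'; available: ",
         paste(sub("\\.yaml$", "", files), collapse = ", "))
  load_config(path)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_csv17 <- function(df, path) {
  # full double precision (%.17g) so that read(write(x)) round-trips exactly
  num <- vapply(df, is.numeric, logical(1))
  out <- df
  out[num] <- lapply(df[num], fmt_num)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Write / read a run archive
#'
#' `write_trajectory()` lays a run out as text: `header.json` (resolved
#' configuration, ancestral `P(T)`, master seed), `records.csv` (one row
#' per chosen Adult per cycle, full double precision), `aggregates.csv`.
#' `read_trajectory()` reconstructs the run; the aggregate table is
#' recomputable from the per-Adult rows, and any community's maturation is
#' replayable from the archive alone (see [replay_community()]).
#'
#' @param run a `commsel_run`.
#' @param dir archive directory (created if needed).
#' @return `write_trajectory()` returns `dir` invisibly;
#'   `read_trajectory()` returns the `commsel_run`.
#' @export
write_trajectory <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg_file <- file.path(dir, "config.yaml")
  save_config(run$header$config, cfg_file)
  jsonlite::write_json(
    list(master_seed = run$header$master_seed,
         P_ancestral = run$header$P_ancestral,
         extinction = isTRUE(run$header$extinction),
         package_version = as.character(utils::packageVersion("commsel"))),
    file.path(dir, "header.json"), auto_unbox = TRUE, digits = NA)
  write_csv17(run$records, file.path(dir, "records.csv"))
  write_csv17(run$aggregates, file.path(dir, "aggregates.csv"))
  invisible(dir)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(dir) {
  need <- file.path(dir, c("config.yaml", "header.json", "records.csv",
                           "aggregates.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("incomplete run archive; missing: ",
         paste(basename(missing), collapse = ", "))
  header <- jsonlite::read_json(file.path(dir, "header.json"),
                                simplifyVector = TRUE)
  config <- load_config(file.path(dir, "config.yaml"))
  records <- utils::read.csv(file.path(dir, "records.csv"))
  aggregates <- utils::read.csv(file.path(dir, "aggregates.csv"))
  structure(list(header = list(config = config,
                               P_ancestral = header$P_ancestral,
                               master_seed = header$master_seed,
                               extinction = isTRUE(header$extinction)),
                 records = records, aggregates = aggregates),
            class = "commsel_run")
}

#' Replay one community of an archived run
#'
#' Re-derives the Newborn and per-community seed of cycle `cycle`,
#' community `j` from the run's master seed (re-running the deterministic
#' seed stream from the start) and matures it again; by construction the
#' result is bit-identical to the original Adult.
#'
#' @param x a `commsel_run`, an archive directory, or a
#'   [selection_config()].
#' @param cycle,j which community to replay.
#' @return The replayed Adult `community`.
#' @export
replay_community <- function(x, cycle, j) {
  config <- if (inherits(x, "selection_config")) x
            else if (inherits(x, "commsel_run")) x$header$config
            else read_trajectory(x)$header$config
  if (cycle < 1 || cycle > config$n_cycles) stop("cycle out of range")
  if (j < 1 || j > config$n_tot) stop("community index out of range")
  cap <- run_selection_core(config, capture = c(cycle, j))
  mature(cap$newborn, config$params, config$mut, config$T, config$dtau,
         seed = cap$seed, excessB = config$monoculture)
}
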