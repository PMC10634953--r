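#' Run a declarative experiment manifest
#'
#' A manifest is a named list (or path to a YAML file) naming a protocol
#' and its parameters; results are returned as tidy tables and optionally
#' written, together with an echo of the manifest and the package version,
#' to an output directory.  Protocols: `simulate` (coupled network run),
#' `capability` (population burst-capability), `capability_map`
#' (conductance-space map), `inap_block` (rhythm vs. block fraction).
#'
#' @param manifest Named list or YAML file path.  Common keys: `protocol`,
#'   `seed`, `duration`, `network` (arguments to [network_spec()]),
#'   `environment` (arguments to [ion_environment()]), `g_tonic`,
#'   `out_dir`.
#' @returns A list with `result` (a tibble or `sim_record`), `manifest`
#'   (as interpreted), and `files` (paths written, if any).
#' @export
run_experiment <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1)
    manifest <- yaml::read_yaml(manifest)
  stopifnot(is.list(manifest), !is.null(manifest$protocol))
  m <- manifest
  env <- do.call(ion_environment, m$environment %||% list())
  spec <- do.call(network_spec,
                  c(m$network %||% list(), list(seed = m$seed %||% 1L)))
  result <- switch(
    m$protocol,
    simulate = {
      net <- build_network(spec, env)
      cfg <- simulation_config(duration = m$duration %||% 10000,
                               transient = m$transient %||% 0)
      simulate_network(net, cfg, g_tonic = m$g_tonic %||% 0)
    },
    capability = {
      pop <- sample_population(spec, env)
      population_capability(pop, env)
    },
    capability_map = {
      map_capability_region(m$g_nap_grid, m$g_leak_grid,
                            g_spk = m$g_spk %||% 0,
                            g_ahp = m$g_ahp %||% 0, env = env)
    },
    inap_block = {
      net <- build_network(spec, env)
      fr <- m$fractions %||% seq(0, 1, by = 0.1)
      cfg <- simulation_config(duration = m$duration %||% 35000,
                               transient = m$transient %||% 5000)
      purrr::map_dfr(fr, function(f) {
        b <- apply_inap_block(net, f)
        rec <- simulate_network(b, cfg, g_tonic = m$g_tonic %||% 0.4)
        rm <- rhythm_metrics(population_rate(rec))
        tibble::tibble(fraction = f, is_rhythmic = rm$is_rhythmic,
                       frequency = rm$frequency, amplitude = rm$amplitude)
      })
    },
    stop("unknown protocol '", m$protocol, "'", call. = FALSE)
  )
  files <- character(0)
  if (!is.null(m$out_dir)) {
    dir.create(m$out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(
      c(m, list(prebotc_version = as.character(utils::packageVersion("prebotc")))),
      file.path(m$out_dir, "manifest.yml")
    )
    files <- file.path(m$out_dir, "manifest.yml")
    if (inherits(result, "sim_record")) {
      f <- file.path(m$out_dir, "raster.tsv")
      utils::write.table(result$spikes, f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      files <- c(files, f)
    } else if (is.data.frame(result)) {
      f <- file.path(m$out_dir, "result.tsv")
      utils::write.table(result, f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      files <- c(files, f)
    }
  }
  list(result = result, manifest = m, files = files)
}

#' Generate reusable fixture configurations
#'
#' `single-burster` writes the canonical pacemaker's parameters;
#' `tiny-network` writes a seeded 10-neuron population and edge list.
#' Identical seeds give byte-identical files.
#'
#' @param kind `"single-burster"` or `"tiny-network"`.
#' @param seed RNG seed for the sampled fixture.
#' @param dir Output directory.
#' @returns Paths of the files written, invisibly.
#' @export
generate_fixture <- function(kind = c("single-burster", "tiny-network"),
                             seed = 1L, dir = tempdir()) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (kind == "single-burster") {
    p <- canonical_burster()
    f <- file.path(dir, "single_burster.yml")
    yaml::write_yaml(list(
      c_m = p$c_m, g_na = p$g_na, g_k = p$g_k, g_spk = p$g_spk,
      g_ahp = p$g_ahp, g_nap = p$g_nap, g_ca = p$g_ca, g_leak = p$g_leak
    ), f)
    return(invisible(f))
  }
  spec <- network_spec(n = 10, seed = seed)
  net <- build_network(spec)
  f1 <- file.path(dir, "tiny_network_neurons.tsv")
  f2 <- file.path(dir, "tiny_network_edges.tsv")
  utils::write.table(net$neurons, f1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(net$edges, f2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(f1, f2))
}

#' Default parameter configuration
#'
#' Reads the flat key-value defaults file shipped with the package: every
#' model symbol (conductances, gating parameters, ion concentrations,
#' network and synapse constants, calibrated spike-shape values) under one
#' key each.
#'
#' @returns A named list of parameter values.
#' @export
default_parameter_config <- function() {
  yaml::read_yaml(system.file("extdata", "default_parameters.yml",
                              package = "prebotc"))
}
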