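# Readers/writers and synthetic fixtures: SWC morphology export, YAML
# config round-trip, sweep-table CSV, and the synthetic trace generator
# used to unit-test the peak classifier without running the network.

#' Synthetic voltage trace with controlled peak heights
#'
#' Generates a deterministic trace of Gaussian bumps of specified heights
#' (relative to a reference maximum) over a flat baseline, with optional
#' Gaussian noise. Used to test [classify_peaks()] and [error_index()]
#' against analytically forced counts.
#'
#' @param heights peak heights relative to `ref_max` (>= 0).
#' @param times peak centres (ms), strictly increasing; `NULL` spaces the
#'   peaks evenly.
#' @param duration trace length (ms).
#' @param dt sample interval (ms).
#' @param baseline baseline voltage (mV).
#' @param ref_max reference maximum height (mV above baseline).
#' @param width Gaussian bump s.d. (ms).
#' @param noise_sd Gaussian noise s.d. (mV).
#' @param seed RNG seed for the noise.
#' @return list with `trace`, `times` (sample times), `peak_times`,
#'   `dt`, `baseline`, `ref_max` and the implied window edges.
#' @export
generate_trace <- function(heights, times = NULL, duration = 1000,
                           dt = 0.25, baseline = -70, ref_max = 80,
                           width = 4, noise_sd = 0, seed = 1L) {
  stopifnot(all(heights >= 0))
  n_pk <- length(heights)
  if (is.null(times)) {
    times <- if (n_pk > 0) (seq_len(n_pk) - 0.5) * duration / max(n_pk, 1)
             else numeric()
  }
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1) {
    stop("peak times must be strictly increasing")
  }
  tt <- seq(0, duration, by = dt)
  v <- rep(baseline, length(tt))
  for (i in seq_len(n_pk)) {
    v <- v + heights[i] * ref_max * exp(-((tt - times[i]) / width)^2 / 2)
  }
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(rng$seed)
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  n_win <- max(n_pk, 1)
  list(trace = v, times = tt, peak_times = times, dt = dt,
       baseline = baseline, ref_max = ref_max,
       windows = seq(0, duration, length.out = n_win + 1))
}

#' Write a morphology as SWC
#'
#' Standard SWC: `id type x y z radius parent`. The compartment level is
#' encoded in the SWC type field (1 soma, 2 primary, 3 secondary,
#' 4 subordinate); coordinates are a deterministic schematic layout
#' (depth along x, section spread along y).
#'
#' @param morph an `msn_morphology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_swc <- function(morph, path) {
  comps <- morph$comps
  lvl <- c(soma = 1L, primary = 2L, secondary = 3L, subordinate = 4L)
  depth <- numeric(nrow(comps))
  for (i in seq_len(nrow(comps))) {
    p <- comps$parent[i]
    depth[i] <- if (is.na(p)) 0 else depth[match(p, comps$id)] +
      comps$length[i]
  }
  lines <- sprintf("%d %d %.3f %.3f %.3f %.3f %d",
                   comps$id, lvl[comps$level],
                   depth, comps$section * 10, 0,
                   comps$diam / 2,
                   ifelse(is.na(comps$parent), -1L, comps$parent))
  writeLines(c("# SWC export: stylized medium spiny neuron",
               sprintf("# receptor_type %s", morph$receptor_type),
               lines), path)
  invisible(path)
}

#' Read an SWC morphology
#'
#' Round-trips files written by [write_swc()]: compartment ids, parentage
#' and level labels are restored exactly. Synapse-site annotations are
#' re-derived from the subordinate-level rule.
#'
#' @param path SWC file.
#' @return an `msn_morphology` (without lesion history).
#' @export
read_swc <- function(path) {
  raw <- readLines(path)
  rt_line <- grep("^# receptor_type", raw, value = TRUE)
  receptor <- if (length(rt_line)) sub("^# receptor_type ", "", rt_line[1])
              else "d1"
  body <- raw[!startsWith(raw, "#") & nzchar(trimws(raw))]
  fields <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) != 7)
  if (length(bad)) {
    stop("SWC parse error at line ", bad[1] + sum(startsWith(raw, "#")),
         ": expected 7 fields")
  }
  m <- do.call(rbind, lapply(fields, as.numeric))
  if (anyNA(m)) stop("SWC parse error: non-numeric field")
  ids <- as.integer(m[, 1]); types <- as.integer(m[, 2])
  parents <- as.integer(m[, 7])
  lvl_names <- c("soma", "primary", "secondary", "subordinate")
  if (any(!types %in% 1:4)) stop("SWC parse error: unknown type code")
  orphan <- which(parents != -1 & !(parents %in% ids))
  if (length(orphan)) {
    stop("SWC parse error at line ", orphan[1],
         ": orphan node (parent ", parents[orphan[1]], " missing)")
  }
  base <- build_morphology(receptor_type = receptor)
  comps <- tibble::tibble(
    id = ids,
    parent = ifelse(parents == -1L, NA_integer_, parents),
    level = lvl_names[types],
    section = NA_integer_, length = NA_real_, diam = 2 * m[, 6],
    v = -85, glut_site = FALSE, da_site = FALSE, da_lost = FALSE,
    glut_removed = FALSE, site_index = NA_integer_)
  # restore section/length/site annotations where ids match the canonical
  # build; otherwise leave the raw tree
  idx <- match(comps$id, base$comps$id)
  ok <- !is.na(idx)
  for (cl in c("section", "length", "glut_site", "da_site", "site_index")) {
    comps[[cl]][ok] <- base$comps[[cl]][idx[ok]]
  }
  structure(
    list(comps = comps, receptor_type = receptor, seed = 1L,
         lesion = list(ns = 0L, nd = 0L, spine_order = "type1_first",
                       removed_spine_sites = integer(),
                       removed_sections = integer(),
                       detached = tibble::tibble())),
    class = "msn_morphology")
}

config_fields <- function() {
  c("n_py", "n_d1", "n_d2", "n_da", "n_stn", "n_gpe", "n_gpi", "n_th",
    "seed", "dopamine_depletion", "ns", "nd", "spine_order",
    "weights", "bias", "duration", "dt", "record_stride")
}

#' Save a network/simulation configuration as YAML
#'
#' @param config a [network_config()].
#' @param path output file.
#' @param sim optional [sim_spec()] whose scalar fields (duration, dt,
#'   record_stride) are stored alongside.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path, sim = NULL) {
  stopifnot(inherits(config, "bg_network_config"))
  x <- unclass(config)
  if (!is.null(sim)) {
    x$duration <- sim$duration
    x$dt <- sim$dt
    x$record_stride <- sim$record_stride
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Load and validate a configuration file
#'
#' YAML (or JSON) configuration; unknown keys are rejected, ranges are
#' validated, and defaults fill the remainder (in particular
#' `dt = 0.025 ms`).
#'
#' @param path config file.
#' @return list with `config` (a `bg_network_config`) and `sim`
#'   (a `bg_sim_spec`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- yaml::read_yaml(path)
  bad <- setdiff(names(x), config_fields())
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "))
  }
  sizes <- intersect(names(x), c("n_py", "n_d1", "n_d2", "n_da", "n_stn",
                                 "n_gpe", "n_gpi", "n_th"))
  for (f in sizes) {
    if (!is.numeric(x[[f]]) || x[[f]] < 1) {
      stop("config field ", f, " must be a positive count")
    }
  }
  if (!is.null(x$dopamine_depletion) &&
      (x$dopamine_depletion < 0 || x$dopamine_depletion > 1)) {
    stop("config field dopamine_depletion must lie in [0, 1]")
  }
  if (!is.null(x$ns) && (x$ns < 0 || x$ns > 32)) {
    stop("config field ns must lie in [0, 32]")
  }
  if (!is.null(x$nd) && (x$nd < 0 || x$nd > 32)) {
    stop("config field nd must lie in [0, 32]")
  }
  cfg_args <- x[intersect(names(x), setdiff(config_fields(),
                                            c("duration", "dt",
                                              "record_stride")))]
  cfg <- do.call(network_config, cfg_args)
  sim <- sim_spec(
    duration = if (is.null(x$duration)) 2000 else x$duration,
    dt = if (is.null(x$dt)) 0.025 else x$dt,
    record_stride = if (is.null(x$record_stride)) 10L
                    else as.integer(x$record_stride))
  list(config = cfg, sim = sim)
}

#' Write spike times as plain text
#'
#' One line per spike: `population id time_ms`.
#'
#' @param rec a `bg_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(rec, path) {
  sp <- rec$spikes
  writeLines(sprintf("%s %d %.3f", sp$population, sp$id, sp$time), path)
  invisible(path)
}

#' Write a sweep table as CSV (deterministic formatting)
#'
#' @param tbl a tibble from one of the sweep drivers.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write an MSN lesion record as JSON
#'
#' Serialises the lesion state of a morphology: spine/dendrite counts and
#' fractions, ordering, and the explicit removed-id lists.
#'
#' @param morph an `msn_morphology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lesion_json <- function(morph, path) {
  l <- morph$lesion
  rec <- list(
    receptor_type = morph$receptor_type,
    ns = l$ns, spine_loss_fraction = l$ns / 32,
    nd = l$nd, degeneration_fraction = l$nd / 32,
    spine_order = l$spine_order,
    removed_spine_sites = l$removed_spine_sites,
    removed_sections = l$removed_sections)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
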