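#' Network configuration
#'
#' Population sizes, connection weight table, dopamine depletion fraction
#' and the MSN lesion specification for a cortico-basal-ganglia-thalamic
#' network. Defaults use ten cells per nucleus, eight dopaminergic cells
#' and one detailed multi-compartment MSN per striatal pathway (D1 direct,
#' D2 indirect), matching the single-MSN lesion analyses.
#'
#' Weights are dimensionless multipliers on the per-class maximal synaptic
#' conductances (see [synapse_params()]); they are the free parameters that
#' stand in for the unavailable published weight table and are calibrated
#' once to reproduce the healthy-state firing phenotypes.
#'
#' @param n_py,n_d1,n_d2,n_da,n_stn,n_gpe,n_gpi,n_th population sizes.
#' @param seed wiring RNG seed.
#' @param dopamine_depletion fraction of dopaminergic neurons removed, in
#'   `[0, 1]`; more than 0.5 defines the parkinsonian (PD) state.
#' @param ns,nd,spine_order MSN lesion specification applied to every MSN
#'   (see [remove_spines()], [degrade_dendrites()]).
#' @param weights named list of connection weights; see defaults in source.
#' @param bias named list of constant bias currents per population
#'   (uA/cm2): `i_appth`, `i_appgpe` (enters the GPe balance equation with
#'   the printed minus sign), `i_appgpi`, `i_appcor`, `i_appda`.
#' @return list of class `bg_network_config`.
#' @export
network_config <- function(n_py = 10, n_d1 = 1, n_d2 = 1, n_da = 8,
                           n_stn = 10, n_gpe = 10, n_gpi = 10, n_th = 10,
                           seed = 1L, dopamine_depletion = 0,
                           ns = 0L, nd = 0L, spine_order = "type1_first",
                           weights = list(), bias = list()) {
  sizes <- c(n_py = n_py, n_d1 = n_d1, n_d2 = n_d2, n_da = n_da,
             n_stn = n_stn, n_gpe = n_gpe, n_gpi = n_gpi, n_th = n_th)
  if (any(sizes < 1)) stop("all population sizes must be >= 1")
  if (dopamine_depletion < 0 || dopamine_depletion > 1) {
    stop("dopamine_depletion must be in [0, 1]")
  }
  w <- default_weights()
  bad <- setdiff(names(weights), names(w))
  if (length(bad)) stop("unknown weight(s): ", paste(bad, collapse = ", "))
  w[names(weights)] <- weights
  b <- default_bias()
  bad <- setdiff(names(bias), names(b))
  if (length(bad)) stop("unknown bias value(s): ", paste(bad, collapse = ", "))
  b[names(bias)] <- bias
  structure(
    list(n_py = n_py, n_d1 = n_d1, n_d2 = n_d2, n_da = n_da, n_stn = n_stn,
         n_gpe = n_gpe, n_gpi = n_gpi, n_th = n_th,
         seed = as.integer(seed), dopamine_depletion = dopamine_depletion,
         ns = as.integer(ns), nd = as.integer(nd), spine_order = spine_order,
         weights = w, bias = b),
    class = "bg_network_config"
  )
}

default_weights <- function() {
  list(
    w_th_py = 0.05,
    w_py_d1_ampa = 1, w_py_d1_nmda = 0.2,
    w_py_d2_ampa = 2.5, w_py_d2_nmda = 0.5,
    w_da_d1 = 0.3, w_da_d2 = 0.75,
    w_py_stn = 0.15, w_gpe_stn = 2,
    w_d2_gpe = 40, w_stn_gpe = 2, w_gpe_gpe = 0.25,
    w_d1_gpi = 20, w_gpe_gpi = 3, w_stn_gpi = 2, w_gpi_gpi = 0.1,
    w_gpi_th = 2.5
  )
}

default_bias <- function() {
  list(i_appth = 0.4, i_appstn = 0, i_appgpe = -1, i_appgpi = 1,
       i_appcor = 1.0, i_appda = 0, i_appmsn = 0)
}

#' Build the network wiring
#'
#' Constructs the deterministic-given-seed edge list realising the circuit
#' contract: every D1/D2 synapse site receives cortical glutamatergic and
#' dopaminergic input (all-to-one); each STN cell receives 3 cortical
#' excitatory and 2 neighbouring GPe inhibitory inputs; each GPe receives 2
#' neighbouring GPe, every D2 (inhibitory) and 2 STN inputs; each GPi
#' receives every D1, 2 random GPe, 2 random STN and 1 neighbouring GPi;
#' each TH receives 3 random GPi inputs; 6 randomly selected cortical cells
#' receive thalamic feedback.
#'
#' @param config a [network_config()].
#' @return object of class `bg_network`: the config, a `wiring` tibble
#'   (`pre_pop`, `pre_id`, `post_pop`, `post_id`, `post_comp`, `class`,
#'   `weight`), the two MSN morphologies, and the removed-DA-cell set.
#' @export
build_network <- function(config = network_config()) {
  stopifnot(inherits(config, "bg_network_config"))
  rng <- local_rng(config$seed)
  w <- config$weights
  need <- function(cond, msg) if (!cond) stop("configuration error: ", msg)
  need(config$n_py >= 3, "STN needs >= 3 cortical cells")
  need(config$n_gpe >= 2, "STN/GPi need >= 2 GPe cells")
  need(config$n_stn >= 2, "GPe/GPi need >= 2 STN cells")
  need(config$n_gpi >= 3, "TH needs >= 3 GPi cells")
  need(config$n_py >= 6, "thalamic feedback targets 6 cortical cells")

  edges <- list()
  add <- function(pre_pop, pre_id, post_pop, post_id, class, weight,
                  post_comp = NA_integer_) {
    edges[[length(edges) + 1L]] <<- tibble::tibble(
      pre_pop = pre_pop, pre_id = as.integer(pre_id),
      post_pop = post_pop, post_id = as.integer(post_id),
      post_comp = as.integer(post_comp), class = class, weight = weight)
  }
  ring <- function(i, n, off) ((i - 1 + off) %% n) + 1

  # morphologies (intact; lesions applied after depletion marking)
  msn <- list()
  for (d1 in seq_len(config$n_d1)) msn[[paste0("d1_", d1)]] <-
    build_morphology("d1", seed = config$seed + d1)
  for (d2 in seq_len(config$n_d2)) msn[[paste0("d2_", d2)]] <-
    build_morphology("d2", seed = config$seed + 100L + d2)

  # cortex / DA -> MSN synapse sites (all-to-one across sites)
  for (nm in names(msn)) {
    m <- msn[[nm]]
    pop <- if (m$receptor_type == "d1") "d1" else "d2"
    idx <- as.integer(sub(".*_", "", nm))
    sites <- m$comps[m$comps$glut_site, c("id", "site_index")]
    for (r in seq_len(nrow(sites))) {
      j <- sites$site_index[r]
      py_src <- ((j - 1) %% config$n_py) + 1
      w_ampa <- if (pop == "d1") w$w_py_d1_ampa else w$w_py_d2_ampa
      w_nmda <- if (pop == "d1") w$w_py_d1_nmda else w$w_py_d2_nmda
      add("py", py_src, pop, idx, "ampa", w_ampa, sites$id[r])
      add("py", py_src, pop, idx, "nmda", w_nmda, sites$id[r])
      # every dopaminergic cell contacts every site (all-to-one), so the
      # dopamine envelope at a surviving site scales with the surviving
      # cell count under depletion
      for (da_src in seq_len(config$n_da)) {
        if (pop == "d1") {
          add("da", da_src, pop, idx, "da_exc", w$w_da_d1 / config$n_da,
              sites$id[r])
        } else {
          add("da", da_src, pop, idx, "da_inh", w$w_da_d2 / config$n_da,
              sites$id[r])
        }
      }
    }
  }

  # STN <- 3 PY (exc), 2 neighbouring GPe (inh)
  for (i in seq_len(config$n_stn)) {
    src <- sample_seeded(seq_len(config$n_py), rng)[1:3]
    for (s in src) add("py", s, "stn", i, "ampa", w$w_py_stn)
    add("gpe", ring(i, config$n_gpe, -1), "stn", i, "gaba", w$w_gpe_stn)
    add("gpe", ring(i, config$n_gpe, +1), "stn", i, "gaba", w$w_gpe_stn)
  }
  # GPe <- 2 neighbouring GPe, all D2, 2 STN
  for (i in seq_len(config$n_gpe)) {
    add("gpe", ring(i, config$n_gpe, -1), "gpe", i, "gaba", w$w_gpe_gpe)
    add("gpe", ring(i, config$n_gpe, +1), "gpe", i, "gaba", w$w_gpe_gpe)
    for (d2 in seq_len(config$n_d2)) {
      add("d2", d2, "gpe", i, "gaba", w$w_d2_gpe)
    }
    add("stn", ring(i, config$n_stn, 0), "gpe", i, "ampa", w$w_stn_gpe)
    add("stn", ring(i, config$n_stn, +1), "gpe", i, "ampa", w$w_stn_gpe)
  }
  # GPi <- all D1, 2 random GPe, 2 random STN, 1 neighbouring GPi
  for (i in seq_len(config$n_gpi)) {
    for (d1 in seq_len(config$n_d1)) {
      add("d1", d1, "gpi", i, "gaba", w$w_d1_gpi)
    }
    src <- sample_seeded(seq_len(config$n_gpe), rng)[1:2]
    for (s in src) add("gpe", s, "gpi", i, "gaba", w$w_gpe_gpi)
    src <- sample_seeded(seq_len(config$n_stn), rng)[1:2]
    for (s in src) add("stn", s, "gpi", i, "ampa", w$w_stn_gpi)
    add("gpi", ring(i, config$n_gpi, +1), "gpi", i, "gaba", w$w_gpi_gpi)
  }
  # TH <- 3 random GPi
  for (i in seq_len(config$n_th)) {
    src <- sample_seeded(seq_len(config$n_gpi), rng)[1:3]
    for (s in src) add("gpi", s, "th", i, "gaba", w$w_gpi_th)
  }
  # 6 random PY <- TH (one random TH source each)
  fed <- sample_seeded(seq_len(config$n_py), rng)[1:6]
  for (p in fed) {
    src <- sample_seeded(seq_len(config$n_th), rng)[1]
    add("th", src, "py", p, "ampa", w$w_th_py)
  }

  net <- structure(
    list(config = config, wiring = dplyr::bind_rows(edges), msn = msn,
         removed_da = integer(), is_pd = FALSE),
    class = "bg_network"
  )
  # depletion + lesions per config
  net <- apply_dopamine_depletion(net, config$dopamine_depletion,
                                  seed = config$seed)
  net <- apply_msn_lesions(net, ns = config$ns, nd = config$nd,
                           order = config$spine_order, seed = config$seed)
  net
}

#' @export
print.bg_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<bg_network> PY %d | D1 %d | D2 %d | DA %d (-%d) | STN %d | GPe %d | GPi %d | TH %d\n",
    cfg$n_py, cfg$n_d1, cfg$n_d2, cfg$n_da, length(x$removed_da),
    cfg$n_stn, cfg$n_gpe, cfg$n_gpi, cfg$n_th))
  cat(sprintf("  %d edges; depletion %.1f%%%s; lesion Ns=%d Nd=%d\n",
              nrow(x$wiring), 100 * cfg$dopamine_depletion,
              if (x$is_pd) " [PD state]" else "", cfg$ns, cfg$nd))
  invisible(x)
}

#' Apply dopamine depletion to a network
#'
#' Removes `ceiling(fraction * n_da)` dopaminergic neurons (all their
#' synapses are silenced, so the dopamine envelope at every synapse site
#' scales down with the surviving cell count) and marks
#' `ceiling(32 * fraction)` dopaminergic sites on every MSN as lost,
#' defining the type-1 spine set used by the spine-removal ordering. The
#' network is in the PD state when the fraction exceeds 0.5.
#'
#' @param net a `bg_network`.
#' @param fraction depletion fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @return the modified network (`is_pd` flag updated).
#' @export
apply_dopamine_depletion <- function(net, fraction, seed = net$config$seed) {
  stopifnot(inherits(net, "bg_network"), fraction >= 0, fraction <= 1)
  cfg <- net$config
  n_remove <- ceiling(fraction * cfg$n_da)
  rng <- local_rng(seed + 7L)
  removed <- if (n_remove > 0) {
    sort(sample_seeded(seq_len(cfg$n_da), rng)[seq_len(n_remove)])
  } else integer()
  n_sites_lost <- ceiling(32 * fraction)
  for (nm in names(net$msn)) {
    m <- net$msn[[nm]]
    comps <- m$comps
    comps$da_lost <- FALSE
    sites <- which(comps$da_site)
    if (n_sites_lost > 0) {
      lost <- sample_seeded(sites, rng)[seq_len(min(n_sites_lost,
                                                    length(sites)))]
      comps$da_lost[lost] <- TRUE
    }
    m$comps <- comps
    net$msn[[nm]] <- m
  }
  # silence every synapse of the removed dopaminergic cells
  wiring <- net$wiring
  drop <- wiring$pre_pop == "da" & wiring$pre_id %in% removed
  net$wiring <- wiring[!drop, ]
  net$removed_da <- removed
  net$is_pd <- fraction > 0.5
  net$config$dopamine_depletion <- fraction
  net
}

# apply spine/dendrite lesions to every MSN and prune affected edges
apply_msn_lesions <- function(net, ns = 0, nd = 0, order = "type1_first",
                              seed = net$config$seed) {
  if (ns == 0 && nd == 0) return(net)
  wiring <- net$wiring
  for (nm in names(net$msn)) {
    m <- net$msn[[nm]]
    if (nd > 0) m <- degrade_dendrites(m, nd, seed = seed)
    if (ns > 0) m <- remove_spines(m, ns, order = order, seed = seed)
    net$msn[[nm]] <- m
    pop <- m$receptor_type
    idx <- as.integer(sub(".*_", "", nm))
    onto <- wiring$post_pop == pop & wiring$post_id == idx &
      !is.na(wiring$post_comp)
    # glutamatergic edges onto removed spines
    removed_sites <- m$comps$id[m$comps$glut_removed]
    drop <- onto & wiring$class %in% c("ampa", "nmda") &
      wiring$post_comp %in% removed_sites
    # any synapse onto a detached compartment
    drop <- drop | (onto & !(wiring$post_comp %in% m$comps$id))
    wiring <- wiring[!drop, ]
  }
  net$wiring <- wiring
  net$config$ns <- as.integer(ns)
  net$config$nd <- as.integer(nd)
  net
}

#' In-degree table of a wiring
#'
#' Tabulates, for every postsynaptic neuron, its in-degree from each
#' presynaptic population (synapse-site contacts onto one MSN count once
#' per presynaptic cell).
#'
#' @param wiring a wiring tibble (or a `bg_network`).
#' @return tibble `post_pop`, `post_id`, `pre_pop`, `indegree`.
#' @export
count_in_degrees <- function(wiring) {
  if (inherits(wiring, "bg_network")) wiring <- wiring$wiring
  if (!nrow(wiring)) {
    return(tibble::tibble(post_pop = character(), post_id = integer(),
                          pre_pop = character(), indegree = integer()))
  }
  dplyr::summarise(
    dplyr::group_by(wiring, post_pop, post_id, pre_pop),
    indegree = dplyr::n_distinct(pre_id),
    .groups = "drop"
  )
}

#' Lesion a single MSN inside a built network
#'
#' Applies spine removal and/or dendrite degeneration to one MSN and prunes
#' every synaptic edge whose target spine or compartment no longer exists.
#'
#' @param net a `bg_network`.
#' @param which MSN name, e.g. `"d1_1"`.
#' @param ns,nd lesion sizes (cumulative targets; 0 leaves the operator out).
#' @param sections optional explicit section set for
#'   [degrade_dendrites()].
#' @param order spine-removal ordering.
#' @param seed RNG seed.
#' @return the modified network.
#' @export
lesion_msn <- function(net, which = "d1_1", ns = 0, nd = 0, sections = NULL,
                       order = "type1_first", seed = net$config$seed) {
  stopifnot(inherits(net, "bg_network"), which %in% names(net$msn))
  m <- net$msn[[which]]
  if (nd > 0 || !is.null(sections)) {
    if (is.null(sections)) {
      m <- degrade_dendrites(m, nd, seed = seed)
    } else {
      m <- degrade_dendrites(m, nd, seed = seed, sections = sections)
    }
  }
  if (ns > 0) m <- remove_spines(m, ns, order = order, seed = seed)
  net$msn[[which]] <- m
  pop <- m$receptor_type
  idx <- as.integer(sub(".*_", "", which))
  wiring <- net$wiring
  onto <- wiring$post_pop == pop & wiring$post_id == idx &
    !is.na(wiring$post_comp)
  removed_sites <- m$comps$id[m$comps$glut_removed]
  drop <- onto & wiring$class %in% c("ampa", "nmda") &
    wiring$post_comp %in% removed_sites
  drop <- drop | (onto & !(wiring$post_comp %in% m$comps$id))
  net$wiring <- wiring[!drop, ]
  net
}
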