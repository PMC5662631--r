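#' Build the stylized MSN morphology
#'
#' Constructs the intact 121-compartment medium spiny neuron tree: one soma
#' with 8 primary trunks (26 primary dendrite sections in chains of 3-4),
#' each trunk branching into 2 secondary sections, each secondary bearing 1
#' subordinate section (32 secondary + subordinate sections; 58 dendrite
#' sections in total). Thirty-two paired glutamatergic/dopaminergic synapse
#' sites sit on subordinate compartments; main dendrites carry no spines.
#'
#' The compartment-per-section mapping (2 per section, with the first 4
#' subordinate sections carrying 3) is a documented modelling choice that
#' realises all published counts simultaneously.
#'
#' @param receptor_type `"d1"` or `"d2"`, the dopamine receptor class of
#'   this MSN.
#' @param seed integer; the intact build is deterministic, the seed is
#'   recorded for downstream lesion operators.
#' @return an object of class `msn_morphology`: list with a `comps` tibble
#'   (`id`, `parent`, `level`, `section`, `length`, `diam`, `v`,
#'   `glut_site`, `da_site`, `da_lost`, `glut_removed`, `site_index`),
#'   the receptor type and an empty lesion record.
#' @examples
#' m <- build_morphology("d1")
#' nrow(m$comps)             # 121
#' n_dendrite_sections(m)    # 58
#' @export
build_morphology <- function(receptor_type = c("d1", "d2"), seed = 1L) {
  receptor_type <- match.arg(receptor_type)
  p <- msn_params()
  rows <- list()
  nid <- 1L
  rows[[1]] <- list(id = 1L, parent = NA_integer_, level = "soma",
                    section = 0L, length = p$soma_diam, diam = p$soma_diam)
  section_id <- 0L
  trunk_primary <- c(4L, 4L, rep(3L, 6))  # 26 primary sections over 8 trunks
  sub_extra <- 0L                          # subordinate sections built so far
  for (trunk in 1:8) {
    parent <- 1L
    # chain of primary sections, 2 compartments each
    for (ps in seq_len(trunk_primary[trunk])) {
      section_id <- section_id + 1L
      for (ci in 1:2) {
        nid <- nid + 1L
        rows[[nid]] <- list(id = nid, parent = parent, level = "primary",
                            section = section_id, length = p$primary_len,
                            diam = p$primary_diam)
        parent <- nid
      }
    }
    trunk_end <- parent
    # two secondary sections per trunk, each with one subordinate child
    for (sb in 1:2) {
      parent <- trunk_end
      section_id <- section_id + 1L
      for (ci in 1:2) {
        nid <- nid + 1L
        rows[[nid]] <- list(id = nid, parent = parent, level = "secondary",
                            section = section_id, length = p$secondary_len,
                            diam = p$secondary_diam)
        parent <- nid
      }
      sub_extra <- sub_extra + 1L
      ncomp_sub <- if (sub_extra <= 4L) 3L else 2L
      section_id <- section_id + 1L
      for (ci in seq_len(ncomp_sub)) {
        nid <- nid + 1L
        rows[[nid]] <- list(id = nid, parent = parent, level = "subordinate",
                            section = section_id, length = p$subordinate_len,
                            diam = p$subordinate_diam)
        parent <- nid
      }
    }
  }
  comps <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  comps$v <- ifelse(comps$level == "soma", -85, -85)
  comps$glut_site <- FALSE
  comps$da_site <- FALSE
  comps$da_lost <- FALSE
  comps$glut_removed <- FALSE
  comps$site_index <- NA_integer_
  # synapse sites: the two distal compartments of every subordinate section
  sub <- comps[comps$level == "subordinate", ]
  site_ids <- unlist(lapply(split(sub$id, sub$section), function(ids) {
    utils::tail(sort(ids), 2)
  }), use.names = FALSE)
  site_ids <- sort(site_ids)
  comps$glut_site[match(site_ids, comps$id)] <- TRUE
  comps$da_site[match(site_ids, comps$id)] <- TRUE
  comps$site_index[match(site_ids, comps$id)] <- seq_along(site_ids)
  structure(
    list(comps = comps, receptor_type = receptor_type, seed = as.integer(seed),
         lesion = list(ns = 0L, nd = 0L, spine_order = "type1_first",
                       removed_spine_sites = integer(),
                       removed_sections = integer(),
                       detached = tibble::tibble())),
    class = "msn_morphology"
  )
}

#' @export
print.msn_morphology <- function(x, ...) {
  cat(sprintf(
    "<msn_morphology> %s: %d compartments, %d dendrite sections, %d glut / %d DA sites\n",
    toupper(x$receptor_type), nrow(x$comps), n_dendrite_sections(x),
    sum(x$comps$glut_site & !x$comps$glut_removed), sum(x$comps$da_site)))
  if (x$lesion$ns > 0 || x$lesion$nd > 0) {
    cat(sprintf("  lesion: Ns = %d (%.1f%%), Nd = %d (%.1f%%)\n",
                x$lesion$ns, 100 * x$lesion$ns / 32,
                x$lesion$nd, 100 * x$lesion$nd / 32))
  }
  invisible(x)
}

#' Count dendrite sections in a morphology
#' @param morph an `msn_morphology`.
#' @return integer number of (attached) dendrite sections.
#' @export
n_dendrite_sections <- function(morph) {
  length(unique(morph$comps$section[morph$comps$level != "soma"]))
}

#' Summary counts of an MSN morphology
#'
#' @param morph an `msn_morphology`.
#' @return one-row tibble: compartments, dendrite sections, soma children,
#'   secondary+subordinate sections, glutamatergic and dopaminergic sites.
#' @export
morphology_counts <- function(morph) {
  comps <- morph$comps
  tibble::tibble(
    n_compartments = nrow(comps),
    n_dendrites = n_dendrite_sections(morph),
    n_soma_children = sum(comps$parent == 1L, na.rm = TRUE),
    n_sec_sub = length(unique(
      comps$section[comps$level %in% c("secondary", "subordinate")])),
    n_glut_sites = sum(comps$glut_site & !comps$glut_removed),
    n_da_sites = sum(comps$da_site)
  )
}

# axial coupling table: one row per parent-child edge with the coefficient
# converting a millivolt difference into a density current (uA/cm2) on
# each side. coef_child applies to the child compartment, coef_parent to
# the parent.
msn_couplings <- function(morph, params = msn_params()) {
  comps <- morph$comps
  area <- compartment_area(comps, params)    # cm2, aligned with comps rows
  kids <- comps[!is.na(comps$parent), ]
  if (!nrow(kids)) {
    return(tibble::tibble(parent = integer(), child = integer(),
                          coef_parent = numeric(), coef_child = numeric(),
                          r_axial = numeric()))
  }
  half_r <- function(len_um, diam_um) {
    len <- len_um * 1e-4; rad <- diam_um / 2 * 1e-4
    (params$ra / 2) * len / (pi * rad^2)     # Ohm
  }
  pr <- match(kids$parent, comps$id)
  ch <- match(kids$id, comps$id)
  r_ax <- half_r(comps$length[pr], comps$diam[pr]) +
    half_r(kids$length, kids$diam)
  tibble::tibble(
    parent = kids$parent, child = kids$id,
    r_axial = r_ax,
    coef_parent = 1e3 / (r_ax * area[pr]),
    coef_child = 1e3 / (r_ax * area[ch])
  )
}

compartment_area <- function(comps, params = msn_params()) {
  ifelse(comps$level == "soma",
         pi * (comps$diam * 1e-4)^2,                       # sphere
         pi * (comps$diam * 1e-4) * (comps$length * 1e-4)) # cylinder side
}

#' Rall-cable interchange current into one compartment
#'
#' Sum over attached neighbours of `(V_j - V_i) / R_ji`, converted to a
#' surface-density current for compartment `i`. Antisymmetric per edge up
#' to the area normalisation of each side.
#'
#' @param morph an `msn_morphology` whose `comps$v` holds the voltages.
#' @param i compartment id.
#' @param params [msn_params()].
#' @return coupling current (uA/cm2, inward positive).
#' @export
cable_coupling_current <- function(morph, i, params = msn_params()) {
  comps <- morph$comps
  if (!i %in% comps$id) stop("compartment ", i, " is detached or unknown")
  cp <- msn_couplings(morph, params)
  vi <- comps$v[match(i, comps$id)]
  cur <- 0
  up <- cp[cp$child == i, ]
  if (nrow(up)) {
    vp <- comps$v[match(up$parent, comps$id)]
    cur <- cur + sum(up$coef_child * (vp - vi))
  }
  dn <- cp[cp$parent == i, ]
  if (nrow(dn)) {
    vc <- comps$v[match(dn$child, comps$id)]
    cur <- cur + sum(dn$coef_parent * (vc - vi))
  }
  cur
}

#' Remove glutamatergic synapse sites (dendritic spine loss)
#'
#' Removes `ns` of the 32 glutamatergic sites. Under the
#' `"type1_first"` ordering, sites whose paired dopaminergic synapse has
#' been lost to dopamine depletion (type-1 sites) are removed before intact
#' (type-2) sites; within each class the order is uniform at the seed.
#' The dendritic topology is unchanged; the spine-loss fraction is `ns/32`.
#'
#' @param morph an `msn_morphology`.
#' @param ns number of spines to remove, 0-32 (cumulative target count).
#' @param order `"type1_first"` or `"random"`.
#' @param seed integer RNG seed for tie-breaking.
#' @return the lesioned `msn_morphology`.
#' @export
remove_spines <- function(morph, ns, order = c("type1_first", "random"),
                          seed = morph$seed) {
  order <- match.arg(order)
  if (!is.numeric(ns) || length(ns) != 1 || is.na(ns) || ns < 0 || ns > 32) {
    stop("ns must be a single integer in [0, 32]")
  }
  ns <- as.integer(ns)
  comps <- morph$comps
  active <- which(comps$glut_site & !comps$glut_removed)
  n_take <- ns - morph$lesion$ns
  if (n_take < 0) stop("morphology already has more than ", ns,
                       " spines removed")
  if (n_take > length(active)) n_take <- length(active)
  if (n_take > 0) {
    rng <- local_rng(seed + 1000L * ns)
    type1 <- active[comps$da_lost[active]]
    type2 <- active[!comps$da_lost[active]]
    ordering <- if (order == "type1_first") {
      c(sample_seeded(type1, rng), sample_seeded(type2, rng))
    } else {
      sample_seeded(active, rng)
    }
    take <- ordering[seq_len(n_take)]
    comps$glut_removed[take] <- TRUE
    morph$lesion$removed_spine_sites <-
      c(morph$lesion$removed_spine_sites, comps$id[take])
  }
  morph$comps <- comps
  morph$lesion$ns <- ns
  morph$lesion$spine_order <- order
  morph
}

#' Disconnect dendrite sections (dendritic tree degeneration)
#'
#' Severs secondary/subordinate dendrite sections from their parent until
#' `nd` sections have been detached; every detached subtree (including any
#' synapse sites on it) is deleted from the morphology. Targets are chosen
#' uniformly at the seed among attached sections whose subtree fits the
#' remaining budget, so the final count is exactly `nd`. The degeneration
#' fraction is `nd/32`.
#'
#' @param morph an `msn_morphology`.
#' @param nd number of secondary/subordinate sections to remove, 0-32
#'   (cumulative target count).
#' @param seed integer RNG seed.
#' @param sections optional explicit section ids to sever (their subtrees
#'   count toward `nd`); used for controlled distal-versus-proximal
#'   comparisons.
#' @return the lesioned `msn_morphology` (detached compartments are kept in
#'   `lesion$detached` for accounting).
#' @export
degrade_dendrites <- function(morph, nd, seed = morph$seed,
                              sections = NULL) {
  if (!is.numeric(nd) || length(nd) != 1 || is.na(nd) || nd < 0 || nd > 32) {
    stop("nd must be a single integer in [0, 32]")
  }
  nd <- as.integer(nd)
  budget <- nd - morph$lesion$nd
  if (budget < 0) stop("morphology already has more than ", nd,
                       " dendrites removed")
  rng <- local_rng(seed + 77L * nd)
  comps <- morph$comps
  detached_all <- morph$lesion$detached
  removed_secs <- morph$lesion$removed_sections
  forced <- sections
  while (budget > 0) {
    cand <- comps[comps$level %in% c("secondary", "subordinate"), ]
    secs <- unique(cand$section)
    if (!is.null(forced)) {
      secs <- intersect(forced, secs)
      if (!length(secs)) break
    }
    # subtree section count per candidate section
    sizes <- vapply(secs, function(s) {
      length(section_subtree(comps, s))
    }, integer(1))
    ok <- secs[sizes <= budget]
    if (!length(ok)) break
    pick <- sample_seeded(ok, rng)[1]
    subtree_secs <- section_subtree(comps, pick)
    drop_rows <- comps$section %in% subtree_secs
    detached_all <- dplyr::bind_rows(detached_all, comps[drop_rows, ])
    comps <- comps[!drop_rows, ]
    removed_secs <- c(removed_secs, subtree_secs)
    budget <- budget - length(subtree_secs)
  }
  morph$comps <- comps
  morph$lesion$nd <- nd
  morph$lesion$removed_sections <- removed_secs
  morph$lesion$detached <- detached_all
  morph
}

# all sections in the subtree rooted at section `s` (inclusive)
section_subtree <- function(comps, s) {
  ids <- comps$id[comps$section == s]
  out <- s
  repeat {
    kids <- comps$section[!is.na(comps$parent) & comps$parent %in% ids &
                            !(comps$section %in% out)]
    if (!length(kids)) break
    out <- c(out, unique(kids))
    ids <- comps$id[comps$section %in% out]
  }
  sort(unique(out))
}

#' Mark dopaminergic synapse sites lost to dopamine depletion
#'
#' Deactivates `ceiling(32 * fraction)` dopaminergic sites (uniform at the
#' seed), defining the type-1 spine set used by [remove_spines()].
#'
#' @param morph an `msn_morphology`.
#' @param fraction dopamine depletion fraction in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return the updated morphology.
#' @export
deplete_da_sites <- function(morph, fraction, seed = morph$seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  comps <- morph$comps
  comps$da_lost <- FALSE
  n_lost <- ceiling(32 * fraction)
  sites <- which(comps$da_site)
  if (n_lost > 0 && length(sites)) {
    rng <- local_rng(seed + 13L)
    take <- sample_seeded(sites, rng)[seq_len(min(n_lost, length(sites)))]
    comps$da_lost[take] <- TRUE
  }
  morph$comps <- comps
  morph
}

# seed-local RNG helpers: avoid touching the global .Random.seed stream
local_rng <- function(seed) {
  env <- new.env()
  env$seed <- as.integer(seed %% .Machine$integer.max)
  env
}

sample_seeded <- function(x, rng) {
  if (length(x) <= 1) return(x)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }, add = TRUE)
  set.seed(rng$seed)
  rng$seed <- (rng$seed * 69069 + 1) %% .Machine$integer.max
  x[sample.int(length(x))]
}
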