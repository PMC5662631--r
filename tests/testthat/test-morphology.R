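# MSN morphology: published counts, cable coupling, lesion operators and
# their invariants.

test_that("intact morphology realises all published counts", {
  for (seed in c(1, 5, 99)) {
    m <- build_morphology("d1", seed = seed)
    cts <- morphology_counts(m)
    expect_equal(cts$n_compartments, 121)
    expect_equal(cts$n_dendrites, 58)
    expect_equal(cts$n_soma_children, 8)
    expect_equal(cts$n_sec_sub, 32)
    expect_equal(cts$n_glut_sites, 32)
    expect_equal(cts$n_da_sites, 32)
  }
})

test_that("synapse sites sit on subordinate compartments only", {
  m <- build_morphology("d2")
  sites <- m$comps[m$comps$glut_site | m$comps$da_site, ]
  expect_true(all(sites$level == "subordinate"))
  expect_setequal(sites$site_index, 1:32)
})

test_that("the compartment graph is a tree rooted at the soma", {
  m <- build_morphology()
  comps <- m$comps
  expect_equal(sum(is.na(comps$parent)), 1)
  expect_equal(comps$level[is.na(comps$parent)], "soma")
  # connected: every compartment reaches the soma by parent links
  for (i in comps$id) {
    j <- i; steps <- 0
    while (!is.na(comps$parent[match(j, comps$id)])) {
      j <- comps$parent[match(j, comps$id)]
      steps <- steps + 1
      expect_lt(steps, 125)
    }
    expect_equal(j, 1L)
  }
})

test_that("coupling current vanishes at uniform potential and conserves charge", {
  m <- build_morphology()
  for (i in c(1, 2, 60, 121)) {
    expect_equal(cable_coupling_current(m, i), 0, tolerance = 1e-9)
  }
  # two-compartment check: current into child equals -(current into parent)
  # after area re-scaling (antisymmetry of the axial flux)
  m$comps$v[m$comps$id == 2] <- -50
  cp <- msn_couplings(m)
  edge <- cp[cp$child == 2, ]
  dv <- m$comps$v[m$comps$id == edge$parent] - (-50)
  flux_child <- edge$coef_child * dv        # density into the child
  flux_parent <- -edge$coef_parent * dv     # density into the parent
  area <- bgnetsim:::compartment_area(m$comps)
  a_par <- area[match(edge$parent, m$comps$id)]
  a_ch <- area[match(2, m$comps$id)]
  expect_equal(flux_child * a_ch, -flux_parent * a_par, tolerance = 1e-12)
  expect_error(cable_coupling_current(m, 999), "detached or unknown")
})

test_that("the soma couples to exactly eight compartments", {
  m <- build_morphology()
  cp <- msn_couplings(m)
  expect_equal(sum(cp$parent == 1), 8)
})

test_that("spine removal: identity at 0, fraction ns/32, silences all sites at 32", {
  m <- build_morphology()
  m0 <- remove_spines(m, 0)
  expect_equal(morphology_counts(m0)$n_glut_sites, 32)
  m16 <- remove_spines(m, 16)
  expect_equal(m16$lesion$ns / 32, 0.5)
  expect_equal(morphology_counts(m16)$n_glut_sites, 16)
  m32 <- remove_spines(m, 32)
  expect_equal(morphology_counts(m32)$n_glut_sites, 0)
  expect_error(remove_spines(m, 40), "0, 32")
})

test_that("type-1-first ordering removes dopamine-lost sites before intact ones", {
  m <- deplete_da_sites(build_morphology(), fraction = 0.25, seed = 3)
  n_type1 <- sum(m$comps$da_lost)
  expect_equal(n_type1, ceiling(32 * 0.25))
  m_les <- remove_spines(m, n_type1, order = "type1_first")
  removed <- m_les$comps$glut_removed
  expect_true(all(which(removed) %in% which(m$comps$da_lost)))
})

test_that("dendrite degeneration removes exact counts and keeps a valid tree", {
  m <- build_morphology()
  m10 <- degrade_dendrites(m, 10, seed = 2)
  expect_equal(m10$lesion$nd / 32, 0.3125)
  expect_equal(n_dendrite_sections(m10), 58 - 10)
  # compartment conservation
  expect_equal(nrow(m10$comps) + nrow(m10$lesion$detached), 121)
  # remaining graph still a tree rooted at soma
  comps <- m10$comps
  expect_true(all(stats::na.omit(comps$parent) %in% comps$id))
  m32 <- degrade_dendrites(m, 32, seed = 2)
  expect_true(all(m32$comps$level %in% c("soma", "primary")))
  expect_equal(morphology_counts(m32)$n_glut_sites, 0)
  expect_equal(morphology_counts(m32)$n_da_sites, 0)
  expect_error(degrade_dendrites(m, -1), "0, 32")
})

test_that("cumulative degeneration matches a single larger lesion in counts", {
  for (seed in 1:5) {
    m <- build_morphology(seed = seed)
    a <- 6; b <- 14
    two_step <- degrade_dendrites(degrade_dendrites(m, a, seed = seed),
                                  b, seed = seed)
    one_step <- degrade_dendrites(m, b, seed = seed)
    expect_equal(n_dendrite_sections(two_step), 58 - b)
    expect_equal(n_dendrite_sections(one_step), 58 - b)
  }
})

test_that("lesion operators are deterministic given the seed", {
  m <- build_morphology()
  a <- degrade_dendrites(m, 8, seed = 11)
  b <- degrade_dendrites(m, 8, seed = 11)
  expect_identical(a$lesion$removed_sections, b$lesion$removed_sections)
  s1 <- remove_spines(deplete_da_sites(m, 0.5, seed = 4), 10, seed = 9)
  s2 <- remove_spines(deplete_da_sites(m, 0.5, seed = 4), 10, seed = 9)
  expect_identical(s1$lesion$removed_spine_sites,
                   s2$lesion$removed_spine_sites)
})

test_that("MSN soma right-hand side balances ionic and coupling currents", {
  m <- build_morphology()
  r <- msn_soma_rhs(m, i_syn = 0)
  expect_true(is.finite(r$dv))
  # uniform potential: coupling contribution must vanish
  expect_equal(r$i_couple, 0, tolerance = 1e-9)
  # injecting current depolarizes: dv increases with i_ext
  r2 <- msn_soma_rhs(m, i_ext = 50)
  expect_gt(r2$dv, r$dv)
})
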