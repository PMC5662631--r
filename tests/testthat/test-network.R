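# Population wiring contracts, dopamine depletion semantics and
# reproducibility.

indeg <- function(net, post, pre) {
  d <- count_in_degrees(net)
  d$indegree[d$post_pop == post & d$pre_pop == pre]
}

test_that("wiring realises the published in-degree contract for every seed", {
  for (seed in seq_len(20)) {
    net <- tiny_network(seed = seed)
    expect_true(all(indeg(net, "stn", "py") == 3), label = paste("seed", seed))
    expect_true(all(indeg(net, "stn", "gpe") == 2))
    expect_true(all(indeg(net, "th", "gpi") == 3))
    expect_true(all(indeg(net, "gpi", "gpe") == 2))
    expect_true(all(indeg(net, "gpi", "stn") == 2))
    expect_true(all(indeg(net, "gpi", "gpi") == 1))
    expect_true(all(indeg(net, "gpe", "gpe") == 2))
    # exactly six cortical cells receive thalamic feedback
    w <- net$wiring
    expect_equal(length(unique(w$post_id[w$post_pop == "py" &
                                           w$pre_pop == "th"])), 6)
    # striatal cells see every cortical and every dopaminergic cell
    expect_true(all(indeg(net, "d1", "py") == net$config$n_py))
    expect_true(all(indeg(net, "d1", "da") == net$config$n_da))
    expect_true(all(indeg(net, "d2", "da") == net$config$n_da))
  }
})

test_that("wiring is reproducible for a fixed seed and differs across seeds", {
  a <- tiny_network(seed = 4)$wiring
  b <- tiny_network(seed = 4)$wiring
  expect_identical(a, b)
  c <- tiny_network(seed = 5)$wiring
  expect_false(identical(a, c))
})

test_that("count_in_degrees of an empty wiring is empty", {
  d <- count_in_degrees(tibble::tibble(pre_pop = character(),
                                       pre_id = integer(),
                                       post_pop = character(),
                                       post_id = integer(),
                                       post_comp = integer(),
                                       class = character(),
                                       weight = numeric()))
  expect_equal(nrow(d), 0)
})

test_that("population sizes too small for the contract are rejected", {
  expect_error(build_network(network_config(n_py = 2)), "configuration error")
  expect_error(build_network(network_config(n_gpi = 2)), "configuration error")
  expect_error(network_config(n_th = 0), "population sizes")
  expect_error(network_config(dopamine_depletion = 1.2), "\\[0, 1\\]")
})

test_that("dopamine depletion removes cells, marks sites, sets the PD flag", {
  net <- tiny_network(seed = 2)
  n0 <- apply_dopamine_depletion(net, 0)
  expect_identical(n0$wiring, net$wiring)
  expect_false(n0$is_pd)

  n50 <- apply_dopamine_depletion(net, 0.5)
  expect_false(n50$is_pd)
  expect_length(n50$removed_da, ceiling(0.5 * net$config$n_da))
  expect_equal(sum(n50$msn$d1_1$comps$da_lost), 16)

  n51 <- apply_dopamine_depletion(net, 0.51)
  expect_true(n51$is_pd)

  n100 <- apply_dopamine_depletion(net, 1)
  expect_equal(sum(n100$wiring$pre_pop == "da"), 0)
})

test_that("active dopaminergic synapse count scales with the surviving cells", {
  net <- tiny_network(seed = 6)
  n_da <- net$config$n_da
  n_sites <- 32 * 2   # two MSNs, 32 sites each, every site x every DA cell
  for (f in c(0, 0.25, 0.5, 1)) {
    nf <- apply_dopamine_depletion(net, f)
    surv <- n_da - ceiling(f * n_da)
    expect_equal(sum(nf$wiring$pre_pop == "da"), n_sites * surv)
  }
})

test_that("network-level lesions prune glutamatergic contacts onto removed spines", {
  cfg <- network_config(ns = 16, seed = 3)
  net <- build_network(cfg)
  glut <- net$wiring[net$wiring$class %in% c("ampa", "nmda") &
                       net$wiring$post_pop %in% c("d1", "d2"), ]
  # 16 surviving sites per MSN, one AMPA + one NMDA contact each
  expect_equal(nrow(glut), 2 * 16 * 2)
  cfg2 <- network_config(nd = 32, seed = 3)
  net2 <- build_network(cfg2)
  onto_msn <- net2$wiring[net2$wiring$post_pop %in% c("d1", "d2"), ]
  expect_equal(nrow(onto_msn), 0)
})

test_that("lesion_msn targets one MSN and leaves the other intact", {
  net <- tiny_network(seed = 8)
  out <- lesion_msn(net, "d1_1", nd = 8)
  expect_equal(n_dendrite_sections(out$msn$d1_1), 50)
  expect_equal(n_dendrite_sections(out$msn$d2_1), 58)
  d1_glut <- out$wiring[out$wiring$post_pop == "d1" &
                          out$wiring$class == "ampa", ]
  expect_true(all(d1_glut$post_comp %in% out$msn$d1_1$comps$id))
})
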