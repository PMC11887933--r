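cfg <- display_config()
clock <- simulation_clock()

condition_graph <- function(cn, offset = "right", config = cfg) {
  spec <- make_condition_spec(cn, offset)
  field <- evolve(oriented_response(render(spec, config)), clock)
  list(spec = spec,
       bg = build_graph(accumulate(field, clock$offset_ms)))
}

test_that("an empty map yields an empty graph", {
  r <- oriented_response(blank_image(cfg))
  bg <- build_graph(r)
  expect_identical(nrow(bg$nodes), 0L)
  expect_equal(igraph::vcount(bg$graph), 0)
})

test_that("collinear bars bridge at 0.2 deg gaps but not across 1.25 deg gaps", {
  two_bars <- function(gap_deg) {
    img <- blank_image(cfg)
    img <- uncrowdr:::draw_vline(img, 0, -2 - gap_deg / 2, -gap_deg / 2,
                                 0.06, 0.25, "a")
    img <- uncrowdr:::draw_vline(img, 0, gap_deg / 2, 2 + gap_deg / 2,
                                 0.06, 0.25, "b")
    build_graph(oriented_response(img))
  }
  expect_identical(max(graph_components(two_bars(0.2))), 1L)
  expect_identical(max(graph_components(two_bars(0.6))), 1L)
  expect_gt(max(graph_components(two_bars(1.25))), 1L)
})

test_that("bipole_params enforces the constrained interval", {
  expect_error(bipole_params(max_bridge_deg = 0))
  p <- bipole_params()
  expect_gt(p$max_bridge_deg, 0.4)  # spans flanker spacing
  expect_lt(p$max_bridge_deg, 1.25) # cannot bridge the gap
})

test_that("grouping links require matching orientation", {
  # a vertical and a horizontal bar, collinear along y, 0.3 deg apart:
  # no grouping link may join them (channels differ), so two components
  bars <- list(list(channel = "vertical", row = -20, col = 0, len_px = 12),
               list(channel = "horizontal", row = -5, col = -5, len_px = 11))
  bg <- build_graph(synthetic_channel_map(bars))
  expect_identical(max(graph_components(bg)), 2L)
  # every long-range edge is a grouping link
  long_range <- igraph::E(bg$graph)$weight > 0.15
  expect_true(all(igraph::E(bg$graph)$type[long_range] == "grouping"))
})

test_that("build_graph components equal the breadth-first connectivity oracle", {
  set.seed(42)
  n_mismatch <- 0L
  for (rep in 1:50) {
    bg <- build_graph(synthetic_channel_map(random_bar_layout()))
    if (nrow(bg$nodes) == 0) next
    got <- graph_components(bg)
    want <- oracle_connectivity(bg$nodes, bg$ppd)
    # same partition: cross-tabulation is a permutation matrix
    tab <- table(got, want)
    ok <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
    if (!ok) n_mismatch <- n_mismatch + 1L
  }
  expect_identical(n_mismatch, 0L)
})

test_that("EQUAL_FLANKERS groups vernier and flankers via terminator links", {
  g <- condition_graph("EQUAL_FLANKERS")
  comp <- graph_components(g$bg)
  cls <- classify_nodes(g$bg, g$spec)
  expect_identical(max(comp), 1L)
  expect_gt(sum(cls == "vernier"), 0)
  expect_gt(sum(cls == "flanker"), 0)
})

test_that("LONG leaves the vernier in its own component", {
  g <- condition_graph("LONG")
  comp <- graph_components(g$bg)
  cls <- classify_nodes(g$bg, g$spec)
  expect_length(intersect(comp[cls == "vernier"], comp[cls == "flanker"]), 0)
})

test_that("Pacman nodes never join the line components", {
  for (cn in c("GAPPED_INWARD", "GAPPED_OUTWARD", "LONG_INWARD")) {
    g <- condition_graph(cn)
    comp <- graph_components(g$bg)
    cls <- classify_nodes(g$bg, g$spec)
    expect_gt(sum(cls == "pacman"), 0)
    expect_length(intersect(comp[cls == "pacman"],
                            comp[cls != "pacman"]), 0)
  }
})

test_that("place_selection covers flanker tops and spares the vernier", {
  spec <- make_condition_spec("LONG", "right")
  sig <- place_selection(spec)
  expect_equal(sig$centers[, "x_deg"], c(-0.8, 0.8))
  expect_equal(sig$centers[, "y_deg"], c(-4.25, -4.25))
  g <- condition_graph("LONG")
  seeds <- seed_nodes(g$bg, sig)
  cls <- classify_nodes(g$bg, g$spec)
  expect_identical(sum(cls[seeds] == "vernier"), 0L)
  # every flanker line's top segment contributes at least one seed
  nd <- g$bg$nodes
  for (x in c(-1.2, -0.8, -0.4, 0.4, 0.8, 1.2)) {
    top <- which(abs(nd$x_deg - x) <= 0.05 & nd$y_deg < -2.15)
    expect_gt(sum(top %in% seeds), 0, label = paste("flanker at", x))
  }
  # no selection without flankers
  empty <- place_selection(make_condition_spec("VERNIER_ONLY", "right"))
  expect_null(empty$centers)
})

test_that("GAPPED selection disks cover only top-segment flanker nodes", {
  g <- condition_graph("GAPPED")
  seeds <- seed_nodes(g$bg, place_selection(g$spec))
  expect_gt(length(seeds), 0)
  expect_true(all(g$bg$nodes$y_deg[seeds] < -1.0))
})

test_that("spread is monotone and equals the geodesic ball oracle", {
  g <- condition_graph("LONG")
  st <- spread(g$bg, place_selection(g$spec), clock)
  l160 <- layer_at(st, 160)
  l220 <- layer_at(st, 220)
  l300 <- layer_at(st, 300)
  expect_true(all(l220 >= l160))
  expect_true(all(l300 >= l220))
  expect_true(all(layer_at(st, 300) %in% c(0L, 1L)))  # exactly one layer each
  # oracle: igraph-independent shortest paths via synchronous edge
  # relaxation to a fixpoint (per-node min aggregation each round)
  el <- igraph::as_edgelist(g$bg$graph)
  w <- igraph::E(g$bg$graph)$weight
  dist <- rep(Inf, nrow(g$bg$nodes))
  dist[st$seeds] <- 0
  idx <- c(el[, 1], el[, 2])
  reached <- 0L
  repeat {
    cand <- c(dist[el[, 2]] + w, dist[el[, 1]] + w)
    agg <- tapply(cand, idx, min)
    newd <- dist
    ids <- as.integer(names(agg))
    newd[ids] <- pmin(newd[ids], agg)
    if (identical(newd, dist)) break
    dist <- newd
    reached <- reached + 1L
    if (reached > length(dist)) stop("relaxation failed to converge")
  }
  for (t in c(160, 200, 260)) {
    expect_identical(layer_at(st, t), as.integer(dist <= 0.1 * (t - 140)),
                     label = paste("ball at", t))
  }
})

test_that("empty seeds leave every node in layer 0 forever", {
  g <- condition_graph("VERNIER_ONLY")
  st <- spread(g$bg, place_selection(g$spec), clock)
  expect_true(all(layer_at(st, clock$end_ms) == 0L))
  # disabled spread behaves identically even with flankers present
  g2 <- condition_graph("LONG")
  st2 <- spread(g2$bg, place_selection(g2$spec), clock, enabled = FALSE)
  expect_true(all(layer_at(st2, clock$end_ms) == 0L))
})

test_that("LONG spread completes within the ~100 ms landmark", {
  g <- condition_graph("LONG")
  st <- spread(g$bg, place_selection(g$spec), clock)
  cls <- classify_nodes(g$bg, g$spec)
  rt <- st$recruit_time_ms[cls == "flanker"]
  expect_true(all(is.finite(rt)))
  completion <- max(rt) - clock$offset_ms
  expect_lte(completion, 100)
  expect_gte(completion, 50)
})

test_that("condition-level layer fractions match the model's account", {
  for (cn in c("LONG", "GAPPED", "GAPPED_INWARD", "GAPPED_OUTWARD")) {
    g <- condition_graph(cn)
    st <- spread(g$bg, place_selection(g$spec), clock)
    near <- layer1_fraction(g$bg, st, g$spec, "flanker",
                            y_range = c(-1.9, 1.9))
    if (cn == "LONG") {
      expect_gte(near, 0.9)
      expect_gte(layer1_fraction(g$bg, st, g$spec, "flanker"), 0.9)
    } else {
      expect_lte(near, 0.1)
    }
    expect_lte(layer1_fraction(g$bg, st, g$spec, "vernier"), 0.1)
  }
  # GAPPED middle segments stay layer 0 at every reported time
  g <- condition_graph("GAPPED")
  st <- spread(g$bg, place_selection(g$spec), clock)
  mid <- classify_nodes(g$bg, g$spec) == "flanker" &
    abs(g$bg$nodes$y_deg) < 0.9
  for (t in seq(140, 300, by = 20)) {
    expect_true(all(layer_at(st, t)[mid] == 0L), label = paste("t =", t))
  }
})

test_that("layer_table exports one row per node per time", {
  g <- condition_graph("VERNIER_ONLY")
  st <- spread(g$bg, place_selection(g$spec), clock)
  tab <- layer_table(g$bg, st, times = c(160, 300))
  expect_identical(nrow(tab), 2L * nrow(g$bg$nodes))
  expect_true(all(tab$layer == 0L))
})
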