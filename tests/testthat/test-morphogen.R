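# Dendrite growth, populations, fixtures and SWC round trips.

test_that("a single target yields a straight two-node segment", {
  tr <- grow_dendrite(c(0, 0, 0), matrix(c(30, 40, 0), 1), reach = 100,
                      balancing_factor = 0.7)
  expect_equal(nrow(tr$nodes), 2L)
  expect_equal(tr$nodes$parent, c(-1L, 1L))
  expect_equal(morph_total_length(tr), 50)
})

test_that("growth with zero balancing factor reproduces the exact minimum spanning tree", {
  skip_if_not_installed("igraph")
  withr::with_seed(31, {
    for (rep in 1:4) {
      pts <- matrix(runif(30, -80, 80), ncol = 3)  # 10 targets
      tr <- grow_dendrite(c(0, 0, 0), pts, reach = Inf, balancing_factor = 0)
      all_pts <- rbind(c(0, 0, 0), pts)
      d <- as.matrix(dist(all_pts))
      g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
      mst_len <- sum(igraph::E(igraph::mst(g))$weight)
      expect_equal(morph_total_length(tr), mst_len, tolerance = 1e-10)
    }
  })
})

test_that("targets beyond reach are dropped with a warning, down to a degenerate tree", {
  far <- matrix(c(500, 0, 0), 1)
  expect_warning(tr <- grow_dendrite(c(0, 0, 0), far, reach = 100), "beyond reach")
  expect_equal(nrow(tr$nodes), 1L)
  near_far <- rbind(c(50, 0, 0), c(500, 0, 0))
  expect_warning(tr2 <- grow_dendrite(c(0, 0, 0), near_far, reach = 100), "1 target")
  expect_equal(nrow(tr2$nodes), 2L)
})

test_that("ball-and-stick geometry is as specified", {
  bs <- ball_and_stick(100, 0, soma_pos = c(0, 0, -50))
  expect_equal(nrow(bs$nodes), 2L)  # soma + basal only
  bs2 <- ball_and_stick(120, 280)
  expect_equal(morph_total_length(bs2), 400)
  expect_setequal(bs2$nodes$type, c(1L, 3L, 4L))
})

test_that("SWC files round-trip and foreign id orderings are reindexed", {
  tr <- make_fixture("swc5")
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(tr, path)
  back <- read_swc(path)
  expect_equal(as.data.frame(back$nodes), as.data.frame(tr$nodes))

  # 3-node toy file: parses to two parent-child segments
  toy <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# toy", "1 1 0 0 0 5 -1", "2 3 0 0 -30 1 1", "3 4 0 0 40 1 1"), toy)
  t3 <- read_swc(toy)
  expect_equal(sum(t3$nodes$parent > 0), 2L)
  expect_equal(morph_total_length(t3), 70)

  # unsorted, non-contiguous ids: accepted after topological reindexing
  scr <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("12 3 0 0 -30 1 7", "7 1 0 0 0 5 -1", "30 4 0 0 40 1 7",
               "31 4 0 0 90 0.5 30"), scr)
  ts <- read_swc(scr)
  expect_equal(ts$nodes$id, 1:4)
  expect_true(all(ts$nodes$parent < ts$nodes$id))  # parents precede children
  expect_equal(morph_total_length(ts), 30 + 40 + 50)

  # malformed input reports the offending line
  bad <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 0 0"), bad)
  expect_error(read_swc(bad), "line 2")
})

test_that("populations have uniform soma depths and stay inside their cylinders", {
  geom <- column_geometry()
  pop <- generate_population(geom, n_pyr = 6, n_int = 12, seed = 21)
  expect_length(generate_population(geom, 0, 0, seed = 1), 0L)

  sz <- vapply(pop, function(tr) tr$meta$soma[3], numeric(1))
  ks <- stats::ks.test(sz, "punif", -250, 0)
  expect_gt(ks$p.value, 0.01)

  for (tr in pop) {
    nd <- tr$nodes
    expect_true(all(nd$parent < nd$id))          # acyclic, topological order
    expect_equal(sum(nd$parent == -1L), 1L)      # single root
    expect_true(all(nd$radius > 0))
    r_xy <- sqrt(nd$x^2 + nd$y^2)
    expect_true(all(r_xy <= geom$radius + 1e-6))
    if (tr$cell_type == "int") {
      expect_true(all(nd$z >= geom$lower[1] - 1e-6 & nd$z <= geom$lower[2] + 1e-6))
    } else {
      in_lower <- nd$z >= geom$lower[1] - 1e-6 & nd$z <= geom$lower[2] + 1e-6
      in_upper <- nd$z >= geom$upper[1] - 1e-6 & nd$z <= geom$upper[2] + 1e-6
      expect_true(all(in_lower | in_upper))
    }
  }
})

test_that("increasing cylinder separation lengthens apical paths monotonically", {
  mean_path <- function(d) {
    pop <- generate_population(column_geometry(cylinder_distance = d),
                               n_pyr = 3, n_int = 0, seed = 5)
    mean(vapply(pop, lfpproxy:::mean_apical_path, numeric(1)))
  }
  paths <- vapply(c(50, 250, 450), mean_path, numeric(1))
  expect_true(all(diff(paths) > 0))
})

test_that("the membrane depth profile is bimodal and reproducible", {
  pop <- generate_population(n_pyr = 4, n_int = 0, seed = 3)
  prof <- surface_depth_profile(pop)
  expect_identical(prof, surface_depth_profile(generate_population(
    n_pyr = 4, n_int = 0, seed = 3)))
  # substantial membrane in each cylinder
  frac_up <- sum(prof$area[prof$z > 0]) / sum(prof$area)
  expect_gt(frac_up, 0.2)
  expect_lt(frac_up, 0.8)
})
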